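test_that("relative risk is the ratio of stratum frequencies", {
  asg <- risk_fixture(10, 3, 100, 10)
  r <- region_entry_risk(asg, source = 1L, region = 9L, sex = "male",
                         age_group = "50-59", baseline = "cluster0")
  expect_equal(r$absolute_risk, 0.3)
  expect_equal(r$baseline_risk, 0.1)
  expect_equal(r$rr, 3.0)
  expect_true(r$ci[1] < 3 && 3 < r$ci[2])
})

test_that("a self-baseline gives RR = 1 exactly", {
  asg <- risk_fixture(10, 3, 100, 10)
  r <- region_entry_risk(asg, source = 0L, region = 9L, sex = "male",
                         age_group = "50-59", baseline = "cluster0",
                         baseline_cluster = 0L)
  expect_identical(r$rr, 1)
})

test_that("zero baseline events flag the estimate instead of dividing", {
  asg <- risk_fixture(10, 3, 50, 0)
  r <- region_entry_risk(asg, source = 1L, region = 9L, sex = "male",
                         age_group = "50-59", baseline = "cluster0")
  expect_true(r$undefined)
  expect_true(is.na(r$rr))
})

test_that("patient-years without full follow-up and no event are excluded", {
  # one-year patients cannot be followed over a 1-year horizon unless the
  # event occurs
  one_year <- toy_assignments(list(x1 = 1L, x2 = 1L))
  asg <- rbind(risk_fixture(10, 3, 100, 10), one_year)
  r <- region_entry_risk(asg, source = 1L, region = 9L, sex = "male",
                         age_group = "50-59", baseline = "cluster0")
  expect_equal(r$exposed_n, 10L)  # the two unfollowed years do not count
})

test_that("Katz interval endpoints agree with a bootstrap on a synthetic stratum", {
  asg <- risk_fixture(400, 48, 2000, 100)
  r <- region_entry_risk(asg, source = 1L, region = 9L, sex = "male",
                         age_group = "50-59", baseline = "cluster0")
  set.seed(1)
  b1 <- rbinom(10000, 400, 48 / 400) / 400
  b0 <- rbinom(10000, 2000, 100 / 2000) / 2000
  boot <- quantile(b1 / b0, c(0.025, 0.975))
  expect_equal(r$rr, (48 / 400) / (100 / 2000))
  expect_lt(abs(r$ci[1] - boot[[1]]) / boot[[1]], 0.10)
  expect_lt(abs(r$ci[2] - boot[[2]]) / boot[[2]], 0.10)
})

test_that("progredient patients are those found outside (or in the region) after 3 years", {
  asg <- toy_assignments(list(
    a = c(2L, 2L, 2L, 9L),   # in set 2003, in region 2006 -> progredient
    b = c(2L, 2L, 2L, 2L),   # still inside -> stable
    c = c(2L, 3L),           # censored before 2006 -> excluded
    d = c(2L, 2L, 2L, 5L)))  # left the set but not into the region
  ps <- progredient_split(asg, cluster_set = c(2L, 3L), region = 9L)
  expect_equal(ps$progredient, "a")
  expect_equal(ps$stable, "b")
  ps2 <- progredient_split(asg, cluster_set = c(2L, 3L))
  expect_setequal(ps2$progredient, c("a", "d"))
  expect_equal(ps2$stable, "b")
})

test_that("Fisher p-values match the closed-form example and both oracles", {
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 7, 3, 7), 1)
  set.seed(6)
  for (i in 1:200) {
    t <- matrix(rpois(4, sample(1:8, 1)), 2)
    p <- fisher_exact_2x2(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
    expect_equal(p, stats::fisher.test(t)$p.value, tolerance = 1e-12)
    expect_equal(p, brute_fisher(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                 tolerance = 1e-12)
  }
})

test_that("comorbidity comparison builds the right tables and adjusts p-values", {
  presence <- data.table(patient_id = paste0("p", 1:5), item = "J44")
  out <- compare_comorbidities(paste0("p", 1:5), paste0("q", 1:5), presence)
  expect_equal(out$p, 2 / 252, tolerance = 1e-12)
  expect_equal(out$n_prog, 5L)
  expect_equal(out$n_stable, 0L)
  # identical prevalence in both groups: p = 1
  pres2 <- data.table(patient_id = c("p1", "q1"), item = "E66")
  out2 <- compare_comorbidities(c("p1", "p2"), c("q1", "q2"), pres2)
  expect_equal(out2$p, 1)
  # Bonferroni over the tested item count, capped at 1
  items <- sprintf("B%03d", 1:131)
  pres3 <- data.table(patient_id = paste0("p", 1:5), item = "B001")
  out3 <- compare_comorbidities(paste0("p", 1:5), paste0("q", 1:5), pres3,
                                items = items)
  expect_equal(out3$p_adjusted, pmin(1, out3$p * 131))
  expect_true(all(out3$p_adjusted >= out3$p))
  expect_true(all(out3[item != "B001", degenerate]))
  expect_error(compare_comorbidities(c("p1"), c("p1"), pres3), "disjoint",
               class = "mmtraj_config_error")
})

test_that("planted sex differences in transition rates are detected and sex-specific clusters skipped", {
  mk <- function(prefix, n, e, sex) {
    seqs <- lapply(seq_len(n), function(i) if (i <= e) c(1L, 2L) else c(1L, 1L))
    names(seqs) <- paste0(prefix, seq_len(n))
    toy_assignments(seqs, sex = sex)
  }
  asg <- rbind(mk("m", 5000, 250, "male"),     # 5% rate
               mk("f", 5000, 750, "female"),   # 15% rate: planted 3x excess
               toy_assignments(list(w = c(7L, 8L, 8L)), sex = "female"))
  net <- estimate_transition_rates(asg)
  gb <- gender_biased_transitions(net, min_at_risk = 100)
  top <- gb[1]
  expect_equal(top$from, 1L)
  expect_equal(top$to, 2L)
  expect_true(top$significant)
  expect_gt(top$female_rate / top$male_rate, 2)
  # cluster 7 exists only in the female layer: skipped, counted
  expect_gte(attr(gb, "skipped"), 1L)
  expect_equal(nrow(gb[from == 7]), 0L)
})

test_that("equal male and female counts are not reported as biased", {
  mk <- function(prefix, sex) {
    seqs <- lapply(1:200, function(i) if (i <= 20) c(1L, 2L) else c(1L, 1L))
    names(seqs) <- paste0(prefix, 1:200)
    toy_assignments(seqs, sex = sex)
  }
  net <- estimate_transition_rates(rbind(mk("m", "male"), mk("f", "female")))
  gb <- gender_biased_transitions(net, min_at_risk = 100)
  expect_equal(gb[from == 1 & to == 2, p], 1)
  expect_false(any(gb$significant))
})

test_that("presence tables list the blocks set at each reference year", {
  st <- toy_stays(
    toy_stay("p", "male", "50-54", "2004-03-01", codes = c("I10", "E11")),
    toy_stay("p", "male", "50-54", "2008-03-01", codes = "J44"))
  hs <- build_health_states(st, "p", cohort_spec(), default_block_table())
  ref <- data.table(patient_id = "p", ref_year = 2006L)
  pres <- presence_at_reference(hs, ref)
  blocks <- default_block_table()
  expect_setequal(pres$item, map_code_to_block(c("I10", "E11"), blocks))
})
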