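# hand-made multilayer net for simulator-facing tests
toy_net <- function(trans, events, clusters) {
  structure(list(trans = trans, events = events, clusters = clusters),
            class = "multilayer_net")
}

test_that("transition rates are at-risk frequencies per stratum", {
  seqs <- c(lapply(1:3, function(i) c(1L, 2L)),   # k -> j
            lapply(4:10, function(i) c(1L, 1L)))  # k -> k
  names(seqs) <- paste0("p", 1:10)
  asg <- toy_assignments(seqs)
  net <- estimate_transition_rates(asg)
  e <- net$trans[from == 1 & to == 2]
  expect_equal(e$n, 3L)
  # 10 uncensored source patient-years in cluster 1 (the first years); the
  # 7 stayers' final years are censored by the window end and enter the
  # at-risk denominator through the censor rate
  expect_equal(e$rate_uncensored, 0.3)
  expect_equal(net$trans[from == 1 & to == 1, rate_uncensored], 0.7)
  ev <- net$events[from == 1]
  expect_equal(ev$at_risk, 17L)
  expect_equal(ev$n_censor, 7L)
  expect_equal(e$rate, 3 / 17)
})

test_that("rows with no at-risk patient-years stay undefined rather than zero", {
  asg <- rbind(toy_assignments(list(m = c(1L, 1L)), sex = "male"),
               toy_assignments(list(f = c(5L, 5L)), sex = "female"))
  net <- estimate_transition_rates(asg)
  expect_equal(nrow(net$events[sex == "male" & from == 5]), 0L)
  expect_equal(nrow(net$events[sex == "female" & from == 5]), 1L)
  expect_true(all(is.finite(net$trans$rate)))
})

test_that("death is attributed to the source year and terminal rows are not at risk", {
  asg <- toy_assignments(list(p = c(1L, 1L, 2L)))
  deaths <- data.table(patient_id = "p", death_year = 2005L)
  net <- estimate_transition_rates(asg, deaths)
  # 2003 -> step to 1; 2004 -> death (2005 is the death year); 2005 excluded
  expect_equal(net$events[from == 1, at_risk], 2L)
  expect_equal(net$events[from == 1, n_death], 1L)
  expect_equal(nrow(net$events[from == 2]), 0L)
  expect_equal(net$trans[from == 1 & to == 1, n], 1L)
})

test_that("rates plus death and censor rates are row-stochastic", {
  reg <- generate_registry(registry_config(n_patients = 2000, seed = 31))
  net <- estimate_transition_rates(ground_truth_assignments(reg),
                                   ground_truth_deaths(reg))
  sums <- net$trans[, .(s = sum(rate)), by = .(sex, age_group, from)]
  ev <- merge(net$events, sums, by = c("sex", "age_group", "from"), all.x = TRUE)
  ev[is.na(s), s := 0]
  expect_lt(max(abs(ev$s + ev$death_rate + ev$censor_rate - 1)), 1e-9)
  expect_true(all(net$trans$rate >= 0))
})

test_that("non-consecutive years are rejected", {
  asg <- toy_assignments(list(p = c(1L, 2L)))
  asg$year <- c(2003L, 2005L)
  expect_error(estimate_transition_rates(asg), "consecutive",
               class = "mmtraj_data_error")
})

test_that("the robustness filter drops weak or thin links and nothing else", {
  seqs <- c(lapply(1:4, function(i) c(1L, 2L)),
            lapply(5:1000, function(i) c(1L, 1L)))
  names(seqs) <- paste0("p", seq_along(seqs))
  net <- estimate_transition_rates(toy_assignments(seqs))
  # q(1->2) = 4/1000 = 0.004 < 0.5%: removed at the printed default
  kept <- robustness_filter(net, min_count = 1)
  expect_equal(nrow(kept[from == 1 & to == 2]), 0L)
  # identity at zero thresholds
  expect_equal(nrow(robustness_filter(net, 0, 0)), nrow(net$trans))
  # strong rate but thin count: removed by the count rule
  seqs2 <- lapply(1:5, function(i) c(3L, 4L))
  names(seqs2) <- paste0("q", 1:5)
  net2 <- estimate_transition_rates(toy_assignments(seqs2))
  expect_equal(nrow(robustness_filter(net2, 0.005, 100)), 0L)
  expect_equal(nrow(robustness_filter(net2, 0.005, 5)), 1L)
})

test_that("collapsing layers pools counts and recomputes rates", {
  asg <- rbind(
    toy_assignments(c(lapply(1:3, function(i) c(1L, 2L)),
                      lapply(4:10, function(i) c(1L, 1L))) |>
                      setNames(paste0("m", 1:10)), sex = "male"),
    toy_assignments(c(lapply(1, function(i) c(1L, 2L)),
                      lapply(2:10, function(i) c(1L, 1L))) |>
                      setNames(paste0("f", 1:10)), sex = "female", age0 = 70L))
  net <- estimate_transition_rates(asg)
  coll <- collapse_layers(net)
  e <- coll$trans[from == 1 & to == 2]
  expect_equal(e$n, 4L)
  expect_equal(e$rate_uncensored, 4 / 20)  # 3/10 and 1/10 pooled
  # single layer collapses to itself
  one <- estimate_transition_rates(toy_assignments(list(p = c(1L, 2L))))
  cone <- collapse_layers(one)
  expect_equal(cone$trans$n, one$trans$n)
  expect_equal(cone$trans$rate, one$trans$rate)
  # collapsed counts equal a brute-force recount from raw assignments
  dt <- data.table::as.data.table(asg)
  data.table::setorder(dt, patient_id, year)
  dt[, nxt := data.table::shift(cluster, -1L), by = patient_id]
  recount <- dt[!is.na(nxt), .N, by = .(from = cluster, to = nxt)]
  m <- merge(coll$trans[, .(from, to, n)], recount,
             by = c("from", "to"), all = TRUE)
  expect_equal(m$n, m$N)
})

test_that("sink states have no outgoing inter-cluster flow", {
  # terminal cluster of a chain is a sink even when its only outflow is death
  asg <- toy_assignments(list(a = c(1L, 2L, 3L, 3L), b = c(1L, 3L, 3L, 3L)))
  deaths <- data.table(patient_id = "a", death_year = 2006L)
  net <- estimate_transition_rates(asg, deaths)
  expect_equal(find_sink_states(collapse_layers(net)), 3L)
  # fully connected toy network: no sinks
  full <- toy_net(
    trans = data.table(sex = "all", age_group = "all",
                       from = c(1L, 2L), to = c(2L, 1L),
                       n = c(5L, 5L), rate = 0.5),
    events = data.table(sex = "all", age_group = "all", from = c(1L, 2L),
                        at_risk = 10L, n_death = 0L, n_censor = 0L),
    clusters = c(1L, 2L))
  expect_equal(find_sink_states(full), integer())
})

test_that("acyclicity holds on fitted models and cycles are reported explicitly", {
  reg <- generate_registry(registry_config(n_patients = 1000, seed = 8))
  spec <- cohort_spec()
  hs <- build_health_states(reg$stays, select_washout_cohort(reg$stays, spec),
                            spec, reg$blocks)
  model <- suppressWarnings(fit_divclus(hs, 6))
  net <- estimate_transition_rates(assign_states(hs, model), hs$deaths)
  expect_true(acyclicity_check(net)$pass)
  # injected back-transition: explicit 2-cycle
  bad <- rbind(net$trans,
               data.table(sex = "male", age_group = "50-59",
                          from = max(net$trans$to), to = min(net$trans$from),
                          n = 1L, rate = 0.01, rate_uncensored = 0.01,
                          age_sum = 50), fill = TRUE)
  chk <- acyclicity_check(bad)
  expect_false(chk$pass)
  expect_gte(length(chk$cycle), 2L)
  # single cluster: trivially acyclic
  expect_true(acyclicity_check(data.table(from = 1L, to = 1L))$pass)
})

test_that("mortality bands label elderly clusters and leave gaps unlabelled", {
  prof <- data.table(cluster = 0:4,
                     mortality = c(0.0025, 0.05, 0.015, 0.0025, 0.005),
                     mean_age = c(72, 70, 68, 40, 60))
  lab <- label_mortality_regions(prof)
  expect_equal(lab$region, c("low", "high", "unlabelled", "unlabelled",
                             "medium"))
  expect_error(label_mortality_regions(prof,
                                       bands = list(a = c(0, 0.01),
                                                    b = c(0.005, 0.02))),
               "disjoint", class = "mmtraj_config_error")
})

test_that("region entries credit the cluster occupied the year before", {
  asg <- toy_assignments(list(a = c(0L, 7L, 42L, 42L), b = c(0L, 0L, 7L, 42L),
                              c = c(42L, 42L, 42L, 42L), d = c(0L, 0L, 0L, 0L)))
  r <- rank_entry_clusters(asg, region = 42L)
  expect_equal(r$cluster, 7L)
  expect_equal(r$n_entries, 2L)  # a and b, once each; c starts inside
  expect_equal(nrow(rank_entry_clusters(asg, region = 99L)), 0L)
})

test_that("a generator that routes region entries through one state ranks it first", {
  gt <- chain3_ground_truth(p_entry = 0.003, p_step = 0.12, hazard_ratio = 25)
  reg <- generate_registry(registry_config(n_patients = 4000, seed = 19,
                                           n_latent_states = 3,
                                           frac_healthy = 0,
                                           ground_truth = gt))
  asg <- ground_truth_assignments(reg)
  r <- rank_entry_clusters(asg, region = 3L)
  expect_equal(r$cluster[1], 2L)
  expect_gt(r[cluster == 2, n_entries] / sum(r$n_entries), 0.7)
})

test_that("collapsed networks export to GraphML and edge lists", {
  asg <- toy_assignments(list(a = c(1L, 2L, 2L), b = c(1L, 1L, 2L)))
  net <- collapse_layers(estimate_transition_rates(asg))
  g <- withr::local_tempfile(fileext = ".graphml")
  e <- withr::local_tempfile(fileext = ".csv")
  export_network(net, graphml = g, edgelist = e)
  gg <- igraph::read_graph(g, format = "graphml")
  expect_equal(sort(igraph::V(gg)$name), c("1", "2"))
  expect_equal(igraph::ecount(gg), 1L)
  expect_equal(nrow(data.table::fread(e)), nrow(net$trans))
})
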