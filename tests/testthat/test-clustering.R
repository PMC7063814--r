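test_that("best split on the two-group example gains the full inertia", {
  m <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  s <- best_binary_split(m)
  expect_true(s$variable %in% 1:2)
  expect_equal(s$gain, 2.0)
  expect_equal(s$inertia, 2.0)
  expect_equal(best_binary_split(matrix(1, 4, 3))$variable, NA_integer_)
  expect_equal(best_binary_split(matrix(1, 4, 3))$gain, 0)
})

test_that("chosen split variable equals the brute-force argmax", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(rbinom(6 * 4, 1, 0.5), nrow = 6)
    s <- best_binary_split(m)
    g <- brute_gains(m)
    if (is.na(s$variable)) {
      expect_true(!any(is.finite(g)) || max(g) <= 1e-12)
    } else {
      cand <- which(g >= max(g) - 1e-12)
      expect_equal(s$variable, cand[1])
      expect_equal(s$gain, max(g), tolerance = 1e-10)
    }
  }
})

test_that("duplicate weighting reproduces the expanded computation", {
  set.seed(5)
  u <- matrix(rbinom(5 * 4, 1, 0.4), nrow = 5)
  w <- c(3, 1, 4, 2, 2)
  expanded <- u[rep(seq_len(5), w), ]
  s1 <- best_binary_split(u, weights = w)
  s2 <- best_binary_split(expanded)
  expect_equal(s1$variable, s2$variable)
  expect_equal(s1$gain, s2$gain, tolerance = 1e-10)
})

test_that("divisive fits hit the trivial cases exactly", {
  m <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  f1 <- fit_divclus(m, 1)
  expect_equal(f1$K, 1L)
  expect_equal(f1$inertia_trace, 2.0)
  f2 <- fit_divclus(m, 2)
  expect_equal(f2$K, 2L)
  expect_equal(tail(f2$inertia_trace, 1), 0)
  expect_equal(cluster_inertia(m, assign_clusters(m, f2)), 0)
  # requesting more leaves than achievable: warning + underfull flag
  expect_warning(f4 <- fit_divclus(m, 4), "achievable")
  expect_true(f4$underfull)
  expect_equal(f4$K, 2L)
})

test_that("greedy fit matches an independent greedy-tree implementation", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    d <- sample(2:5, 1)
    k <- sample(2:4, 1)
    m <- matrix(rbinom(n * d, 1, runif(1, 0.2, 0.8)), nrow = n)
    fit <- suppressWarnings(fit_divclus(m, k))
    got <- cluster_inertia(m, assign_clusters(m, fit))
    want <- brute_divclus_inertia(m, k)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("assignment agrees with a linear scan over leaf criteria", {
  set.seed(31)
  m <- matrix(rbinom(200 * 6, 1, 0.4), nrow = 200)
  fit <- suppressWarnings(fit_divclus(m, 6))
  asg <- assign_clusters(m, fit)
  probe <- matrix(rbinom(1000 * 6, 1, 0.5), nrow = 1000)
  got <- assign_clusters(probe, fit)
  for (i in seq_len(nrow(probe))) {
    sat <- vapply(fit$leaves, function(l) {
      all(probe[i, l$include] == 1) && all(probe[i, l$exclude] == 0)
    }, logical(1))
    expect_equal(sum(sat), 1L)  # partition property
    expect_equal(fit$leaves[[which(sat)]]$cluster, got[i])
  }
  expect_error(assign_clusters(matrix(0, 1, 5), fit), "length",
               class = "mmtraj_data_error")
})

test_that("the all-zero vector lands in the all-exclusion healthy cluster", {
  set.seed(8)
  m <- rbind(matrix(0, 30, 5), matrix(rbinom(300, 1, 0.5), ncol = 5))
  fit <- suppressWarnings(fit_divclus(m, 5))
  zero_cl <- assign_clusters(matrix(0, 1, 5), fit)
  expect_equal(zero_cl, 0L)
  leaf0 <- fit$leaves[[1]]
  expect_equal(leaf0$cluster, 0L)
  expect_length(leaf0$include, 0)
  expect_gt(length(leaf0$exclude), 0)
})

test_that("criteria are consistent across leaf pairs", {
  set.seed(77)
  m <- matrix(rbinom(400 * 8, 1, 0.35), nrow = 400)
  fit <- suppressWarnings(fit_divclus(m, 7))
  for (l in fit$leaves)
    expect_length(intersect(l$include, l$exclude), 0)
  for (i in seq_along(fit$leaves)) for (j in seq_along(fit$leaves)) {
    if (i == j) next
    a <- fit$leaves[[i]]; b <- fit$leaves[[j]]
    expect_gt(length(union(intersect(a$include, b$exclude),
                           intersect(a$exclude, b$include))), 0)
  }
})

test_that("inertia matches brute force and decreases along the sequence", {
  set.seed(13)
  m <- matrix(rbinom(100 * 5, 1, 0.5), nrow = 100)
  fit <- suppressWarnings(fit_divclus(m, 6))
  asg <- assign_clusters(m, fit)
  expect_equal(cluster_inertia(m, asg), brute_inertia(m, asg),
               tolerance = 1e-9)
  expect_true(all(diff(fit$inertia_trace) <= 1e-9))
  # one observation per cluster -> zero inertia
  distinct <- unique(m)
  fitd <- suppressWarnings(fit_divclus(distinct, nrow(distinct)))
  if (fitd$K == nrow(unique(distinct)))
    expect_equal(cluster_inertia(distinct, assign_clusters(distinct, fitd)), 0)
})

test_that("cluster profiles report sizes, mortality and forced prevalences", {
  gt <- chain3_ground_truth(p_death = 0.05)
  reg <- generate_registry(registry_config(n_patients = 3000, seed = 17,
                                           n_latent_states = 3,
                                           frac_healthy = 0, diagnosis_noise = 0,
                                           ground_truth = gt))
  spec <- cohort_spec()
  coh <- select_washout_cohort(reg$stays, spec)
  hs <- build_health_states(reg$stays, coh, spec, reg$blocks)
  fit <- suppressWarnings(fit_divclus(hs, 3))
  prof <- characterise_clusters(fit, hs)
  expect_equal(sum(prof$size), nrow(hs$index))
  expect_equal(prof$n_male + prof$n_female, prof$size)
  # the terminal latent state has no outgoing moves, so the fraction of its
  # patient-years ending in death estimates the planted 5% yearly death
  # probability directly; check the exact binomial CI covers it
  term <- prof[which.max(prof$cluster)]
  expect_gt(term$size, 500)
  ci <- binom_ci(round(term$mortality * term$size), term$size)
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
  # prevalence is 1 on inclusion criteria, 0 on exclusion criteria
  prev <- attr(prof, "prevalence")
  for (l in fit$leaves) {
    if (prof$size[l$cluster + 1] == 0) next
    expect_true(all(prev[l$cluster + 1, l$include] == 1))
    expect_true(all(prev[l$cluster + 1, l$exclude] == 0))
  }
})

test_that("the permutation diagnostic separates correlated from independent data", {
  set.seed(4)
  # perfectly correlated two-block data
  z <- rbinom(300, 1, 0.5)
  corr <- cbind(z, z)
  d <- choose_k_diagnostic(corr, k_grid = 1:2, n_null = 10, seed = 2)
  expect_lt(d$inertia[2], d$null_mean[2])
  expect_true(all(diff(d$inertia) <= 1e-9))
  expect_true(all(diff(d$null_mean) <= 1e-9))
  # independent columns: real curve inside the null band
  ind <- cbind(rbinom(300, 1, 0.5), rbinom(300, 1, 0.5))
  d2 <- choose_k_diagnostic(ind, k_grid = 2L, n_null = 20, seed = 3)
  expect_gte(d2$inertia, d2$null_lo - 1e-9)
  expect_lte(d2$inertia, d2$null_hi + 1e-9)
})

test_that("cluster models survive a JSON round trip", {
  set.seed(2)
  m <- matrix(rbinom(60 * 4, 1, 0.5), nrow = 60)
  fit <- suppressWarnings(fit_divclus(m, 4))
  f <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(fit, f)
  back <- read_cluster_model(f)
  expect_equal(assign_clusters(m, back), assign_clusters(m, fit))
  defs <- cluster_definitions(fit, default_block_table(4))
  expect_true(all(c("cluster_id", "criterion_type", "block_id",
                    "block_label") %in% names(defs)))
})
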