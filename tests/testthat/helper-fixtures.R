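# Shared fixtures, built in code.

library(data.table)

# tiny hand-made stay table ---------------------------------------------------
toy_stay <- function(patient_id, sex, age_group, date, type = "normal",
                     codes = "Z00") {
  data.table(patient_id = patient_id, sex = sex, age_group = age_group,
             admission_date = as.Date(date),
             release_date = as.Date(date) + 1L,
             release_type = type,
             diagnoses = paste(codes, collapse = ";"))
}

toy_stays <- function(...) rbindlist(list(...))

# minimal assignment table from per-patient cluster sequences ----------------
# seqs: named list, patient -> integer vector of clusters (consecutive years
# starting at `start_year`); ages advance from `age0`
toy_assignments <- function(seqs, start_year = 2003L, sex = "male", age0 = 50L) {
  rbindlist(lapply(names(seqs), function(p) {
    k <- length(seqs[[p]])
    data.table(patient_id = p, year = start_year + seq_len(k) - 1L,
               sex = sex, age = age0 + seq_len(k) - 1L,
               age_group = mmtraj:::age_band_10y(age0 + seq_len(k) - 1L),
               cluster = seqs[[p]])
  }))
}

# brute-force oracles ---------------------------------------------------------

# inertia by direct distance computation
brute_inertia <- function(m, assignment) {
  tot <- 0
  for (cl in unique(assignment)) {
    sub <- m[assignment == cl, , drop = FALSE]
    cen <- colMeans(sub)
    tot <- tot + sum(sweep(sub, 2L, cen)^2)
  }
  tot
}

# gains of every single-variable split, computed naively
brute_gains <- function(m) {
  parent <- brute_inertia(m, rep(1L, nrow(m)))
  vapply(seq_len(ncol(m)), function(v) {
    s <- m[, v]
    if (all(s == 0) || all(s == 1)) return(-Inf)
    parent - brute_inertia(m, s)
  }, numeric(1))
}

# independent greedy monothetic clustering with the documented tie rule:
# max gain over (leaf, variable); ties -> earliest-created leaf, lowest
# variable. Returns the total within-cluster inertia at K leaves.
brute_divclus_inertia <- function(m, K) {
  leaves <- list(list(id = 1L, rows = seq_len(nrow(m))))
  next_id <- 2L
  repeat {
    if (length(leaves) >= K) break
    best <- NULL
    for (li in seq_along(leaves)) {
      sub <- m[leaves[[li]]$rows, , drop = FALSE]
      if (nrow(sub) < 2L) next
      g <- brute_gains(sub)
      if (!any(is.finite(g)) || max(g) <= 1e-12) next
      cand <- which(g >= max(g) - 1e-12)
      v <- cand[1L]
      if (is.null(best) || g[v] > best$gain + 1e-12 ||
          (g[v] >= best$gain - 1e-12 &&
           leaves[[li]]$id < leaves[[best$li]]$id)) {
        best <- list(li = li, v = v, gain = g[v])
      }
    }
    if (is.null(best)) break
    rows <- leaves[[best$li]]$rows
    on1 <- rows[m[rows, best$v] == 1]
    on0 <- setdiff(rows, on1)
    leaves[[best$li]] <- list(id = next_id, rows = on0)
    leaves[[length(leaves) + 1L]] <- list(id = next_id + 1L, rows = on1)
    next_id <- next_id + 2L
  }
  assignment <- integer(nrow(m))
  for (li in seq_along(leaves)) assignment[leaves[[li]]$rows] <- li
  brute_inertia(m, assignment)
}

# two-sided Fisher p via explicit binomial-coefficient enumeration (an
# independent route from dhyper)
brute_fisher <- function(a, b, c_, d_) {
  m <- a + b; n <- c_ + d_; k <- a + c_
  supp <- max(0L, k - n):min(k, m)
  logp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  p <- exp(logp)
  p0 <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(p[p <= p0 * (1 + 1e-7)]))
}

# exact binomial confidence interval (Clopper-Pearson)
binom_ci <- function(x, n, level = 0.95) {
  a <- 1 - level
  lo <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(lo, hi)
}

# assignment fixture with exact exposed/baseline event counts in one stratum
risk_fixture <- function(n1, e1, n0, e0) {
  mk <- function(prefix, n, e, cl) {
    seqs <- lapply(seq_len(n), function(i) {
      if (i <= e) c(cl, 9L) else c(cl, cl)
    })
    names(seqs) <- paste0(prefix, seq_len(n))
    toy_assignments(seqs)
  }
  rbind(mk("e", n1, e1, 1L), mk("b", n0, e0, 0L))
}

# one large registry shared by the acceptance checks (generated lazily once)
.acc_cache <- new.env(parent = emptyenv())
acceptance_registry <- function() {
  if (is.null(.acc_cache$reg))
    .acc_cache$reg <- generate_registry(
      registry_config(n_patients = 50000L, seed = 2024L))
  .acc_cache$reg
}
acceptance_states <- function() {
  if (is.null(.acc_cache$hs)) {
    reg <- acceptance_registry()
    spec <- cohort_spec()
    coh <- select_washout_cohort(reg$stays, spec)
    .acc_cache$hs <- build_health_states(reg$stays, coh, spec, reg$blocks)
  }
  .acc_cache$hs
}

# a small ground truth with a planted chain over three blocks --------------
# state 1 = {}, 2 = {b1}, 3 = {b1, b2}; region entry (state 3) is twice as
# likely from state 2 as from state 1; rates identical across strata
chain3_ground_truth <- function(p_entry = 0.02, p_step = 0.05,
                                hazard_ratio = 2, p_death = 0.002) {
  S <- 3L
  rates <- array(0, dim = c(2L, 11L, S, S + 1L))
  for (g in 1:2) for (a in 1:11) {
    rates[g, a, 1L, 2L] <- p_step
    rates[g, a, 1L, 3L] <- p_entry
    rates[g, a, 2L, 3L] <- hazard_ratio * p_entry
    rates[g, a, , S + 1L] <- p_death
    for (s in 1:S) rates[g, a, s, s] <- 1 - sum(rates[g, a, s, -s])
  }
  ground_truth(states = list(integer(), 10L, c(10L, 20L)), rates = rates)
}
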