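#' Configuration for the synthetic hospital registry
#'
#' Bundles and validates the parameters of [generate_registry()]. The
#' defaults emulate the shape of a national inpatient registry observed over
#' 1997--2014: level-3 ICD-10 diagnoses grouped into 131 WHO blocks, a
#' quarter of patients who never acquire a chronic (A00--N99) diagnosis, and
#' roughly 0.3 hospital stays per person-year.
#'
#' @param n_patients number of patients to simulate (>= 1).
#' @param years inclusive calendar-year interval, length 2; must span at
#'   least 7 years so that a 6-year washout leaves observation time.
#' @param n_blocks number of diagnosis blocks `D` (131 loads the packaged
#'   WHO table, other values synthesise ranges).
#' @param n_latent_states number of planted multimorbidity states including
#'   the empty (no chronic diagnosis) state.
#' @param seed integer random seed; identical configurations reproduce the
#'   registry bit for bit.
#' @param frac_healthy fraction of patients who never receive an A00--N99
#'   code (they only carry chapter O--Z placeholder codes).
#' @param mean_stays_per_year Poisson mean of stays per patient-year; a stay
#'   is forced in any year in which a new latent state is acquired and in
#'   the year of in-hospital death.
#' @param diagnosis_noise probability that a stay carries one extra random
#'   acute block unrelated to the latent state.
#' @param ground_truth optional [ground_truth()] object overriding the
#'   default randomly generated latent dynamics.
#' @return A list of class `registry_config`.
#' @export
registry_config <- function(n_patients,
                            years = c(1997L, 2014L),
                            n_blocks = 131L,
                            n_latent_states = 6L,
                            seed = 1L,
                            frac_healthy = 0.25,
                            mean_stays_per_year = 0.3,
                            diagnosis_noise = 0.1,
                            ground_truth = NULL) {
  assert_count(n_patients, "n_patients")
  if (length(years) != 2L || !is.numeric(years) || years[2L] < years[1L])
    config_error("years must be an increasing calendar-year interval of length 2")
  if (diff(years) + 1L < 7L)
    config_error("years must span at least 7 calendar years (6-year washout + observation)")
  assert_count(n_blocks, "n_blocks")
  assert_count(n_latent_states, "n_latent_states", min = 2L)
  assert_count(seed, "seed", min = 0L)
  assert_fraction(frac_healthy, "frac_healthy")
  assert_fraction(diagnosis_noise, "diagnosis_noise")
  if (!is.numeric(mean_stays_per_year) || mean_stays_per_year <= 0)
    config_error("mean_stays_per_year must be a positive rate")
  structure(list(
    n_patients = as.integer(n_patients),
    years = as.integer(years),
    n_blocks = as.integer(n_blocks),
    n_latent_states = as.integer(n_latent_states),
    seed = as.integer(seed),
    frac_healthy = frac_healthy,
    mean_stays_per_year = mean_stays_per_year,
    diagnosis_noise = diagnosis_noise,
    ground_truth = ground_truth
  ), class = "registry_config")
}

#' Ground-truth latent dynamics for the synthetic registry
#'
#' A ground truth consists of `S` latent multimorbidity states -- nested
#' sets of diagnosis blocks, state 1 being the empty set -- and, per sex and
#' 10-year age band, a row-stochastic yearly transition kernel over
#' `(state 1..S, death)`. Because the block sets grow monotonically along
#' every transition with positive probability, the latent state graph is
#' acyclic by construction, mirroring the one-way structure that cumulative
#' diagnosis histories impose on cluster transitions.
#'
#' @param states list of integer vectors of block ids (0-based); must be
#'   nested along all transitions carrying positive probability.
#' @param rates numeric array of dimension `(2 sexes, 11 age bands, S, S+1)`;
#'   entry `[g, a, s, t]` is the probability of moving from state `s` to
#'   state `t` (the diagonal `t = s` holds the staying probability and
#'   column `S+1` the in-hospital death probability). Rows must sum to 1.
#' @return A list of class `mmtraj_ground_truth`.
#' @export
ground_truth <- function(states, rates) {
  S <- length(states)
  if (!is.array(rates) || !all(dim(rates) == c(2L, 11L, S, S + 1L)))
    config_error("rates must be a (2, 11, S, S+1) array with S = length(states)")
  sums <- apply(rates, c(1L, 2L, 3L), sum)
  if (any(abs(sums - 1) > 1e-12))
    config_error("ground truth rows must sum to 1 (max deviation ",
                 format(max(abs(sums - 1))), ")")
  if (any(rates < 0)) config_error("ground truth rates must be non-negative")
  if (length(states[[1L]]) != 0L)
    config_error("latent state 1 must be the empty block set")
  for (s in seq_len(S)) for (t in seq_len(S)) {
    if (t == s) next
    if (any(rates[, , s, t] > 0)) {
      if (!all(states[[s]] %in% states[[t]]) ||
          length(states[[t]]) <= length(states[[s]]))
        config_error("transition ", s, " -> ", t,
                     " has positive rate but block sets are not strictly nested")
    }
  }
  structure(list(states = lapply(states, as.integer), rates = rates),
            class = "mmtraj_ground_truth")
}

#' Default randomly generated ground truth
#'
#' Builds a nested chain of latent states (each state adds one or two blocks
#' to its predecessor) with yearly progression rates that increase with age,
#' small sex differences, and in-hospital death probabilities that rise with
#' both latent-state severity and age. Uses the current RNG stream.
#'
#' @param n_blocks number of diagnosis blocks available.
#' @param n_latent_states chain length `S` (including the empty state).
#' @param base_progression yearly base probability of advancing one state.
#' @return A [ground_truth()] object.
#' @export
default_ground_truth <- function(n_blocks, n_latent_states,
                                 base_progression = 0.10) {
  S <- n_latent_states
  pool <- sample.int(n_blocks, min(n_blocks, 2L * S)) - 1L
  states <- vector("list", S)
  states[[1L]] <- integer()
  used <- 0L
  for (s in 2L:S) {
    k <- if (used + 2L <= length(pool)) sample(1:2, 1L) else 1L
    states[[s]] <- sort(c(states[[s - 1L]], pool[used + seq_len(k)]))
    used <- used + k
  }
  rates <- array(0, dim = c(2L, 11L, S, S + 1L))
  for (g in 1:2) for (a in 1:11) for (s in 1:S) {
    sexm <- if (g == 1L) 1.05 else 0.95
    af <- 0.25 + 0.08 * (a - 1L)
    p_next <- if (s < S) base_progression * af * sexm else 0
    p_skip <- if (s < S - 1L) 0.25 * p_next else 0
    sev <- (s - 1L) / (S - 1L)
    p_death <- min(0.001 + 0.06 * sev^2 * min(max(exp(0.25 * (a - 7L)), 0.15), 2.5), 0.15)
    if (s < S) rates[g, a, s, s + 1L] <- p_next
    if (s < S - 1L) rates[g, a, s, s + 2L] <- p_skip
    rates[g, a, s, S + 1L] <- p_death
    rates[g, a, s, s] <- 1 - p_next - p_skip - p_death
  }
  ground_truth(states, rates)
}

#' Generate a synthetic hospital-stay registry
#'
#' Simulates patients through the planted latent dynamics year by year and
#' emits one row per hospital stay
#' (`patient_id, sex, age_group, admission_date, release_date, release_type,
#' diagnoses`), with `;`-separated level-3 ICD-10 codes. Non-healthy
#' patients acquire the blocks of their latent state on a stay in the
#' acquisition year; stays may additionally carry one random acute block
#' (diagnosis noise) and re-reported chronic codes. Healthy patients and
#' stays with nothing chronic to report carry chapter O--Z placeholder
#' codes only. At most one stay per patient is typed `death`, and it is the
#' patient's last.
#'
#' @param config a [registry_config()].
#' @return A list of class `mmtraj_registry` with elements `stays`
#'   (`data.table`), `blocks` (the block table used), and `ground_truth`
#'   (the [ground_truth()] plus `$paths`, the latent state of every
#'   non-healthy patient-year, and `$patients`, per-patient metadata).
#' @export
generate_registry <- function(config) {
  if (!inherits(config, "registry_config"))
    config_error("config must be created by registry_config()")
  withr::with_seed(config$seed, generate_registry_impl(config))
}

generate_registry_impl <- function(config) {
  blocks <- default_block_table(config$n_blocks)
  gt <- config$ground_truth %||% default_ground_truth(config$n_blocks,
                                                      config$n_latent_states)
  S <- length(gt$states)
  y0 <- config$years[1L]
  y1 <- config$years[2L]
  n_years <- y1 - y0 + 1L
  n <- config$n_patients

  patients <- data.table::data.table(
    pidx = seq_len(n),
    patient_id = sprintf("P%07d", seq_len(n)),
    sex = SEXES[1L + (runif(n) < 0.5)],
    birth_year = y0 - sample(0:89, n, replace = TRUE),
    healthy = runif(n) < config$frac_healthy
  )
  g_idx <- ifelse(patients$sex == "male", 1L, 2L)

  # latent-state paths (non-healthy patients), yearly kernel draws
  staterec <- matrix(NA_integer_, nrow = n, ncol = n_years)
  dy <- rep(NA_integer_, n)
  state <- rep(1L, n)
  alive <- rep(TRUE, n)
  for (j in seq_len(n_years)) {
    year <- y0 + j - 1L
    act <- which(alive & !patients$healthy)
    if (length(act)) {
      band <- age_band_index(year - patients$birth_year[act])
      M <- vapply(seq_len(S + 1L), function(t)
        gt$rates[cbind(g_idx[act], band, state[act], t)], numeric(length(act)))
      if (length(act) == 1L) M <- matrix(M, nrow = 1L)
      cum <- M
      for (t in 2:(S + 1L)) cum[, t] <- cum[, t] + cum[, t - 1L]
      u <- runif(length(act))
      out <- 1L + as.integer(rowSums(cum < u))
      died <- out == S + 1L
      state[act[!died]] <- out[!died]
      staterec[cbind(act, j)] <- state[act]
      if (any(died)) {
        dy[act[died]] <- year
        alive[act[died]] <- FALSE
      }
    }
    hl <- which(alive & patients$healthy)
    staterec[cbind(hl, j)] <- 1L
  }
  patients[, death_year := dy]

  # patient-year table over alive years (incl. the death year)
  last_j <- ifelse(is.na(dy), n_years, dy - y0 + 1L)
  py <- data.table::data.table(
    pidx = rep(seq_len(n), last_j),
    j = unlist(lapply(last_j, seq_len), use.names = FALSE)
  )
  py[, year := y0 + j - 1L]
  py[, state := staterec[cbind(pidx, j)]]
  py[, prev_state := data.table::shift(state, fill = 1L), by = pidx]
  py[, acquired := state != prev_state]
  py[, death := !is.na(dy[pidx]) & year == dy[pidx]]

  # stays per patient-year; >= 1 forced on acquisition and death years
  py[, n_stays := rpois(.N, config$mean_stays_per_year)]
  py[acquired | death, n_stays := pmax(n_stays, 1L)]
  st <- py[n_stays > 0L][rep(seq_len(.N), n_stays[n_stays > 0L])]
  st[, stay_no := data.table::rowid(pidx, year)]
  st[, doy := sort(sample.int(350L, .N, replace = TRUE)), by = .(pidx, year)]
  st[, admission_date := as.Date(sprintf("%d-01-01", year)) + doy - 1L]
  los <- pmin(rpois(nrow(st), 3L), 20L)
  st[, release_date := pmin(admission_date + los,
                            as.Date(sprintf("%d-12-31", year)))]
  st[, is_first := stay_no == 1L]
  st[, is_last := stay_no == max(stay_no), by = .(pidx, year)]
  st[, release_type := ifelse(runif(.N) < 0.1, "transfer", "normal")]
  st[death & is_last, release_type := "death"]

  # --- diagnosis codes ------------------------------------------------------
  state_blocks <- gt$states
  max_b <- max(1L, max(lengths(state_blocks)))
  bm <- matrix(NA_integer_, nrow = S, ncol = max_b)
  for (s in seq_len(S)) if (length(state_blocks[[s]]))
    bm[s, seq_along(state_blocks[[s]])] <- state_blocks[[s]]
  set_size <- lengths(state_blocks)

  st[, row := .I]
  # (a) newly acquired blocks on the first stay of an acquisition year
  acq <- st[acquired & is_first]
  acq_codes <- if (nrow(acq)) {
    # new blocks depend only on the (prev_state, state) pair: S^2 lookups
    pair_new <- lapply(seq_len(S), function(p) lapply(seq_len(S), function(s)
      setdiff(state_blocks[[s]], state_blocks[[p]])))
    newb <- mapply(function(s, p) pair_new[[p]][[s]],
                   acq$state, acq$prev_state, SIMPLIFY = FALSE)
    data.table::data.table(row = rep(acq$row, lengths(newb)),
                           block = unlist(newb, use.names = FALSE))
  } else data.table::data.table(row = integer(), block = integer())
  # (b) re-reported chronic blocks (sampled with replacement from the
  #     current latent set; duplicates collapse at assembly)
  k_re <- rpois(nrow(st), 1.2)
  k_re <- pmin(k_re, set_size[st$state])
  re_rows <- rep(st$row, k_re)
  if (length(re_rows)) {
    re_state <- rep(st$state, k_re)
    pick <- ceiling(runif(length(re_rows)) * set_size[re_state])
    re_codes <- data.table::data.table(row = re_rows,
                                       block = bm[cbind(re_state, pick)])
  } else re_codes <- data.table::data.table(row = integer(), block = integer())
  # (c) diagnosis noise: one extra random acute block on some stays
  noise_rows <- st$row[!patients$healthy[st$pidx] &
                         runif(nrow(st)) < config$diagnosis_noise]
  noise_codes <- data.table::data.table(
    row = noise_rows,
    block = sample.int(config$n_blocks, length(noise_rows), replace = TRUE) - 1L)
  chronic <- data.table::rbindlist(list(acq_codes, re_codes, noise_codes))
  chronic <- unique(chronic)
  chronic[, code := sample_code_in_block(block, blocks)]

  # (d) chapter O--Z placeholder codes for stays with no chronic code
  has_chronic <- st$row %in% chronic$row
  fill_rows <- st$row[!has_chronic]
  n_fill <- 1L + rpois(length(fill_rows), 0.8)
  fr <- rep(fill_rows, n_fill)
  letters_oz <- sample(c("O", "R", "Z"), length(fr), replace = TRUE,
                       prob = c(0.15, 0.35, 0.5))
  filler <- data.table::data.table(
    row = fr, code = paste0(letters_oz, sprintf("%02d", sample(0:99, length(fr), TRUE))))

  all_codes <- data.table::rbindlist(
    list(chronic[, .(row, code)], filler), use.names = TRUE)
  data.table::setorder(all_codes, row, code)
  diag_str <- all_codes[, .(diagnoses = paste(code, collapse = ";")), by = row]
  st[diag_str, diagnoses := i.diagnoses, on = "row"]

  st[, age := year - patients$birth_year[pidx]]
  stays <- st[, .(
    patient_id = patients$patient_id[pidx],
    sex = patients$sex[pidx],
    age_group = age_band_5y(age),
    admission_date, release_date, release_type, diagnoses)]
  data.table::setorder(stays, patient_id, admission_date)

  paths <- py[!patients$healthy[pidx],
              .(patient_id = patients$patient_id[pidx],
                year,
                sex = patients$sex[pidx],
                age = year - patients$birth_year[pidx],
                state)]
  paths[, age_group := age_band_10y(age)]
  data.table::setorder(paths, patient_id, year)

  gt$paths <- paths
  gt$patients <- patients[, .(patient_id, sex, birth_year, healthy, death_year)]
  structure(list(stays = stays[], blocks = blocks, ground_truth = gt),
            class = "mmtraj_registry")
}

#' Latent-state assignments and deaths from a synthetic registry
#'
#' Convenience accessors used to exercise the transition-rate estimator
#' directly against the planted dynamics: `ground_truth_assignments()`
#' returns one row per (non-healthy) patient-year with the latent state as
#' the `cluster` column, and `ground_truth_deaths()` the in-hospital death
#' years.
#'
#' @param registry a `mmtraj_registry` from [generate_registry()].
#' @return A `data.table`.
#' @export
ground_truth_assignments <- function(registry) {
  p <- data.table::copy(registry$ground_truth$paths)
  data.table::setnames(p, "state", "cluster")
  p[]
}

#' @rdname ground_truth_assignments
#' @export
ground_truth_deaths <- function(registry) {
  registry$ground_truth$patients[!is.na(death_year),
                                 .(patient_id, death_year)]
}

#' @export
print.mmtraj_registry <- function(x, ...) {
  cat("<mmtraj_registry>\n")
  cat("  stays:   ", nrow(x$stays), " rows, ",
      data.table::uniqueN(x$stays$patient_id), " patients\n", sep = "")
  cat("  blocks:  ", nrow(x$blocks), "\n", sep = "")
  cat("  latent states: ", length(x$ground_truth$states), "\n", sep = "")
  invisible(x)
}
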