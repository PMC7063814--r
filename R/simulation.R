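#' Simulate patient trajectories from a multilayer network
#'
#' Evolves a synthetic cohort through the estimated cluster transition
#' model: each year, a patient's next cluster (or in-hospital death) is
#' drawn from the layer matching their current sex and 10-year age group,
#' conditional on not being censored; ages advance one year per step and
#' patients switch layers at band boundaries (the oldest band is absorbing
#' for age). Patients in a cluster/stratum with no at-risk data stay put
#' and the event is logged. A sampled death happens during the following
#' year: that year's row is the patient's terminal record (same cluster),
#' mirroring how registry data records the death-year hospital stay and how
#' the estimator attributes the death outcome to the preceding source year.
#'
#' @param net a stratified `multilayer_net` (or collapsed, in which case
#'   the single layer serves all strata).
#' @param start `data.table(sex, age, cluster[, prob])` start distribution;
#'   rows are sampled with probability `prob` (uniform over rows when
#'   absent). See [start_distribution()].
#' @param n_patients cohort size.
#' @param years inclusive calendar interval to simulate (default
#'   2003--2014).
#' @param seed random seed.
#' @return list with `assignments` (same schema as real assignment
#'   tables), `deaths` (`patient_id, death_year`) and `n_undefined`
#'   (patient-years that hit an unpopulated row).
#' @export
simulate_cohort <- function(net, start, n_patients, years = c(2003L, 2014L),
                            seed = 1L) {
  assert_count(n_patients, "n_patients")
  withr::with_seed(seed,
                   simulate_cohort_impl(net, start, n_patients, years))
}

simulate_cohort_impl <- function(net, start, n_patients, years) {
  start <- data.table::as.data.table(start)
  if (!"prob" %in% names(start)) start[, prob := 1 / .N]
  if (abs(sum(start$prob) - 1) > 1e-12)
    config_error("start distribution must sum to 1")
  collapsed <- identical(unique(net$events$sex), "all")

  # lookup of conditional (uncensored) next-step distributions per row
  ev <- net$events[, .(sex, age_group, from, trials = at_risk - n_censor,
                       n_death)]
  tr <- net$trans[, .(sex, age_group, from, to, n)]
  key_of <- function(sex, age_group, from) paste(sex, age_group, from, sep = "/")
  ev[, key := key_of(sex, age_group, from)]
  tr[, key := key_of(sex, age_group, from)]
  tr_split <- split(tr[, .(to, n)], tr$key)
  ev_split <- split(ev[, .(trials, n_death)], ev$key)

  draw_group <- function(key, k) {
    # returns integer vector of next clusters, NA_integer_ for death,
    # -1L marks "row undefined"
    e <- ev_split[[key]]
    if (is.null(e) || e$trials[1L] <= 0) return(rep(-1L, k))
    t <- tr_split[[key]]
    targets <- c(if (!is.null(t)) t$to, NA_integer_)
    weights <- c(if (!is.null(t)) t$n, e$n_death[1L])
    if (sum(weights) <= 0) return(rep(-1L, k))
    idx <- sample.int(length(targets), k, replace = TRUE, prob = weights)
    targets[idx]
  }

  pick <- sample.int(nrow(start), n_patients, replace = TRUE,
                     prob = start$prob)
  cur <- data.table::data.table(
    pidx = seq_len(n_patients),
    sex = start$sex[pick],
    age = start$age[pick],
    cluster = start$cluster[pick],
    terminal = FALSE)
  y0 <- years[1L]
  y1 <- years[2L]
  rows <- vector("list", y1 - y0 + 1L)
  deaths <- data.table::data.table(pidx = integer(), death_year = integer())
  n_undefined <- 0L
  for (year in y0:y1) {
    cur[, age_group := age_band_10y(age)]
    rows[[year - y0 + 1L]] <- data.table::data.table(
      pidx = cur$pidx, year = year, sex = cur$sex, age = cur$age,
      age_group = cur$age_group, cluster = cur$cluster)
    if (year == y1) break
    # patients whose death year was just recorded leave the cohort
    cur <- cur[terminal == FALSE]
    if (nrow(cur) == 0L) break
    cur[, key := if (collapsed) paste("all", "all", cluster, sep = "/")
        else paste(sex, age_group, cluster, sep = "/")]
    nxt <- cur[, .(pidx = pidx, res = draw_group(key[1L], .N)), by = key]
    cur[nxt, res := i.res, on = "pidx"]
    n_undefined <- n_undefined + sum(cur$res == -1L, na.rm = TRUE)
    # a sampled death happens during the next year: the patient keeps the
    # current cluster, the next year's row is their terminal record
    died <- cur[is.na(res)]
    if (nrow(died))
      deaths <- rbind(deaths, died[, .(pidx, death_year = year + 1L)])
    cur[is.na(res), terminal := TRUE]
    cur[!is.na(res) & res != -1L, cluster := res]
    cur[, res := NULL]
    cur[, age := age + 1L]
  }
  asg <- data.table::rbindlist(rows)
  asg[, patient_id := sprintf("S%07d", pidx)]
  deaths[, patient_id := sprintf("S%07d", pidx)]
  out <- asg[, .(patient_id, year, sex, age, age_group, cluster)]
  data.table::setorder(out, patient_id, year)
  list(assignments = out[],
       deaths = deaths[, .(patient_id, death_year)],
       n_undefined = n_undefined)
}

#' Start distribution from a real cohort
#'
#' Empirical distribution of (sex, age, cluster) in the first observation
#' year of an assignment table, used to match simulated and real cohorts.
#'
#' @param assignments assignment table.
#' @return `data.table(sex, age, cluster, prob)`.
#' @export
start_distribution <- function(assignments) {
  a <- data.table::as.data.table(assignments)
  first <- a[a[, .I[which.min(year)], by = patient_id]$V1]
  out <- first[, .(prob = .N / nrow(first)), by = .(sex, age, cluster)]
  data.table::setorder(out, sex, age, cluster)
  out[]
}

#' Single-disease benchmark cluster assignments
#'
#' Benchmark models label each patient-year by a single diagnosis block
#' instead of a multimorbidity pattern: the most recently acquired block
#' (`mode = "most_recent"`, by first admission date, ties towards the
#' lower block id) or the block with the lowest population prevalence
#' among those acquired (`mode = "least_frequent"`). Patient-years with an
#' all-zero vector map to the dedicated healthy label 0; block `b` maps to
#' label `b + 1`.
#'
#' @param hs a `health_states` object.
#' @param stays the stay table (provides acquisition dates).
#' @param mode `"most_recent"` or `"least_frequent"`.
#' @return Assignment `data.table`
#'   (`patient_id, year, sex, age, age_group, cluster`).
#' @export
benchmark_assign <- function(hs, stays, mode = c("most_recent", "least_frequent")) {
  mode <- match.arg(mode)
  long <- explode_diagnoses(stays[patient_id %in% unique(hs$index$patient_id)])
  long[, block := map_code_to_block(code, hs$blocks)]
  acq <- long[!is.na(block),
              .(acq_date = min(admission_date), acq_year = min(year)),
              by = .(patient_id, block)]
  py <- hs$index[, .(patient_id, year)]
  hits <- acq[py, on = .(patient_id, acq_year <= year),
              nomatch = 0L, allow.cartesian = TRUE,
              .(patient_id, year = acq_year, block, acq_date)]
  if (mode == "most_recent") {
    data.table::setorder(hits, patient_id, year, -acq_date, block)
    lab <- hits[, .SD[1L], by = .(patient_id, year), .SDcols = "block"]
  } else {
    prev <- hits[, .N, by = block]  # patient-year prevalence of each block
    hits[prev, nblock := i.N, on = "block"]
    data.table::setorder(hits, patient_id, year, nblock, block)
    lab <- hits[, .SD[1L], by = .(patient_id, year), .SDcols = "block"]
  }
  out <- hs$index[, .(patient_id, year, sex, age, age_group)]
  out[lab, cluster := i.block + 1L, on = c("patient_id", "year")]
  out[is.na(cluster), cluster := 0L]
  out[]
}

#' Compare trajectory models against real data
#'
#' For each candidate model (an assignment table plus its fitted
#' transition network), simulates a cohort matched to the real cohort's
#' start distribution and compares simulated against real trajectory
#' statistics by total-variation distance: the distribution of reduced
#' trajectory lengths and the distribution of clusters occupied in the
#' final observed year. Each model is evaluated in its own label space, so
#' the numbers measure how well the model's dynamics reproduce its own
#' description of the data.
#'
#' @param models named list; each element is `list(assignments, net)`.
#' @param n_sim simulated cohort size per model.
#' @param years calendar interval of the real data.
#' @param seed seed for the simulations.
#' @param states optional `health_states` used to also report the
#'   within-cluster inertia of each model's induced partition.
#' @return `data.table(model, tv_length, tv_final, n_undefined[, inertia])`.
#' @export
compare_models <- function(models, n_sim = 20000L, years = c(2003L, 2014L),
                           seed = 1L, states = NULL) {
  res <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    real <- data.table::as.data.table(m$assignments)
    sim <- simulate_cohort(m$net, start_distribution(real), n_sim,
                           years = years, seed = seed + i)
    rl_real <- table(reduced_keys(real)$len)
    rl_sim <- table(reduced_keys(sim$assignments)$len)
    fin_real <- table(real[real[, .I[which.max(year)], by = patient_id]$V1, cluster])
    fin_sim <- table(sim$assignments[
      sim$assignments[, .I[which.max(year)], by = patient_id]$V1, cluster])
    row <- data.table::data.table(
      model = names(models)[i],
      tv_length = tv_distance(rl_real, rl_sim),
      tv_final = tv_distance(fin_real, fin_sim),
      n_undefined = sim$n_undefined)
    if (!is.null(states)) {
      key <- states$index[, paste(patient_id, year)]
      mkey <- real[, paste(patient_id, year)]
      row[, inertia := cluster_inertia(states, real$cluster[match(key, mkey)])]
    }
    row
  })
  data.table::rbindlist(res)
}
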