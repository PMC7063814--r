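#' Reduced disease trajectories
#'
#' A patient's disease trajectory is the yearly sequence of clusters; the
#' *reduced* trajectory removes consecutive repeats, and its length counts
#' the distinct successive health states visited.
#'
#' @param traj integer (or character) vector of cluster ids.
#' @return The reduced sequence (empty input gives an empty result).
#' @export
reduce_trajectory <- function(traj) {
  if (length(traj) == 0L) return(traj)
  traj[c(TRUE, traj[-1L] != traj[-length(traj)])]
}

# list of per-patient cluster sequences, in year order
trajectory_list <- function(assignments, patients = NULL) {
  a <- data.table::as.data.table(assignments)
  if (!is.null(patients)) a <- a[patient_id %in% patients]
  data.table::setorder(a, patient_id, year)
  split(a$cluster, a$patient_id)
}

# reduced trajectories keyed for tallying: "0|3|7"
reduced_keys <- function(assignments, patients = NULL) {
  a <- data.table::as.data.table(assignments)
  if (!is.null(patients)) a <- a[patient_id %in% patients]
  data.table::setorder(a, patient_id, year)
  a[, keep := c(TRUE, cluster[-1L] != cluster[-.N]), by = patient_id]
  a[keep == TRUE,
    .(key = paste(cluster, collapse = "|"), len = .N), by = patient_id]
}

#' Distribution of reduced-trajectory lengths
#'
#' Relative frequencies of the number of distinct successive clusters
#' visited per patient during the observation period, optionally restricted
#' to a subcohort.
#'
#' @param assignments assignment table
#'   (`patient_id, year, ..., cluster`).
#' @param subcohort optional character vector of patient ids.
#' @return `data.table(length, n, freq)` with `freq` summing to 1 (empty
#'   for an empty cohort).
#' @export
length_distribution <- function(assignments, subcohort = NULL) {
  rk <- reduced_keys(assignments, subcohort)
  if (nrow(rk) == 0L)
    return(data.table::data.table(length = integer(), n = integer(),
                                  freq = numeric()))
  out <- rk[, .(n = .N), by = .(length = len)]
  out[, freq := n / sum(n)]
  data.table::setorder(out, length)
  out[]
}

#' Mean reduced-trajectory length by age at observation start
#'
#' Patients are binned by their 5-year age band in their first observed
#' year; for each band the mean and standard error (SD/sqrt(n)) of the
#' reduced length are reported. Empty bands are omitted.
#'
#' @param assignments assignment table with an `age` column.
#' @return `data.table(age_band, n, mean_length, se)` ordered by band.
#' @export
mean_length_by_age <- function(assignments) {
  a <- data.table::as.data.table(assignments)
  data.table::setorder(a, patient_id, year)
  start <- a[, .SD[1L], by = patient_id, .SDcols = "age"]
  start[, age_band := age_band_5y(age)]
  rk <- reduced_keys(a)
  rk[start, age_band := i.age_band, on = "patient_id"]
  out <- rk[, .(n = .N, mean_length = mean(len),
                se = sd(len) / sqrt(.N)), by = age_band]
  out[, lo := band_lower(age_band)]
  data.table::setorder(out, lo)
  out[, lo := NULL]
  out[]
}

#' Most frequent reduced trajectory of a given length
#'
#' In `mode = "exact"` (default) the tally runs over patients whose full
#' reduced trajectory has length exactly `L`; in `mode = "prefix"` over the
#' first `L` entries of every reduced trajectory of length at least `L`
#' (so a patient following `(0, 85, 89, 114)` counts towards the prefix
#' `(0, 85, 89)`). Ties are broken towards the lexicographically smallest
#' sequence and reported.
#'
#' @param assignments assignment table.
#' @param L target reduced length (>= 1).
#' @param subcohort optional patient id subset.
#' @param mode `"exact"` or `"prefix"`.
#' @return list with `sequence` (integer vector), `count`, `ties`
#'   (number of sequences sharing the maximal count), or `NULL` when no
#'   trajectory qualifies.
#' @export
most_frequent_reduced <- function(assignments, L, subcohort = NULL,
                                  mode = c("exact", "prefix")) {
  assert_count(L, "L")
  mode <- match.arg(mode)
  rk <- reduced_keys(assignments, subcohort)
  if (mode == "exact") {
    rk <- rk[len == L]
    keys <- rk$key
  } else {
    rk <- rk[len >= L]
    keys <- vapply(strsplit(rk$key, "|", fixed = TRUE),
                   function(p) paste(p[seq_len(L)], collapse = "|"), "")
  }
  if (length(keys) == 0L) return(NULL)
  tab <- sort(table(keys), decreasing = TRUE)
  top <- tab[tab == tab[1L]]
  seqs <- lapply(names(top), function(k)
    as.integer(strsplit(k, "|", fixed = TRUE)[[1L]]))
  ord <- order(vapply(seqs, function(s)
    paste(sprintf("%06d", s), collapse = ","), ""))
  list(sequence = seqs[[ord[1L]]], count = as.integer(top[1L]),
       ties = length(top))
}

#' Export trajectories to CSV
#'
#' Writes the per patient-year cluster table and, optionally, a reduced
#' trajectory summary (`sequence, count`).
#'
#' @param assignments assignment table.
#' @param file output CSV for the raw trajectories.
#' @param reduced_file optional output CSV for the reduced-sequence tally.
#' @export
write_trajectories <- function(assignments, file, reduced_file = NULL) {
  a <- data.table::as.data.table(assignments)[, .(patient_id, year, cluster)]
  data.table::setorder(a, patient_id, year)
  data.table::fwrite(a, file)
  if (!is.null(reduced_file)) {
    rk <- reduced_keys(assignments)
    tally <- rk[, .(count = .N), by = .(sequence = key)]
    data.table::setorder(tally, -count, sequence)
    data.table::fwrite(tally, reduced_file)
  }
  invisible(file)
}
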