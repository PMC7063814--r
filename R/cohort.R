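#' Cohort specification
#'
#' Defines the washout and observation windows and the code range whose
#' absence during washout qualifies a patient for the cohort. The defaults
#' are a 1997--2002 washout free of any A00--N99 diagnosis followed by
#' observation 2003--2014, which standardises the initial health state of
#' every cohort member to "no known chronic diagnosis".
#'
#' @param washout inclusive calendar-year interval of the washout period.
#' @param observation inclusive calendar-year interval of the observation
#'   period; must start after the washout ends.
#' @param excluded_range length-2 character vector, the inclusive level-3
#'   code range that must be absent during washout.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(washout = c(1997L, 2002L),
                        observation = c(2003L, 2014L),
                        excluded_range = c("A00", "N99")) {
  if (length(washout) != 2L || washout[2L] < washout[1L])
    config_error("washout must be a non-empty year interval")
  if (length(observation) != 2L || observation[2L] < observation[1L])
    config_error("observation must be a non-empty year interval")
  if (observation[1L] <= washout[2L])
    config_error("washout must precede the observation period")
  code_index(excluded_range)  # validates format
  structure(list(washout = as.integer(washout),
                 observation = as.integer(observation),
                 excluded_range = excluded_range),
            class = "cohort_spec")
}

# one row per (stay, code): patient_id, year, admission_date, code
explode_diagnoses <- function(stays) {
  codes <- strsplit(stays$diagnoses, ";", fixed = TRUE)
  n <- lengths(codes)
  if (any(n == 0L)) data_error("stay with empty diagnoses list")
  data.table::data.table(
    patient_id = rep(stays$patient_id, n),
    admission_date = rep(stays$admission_date, n),
    year = rep(data.table::year(stays$admission_date), n),
    code = unlist(codes, use.names = FALSE)
  )
}

#' Select the washout cohort
#'
#' Returns the ids of all patients in the stay table that have no stay in
#' the washout interval carrying a diagnosis inside the excluded code range
#' (after truncation to level 3). Patients with only out-of-range codes
#' during washout, and patients entirely absent from the washout years, are
#' retained.
#'
#' @param stays a stay table (`data.table` as produced by
#'   [generate_registry()] or read from CSV).
#' @param spec a [cohort_spec()].
#' @return Character vector of retained patient ids (sorted).
#' @export
select_washout_cohort <- function(stays, spec = cohort_spec()) {
  all_pat <- sort(unique(stays$patient_id))
  if (length(all_pat) == 0L) return(character())
  long <- explode_diagnoses(stays)
  wo <- long[year >= spec$washout[1L] & year <= spec$washout[2L]]
  bad <- unique(wo[code_in_range(code, spec$excluded_range[1L],
                                 spec$excluded_range[2L]), patient_id])
  setdiff(all_pat, bad)
}

#' In-hospital deaths recorded in a stay table
#'
#' @param stays a stay table.
#' @return `data.table` with columns `patient_id, death_year` (year of the
#'   death-typed release).
#' @export
extract_deaths <- function(stays) {
  d <- stays[release_type == "death",
             .(death_year = data.table::year(release_date)), by = patient_id]
  if (anyDuplicated(d$patient_id))
    data_error("patient with more than one death-typed release")
  d[]
}

# per-patient metadata derived from the stay table: sex from the first stay,
# birth year from the 5-year age band at first admission (band midpoint)
patient_meta <- function(stays) {
  first <- stays[order(admission_date), .SD[1L], by = patient_id,
                 .SDcols = c("sex", "age_group", "admission_date")]
  first[, birth_year := data.table::year(admission_date) -
          (band_lower(age_group) + 2L)]
  deaths <- extract_deaths(stays)
  meta <- deaths[first, on = "patient_id"]
  meta[, .(patient_id, sex, birth_year, death_year)]
}

#' Build per-patient, per-year cumulative health states
#'
#' For every cohort patient and every observation year up to and including
#' the year of in-hospital death, computes the cumulative binary vector
#' over diagnosis blocks: component `b` is 1 iff any stay admitted up to 31
#' December of that year carried a code mapping into block `b`. Vectors are
#' componentwise non-decreasing over time by construction. Duplicate
#' vectors are stored once and referenced by id, so downstream clustering
#' scales with the number of distinct health states.
#'
#' @param stays a stay table.
#' @param cohort character vector of patient ids (e.g. from
#'   [select_washout_cohort()]).
#' @param spec a [cohort_spec()].
#' @param blocks a `block_table`.
#' @return An object of class `health_states`: a list with `index`
#'   (`data.table`: `patient_id, year, sex, age, age_group, vector_id`),
#'   `vectors` (sparse 0/1 matrix, one row per distinct vector), `D`,
#'   `blocks` and `deaths`.
#' @export
build_health_states <- function(stays, cohort, spec = cohort_spec(),
                                blocks = default_block_table()) {
  st <- stays[patient_id %in% cohort]
  if (nrow(st) == 0L && length(cohort) > 0L)
    data_error("cohort patients not present in stay table")
  meta <- patient_meta(st)

  # consistency: no stay admitted after a death-typed release
  dd <- st[release_type == "death", .(patient_id, dr = release_date)]
  if (nrow(dd)) {
    late <- dd[st, on = "patient_id", nomatch = 0L][admission_date > dr]
    if (nrow(late))
      data_error("stay admitted after death-typed release for patient ",
                 late$patient_id[1L])
  }

  long <- explode_diagnoses(st)
  long[, block := map_code_to_block(code, blocks)]
  acq <- long[!is.na(block), .(acq_year = min(year)), by = .(patient_id, block)]

  obs0 <- spec$observation[1L]
  obs1 <- spec$observation[2L]
  meta[, last_year := pmin(ifelse(is.na(death_year), obs1, death_year), obs1)]
  meta <- meta[last_year >= obs0]
  ny <- meta$last_year - obs0 + 1L
  index <- data.table::data.table(
    patient_id = rep(meta$patient_id, ny),
    year = unlist(lapply(ny, function(k) obs0 + seq_len(k) - 1L),
                  use.names = FALSE)
  )
  index <- meta[, .(patient_id, sex, birth_year)][index, on = "patient_id"]
  index[, age := year - birth_year]
  index[, age_group := age_band_10y(age)]
  index[, birth_year := NULL]

  # membership: block present in year y iff acquired in some year <= y
  # (in the non-equi join result the column named `acq_year` carries the
  # value of the join boundary, i.e. the snapshot year)
  acq2 <- acq[, .(patient_id, block, acq_year)][
    index[, .(patient_id, year)], on = .(patient_id, acq_year <= year),
    nomatch = 0L, allow.cartesian = TRUE]
  acq2 <- acq2[, .(patient_id, year = acq_year, block)]
  data.table::setorder(acq2, patient_id, year, block)
  keys <- acq2[, .(key = paste(block, collapse = ",")), by = .(patient_id, year)]
  index[keys, key := i.key, on = c("patient_id", "year")]
  index[is.na(key), key := ""]

  ukeys <- sort(unique(index$key))
  index[, vector_id := match(key, ukeys)]
  index[, key := NULL]
  D <- nrow(blocks)
  parts <- strsplit(ukeys, ",", fixed = TRUE)
  lens <- lengths(parts)
  trip_i <- rep(seq_along(ukeys), lens)
  trip_j <- as.integer(unlist(parts, use.names = FALSE)) + 1L
  vectors <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = 1,
                                  dims = c(length(ukeys), D))
  deaths <- meta[!is.na(death_year), .(patient_id, death_year)]
  data.table::setorder(index, patient_id, year)
  structure(list(index = index[], vectors = vectors, D = D,
                 blocks = blocks, deaths = deaths[]),
            class = "health_states")
}

#' Dense matrix of per patient-year health-state vectors
#'
#' @param hs a `health_states` object.
#' @param rows optional row subset of `hs$index`.
#' @return Sparse 0/1 matrix with one row per (patient, year) of `hs$index`.
#' @export
state_matrix <- function(hs, rows = NULL) {
  ids <- if (is.null(rows)) hs$index$vector_id else hs$index$vector_id[rows]
  hs$vectors[ids, , drop = FALSE]
}

#' @export
print.health_states <- function(x, ...) {
  cat("<health_states> ", nrow(x$index), " patient-years, ",
      data.table::uniqueN(x$index$patient_id), " patients, D = ", x$D,
      ", ", nrow(x$vectors), " distinct vectors\n", sep = "")
  invisible(x)
}

#' Export health states to CSV
#'
#' `format = "sparse"` writes one row per set bit
#' (`patient_id,year,block_id`); `format = "dense"` writes one row per
#' patient-year with the vector as a 0/1 string of length `D`.
#'
#' @param hs a `health_states` object.
#' @param file output path.
#' @param format `"sparse"` or `"dense"`.
#' @export
write_health_states <- function(hs, file, format = c("sparse", "dense")) {
  format <- match.arg(format)
  if (format == "sparse") {
    tr <- Matrix::summary(hs$vectors)
    long <- data.table::data.table(vector_id = tr$i, block_id = tr$j - 1L)
    out <- long[hs$index, on = "vector_id", allow.cartesian = TRUE, nomatch = 0L,
                .(patient_id, year, block_id)]
    data.table::setorder(out, patient_id, year, block_id)
  } else {
    m <- as.matrix(state_matrix(hs))
    out <- hs$index[, .(patient_id, year, sex, age_group)]
    out[, vector := apply(m, 1L, paste, collapse = "")]
  }
  data.table::fwrite(out, file)
  invisible(file)
}
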