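#' Two-sided Fisher exact test for 2x2 tables
#'
#' Computes the two-sided p-value by hypergeometric point-probability
#' summation: the sum of the probabilities of all tables (with the observed
#' margins) whose point probability does not exceed that of the observed
#' table (up to a relative tolerance of 1e-7, the standard convention).
#' Vectorised over tables, which makes screening thousands of transitions
#' cheap.
#'
#' @param a,b,c_,d_ cell counts of the tables `rbind(c(a, b), c(c_, d_))`.
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c_, d_) {
  n <- length(a)
  stopifnot(length(b) == n, length(c_) == n, length(d_) == n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[i] + b[i]          # row 1 total
    nn <- c_[i] + d_[i]       # row 2 total
    k <- a[i] + c_[i]         # column 1 total
    support <- max(0L, k - nn):min(k, m)
    probs <- dhyper(support, m, nn, k)
    p0 <- dhyper(a[i], m, nn, k)
    p[i] <- min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
  }
  p
}

#' Relative risk of region entry from a cluster
#'
#' Patient-year analysis of the risk of stepping into a region (set of
#' clusters) within `horizon` years. Every observation year in which a
#' patient occupies the source cluster contributes one at-risk trial; the
#' baseline population is either all patient-years of the same stratum not
#' already in the region (`baseline = "all"`) or the healthy-cluster
#' patient-years of the stratum (`baseline = "cluster0"`). Patient-years
#' with fewer than `horizon` remaining observed years and no event are
#' excluded from both denominators. The relative risk carries a 95%
#' confidence interval from the normal approximation on the log scale
#' (Katz), `SE = sqrt(1/e1 - 1/n1 + 1/e0 - 1/n0)`.
#'
#' @param assignments assignment table.
#' @param source source cluster id (must not belong to `region`).
#' @param region integer vector of region cluster ids.
#' @param sex `"male"`, `"female"` or `NULL` to pool sexes.
#' @param age_group 10-year band label (e.g. `"50-59"`) or `NULL` to pool.
#' @param horizon years of lookahead (>= 1, default 1).
#' @param baseline `"all"` or `"cluster0"`.
#' @param baseline_cluster cluster id of the healthy cluster (default 0).
#' @return list of class `risk_estimate`: exposed/baseline events and
#'   trials, `absolute_risk`, `baseline_risk`, `rr`, `ci` (length 2),
#'   `ci_half_width`, and the stratum/settings echoed. `rr` is `NA` with
#'   `undefined = TRUE` when the baseline has no events.
#' @export
region_entry_risk <- function(assignments, source, region,
                              sex = NULL, age_group = NULL,
                              horizon = 1L,
                              baseline = c("all", "cluster0"),
                              baseline_cluster = 0L) {
  assert_count(horizon, "horizon")
  baseline <- match.arg(baseline)
  if (source %in% region) config_error("source cluster must lie outside the region")
  a <- data.table::as.data.table(assignments)
  data.table::setorder(a, patient_id, year)
  a[, in_region := cluster %in% region]
  a[, last_year := max(year), by = patient_id]
  first_entry <- a[in_region == TRUE, .(fy = min(year)), by = patient_id]
  a[first_entry, fy := i.fy, on = "patient_id"]
  a[is.na(fy), fy := .Machine$integer.max]
  a[, event := fy > year & fy <= year + horizon]
  a[, followed := (last_year >= year + horizon) | event]

  sel_stratum <- rep(TRUE, nrow(a))
  if (!is.null(sex)) sel_stratum <- sel_stratum & a$sex == sex
  if (!is.null(age_group)) sel_stratum <- sel_stratum & a$age_group == age_group

  exp_rows <- a[sel_stratum & cluster == source & followed & in_region == FALSE]
  base_rows <- if (baseline == "all") {
    a[sel_stratum & in_region == FALSE & followed == TRUE]
  } else {
    a[sel_stratum & cluster == baseline_cluster & followed & in_region == FALSE]
  }
  e1 <- sum(exp_rows$event); n1 <- nrow(exp_rows)
  e0 <- sum(base_rows$event); n0 <- nrow(base_rows)
  p1 <- if (n1 > 0) e1 / n1 else NA_real_
  p0 <- if (n0 > 0) e0 / n0 else NA_real_
  undefined <- is.na(p0) || e0 == 0 || is.na(p1)
  rr <- if (undefined) NA_real_ else p1 / p0
  ci <- c(NA_real_, NA_real_)
  if (!undefined && e1 > 0) {
    se <- sqrt(1 / e1 - 1 / n1 + 1 / e0 - 1 / n0)
    ci <- exp(log(rr) + c(-1, 1) * qnorm(0.975) * se)
  }
  structure(list(source = source, region = region, sex = sex,
                 age_group = age_group, horizon = horizon,
                 baseline = baseline,
                 exposed_events = e1, exposed_n = n1,
                 baseline_events = e0, baseline_n = n0,
                 absolute_risk = p1, baseline_risk = p0,
                 rr = rr, ci = ci,
                 ci_half_width = if (all(is.finite(ci))) diff(ci) / 2 else NA_real_,
                 undefined = undefined),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat("<risk_estimate> cluster ", x$source, " -> region {",
      paste(x$region, collapse = ","), "}",
      if (!is.null(x$sex)) paste0(", ", x$sex) else "",
      if (!is.null(x$age_group)) paste0(" ", x$age_group) else "",
      ", horizon ", x$horizon, "y\n", sep = "")
  cat(sprintf("  absolute risk %.4f (%d/%d), baseline %.4f (%d/%d)\n",
              x$absolute_risk, x$exposed_events, x$exposed_n,
              x$baseline_risk, x$baseline_events, x$baseline_n))
  if (x$undefined) cat("  RR undefined (no baseline events)\n")
  else cat(sprintf("  RR %.3f [95%% CI %.3f, %.3f] (+/- %.3f)\n",
                   x$rr, x$ci[1L], x$ci[2L], x$ci_half_width))
  invisible(x)
}

#' Split patients into progredient and stable groups
#'
#' From all patients observed in a given cluster set, *progredient*
#' patients are those found outside the set `horizon` years after their
#' first year in it (when `region` is supplied, "outside" is narrowed to
#' "inside the region"); *stable* patients are still inside the set.
#' Patients unobserved at the follow-up year are excluded, as are patients
#' that (with `region` given) left the set without entering the region.
#'
#' @param assignments assignment table.
#' @param cluster_set integer vector of cluster ids defining the group.
#' @param region optional region cluster ids narrowing "progression".
#' @param horizon follow-up in years (default 3).
#' @return list with `progredient`, `stable` (patient id vectors) and
#'   `reference` (`data.table(patient_id, ref_year)`).
#' @export
progredient_split <- function(assignments, cluster_set, region = NULL,
                              horizon = 3L) {
  assert_count(horizon, "horizon")
  a <- data.table::as.data.table(assignments)
  data.table::setorder(a, patient_id, year)
  ref <- a[cluster %in% cluster_set, .(ref_year = min(year)), by = patient_id]
  fu <- a[ref[, .(patient_id, year = ref_year + horizon)],
          on = c("patient_id", "year"), nomatch = 0L]
  fu[, inside := cluster %in% cluster_set]
  prog <- if (is.null(region)) {
    fu[inside == FALSE, patient_id]
  } else {
    fu[cluster %in% region, patient_id]
  }
  stab <- fu[inside == TRUE, patient_id]
  list(progredient = sort(prog), stable = sort(stab),
       reference = ref[])
}

#' Compare comorbidities between progredient and stable patients
#'
#' Per tested item (diagnosis block or level-3 code), builds the 2x2 table
#' of group membership against item presence and evaluates it with the
#' two-sided Fisher exact test; p-values are Bonferroni-adjusted over the
#' number of tested items. Items absent from both groups are flagged
#' degenerate (p = 1).
#'
#' @param progredient,stable disjoint patient id vectors.
#' @param presence `data.table(patient_id, item)` listing the items present
#'   for each patient at the reference year (block ids or codes -- the
#'   granularity is the caller's choice).
#' @param items optional vector of items to test (default: all items
#'   observed in either group).
#' @param alpha significance level applied to the adjusted p-values.
#' @return `data.table(item, n_prog, prog_total, n_stable, stable_total,
#'   odds_ratio, p, p_adjusted, significant, degenerate)`.
#' @export
compare_comorbidities <- function(progredient, stable, presence,
                                  items = NULL, alpha = 0.05) {
  if (length(intersect(progredient, stable)))
    config_error("progredient and stable groups must be disjoint")
  pr <- data.table::as.data.table(presence)
  pr_p <- pr[patient_id %in% progredient]
  pr_s <- pr[patient_id %in% stable]
  items <- items %||% sort(unique(c(pr_p$item, pr_s$item)))
  np <- length(progredient)
  ns <- length(stable)
  cp <- pr_p[, .N, by = item][match(items, item), N]
  cs <- pr_s[, .N, by = item][match(items, item), N]
  cp[is.na(cp)] <- 0L
  cs[is.na(cs)] <- 0L
  p <- fisher_exact_2x2(cp, np - cp, cs, ns - cs)
  or <- (cp * (ns - cs)) / pmax(1e-300, (np - cp) * cs)
  or[cs == 0 & cp == 0] <- NA_real_
  out <- data.table::data.table(
    item = items, n_prog = cp, prog_total = np,
    n_stable = cs, stable_total = ns,
    odds_ratio = or, p = p,
    p_adjusted = pmin(1, p * length(items)),
    degenerate = cp == 0L & cs == 0L)
  out[, significant := p_adjusted < alpha & !degenerate]
  data.table::setorder(out, p_adjusted, item)
  out[]
}

#' Screen cluster transitions for gender bias
#'
#' For every inter-cluster (age group, source, target) transition populated
#' in both sex layers with at least `min_at_risk` uncensored at-risk
#' patient-years per sex (self-loops are the complement of the moves and
#' are not tested separately), tests equality of the male and female
#' transition rates with the
#' two-sided Fisher exact test on the 2x2 (sex x transitioned) table, and
#' adjusts with Bonferroni over all tested triples. Triples with one sex
#' absent (sex-specific clusters) are skipped and counted.
#'
#' @param net a stratified `multilayer_net`.
#' @param alpha significance level applied to adjusted p-values.
#' @param min_at_risk minimum uncensored at-risk patient-years per sex.
#' @return `data.table(age_group, from, to, male_rate, female_rate,
#'   n_male, n_female, p, p_adjusted, significant)` sorted by adjusted p;
#'   the number of skipped triples is attached as attribute `"skipped"`.
#' @export
gender_biased_transitions <- function(net, alpha = 0.05, min_at_risk = 100L) {
  tr <- data.table::copy(net$trans)
  ev <- net$events[, .(sex, age_group, from,
                       trials = at_risk - n_censor)]
  tr <- tr[from != to]  # self-loops are the complement of the moves tested
  wide <- unique(tr[, .(age_group, from, to)])
  # transition counts per sex (0 when the sex has at-risk years but the
  # transition was never observed), trial counts from the events table
  wide[tr[sex == "male"], n_male := i.n, on = c("age_group", "from", "to")]
  wide[tr[sex == "female"], n_female := i.n, on = c("age_group", "from", "to")]
  wide[ev[sex == "male"], trials_male := i.trials, on = c("age_group", "from")]
  wide[ev[sex == "female"], trials_female := i.trials, on = c("age_group", "from")]
  wide[is.na(n_male) & !is.na(trials_male), n_male := 0]
  wide[is.na(n_female) & !is.na(trials_female), n_female := 0]
  skipped <- sum(is.na(wide$trials_male) | is.na(wide$trials_female) |
                   wide$trials_male < min_at_risk |
                   wide$trials_female < min_at_risk)
  keep <- wide[!is.na(trials_male) & !is.na(trials_female) &
                 trials_male >= min_at_risk & trials_female >= min_at_risk]
  if (nrow(keep) == 0L) {
    out <- data.table::data.table(age_group = character(), from = integer(),
                                  to = integer(), male_rate = numeric(),
                                  female_rate = numeric(), n_male = integer(),
                                  n_female = integer(), p = numeric(),
                                  p_adjusted = numeric(),
                                  significant = logical())
    data.table::setattr(out, "skipped", skipped)
    return(out)
  }
  keep[, p := fisher_exact_2x2(n_male, trials_male - n_male,
                               n_female, trials_female - n_female)]
  keep[, p_adjusted := pmin(1, p * .N)]
  keep[, male_rate := n_male / trials_male]
  keep[, female_rate := n_female / trials_female]
  keep[, significant := p_adjusted < alpha]
  out <- keep[, .(age_group, from, to, male_rate, female_rate,
                  n_male = as.integer(n_male), n_female = as.integer(n_female),
                  p, p_adjusted, significant)]
  data.table::setorder(out, p_adjusted, age_group, from, to)
  data.table::setattr(out, "skipped", skipped)
  out[]
}

#' Presence table of blocks at each patient's reference year
#'
#' Helper for [compare_comorbidities()]: lists, per patient, the diagnosis
#' blocks set in the health-state vector of the patient's reference year.
#'
#' @param hs a `health_states` object.
#' @param reference `data.table(patient_id, ref_year)` (e.g. from
#'   [progredient_split()]).
#' @return `data.table(patient_id, item)` with `item` = block id.
#' @export
presence_at_reference <- function(hs, reference) {
  idx <- hs$index[reference, on = c("patient_id", year = "ref_year"),
                  nomatch = 0L, .(patient_id, vector_id)]
  tr <- Matrix::summary(hs$vectors)
  long <- data.table::data.table(vector_id = tr$i, item = tr$j - 1L)
  out <- long[idx, on = "vector_id", allow.cartesian = TRUE, nomatch = 0L,
              .(patient_id, item)]
  data.table::setorder(out, patient_id, item)
  unique(out)
}
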