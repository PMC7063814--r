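#' Sex/age-stratified multilayer network of yearly cluster transitions
#'
#' For each layer (sex, 10-year age group) and source cluster `k`, the
#' transition rate `q[g, a, k, j]` is the fraction of the layer's at-risk
#' patient-years in `k` that are found in cluster `j` one year later. A
#' transition's layer is determined by the patient's sex and age group in
#' the *source* year. Every at-risk patient-year is attributed exactly one
#' outcome: a cluster next year, in-hospital death (when the *following*
#' year is the patient's recorded death year), or censoring (end of the
#' observation window). The death-year row itself is the terminal event and
#' is excluded from the at-risk denominators. Rates over clusters plus the
#' death and censor rates sum to one per populated row.
#'
#' @param assignments `data.table` with columns
#'   `patient_id, year, sex, age, age_group, cluster`, consecutive years
#'   per patient.
#' @param deaths `data.table(patient_id, death_year)` of in-hospital
#'   deaths.
#' @return An object of class `multilayer_net`: list with `trans`
#'   (`sex, age_group, from, to, n, rate, rate_uncensored, age_sum`),
#'   `events` (`sex, age_group, from, at_risk, n_death, n_censor,
#'   death_rate, censor_rate`) and `clusters`.
#' @export
estimate_transition_rates <- function(assignments, deaths = NULL) {
  a <- data.table::as.data.table(assignments)
  need <- c("patient_id", "year", "sex", "age", "age_group", "cluster")
  if (!all(need %in% names(a)))
    data_error("assignments must have columns ", paste(need, collapse = ", "))
  data.table::setorder(a, patient_id, year)
  gap <- a[, any(diff(year) != 1L), by = patient_id]$V1
  if (any(gap))
    data_error("assignments must cover consecutive years per patient")
  a[, nxt := data.table::shift(cluster, -1L), by = patient_id]
  if (!is.null(deaths) && nrow(deaths))
    a[deaths, death_year := i.death_year, on = "patient_id"]
  else
    a[, death_year := NA_integer_]
  # outcome attribution: the recorded death-year row is the terminal event
  # itself and is not at risk; the *preceding* year carries the death
  # outcome. All other rows step to the next year's cluster or are
  # censored by the window end.
  a[, outcome := data.table::fifelse(
    !is.na(death_year) & year == death_year, "terminal",
    data.table::fifelse(
      !is.na(death_year) & year + 1L == death_year, "death",
      data.table::fifelse(!is.na(nxt), "step", "censor")))]
  a <- a[outcome != "terminal"]

  trans <- a[outcome == "step",
             .(n = .N, age_sum = sum(age)),
             by = .(sex, age_group, from = cluster, to = nxt)]
  events <- a[, .(at_risk = .N,
                  n_death = sum(outcome == "death"),
                  n_censor = sum(outcome == "censor")),
              by = .(sex, age_group, from = cluster)]
  trans[events, at_risk := i.at_risk, on = c("sex", "age_group", "from")]
  trans[, rate := n / at_risk]
  trans[events, nc := i.n_censor, on = c("sex", "age_group", "from")]
  trans[, rate_uncensored := n / (at_risk - nc)]
  trans[, c("at_risk", "nc") := NULL]
  events[, death_rate := n_death / at_risk]
  events[, censor_rate := n_censor / at_risk]
  data.table::setorder(trans, sex, age_group, from, to)
  data.table::setorder(events, sex, age_group, from)
  structure(list(trans = trans[], events = events[],
                 clusters = sort(unique(c(a$cluster)))),
            class = "multilayer_net")
}

#' @export
print.multilayer_net <- function(x, ...) {
  cat("<multilayer_net> ", length(x$clusters), " clusters, ",
      nrow(unique(x$events[, .(sex, age_group)])), " layers, ",
      nrow(x$trans), " edges\n", sep = "")
  invisible(x)
}

#' Robustness filter for network links
#'
#' Keeps links whose transition rate exceeds `min_rate` and whose
#' transition count reaches `min_count`, the statistical-robustness rule
#' used when drawing the network: a printed default of 0.5% for the rate
#' and a configurable minimum count guard against rates estimated from a
#' handful of patients.
#'
#' @param net a `multilayer_net` (stratified or collapsed).
#' @param min_rate minimum transition rate (default 0.005).
#' @param min_count minimum transition count (default 100).
#' @return The filtered edge `data.table` (same columns as `net$trans`).
#' @export
robustness_filter <- function(net, min_rate = 0.005, min_count = 100L) {
  net$trans[rate > min_rate & n >= min_count]
}

#' Collapse network layers
#'
#' Sums transition and event counts over all (sex, age group) layers and
#' recomputes rates from the pooled counts; the mean age of transitioning
#' patients is carried per edge (used for age-colouring network figures).
#'
#' @param net a `multilayer_net`.
#' @return A `multilayer_net` with a single layer labelled `all`.
#' @export
collapse_layers <- function(net) {
  trans <- net$trans[, .(n = sum(n), age_sum = sum(age_sum)),
                     by = .(from, to)]
  events <- net$events[, .(at_risk = sum(at_risk), n_death = sum(n_death),
                           n_censor = sum(n_censor)), by = from]
  trans[events, at_risk := i.at_risk, on = "from"]
  trans[, rate := n / at_risk]
  trans[events, nc := i.n_censor, on = "from"]
  trans[, rate_uncensored := n / (at_risk - nc)]
  trans[, mean_age := age_sum / n]
  trans[, c("at_risk", "nc") := NULL]
  events[, death_rate := n_death / at_risk]
  events[, censor_rate := n_censor / at_risk]
  trans[, `:=`(sex = "all", age_group = "all")]
  events[, `:=`(sex = "all", age_group = "all")]
  data.table::setcolorder(trans, c("sex", "age_group", "from", "to"))
  data.table::setcolorder(events, c("sex", "age_group", "from"))
  data.table::setorder(trans, from, to)
  structure(list(trans = trans[], events = events[], clusters = net$clusters),
            class = "multilayer_net")
}

#' Sink states of the cluster network
#'
#' Clusters with no outgoing inter-cluster link in the (optionally
#' filtered) collapsed network. Self-loops and deaths do not count as
#' outgoing: a cluster whose only outflow is death is a sink -- patients
#' entering it never move to another cluster.
#'
#' @param net a `multilayer_net`.
#' @param edges optional pre-filtered edge table (e.g. from
#'   [robustness_filter()]); defaults to all edges of `net`.
#' @return Sorted integer vector of sink cluster ids.
#' @export
find_sink_states <- function(net, edges = NULL) {
  e <- edges %||% net$trans
  out <- unique(e[from != to, from])
  sort(setdiff(net$clusters, out))
}

#' Check acyclicity of observed inter-cluster transitions
#'
#' Cumulative diagnosis vectors force inter-cluster steps into one
#' direction; a cycle indicates inconsistent criteria or corrupted data.
#' Self-loops are ignored.
#'
#' @param edges edge table with columns `from, to` (e.g. `net$trans`), or a
#'   `multilayer_net`.
#' @return list with `pass` (logical) and `cycle` (an explicit cluster
#'   cycle when `pass` is `FALSE`, otherwise `NULL`).
#' @export
acyclicity_check <- function(edges) {
  if (inherits(edges, "multilayer_net")) edges <- edges$trans
  e <- unique(data.table::as.data.table(edges)[from != to, .(from, to)])
  if (nrow(e) == 0L) return(list(pass = TRUE, cycle = NULL))
  g <- igraph::graph_from_data_frame(
    e[, .(from = as.character(from), to = as.character(to))], directed = TRUE)
  if (igraph::is_dag(g)) return(list(pass = TRUE, cycle = NULL))
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize >= 2L)[1L]
  members <- which(comp$membership == big)
  sub <- igraph::induced_subgraph(g, members)
  v1 <- igraph::V(sub)[1L]
  succ <- igraph::neighbors(sub, v1, mode = "out")[1L]
  back <- igraph::shortest_paths(sub, from = succ, to = v1, mode = "out")$vpath[[1L]]
  cycle <- as.integer(c(igraph::V(sub)$name[v1],
                        igraph::V(sub)$name[back]))
  list(pass = FALSE, cycle = cycle)
}

#' Label clusters into mortality regions
#'
#' Clusters whose mean age reaches `min_mean_age` are labelled by the
#' mortality band containing their yearly in-hospital mortality. The
#' default bands are the low (0.2--0.3%), medium (0.3--1%) and high
#' (2--11%) elderly regions; bands are half-open `[lo, hi)` except the
#' upper end of each band's printed range, which is included. Clusters
#' falling in no band, or younger than `min_mean_age`, are unlabelled.
#'
#' @param profiles cluster profile table from [characterise_clusters()].
#' @param bands named list of `c(lo, hi)` mortality fractions; must be
#'   disjoint.
#' @param min_mean_age minimum cluster mean age in years (default 55).
#' @return `data.table` with columns `cluster, mortality, mean_age,
#'   region` (`"low"/"medium"/"high"/"unlabelled"` for default bands).
#' @export
label_mortality_regions <- function(profiles,
                                    bands = list(low = c(0.002, 0.003),
                                                 medium = c(0.003, 0.01),
                                                 high = c(0.02, 0.11)),
                                    min_mean_age = 55) {
  bl <- vapply(bands, `[`, 0, 1L)
  bh <- vapply(bands, `[`, 0, 2L)
  o <- order(bl)
  if (any(bl[o][-1L] < bh[o][-length(o)]))
    config_error("mortality bands must be disjoint")
  out <- data.table::as.data.table(profiles)[, .(cluster, mortality, mean_age)]
  out[, region := "unlabelled"]
  nb <- names(bands)
  for (i in seq_along(bands)) {
    hi_open <- any(abs(bl - bh[i]) < 1e-15)  # shared boundary goes upward
    sel <- !is.na(out$mortality) & !is.na(out$mean_age) &
      out$mean_age >= min_mean_age & out$mortality >= bl[i] &
      (if (hi_open) out$mortality < bh[i] else out$mortality <= bh[i])
    out[sel, region := nb[i]]
  }
  out[]
}

#' Rank clusters by region entries
#'
#' For each patient, finds the first year assigned to a region cluster and
#' credits the cluster occupied the year before (one credit per patient;
#' patients already in the region in their first observed year contribute
#' nothing). Clusters are ranked by descending entry count.
#'
#' @param assignments assignment table (see
#'   [estimate_transition_rates()]).
#' @param region non-empty integer vector of region cluster ids.
#' @return `data.table(cluster, n_entries)` sorted by descending count
#'   (ties towards the lower cluster id).
#' @export
rank_entry_clusters <- function(assignments, region) {
  if (length(region) == 0L) config_error("region must be non-empty")
  a <- data.table::as.data.table(assignments)
  data.table::setorder(a, patient_id, year)
  a[, in_region := cluster %in% region]
  if (!any(a$in_region))
    return(data.table::data.table(cluster = integer(), n_entries = integer()))
  entry <- a[in_region == TRUE, .(entry_year = min(year)), by = patient_id]
  # the credited cluster is the one occupied the year before first entry
  prev_year <- a[entry[, .(patient_id, year = entry_year - 1L)],
                 on = c("patient_id", "year"), nomatch = 0L]
  counts <- prev_year[, .(n_entries = .N), by = cluster]
  data.table::setorder(counts, -n_entries, cluster)
  counts[]
}

#' Export a collapsed network to GraphML and edge-list CSV
#'
#' The GraphML carries node attributes `size` (at-risk patient-years) and
#' `mortality`, and edge attributes `rate`, `n` and `mean_age`; the edge
#' list CSV mirrors `net$trans`.
#'
#' @param net a `multilayer_net` (collapse first for a single-layer file).
#' @param graphml,edgelist output paths (`NULL` to skip either).
#' @param profiles optional cluster profiles to source node mortality from.
#' @export
export_network <- function(net, graphml = NULL, edgelist = NULL,
                           profiles = NULL) {
  if (!is.null(edgelist)) data.table::fwrite(net$trans, edgelist)
  if (!is.null(graphml)) {
    e <- net$trans[from != to]
    g <- igraph::graph_from_data_frame(
      e[, .(from = as.character(from), to = as.character(to),
            rate = rate, n = n,
            mean_age = if ("mean_age" %in% names(e)) mean_age else NA_real_)],
      directed = TRUE,
      vertices = data.frame(name = as.character(net$clusters)))
    sizes <- net$events[, .(size = sum(at_risk),
                            deaths = sum(n_death)), by = from]
    idx <- match(as.character(net$clusters), as.character(sizes$from))
    igraph::V(g)$size <- sizes$size[idx]
    mort <- if (!is.null(profiles)) {
      profiles$mortality[match(net$clusters, profiles$cluster)]
    } else sizes$deaths[idx] / sizes$size[idx]
    igraph::V(g)$mortality <- mort
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(NULL)
}
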