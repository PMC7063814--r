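#' Monothetic divisive clustering of binary health states
#'
#' The clustering engine partitions the observed cumulative diagnosis
#' vectors into `K` clusters by recursive monothetic splits: each split
#' questions a single diagnosis block and separates the current cluster into
#' the vectors with (`1`) and without (`0`) that block, choosing at every
#' step the (cluster, block) pair whose bipartition maximally decreases the
#' total within-cluster inertia (sum of squared Euclidean distances to the
#' cluster centroid). Each resulting cluster is therefore described by
#' interpretable inclusion criteria (blocks answered 1 on its path) and
#' exclusion criteria (blocks answered 0).
#'
#' @name divclus
NULL

# weighted inertia of a set of binary columsums s with total weight n:
# sum_v n p_v (1 - p_v) = sum_v (s_v - s_v^2 / n)
inertia_from_counts <- function(s, n) {
  if (n <= 0) return(0)
  sum(s) - sum(s * s) / n
}

# gains of all single-variable splits for weighted binary vectors
# U: (sparse) 0/1 matrix, w: weights. Returns list(gain = numeric(D),
# counts s, crossprod C, n, inertia)
split_gains <- function(U, w) {
  n <- sum(w)
  C <- as.matrix(Matrix::crossprod(U, U * w))
  s <- diag(C)
  Ip <- inertia_from_counts(s, n)
  n1 <- s
  n0 <- n - s
  I1 <- colSums(C) - colSums(C * C) / ifelse(n1 > 0, n1, 1)
  S0 <- s - C  # column v: counts of each variable among the 0-branch
  I0 <- colSums(S0) - colSums(S0 * S0) / ifelse(n0 > 0, n0, 1)
  gain <- Ip - I1 - I0
  gain[n1 <= 0 | n0 <= 0] <- -Inf  # constant variables cannot split
  list(gain = gain, s = s, n = n, inertia = Ip)
}

#' Best single-variable split of a set of binary vectors
#'
#' Evaluates, for every variable, the decrease in within-cluster inertia
#' obtained by splitting the (weighted) vectors into the `0`- and
#' `1`-subsets on that variable, and returns the maximising variable. Ties
#' within `1e-12` are broken towards the lowest variable index. When all
#' vectors are identical (no variable splits), a no-split signal is
#' returned: `variable = NA`, `gain = 0`.
#'
#' @param x 0/1 matrix (rows = observations).
#' @param weights optional non-negative observation weights (multiplicity).
#' @return list with `variable` (1-based column index or `NA`), `gain`,
#'   and `inertia` (the parent's inertia).
#' @export
best_binary_split <- function(x, weights = NULL) {
  x <- as_binary_matrix(x)
  w <- weights %||% rep(1, nrow(x))
  if (length(w) != nrow(x)) config_error("weights must match nrow(x)")
  g <- split_gains(x, w)
  if (!any(is.finite(g$gain)) || max(g$gain) <= 1e-12)
    return(list(variable = NA_integer_, gain = 0, inertia = g$inertia))
  best <- max(g$gain)
  cand <- which(g$gain >= best - 1e-12)
  list(variable = cand[1L], gain = g$gain[cand[1L]], inertia = g$inertia)
}

as_binary_matrix <- function(x) {
  if (inherits(x, "health_states")) return(state_matrix(x))
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  if (!inherits(x, "Matrix")) config_error("x must be a matrix of 0/1 values")
  x
}

# collapse duplicate rows; returns list(U unique matrix, w counts,
# map row -> unique id)
weighted_unique <- function(x) {
  if (inherits(x, "health_states")) {
    w <- tabulate(x$index$vector_id, nbins = nrow(x$vectors))
    return(list(U = x$vectors, w = w, map = x$index$vector_id))
  }
  x <- as_binary_matrix(x)
  key <- apply(as.matrix(x), 1L, paste, collapse = "")
  uk <- unique(key)
  map <- match(key, uk)
  U <- x[match(uk, key), , drop = FALSE]
  list(U = U, w = as.numeric(tabulate(map, nbins = length(uk))), map = map)
}

#' Fit a monothetic divisive cluster model
#'
#' Starting from a single cluster containing every observed vector, the
#' algorithm repeatedly performs the (cluster, variable) split with the
#' largest achievable inertia gain until `K` clusters exist or no split
#' yields a positive gain. Ties within `1e-12` of the maximal gain are
#' broken towards the earliest-created leaf, then the lowest variable
#' index, making the fit deterministic. Duplicate vectors are weighted by
#' multiplicity rather than enumerated.
#'
#' Final cluster labels `0..K-1` order the leaves by the size of their
#' inclusion set and then lexicographically, so the leaf whose path answers
#' are all 0 -- the "healthy cluster" containing the all-zero vector -- is
#' always cluster 0.
#'
#' @param x a `health_states` object or 0/1 matrix.
#' @param K target number of clusters.
#' @return An object of class `divclus_model`: list with `tree`, `K`
#'   (achieved), `D`, `leaves` (per cluster: `include`, `exclude` as
#'   1-based variable indices), `inertia_trace` (total within inertia after
#'   0, 1, ... splits) and `underfull` (TRUE when fewer than `K` leaves
#'   were achievable, reported with a warning).
#' @export
fit_divclus <- function(x, K) {
  assert_count(K, "K")
  wu <- weighted_unique(x)
  U <- wu$U
  D <- ncol(U)

  new_leaf <- function(id, members, include, exclude) {
    sub <- U[members, , drop = FALSE]
    w <- wu$w[members]
    g <- split_gains(sub, w)
    usable <- is.finite(g$gain) & g$gain > 1e-12
    if (any(usable)) {
      best <- max(g$gain[usable])
      cand <- which(usable & g$gain >= best - 1e-12)
      bv <- cand[1L]
      bg <- g$gain[bv]
    } else {
      bv <- NA_integer_
      bg <- -Inf
    }
    list(id = id, members = members, include = include, exclude = exclude,
         inertia = g$inertia, best_var = bv, best_gain = bg)
  }

  leaves <- list(new_leaf(1L, seq_len(nrow(U)), integer(), integer()))
  splits <- list()  # records: id, var, child0, child1
  next_id <- 2L
  trace <- sum(vapply(leaves, `[[`, 0, "inertia"))
  while (length(leaves) < K) {
    gains <- vapply(leaves, `[[`, 0, "best_gain")
    if (!any(is.finite(gains)) || max(gains) <= 1e-12) break
    best <- max(gains)
    cand <- which(gains >= best - 1e-12)
    # tie rule: earliest-created leaf (lowest label); variable ties were
    # already resolved towards the lowest index inside each leaf
    ids <- vapply(leaves[cand], `[[`, 0L, "id")
    li <- cand[which.min(ids)]
    leaf <- leaves[[li]]
    v <- leaf$best_var
    on1 <- leaf$members[as.vector(U[leaf$members, v] == 1)]
    on0 <- setdiff(leaf$members, on1)
    c0 <- new_leaf(next_id, on0, leaf$include, sort(c(leaf$exclude, v)))
    c1 <- new_leaf(next_id + 1L, on1, sort(c(leaf$include, v)), leaf$exclude)
    splits[[length(splits) + 1L]] <-
      list(id = leaf$id, var = v, child0 = next_id, child1 = next_id + 1L)
    next_id <- next_id + 2L
    leaves[[li]] <- c0
    leaves[[length(leaves) + 1L]] <- c1
    trace <- c(trace, sum(vapply(leaves, `[[`, 0, "inertia")))
  }
  underfull <- length(leaves) < K
  if (underfull)
    warning("only ", length(leaves), " clusters achievable (requested ", K, ")")

  # final labels: by inclusion-set size, then lexicographic inclusion set
  ord <- order(vapply(leaves, function(l) length(l$include), 0L),
               vapply(leaves, function(l)
                 paste(sprintf("%05d", l$include), collapse = ","), ""),
               vapply(leaves, `[[`, 0L, "id"))
  leaves <- leaves[ord]
  label_of <- setNames(seq_along(leaves) - 1L,
                       vapply(leaves, `[[`, 0L, "id"))

  # rebuild nested tree from the split records
  split_by_id <- setNames(splits, vapply(splits, `[[`, 0L, "id"))
  build <- function(id) {
    sp <- split_by_id[[as.character(id)]]
    if (is.null(sp))
      return(list(leaf = TRUE, cluster = unname(label_of[as.character(id)])))
    list(leaf = FALSE, variable = sp$var,
         child0 = build(sp$child0), child1 = build(sp$child1))
  }
  model <- structure(list(
    tree = build(1L),
    K = length(leaves),
    D = D,
    leaves = lapply(leaves, function(l)
      list(cluster = unname(label_of[as.character(l$id)]),
           include = l$include, exclude = l$exclude,
           creation_id = l$id)),
    inertia_trace = trace,
    underfull = underfull
  ), class = "divclus_model")
  model
}

#' Assign binary vectors to clusters
#'
#' Descends the monothetic tree on the questioned variables. The returned
#' cluster's inclusion criteria are all 1 and its exclusion criteria all 0
#' in the assigned vector.
#'
#' @param x a `health_states` object or 0/1 matrix with `D` columns.
#' @param model a `divclus_model`.
#' @return Integer vector of cluster labels, one per row of `x` (per
#'   patient-year for `health_states` input).
#' @export
assign_clusters <- function(x, model) {
  is_hs <- inherits(x, "health_states")
  m <- if (is_hs) x$vectors else as_binary_matrix(x)
  if (ncol(m) != model$D)
    data_error("vector length ", ncol(m), " does not match model D = ", model$D)
  out <- integer(nrow(m))
  descend <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) {
      out[idx] <<- node$cluster
      return()
    }
    ones <- idx[as.vector(m[idx, node$variable] == 1)]
    descend(node$child1, ones)
    descend(node$child0, setdiff(idx, ones))
  }
  descend(model$tree, seq_len(nrow(m)))
  if (is_hs) out[x$index$vector_id] else out
}

#' Per patient-year cluster assignments
#'
#' Convenience wrapper joining [assign_clusters()] onto the health-state
#' index, producing the assignment table consumed by the transition,
#' trajectory and risk modules.
#'
#' @param hs a `health_states` object.
#' @param model a `divclus_model`.
#' @return `data.table` with columns
#'   `patient_id, year, sex, age, age_group, cluster`.
#' @export
assign_states <- function(hs, model) {
  out <- hs$index[, .(patient_id, year, sex, age, age_group)]
  out[, cluster := assign_clusters(hs, model)]
  out[]
}

#' Total within-cluster inertia of an assignment
#'
#' Sum over clusters of squared Euclidean distances of member vectors to
#' their cluster centroid.
#'
#' @param x a `health_states` object or 0/1 matrix.
#' @param assignment cluster label per row (per patient-year for
#'   `health_states`).
#' @return A single non-negative number.
#' @export
cluster_inertia <- function(x, assignment) {
  if (inherits(x, "health_states")) {
    m <- x$vectors
    rows_per <- x$index$vector_id
  } else {
    wu <- weighted_unique(x)
    m <- wu$U
    rows_per <- wu$map
  }
  if (length(assignment) != length(rows_per))
    data_error("assignment length does not match the number of observations")
  agg <- data.table::data.table(uid = rows_per,
                                cl = assignment)[, .N, by = .(uid, cl)]
  total <- 0
  for (lab in unique(agg$cl)) {
    sub <- agg[agg$cl == lab]
    s <- as.numeric(Matrix::crossprod(m[sub$uid, , drop = FALSE], sub$N))
    total <- total + inertia_from_counts(s, sum(sub$N))
  }
  total
}

#' Characterise fitted clusters
#'
#' Computes, per cluster, the number of assigned patient-years, sex counts,
#' mean age, yearly in-hospital mortality (fraction of assigned
#' patient-years that end in in-hospital death), and the per-block
#' prevalence vector. Prevalence is exactly 1 on inclusion criteria and 0
#' on exclusion criteria by construction.
#'
#' @param model a `divclus_model`.
#' @param hs a `health_states` object.
#' @param deaths `data.table(patient_id, death_year)`; defaults to
#'   `hs$deaths`.
#' @return `data.table` with one row per cluster (`cluster, size, n_male,
#'   n_female, mean_age, mortality, empty`); the per-block prevalence
#'   matrix (clusters x D) is attached as attribute `"prevalence"`.
#' @export
characterise_clusters <- function(model, hs, deaths = hs$deaths) {
  asg <- assign_states(hs, model)
  asg[deaths, death_year := i.death_year, on = "patient_id"]
  asg[, dies := !is.na(death_year) & year == death_year]
  prof <- asg[, .(size = .N,
                  n_male = sum(sex == "male"),
                  n_female = sum(sex == "female"),
                  mean_age = mean(age),
                  mortality = mean(dies)), by = cluster]
  all_cl <- data.table::data.table(cluster = 0:(model$K - 1L))
  prof <- prof[all_cl, on = "cluster"]
  prof[is.na(size), `:=`(size = 0L, n_male = 0L, n_female = 0L)]
  prof[, empty := size == 0L]
  data.table::setorder(prof, cluster)

  vid <- hs$index$vector_id
  cl <- assign_clusters(hs, model)
  dtw <- data.table::data.table(uid = vid, cl = cl)[, .N, by = .(uid, cl)]
  prev <- matrix(NA_real_, nrow = model$K, ncol = model$D)
  for (k in 0:(model$K - 1L)) {
    sub <- dtw[cl == k]
    if (nrow(sub) == 0L) next
    s <- as.numeric(Matrix::crossprod(hs$vectors[sub$uid, , drop = FALSE], sub$N))
    prev[k + 1L, ] <- s / sum(sub$N)
  }
  data.table::setattr(prof, "prevalence", prev)
  prof[]
}

#' Inertia diagnostic for the choice of K
#'
#' Compares the within-cluster inertia of the divisive sequence on the data
#' with the inertia obtained on null datasets in which every column is
#' independently permuted across observations -- destroying inter-block
#' correlations while preserving marginal prevalences. On data whose blocks
#' are genuinely correlated the real curve falls below the null band, and
#' the gap indicates how many clusters capture real structure.
#'
#' @param x a `health_states` object or 0/1 matrix.
#' @param k_grid increasing vector of cluster counts to report.
#' @param n_null number of permuted null datasets.
#' @param seed seed for the permutations.
#' @return `data.frame` with columns `k, inertia, null_mean, null_sd,
#'   null_lo, null_hi` (2.5/97.5 null percentiles).
#' @export
choose_k_diagnostic <- function(x, k_grid, n_null = 10L, seed = 1L) {
  if (is.unsorted(k_grid)) config_error("k_grid must be sorted ascending")
  m <- as.matrix(as_binary_matrix(x))
  kmax <- max(k_grid)
  trace_at <- function(mat) {
    fit <- suppressWarnings(fit_divclus(mat, kmax))
    tr <- fit$inertia_trace
    tr[pmin(k_grid, length(tr))]
  }
  real <- trace_at(m)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      perm <- apply(m, 2L, sample)
      trace_at(perm)
    }, numeric(length(k_grid)))
  })
  null <- matrix(null, nrow = length(k_grid))
  data.frame(k = k_grid,
             inertia = real,
             null_mean = rowMeans(null),
             null_sd = apply(null, 1L, sd),
             null_lo = apply(null, 1L, quantile, probs = 0.025),
             null_hi = apply(null, 1L, quantile, probs = 0.975))
}

#' Cluster definitions as a criteria table
#'
#' One row per (cluster, criterion): inclusion criteria are the blocks
#' answered 1 on the cluster's path, exclusion criteria those answered 0.
#'
#' @param model a `divclus_model`.
#' @param blocks optional `block_table` used to attach block ids/labels.
#' @return `data.table` with columns `cluster_id, criterion_type, block_id`
#'   (and `block_label` when `blocks` is given).
#' @export
cluster_definitions <- function(model, blocks = NULL) {
  rows <- lapply(model$leaves, function(l) {
    data.table::data.table(
      cluster_id = l$cluster,
      criterion_type = c(rep("include", length(l$include)),
                         rep("exclude", length(l$exclude))),
      variable = c(l$include, l$exclude))
  })
  out <- data.table::rbindlist(rows)
  out[, block_id := variable - 1L]
  if (!is.null(blocks))
    out[, block_label := blocks$label[match(block_id, blocks$block_id)]]
  out[, variable := NULL]
  data.table::setorder(out, cluster_id, criterion_type, block_id)
  out[]
}

#' Serialise / restore a cluster model
#'
#' @param model a `divclus_model`.
#' @param file path of the JSON file.
#' @export
write_cluster_model <- function(model, file) {
  jsonlite::write_json(unclass(model), file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  fix_node <- function(n) {
    if (isTRUE(n$leaf)) return(list(leaf = TRUE, cluster = as.integer(n$cluster)))
    list(leaf = FALSE, variable = as.integer(n$variable),
         child0 = fix_node(n$child0), child1 = fix_node(n$child1))
  }
  raw$tree <- fix_node(raw$tree)
  raw$K <- as.integer(raw$K)
  raw$D <- as.integer(raw$D)
  raw$leaves <- lapply(raw$leaves, function(l)
    list(cluster = as.integer(l$cluster),
         include = as.integer(unlist(l$include)),
         exclude = as.integer(unlist(l$exclude)),
         creation_id = as.integer(l$creation_id)))
  structure(raw, class = "divclus_model")
}

#' @export
print.divclus_model <- function(x, ...) {
  cat("<divclus_model> K = ", x$K, ", D = ", x$D,
      ", final within-inertia = ",
      format(tail(x$inertia_trace, 1L), digits = 6), "\n", sep = "")
  invisible(x)
}
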