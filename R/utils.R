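#' @import data.table
#' @importFrom stats rpois runif rbinom dhyper qnorm setNames aggregate quantile sd
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent error class so callers/tests can distinguish
# configuration problems from data problems
config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("mmtraj_config_error", "error")))
}

data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("mmtraj_data_error", "error")))
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    config_error(name, " must be a single integer >= ", min, " (got ", deparse(x), ")")
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    config_error(name, " must be a single number in [0, 1] (got ", deparse(x), ")")
  invisible(as.numeric(x))
}

#' Total-variation distance between two discrete distributions
#'
#' Distributions are given as named numeric vectors of probabilities (or
#' counts, which are normalised); the support is the union of the names.
#'
#' @param p,q named numeric vectors (probabilities or counts).
#' @return A single number in \[0, 1\].
#' @export
tv_distance <- function(p, q) {
  if (sum(p) <= 0 || sum(q) <= 0) return(NA_real_)
  p <- p / sum(p)
  q <- q / sum(q)
  supp <- union(names(p), names(q))
  pv <- setNames(numeric(length(supp)), supp)
  qv <- pv
  pv[names(p)] <- p
  qv[names(q)] <- q
  0.5 * sum(abs(pv - qv))
}

# 10-year age band label for an age in years ("0-9", ..., "100+")
age_band_10y <- function(age) {
  lo <- pmin(floor(age / 10), 10L) * 10L
  ifelse(lo >= 100, "100+", paste0(lo, "-", lo + 9L))
}

# 5-year age band label ("0-4", "5-9", ..., "100+")
age_band_5y <- function(age) {
  lo <- pmin(floor(age / 5), 20L) * 5L
  ifelse(lo >= 100, "100+", paste0(lo, "-", lo + 4L))
}

# lower bound (years) of a 5- or 10-year band label
band_lower <- function(band) {
  as.integer(sub("[-+].*$", "", band))
}

# band index 1..11 for the 10-year bands used in rate arrays
age_band_index <- function(age) {
  pmin(floor(age / 10), 10L) + 1L
}

AGE_BANDS_10Y <- c(paste0(seq(0, 90, 10), "-", seq(9, 99, 10)), "100+")
SEXES <- c("male", "female")
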