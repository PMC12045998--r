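#' Monte-Carlo propagation of calibration uncertainty
#'
#' Parameter estimates are treated as independent normal variables with
#' mean at the calibrated value and standard deviation equal to the
#' posterior sigma. Draws are propagated through the scaling model per
#' (crop, country) key; the first quartile, median and third quartile of
#' the resulting mass sample define the Low, Median and High scenarios.
#'
#' @name uncertainty_mc
NULL

#' Draw parameter realizations
#'
#' Independent normal draws per parameter; non-positive draws are rejected
#' and re-drawn (the scaling model needs positive factors, and rejection
#' keeps the sampling distribution unimodal, unlike clamping). A zero
#' sigma degenerates to the point estimate.
#'
#' @param result a `calibration_result`, or a list with elements `k_hat`
#'   and `sigma` (e.g. one entry of [load_reference_calibration()]).
#' @param n number of realizations (default 1000).
#' @param seed integer RNG seed; draws are reproducible given the seed.
#' @return `n` x 7 matrix, one realization per row.
#' @export
sample_parameters <- function(result, n = 1000, seed = 1L) {
  k <- as_parameters(result$k_hat)
  sig <- as_parameters(result$sigma)
  names(sig) <- parameter_names()
  if (anyNA(sig)) stop("sigma contains NA/NaN")
  if (any(sig < 0)) stop("sigma must be nonnegative")
  set.seed(seed)
  draws <- matrix(0, n, 7, dimnames = list(NULL, parameter_names()))
  for (j in seq_len(7)) {
    x <- stats::rnorm(n, k[j], sig[j])
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), k[j], sig[j])
    draws[, j] <- x
  }
  draws
}

#' Propagate parameter draws to mass realizations
#'
#' Evaluates the scaling model for every draw on every (crop, country) key
#' of the first-guess table; keys with non-positive first-guess mass are
#' skipped with a message.
#'
#' @param draws matrix from [sample_parameters()].
#' @param m_tilde first-guess `mass_table` (one major group).
#' @param regions named country -> region vector.
#' @return `n` x `n_keys` matrix of masses (kg); column names are
#'   `major_group|crop|country` keys.
#' @export
propagate <- function(draws, m_tilde, regions = load_regions()) {
  keep <- m_tilde$mass_kg > 0
  if (any(!keep))
    message(sum(!keep), " key(s) with non-positive first-guess mass skipped")
  tab <- m_tilde[keep, , drop = FALSE]
  if (!nrow(tab)) stop("no keys to propagate")
  region <- assign_region(tab$country, regions)
  out <- matrix(0, nrow(draws), nrow(tab),
                dimnames = list(NULL, mass_key(tab)))
  for (j in seq_len(nrow(tab))) {
    kc <- draws[, paste0("k_", calibration_crop(tab$crop[j]))]
    kl <- draws[, paste0("k_", region[j])]
    out[, j] <- kc * kl * tab$mass_kg[j]^draws[, "alpha"]
  }
  out
}

#' Scenario quartiles of the propagated sample
#'
#' Per key: Low = first quartile, Median = second, High = third, using the
#' linear-interpolation quantile estimator (R type 7), so results are
#' reproducible across implementations.
#'
#' @param samples matrix from [propagate()] (>= 4 realizations).
#' @param seed seed recorded in the output metadata.
#' @return `scenario_mass_table`: data frame (`major_group`, `crop`,
#'   `country`, `m_low`, `m_median`, `m_high`) with attributes
#'   `n_realizations` and `seed`.
#' @export
scenario_quartiles <- function(samples, seed = NA_integer_) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1,
                                               dimnames = list(NULL, colnames(samples)))
  if (nrow(samples) < 4) stop("need at least 4 realizations")
  q <- apply(samples, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
             names = FALSE, type = 7)
  parts <- do.call(rbind, strsplit(colnames(samples), "|", fixed = TRUE))
  out <- data.frame(major_group = parts[, 1], crop = parts[, 2],
                    country = parts[, 3],
                    m_low = q[1, ], m_median = q[2, ], m_high = q[3, ],
                    stringsAsFactors = FALSE)
  out <- out[order(out$major_group, out$crop, out$country), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_realizations") <- nrow(samples)
  attr(out, "seed") <- seed
  class(out) <- c("scenario_mass_table", class(out))
  out
}

#' Monte-Carlo convergence check
#'
#' Relative variation of the three scenario statistics (Q1, median, Q3)
#' between successive checkpoint sample sizes,
#' `|stat(n_k) - stat(n_{k-1})| / stat(n_{k-1})`. For a matrix of samples
#' the check is applied per key and to the aggregate (the per-realization
#' total over keys). A sample size is considered sufficient when the
#' maximum variation is below 0.05 (5%).
#'
#' @param samples numeric vector of mass realizations, or a matrix from
#'   [propagate()].
#' @param checkpoints increasing sample sizes, all <= the number of
#'   realizations (default `c(250, 500, 1000)` truncated to the sample).
#' @return for a vector: the maximum relative variation, with attribute
#'   `by_statistic`. For a matrix: list with `per_key` (named vector of
#'   per-key maxima), `aggregate` (variation of the summed mass) and
#'   `max` (overall maximum).
#' @export
convergence_check <- function(samples, checkpoints = c(250, 500, 1000)) {
  if (!is.null(dim(samples))) {
    per_key <- apply(samples, 2, convergence_check, checkpoints = checkpoints)
    agg <- convergence_check(rowSums(samples), checkpoints = checkpoints)
    return(list(per_key = per_key, aggregate = as.numeric(agg),
                max = max(per_key, agg)))
  }
  checkpoints <- sort(unique(checkpoints[checkpoints <= length(samples)]))
  if (length(checkpoints) < 2) stop("need at least two usable checkpoints")
  stat <- vapply(checkpoints, function(n)
    stats::quantile(samples[seq_len(n)], c(0.25, 0.5, 0.75), names = FALSE,
                    type = 7), numeric(3))
  if (any(stat[, -ncol(stat)] == 0))
    stop("relative variation undefined: a checkpoint statistic is zero")
  rel <- abs(stat[, -1, drop = FALSE] - stat[, -ncol(stat), drop = FALSE]) /
    abs(stat[, -ncol(stat), drop = FALSE])
  structure(max(rel),
            by_statistic = stats::setNames(apply(rel, 1, max),
                                           c("Q1", "median", "Q3")))
}
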