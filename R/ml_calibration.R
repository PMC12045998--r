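#' Scaling-model parameters
#'
#' The applied-mass scaling model adjusts the first-guess mass per
#' (crop, country) as
#' \deqn{m = k_C(crop) \cdot k_L(region) \cdot \tilde m^{\alpha}}
#' with one multiplicative factor per calibration crop class (Corn, Wheat,
#' AOC), one per European region (SEU, CEU, NEU) and a power `alpha`
#' shared by all keys. All seven parameters are strictly positive.
#'
#' @param k_Corn,k_Wheat,k_AOC crop factors.
#' @param k_SEU,k_CEU,k_NEU region factors.
#' @param alpha power on the first-guess mass.
#' @return named numeric vector of class `scaling_parameters`.
#' @export
scaling_parameters <- function(k_Corn = 1, k_Wheat = 1, k_AOC = 1,
                               k_SEU = 1, k_CEU = 1, k_NEU = 1, alpha = 1) {
  p <- c(k_Corn = k_Corn, k_Wheat = k_Wheat, k_AOC = k_AOC,
         k_SEU = k_SEU, k_CEU = k_CEU, k_NEU = k_NEU, alpha = alpha)
  if (!all(is.finite(p)) || any(p <= 0))
    stop("all scaling parameters must be finite and strictly positive")
  structure(p, class = "scaling_parameters")
}

#' @rdname scaling_parameters
#' @export
parameter_names <- function() c("k_Corn", "k_Wheat", "k_AOC",
                                "k_SEU", "k_CEU", "k_NEU", "alpha")

as_parameters <- function(x) {
  if (!is.numeric(x) || length(x) != 7L) stop("expected a 7-parameter vector")
  stats::setNames(as.numeric(x), parameter_names())
}

#' Evaluate the scaling model
#'
#' @param p [scaling_parameters] (or any named 7-vector in the same order).
#' @param crop calibration crop class, in {Corn, Wheat, AOC} (vectorized).
#' @param country country name (vectorized).
#' @param m_tilde strictly positive first-guess mass in kg (vectorized).
#' @param regions named country -> region vector from [load_regions()].
#' @return scaled mass in kg.
#' @export
scaled_mass <- function(p, crop, country, m_tilde, regions = load_regions()) {
  p <- as_parameters(p)
  if (any(m_tilde <= 0)) stop("m_tilde must be strictly positive")
  if (!all(crop %in% c("Corn", "Wheat", "AOC")))
    stop("crop must be one of Corn, Wheat, AOC")
  k_c <- p[paste0("k_", crop)]
  k_l <- p[paste0("k_", assign_region(country, regions))]
  unname(k_c * k_l * m_tilde^p["alpha"])
}

# Align first-guess and reference tables on shared keys with positive mass.
# Returns the design pieces needed by the objective and its Jacobian.
calibration_data <- function(m_tilde, m_star, regions) {
  kt <- paste(m_tilde$crop, m_tilde$country, sep = "|")
  ks <- paste(m_star$crop, m_star$country, sep = "|")
  common <- intersect(kt, ks)
  it <- match(common, kt)
  is_ <- match(common, ks)
  ok <- m_tilde$mass_kg[it] > 0 & m_star$mass_kg[is_] > 0
  n_skipped <- (length(kt) - sum(ok)) + (length(ks) - sum(ok))
  if (!any(ok)) stop("no overlapping (crop, country) keys with positive mass")
  list(crop = m_tilde$crop[it][ok],
       country = m_tilde$country[it][ok],
       region = assign_region(m_tilde$country[it][ok], regions),
       t = log10(m_tilde$mass_kg[it][ok]),
       y = log10(m_star$mass_kg[is_][ok]),
       n_skipped = n_skipped)
}

obj_from_data <- function(p, d) {
  p <- as_parameters(p)
  model <- log10(p[paste0("k_", d$crop)]) + log10(p[paste0("k_", d$region)]) +
    p["alpha"] * d$t
  sum((d$y - unname(model))^2)
}

grad_from_data <- function(p, d) {
  p <- as_parameters(p)
  model <- log10(p[paste0("k_", d$crop)]) + log10(p[paste0("k_", d$region)]) +
    p["alpha"] * d$t
  r <- d$y - unname(model)
  g <- numeric(7)
  names(g) <- parameter_names()
  for (cl in c("Corn", "Wheat", "AOC")) {
    i <- d$crop == cl
    g[paste0("k_", cl)] <- -2 * sum(r[i]) / (p[paste0("k_", cl)] * log(10))
  }
  for (rg in c("SEU", "CEU", "NEU")) {
    i <- d$region == rg
    g[paste0("k_", rg)] <- -2 * sum(r[i]) / (p[paste0("k_", rg)] * log(10))
  }
  g["alpha"] <- -2 * sum(r * d$t)
  g
}

# Jacobian of the log10 model w.r.t. the parameters at p (n x 7)
model_jacobian <- function(p, d) {
  p <- as_parameters(p)
  n <- length(d$y)
  G <- matrix(0, n, 7, dimnames = list(NULL, parameter_names()))
  for (cl in c("Corn", "Wheat", "AOC"))
    G[d$crop == cl, paste0("k_", cl)] <- 1 / (p[paste0("k_", cl)] * log(10))
  for (rg in c("SEU", "CEU", "NEU"))
    G[d$region == rg, paste0("k_", rg)] <- 1 / (p[paste0("k_", rg)] * log(10))
  G[, "alpha"] <- d$t
  G
}

#' Calibration objective
#'
#' Sum of squared log10 residuals between reference and scaled masses over
#' the (crop, country) keys present in both tables with positive mass;
#' keys missing from either table are skipped (their count is attached as
#' attribute `n_skipped`). Log mass is used because applied masses span
#' several orders of magnitude across countries.
#'
#' @param p [scaling_parameters].
#' @param m_tilde first-guess `mass_table` (one major group).
#' @param m_star reference `mass_table` (same major group).
#' @param regions named country -> region vector.
#' @return the objective value J (>= 0).
#' @export
objective <- function(p, m_tilde, m_star, regions = load_regions()) {
  d <- calibration_data(m_tilde, m_star, regions)
  structure(obj_from_data(p, d), n_skipped = d$n_skipped)
}

#' Maximum-likelihood calibration of the scaling model
#'
#' Minimizes the log10 least-squares objective with a bounded quasi-Newton
#' search (L-BFGS-B with analytic gradient) from the all-ones start, i.e.
#' taking the first-guess mass as the initial solution. The crop/region
#' factor split is not identifiable (multiplying all crop factors and
#' dividing all region factors by the same constant leaves the model
#' unchanged); only the products k_C*k_L and alpha are determined by the
#' data, and the reported parameters are the point the bounded search
#' converges to. Posterior standard deviations come from a Gauss-Newton
#' linearization at the optimum and the NLL from the Gaussian likelihood
#' with maximum-likelihood residual variance.
#'
#' @inheritParams objective
#' @param k_bounds bounds for every multiplicative factor (default
#'   `c(1e-3, 1e3)`).
#' @param alpha_bounds bounds for the power (default `c(0.1, 2)`).
#' @param factr L-BFGS-B convergence factor (objective tolerance
#'   `factr * .Machine$double.eps`; the default targets ~1e-10 on J).
#' @return a `calibration_result`: list with `k_hat`, `sigma`,
#'   `covariance`, `J_min`, `NLL`, `n_obs`, `n_skipped`, `fitted`
#'   (mass_table role "fitted"), `convergence`, `jacobian`.
#' @export
calibrate <- function(m_tilde, m_star, regions = load_regions(),
                      k_bounds = c(1e-3, 1e3), alpha_bounds = c(0.1, 2),
                      factr = 1e-10 / .Machine$double.eps) {
  d <- calibration_data(m_tilde, m_star, regions)
  lower <- c(rep(k_bounds[1], 6), alpha_bounds[1])
  upper <- c(rep(k_bounds[2], 6), alpha_bounds[2])
  fit <- stats::optim(
    par = rep(1, 7),
    fn = function(par) obj_from_data(par, d),
    gr = function(par) grad_from_data(par, d),
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(factr = factr, maxit = 1000L)
  )
  if (fit$convergence != 0 && fit$convergence != 52)
    stop("optimizer failed (code ", fit$convergence, "): ", fit$message)
  k_hat <- do.call(scaling_parameters, as.list(as_parameters(fit$par)))
  G <- model_jacobian(k_hat, d)
  n <- length(d$y)
  post <- if (n > ncol(G)) posterior_sigma(G, fit$value, n) else
    list(sigma = rep(NA_real_, 7), covariance = matrix(NA_real_, 7, 7))
  mg <- unique(m_tilde$major_group)
  m_hat <- scaled_mass(k_hat, d$crop, d$country,
                       10^d$t, regions)
  structure(list(
    k_hat = k_hat,
    sigma = stats::setNames(post$sigma, parameter_names()),
    covariance = post$covariance,
    J_min = fit$value,
    NLL = negative_log_likelihood(fit$value, n),
    n_obs = n,
    n_skipped = d$n_skipped,
    fitted = mass_table(rep(mg[1], n), d$crop, d$country, m_hat, role = "fitted"),
    convergence = fit$convergence,
    jacobian = G
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  est <- rbind(estimate = unclass(x$k_hat), sigma = x$sigma)
  print(round(est, 4))
  cat(sprintf("J_min = %.4g  NLL = %.4g  n_obs = %d (skipped %d)\n",
              x$J_min, x$NLL, x$n_obs, x$n_skipped))
  invisible(x)
}

#' Gauss-Newton posterior standard deviations
#'
#' With G the Jacobian of the log10-model predictions with respect to the
#' parameters at the optimum and s^2 = J_min / (n_obs - p) the unbiased
#' residual variance, the posterior covariance is s^2 (G'G)^-1 and sigma
#' its diagonal square root. For the full 7-parameter model G'G is rank
#' deficient by one (the crop/region gauge direction), in which case the
#' Moore-Penrose pseudo-inverse is used and a warning emitted.
#'
#' @param G n x p Jacobian matrix, or a `calibration_result` (in which case
#'   the remaining arguments are taken from it).
#' @param J_min objective value at the optimum.
#' @param n_obs number of observations (> p required).
#' @return list with `sigma` (length p) and `covariance` (p x p).
#' @export
posterior_sigma <- function(G, J_min = NULL, n_obs = NULL) {
  if (inherits(G, "calibration_result")) {
    J_min <- G$J_min; n_obs <- G$n_obs; G <- G$jacobian
  }
  p <- ncol(G)
  if (n_obs <= p) stop("need more observations than parameters (n_obs > ", p, ")")
  s2 <- J_min / (n_obs - p)
  gtg <- crossprod(G)
  inv <- tryCatch({
    if (rcond(gtg) < 1e-12) stop("near-singular")
    solve(gtg)
  }, error = function(e) {
    warning("G'G is singular (non-identifiable direction); using pseudo-inverse")
    MASS::ginv(gtg)
  })
  cov <- s2 * inv
  list(sigma = sqrt(pmax(diag(cov), 0)), covariance = cov)
}

#' Gaussian negative log-likelihood at the optimum
#'
#' Under independent Gaussian log10 residuals, profiling out the variance
#' at its maximum-likelihood value `J_min / n_obs` gives
#' `NLL = (n/2) (ln(2 pi J_min / n) + 1)`. A perfect fit (`J_min = 0`)
#' returns `-Inf` as a documented sentinel.
#'
#' @param J_min objective value at the optimum.
#' @param n_obs number of observations.
#' @return the NLL (lower means higher fidelity to the reference data).
#' @export
negative_log_likelihood <- function(J_min, n_obs) {
  if (n_obs <= 0) stop("n_obs must be positive")
  if (J_min < 0) stop("J_min must be nonnegative")
  if (J_min == 0) return(-Inf)
  (n_obs / 2) * (log(2 * pi * J_min / n_obs) + 1)
}
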