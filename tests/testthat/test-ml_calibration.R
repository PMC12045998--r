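test_that("the scaling model evaluates as k_C * k_L * m^alpha", {
  # identity parameters leave the first guess unchanged
  expect_equal(scaled_mass(scaling_parameters(), "Corn", "Italy", 1234), 1234)
  # direct product
  p <- scaling_parameters(k_Corn = 2, k_SEU = 3)
  expect_equal(scaled_mass(p, "Corn", "Italy", 1e4), 6e4)
  # independent hand evaluation with the published herbicide estimates
  ref <- load_reference_calibration()$H$k_hat
  expect_equal(scaled_mass(ref, "Wheat", "Italy", 1e5),
               1.900 * 1.065 * 10^(5 * 0.906))
  expect_error(scaled_mass(p, "Corn", "Italy", 0), "positive")
  expect_error(scaling_parameters(k_Corn = -1), "positive")
})

test_that("the objective is the sum of squared log10 residuals over shared keys", {
  regions <- load_regions()
  mt <- mass_table(rep("H", 2), c("Corn", "Wheat"), c("Italy", "France"),
                   c(1e4, 1e5))
  # perfect fit
  ms <- mass_table(rep("H", 2), c("Corn", "Wheat"), c("Italy", "France"),
                   mt$mass_kg, role = "reference")
  expect_equal(as.numeric(objective(scaling_parameters(), mt, ms, regions)), 0)
  # one key, one decade off: J = 1
  ms1 <- mass_table("H", "Corn", "Italy", 1e5, role = "reference")
  expect_equal(as.numeric(objective(scaling_parameters(), mt, ms1, regions)), 1,
               tolerance = 1e-12)
  expect_equal(attr(objective(scaling_parameters(), mt, ms1, regions),
                    "n_skipped"), 1)

  # 12-key random fixture vs term-by-term accumulation
  set.seed(17)
  countries <- names(regions)[seq(1, 23, 2)]
  mt12 <- mass_table(rep("H", 12), rep(c("Corn", "Wheat", "AOC"), 4),
                     countries, 10^stats::runif(12, 3, 6))
  ms12 <- mass_table(rep("H", 12), rep(c("Corn", "Wheat", "AOC"), 4),
                     countries, 10^stats::runif(12, 3, 6), role = "reference")
  p <- scaling_parameters(1.3, 0.8, 2.1, 0.6, 1.7, 1.1, 0.95)
  acc <- 0
  for (i in seq_len(12)) {
    m <- scaled_mass(p, ms12$crop[i], ms12$country[i],
                     mt12$mass_kg[match(mass_key_strings(ms12)[i],
                                        mass_key_strings(mt12))])
    acc <- acc + (log10(ms12$mass_kg[i]) - log10(m))^2
  }
  expect_equal(as.numeric(objective(p, mt12, ms12, regions)), acc,
               tolerance = 1e-12)
  expect_error(objective(p, mt12, mass_table("F", "Corn", "Italy", 1,
                                             role = "reference"), regions),
               "no overlapping")
})

test_that("calibration from the all-ones start recovers identifiable combinations", {
  tax <- load_taxonomy()
  mt <- panel_first_guess("H")

  # truth = all ones, zero noise: optimum at the start point
  ones <- list(H = scaling_parameters())
  g0 <- gen_reference_masses(tiny_scenario(noise_sd_log10 = 0,
                                           truth_params = ones), mt)
  fit0 <- suppressWarnings(calibrate(mt, g0$reference))
  expect_lt(max(abs(kl_products(fit0$k_hat) - 1)), 1e-3)
  expect_lt(abs(fit0$k_hat["alpha"] - 1), 1e-3)

  # distinct truth, zero noise: products and alpha recovered within 1e-3
  truth <- scaling_parameters(0.542, 1.9, 2.746, 1.065, 1.15, 2.364, 0.906)
  g1 <- gen_reference_masses(tiny_scenario(noise_sd_log10 = 0,
                                           truth_params = list(H = truth)), mt)
  fit1 <- suppressWarnings(calibrate(mt, g1$reference))
  expect_lt(max(abs(kl_products(fit1$k_hat) - kl_products(truth))), 1e-3)
  expect_lt(abs(fit1$k_hat["alpha"] - truth["alpha"]), 1e-3)
  expect_equal(fit1$n_obs, nrow(mt))
  # J at the optimum never exceeds the first-guess misfit
  expect_lte(fit1$J_min,
             as.numeric(objective(scaling_parameters(), mt, g1$reference)))
  # fitted masses reproduce the model at k_hat
  i <- 5
  expect_equal(fit1$fitted$mass_kg[i],
               scaled_mass(fit1$k_hat, fit1$fitted$crop[i],
                           fit1$fitted$country[i],
                           mt$mass_kg[match(mass_key_strings(fit1$fitted)[i],
                                            mass_key_strings(mt))]))
})

test_that("the crop/region split is a gauge freedom of the model", {
  mt <- panel_first_guess("H")
  g <- gen_reference_masses(tiny_scenario(noise_sd_log10 = 0.1), mt)
  regions <- load_regions()
  p <- scaling_parameters(1.3, 0.8, 2.1, 0.6, 1.7, 1.1, 0.95)
  for (c_scale in c(0.5, 2, 7)) {
    q <- scaling_parameters(1.3 * c_scale, 0.8 * c_scale, 2.1 * c_scale,
                            0.6 / c_scale, 1.7 / c_scale, 1.1 / c_scale, 0.95)
    expect_equal(as.numeric(objective(p, mt, g$reference, regions)),
                 as.numeric(objective(q, mt, g$reference, regions)),
                 tolerance = 1e-10)
  }
})

test_that("a reduced problem agrees with an exhaustive grid search", {
  # single crop and region: only the product k_Corn*k_SEU and alpha matter
  set.seed(12)
  countries <- c("Italy", "Spain", "France", "Greece", "Portugal", "Malta",
                 "Cyprus", "Bulgaria")
  mt <- mass_table(rep("H", 8), rep("Corn", 8), countries, 10^runif(8, 3, 6))
  truth <- scaling_parameters(k_Corn = 1.8, k_SEU = 1.2, alpha = 0.9)
  ms <- mass_table(mt$major_group, mt$crop, mt$country,
                   scaled_mass(truth, mt$crop, mt$country, mt$mass_kg),
                   role = "reference")
  fit <- suppressWarnings(calibrate(mt, ms))

  # oracle: dense grid over (product, alpha)
  grid_p <- seq(1.5, 3, by = 0.005)
  grid_a <- seq(0.8, 1.0, by = 0.001)
  t <- log10(mt$mass_kg); y <- log10(ms$mass_kg)
  J <- outer(grid_p, grid_a, function(pp, aa)
    vapply(seq_along(pp), function(i) sum((y - log10(pp[i]) - aa[i] * t)^2), 0))
  best <- arrayInd(which.min(J), dim(J))
  expect_lt(abs(fit$k_hat["k_Corn"] * fit$k_hat["k_SEU"] -
                  grid_p[best[1]]), 0.005 + 1e-9)
  expect_lt(abs(fit$k_hat["alpha"] - grid_a[best[2]]), 0.001 + 1e-9)
  expect_lte(fit$J_min, min(J) + 1e-9)
})

test_that("posterior sigma follows the Gauss-Newton formula", {
  # reduced single-parameter model: regression through the origin in log10
  # space, sigma_alpha = s / sqrt(sum t^2)
  t <- c(3, 4.5, 6)
  y <- c(2.8, 4.9, 5.6)
  alpha_hat <- sum(t * y) / sum(t * t)
  J_min <- sum((y - alpha_hat * t)^2)
  G <- matrix(t, ncol = 1)
  ps <- posterior_sigma(G, J_min, 3)
  expect_equal(ps$sigma, sqrt(J_min / (3 - 1) / sum(t^2)))

  # doubling every residual doubles sigma
  ps2 <- posterior_sigma(G, 4 * J_min, 3)
  expect_equal(ps2$sigma, 2 * ps$sigma)

  # full model: zero-noise fit has machine-scale sigma, and the gauge
  # direction makes G'G singular (pseudo-inverse warning)
  mt <- panel_first_guess("H")
  g <- gen_reference_masses(tiny_scenario(noise_sd_log10 = 0), mt)
  expect_warning(fit <- calibrate(mt, g$reference), "singular|pseudo")
  expect_true(all(fit$sigma < 1e-4))
  expect_true(all(eigen(fit$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  expect_error(posterior_sigma(G, J_min, 1), "more observations")
})

test_that("the profiled Gaussian NLL has its closed form and monotonicity", {
  # constructed zero: sigma2_ML = 1/(2 pi e)
  expect_equal(negative_log_likelihood(2 / (2 * pi * exp(1)), 2), 0,
               tolerance = 1e-12)
  # strictly increasing in J at fixed n
  J <- seq(0.5, 20, length.out = 30)
  nll <- vapply(J, negative_log_likelihood, 0, n_obs = 10)
  expect_true(all(diff(nll) > 0))
  # random grid vs direct formula evaluation
  set.seed(4)
  for (i in 1:20) {
    n <- sample(3:100, 1)
    Ji <- stats::runif(1, 1e-3, 50)
    expect_equal(negative_log_likelihood(Ji, n),
                 n / 2 * (log(2 * pi * Ji / n) + 1))
  }
  expect_identical(negative_log_likelihood(0, 5), -Inf)
})
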