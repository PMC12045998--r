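# Shared desk-scale fixtures, all built in code.

# Small raster scenario: 4 SEU countries, 100x100 fine grid at 50 m,
# upscaled x5 to 250 m cells (6.25 ha), low noise, no sparsity.
tiny_scenario <- function(seed = 42L, ...) {
  args <- list(seed = seed, grid_shape = c(100L, 100L), upscale_factor = 5L,
               cell_size_fine = 50, n_countries = 4L,
               noise_sd_log10 = 0.05, sparsity = 0)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_scenario, args)
}

# Full-panel first-guess mass table: 3 crops x all fixture countries for
# one major group, masses spanning several decades.
panel_first_guess <- function(mg = "H", seed = 99L) {
  countries <- names(load_regions())
  n <- 3L * length(countries)
  set.seed(seed)
  mass_table(rep(mg, n),
             rep(c("Corn", "Wheat", "AOC"), each = length(countries)),
             rep(countries, 3), 10^stats::runif(n, 4, 7))
}

mass_key_strings <- function(tab) {
  paste(tab$major_group, tab$crop, tab$country, sep = "|")
}

# k_C * k_L products over all (crop, region) combinations of a 7-vector
kl_products <- function(p) {
  p <- stats::setNames(as.numeric(p), parameter_names())
  outer(p[c("k_Corn", "k_Wheat", "k_AOC")], p[c("k_SEU", "k_CEU", "k_NEU")])
}

expect_raster_equal <- function(a, b, tolerance = 0) {
  expect_equal(a$values, b$values, tolerance = tolerance)
  expect_equal(c(a$xmin, a$ymax, a$cellsize), c(b$xmin, b$ymax, b$cellsize))
  expect_identical(a$crs, b$crs)
}

# run the tiny scenario end to end once per session and cache the outputs
pipeline_fixture <- local({
  cache <- NULL
  function(noise = 0.05, seed = 42L) {
    key <- paste(noise, seed)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    s <- tiny_scenario(seed = seed, grid_shape = c(150L, 150L),
                       n_countries = 8L, noise_sd_log10 = noise)
    out <- file.path(tempfile("pipe"), "run")
    man <- suppressMessages(run_pipeline(s, out, mc_n = 400, threshold_kg = 1))
    value <- list(scenario = s, out = out, manifest = man)
    cache <<- list(key = key, value = value)
    value
  }
})
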