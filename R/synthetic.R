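#' Synthetic pipeline inputs with known ground truth
#'
#' Generates every input the pipeline consumes — co-registered fine crop
#' and land-cover rasters, a country partition, coarse first-guess rate
#' grids, authorizations and chemical-class-level reference mass records —
#' with the statistical structure the analysis assumes, so all stages run
#' at desk scale and parameter recovery can be tested against the known
#' generating parameters.
#'
#' @param seed integer master seed; every generated artefact derives its
#'   RNG stream from it, so the whole bundle is reproducible.
#' @param grid_shape (rows, cols) of the fine crop raster.
#' @param upscale_factor block size of the modal upscaling (25 in
#'   production: 10 m to 250 m).
#' @param cell_size_fine fine cell edge in metres (10 in production).
#' @param n_countries number of contiguous axis-aligned country blocks.
#' @param class_probabilities named vector of fused-map code frequencies
#'   (must sum to 1); the default mirrors the continental surface-area
#'   shares of the major classes plus woodland/grassland shares that
#'   exercise the land-cover fusion rules.
#' @param ai_list ingredient names (subset of the shipped taxonomy) to
#'   generate rate grids for; the default covers one ingredient per major
#'   group applicable to all or several crops.
#' @param apr_mean,apr_cv mean (kg/ha) and coefficient of variation of the
#'   log-normal coarse application rates.
#' @param truth_params list of [scaling_parameters] per major group used
#'   to generate reference masses; defaults to the published 2018 EU
#'   estimates ([load_reference_calibration()]).
#' @param noise_sd_log10 s.d. of the multiplicative log10-normal noise on
#'   reference masses.
#' @param sparsity fraction of (crop, country) reference keys dropped.
#' @param years reporting years of the reference records.
#' @param countries country names; default takes the first `n_countries`
#'   entries of the shipped region fixture.
#' @return a `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1L,
                               grid_shape = c(500L, 500L),
                               upscale_factor = 25L,
                               cell_size_fine = 10,
                               n_countries = 27L,
                               class_probabilities = NULL,
                               ai_list = c("Glyphosate", "Azoxystrobin", "Chlorpyrifos"),
                               apr_mean = 1, apr_cv = 0.5,
                               truth_params = NULL,
                               noise_sd_log10 = 0.2,
                               sparsity = 0.3,
                               years = 2015:2020,
                               countries = NULL) {
  if (is.null(class_probabilities))
    class_probabilities <- c(
      "211" = 0.20, "212" = 0.02, "213" = 0.08, "216" = 0.14, "217" = 0.01,
      "221" = 0.01, "232" = 0.05, "233" = 0.02, "240" = 0.01, "290" = 0.03,
      "350" = 0.06, "510" = 0.15, "300" = 0.11, "500" = 0.11
    )
  if (abs(sum(class_probabilities) - 1) > 1e-8)
    stop("class probabilities must sum to 1")
  if (upscale_factor < 1) stop("upscale_factor must be >= 1")
  if (noise_sd_log10 < 0) stop("noise_sd_log10 must be nonnegative")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  if (apr_mean <= 0) stop("apr_mean must be positive")
  if (is.null(countries)) {
    pool <- names(load_regions())
    if (n_countries > length(pool))
      stop("at most ", length(pool), " countries available")
    countries <- pool[seq_len(n_countries)]
  }
  if (is.null(truth_params)) {
    ref <- load_reference_calibration()
    truth_params <- lapply(ref, `[[`, "k_hat")
  }
  structure(list(
    seed = as.integer(seed), grid_shape = as.integer(grid_shape),
    upscale_factor = as.integer(upscale_factor),
    cell_size_fine = cell_size_fine, n_countries = as.integer(n_countries),
    class_probabilities = class_probabilities, ai_list = ai_list,
    apr_mean = apr_mean, apr_cv = apr_cv, truth_params = truth_params,
    noise_sd_log10 = noise_sd_log10, sparsity = sparsity, years = years,
    countries = countries
  ), class = "synthetic_scenario")
}

# deterministic per-stage seed below 2^31, derived from the master seed
stage_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Generate the crop, land-cover and country rasters
#'
#' The fine crop raster draws codes independently with the scenario's
#' class frequencies. The land-cover raster agrees with a generic arable
#' background except for planted disagreement patches that exercise the
#' three fusion rules: rice fields dropped anywhere (1% of pixels), and
#' vineyard/orchard/olive resp. pasture overlays on half of the
#' woodland/shrubland resp. grassland pixels. Countries are contiguous
#' axis-aligned blocks partitioning the grid.
#'
#' @param s a [synthetic_scenario].
#' @return list with `fine`, `corine` ([apr_raster]s), `countries`
#'   (country-ID [apr_raster]) and `country_table` (`id`, `country`).
#' @export
gen_crop_raster <- function(s) {
  nr <- s$grid_shape[1]; nc <- s$grid_shape[2]
  n <- nr * nc
  codes <- as.numeric(names(s$class_probabilities))
  set.seed(stage_seed(s$seed, "crop"))
  fine <- matrix(codes[sample.int(length(codes), n, replace = TRUE,
                                  prob = s$class_probabilities)],
                 nr, nc)
  corine <- matrix(211, nr, nc)            # generic non-irrigated arable land
  rice <- stats::runif(n) < 0.01
  corine[rice] <- fusion_codes$corine["rice_fields"]
  wood <- !rice & fine == fusion_codes$eucm["woodland_shrubland"] &
    stats::runif(n) < 0.5
  corine[wood] <- sample(fusion_codes$corine[c("vineyards", "fruit_trees_berries",
                                               "olive_groves")],
                         sum(wood), replace = TRUE)
  grass <- !rice & fine == fusion_codes$eucm["grasslands"] & stats::runif(n) < 0.5
  corine[grass] <- fusion_codes$corine["pastures"]

  # country partition: bands of rows, each band split into column blocks
  k <- s$n_countries
  bands <- max(1L, floor(sqrt(k)))
  per_band <- diff(round(seq(0, k, length.out = bands + 1)))
  if (any(per_band == 0)) stop("cannot place ", k, " countries in ", bands, " bands")
  row_edges <- round(seq(0, nr, length.out = bands + 1))
  ids <- matrix(0L, nr, nc)
  next_id <- 1L
  for (b in seq_len(bands)) {
    col_edges <- round(seq(0, nc, length.out = per_band[b] + 1))
    if (row_edges[b + 1] <= row_edges[b] || any(diff(col_edges) < 1))
      stop("zero-area country block; enlarge the grid or reduce n_countries")
    rows <- (row_edges[b] + 1):row_edges[b + 1]
    for (cb in seq_len(per_band[b])) {
      cols <- (col_edges[cb] + 1):col_edges[cb + 1]
      ids[rows, cols] <- next_id
      next_id <- next_id + 1L
    }
  }
  cs <- s$cell_size_fine
  geo <- function(v) apr_raster(v, xmin = 0, ymax = nr * cs, cellsize = cs)
  list(fine = geo(fine), corine = geo(corine), countries = geo(ids),
       country_table = data.frame(id = seq_len(k), country = s$countries,
                                  stringsAsFactors = FALSE))
}

#' Generate a coarse first-guess rate grid
#'
#' Log-normal rates with mean `apr_mean` and coefficient of variation
#' `apr_cv` on a grid substantially coarser than the upscaled crop grid,
#' offset from the fine grid's origin so nearest-neighbour projection is
#' nontrivial. A zero CV gives a constant grid.
#'
#' @param s a [synthetic_scenario].
#' @param ai,crop tags entering the RNG stream (distinct grids per
#'   ingredient and crop).
#' @return coarse [apr_raster] (kg/ha), all values positive.
#' @export
gen_coarse_apr <- function(s, ai = s$ai_list[1], crop = "ALL") {
  if (s$apr_mean <= 0) stop("apr_mean must be positive")
  cs_fine <- s$cell_size_fine
  extent_x <- s$grid_shape[2] * cs_fine
  extent_y <- s$grid_shape[1] * cs_fine
  cs <- cs_fine * s$upscale_factor * 2      # coarser than the upscaled grid
  off <- 0.37 * cs                          # origin offset: centres never align
  nc <- ceiling((extent_x + 2 * off) / cs)
  nr <- ceiling((extent_y + 2 * off) / cs)
  set.seed(stage_seed(s$seed, paste("apr", ai, crop)))
  if (s$apr_cv == 0) {
    v <- matrix(s$apr_mean, nr, nc)
  } else {
    sdlog <- sqrt(log(1 + s$apr_cv^2))
    meanlog <- log(s$apr_mean) - sdlog^2 / 2
    v <- matrix(stats::rlnorm(nr * nc, meanlog, sdlog), nr, nc)
  }
  apr_raster(v, xmin = -off, ymax = extent_y + off, cellsize = cs)
}

#' Generate an authorization table
#'
#' All scenario ingredients approved everywhere except an optional set of
#' bans.
#'
#' @param s a [synthetic_scenario].
#' @param banned optional data frame (`ai_name`, `country`) of banned pairs.
#' @return authorization data frame (`ai_name`, `country`, `approved`).
#' @export
gen_authorizations <- function(s, banned = NULL) {
  tab <- expand.grid(ai_name = s$ai_list, country = s$countries,
                     stringsAsFactors = FALSE)
  tab$approved <- TRUE
  if (!is.null(banned))
    tab$approved[paste(tab$ai_name, tab$country) %in%
                   paste(banned$ai_name, banned$country)] <- FALSE
  tab
}

#' Generate chemical-class reference mass records
#'
#' Applies the scaling model forward to a first-guess mass table using the
#' scenario's ground-truth parameters, multiplies each (major group, crop,
#' country) key by log10-normal noise, drops keys at the sparsity rate,
#' and disaggregates each surviving key into chemical-class records with
#' fixed random weights, replicated identically over the reporting years.
#' Crop keys are expanded back to source crop labels (two wheat and two
#' maize labels; soy/pulses labels for AOC) so the full preparation chain
#' is exercised; an extra record per key carries a chemical class outside
#' the taxonomy (10% of the key mass) to exercise class selection.
#'
#' @param s a [synthetic_scenario].
#' @param first_guess first-guess `mass_table` (strictly positive masses).
#' @param tax `pesticide_taxonomy` supplying the class codes per group.
#' @return list with `records` (raw data frame for
#'   [prepare_calibration()]), `reference` (the noisy per-key masses
#'   actually encoded, a `mass_table`), `dropped` (keys removed by
#'   sparsity) and `truth_params`.
#' @export
gen_reference_masses <- function(s, first_guess, tax = load_taxonomy()) {
  if (any(first_guess$mass_kg <= 0))
    stop("first-guess masses must be strictly positive")
  if (is.null(s$truth_params)) stop("scenario lacks truth_params")
  mgs <- unique(first_guess$major_group)
  missing <- setdiff(mgs, names(s$truth_params))
  if (length(missing)) stop("truth_params missing for group(s): ",
                            paste(missing, collapse = ", "))
  regions <- load_regions()
  set.seed(stage_seed(s$seed, "reference"))
  p <- lapply(s$truth_params, as_parameters)
  model <- vapply(seq_len(nrow(first_guess)), function(i)
    scaled_mass(p[[first_guess$major_group[i]]], first_guess$crop[i],
                first_guess$country[i], first_guess$mass_kg[i], regions), 0)
  eps <- stats::rnorm(nrow(first_guess), 0, s$noise_sd_log10)
  m_star <- model * 10^eps
  keep <- stats::runif(nrow(first_guess)) >= s$sparsity
  labels <- list(
    Wheat = c("Common wheat and spelt", "Durum wheat"),
    Corn = c("Grain maize and corn-cob-mix", "Green maize"),
    AOC = c("Soybeans", "Dry pulses")
  )
  recs <- vector("list", sum(keep))
  ki <- 0L
  for (i in which(keep)) {
    mg <- first_guess$major_group[i]
    classes <- unique(tax$chem_class_code[tax$major_group == mg])
    w <- stats::rgamma(length(classes), 1)
    w <- w / sum(w)
    lab <- labels[[first_guess$crop[i]]]
    one <- data.frame(
      country = first_guess$country[i],
      crop_label = lab[(seq_along(classes) - 1L) %% length(lab) + 1L],
      chem_class_code = classes,
      mass_kg = m_star[i] * w, stringsAsFactors = FALSE)
    extra <- data.frame(country = first_guess$country[i], crop_label = lab[1],
                        chem_class_code = paste0(mg, "00_00"),
                        mass_kg = 0.1 * m_star[i], stringsAsFactors = FALSE)
    ki <- ki + 1L
    recs[[ki]] <- rbind(one, extra)
  }
  if (!ki) stop("sparsity removed every reference key")
  rec <- do.call(rbind, recs)
  rec <- rec[rep(seq_len(nrow(rec)), each = length(s$years)), ]
  rec$year <- rep(s$years, times = nrow(rec) / length(s$years))
  rownames(rec) <- NULL
  list(
    records = rec,
    reference = mass_table(first_guess$major_group[keep],
                           first_guess$crop[keep], first_guess$country[keep],
                           m_star[keep], role = "reference"),
    dropped = mass_key(first_guess)[!keep],
    truth_params = s$truth_params
  )
}
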