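#' Scenario correction factors
#'
#' The ratio of scenario to first-guess mass per (major group, crop,
#' country) and scenario. Because every grid cell has the same surface
#' area in the equal-area CRS, multiplying the first-guess rate raster by
#' these factors rescales the mapped mass to the scenario mass exactly.
#'
#' @param scenarios `scenario_mass_table` from [scenario_quartiles()].
#' @param m_tilde first-guess `mass_table` on the same keys.
#' @return data frame (`major_group`, `crop`, `country`, `scenario`, `K`)
#'   with `scenario` in {Low, Median, High}.
#' @export
correction_factors <- function(scenarios, m_tilde) {
  idx <- match(mass_key(scenarios), mass_key(m_tilde))
  if (anyNA(idx))
    stop("first-guess mass missing for key(s): ",
         paste(mass_key(scenarios)[is.na(idx)], collapse = ", "))
  mt <- m_tilde$mass_kg[idx]
  bad <- mt == 0 & (scenarios$m_low > 0 | scenarios$m_median > 0 |
                      scenarios$m_high > 0)
  if (any(bad))
    stop("zero first-guess mass with positive scenario mass for key(s): ",
         paste(mass_key(scenarios)[bad], collapse = ", "))
  long <- do.call(rbind, lapply(c("Low", "Median", "High"), function(s) {
    col <- c(Low = "m_low", Median = "m_median", High = "m_high")[[s]]
    data.frame(major_group = scenarios$major_group, crop = scenarios$crop,
               country = scenarios$country, scenario = s,
               K = scenarios[[col]] / mt, stringsAsFactors = FALSE)
  }))
  long <- long[order(long$major_group, long$crop, long$country, long$scenario), ]
  rownames(long) <- NULL
  long
}

#' Apply correction factors to a first-guess rate raster
#'
#' Per-pixel multiplication of the first-guess application rate by the
#' correction factor matching the pixel's crop class and country and the
#' ingredient's major group, for one scenario. Pixels whose crop class is
#' excluded (nodata) or outside the ingredient's applicable crops are
#' nodata in the output. A key without a factor (no reference data for
#' that country) falls back to the unweighted mean factor of same-region
#' countries for the same crop and scenario, with a warning.
#'
#' @param apr_tilde first-guess rate [apr_raster] for one ingredient.
#' @param K factor table from [correction_factors()].
#' @param crops aggregated PCG crop-class [apr_raster].
#' @param countries country-ID [apr_raster].
#' @param country_table data frame (`id`, `country`).
#' @param tax `pesticide_taxonomy`.
#' @param ai ingredient name (must be in `tax`).
#' @param scenario one of "Low", "Median", "High".
#' @param regions named country -> region vector (for the fallback).
#' @return scenario rate [apr_raster] with attributes `ai` and `scenario`.
#' @export
apply_correction <- function(apr_tilde, K, crops, countries, country_table,
                             tax, ai, scenario = "Median",
                             regions = load_regions()) {
  stopifnot(scenario %in% c("Low", "Median", "High"))
  stop_if_misregistered(apr_tilde, crops, countries, what = "pipeline rasters")
  row <- tax[tax$ai_name == ai, ]
  if (!nrow(row)) stop("unknown ingredient: ", ai)
  mg <- row$major_group
  ks <- K[K$scenario == scenario & K$major_group == mg, , drop = FALSE]
  cls <- names(pcg_class_codes)[match(crops$values, pcg_class_codes)]
  ctry <- country_table$country[match(countries$values, country_table$id)]
  applicable <- !is.na(cls) & cls %in% row$applicable_crops[[1]] & !is.na(ctry)
  key <- paste(calibration_crop(cls), ctry, sep = "|")
  fac <- ks$K[match(key, paste(ks$crop, ks$country, sep = "|"))]
  miss <- applicable & is.na(fac)
  if (any(miss)) {
    mk <- unique(key[miss])
    warning(length(mk), " (crop, country) key(s) without a factor for ", ai,
            "; using region-average fallback")
    ks$region <- assign_region(ks$country, regions)
    for (k in mk) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      donors <- ks$K[ks$crop == parts[1] &
                       ks$region == assign_region(parts[2], regions)]
      fac[miss & key == k] <- if (length(donors)) mean(donors) else NA_real_
    }
  }
  v <- apr_tilde$values * ifelse(applicable, fac, NA_real_)
  out <- apr_raster(matrix(v, nrow(apr_tilde$values)),
                    apr_tilde$xmin, apr_tilde$ymax, apr_tilde$cellsize,
                    apr_tilde$crs, apr_tilde$nodata)
  attr(out, "ai") <- ai
  attr(out, "scenario") <- scenario
  out
}

#' Write scenario rate maps
#'
#' One ASCII-grid file per (ingredient, scenario), named
#' `<ai>_<scenario>.asc` (ingredient names sanitized to filesystem-safe
#' tokens), values in kg/ha with the grid's nodata tag and EPSG sidecar.
#'
#' @param grids list of [apr_raster]s carrying `ai` and `scenario`
#'   attributes (as produced by [apply_correction()]).
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_scenario_maps <- function(grids, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(grids, function(g) {
    ai <- attr(g, "ai"); s <- attr(g, "scenario")
    if (is.null(ai) || is.null(s)) stop("grid lacks ai/scenario tags")
    fn <- paste0(gsub("[^A-Za-z0-9._-]+", "_", ai), "_", s, ".asc")
    write_raster(g, file.path(out_dir, fn))
    file.path(out_dir, fn)
  }, "")
  invisible(unname(paths))
}
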