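#' Per-key quality index
#'
#' Accuracy score built from the relative estimation residual:
#' `QI = 1 - |m_hat - m_star| / (m_hat + m_star)`. Equal masses give 1, a
#' vanishing reference (or estimate) gives 0; the score is symmetric in
#' its arguments and invariant to a common rescaling.
#'
#' @param m_hat fitted mass (kg), vectorized.
#' @param m_star reference mass (kg), vectorized.
#' @return QI in \[0, 1\].
#' @export
quality_index <- function(m_hat, m_star) {
  if (any(m_hat < 0) || any(m_star < 0)) stop("masses must be nonnegative")
  if (any(m_hat + m_star == 0)) stop("QI undefined when both masses are zero")
  1 - abs(m_hat - m_star) / (m_hat + m_star)
}

#' Quality-index table with regional fallback
#'
#' Builds the QI for every requested key. Keys with both a fitted and a
#' reference mass get the direct index; keys lacking reference data
#' receive the unweighted mean of the direct indices of same-region
#' countries for the same crop and major group, flagged
#' `region_fallback`. A fallback never overwrites a direct value.
#'
#' @param m_hat fitted `mass_table`.
#' @param m_star reference `mass_table`.
#' @param keys data frame (`major_group`, `crop`, `country`) listing the
#'   keys that need an index (typically the first-guess mass keys).
#' @param regions named country -> region vector.
#' @return data frame (`major_group`, `crop`, `country`, `qi`, `flag`).
#' @export
qi_with_fallback <- function(m_hat, m_star, keys, regions = load_regions()) {
  kh <- mass_key(m_hat)
  ks <- mass_key(m_star)
  common <- intersect(kh, ks)
  direct <- data.frame(
    key = common,
    qi = quality_index(m_hat$mass_kg[match(common, kh)],
                       m_star$mass_kg[match(common, ks)]),
    stringsAsFactors = FALSE)
  kk <- paste(keys$major_group, keys$crop, keys$country, sep = "|")
  out <- data.frame(major_group = keys$major_group, crop = keys$crop,
                    country = keys$country,
                    qi = direct$qi[match(kk, direct$key)],
                    flag = "direct", stringsAsFactors = FALSE)
  need <- is.na(out$qi)
  if (any(need)) {
    region <- assign_region(out$country, regions)
    dparts <- do.call(rbind, strsplit(direct$key, "|", fixed = TRUE))
    dregion <- assign_region(dparts[, 3], regions)
    for (i in which(need)) {
      donors <- direct$qi[dparts[, 1] == out$major_group[i] &
                            dparts[, 2] == out$crop[i] &
                            dregion == region[i]]
      if (!length(donors))
        stop("no donor QI for (", out$major_group[i], ", ", out$crop[i],
             ", region ", region[i], ")")
      out$qi[i] <- mean(donors)
      out$flag[i] <- "region_fallback"
    }
  }
  out[order(out$major_group, out$crop, out$country), , drop = FALSE]
}

#' Quality-index raster
#'
#' Spatializes the QI table on the application-rate grid: each pixel takes
#' the index of its (major group of the ingredient, crop class, country)
#' key. Pixels with excluded/nodata crop class, a crop outside the
#' ingredient's applicable set (where its rate map is nodata too) or an
#' unknown country are nodata. All ingredients of a major group share the
#' group index.
#'
#' @param qi table from [qi_with_fallback()].
#' @param crops aggregated PCG crop-class [apr_raster].
#' @param countries country-ID [apr_raster].
#' @param country_table data frame (`id`, `country`).
#' @param tax `pesticide_taxonomy`.
#' @param ai ingredient name selecting the major group.
#' @return [apr_raster] of QI values in \[0, 1\].
#' @export
qi_raster <- function(qi, crops, countries, country_table, tax, ai) {
  stop_if_misregistered(crops, countries, what = "crop and country rasters")
  row <- tax[tax$ai_name == ai, ]
  if (!nrow(row)) stop("unknown ingredient: ", ai)
  sub <- qi[qi$major_group == row$major_group, , drop = FALSE]
  cls <- names(pcg_class_codes)[match(crops$values, pcg_class_codes)]
  ctry <- country_table$country[match(countries$values, country_table$id)]
  mapped <- !is.na(cls) & cls %in% row$applicable_crops[[1]] & !is.na(ctry)
  key <- paste(calibration_crop(cls), ctry, sep = "|")
  val <- sub$qi[match(key, paste(sub$crop, sub$country, sep = "|"))]
  if (any(mapped & is.na(val))) {
    bad <- unique(key[mapped & is.na(val)])
    stop("QI missing (after fallback) for key(s): ", paste(bad, collapse = ", "))
  }
  v <- ifelse(mapped, val, NA_real_)
  apr_raster(matrix(v, nrow(crops$values)), crops$xmin, crops$ymax,
             crops$cellsize, crops$crs, crops$nodata)
}

#' Scenario-to-reference validation ratios
#'
#' Element-wise ratio of scenario to reference mass per key and scenario,
#' ideally 1. Keys without reference data, or with a zero reference mass,
#' are skipped with a message.
#'
#' @param scenarios `scenario_mass_table`.
#' @param m_star reference `mass_table`.
#' @return data frame (`major_group`, `crop`, `country`, `scenario`, `R`).
#' @export
validation_ratio <- function(scenarios, m_star) {
  idx <- match(mass_key(scenarios), mass_key(m_star))
  usable <- !is.na(idx) & m_star$mass_kg[idx] > 0
  if (any(!usable))
    message(sum(!usable), " key(s) without positive reference mass skipped")
  sc <- scenarios[usable, , drop = FALSE]
  ref <- m_star$mass_kg[idx[usable]]
  if (!nrow(sc)) stop("no keys with positive reference mass")
  out <- do.call(rbind, lapply(c("Low", "Median", "High"), function(s) {
    col <- c(Low = "m_low", Median = "m_median", High = "m_high")[[s]]
    data.frame(major_group = sc$major_group, crop = sc$crop,
               country = sc$country, scenario = s, R = sc[[col]] / ref,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$major_group, out$crop, out$country, out$scenario), ]
  rownames(out) <- NULL
  out
}
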