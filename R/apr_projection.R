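#' Applied-mass tables
#'
#' The pipeline's tabular currency: applied mass in kg keyed by
#' (major_group, crop, country), where `crop` is the 3-class calibration
#' key (Corn, Wheat, AOC). A `role` attribute distinguishes first-guess,
#' reference, fitted and scenario masses.
#'
#' @param major_group,crop,country,mass_kg vectors of equal length.
#' @param role one of "first_guess", "reference", "fitted", "scenario".
#' @return data frame of class `mass_table`, sorted by key.
#' @export
mass_table <- function(major_group, crop, country, mass_kg, role = "first_guess") {
  tab <- data.frame(major_group = major_group, crop = crop, country = country,
                    mass_kg = mass_kg, stringsAsFactors = FALSE)
  if (anyDuplicated(tab[c("major_group", "crop", "country")]))
    stop("duplicate (major_group, crop, country) key in mass table")
  if (any(tab$mass_kg < 0)) stop("mass must be nonnegative")
  tab <- tab[order(tab$major_group, tab$crop, tab$country), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "role") <- role
  class(tab) <- c("mass_table", class(tab))
  tab
}

mass_key <- function(tab) paste(tab$major_group, tab$crop, tab$country, sep = "|")

#' Project a coarse rate grid onto a fine grid
#'
#' Nearest-neighbour regridding: each fine cell takes the value of the
#' coarse cell whose centre is closest to the fine cell centre. Coarse
#' nodata propagates. Both grids must share a projected CRS; fine centres
#' falling more than `max_extrapolation` coarse cells outside the coarse
#' extent are an error (no long-range extrapolation).
#'
#' @param coarse [apr_raster] of application rates (kg/ha).
#' @param target [apr_raster] whose geometry (shape, transform, CRS)
#'   defines the output grid; its values are ignored.
#' @param max_extrapolation maximum allowed distance beyond the coarse
#'   extent, in coarse-cell units (default 0.5).
#' @return [apr_raster] on the target geometry.
#' @export
project_apr <- function(coarse, target, max_extrapolation = 0.5) {
  if (coarse$crs != target$crs)
    stop("coarse and target grids must share a CRS (EPSG:", target$crs,
         " expected); reproject the coarse grid first")
  dt <- dim(target$values)
  xc <- cell_centers_x(target)
  yc <- cell_centers_y(target)
  # fractional index of the nearest coarse centre along each axis
  jf <- (xc - coarse$xmin) / coarse$cellsize + 0.5
  if_ <- (coarse$ymax - yc) / coarse$cellsize + 0.5
  dc <- dim(coarse$values)
  slack <- max_extrapolation
  if (any(jf < 0.5 - slack | jf > dc[2] + 0.5 + slack) ||
      any(if_ < 0.5 - slack | if_ > dc[1] + 0.5 + slack))
    stop("target extent lies beyond the coarse grid by more than ",
         max_extrapolation, " coarse cells")
  j <- pmin(pmax(round(jf), 1L), dc[2])
  i <- pmin(pmax(round(if_), 1L), dc[1])
  out <- coarse$values[cbind(rep(i, times = dt[2]), rep(j, each = dt[1]))]
  apr_raster(matrix(out, dt[1], dt[2]),
             target$xmin, target$ymax, target$cellsize, target$crs,
             coarse$nodata)
}

#' Apply country authorizations to a rate grid
#'
#' Pixels in countries where the active ingredient is not approved are set
#' to zero application rate (not nodata, so mass sums stay well defined);
#' approved countries pass through unchanged. Every country present in the
#' country raster must have an authorization record for the ingredient.
#'
#' @param fine [apr_raster] of application rates on the fine grid.
#' @param ai_name active ingredient the grid belongs to.
#' @param auth authorization data frame from [load_authorizations()].
#' @param countries co-registered country-ID [apr_raster].
#' @param country_table data frame (`id`, `country`) decoding the raster IDs.
#' @return masked [apr_raster].
#' @export
apply_authorization <- function(fine, ai_name, auth, countries, country_table) {
  stop_if_misregistered(fine, countries, what = "rate and country rasters")
  present_ids <- sort(unique(countries$values[!is.na(countries$values)]))
  present <- country_table$country[match(present_ids, country_table$id)]
  if (anyNA(present)) stop("country raster contains IDs missing from country_table")
  rec <- auth[auth$ai_name == ai_name, , drop = FALSE]
  missing <- setdiff(present, rec$country)
  if (length(missing))
    stop("no authorization record for ", ai_name, " in: ",
         paste(missing, collapse = ", "))
  banned <- rec$country[!rec$approved]
  banned_ids <- country_table$id[country_table$country %in% banned]
  v <- fine$values
  v[!is.na(countries$values) & countries$values %in% banned_ids & !is.na(v)] <- 0
  apr_raster(v, fine$xmin, fine$ymax, fine$cellsize, fine$crs, fine$nodata)
}

#' First-guess applied mass per (major group, crop, country)
#'
#' Accumulates, for every active ingredient, application rate times cell
#' area over the pixels whose PCG crop class is in the ingredient's
#' applicable set, into the ingredient's major group; crop keys use the
#' 3-class calibration pooling (Corn, Wheat, all else AOC).
#'
#' @param fine_by_ai named list of co-registered [apr_raster]s (kg/ha),
#'   names are ingredient names present in `tax`.
#' @param crops aggregated PCG crop-class [apr_raster].
#' @param countries country-ID [apr_raster].
#' @param country_table data frame (`id`, `country`).
#' @param tax `pesticide_taxonomy`.
#' @param cell_area cell area in ha; default from the crop raster
#'   transform (6.25 ha at 250 m).
#' @return `mass_table` of first-guess masses.
#' @export
first_guess_mass <- function(fine_by_ai, crops, countries, country_table, tax,
                             cell_area = cell_area_ha(crops)) {
  if (cell_area <= 0) stop("cell_area must be positive")
  for (r in fine_by_ai) stop_if_misregistered(crops, r, what = "rate and crop rasters")
  stop_if_misregistered(crops, countries, what = "crop and country rasters")
  unknown <- setdiff(names(fine_by_ai), tax$ai_name)
  if (length(unknown)) stop("ingredients not in taxonomy: ",
                            paste(unknown, collapse = ", "))
  cls <- names(pcg_class_codes)[match(crops$values, pcg_class_codes)]
  ctry <- country_table$country[match(countries$values, country_table$id)]
  acc <- new.env(parent = emptyenv())
  for (ai in names(fine_by_ai)) {
    row <- tax[tax$ai_name == ai, ]
    ok <- !is.na(cls) & cls %in% row$applicable_crops[[1]] & !is.na(ctry)
    v <- fine_by_ai[[ai]]$values
    ok <- ok & !is.na(v)
    if (!any(ok)) next
    key <- paste(row$major_group, calibration_crop(cls[ok]), ctry[ok], sep = "|")
    m <- tapply(v[ok] * cell_area, key, sum)
    for (k in names(m)) assign(k, m[[k]] + mget(k, acc, ifnotfound = 0)[[1]], acc)
  }
  keys <- ls(acc)
  if (!length(keys)) stop("no mass accumulated: empty overlap of crops and rates")
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  mass_table(parts[, 1], parts[, 2], parts[, 3],
             vapply(keys, get, 0, envir = acc), role = "first_guess")
}
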