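#' Controlled vocabularies for the application-rate pipeline
#'
#' The pipeline works with the ten PEST-CHEMGRIDS cropping systems. Cotton
#' and Alfalfa cannot be resolved in the European crop map (they are folded
#' into composite source classes) and are excluded, leaving eight mapped
#' classes. Calibration pools everything except Corn and Wheat into a
#' single "Any Other Crop" (AOC) class.
#'
#' @format `pcg_cropping_systems`: character vector of the 10 PCG classes.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
pcg_cropping_systems <- c("Corn", "Soybean", "Wheat", "Cotton", "Rice",
                          "Alfalfa", "VegFru", "OrcGra", "PasHay", "Other")

#' @rdname vocabularies
#' @export
excluded_cropping_systems <- c("Cotton", "Alfalfa")

#' Mapped PCG crop classes
#'
#' The cropping systems actually mapped: the 10 PCG systems minus the
#' excluded ones (Cotton, Alfalfa).
#'
#' @return character vector of 8 class names.
#' @export
mapped_crop_classes <- function() {
  setdiff(pcg_cropping_systems, excluded_cropping_systems)
}

# Integer codes used for aggregated crop rasters (nodata for EXCLUDED).
#' @rdname vocabularies
#' @export
pcg_class_codes <- stats::setNames(1:8, c("Corn", "Soybean", "Wheat", "Rice",
                                          "VegFru", "OrcGra", "PasHay", "Other"))

#' Calibration crop pooling
#'
#' Maps an 8-class PCG crop name to the 3-class calibration key:
#' Corn and Wheat stay; every other class pools into AOC.
#'
#' @param crop_class character vector of PCG class names.
#' @return character vector in {Corn, Wheat, AOC}.
#' @export
calibration_crop <- function(crop_class) {
  ifelse(crop_class %in% c("Corn", "Wheat"), crop_class, "AOC")
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "aprmap")
  if (!nzchar(path)) stop("fixture not found: ", file)
  path
}

#' Load the active-ingredient taxonomy
#'
#' Reads the EUROSTAT-style taxonomy of active ingredients: each ingredient
#' belongs to one chemical class (codes like `H01_01`), each chemical class
#' to one major group (H herbicides, F fungicides, I insecticides, Z other
#' plant-protection products), and each ingredient carries the set of crop
#' classes it applies to (`ALL` expands to all 8 mapped classes).
#'
#' @param path CSV with columns `ai_name`, `chem_class_code`,
#'   `chem_class_name`, `major_group`, `crops` (semicolon-separated class
#'   names or `ALL`). Defaults to the taxonomy shipped with the package.
#' @return a `pesticide_taxonomy`: data frame with one row per ingredient
#'   and a list-column `applicable_crops`.
#' @export
load_taxonomy <- function(path = pkg_extdata("taxonomy.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ai_name", "chem_class_code", "chem_class_name", "major_group", "crops")
  if (!all(need %in% names(tab))) stop("taxonomy must have columns: ",
                                       paste(need, collapse = ", "))
  if (nrow(tab) == 0L) stop("taxonomy file is empty")
  if (anyDuplicated(tab$ai_name))
    stop("duplicate ai_name in taxonomy: ",
         paste(unique(tab$ai_name[duplicated(tab$ai_name)]), collapse = ", "))
  if (!all(tab$major_group %in% c("H", "F", "I", "Z")))
    stop("major_group must be one of H, F, I, Z")
  if (any(substr(tab$chem_class_code, 1, 1) != tab$major_group))
    stop("chem_class_code leading letter must equal major_group")
  classes <- mapped_crop_classes()
  tab$applicable_crops <- lapply(strsplit(tab$crops, ";", fixed = TRUE), function(tok) {
    tok <- trimws(tok)
    if (identical(tok, "ALL")) return(classes)
    bad <- setdiff(tok, classes)
    if (length(bad)) stop("unknown crop token(s) in taxonomy: ",
                          paste(bad, collapse = ", "))
    tok
  })
  class(tab) <- c("pesticide_taxonomy", class(tab))
  tab
}

#' Count active ingredients, optionally excluding major groups
#'
#' The full taxonomy lists the ingredients approved in at least one
#' country; mapping excludes the "Other PPP" group Z (only two
#' ingredients), so the mapped product covers the H/F/I groups.
#'
#' @param tax a `pesticide_taxonomy` from [load_taxonomy()].
#' @param exclude_groups character vector of major groups to drop.
#' @return integer count of distinct ingredients.
#' @export
count_active_ingredients <- function(tax, exclude_groups = character()) {
  length(unique(tax$ai_name[!tax$major_group %in% exclude_groups]))
}

#' Load the country-to-region assignment
#'
#' EU countries are grouped into southern (SEU), central (CEU) and northern
#' (NEU) Europe. The shipped fixture lists 8 SEU + 13 CEU + 6 NEU
#' countries; Croatia is not assigned a region and is accepted only through
#' `override`.
#'
#' @param path CSV with columns `country`, `region`.
#' @param override optional named character vector of extra or replacement
#'   assignments, e.g. `c(Croatia = "SEU")`.
#' @return named character vector country -> region.
#' @export
load_regions <- function(path = pkg_extdata("regions.csv"), override = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(tab$country)) stop("duplicate country in region table")
  if (!all(tab$region %in% c("SEU", "CEU", "NEU")))
    stop("region must be one of SEU, CEU, NEU")
  reg <- stats::setNames(tab$region, tab$country)
  if (!is.null(override)) {
    if (!all(override %in% c("SEU", "CEU", "NEU")))
      stop("override regions must be SEU, CEU or NEU")
    reg[names(override)] <- override
  }
  reg
}

#' Region of a country
#'
#' @param country character vector of country names.
#' @param regions named vector from [load_regions()].
#' @return character vector of regions (SEU/CEU/NEU).
#' @export
assign_region <- function(country, regions = load_regions()) {
  missing <- setdiff(unique(country), names(regions))
  if (length(missing))
    stop("no region assignment for: ", paste(missing, collapse = ", "))
  unname(regions[country])
}

#' Load the crop-class correspondence table
#'
#' Crosswalk from fused crop-map raster codes to the PCG crop classes;
#' source classes that cannot be attributed to a mapped class (composite
#' industrial/fodder classes, bare land) carry target `EXCLUDED`.
#'
#' @param path CSV with columns `source_code`, `source_label`, `target_class`.
#' @return a `crop_class_map` data frame.
#' @export
load_crop_classes <- function(path = pkg_extdata("crop_classes.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_code", "source_label", "target_class")
  if (!all(need %in% names(tab))) stop("crop class map must have columns: ",
                                       paste(need, collapse = ", "))
  if (anyDuplicated(tab$source_code)) stop("duplicate source_code in crop class map")
  ok <- c(mapped_crop_classes(), "EXCLUDED")
  if (!all(tab$target_class %in% ok))
    stop("unknown target_class: ",
         paste(setdiff(tab$target_class, ok), collapse = ", "))
  class(tab) <- c("crop_class_map", class(tab))
  tab
}

#' Map raster codes to PCG crop classes
#'
#' Unlisted codes (non-agricultural land cover and the like) map to
#' `EXCLUDED` with a warning rather than an error.
#'
#' @param code integer vector of source raster codes.
#' @param class_map a `crop_class_map` from [load_crop_classes()].
#' @return character vector of target classes (`EXCLUDED` included).
#' @export
map_crop_label <- function(code, class_map = load_crop_classes()) {
  idx <- match(code, class_map$source_code)
  out <- class_map$target_class[idx]
  if (anyNA(idx)) {
    warning("unlisted crop code(s) mapped to EXCLUDED: ",
            paste(sort(unique(code[is.na(idx)])), collapse = ", "))
    out[is.na(idx)] <- "EXCLUDED"
  }
  out
}

#' Load an authorization table
#'
#' Country-specific approval status per active ingredient (the 2018-style
#' authorizations-and-bans snapshot). Missing (ingredient, country) pairs
#' are an error downstream: approval is never assumed by default.
#'
#' @param path CSV with columns `ai_name`, `country`, `approved` (0/1).
#' @return data frame with logical `approved`.
#' @export
load_authorizations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ai_name", "country", "approved")
  if (!all(need %in% names(tab))) stop("authorization table must have columns: ",
                                       paste(need, collapse = ", "))
  if (anyDuplicated(tab[c("ai_name", "country")]))
    stop("duplicate (ai_name, country) pair in authorization table")
  tab$approved <- as.logical(tab$approved)
  if (anyNA(tab$approved)) stop("approved must be 0/1")
  tab
}

#' Reference calibration estimates for the 2018 EU-28 product
#'
#' Published maximum-likelihood parameter estimates and posterior standard
#' deviations of the crop-by-region scaling model, per pesticide major
#' group, for the continental-scale 2018 calibration that this package
#' re-implements, together with the negative log-likelihood at the
#' optimum. Used as realistic example inputs for uncertainty propagation.
#'
#' @param path CSV fixture shipped with the package.
#' @return list keyed by major group; each element has `k_hat`
#'   ([scaling_parameters]), `sigma` (named 7-vector) and `nll`.
#' @export
load_reference_calibration <- function(path = pkg_extdata("eu_calibration_2018.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    list(
      k_hat = scaling_parameters(row$k_Corn, row$k_Wheat, row$k_AOC,
                                 row$k_SEU, row$k_CEU, row$k_NEU, row$alpha),
      sigma = stats::setNames(
        as.numeric(row[c("sd_k_Corn", "sd_k_Wheat", "sd_k_AOC", "sd_k_SEU",
                         "sd_k_CEU", "sd_k_NEU", "sd_alpha")]),
        parameter_names()),
      nll = row$nll
    )
  })
  stats::setNames(out, tab$major_group)
}
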