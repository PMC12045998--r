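#' Assemble the reference (calibration) mass dataset
#'
#' Country-level applied-mass statistics come as sparse records keyed by
#' (country, crop label, chemical class, year). Preparation follows a fixed
#' order: average over the reporting window, keep only chemical classes
#' represented in the mapped taxonomy, pool crop labels into the 3-class
#' calibration key, aggregate chemical classes to major groups, and drop
#' keys below a minimum mass.
#'
#' @name calibration_prep
NULL

#' Average mass records over a year window
#'
#' Sparse-in-time records are averaged per (country, crop label, chemical
#' class) over the years present in the window; missing years are skipped,
#' never zero-filled, so a single-year record passes through unchanged.
#'
#' @param records data frame (`country`, `crop_label`, `chem_class_code`,
#'   `year`, `mass_kg`).
#' @param window integer vector of years (default 2015:2020, centring the
#'   reference on 2018).
#' @return records without a `year` column.
#' @export
average_years <- function(records, window = 2015:2020) {
  if (!length(window)) stop("empty year window")
  rec <- records[records$year %in% window, , drop = FALSE]
  if (!nrow(rec))
    return(data.frame(country = character(), crop_label = character(),
                      chem_class_code = character(), mass_kg = numeric(),
                      stringsAsFactors = FALSE))
  out <- stats::aggregate(mass_kg ~ country + crop_label + chem_class_code,
                          data = rec, FUN = mean)
  out[order(out$country, out$crop_label, out$chem_class_code), , drop = FALSE]
}

#' Keep records of chemical classes present in the taxonomy
#'
#' @param records data frame with a `chem_class_code` column.
#' @param tax `pesticide_taxonomy`.
#' @return filtered records.
#' @export
select_classes <- function(records, tax) {
  records[records$chem_class_code %in% tax$chem_class_code, , drop = FALSE]
}

# crop labels pooled into the calibration classes
wheat_labels <- c("Common spring wheat and spelt", "Common wheat and spelt",
                  "Common winter wheat and spelt", "Durum wheat")
corn_labels <- c("Grain maize and corn-cob-mix", "Green maize")

#' Pool source crop labels into the calibration crop classes
#'
#' Wheat-type labels map to Wheat, maize-type labels to Corn, and every
#' other label (including Soybeans and Rice, which cover a negligible
#' share of the study area) to AOC; masses are summed within the pooled key.
#'
#' @param records data frame (`country`, `crop_label`, `chem_class_code`,
#'   `mass_kg`).
#' @return records with a `crop` column in {Corn, Wheat, AOC}.
#' @export
map_crops_to_calibration <- function(records) {
  crop <- rep("AOC", nrow(records))
  crop[records$crop_label %in% wheat_labels] <- "Wheat"
  crop[records$crop_label %in% corn_labels] <- "Corn"
  rec <- records
  rec$crop <- crop
  if (!nrow(rec))
    return(data.frame(country = character(), crop = character(),
                      chem_class_code = character(), mass_kg = numeric(),
                      stringsAsFactors = FALSE))
  out <- stats::aggregate(mass_kg ~ country + crop + chem_class_code,
                          data = rec, FUN = sum)
  out[order(out$country, out$crop, out$chem_class_code), , drop = FALSE]
}

#' Drop keys below a minimum mass
#'
#' Keys whose mass is smaller than `threshold` are removed ("smaller
#' than": a key at exactly the threshold is retained); the number of
#' removals is reported.
#'
#' @param tab `mass_table`.
#' @param threshold minimum retained mass in kg (default 100).
#' @return filtered `mass_table`.
#' @export
filter_small <- function(tab, threshold = 100) {
  drop <- tab$mass_kg < threshold
  if (any(drop))
    message(sum(drop), " reference key(s) below ", threshold, " kg dropped")
  out <- tab[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full calibration-data preparation
#'
#' Chains [average_years()], [select_classes()],
#' [map_crops_to_calibration()], aggregation of chemical classes to major
#' groups (keeping H, F, I) and [filter_small()], in that order.
#'
#' @inheritParams average_years
#' @param tax `pesticide_taxonomy`.
#' @param threshold minimum retained mass in kg.
#' @return `mass_table` with role "reference".
#' @export
prepare_calibration <- function(records, tax, window = 2015:2020, threshold = 100) {
  rec <- average_years(records, window)
  rec <- select_classes(rec, tax)
  rec <- map_crops_to_calibration(rec)
  rec$major_group <- substr(rec$chem_class_code, 1, 1)
  rec <- rec[rec$major_group %in% c("H", "F", "I"), , drop = FALSE]
  if (!nrow(rec)) stop("no reference records survive preparation")
  agg <- stats::aggregate(mass_kg ~ major_group + crop + country,
                          data = rec, FUN = sum)
  tab <- mass_table(agg$major_group, agg$crop, agg$country, agg$mass_kg,
                    role = "reference")
  filter_small(tab, threshold)
}

#' Coverage fractions of the reference dataset
#'
#' The reference dataset keeps only chemical classes present in the mapped
#' taxonomy; its significance is the ratio F* of retained to total
#' major-group mass per (major group, crop, country). Ratios above 1
#' (possible when major-group totals and class-level records are reported
#' asynchronously) are disregarded, as are keys with a zero total.
#' Per-group aggregate fractions are mass-weighted means over the retained
#' keys, using the total mass as weight.
#'
#' @param selected reference `mass_table` (retained subset).
#' @param totals `mass_table` of full major-group masses on the same keys.
#' @return list with `table` (per-key F*) and `aggregates` (named
#'   per-major-group mass-weighted fractions).
#' @export
coverage_fractions <- function(selected, totals) {
  idx <- match(mass_key(selected), mass_key(totals))
  if (anyNA(idx))
    stop("totals missing for key(s): ",
         paste(mass_key(selected)[is.na(idx)], collapse = ", "))
  tot <- totals$mass_kg[idx]
  f <- selected$mass_kg / tot
  bad_zero <- tot == 0 & selected$mass_kg > 0
  over <- !bad_zero & f > 1
  if (any(bad_zero))
    message(sum(bad_zero), " key(s) dropped: zero total with positive selection")
  if (any(over))
    message(sum(over), " key(s) dropped: coverage fraction above 1")
  keep <- !bad_zero & !over & is.finite(f)
  tab <- data.frame(major_group = selected$major_group[keep],
                    crop = selected$crop[keep],
                    country = selected$country[keep],
                    coverage = f[keep], stringsAsFactors = FALSE)
  agg <- vapply(split(seq_len(nrow(tab)), tab$major_group), function(i) {
    w <- tot[keep][i]
    sum(tab$coverage[i] * w) / sum(w)
  }, 0)
  list(table = tab, aggregates = agg)
}
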