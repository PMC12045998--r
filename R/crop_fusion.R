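#' Land-cover codes involved in the fusion rules
#'
#' The fine crop map cannot resolve rice, woody permanent crops or managed
#' pastures on its own; those classes are taken from the land-cover
#' inventory. `eucm_codes` are the fine-map codes touched by the rules
#' (woodland/shrubland incl. permanent crops; grasslands) and the codes
#' written by them (rice, orchards-and-grapes, pastures). `corine_codes`
#' are the level-3 land-cover inventory codes that trigger them.
#'
#' @export
fusion_codes <- list(
  eucm = c(woodland_shrubland = 300, grasslands = 500,
           rice = 217, orcgra = 350, pastures = 510),
  corine = c(rice_fields = 213, vineyards = 221,
             fruit_trees_berries = 222, olive_groves = 223, pastures = 231)
)

#' Correct the fine crop map with the land-cover inventory
#'
#' Applies the three fusion rules pixel-wise, in a single pass:
#' 1. land cover says rice -> crop map becomes rice;
#' 2. crop map says woodland/shrubland (which hides woody permanent crops)
#'    and land cover says vineyards, fruit trees and berry plantations or
#'    olive groves -> orchards and grapes;
#' 3. crop map says grasslands and land cover says pastures -> pastures.
#' No pixel can satisfy two rules (the triggering source codes are
#' disjoint), so the pass order is immaterial. Counts of changed pixels per
#' rule are attached as attribute `rule_counts` and reported via message.
#'
#' @param eucm fine categorical crop raster ([apr_raster]).
#' @param corine co-registered categorical land-cover raster.
#' @param codes code table, see [fusion_codes].
#' @return corrected crop raster with attribute `rule_counts`.
#' @export
apply_corine_corrections <- function(eucm, corine, codes = fusion_codes) {
  stop_if_misregistered(eucm, corine, what = "crop and land-cover rasters")
  v <- eucm$values
  cv <- corine$values
  ec <- codes$eucm
  cc <- codes$corine
  r1 <- !is.na(cv) & cv == cc["rice_fields"]
  r2 <- !is.na(v) & v == ec["woodland_shrubland"] & !is.na(cv) &
    cv %in% cc[c("vineyards", "fruit_trees_berries", "olive_groves")]
  r3 <- !is.na(v) & v == ec["grasslands"] & !is.na(cv) & cv == cc["pastures"]
  v[r1] <- ec["rice"]
  v[r2] <- ec["orcgra"]
  v[r3] <- ec["pastures"]
  out <- apr_raster(v, eucm$xmin, eucm$ymax, eucm$cellsize, eucm$crs, eucm$nodata)
  counts <- c(rice = sum(r1), orchards = sum(r2), pastures = sum(r3))
  message(sprintf("corine corrections: rice %d, orchards %d, pastures %d pixels",
                  counts[1], counts[2], counts[3]))
  attr(out, "rule_counts") <- counts
  out
}

#' Modal block upscaling of a categorical raster
#'
#' Coarsens a categorical raster by an integer factor, assigning each
#' output pixel the most frequent code among the `factor x factor` fine
#' pixels it covers. Nodata cells are excluded from the counts; an
#' all-nodata block stays nodata. Frequency ties break to the smallest
#' code, so the result is deterministic and independent of pixel order.
#' Edge blocks that do not divide evenly are aggregated from the pixels
#' available.
#'
#' @param r categorical [apr_raster].
#' @param factor integer >= 1 (25 takes a 10 m grid to 250 m).
#' @return upscaled [apr_raster] with cell size multiplied by `factor`.
#' @export
modal_upscale <- function(r, factor) {
  if (length(factor) != 1L || factor < 1 || factor != round(factor))
    stop("`factor` must be a single integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(r)
  d <- dim(r$values)
  nr <- ceiling(d[1] / factor)
  nc <- ceiling(d[2] / factor)
  out <- matrix(NA_real_, nr, nc)
  bi <- (seq_len(d[1]) - 1L) %/% factor + 1L
  bj <- (seq_len(d[2]) - 1L) %/% factor + 1L
  for (i in seq_len(nr)) {
    rows <- which(bi == i)
    sub <- r$values[rows, , drop = FALSE]
    for (j in seq_len(nc)) {
      block <- sub[, bj == j]
      block <- block[!is.na(block)]
      if (length(block)) {
        tab <- table(block)
        # ties: table() orders by numeric code, which.max takes the first
        out[i, j] <- as.numeric(names(tab)[which.max(tab)])
      }
    }
  }
  apr_raster(out, r$xmin, r$ymax, r$cellsize * factor, r$crs, r$nodata)
}

#' Aggregate raster codes to PCG crop classes
#'
#' Replaces fused-map codes by the integer codes of the 8 PCG classes
#' ([pcg_class_codes]); `EXCLUDED` source classes and unlisted codes
#' become nodata.
#'
#' @param r categorical [apr_raster] of fused-map codes.
#' @param class_map a `crop_class_map` from [load_crop_classes()].
#' @return [apr_raster] of PCG class codes.
#' @export
aggregate_labels <- function(r, class_map = load_crop_classes()) {
  v <- r$values
  keep <- !is.na(v)
  cls <- suppressWarnings(map_crop_label(v[keep], class_map))
  code <- pcg_class_codes[cls]          # EXCLUDED -> NA
  v[keep] <- unname(code)
  apr_raster(v, r$xmin, r$ymax, r$cellsize, r$crs, r$nodata)
}

#' Crop-class surface-area shares
#'
#' Per-class percentage of the mapped (non-nodata) surface area of an
#' aggregated crop raster. With square cells in an equal-area CRS the
#' shares reduce to pixel-count shares.
#'
#' @param r aggregated [apr_raster] of PCG class codes.
#' @return data frame (`class`, `area_ha`, `share_pct`), shares summing to 100.
#' @export
class_area_table <- function(r) {
  v <- r$values[!is.na(r$values)]
  if (!length(v)) stop("raster has no mapped pixels")
  counts <- table(factor(v, levels = pcg_class_codes))
  area <- as.numeric(counts) * cell_area_ha(r)
  out <- data.frame(class = names(pcg_class_codes),
                    area_ha = area,
                    share_pct = 100 * area / sum(area),
                    stringsAsFactors = FALSE)
  out[out$area_ha > 0, , drop = FALSE]
}
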