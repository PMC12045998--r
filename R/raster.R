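#' Lightweight georeferenced raster
#'
#' An in-memory raster on a regular, axis-aligned grid in a projected CRS.
#' Values are stored as a matrix whose first row is the northernmost row of
#' the map (the usual raster convention). The georeference is the minimal
#' affine north-up transform: the coordinate of the grid's upper-left corner
#' plus a single (square) cell size in CRS units.
#'
#' @param values numeric or integer matrix; `NA` entries are converted to
#'   `nodata` on write and treated as missing throughout.
#' @param xmin x coordinate of the left edge of the first column (CRS units).
#' @param ymax y coordinate of the top edge of the first row (CRS units).
#' @param cellsize positive cell edge length in CRS units (metres for
#'   EPSG:3035; 250 in the production maps).
#' @param crs integer EPSG code of a projected CRS (default 3035, the
#'   European equal-area grid).
#' @param nodata value reserved for missing cells (default -9999).
#'
#' @return An object of class `apr_raster`.
#' @export
apr_raster <- function(values, xmin = 0, ymax = nrow(values) * cellsize,
                       cellsize = 1, crs = 3035L, nodata = -9999) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  values[!is.na(values) & values == nodata] <- NA
  structure(
    list(values = values, xmin = xmin, ymax = ymax,
         cellsize = cellsize, crs = as.integer(crs), nodata = nodata),
    class = "apr_raster"
  )
}

#' @export
dim.apr_raster <- function(x) dim(x$values)

#' @export
print.apr_raster <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<apr_raster> %d x %d, cell %g, EPSG:%d\n", d[1], d[2],
              x$cellsize, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + d[2] * x$cellsize,
              x$ymax - d[1] * x$cellsize, x$ymax))
  if (length(v)) cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                             min(v), max(v), sum(is.na(x$values))))
  else cat("  values: all nodata\n")
  invisible(x)
}

#' Cell-centre coordinates
#'
#' @param r an [apr_raster].
#' @return `cell_centers_x`: x coordinates of the column centres;
#'   `cell_centers_y`: y coordinates of the row centres (north to south).
#' @keywords internal
cell_centers_x <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cellsize

#' @rdname cell_centers_x
#' @keywords internal
cell_centers_y <- function(r) r$ymax - (seq_len(nrow(r$values)) - 0.5) * r$cellsize

#' Cell surface area in hectares
#'
#' Computed from the projected transform: for an area-true CRS such as
#' EPSG:3035 a square cell of edge `cellsize` metres covers
#' `cellsize^2 / 1e4` ha, so the production 250 m grid has 6.25 ha cells.
#'
#' @param r an [apr_raster].
#' @return cell area in hectares.
#' @export
cell_area_ha <- function(r) r$cellsize^2 / 1e4

#' Test that two rasters are co-registered
#'
#' Same shape, origin, cell size and CRS (coordinates compared with a
#' small tolerance relative to the cell size).
#'
#' @param a,b [apr_raster] objects.
#' @return logical.
#' @export
same_grid <- function(a, b) {
  tol <- 1e-6 * a$cellsize
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cellsize - b$cellsize) < tol && a$crs == b$crs
}

stop_if_misregistered <- function(..., what = "rasters") {
  rs <- list(...)
  for (i in seq_along(rs)[-1])
    if (!same_grid(rs[[1]], rs[[i]]))
      stop(what, " are not co-registered (shape/transform/CRS mismatch)")
  invisible(TRUE)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange: the standard six-line ESRI ASCII header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' the value rows from north to south. The CRS is carried in a `.prj`
#' sidecar file holding the EPSG code, written and read alongside the grid.
#'
#' @param r an [apr_raster].
#' @param path file path (conventionally `.asc`).
#' @return `write_raster` returns `path` invisibly; `read_raster` returns an
#'   [apr_raster].
#' @export
write_raster <- function(r, path) {
  d <- dim(r$values)
  v <- r$values
  v[is.na(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymax - d[1] * r$cellsize),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", r$nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("EPSG:%d", r$crs), sub("\\.asc$", ".prj", path))
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- strsplit(trimws(lines), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% key)) stop("malformed ASCII grid header in ", path)
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(as.integer(val["nrows"]), as.integer(val["ncols"]))))
    stop("grid body does not match header dimensions in ", path)
  prj <- sub("\\.asc$", ".prj", path)
  if (!file.exists(prj)) stop("CRS sidecar missing: ", prj)
  crs <- as.integer(sub("EPSG:", "", readLines(prj, n = 1L), fixed = TRUE))
  apr_raster(m,
             xmin = unname(val["xllcorner"]),
             ymax = unname(val["yllcorner"] + val["nrows"] * val["cellsize"]),
             cellsize = unname(val["cellsize"]),
             crs = crs, nodata = unname(val["nodata_value"]))
}
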