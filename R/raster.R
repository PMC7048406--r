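#' Georeferenced single-band raster grid
#'
#' A minimal north-up raster: a numeric matrix (row 1 = top), square cells,
#' an affine geotransform given by the top-left corner and cell size, and a
#' nodata sentinel stored exactly in absent cells. Cell `(r, c)` covers the
#' half-open box `x in [xmin + (c-1)*cs, xmin + c*cs)`,
#' `y in (ymax - r*cs, ymax - (r-1)*cs]` — left/top edges inclusive.
#'
#' @param values numeric matrix; nodata cells hold `nodata` exactly.
#' @param xmin x coordinate of the left edge (map units, e.g. m).
#' @param ymax y coordinate of the top edge.
#' @param cellsize cell side length, > 0.
#' @param nodata sentinel for absent cells (default -9999).
#' @param crs free-text coordinate reference tag (not interpreted).
#' @return An object of class `geo_grid`.
#' @export
geo_grid <- function(values, xmin = 0, ymax = nrow(values) * cellsize,
                     cellsize = 30, nodata = -9999, crs = "") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.finite(cellsize) || cellsize <= 0) {
    stop("`cellsize` must be positive", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("use the nodata sentinel, not NA/Inf, for absent cells",
         call. = FALSE)
  }
  structure(list(values = values, xmin = as.numeric(xmin),
                 ymax = as.numeric(ymax), cellsize = as.numeric(cellsize),
                 nodata = as.numeric(nodata), crs = as.character(crs)),
            class = "geo_grid")
}

#' @export
print.geo_grid <- function(x, ...) {
  v <- valid_cells(x)
  cat(sprintf(
    "<geo_grid> %d x %d cells of %g, origin (%g, %g), nodata %g (%d cells valid)\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymax, x$nodata,
    sum(v)))
  invisible(x)
}

valid_cells <- function(grid) grid$values != grid$nodata

#' Write / read a raster as an ESRI ASCII grid
#'
#' The ESRI ASCII grid (`.asc`) is a plain-text single-band raster format
#' with a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of cell values, top row
#' first. Values are written with 17 significant digits, so a
#' write-read round trip reproduces doubles and the geotransform exactly.
#'
#' @param grid a [geo_grid].
#' @param path file path (conventionally `.asc`).
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [geo_grid].
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "geo_grid"))
  m <- grid$values
  yll <- grid$ymax - nrow(m) * grid$cellsize
  num <- function(x) sprintf("%.17g", x)
  header <- c(paste("ncols", ncol(m)),
              paste("nrows", nrow(m)),
              paste("xllcorner", num(grid$xmin)),
              paste("yllcorner", num(yll)),
              paste("cellsize", num(grid$cellsize)),
              paste("NODATA_value", num(grid$nodata)))
  rows <- apply(m, 1L, function(r) paste(num(r), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("not an ASCII grid: ", path, call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  geo_grid(m, xmin = hdr$xllcorner,
           ymax = hdr$yllcorner + nr * hdr$cellsize,
           cellsize = hdr$cellsize, nodata = hdr$nodata_value)
}

#' Locate the cell containing a point
#'
#' Uses the half-open cell convention of [geo_grid]: a point on a shared
#' vertical edge belongs to the cell on its right, a point on a shared
#' horizontal edge to the cell below it; the raster's top and left outer
#' edges are inclusive, bottom and right exclusive.
#'
#' @param grid a [geo_grid].
#' @param x,y point coordinates (map units).
#' @return A data frame with integer columns `row`, `col` (NA when the point
#'   falls outside the raster bounds).
#' @export
cell_at_xy <- function(grid, x, y) {
  stopifnot(inherits(grid, "geo_grid"))
  if (length(x) != length(y)) stop("x/y length mismatch", call. = FALSE)
  col <- floor((x - grid$xmin) / grid$cellsize) + 1
  row <- floor((grid$ymax - y) / grid$cellsize) + 1
  out <- col >= 1 & col <= ncol(grid$values) &
    row >= 1 & row <= nrow(grid$values)
  col[!out] <- NA_integer_
  row[!out] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}
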