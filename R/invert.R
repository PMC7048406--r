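#' Apply the inversion model to an NDVI raster
#'
#' Evaluates the composite model cell by cell to produce a biomass map.
#' Nodata cells propagate unchanged; valid cells with NDVI outside \[-1, 1\]
#' are set to nodata and counted (with a warning). Cells whose predicted
#' biomass exceeds `saturation_threshold` are flagged in a boolean mask —
#' NDVI loses sensitivity in dense canopies, so estimates above roughly
#' 250 g m\eqn{^{-2}} are unreliable; they are flagged, not clamped or
#' removed.
#'
#' @param ndvi a [geo_grid] of satellite NDVI.
#' @param model a `composite_model`.
#' @param saturation_threshold biomass level (g m\eqn{^{-2}}) above which
#'   cells are flagged as saturated.
#' @return An object of class `biomass_raster`: list with `grid` (a
#'   [geo_grid] of biomass), `saturated` (logical matrix, `FALSE` at nodata
#'   cells), `saturation_threshold`, `n_out_of_range`.
#' @export
apply_model <- function(ndvi, model, saturation_threshold = 250) {
  stopifnot(inherits(ndvi, "geo_grid"), inherits(model, "composite_model"))
  if (!is.finite(saturation_threshold) || saturation_threshold <= 0) {
    stop("`saturation_threshold` must be positive", call. = FALSE)
  }
  v <- ndvi$values
  valid <- valid_cells(ndvi)
  if (!any(valid)) {
    warning("raster contains no valid NDVI cells", call. = FALSE)
  }
  in_range <- valid & abs(v) <= 1
  n_oor <- sum(valid & !in_range)
  if (n_oor > 0L) {
    warning(n_oor, " valid cell(s) had NDVI outside [-1, 1]; set to nodata",
            call. = FALSE)
  }
  out <- matrix(ndvi$nodata, nrow = nrow(v), ncol = ncol(v))
  out[in_range] <- predict(model, v[in_range])
  sat <- matrix(FALSE, nrow = nrow(v), ncol = ncol(v))
  sat[in_range] <- out[in_range] > saturation_threshold
  grid <- geo_grid(out, xmin = ndvi$xmin, ymax = ndvi$ymax,
                   cellsize = ndvi$cellsize, nodata = ndvi$nodata,
                   crs = ndvi$crs)
  structure(list(grid = grid, saturated = sat,
                 saturation_threshold = saturation_threshold,
                 n_out_of_range = n_oor),
            class = "biomass_raster")
}

#' @export
print.biomass_raster <- function(x, ...) {
  v <- valid_cells(x$grid)
  cat(sprintf(
    "<biomass_raster> %d valid cells, %d saturated (> %g g m-2), %d NDVI out of range\n",
    sum(v), sum(x$saturated), x$saturation_threshold, x$n_out_of_range))
  print(x$grid)
  invisible(x)
}

#' Extract predicted biomass at point locations
#'
#' Reads the value of the pixel whose cell contains each point (nearest-cell
#' lookup, no interpolation, see [cell_at_xy()] for the edge convention).
#' Points outside the raster bounds or falling on nodata pixels yield `NA`
#' with a per-point status rather than an error.
#'
#' @param raster a `biomass_raster` (from [apply_model()]) or a plain
#'   [geo_grid].
#' @param points data frame with columns `x`, `y` and optionally `point_id`.
#' @return A data frame: `point_id`, `x`, `y`, `row`, `col`, `value`
#'   (`NA` when unavailable), `saturated` (logical, `NA` when no value),
#'   `status` (`"ok"`, `"nodata"`, or `"out_of_bounds"`).
#' @export
extract_at_points <- function(raster, points) {
  grid <- if (inherits(raster, "biomass_raster")) raster$grid else raster
  stopifnot(inherits(grid, "geo_grid"))
  if (!all(c("x", "y") %in% names(points))) {
    stop("`points` needs columns x and y", call. = FALSE)
  }
  sat <- if (inherits(raster, "biomass_raster")) raster$saturated else NULL
  id <- if ("point_id" %in% names(points)) points$point_id
        else seq_len(nrow(points))
  rc <- cell_at_xy(grid, points$x, points$y)
  n <- nrow(points)
  value <- rep(NA_real_, n)
  satur <- rep(NA, n)
  status <- rep("out_of_bounds", n)
  inb <- !is.na(rc$row)
  idx <- cbind(rc$row[inb], rc$col[inb])
  vals <- grid$values[idx]
  nod <- vals == grid$nodata
  value[inb][!nod] <- vals[!nod]
  status[inb] <- ifelse(nod, "nodata", "ok")
  if (!is.null(sat)) satur[inb][!nod] <- sat[idx][!nod]
  data.frame(point_id = id, x = points$x, y = points$y,
             row = rc$row, col = rc$col, value = value,
             saturated = satur, status = status)
}
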