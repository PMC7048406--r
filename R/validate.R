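#' Validate predicted biomass against field measurements
#'
#' Compares predicted biomass (extracted from the inverted raster) with
#' measured biomass at held-out locations and reports the accuracy
#' statistics: SE ([standard_error()]), MEC ([mec()]) and the OLS line of
#' predicted on actual with its R-squared. Pairs with missing predictions
#' (e.g. points that fell on nodata pixels) are dropped pairwise; the count
#' of dropped pairs is recorded and reported with a warning.
#'
#' @param actual measured biomass, g m\eqn{^{-2}}, all positive.
#' @param predicted predicted biomass, same length; may contain `NA`.
#' @return An object of class `validation_report`: list with `n`,
#'   `n_dropped`, `se`, `mec`, `slope`, `intercept`, `r2`, `pairs` (data
#'   frame of the retained actual/predicted values).
#' @export
validate_predictions <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual/predicted length mismatch", call. = FALSE)
  }
  if (anyNA(actual)) stop("`actual` must not contain NA", call. = FALSE)
  keep <- !is.na(predicted)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    warning(n_dropped, " pair(s) dropped for missing predictions",
            call. = FALSE)
  }
  actual <- actual[keep]
  predicted <- predicted[keep]
  if (length(actual) < 2L) {
    stop("need at least 2 complete actual/predicted pairs", call. = FALSE)
  }
  if (any(actual <= 0)) {
    stop("measured biomass must be positive", call. = FALSE)
  }
  fit <- stats::lm(predicted ~ actual)
  structure(list(n = length(actual), n_dropped = n_dropped,
                 se = standard_error(actual, predicted),
                 mec = mec(actual, predicted),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = lm_r2(fit),
                 pairs = data.frame(actual = actual, predicted = predicted)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d (%d dropped)\n", x$n, x$n_dropped))
  cat(sprintf("  SE  = %.2f g m-2\n  MEC = %.2f %%\n", x$se, x$mec))
  cat(sprintf("  predicted = %.3f actual %+.3f  (R2 = %.3f)\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Scatter plot of predicted versus actual biomass
#'
#' @param x a `validation_report`.
#' @param ... passed to [graphics::plot].
#' @export
plot.validation_report <- function(x, ...) {
  lim <- range(0, x$pairs$actual, x$pairs$predicted)
  graphics::plot(x$pairs$actual, x$pairs$predicted, xlim = lim, ylim = lim,
                 xlab = "Measured AGB (g m-2)",
                 ylab = "Predicted AGB (g m-2)",
                 main = sprintf("SE = %.2f g m-2, MEC = %.2f%%", x$se, x$mec),
                 ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  obj <- report[c("n", "n_dropped", "se", "mec", "slope", "intercept", "r2")]
  obj$pairs <- report$pairs
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
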