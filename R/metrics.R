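#' Prediction error statistics: SE and MEC
#'
#' `standard_error()` is the root of the mean squared difference between
#' measured and predicted values,
#' \deqn{SE = \sqrt{\sum_i (y_i - y'_i)^2 / n},}
#' reported in the units of `y` (g m\eqn{^{-2}} for biomass). `mec()` is the
#' mean error coefficient, the mean absolute relative error in percent,
#' \deqn{MEC = 100 \cdot \sum_i |(y_i - y'_i) / y_i| / n.}
#'
#' These two statistics are the accuracy measures used throughout the
#' package, both for ranking regression families on held-out quadrats and
#' for the final raster-prediction validation; a single implementation is
#' shared by both stages.
#'
#' @param y numeric vector of measured values.
#' @param y_pred numeric vector of predicted values, same length as `y`.
#' @return A single non-negative number: `standard_error()` in the units of
#'   `y`, `mec()` in percent.
#' @examples
#' standard_error(c(100, 200), c(90, 220)) # sqrt((100 + 400)/2)
#' mec(c(100, 200), c(90, 220))            # 10%
#' @export
standard_error <- function(y, y_pred) {
  check_pair(y, y_pred)
  sqrt(mean((y - y_pred)^2))
}

#' @rdname standard_error
#' @export
mec <- function(y, y_pred) {
  check_pair(y, y_pred)
  zero <- which(y == 0)
  if (length(zero) > 0L) {
    stop("relative error undefined: `y` is zero at position(s) ",
         paste(utils::head(zero, 5L), collapse = ", "),
         if (length(zero) > 5L) ", ...", call. = FALSE)
  }
  100 * mean(abs((y - y_pred) / y))
}

check_pair <- function(y, y_pred) {
  if (!is.numeric(y) || !is.numeric(y_pred)) {
    stop("`y` and `y_pred` must be numeric", call. = FALSE)
  }
  if (length(y) != length(y_pred)) {
    stop("`y` and `y_pred` must have equal length (got ", length(y),
         " and ", length(y_pred), ")", call. = FALSE)
  }
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(y) || anyNA(y_pred)) {
    stop("`y` and `y_pred` must not contain missing values", call. = FALSE)
  }
  invisible(TRUE)
}
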