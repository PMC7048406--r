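#' Calibrate satellite NDVI against plot-mean ground NDVI
#'
#' Ordinary least squares of plot-mean ground NDVI on satellite NDVI,
#' \deqn{SOC\_NDVI = c \cdot TM\_NDVI + d,}
#' fitted at plot level (one 30 x 30 m plot per satellite pixel). The
#' regression direction is fixed as ground-on-satellite because the result
#' is substituted into the ground biomass model, which takes ground NDVI as
#' its argument.
#'
#' @param plots data frame with columns `soc_ndvi_mean` and `tm_ndvi`
#'   (alternatively pass two numeric vectors as `plots` and `soc`).
#' @param soc optional numeric vector of ground NDVI when `plots` is a
#'   numeric vector of satellite NDVI.
#' @return An object of class `cross_calibration`: list with `slope`,
#'   `intercept`, `n`, `r2`.
#' @export
fit_cross_calibration <- function(plots, soc = NULL) {
  if (is.data.frame(plots)) {
    if (!all(c("soc_ndvi_mean", "tm_ndvi") %in% names(plots))) {
      stop("need columns soc_ndvi_mean and tm_ndvi", call. = FALSE)
    }
    tm <- plots$tm_ndvi
    soc <- plots$soc_ndvi_mean
  } else {
    tm <- plots
  }
  if (length(tm) != length(soc)) stop("length mismatch", call. = FALSE)
  if (length(tm) < 3L) stop("need at least 3 plots", call. = FALSE)
  if (anyNA(tm) || anyNA(soc)) stop("missing NDVI values", call. = FALSE)
  if (any(abs(tm) > 1) || any(abs(soc) > 1)) {
    stop("NDVI values must lie in [-1, 1]", call. = FALSE)
  }
  if (stats::var(tm) == 0) {
    stop("satellite NDVI has zero variance; calibration line is undefined",
         call. = FALSE)
  }
  fit <- stats::lm(soc ~ tm)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(tm),
                 r2 = lm_r2(fit)),
            class = "cross_calibration")
}

#' @export
print.cross_calibration <- function(x, ...) {
  cat(sprintf(
    "<cross_calibration> SOC_NDVI = %.3f TM_NDVI %+.3f  (n = %d, R2 = %.3f)\n",
    x$slope, x$intercept, x$n, x$r2))
  invisible(x)
}

#' Compose the ground biomass model with the NDVI cross-calibration
#'
#' Substitutes the plot-level calibration `SOC_NDVI = c TM_NDVI + d` into the
#' exponential ground model `AGB = a e^(b SOC_NDVI)` to obtain the satellite
#' inversion model
#' \deqn{AGB(t) = a \, e^{b (c t + d)},}
#' with `t` the satellite NDVI. Only the exponential ground family composes
#' into this closed form; other families are refused. The four parent
#' constants are stored unreduced to preserve provenance; the algebraically
#' equivalent reduced form `(a e^{bd}) e^{(bc) t}` is available from
#' `reduced_coefficients()`.
#'
#' @param ground a `regression_fit` with `family == "exponential"`.
#' @param cross a `cross_calibration`.
#' @return An object of class `composite_model`: list with `a`, `b`, `c`,
#'   `d` and the parent fits.
#' @export
compose_model <- function(ground, cross) {
  stopifnot(inherits(ground, "regression_fit"),
            inherits(cross, "cross_calibration"))
  if (ground$family != "exponential") {
    stop("composition is defined for the exponential ground family only, ",
         "got '", ground$family, "'", call. = FALSE)
  }
  structure(list(a = ground$a, b = ground$b,
                 c = cross$slope, d = cross$intercept,
                 ground = ground, cross = cross),
            class = "composite_model")
}

#' Construct a composite inversion model from its four constants
#'
#' Convenience constructor for `AGB(t) = a e^(b (c t + d))` when the parent
#' fits are not at hand (e.g. when the constants come from a publication or
#' a serialized model file).
#'
#' @param a scale of the ground model, g m\eqn{^{-2}}, > 0.
#' @param b exponential rate of the ground model per NDVI unit.
#' @param c,d slope and intercept of the satellite-to-ground NDVI
#'   calibration.
#' @return A `composite_model`.
#' @export
composite_model <- function(a, b, c, d) {
  if (!is.finite(a) || a <= 0) stop("`a` must be positive", call. = FALSE)
  for (v in list(b, c, d)) if (!is.finite(v)) stop("non-finite coefficient",
                                                   call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, ground = NULL, cross = NULL),
            class = "composite_model")
}

#' @rdname compose_model
#' @param model a `composite_model`.
#' @return `reduced_coefficients()` returns `c(a = a e^{bd}, b = bc)` of the
#'   single-exponential reduced form.
#' @export
reduced_coefficients <- function(model) {
  stopifnot(inherits(model, "composite_model"))
  c(a = model$a * exp(model$b * model$d), b = model$b * model$c)
}

#' Predict biomass from satellite NDVI
#'
#' Evaluates `AGB(t) = a e^(b (c t + d))` at satellite NDVI `t`. Inputs must
#' lie in \[-1, 1\]; the result is positive and strictly increasing in `t`
#' whenever `b c > 0`.
#'
#' @param object a `composite_model`.
#' @param tm_ndvi satellite NDVI values in \[-1, 1\].
#' @param ... unused.
#' @return Predicted biomass, g m\eqn{^{-2}}.
#' @export
predict.composite_model <- function(object, tm_ndvi, ...) {
  if (any(!is.finite(tm_ndvi)) || any(abs(tm_ndvi) > 1)) {
    stop("satellite NDVI must lie in [-1, 1]", call. = FALSE)
  }
  object$a * exp(object$b * (object$c * tm_ndvi + object$d))
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf(
    "<composite_model> AGB = %.3f e^(%.3f (%.3f TM_NDVI %+.3f))  [g m-2]\n",
    x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Serialize / restore a composite model as JSON
#'
#' Stores the four constants plus, when available, the parent fits'
#' coefficients and R-squared values for provenance.
#'
#' @param model a `composite_model`.
#' @param path JSON file path.
#' @return `write_composite_model()` returns `path` invisibly;
#'   `read_composite_model()` returns a `composite_model`.
#' @export
write_composite_model <- function(model, path) {
  stopifnot(inherits(model, "composite_model"))
  obj <- list(a = model$a, b = model$b, c = model$c, d = model$d)
  if (!is.null(model$ground)) {
    obj$ground <- list(family = model$ground$family, a = model$ground$a,
                       b = model$ground$b, n = model$ground$n,
                       r2 = model$ground$r2, adj_r2 = model$ground$adj_r2)
  }
  if (!is.null(model$cross)) {
    obj$cross <- list(slope = model$cross$slope,
                      intercept = model$cross$intercept,
                      n = model$cross$n, r2 = model$cross$r2)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_composite_model
#' @export
read_composite_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  composite_model(obj$a, obj$b, obj$c, obj$d)
}
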