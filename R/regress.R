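#' Partition quadrats into model / holdout / train / test sets
#'
#' Reproduces the two-level split used for the ground model: the full set of
#' quadrats is divided into a model-building group and a holdout group
#' reserved for validating the final raster inversion; within the model
#' group, a training subset is drawn for fitting the regression families and
#' the remainder is used to score them. With the default campaign of 173
#' quadrats the sizes are 153/20 and 115/38. Sampling is uniform without
#' replacement and reproducible under `seed`.
#'
#' @param ids vector of quadrat identifiers (unique).
#' @param sizes integer `c(model, holdout, train)`; `model + holdout` must
#'   equal `length(ids)` and `train < model`.
#' @param seed integer seed for the partition.
#' @return A list of class `data_split` with elements `model_ids`,
#'   `holdout_ids`, `train_ids`, `test_ids`, `sizes`, `seed`.
#' @export
split_data <- function(ids, sizes = c(153, 20, 115), seed = 1L) {
  if (anyDuplicated(ids)) stop("quadrat ids must be unique", call. = FALSE)
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes <= 0L)) {
    stop("`sizes` must be c(model, holdout, train), all positive",
         call. = FALSE)
  }
  if (sizes[1] + sizes[2] != length(ids)) {
    stop("model + holdout sizes (", sizes[1] + sizes[2],
         ") must equal the number of quadrats (", length(ids), ")",
         call. = FALSE)
  }
  if (sizes[3] >= sizes[1]) {
    stop("train size must be smaller than the model-group size",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  model_ids <- sort(sample(ids, sizes[1]))
  holdout_ids <- sort(setdiff(ids, model_ids))
  train_ids <- sort(sample(model_ids, sizes[3]))
  test_ids <- sort(setdiff(model_ids, train_ids))
  structure(list(model_ids = model_ids, holdout_ids = holdout_ids,
                 train_ids = train_ids, test_ids = test_ids,
                 sizes = sizes, seed = as.integer(seed)),
            class = "data_split")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

regression_families <- c("linear", "logarithmic", "power", "exponential")

#' Fit one regression family of biomass against NDVI
#'
#' The four candidate forms relating aboveground biomass `y` (g m\eqn{^{-2}})
#' to ground NDVI `x` are:
#' \describe{
#'   \item{linear}{`y = a x + b`, ordinary least squares.}
#'   \item{logarithmic}{`y = a ln(x) + b`, OLS on `ln(x)`.}
#'   \item{power}{`y = a x^b`, OLS of `ln(y)` on `ln(x)`, `a = exp(intercept)`.}
#'   \item{exponential}{`y = a e^(b x)`, OLS of `ln(y)` on `x`,
#'     `a = exp(intercept)`.}
#' }
#' The power and exponential forms are linearized by logs (the convention
#' behind spreadsheet trendline equations), which is deterministic; set
#' `refine = TRUE` to polish them with nonlinear least squares
#' ([stats::nls]) started from the log-linear estimate.
#'
#' `r2` is the coefficient of determination on the ORIGINAL biomass scale,
#' `1 - SS_res / SS_tot` with back-transformed predictions;
#' `adj_r2 = 1 - (1 - r2)(n - 1)/(n - 2)`. For log-linearized families
#' `r2_fit_scale` additionally reports the R-squared of the underlying OLS
#' on its transformed scale, since published equations of this form do not
#' always state which scale their R-squared used.
#'
#' @param x NDVI values (unitless); must be positive for the logarithmic and
#'   power families.
#' @param y biomass values (g m\eqn{^{-2}}); must be positive for the power
#'   and exponential families.
#' @param family one of `"linear"`, `"logarithmic"`, `"power"`,
#'   `"exponential"`.
#' @param refine logical; polish power/exponential fits with [stats::nls].
#' @return An object of class `regression_fit`: list with `family`, `a`,
#'   `b`, `n`, `r2`, `adj_r2`, `r2_fit_scale`, `equation`.
#' @export
fit_family <- function(x, y, family = regression_families, refine = FALSE) {
  family <- match.arg(family)
  if (length(x) != length(y)) stop("x/y length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y", call. = FALSE)
  if (family %in% c("logarithmic", "power") && any(x <= 0)) {
    stop("family '", family, "' needs x > 0; offending record(s) at ",
         paste(utils::head(which(x <= 0), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (family %in% c("power", "exponential") && any(y <= 0)) {
    stop("family '", family, "' needs y > 0; offending record(s) at ",
         paste(utils::head(which(y <= 0), 5L), collapse = ", "),
         call. = FALSE)
  }

  r2_fit_scale <- NA_real_
  if (family == "linear") {
    fit <- stats::lm(y ~ x)
    a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  } else if (family == "logarithmic") {
    lx <- log(x)
    fit <- stats::lm(y ~ lx)
    a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  } else if (family == "power") {
    fit <- stats::lm(log(y) ~ log(x))
    a <- exp(unname(stats::coef(fit)[1])); b <- unname(stats::coef(fit)[2])
    r2_fit_scale <- lm_r2(fit)
  } else {
    fit <- stats::lm(log(y) ~ x)
    a <- exp(unname(stats::coef(fit)[1])); b <- unname(stats::coef(fit)[2])
    r2_fit_scale <- lm_r2(fit)
  }

  if (refine && family %in% c("power", "exponential")) {
    form <- if (family == "power") y ~ a * x^b else y ~ a * exp(b * x)
    nls_fit <- try(stats::nls(form, data = data.frame(x = x, y = y),
                              start = list(a = a, b = b)), silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      a <- unname(stats::coef(nls_fit)["a"])
      b <- unname(stats::coef(nls_fit)["b"])
    }
  }

  out <- structure(list(family = family, a = a, b = b, n = n,
                        r2 = NA_real_, adj_r2 = NA_real_,
                        r2_fit_scale = r2_fit_scale,
                        equation = family_equation(family, a, b)),
                   class = "regression_fit")
  pred <- predict(out, x)
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  out$r2 <- 1 - ss_res / ss_tot
  out$adj_r2 <- 1 - (1 - out$r2) * (n - 1) / (n - 2)
  out
}

family_equation <- function(family, a, b) {
  switch(family,
         linear = sprintf("y = %.3f x %+.3f", a, b),
         logarithmic = sprintf("y = %.3f ln(x) %+.3f", a, b),
         power = sprintf("y = %.3f x^%.3f", a, b),
         exponential = sprintf("y = %.3f e^(%.3f x)", a, b))
}

#' Predict biomass from a fitted regression family
#'
#' @param object a `regression_fit`.
#' @param newx NDVI values at which to predict.
#' @param ... unused.
#' @return Predicted biomass, g m\eqn{^{-2}}.
#' @export
predict.regression_fit <- function(object, newx, ...) {
  switch(object$family,
         linear = object$a * newx + object$b,
         logarithmic = object$a * log(newx) + object$b,
         power = object$a * newx^object$b,
         exponential = object$a * exp(object$b * newx))
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s: %s  (n = %d, R2 = %.3f, adj R2 = %.3f)\n",
              x$family, x$equation, x$n, x$r2, x$adj_r2))
  invisible(x)
}

#' Fit and score all four regression families
#'
#' Fits each family on the training quadrats, scores each on the test
#' quadrats with [standard_error()] and [mec()], and selects the family with
#' the highest training R-squared (original scale), breaking ties by the
#' smaller test SE. Families that cannot be fitted on the data (e.g. a log
#' family with non-positive NDVI) are recorded as failed and excluded from
#' selection.
#'
#' @param train,test data frames with columns `soc_ndvi` and `agb_g_m2`.
#' @param families character vector of families to consider.
#' @return An object of class `family_comparison`: list with `fits` (named
#'   list of [fit_family] results or `NULL` for failures), `table` (a data
#'   frame, one column per family, rows equation / n / r2 / adj_r2 / se /
#'   mec), `selected` (family name), `failed` (character vector).
#' @export
compare_families <- function(train, test, families = regression_families) {
  for (d in list(train, test)) {
    if (!all(c("soc_ndvi", "agb_g_m2") %in% names(d))) {
      stop("need columns soc_ndvi and agb_g_m2", call. = FALSE)
    }
  }
  fits <- stats::setNames(vector("list", length(families)), families)
  se_v <- mec_v <- stats::setNames(rep(NA_real_, length(families)), families)
  for (fam in families) {
    fit <- try(fit_family(train$soc_ndvi, train$agb_g_m2, fam),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    fits[[fam]] <- fit
    pred <- predict(fit, test$soc_ndvi)
    se_v[fam] <- standard_error(test$agb_g_m2, pred)
    mec_v[fam] <- mec(test$agb_g_m2, pred)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no regression family could be fitted", call. = FALSE)
  r2 <- vapply(families, function(f) if (ok[f]) fits[[f]]$r2 else -Inf,
               numeric(1))
  best_r2 <- max(r2)
  cand <- families[ok & abs(r2 - best_r2) < 1e-12]
  selected <- if (length(cand) > 1L) cand[which.min(se_v[cand])] else cand

  tab <- data.frame(row.names = c("equation", "n", "r2", "adj_r2",
                                  "se_g_m2", "mec_pct"))
  for (fam in families) {
    col <- if (ok[fam]) {
      f <- fits[[fam]]
      c(f$equation, f$n, round(f$r2, 4), round(f$adj_r2, 4),
        round(se_v[fam], 2), round(mec_v[fam], 2))
    } else rep("failed", 6L)
    tab[[fam]] <- col
  }
  structure(list(fits = fits, table = tab, se = se_v, mec = mec_v,
                 selected = selected, failed = families[!ok],
                 n_train = nrow(train), n_test = nrow(test)),
            class = "family_comparison")
}

#' @export
print.family_comparison <- function(x, ...) {
  cat(sprintf("<family_comparison> %d train / %d test quadrats; selected: %s\n",
              x$n_train, x$n_test, x$selected))
  print(x$table)
  invisible(x)
}

# R-squared of an lm fit without summary.lm (avoids its perfect-fit warning)
lm_r2 <- function(fit) {
  y <- stats::model.response(stats::model.frame(fit))
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}
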