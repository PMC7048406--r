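test_that("split_data produces the 153/20 and 115/38 partitions", {
  ids <- sprintf("Q%03d", 1:173)
  sp <- split_data(ids, sizes = c(153, 20, 115), seed = 5)
  expect_length(sp$model_ids, 153)
  expect_length(sp$holdout_ids, 20)
  expect_length(sp$train_ids, 115)
  expect_length(sp$test_ids, 38)
  # partition laws: disjoint and exhaustive at both levels
  expect_setequal(c(sp$model_ids, sp$holdout_ids), ids)
  expect_length(intersect(sp$model_ids, sp$holdout_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), sp$model_ids)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  # reproducible under seed
  expect_identical(sp, split_data(ids, sizes = c(153, 20, 115), seed = 5))
  expect_false(identical(sp$train_ids,
                         split_data(ids, sizes = c(153, 20, 115),
                                    seed = 6)$train_ids))
})

test_that("split_data rejects inconsistent sizes", {
  ids <- 1:100
  expect_error(split_data(ids, sizes = c(90, 20, 60)), "must equal")
  expect_error(split_data(ids, sizes = c(80, 20, 80)), "smaller")
  expect_error(split_data(c(1, 1, 2), sizes = c(2, 1, 1)), "unique")
})

test_that("each family recovers exact generating laws", {
  x <- seq(0.2, 0.9, length.out = 40)
  exp_fit <- fit_family(x, 12.523 * exp(3.370 * x), "exponential")
  expect_lt(rel_err(exp_fit$a, 12.523), 1e-6)
  expect_lt(rel_err(exp_fit$b, 3.370), 1e-6)
  expect_equal(exp_fit$r2, 1, tolerance = 1e-10)

  lin_fit <- fit_family(x, 2 * x + 1, "linear")
  expect_equal(lin_fit$a, 2, tolerance = 1e-10)
  expect_equal(lin_fit$b, 1, tolerance = 1e-10)
  expect_equal(lin_fit$r2, 1, tolerance = 1e-10)

  log_fit <- fit_family(x, 3 * log(x) + 7, "logarithmic")
  expect_equal(log_fit$a, 3, tolerance = 1e-8)
  expect_equal(log_fit$b, 7, tolerance = 1e-8)

  pow_fit <- fit_family(x, 5 * x^1.7, "power")
  expect_lt(rel_err(pow_fit$a, 5), 1e-8)
  expect_lt(rel_err(pow_fit$b, 1.7), 1e-8)
})

test_that("all four families agree with the normal-equations oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    x <- runif(n, 0.1, 0.95)
    y <- runif(n, 10, 300)
    for (fam in c("linear", "logarithmic", "power", "exponential")) {
      fit <- fit_family(x, y, fam)
      coefs <- switch(fam,
                      linear = ols_normal_equations(x, y),
                      logarithmic = ols_normal_equations(log(x), y),
                      power = ols_normal_equations(log(x), log(y)),
                      exponential = ols_normal_equations(x, log(y)))
      a_ref <- if (fam %in% c("power", "exponential")) exp(coefs[1])
               else coefs[2]
      b_ref <- if (fam %in% c("power", "exponential")) coefs[2] else coefs[1]
      expect_lt(rel_err(fit$a, a_ref), 1e-10)
      expect_lt(rel_err(fit$b, b_ref), 1e-10)
    }
  }
})

test_that("adjusted R2 is strictly below R2 for imperfect fits", {
  set.seed(8)
  x <- runif(30, 0.2, 0.9)
  y <- 100 * x + rnorm(30, 0, 10)
  fit <- fit_family(x, y, "linear")
  expect_lt(fit$r2, 1)
  expect_lt(fit$adj_r2, fit$r2)
})

test_that("log-requiring families refuse non-positive data with a pointer", {
  x <- c(0.5, -0.1, 0.7); y <- c(10, 20, 30)
  expect_error(fit_family(x, y, "logarithmic"), "record\\(s\\) at 2")
  expect_error(fit_family(x, y, "power"), "x > 0")
  expect_error(fit_family(c(0.5, 0.6, 0.7), c(10, -2, 30), "exponential"),
               "y > 0")
  expect_error(fit_family(c(0.1, 0.2), c(1, 2), "linear"), "at least 3")
})

test_that("nls refinement reproduces exact coefficients on clean data", {
  x <- seq(0.25, 0.85, length.out = 30)
  y <- 12.523 * exp(3.370 * x)
  fit <- fit_family(x, y, "exponential", refine = TRUE)
  expect_lt(rel_err(fit$a, 12.523), 1e-6)
  expect_lt(rel_err(fit$b, 3.370), 1e-6)
})

test_that("compare_families selects the true family and shapes its table", {
  x <- seq(0.2, 0.9, length.out = 60)
  lin <- data.frame(soc_ndvi = x, agb_g_m2 = 2 * x + 1)
  cmp <- compare_families(lin[1:40, ], lin[41:60, ])
  expect_identical(cmp$selected, "linear")
  expect_equal(cmp$fits$linear$r2, 1, tolerance = 1e-10)
  expect_identical(dim(cmp$table), c(6L, 4L))
  expect_identical(names(cmp$table),
                   c("linear", "logarithmic", "power", "exponential"))
  expect_identical(rownames(cmp$table),
                   c("equation", "n", "r2", "adj_r2", "se_g_m2", "mec_pct"))
})

test_that("exponential data with 20% CV noise selects exponential in the
           majority of seeded runs", {
  sel <- vapply(1:25, function(s) {
    set.seed(s)
    x <- runif(153, 0.27, 0.85)
    y <- pmax(12.523 * exp(3.370 * x) * (1 + rnorm(153, 0, 0.2)), 0.01)
    d <- data.frame(soc_ndvi = x, agb_g_m2 = y)
    compare_families(d[1:115, ], d[116:153, ])$selected
  }, character(1))
  expect_gt(mean(sel == "exponential"), 0.5)
})

test_that("unfittable families are recorded as failed, not fatal", {
  x <- seq(0.2, 0.9, length.out = 40)
  y <- 2 * x + 1
  y[5] <- -1                      # breaks power and exponential
  d <- data.frame(soc_ndvi = x, agb_g_m2 = y)
  cmp <- compare_families(d[1:25, ], d[26:40, ])
  expect_setequal(cmp$failed, c("power", "exponential"))
  expect_true(all(cmp$table$power == "failed"))
  expect_identical(cmp$selected, "linear")
})
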