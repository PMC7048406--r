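test_that("cross-calibration recovers an exact linear relation", {
  tm <- seq(-0.2, 0.95, length.out = 39)
  soc <- REF_C * tm + REF_D
  cal <- fit_cross_calibration(data.frame(soc_ndvi_mean = soc, tm_ndvi = tm))
  expect_equal(cal$slope, REF_C, tolerance = 1e-10)
  expect_equal(cal$intercept, REF_D, tolerance = 1e-10)
  expect_equal(cal$r2, 1, tolerance = 1e-12)
  expect_identical(cal$n, 39L)
})

test_that("constant ground NDVI gives a zero-slope calibration", {
  cal <- fit_cross_calibration(c(0.1, 0.4, 0.7), rep(0.55, 3))
  expect_equal(cal$slope, 0, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.55, tolerance = 1e-12)
})

test_that("cross-calibration agrees with the normal-equations oracle", {
  set.seed(21)
  for (i in 1:10) {
    tm <- runif(5, -0.5, 0.9)
    soc <- runif(5, 0.1, 0.9)
    cal <- fit_cross_calibration(tm, soc)
    ref <- ols_normal_equations(tm, soc)
    expect_lt(rel_err(cal$intercept, ref[1]), 1e-10)
    expect_lt(rel_err(cal$slope, ref[2]), 1e-10)
  }
})

test_that("degenerate or invalid plot data is refused", {
  expect_error(fit_cross_calibration(rep(0.5, 5), runif(5, 0.2, 0.8)),
               "zero variance")
  expect_error(fit_cross_calibration(c(0.1, 0.2), c(0.3, 0.4)),
               "at least 3")
  expect_error(fit_cross_calibration(c(0.1, 0.2, 1.4), c(0.3, 0.4, 0.5)),
               "\\[-1, 1\\]")
})

test_that("composition stores the four constants and refuses other families", {
  ground <- fit_family(seq(0.2, 0.9, length.out = 20),
                       REF_A * exp(REF_B * seq(0.2, 0.9, length.out = 20)),
                       "exponential")
  cal <- fit_cross_calibration(
    data.frame(soc_ndvi_mean = REF_C * seq(0, 0.9, length.out = 10) + REF_D,
               tm_ndvi = seq(0, 0.9, length.out = 10)))
  model <- compose_model(ground, cal)
  expect_lt(rel_err(model$a, REF_A), 1e-6)
  expect_lt(rel_err(model$b, REF_B), 1e-6)
  expect_lt(rel_err(model$c, REF_C), 1e-10)
  expect_lt(rel_err(model$d, REF_D), 1e-10)

  lin <- fit_family(c(0.2, 0.5, 0.8), c(1, 2, 3), "linear")
  expect_error(compose_model(lin, cal), "exponential ground family only")
})

test_that("identity calibration reduces the composite to the ground model", {
  ground <- fit_family(seq(0.2, 0.9, length.out = 20),
                       30 * exp(2 * seq(0.2, 0.9, length.out = 20)),
                       "exponential")
  ident <- structure(list(slope = 1, intercept = 0, n = 10L, r2 = 1),
                     class = "cross_calibration")
  model <- compose_model(ground, ident)
  t <- seq(-1, 1, length.out = 21)
  expect_equal(predict(model, t), predict(ground, t), tolerance = 1e-12)
})

test_that("composite evaluation matches its closed form and is monotone", {
  model <- composite_model(REF_A, REF_B, REF_C, REF_D)
  # log-domain closed-form oracle at t = 0.5
  expect_lt(rel_err(predict(model, 0.5),
                    exp(log(REF_A) + REF_B * (REF_C * 0.5 + REF_D))), 1e-12)
  # exponent-zero point returns a exactly
  expect_equal(predict(model, -REF_D / REF_C), REF_A, tolerance = 1e-12)
  grid <- seq(-1, 1, length.out = 201)
  v <- predict(model, grid)
  expect_true(all(v > 0))
  expect_true(all(diff(v) > 0))          # b*c > 0 => strictly increasing
  # reduced and nested forms agree
  rc <- reduced_coefficients(model)
  expect_equal(predict(model, grid), rc["a"] * exp(rc["b"] * grid),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(predict(model, 1.2), "\\[-1, 1\\]")
})

test_that("composition is exact: composite(t) equals ground(c t + d)", {
  set.seed(3)
  ground <- fit_family(runif(20, 0.2, 0.9),
                       exp(runif(20, 2, 5)), "exponential")
  cal <- fit_cross_calibration(runif(10, -0.5, 0.9), runif(10, 0.2, 0.9))
  model <- compose_model(ground, cal)
  t <- seq(-1, 1, length.out = 101)
  expect_equal(predict(model, t),
               predict(ground, cal$slope * t + cal$intercept),
               tolerance = 1e-12)
})

test_that("composite models survive a JSON round trip", {
  ground <- fit_family(seq(0.2, 0.9, length.out = 20),
                       REF_A * exp(REF_B * seq(0.2, 0.9, length.out = 20)),
                       "exponential")
  cal <- fit_cross_calibration(
    data.frame(soc_ndvi_mean = REF_C * seq(0, 0.9, length.out = 10) + REF_D,
               tm_ndvi = seq(0, 0.9, length.out = 10)))
  model <- compose_model(ground, cal)
  path <- withr::local_tempfile(fileext = ".json")
  write_composite_model(model, path)
  back <- read_composite_model(path)
  for (k in c("a", "b", "c", "d")) expect_equal(back[[k]], model[[k]])
  t <- seq(-1, 1, length.out = 11)
  expect_equal(predict(back, t), predict(model, t))
})
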