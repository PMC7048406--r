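wl <- seq(400, 1000, by = 2.3)

test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(spectrum(c(500, 600), c(0.1, 0.2)), "spectrum")
  expect_error(spectrum(c(600, 500), c(0.1, 0.2)), "strictly increasing")
  expect_error(spectrum(c(500, 600), c(0.1)), "lengths differ")
  expect_error(spectrum(c(500, 600), c(-0.1, 0.2)), "\\[0, 1.2\\]")
  expect_error(spectrum(c(500, 600), c(0.1, 1.3)), "\\[0, 1.2\\]")
  expect_error(spectrum(c(500, 600), c(0.1, NA)), "finite")
})

test_that("reflectance calibration handles identity, zero and midpoint cases", {
  panel <- rep(4000, length(wl)); dark <- rep(200, length(wl))
  expect_equal(calibrate_reflectance(wl, panel, panel, dark)$reflectance,
               rep(1, length(wl)))
  expect_equal(calibrate_reflectance(wl, dark, panel, dark)$reflectance,
               rep(0, length(wl)))
  mid <- dark + 0.5 * (panel - dark)
  expect_equal(calibrate_reflectance(wl, mid, panel, dark)$reflectance,
               rep(0.5, length(wl)))
  # panel of known reflectivity < 1 scales linearly
  expect_equal(
    calibrate_reflectance(wl, mid, panel, dark, panel_reflectivity = 0.8)$
      reflectance,
    rep(0.4, length(wl)))
})

test_that("calibration is invariant to a global gain on all count vectors", {
  set.seed(11)
  target <- runif(length(wl), 500, 3000)
  panel <- runif(length(wl), 3500, 4000)
  dark <- runif(length(wl), 100, 300)
  base <- calibrate_reflectance(wl, target, panel, dark)
  gained <- calibrate_reflectance(wl, 2.5 * target, 2.5 * panel, 2.5 * dark)
  expect_equal(gained$reflectance, base$reflectance)
})

test_that("calibration reports the channel where panel <= dark", {
  panel <- rep(4000, 5); dark <- rep(200, 5)
  panel[3] <- 150
  expect_error(calibrate_reflectance(c(500, 550, 600, 650, 700),
                                     rep(1000, 5), panel, dark),
               "600")
  # values above 1.2 are clipped with a warning, not an error
  expect_warning(
    s <- calibrate_reflectance(c(500, 550), c(5000, 1000), c(4000, 4000),
                               c(0, 0)),
    "clipped")
  expect_equal(s$reflectance, c(1.2, 0.25))
})

test_that("band resampling is the unweighted in-window mean", {
  flat <- spectrum(wl, rep(0.3, length(wl)))
  expect_equal(resample_band(flat, c(630, 680)), 0.3)
  two <- spectrum(c(600, 640, 660, 700), c(0.9, 0.1, 0.3, 0.9))
  expect_equal(resample_band(two, c(630, 680)), 0.2)
  # endpoints are inclusive on both sides
  edge <- spectrum(c(630, 680), c(0.1, 0.5))
  expect_equal(resample_band(edge, c(630, 680)), 0.3)
  # channels outside the window never contribute
  padded <- spectrum(c(629.9, 640, 660, 680.1), c(1, 0.1, 0.3, 1))
  expect_equal(resample_band(padded, c(630, 680)), 0.2)
  expect_error(resample_band(flat, c(1200, 1300)), "no spectral channel")
})

test_that("band means are grid-resolution stable to 0.005", {
  # smooth synthetic reflectance sampled at instrument (2.3 nm) and 1 nm
  f <- function(l) 0.05 + 0.4 / (1 + exp(-(l - 715) / 12)) +
    0.05 * exp(-((l - 550)^2) / 1800)
  coarse <- spectrum(seq(400, 1000, by = 2.3), f(seq(400, 1000, by = 2.3)))
  fine <- spectrum(seq(400, 1000, by = 1), f(seq(400, 1000, by = 1)))
  for (band in ndvi_bands()) {
    expect_lt(abs(resample_band(coarse, band) - resample_band(fine, band)),
              0.005)
  }
})

test_that("compute_ndvi matches its closed form and boundary cases", {
  expect_equal(compute_ndvi(0.05, 0.40), 0.35 / 0.45)
  expect_identical(compute_ndvi(0.3, 0.3), 0)
  expect_identical(compute_ndvi(0, 0.4), 1)
  expect_error(compute_ndvi(0, 0), "undefined")
  expect_error(compute_ndvi(-0.1, 0.4), "non-negative")
})

test_that("NDVI stays in [-1, 1] and is monotone in each band", {
  set.seed(4)
  red <- runif(200, 0, 1.2); nir <- runif(200, 0, 1.2)
  keep <- red + nir > 0
  v <- compute_ndvi(red[keep], nir[keep])
  expect_true(all(v >= -1 & v <= 1))
  nir_grid <- seq(0.01, 1, length.out = 50)
  expect_true(all(diff(compute_ndvi(rep(0.2, 50), nir_grid)) > 0))
  red_grid <- seq(0.01, 1, length.out = 50)
  expect_true(all(diff(compute_ndvi(red_grid, rep(0.5, 50))) < 0))
})

test_that("quadrat NDVI averages per-spectrum NDVI (mean-of-NDVI convention)", {
  s1 <- spectrum(c(650, 860), c(0.05, 0.50))
  s2 <- spectrum(c(650, 860), c(0.30, 0.35))
  expect_equal(quadrat_ndvi(s1), compute_ndvi(0.05, 0.50))
  expect_equal(quadrat_ndvi(list(s1, s1)), quadrat_ndvi(s1))
  mean_of_ndvi <- mean(c(compute_ndvi(0.05, 0.5), compute_ndvi(0.3, 0.35)))
  ndvi_of_mean <- compute_ndvi(mean(c(0.05, 0.3)), mean(c(0.5, 0.35)))
  expect_equal(quadrat_ndvi(list(s1, s2)), mean_of_ndvi)
  expect_false(isTRUE(all.equal(mean_of_ndvi, ndvi_of_mean)))
  expect_error(quadrat_ndvi(list()), "at least one")
})

test_that("plot mean NDVI is the arithmetic mean and permutation invariant", {
  expect_equal(plot_mean_ndvi(c(0.4, 0.6)), 0.5)
  expect_equal(plot_mean_ndvi(0.37), 0.37)
  v <- c(0.2, 0.5, 0.8, 0.33)
  expect_equal(plot_mean_ndvi(v), plot_mean_ndvi(rev(v)))
  expect_error(plot_mean_ndvi(numeric(0)), "at least one")
})

test_that("spectra tables round-trip through spectra_from_table", {
  s <- list(A = spectrum(c(500, 600), c(0.1, 0.2)),
            B = spectrum(c(500, 600), c(0.3, 0.4)))
  tbl <- data.frame(quadrat_id = rep(c("A", "B"), each = 2),
                    wavelength_nm = rep(c(500, 600), 2),
                    reflectance = c(0.1, 0.2, 0.3, 0.4))
  out <- spectra_from_table(tbl)
  expect_equal(out$A$reflectance, s$A$reflectance)
  expect_equal(out$B$reflectance, s$B$reflectance)
  expect_error(spectra_from_table(tbl[, 1:2]), "needs columns")
})
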