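#' Configuration of a synthetic field campaign
#'
#' Defines the statistical structure the inversion pipeline assumes: a set
#' of 30 x 30 m plots (one satellite pixel each) containing 1 x 1 m
#' quadrats; quadrat biomass following an exponential law in ground NDVI,
#' `AGB = a e^(b SOC_NDVI)`, with multiplicative noise; plot-level satellite
#' NDVI linearly related to the plot-mean ground NDVI through
#' `SOC_NDVI = c TM_NDVI + d` with additive noise; and a small NDVI raster
#' holding the plot pixels. Defaults reproduce the study layout of 39 plots
#' and 173 quadrats and the published model constants
#' a = 12.523 g m\eqn{^{-2}}, b = 3.370, c = 0.462, d = 0.413.
#'
#' @param n_plots number of plots (>= 2).
#' @param n_quadrats total number of quadrats across plots; distributed as
#'   evenly as integer counts allow (first plots take the remainder).
#' @param ground_a,ground_b exponential ground-model constants
#'   (`ground_a` > 0, g m\eqn{^{-2}}).
#' @param cross_slope,cross_intercept ground-on-satellite NDVI calibration
#'   line; `cross_slope` must be nonzero so the line can be inverted when
#'   generating satellite NDVI from ground NDVI.
#' @param agb_noise_cv relative (coefficient-of-variation) noise on quadrat
#'   biomass, >= 0.
#' @param ndvi_noise_sd additive noise s.d. on plot satellite NDVI, >= 0.
#' @param spectral_noise_sd additive reflectance noise s.d. on simulated
#'   spectra, >= 0.
#' @param cover_range vegetation cover interval (within \[0, 1\]) from which
#'   plot-level cover means are drawn. The default keeps quadrat ground NDVI
#'   roughly in \[0.27, 0.85\], so that the implied satellite NDVI
#'   `(SOC - d)/c` stays inside \[-1, 1\].
#' @param cover_sd within-plot s.d. of quadrat cover around the plot mean.
#' @param wavelength_nm spectral grid of the simulated spectrometer; the
#'   default is 400--1000 nm at 2.3 nm resolution.
#' @param raster_dim `c(nrow, ncol)` of the NDVI raster.
#' @param cellsize raster cell size in m (satellite pixel, default 30).
#' @param nodata raster nodata sentinel.
#' @param seed integer seed; identical configs + seed give byte-identical
#'   campaigns.
#' @return A validated list of class `campaign_config`.
#' @export
campaign_config <- function(n_plots = 39L, n_quadrats = 173L,
                            ground_a = 12.523, ground_b = 3.370,
                            cross_slope = 0.462, cross_intercept = 0.413,
                            agb_noise_cv = 0.2, ndvi_noise_sd = 0.05,
                            spectral_noise_sd = 0.005,
                            cover_range = c(0.15, 0.95), cover_sd = 0.06,
                            wavelength_nm = seq(400, 1000, by = 2.3),
                            raster_dim = c(50L, 50L), cellsize = 30,
                            nodata = -9999, seed = 1L) {
  n_plots <- as.integer(n_plots); n_quadrats <- as.integer(n_quadrats)
  if (n_plots < 2L) stop("need at least 2 plots", call. = FALSE)
  if (n_quadrats < n_plots) {
    stop("need at least one quadrat per plot", call. = FALSE)
  }
  if (!is.finite(ground_a) || ground_a <= 0) {
    stop("`ground_a` must be positive", call. = FALSE)
  }
  if (cross_slope == 0) {
    stop("degenerate cross-calibration: `cross_slope` must be nonzero",
         call. = FALSE)
  }
  for (v in c(agb_noise_cv, ndvi_noise_sd, spectral_noise_sd, cover_sd)) {
    if (!is.finite(v) || v < 0) stop("noise parameters must be >= 0",
                                     call. = FALSE)
  }
  if (length(cover_range) != 2L || cover_range[1] >= cover_range[2] ||
      cover_range[1] < 0 || cover_range[2] > 1) {
    stop("`cover_range` must be an interval inside [0, 1]", call. = FALSE)
  }
  if (length(raster_dim) != 2L ||
      prod(raster_dim) < n_plots) {
    stop("raster too small to hold one pixel per plot", call. = FALSE)
  }
  structure(list(n_plots = n_plots, n_quadrats = n_quadrats,
                 ground_a = ground_a, ground_b = ground_b,
                 cross_slope = cross_slope,
                 cross_intercept = cross_intercept,
                 agb_noise_cv = agb_noise_cv, ndvi_noise_sd = ndvi_noise_sd,
                 spectral_noise_sd = spectral_noise_sd,
                 cover_range = as.numeric(cover_range),
                 cover_sd = cover_sd,
                 wavelength_nm = as.numeric(wavelength_nm),
                 raster_dim = as.integer(raster_dim),
                 cellsize = as.numeric(cellsize),
                 nodata = as.numeric(nodata), seed = as.integer(seed)),
            class = "campaign_config")
}

#' Idealized vegetation and soil endmember spectra
#'
#' Builds the two pure-material reference spectra used by the linear mixing
#' simulator: green vegetation with strong chlorophyll absorption in the red
#' (logistic red edge near 720 nm, small green-reflectance bump at 550 nm)
#' and a NIR plateau, and bare soil as a gently rising line. The shapes are
#' piecewise-smooth idealizations — only the band-window means matter
#' downstream: the vegetation endmember has red-window reflectance well
#' below its NIR-window reflectance (NDVI > 0.8) while soil NDVI is near 0.
#'
#' @param wavelength_nm strictly increasing grid that must span both NDVI
#'   windows (reach 630 nm on the left and 885 nm on the right, with at
#'   least one channel inside each window).
#' @return A list with [spectrum] elements `vegetation` and `soil`.
#' @export
make_endmembers <- function(wavelength_nm) {
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  bands <- ndvi_bands()
  for (b in bands) {
    if (!any(wavelength_nm >= b[1] & wavelength_nm <= b[2])) {
      stop(sprintf("wavelength grid does not cover the %g-%g nm window",
                   b[1], b[2]), call. = FALSE)
    }
  }
  wl <- as.numeric(wavelength_nm)
  veg <- 0.025 + 0.525 / (1 + exp(-(wl - 720) / 14)) +
    0.06 * exp(-((wl - 550)^2) / (2 * 30^2))
  soil <- 0.12 + 2e-4 * (wl - 400)
  list(vegetation = spectrum(wl, pmin(pmax(veg, 0), 1.2)),
       soil = spectrum(wl, pmin(pmax(soil, 0), 1.2)))
}

#' Simulate one quadrat's spectrum by linear mixing
#'
#' Mixes the vegetation and soil endmembers by fractional vegetation cover,
#' adds independent Gaussian reflectance noise per channel, and clips to
#' \[0, 1.2\]:
#' `reflectance = cover * veg + (1 - cover) * soil + noise`.
#'
#' @param cover fractional vegetation cover in \[0, 1\].
#' @param endmembers list with `vegetation` and `soil` spectra on a common
#'   grid (see [make_endmembers()]).
#' @param noise_sd reflectance noise s.d. (>= 0). Drawn from the current RNG
#'   stream; seed externally for reproducibility.
#' @return A [spectrum].
#' @export
simulate_quadrat_spectrum <- function(cover, endmembers, noise_sd = 0) {
  if (!is.finite(cover) || cover < 0 || cover > 1) {
    stop("`cover` must lie in [0, 1]", call. = FALSE)
  }
  veg <- endmembers$vegetation; soil <- endmembers$soil
  if (!identical(veg$wavelength_nm, soil$wavelength_nm)) {
    stop("endmembers must share one wavelength grid", call. = FALSE)
  }
  refl <- cover * veg$reflectance + (1 - cover) * soil$reflectance
  if (noise_sd > 0) {
    refl <- refl + stats::rnorm(length(refl), 0, noise_sd)
  }
  spectrum(veg$wavelength_nm, pmin(pmax(refl, 0), 1.2))
}

#' Simulate a complete synthetic field campaign
#'
#' Generates, deterministically under the config seed:
#' \enumerate{
#'   \item plot-level vegetation cover means (uniform over `cover_range`)
#'     and quadrat covers (Gaussian around the plot mean, s.d. `cover_sd`,
#'     clipped to \[0, 1\]);
#'   \item one mixed spectrum per quadrat ([simulate_quadrat_spectrum()]),
#'     from which the quadrat ground NDVI is computed with the package's own
#'     NDVI stack;
#'   \item quadrat biomass `AGB = a e^(b SOC_NDVI) (1 + eps)`,
#'     `eps ~ N(0, agb_noise_cv)`, floored at 0.01 g m\eqn{^{-2}};
#'   \item plot satellite NDVI `TM = (mean(SOC) - d)/c + eta`,
#'     `eta ~ N(0, ndvi_noise_sd)`, clipped to \[-1, 1\];
#'   \item an NDVI raster with each plot's satellite NDVI at its pixel and
#'     nodata elsewhere; quadrat coordinates are jittered uniformly inside
#'     their plot's pixel.
#' }
#'
#' @param config a [campaign_config()].
#' @return An object of class `agb_campaign`: list with data frames
#'   `quadrats` (`quadrat_id`, `plot_id`, `soc_ndvi`, `agb_g_m2`, `x`, `y`),
#'   `plots` (`plot_id`, `soc_ndvi_mean`, `tm_ndvi`, `row`, `col`, `x`,
#'   `y`), `spectra` (long format), the `raster` ([geo_grid]), `endmembers`,
#'   and the `config`.
#' @export
simulate_campaign <- function(config = campaign_config()) {
  stopifnot(inherits(config, "campaign_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  np <- config$n_plots; nq <- config$n_quadrats
  base <- nq %/% np; extra <- nq %% np
  quadrats_per_plot <- rep(base, np) + c(rep(1L, extra), rep(0L, np - extra))

  em <- make_endmembers(config$wavelength_nm)
  bands <- ndvi_bands()

  plot_cover <- stats::runif(np, config$cover_range[1], config$cover_range[2])
  nr <- config$raster_dim[1]; nc <- config$raster_dim[2]
  cells <- sample.int(nr * nc, np)          # one distinct pixel per plot
  prow <- (cells - 1L) %/% nc + 1L
  pcol <- (cells - 1L) %% nc + 1L
  cs <- config$cellsize
  xmin <- 0; ymax <- nr * cs
  px <- xmin + (pcol - 0.5) * cs
  py <- ymax - (prow - 0.5) * cs

  quad_plot <- rep(seq_len(np), quadrats_per_plot)
  n_quad <- length(quad_plot)
  cover <- pmin(pmax(stats::rnorm(n_quad, plot_cover[quad_plot],
                                  config$cover_sd), 0), 1)

  spectra_list <- vector("list", n_quad)
  soc <- numeric(n_quad)
  for (i in seq_len(n_quad)) {
    s <- simulate_quadrat_spectrum(cover[i], em, config$spectral_noise_sd)
    spectra_list[[i]] <- s
    soc[i] <- quadrat_ndvi(s, bands)
  }

  eps <- stats::rnorm(n_quad, 0, config$agb_noise_cv)
  agb <- pmax(config$ground_a * exp(config$ground_b * soc) * (1 + eps), 0.01)

  # quadrat coordinates: jittered inside the plot's 30 m pixel
  qx <- px[quad_plot] + stats::runif(n_quad, -0.45, 0.45) * cs
  qy <- py[quad_plot] + stats::runif(n_quad, -0.45, 0.45) * cs

  quadrat_id <- sprintf("Q%03d", seq_len(n_quad))
  quadrats <- data.frame(quadrat_id = quadrat_id,
                         plot_id = sprintf("P%02d", quad_plot),
                         soc_ndvi = soc, agb_g_m2 = agb, x = qx, y = qy)

  soc_mean <- as.numeric(tapply(soc, quad_plot, mean))
  eta <- stats::rnorm(np, 0, config$ndvi_noise_sd)
  tm <- (soc_mean - config$cross_intercept) / config$cross_slope + eta
  tm <- pmin(pmax(tm, -1), 1)

  plots <- data.frame(plot_id = sprintf("P%02d", seq_len(np)),
                      soc_ndvi_mean = soc_mean, tm_ndvi = tm,
                      row = prow, col = pcol, x = px, y = py)

  m <- matrix(config$nodata, nrow = nr, ncol = nc)
  m[cbind(prow, pcol)] <- tm
  raster <- geo_grid(m, xmin = xmin, ymax = ymax, cellsize = cs,
                     nodata = config$nodata, crs = "local")

  spectra <- data.frame(
    quadrat_id = rep(quadrat_id,
                     each = length(config$wavelength_nm)),
    wavelength_nm = rep(config$wavelength_nm, n_quad),
    reflectance = unlist(lapply(spectra_list, `[[`, "reflectance")))

  structure(list(quadrats = quadrats, plots = plots, spectra = spectra,
                 raster = raster, endmembers = em, config = config),
            class = "agb_campaign")
}

#' @export
print.agb_campaign <- function(x, ...) {
  cat(sprintf(
    "<agb_campaign> %d plots, %d quadrats; SOC_NDVI %.2f-%.2f, AGB %.1f-%.1f g m-2\n",
    nrow(x$plots), nrow(x$quadrats), min(x$quadrats$soc_ndvi),
    max(x$quadrats$soc_ndvi), min(x$quadrats$agb_g_m2),
    max(x$quadrats$agb_g_m2)))
  invisible(x)
}

#' Write a synthetic campaign to disk
#'
#' Writes `quadrats.csv`, `plots.csv`, `spectra.csv`, `ndvi.asc` (ESRI
#' ASCII grid) and `config.json` into a directory. All outputs are plain
#' text and byte-identical across runs with the same config and seed.
#'
#' @param campaign an `agb_campaign`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "agb_campaign"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(campaign$quadrats, file.path(dir, "quadrats.csv"),
                   row.names = FALSE)
  utils::write.csv(campaign$plots, file.path(dir, "plots.csv"),
                   row.names = FALSE)
  utils::write.csv(campaign$spectra, file.path(dir, "spectra.csv"),
                   row.names = FALSE)
  write_ascii_grid(campaign$raster, file.path(dir, "ndvi.asc"))
  cfg <- unclass(campaign$config)
  cfg$wavelength_nm <- NULL                 # implied by spectra.csv
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
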