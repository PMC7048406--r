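#' Configuration for the end-to-end inversion pipeline
#'
#' Bundles the synthetic-campaign settings with the analysis constants: the
#' two-level data split (model/holdout, then train/test inside the model
#' group), the regression families considered, the NDVI band windows, and
#' the biomass saturation threshold (250 g m\eqn{^{-2}}, above which NDVI
#' saturates in dense canopies and estimates are flagged).
#'
#' @param campaign a [campaign_config()].
#' @param split integer `c(model, holdout, train)`; defaults to the study
#'   layout 153/20 with 115 training quadrats.
#' @param families regression families passed to [compare_families()].
#' @param saturation_threshold g m\eqn{^{-2}}; see [apply_model()].
#' @param bands see [ndvi_bands()].
#' @param seed seed for the data split (the campaign has its own seed).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(campaign = campaign_config(),
                            split = c(153, 20, 115),
                            families = regression_families,
                            saturation_threshold = 250,
                            bands = ndvi_bands(), seed = 1L) {
  stopifnot(inherits(campaign, "campaign_config"))
  families <- match.arg(families, regression_families, several.ok = TRUE)
  structure(list(campaign = campaign, split = as.integer(split),
                 families = families,
                 saturation_threshold = saturation_threshold,
                 bands = bands, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain top-level keys `campaign` (a mapping of
#' [campaign_config()] arguments), `split`, `families`,
#' `saturation_threshold`, `bands` (mapping with `red` and `nir` two-element
#' lists) and `seed`. Unknown keys at either level are rejected rather than
#' silently ignored.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("campaign", "split", "families", "saturation_threshold",
             "bands", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  camp_args <- raw$campaign %||% list()
  bad <- setdiff(names(camp_args), names(formals(campaign_config)))
  if (length(bad) > 0L) {
    stop("unknown campaign key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- list(campaign = do.call(campaign_config, camp_args))
  if (!is.null(raw$split)) args$split <- unlist(raw$split)
  if (!is.null(raw$families)) args$families <- unlist(raw$families)
  if (!is.null(raw$saturation_threshold)) {
    args$saturation_threshold <- raw$saturation_threshold
  }
  if (!is.null(raw$bands)) {
    args$bands <- ndvi_bands(red = unlist(raw$bands$red),
                             nir = unlist(raw$bands$nir))
  }
  if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic inversion pipeline
#'
#' Executes, in order: campaign simulation; recomputation of quadrat ground
#' NDVI from the simulated spectra through the package's calibration /
#' resampling / NDVI stack; the two-level data split; fitting and scoring of
#' the regression families; the plot-level satellite-to-ground NDVI
#' cross-calibration; composition of the exponential ground fit with the
#' calibration into the satellite inversion model; raster inversion;
#' extraction of predicted biomass at the holdout quadrats' coordinates; and
#' validation against their measured biomass.
#'
#' The composite model is always built from the exponential family fit (the
#' only family whose composition with a linear NDVI map stays in closed
#' form); the family ranking is reported alongside so a non-exponential
#' winner is visible rather than silently discarded.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all stage outputs plus a
#'   `manifest.json` are written there as plain text.
#' @return A list of class `pipeline_result` with elements `campaign`,
#'   `split`, `comparison`, `ground_fit`, `crosscal`, `composite`,
#'   `biomass`, `predictions`, `validation`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  campaign <- simulate_campaign(config$campaign)

  # recompute quadrat NDVI from the spectra table through the NDVI stack;
  # downstream stages use the recomputed values
  specs <- spectra_from_table(campaign$spectra)
  soc <- vapply(specs, quadrat_ndvi, numeric(1), bands = config$bands)
  quadrats <- campaign$quadrats
  quadrats$soc_ndvi <- unname(soc[quadrats$quadrat_id])

  split <- split_data(quadrats$quadrat_id, sizes = config$split,
                      seed = config$seed)
  train <- quadrats[quadrats$quadrat_id %in% split$train_ids, ]
  test <- quadrats[quadrats$quadrat_id %in% split$test_ids, ]
  holdout <- quadrats[quadrats$quadrat_id %in% split$holdout_ids, ]

  comparison <- compare_families(train, test, families = config$families)
  ground_fit <- comparison$fits[["exponential"]]
  if (is.null(ground_fit)) {
    stop("pipeline halted at stage 'fit': exponential family unfittable",
         call. = FALSE)
  }

  crosscal <- fit_cross_calibration(campaign$plots)
  composite <- compose_model(ground_fit, crosscal)

  biomass <- apply_model(campaign$raster, composite,
                         saturation_threshold = config$saturation_threshold)
  predictions <- extract_at_points(
    biomass, data.frame(point_id = holdout$quadrat_id,
                        x = holdout$x, y = holdout$y))
  validation <- validate_predictions(holdout$agb_g_m2, predictions$value)

  result <- structure(list(campaign = campaign, split = split,
                           comparison = comparison, ground_fit = ground_fit,
                           crosscal = crosscal, composite = composite,
                           biomass = biomass, predictions = predictions,
                           validation = validation, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== inversion pipeline result ==\n")
  print(x$campaign)
  print(x$comparison)
  print(x$crosscal)
  print(x$composite)
  print(x$validation)
  invisible(x)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_campaign(result$campaign, out_dir)
  utils::write.csv(cbind(statistic = rownames(result$comparison$table),
                         result$comparison$table),
                   file.path(out_dir, "comparison_table.csv"),
                   row.names = FALSE)
  fits <- lapply(Filter(Negate(is.null), result$comparison$fits), function(f) {
    f[c("family", "a", "b", "n", "r2", "adj_r2", "r2_fit_scale")]
  })
  jsonlite::write_json(list(fits = fits,
                            selected = result$comparison$selected,
                            split = result$split[c("sizes", "seed")]),
                       file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(result$crosscal),
                       file.path(out_dir, "crosscal.json"),
                       auto_unbox = TRUE, digits = NA)
  write_composite_model(result$composite,
                        file.path(out_dir, "composite_model.json"))
  write_ascii_grid(result$biomass$grid, file.path(out_dir, "agb.asc"))
  utils::write.csv(result$predictions,
                   file.path(out_dir, "predictions.csv"), row.names = FALSE)
  write_validation_report(result$validation,
                          file.path(out_dir, "validation_report.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("grassinvert")),
    campaign_seed = result$campaign$config$seed,
    split_seed = result$split$seed,
    selected_family = result$comparison$selected,
    composite = result$composite[c("a", "b", "c", "d")],
    validation = result$validation[c("n", "se", "mec", "r2")],
    outputs = c("quadrats.csv", "plots.csv", "spectra.csv", "ndvi.asc",
                "config.json", "comparison_table.csv", "fits.json",
                "crosscal.json", "composite_model.json", "agb.asc",
                "predictions.csv", "validation_report.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Recompute the analysis from deposited field tables
#'
#' Runs the analysis stages on externally supplied tables instead of a
#' simulated campaign: the family comparison on the quadrat table (split
#' per `split`/`seed`), the plot-level cross-calibration, their composition,
#' and — when an actual/predicted table is supplied — the final validation
#' statistics. This is the entry point for reproducing published statistics
#' from a study's deposited quadrat, plot and validation tables.
#'
#' @param quadrats data frame (or CSV path) with columns `soc_ndvi`,
#'   `agb_g_m2` and optionally `quadrat_id`.
#' @param plots data frame (or CSV path) with columns `soc_ndvi_mean`,
#'   `tm_ndvi`.
#' @param validation_pairs optional data frame (or CSV path) with columns
#'   `actual` and `predicted` (g m\eqn{^{-2}}).
#' @param split,seed passed to [split_data()].
#' @return A list with `comparison`, `ground_fit`, `crosscal`, `composite`,
#'   and (if pairs were given) `validation`.
#' @export
analyze_field_tables <- function(quadrats, plots, validation_pairs = NULL,
                                 split = c(153, 20, 115), seed = 1L) {
  as_table <- function(x) if (is.character(x)) utils::read.csv(x) else x
  quadrats <- as_table(quadrats)
  plots <- as_table(plots)
  validation_pairs <- if (!is.null(validation_pairs)) {
    as_table(validation_pairs)
  }
  if (!"quadrat_id" %in% names(quadrats)) {
    quadrats$quadrat_id <- seq_len(nrow(quadrats))
  }
  sp <- split_data(quadrats$quadrat_id, sizes = split, seed = seed)
  train <- quadrats[quadrats$quadrat_id %in% sp$train_ids, ]
  test <- quadrats[quadrats$quadrat_id %in% sp$test_ids, ]
  comparison <- compare_families(train, test)
  ground_fit <- comparison$fits[["exponential"]]
  crosscal <- fit_cross_calibration(plots)
  out <- list(comparison = comparison, ground_fit = ground_fit,
              crosscal = crosscal,
              composite = compose_model(ground_fit, crosscal))
  if (!is.null(validation_pairs)) {
    out$validation <- validate_predictions(validation_pairs$actual,
                                           validation_pairs$predicted)
  }
  out
}
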