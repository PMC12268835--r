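.manifest <- function(stage, seeds, counts) {
  list(stage = stage,
       package = as.character(utils::packageVersion("mimicsLitter")),
       r_version = R.version.string,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       seeds = seeds, counts = counts)
}

#' Run the historical experiment
#'
#' Steady states, litterbag simulations and effect sizes for the seven-site
#' historical design (7 sites x 3 litters x 3 soil moistures = 63 runs)
#' under the default parameters and, optionally, each calibrated multiplier
#' set.
#'
#' @param sites Rows of [siteTable()] (defaults to the calibration sites).
#' @param params Default parameter set.
#' @param sets Calibrated multiplier sets (data.frame as [calibratedSets()]);
#'   `NULL` runs the default parameterisation only.
#' @param forcing_seed Daily-climatology seed.
#' @param out_dir Optional directory to write result CSVs into.
#' @return List: `steady`, `runs` and `effects` per parameterisation
#'   (`default` plus one per set), and a `manifest`.
#' @export
runHistorical <- function(sites = siteTable("calibration"),
                          params = mimicsParams(), sets = calibratedSets(),
                          forcing_seed = 1L, out_dir = NULL) {
  par_list <- list(default = params)
  if (!is.null(sets)) {
    for (i in seq_len(nrow(sets))) {
      par_list[[sets$set_id[i]]] <- applyMultipliers(params, sets[i, ])
    }
  }
  res <- lapply(par_list, function(p) {
    steady <- steadyStateTable(sites, p)
    runs <- litterbagDesign(sites, p, steady = steady,
                            forcing_seed = forcing_seed)
    eff <- fitMassLossModel(preparePredictors(runsToObservations(runs)))
    list(steady = steady, runs = runs, effects = eff)
  })
  out <- list(results = res,
              manifest = .manifest("historical",
                                   seeds = list(forcing = forcing_seed),
                                   counts = list(
                                     sites = nrow(sites),
                                     runs_default = nrow(res$default$steady),
                                     parameterisations = length(par_list))))
  if (!is.null(out_dir)) .writeBundle(out, out_dir, "historical")
  out
}

#' Run the validation experiment
#'
#' Default and calibrated simulations at the held-out validation sites, with
#' goodness of fit against supplied (or synthetic) observed site-mean mass
#' loss.
#'
#' @param sites Validation site rows; must include the three held-out sites.
#' @param observed Optional list with `means` (`site_id`, `timepoint`,
#'   `mass_loss_pct`); `NULL` generates synthetic observations from the
#'   default model.
#' @inheritParams runHistorical
#' @return List: per-parameterisation runs and RMSE vs the observations,
#'   plus a `manifest`.
#' @export
runValidation <- function(sites = siteTable("validation"),
                          observed = NULL, params = mimicsParams(),
                          sets = calibratedSets(), forcing_seed = 1L,
                          out_dir = NULL) {
  need <- c("UNDE", "MLBS", "SCBI")
  missing <- setdiff(need, sites$site_id)
  if (length(missing)) {
    stop("validation site table lacks required site(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(observed)) {
    observed <- syntheticObservedMassLoss(sites, params = params,
                                          seed = forcing_seed,
                                          forcing_seed = forcing_seed)
  }
  hist <- runHistorical(sites, params, sets, forcing_seed)
  fits <- lapply(hist$results, function(r) {
    m <- merge(aggregate(mass_loss_pct ~ site_id + timepoint, r$runs, mean),
               observed$means, by = c("site_id", "timepoint"),
               suffixes = c("_sim", "_obs"))
    c(rmse = sqrt(mean((m$mass_loss_pct_sim - m$mass_loss_pct_obs)^2)),
      bias = mean(m$mass_loss_pct_sim - m$mass_loss_pct_obs))
  })
  out <- list(results = hist$results, goodness_of_fit = fits,
              observed = observed,
              manifest = .manifest("validation",
                                   seeds = list(forcing = forcing_seed),
                                   counts = list(
                                     sites = nrow(sites),
                                     runs_per_parameterisation =
                                       nrow(hist$results$default$steady))))
  if (!is.null(out_dir)) .writeBundle(out, out_dir, "validation")
  out
}

#' Run the climate-change experiment
#'
#' Anomaly-forced future runs for the default and calibrated models, the
#' per-run change in mass loss, the calibrated-vs-default difference table
#' (7 sites x 2 timepoints x 3 litters x 3 moistures = 126 rows) and its
#' mixed-model driver analysis in the three covariate variants.
#'
#' @param anomaly A `climate_anomaly` (default: the synthetic SSP-like
#'   anomaly).
#' @inheritParams runHistorical
#' @return List: `historical` and `future` run tables per parameterisation,
#'   `response` (the difference table), `drivers` (one fit per covariate
#'   variant), `manifest`.
#' @export
runClimate <- function(sites = siteTable("calibration"),
                       anomaly = syntheticAnomaly(),
                       params = mimicsParams(), sets = calibratedSets(),
                       forcing_seed = 1L, out_dir = NULL) {
  par_list <- list(default = params)
  for (i in seq_len(nrow(sets))) {
    par_list[[sets$set_id[i]]] <- applyMultipliers(params, sets[i, ])
  }
  hist <- lapply(par_list, function(p) {
    litterbagDesign(sites, p, forcing_seed = forcing_seed)
  })
  future <- lapply(par_list, function(p) {
    litterbagDesignFuture(sites, anomaly, p, forcing_seed = forcing_seed)
  })
  cal_ids <- setdiff(names(par_list), "default")
  response <- climateResponse(hist$default, future$default,
                              hist[cal_ids], future[cal_ids])
  drivers <- lapply(c("historical", "future", "delta"), function(v) {
    driverAnalysis(response, sites, anomaly, v)
  })
  names(drivers) <- c("historical", "future", "delta")
  out <- list(historical = hist, future = future, response = response,
              drivers = drivers,
              manifest = .manifest("climate",
                                   seeds = list(forcing = forcing_seed),
                                   counts = list(
                                     response_rows = nrow(response),
                                     parameterisations = length(par_list))))
  if (!is.null(out_dir)) .writeBundle(out, out_dir, "climate")
  out
}

.writeBundle <- function(bundle, dir, stage) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$results)) {
    for (nm in names(bundle$results)) {
      write.csv(bundle$results[[nm]]$runs,
                file.path(dir, paste0(stage, "_runs_", nm, ".csv")),
                row.names = FALSE)
    }
  }
  if (!is.null(bundle$response)) {
    write.csv(bundle$response, file.path(dir, paste0(stage, "_response.csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
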