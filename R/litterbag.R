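#' Initialise a litterbag
#'
#' Partitions the initial bag carbon between metabolic and structural litter
#' by [fmetFraction()] of the litter's lignin:N ratio. The default initial
#' carbon density corresponds to roughly 5 g of leaf litter (45% C) in a
#' 20 x 20 cm bag spread over the configured bulk-soil depth.
#'
#' @param lignin_n Litter lignin:N ratio.
#' @param params A [MimicsParams-class] object.
#' @param bag0 Initial bag carbon (mgC cm-3).
#' @return Named numeric vector `c(bag_m =, bag_s =)` summing to `bag0`.
#' @export
initializeLitterbag <- function(lignin_n, params = mimicsParams(),
                                bag0 = 0.056) {
  fmet <- fmetFraction(lignin_n, params)
  c(bag_m = bag0 * fmet, bag_s = bag0 * (1 - fmet))
}

#' Simulate litterbag decomposition over a steady-state background
#'
#' Overlays metabolic and structural litterbag pools on a converged site
#' steady state and decomposes them day by day with the background microbial
#' pools (held fixed at steady state) and the daily temperature / moisture
#' climatology, cycled over years. All decomposed carbon - the respired and
#' the would-be-assimilated share alike - leaves the system; the bag feeds
#' nothing back to the underlying model.
#'
#' @param background A steady state from [steadyState()] (its `forcing`
#'   attribute supplies the lignin:N ratio unless `lignin_n` is given).
#' @param daily Daily forcing climatology from [generateDailyForcing()]
#'   (365 rows).
#' @param params A [MimicsParams-class] object.
#' @param years Number of calendar years simulated (deployment year included).
#' @param deployment_day Day of year of deployment (315 = November 11).
#' @param lignin_n Optional override of the bag litter's lignin:N.
#' @param bag0 Initial bag carbon (mgC cm-3).
#' @param substeps Integration substeps per day (daily RK4 within each).
#' @return data.frame with `day` (0 = deployment), `mass_remaining`
#'   (fraction of initial), `bag_m`, `bag_s`; attributes `respired` and
#'   `assimilated` give the cumulative split of the lost carbon.
#' @export
simulateLitterbag <- function(background, daily, params = mimicsParams(),
                              years = 3, deployment_day = 315,
                              lignin_n = NULL, bag0 = 0.056, substeps = 1) {
  forcing <- attr(background, "forcing")
  if (is.null(forcing) || !isTRUE(attr(background, "converged"))) {
    stop("background must be a converged steady state from steadyState()")
  }
  if (is.null(lignin_n)) lignin_n <- forcing$lignin_n
  stopifnot(nrow(daily) == 365)
  bag <- initializeLitterbag(lignin_n, params, bag0)

  # daily series from deployment to the end of the final calendar year
  ndays <- years * 365 - deployment_day
  idx <- ((deployment_day + seq_len(ndays) - 1) %% 365) + 1
  res <- .litterbagRunCpp(bag[["bag_m"]], bag[["bag_s"]],
                          background[["mic_r"]], background[["mic_k"]],
                          daily$soil_t[idx], daily$moisture[idx],
                          .paramVector(params), substeps = substeps)
  out <- data.frame(day = 0:ndays,
                    mass_remaining = res$mass / res$mass[1],
                    bag_m = res$bag_m, bag_s = res$bag_s)
  attr(out, "respired") <- res$respired
  attr(out, "assimilated") <- res$assimilated
  out
}

#' Percent mass loss at the collection timepoints
#'
#' Field collections happened roughly 10 and 21 months after deployment;
#' with 1 month = 30.42 days these land at days 304 and 639.
#'
#' @param series Result of [simulateLitterbag()] (or any data.frame with
#'   `day` and `mass_remaining`).
#' @param months Numeric vector of collection timepoints in months.
#' @return Named numeric vector of percent mass loss, one per timepoint.
#' @export
massLossAt <- function(series, months = c(10, 21)) {
  days <- round(months * 30.42)
  if (max(days) > max(series$day)) {
    stop("series too short: needs at least ", max(days), " days")
  }
  loss <- vapply(days, function(d) {
    100 * (1 - series$mass_remaining[match(d, series$day)])
  }, numeric(1))
  setNames(loss, paste0("t", seq_along(months)))
}

#' Run the litterbag design for a set of sites under one parameterisation
#'
#' Enumerates site x litter x moisture variant (the 63-run historical design
#' for the seven calibration sites), simulates each litterbag, and tabulates
#' mass loss at the two collection timepoints.
#'
#' @param sites Rows of [siteTable()].
#' @param params A [MimicsParams-class] object.
#' @param steady Optional precomputed [steadyStateTable()] for `sites` under
#'   `params` (computed if `NULL`).
#' @param forcing_seed Seed for the daily climatologies.
#' @param years,deployment_day,bag0 Passed to [simulateLitterbag()].
#' @return data.frame: one row per run and timepoint with `site_id`,
#'   `litter_id`, `moisture_variant`, `timepoint`, `mass_loss_pct`, plus the
#'   run's steady-state `co_ratio`, `moisture`, `lignin_n` and viability
#'   flags (the predictors of the model-output effect-size stage).
#' @export
litterbagDesign <- function(sites, params = mimicsParams(), steady = NULL,
                            forcing_seed = 1L, years = 3,
                            deployment_day = 315, bag0 = 0.056) {
  if (is.null(steady)) steady <- steadyStateTable(sites, params)
  pv <- .paramVector(params)
  n <- nrow(steady)
  ndays <- years * 365 - deployment_day
  idx <- ((deployment_day + seq_len(ndays) - 1) %% 365) + 1
  tp_days <- round(c(10, 21) * 30.42) + 1L   # series index of each timepoint
  site_rows <- match(steady$site_id, sites$site_id)
  mult <- ifelse(steady$moisture_variant == "min", sites$mult_min[site_rows],
                 ifelse(steady$moisture_variant == "max",
                        sites$mult_max[site_rows], 1))
  fmet <- fmetFraction(steady$lignin_n, params)
  loss <- matrix(NA_real_, n, 2)
  for (j in seq_len(n)) {
    daily <- .dailyForcingCached(sites[site_rows[j], , drop = FALSE],
                                 forcing_seed, mult[j])
    res <- .litterbagRunCpp(bag0 * fmet[j], bag0 * (1 - fmet[j]),
                            steady$mic_r[j], steady$mic_k[j],
                            daily$soil_t[idx], daily$moisture[idx], pv,
                            substeps = 1L)
    loss[j, ] <- 100 * (1 - res$mass[tp_days] / res$mass[1])
  }
  out <- data.frame(
    site_id = rep(steady$site_id, 2), litter_id = rep(steady$litter_id, 2),
    moisture_variant = rep(steady$moisture_variant, 2),
    timepoint = rep(1:2, each = n), mass_loss_pct = c(loss[, 1], loss[, 2]),
    lignin_n = rep(steady$lignin_n, 2), moisture = rep(steady$moisture, 2),
    co_ratio = rep(steady$co_ratio, 2),
    viable_r = rep(steady$viable_r, 2), viable_k = rep(steady$viable_k, 2))
  rownames(out) <- NULL
  out
}

# daily climatologies are deterministic in (site, seed, multiplier): memoise
.forcingCache <- new.env(parent = emptyenv())

.dailyForcingCached <- function(site, seed, mult) {
  key <- paste(site$site_id, seed, signif(mult, 12), sep = "|")
  hit <- .forcingCache[[key]]
  if (!is.null(hit)) return(hit)
  val <- generateDailyForcing(site, seed = seed, moisture_mult = mult)
  .forcingCache[[key]] <- val
  val
}
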