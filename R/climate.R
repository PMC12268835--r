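.MONTH_OF_DOY <- rep(1:12, c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))

#' Apply a monthly climate anomaly to a daily climatology
#'
#' Adds each month's temperature delta to the daily soil temperature, adds
#' the moisture delta to the soil-moisture scalar (clipping to \eqn{[0, 1]}
#' and flagging clipped days), and scales daily litterfall by the month's
#' multiplier. A zero anomaly is the identity.
#'
#' @param daily Daily climatology from [generateDailyForcing()].
#' @param anomaly A `climate_anomaly` data.frame (`year`, `month`, `d_temp`,
#'   `d_moisture`, `litterfall_mult`); multiple years are averaged by month
#'   unless `year` selects one.
#' @param year Optional single anomaly year to use.
#' @return The perturbed daily climatology; attribute `clipped_days` counts
#'   moisture values clipped at the bounds.
#' @export
applyAnomalies <- function(daily, anomaly, year = NULL) {
  stopifnot(nrow(daily) == 365)
  if (!is.null(year)) anomaly <- anomaly[anomaly$year == year, , drop = FALSE]
  if (!all(1:12 %in% anomaly$month)) {
    stop("anomaly calendar does not cover all 12 months")
  }
  am <- aggregate(cbind(d_temp, d_moisture, litterfall_mult) ~ month,
                  anomaly, mean)
  am <- am[order(am$month), ]
  mo <- .MONTH_OF_DOY[daily$doy]
  out <- daily
  out$soil_t <- daily$soil_t + am$d_temp[mo]
  raw <- daily$moisture + am$d_moisture[mo]
  out$moisture <- pmin(pmax(raw, 0), 1)
  out$litterfall <- daily$litterfall * am$litterfall_mult[mo]
  attr(out, "clipped_days") <- sum(raw < 0 | raw > 1)
  attr(out, "site_id") <- attr(daily, "site_id")
  out
}

#' Site table under a climate anomaly
#'
#' Shifts the annual-mean forcing statistics of each site by the anomaly's
#' annual means (temperature and moisture additive, moisture clipped;
#' litterfall multiplicative), giving the constant forcing from which future
#' steady states are solved.
#'
#' @param sites Rows of [siteTable()].
#' @param anomaly A `climate_anomaly` data.frame.
#' @return The modified site table.
#' @export
futureSites <- function(sites, anomaly) {
  out <- sites
  out$soil_t_mean <- sites$soil_t_mean + mean(anomaly$d_temp)
  out$moisture_mean <- pmin(pmax(sites$moisture_mean +
                                   mean(anomaly$d_moisture), 0), 1)
  out$litterfall <- sites$litterfall * mean(anomaly$litterfall_mult)
  out
}

#' Run the litterbag design under anomaly forcing
#'
#' Future counterpart of [litterbagDesign()]: steady states are re-solved
#' from the anomaly-shifted annual means and litterbags decompose under the
#' anomaly-perturbed daily climatology.
#'
#' @param sites Rows of [siteTable()] (historical statistics).
#' @param anomaly A `climate_anomaly` data.frame.
#' @param params A [MimicsParams-class] object.
#' @param forcing_seed Daily-climatology seed (shared with the historical
#'   runs so only the anomaly differs).
#' @return As [litterbagDesign()].
#' @export
litterbagDesignFuture <- function(sites, anomaly, params = mimicsParams(),
                                  forcing_seed = 1L) {
  fsites <- futureSites(sites, anomaly)
  steady <- steadyStateTable(fsites, params)
  pv <- .paramVector(params)
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(fsites))) {
    site <- fsites[i, , drop = FALSE]
    hsite <- sites[i, , drop = FALSE]
    sub <- steady[steady$site_id == site$site_id, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      run <- sub[j, ]
      mult <- switch(run$moisture_variant, mean = 1, min = site$mult_min,
                     max = site$mult_max)
      daily <- applyAnomalies(
        generateDailyForcing(hsite, seed = forcing_seed,
                             moisture_mult = mult), anomaly)
      bag <- initializeLitterbag(run$lignin_n, params)
      ndays <- 3 * 365 - 315
      idx <- ((315 + seq_len(ndays) - 1) %% 365) + 1
      res <- .litterbagRunCpp(bag[["bag_m"]], bag[["bag_s"]],
                              run$mic_r, run$mic_k,
                              daily$soil_t[idx], daily$moisture[idx], pv,
                              substeps = 1L)
      series <- data.frame(day = 0:ndays,
                           mass_remaining = res$mass / res$mass[1])
      loss <- massLossAt(series)
      for (tp in seq_along(loss)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          site_id = run$site_id, litter_id = run$litter_id,
          moisture_variant = run$moisture_variant, timepoint = tp,
          mass_loss_pct = loss[[tp]], lignin_n = run$lignin_n,
          moisture = run$moisture, co_ratio = run$co_ratio,
          viable_r = run$viable_r, viable_k = run$viable_k)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Climate-change response and calibrated-vs-default difference
#'
#' Computes the per-run change in mass loss from the historical to the
#' future run (`delta = future - historical`) for the default and each
#' calibrated parameterisation, and the percent difference between the
#' calibrated (mean over sets) and default responses. Where the default
#' response is below `guard` percentage points in magnitude the ratio is
#' unstable and the absolute difference is reported instead (flagged).
#'
#' @param hist_default,future_default [litterbagDesign()] /
#'   [litterbagDesignFuture()] results under default parameters.
#' @param hist_calibrated,future_calibrated Named lists of run tables, one
#'   per calibrated set.
#' @param guard Minimum `|delta_default|` for a percent difference.
#' @return data.frame keyed by site, litter, moisture variant and timepoint
#'   with `delta_default`, `delta_calibrated`, `difference` and
#'   `difference_type` (`"percent"` or `"absolute"`).
#' @export
climateResponse <- function(hist_default, future_default,
                            hist_calibrated, future_calibrated,
                            guard = 0.1) {
  key <- c("site_id", "litter_id", "moisture_variant", "timepoint")
  .keyString <- function(x) do.call(paste, c(x[key], sep = "|"))
  .delta <- function(h, f) {
    if (nrow(h) != nrow(f)) stop("unmatched run designs between eras")
    m <- merge(h[, c(key, "mass_loss_pct")], f[, c(key, "mass_loss_pct")],
               by = key, suffixes = c("_hist", "_future"))
    if (nrow(m) != nrow(h)) stop("unmatched run designs between eras")
    m$delta <- m$mass_loss_pct_future - m$mass_loss_pct_hist
    m <- m[order(.keyString(m)), c(key, "delta")]
    rownames(m) <- NULL
    m
  }
  dd <- .delta(hist_default, future_default)
  stopifnot(length(hist_calibrated) == length(future_calibrated))
  dcs <- lapply(seq_along(hist_calibrated), function(i) {
    .delta(hist_calibrated[[i]], future_calibrated[[i]])
  })
  dc <- dcs[[1]]
  if (length(dcs) > 1) {
    for (i in 2:length(dcs)) {
      if (!identical(.keyString(dc), .keyString(dcs[[i]]))) {
        stop("calibrated run designs do not match")
      }
      dc$delta <- dc$delta + dcs[[i]]$delta
    }
    dc$delta <- dc$delta / length(dcs)
  }
  out <- merge(dd, dc, by = key, suffixes = c("_default", "_calibrated"))
  small <- abs(out$delta_default) < guard
  out$difference <- ifelse(small,
                           out$delta_calibrated - out$delta_default,
                           100 * (out$delta_calibrated - out$delta_default) /
                             abs(out$delta_default))
  out$difference_type <- ifelse(small, "absolute", "percent")
  out
}

#' Drivers of the calibrated-vs-default climate response
#'
#' Mixed-effects model of the calibrated-vs-default difference on site clay,
#' site soil-moisture variability (max minus min multiplier) and litter
#' quality, plus annual litterfall, mean soil temperature and the run's soil
#' moisture in one of three covariate variants: their historical values,
#' their future values, or the future-minus-historical change. Moisture
#' levels are log transformed (the delta variant uses the raw change);
#' all predictors are standardized; "plot" (litter x moisture combination)
#' is nested within site as a random intercept.
#'
#' @param differences Result of [climateResponse()].
#' @param sites Rows of [siteTable()].
#' @param anomaly The `climate_anomaly` used for the future runs.
#' @param variant `"historical"`, `"future"` or `"delta"`.
#' @return List: `coefficients` (standardized fixed effects), `fit`,
#'   `variant`.
#' @export
driverAnalysis <- function(differences, sites,
                           anomaly = syntheticAnomaly(),
                           variant = c("historical", "future", "delta")) {
  variant <- match.arg(variant)
  d <- differences
  si <- sites[match(d$site_id, sites$site_id), ]
  if (is.null(d$lignin_n)) {
    cols <- match(paste0("lignin_n_", d$litter_id), names(si))
    d$lignin_n <- as.numeric(si[cbind(seq_len(nrow(si)), cols)])
  }
  dT <- mean(anomaly$d_temp)
  dM <- mean(anomaly$d_moisture)
  lmult <- mean(anomaly$litterfall_mult)
  moist_hist <- si$moisture_mean *
    ifelse(d$moisture_variant == "min", si$mult_min,
           ifelse(d$moisture_variant == "max", si$mult_max, 1))
  covs <- switch(variant,
    historical = data.frame(litterfall = si$litterfall,
                            soil_t = si$soil_t_mean,
                            moisture = log(moist_hist)),
    future = data.frame(litterfall = si$litterfall * lmult,
                        soil_t = si$soil_t_mean + dT,
                        moisture = log(pmin(pmax(moist_hist + dM, 1e-6), 1))),
    delta = data.frame(litterfall = si$litterfall * (lmult - 1),
                       soil_t = rep(dT, nrow(d)),
                       moisture = pmin(pmax(moist_hist + dM, 0), 1) -
                         moist_hist))
  dat <- data.frame(y = d$difference,
                    clay = si$clay_pct,
                    moist_var = si$mult_max - si$mult_min,
                    lignin_n = d$lignin_n, covs,
                    site = d$site_id,
                    plot = paste(d$litter_id, d$moisture_variant, sep = "."))
  zc <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  preds <- c("clay", "moist_var", "lignin_n", "litterfall", "soil_t",
             "moisture")
  for (p in preds) dat[[paste0("z_", p)]] <- zc(dat[[p]])
  keep <- preds[vapply(preds, function(p) sd(dat[[p]]) > 0, logical(1))]
  dat$plot_in_site <- interaction(dat$site, dat$plot, drop = TRUE)
  form <- as.formula(paste("y ~", paste(paste0("z_", keep), collapse = " + "),
                           "+ (1 | site) + (1 | plot_in_site)"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = TRUE, control = ctrl)))
  co <- lme4::fixef(fit)
  co <- co[setdiff(names(co), "(Intercept)")]
  names(co) <- sub("^z_", "", names(co))
  list(coefficients = co, fit = fit, variant = variant, n = nrow(dat))
}
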