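#' Draw Monte Carlo multiplier sets
#'
#' Independent uniform draws of the four calibration multipliers within their
#' admissible ranges.
#'
#' @param n Number of sets (the full calibration used 5000).
#' @param ranges Ranges as from [multiplierRanges()].
#' @param seed Integer seed.
#' @return data.frame with `draw`, `m_tau_r`, `m_beta`, `m_vmod_m`,
#'   `m_vmod_s`.
#' @export
sampleParameterSets <- function(n = 5000, ranges = multiplierRanges(),
                                seed = 1L) {
  stopifnot(n >= 1)
  for (r in ranges) if (length(r) != 2 || r[1] >= r[2]) stop("invalid range")
  .withSeed(seed, {
    out <- data.frame(draw = seq_len(n))
    for (nm in names(ranges)) {
      out[[nm]] <- runif(n, ranges[[nm]][1], ranges[[nm]][2])
    }
    out
  })
}

#' Evaluate one multiplier set against observations
#'
#' Applies the multipliers to the default parameters, runs the full
#' site x litter x moisture litterbag design, fits the model-output
#' effect-size regression, and measures RMSE between site-mean simulated and
#' observed mass loss across sites and timepoints.
#'
#' @param mults Named multipliers (one row of [sampleParameterSets()]).
#' @param sites Rows of [siteTable()].
#' @param observed List with `means` (site x timepoint observed means) as
#'   produced by [syntheticObservedMassLoss()] or assembled from field data.
#' @param params Default parameter set.
#' @param warm Optional warm-start [steadyStateTable()] computed under the
#'   multiplied parameters themselves (same-parameterisation reuse only).
#' @param forcing_seed Seed of the daily climatologies.
#' @param fitter Optional fast effect fitter from [makeEffectFitter()]
#'   (defaults to [fitMassLossModel()]).
#' @return An `eval_record` list: `mults`, `site_means`, `rmse`, `effects`
#'   (relative effect sizes), `viable_all`, `failed` (solver failure is
#'   recorded, not silently dropped).
#' @export
evaluateSet <- function(mults, sites, observed, params = mimicsParams(),
                        warm = NULL, forcing_seed = 1L, fitter = NULL) {
  if (is.data.frame(mults)) mults <- unlist(mults[1, c("m_tau_r", "m_beta",
                                                       "m_vmod_m", "m_vmod_s")])
  rec <- list(mults = mults, failed = FALSE, message = NULL)
  res <- tryCatch({
    par_c <- applyMultipliers(params, mults)
    steady <- steadyStateTable(sites, par_c, warm = warm)
    runs <- litterbagDesign(sites, par_c, steady = steady,
                            forcing_seed = forcing_seed)
    site_means <- aggregate(mass_loss_pct ~ site_id + timepoint, runs, mean)
    design <- preparePredictors(runsToObservations(runs))
    eff <- if (is.null(fitter)) fitMassLossModel(design) else fitter(design)
    m <- merge(site_means, observed$means, by = c("site_id", "timepoint"),
               suffixes = c("_sim", "_obs"))
    list(site_means = site_means,
         rmse = sqrt(mean((m$mass_loss_pct_sim - m$mass_loss_pct_obs)^2)),
         effects = eff$relative,
         viable_all = all(runs$viable_r | runs$viable_k),
         runs = runs)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    rec$failed <- TRUE
    rec$message <- conditionMessage(res)
    rec$rmse <- NA_real_
    rec$effects <- c(moisture = NA_real_, lignin_n = NA_real_,
                     co_ratio = NA_real_)
    rec$viable_all <- FALSE
  } else {
    rec <- c(rec, res)
  }
  class(rec) <- "eval_record"
  rec
}

#' Apply the four calibration filters
#'
#' A record survives iff it (1) keeps simulated site-mean mass loss within
#' the observed minimum-maximum envelope for every site and timepoint,
#' (2) has relative effect sizes within `effect_tol` units of the observed
#' ones for all three drivers, (3) has RMSE below `rmse_max` percent, and
#' (4) maintains a viable copiotrophic or oligotrophic group in every run.
#'
#' @param records List of `eval_record`s from [evaluateSet()].
#' @param envelope Observed envelope (`site_id`, `timepoint`,
#'   `mass_loss_pct_min`, `mass_loss_pct_max`).
#' @param observed_effects Observed relative effect sizes (named, three
#'   drivers).
#' @param rmse_max RMSE threshold (%; default 5.4).
#' @param effect_tol Per-driver tolerance on the relative-effect-size scale
#'   (default 10); a length-3 vector gives per-driver tolerances.
#' @return List: `survivors` (indices), `verdicts` (logical matrix, one
#'   column per criterion), `failure_counts`.
#' @export
filterSets <- function(records, envelope, observed_effects, rmse_max = 5.4,
                       effect_tol = 10) {
  if (length(effect_tol) == 1) effect_tol <- rep(effect_tol, 3)
  verdicts <- t(vapply(records, function(r) {
    if (r$failed) return(c(envelope = FALSE, effects = FALSE, rmse = FALSE,
                           viability = FALSE))
    m <- merge(r$site_means, envelope, by = c("site_id", "timepoint"))
    c(envelope = all(m$mass_loss_pct >= m$mass_loss_pct_min &
                       m$mass_loss_pct <= m$mass_loss_pct_max),
      effects = all(abs(r$effects - observed_effects[names(r$effects)]) <=
                      effect_tol),
      rmse = r$rmse < rmse_max,
      viability = isTRUE(r$viable_all))
  }, logical(4)))
  keep <- rowSums(verdicts) == 4L
  list(survivors = which(keep), verdicts = verdicts,
       failure_counts = colSums(!verdicts))
}

#' Select the best surviving parameter sets
#'
#' Survivors are ranked by ascending mass-loss RMSE - matching decomposition
#' is prioritised over matching effect sizes - with ties broken by the summed
#' absolute effect-size deviation from the observations.
#'
#' @param records List of `eval_record`s.
#' @param survivors Indices from [filterSets()].
#' @param observed_effects Observed relative effect sizes (for the
#'   tie-break).
#' @param k Number of sets to keep (default 3).
#' @return data.frame of the ranked selections (index, multipliers, RMSE,
#'   effect deviation); fewer than `k` survivors are all returned with a
#'   warning.
#' @export
selectBest <- function(records, survivors, observed_effects, k = 3) {
  if (length(survivors) == 0) {
    stop("no surviving parameter sets; consider loosening the filter thresholds")
  }
  if (length(survivors) < k) {
    warning("only ", length(survivors), " survivors for k = ", k)
  }
  tab <- do.call(rbind, lapply(survivors, function(i) {
    r <- records[[i]]
    data.frame(index = i, t(r$mults), rmse = r$rmse,
               eff_dev = sum(abs(r$effects -
                                   observed_effects[names(r$effects)])))
  }))
  tab <- tab[order(tab$rmse, tab$eff_dev), , drop = FALSE]
  head(tab, k)
}

#' Stability of the selection under run holdout
#'
#' Repeats filtering and selection on random subsets that leave out a
#' fraction of the evaluated runs, and reports how consistently the
#' full-data selections are re-selected: for each replicate, the fraction of
#' full-data selected sets that remain available and are selected again.
#'
#' @param records List of `eval_record`s.
#' @param envelope,observed_effects,rmse_max,effect_tol As in [filterSets()].
#' @param holdout Fraction of records left out per replicate (default 0.10).
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @param k Selection size.
#' @return List: `overlap` (per-replicate fractions), `mean_overlap`,
#'   `full_selection` (indices).
#' @export
stabilityCheck <- function(records, envelope, observed_effects,
                           rmse_max = 5.4, effect_tol = 10, holdout = 0.10,
                           replicates = 20, seed = 1L, k = 3) {
  if (length(records) < 10) stop("need at least 10 records")
  flt <- filterSets(records, envelope, observed_effects, rmse_max, effect_tol)
  full_sel <- selectBest(records, flt$survivors, observed_effects, k)$index
  n <- length(records)
  overlap <- .withSeed(seed, {
    vapply(seq_len(replicates), function(rep) {
      keep <- sort(sample(n, round((1 - holdout) * n)))
      sub_flt_surv <- intersect(flt$survivors, keep)
      if (length(sub_flt_surv) == 0) return(0)
      sub_sel <- selectBest(records, sub_flt_surv, observed_effects, k)$index
      avail <- intersect(full_sel, keep)
      if (length(avail) == 0) return(NA_real_)
      mean(avail %in% sub_sel)
    }, numeric(1))
  })
  list(overlap = overlap, mean_overlap = mean(overlap, na.rm = TRUE),
       full_selection = full_sel)
}

#' Full Monte Carlo calibration
#'
#' Orchestrates the calibration stage: draws multiplier sets, evaluates each
#' against the observations (with warm-started steady states), applies the
#' four filters, ranks the survivors, and runs the holdout stability check.
#'
#' @param sites Rows of [siteTable()].
#' @param observed Observation list with `means`, `envelope`, `effects`
#'   (as from [syntheticObservedMassLoss()] or field data of that shape).
#' @param n Number of Monte Carlo draws.
#' @param seed Integer seed.
#' @param params Default parameter set.
#' @param rmse_max,effect_tol Filter thresholds.
#' @param k Number of best sets.
#' @param forcing_seed Daily-climatology seed.
#' @param stability Run the holdout stability check?
#' @return A `calibration_result` list: `draws`, `records`, `summary`
#'   (one row per draw), `filter`, `best`, `stability`.
#' @export
calibrate <- function(sites, observed, n = 5000, seed = 1L,
                      params = mimicsParams(), rmse_max = 5.4,
                      effect_tol = 10, k = 3, forcing_seed = 1L,
                      stability = TRUE) {
  draws <- sampleParameterSets(n, seed = seed)
  template <- preparePredictors(runsToObservations(
    litterbagDesign(sites, params, forcing_seed = forcing_seed)))
  fitter <- makeEffectFitter(template)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    records[[i]] <- evaluateSet(draws[i, ], sites, observed, params,
                                forcing_seed = forcing_seed,
                                fitter = fitter)
  }
  summary_tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- records[[i]]
    data.frame(draw = i, t(r$mults), rmse = r$rmse,
               eff_moisture = r$effects[["moisture"]],
               eff_lignin_n = r$effects[["lignin_n"]],
               eff_co_ratio = r$effects[["co_ratio"]],
               viable_all = r$viable_all, failed = r$failed)
  }))
  flt <- filterSets(records, observed$envelope, observed$effects,
                    rmse_max, effect_tol)
  best <- if (length(flt$survivors)) {
    selectBest(records, flt$survivors, observed$effects, k)
  } else NULL
  stab <- if (stability && length(flt$survivors)) {
    stabilityCheck(records, observed$envelope, observed$effects,
                   rmse_max, effect_tol, seed = seed, k = k)
  } else NULL
  structure(list(draws = draws, records = records, summary = summary_tab,
                 filter = flt, best = best, stability = stab),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Monte Carlo calibration: %d draws, %d survivors\n",
              nrow(x$draws), length(x$filter$survivors)))
  cat("per-criterion failure counts:\n")
  print(x$filter$failure_counts)
  if (!is.null(x$best)) {
    cat("best sets:\n")
    print(x$best, row.names = FALSE)
  }
  invisible(x)
}
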