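#' Configuration of the synthetic observation generator
#'
#' Defaults emulate the field study the pipeline was designed around: seven
#' temperate-forest sites with 5-12 plots each (62 plots, two collection
#' timepoints, 124 rows), a positive standardized soil-moisture effect and
#' negative lignin:N and copiotroph:oligotroph effects on percent mass loss,
#' and site / plot-within-site random intercepts.
#'
#' @param b_moisture,b_lignin_n,b_co_ratio Fixed-effect coefficients on the
#'   standardized scale (percent mass loss per SD).
#' @param intercepts Mean mass loss at the two timepoints (%).
#' @param sd_site,sd_plot,sd_resid Random-intercept and residual SDs (%).
#' @param plots_per_site Named integer vector of plots per site.
#' @param seed Integer seed.
#' @return An `obs_generator_config` list.
#' @export
observationConfig <- function(b_moisture = 8, b_lignin_n = -7,
                              b_co_ratio = -5, intercepts = c(30, 55),
                              sd_site = 5, sd_plot = 3, sd_resid = 5,
                              plots_per_site = c(TREE = 10, BART = 8,
                                                 HARV = 5, GRSM = 5,
                                                 SERC = 12, TALL = 11,
                                                 LENO = 11),
                              seed = 1L) {
  stopifnot(b_moisture > 0, b_lignin_n < 0, b_co_ratio < 0,
            sd_site >= 0, sd_plot >= 0, sd_resid >= 0)
  structure(list(b = c(moisture = b_moisture, lignin_n = b_lignin_n,
                       co_ratio = b_co_ratio),
                 intercepts = intercepts, sd_site = sd_site,
                 sd_plot = sd_plot, sd_resid = sd_resid,
                 plots_per_site = plots_per_site, seed = seed),
            class = "obs_generator_config")
}

#' Generate a synthetic plot-level observation table
#'
#' Draws plot covariates (log-normal soil moisture around each site's mean,
#' lignin:N anchored on the site's three litter values, log-normal
#' copiotroph:oligotroph ratio) and builds percent mass loss as
#' intercept + sum of standardized fixed effects + site and plot random
#' intercepts + residual, clipped to \eqn{[0, 100]}. The generating truth is
#' attached for closed-loop recovery tests.
#'
#' @param cfg An [observationConfig()].
#' @param sites Site table rows anchoring the covariates.
#' @return Observation table (columns `site`, `plot`, `timepoint`,
#'   `mass_loss`, `moisture`, `lignin_n`, `co_ratio`) with attribute `truth`
#'   (the generating coefficients and variance components).
#' @export
generateObservations <- function(cfg = observationConfig(),
                                 sites = siteTable("calibration")) {
  stopifnot(inherits(cfg, "obs_generator_config"))
  sites <- sites[sites$site_id %in% names(cfg$plots_per_site), , drop = FALSE]
  .withSeed(cfg$seed, {
    plot_rows <- list()
    for (i in seq_len(nrow(sites))) {
      site <- sites[i, ]
      np <- cfg$plots_per_site[[site$site_id]]
      lig3 <- siteLigninN(site)
      plot_rows[[i]] <- data.frame(
        site = site$site_id, plot = paste0("p", seq_len(np)),
        moisture = exp(rnorm(np, log(site$moisture_mean), 0.3)),
        lignin_n = pmax(sample(lig3, np, replace = TRUE) + rnorm(np, 0, 3), 2),
        co_ratio = exp(rnorm(np, log(1.5), 0.5)))
    }
    plots <- do.call(rbind, plot_rows)
    zf <- function(x) (x - mean(x)) / sd(x)
    lin <- cfg$b[["moisture"]] * zf(log(plots$moisture)) +
      cfg$b[["lignin_n"]] * zf(plots$lignin_n) +
      cfg$b[["co_ratio"]] * zf(plots$co_ratio)
    site_re <- setNames(rnorm(nrow(sites), 0, cfg$sd_site), sites$site_id)
    plot_re <- rnorm(nrow(plots), 0, cfg$sd_plot)
    out <- do.call(rbind, lapply(1:2, function(tp) {
      mass <- cfg$intercepts[tp] + lin + site_re[plots$site] + plot_re +
        rnorm(nrow(plots), 0, cfg$sd_resid)
      data.frame(site = plots$site, plot = plots$plot, timepoint = tp,
                 mass_loss = pmin(pmax(mass, 0), 100),
                 moisture = plots$moisture, lignin_n = plots$lignin_n,
                 co_ratio = plots$co_ratio)
    }))
    rownames(out) <- NULL
    attr(out, "truth") <- list(b = cfg$b, sd_site = cfg$sd_site,
                               sd_plot = cfg$sd_plot, sd_resid = cfg$sd_resid)
    out
  })
}

#' Generate a labelled synthetic ASV count table
#'
#' Multinomial counts per sample with known copiotroph / oligotroph /
#' unassigned read proportions; lineages are built from the packaged rule set
#' so the classification stage recovers the labels, and the true per-sample
#' ratio is attached.
#'
#' @param n_samples,n_taxa Table dimensions.
#' @param p_copiotroph,p_oligotroph Expected read proportions of each group
#'   (remainder unassigned; must sum to at most 1).
#' @param depth_range Integer range the per-sample depths are drawn from.
#' @param seed Integer seed.
#' @return List: `asv` (an `asv_table`), `groups` (true label per taxon),
#'   `true_ratio` (`p_copiotroph` / `p_oligotroph`), `rules`.
#' @export
generateAsvTable <- function(n_samples = 12, n_taxa = 60,
                             p_copiotroph = 0.35, p_oligotroph = 0.45,
                             depth_range = c(2447, 12000), seed = 1L) {
  stopifnot(p_copiotroph >= 0, p_oligotroph > 0,
            p_copiotroph + p_oligotroph <= 1)
  rules <- classificationRules()
  .withSeed(seed, {
    n_c <- max(round(n_taxa * 0.35), 1)
    n_o <- max(round(n_taxa * 0.35), 1)
    n_u <- n_taxa - n_c - n_o
    cop_names <- rules$name[rules$group == "copiotroph"]
    oli_names <- rules$name[rules$group == "oligotroph"]
    cop_rank <- rules$rank[rules$group == "copiotroph"]
    oli_rank <- rules$rank[rules$group == "oligotroph"]
    ci <- sample(seq_along(cop_names), n_c, replace = TRUE)
    oi <- sample(seq_along(oli_names), n_o, replace = TRUE)
    lineage <- c(paste0(cop_rank[ci], ":", cop_names[ci]),
                 paste0(oli_rank[oi], ":", oli_names[oi]),
                 if (n_u > 0) paste0("phylum:Unknown", seq_len(n_u)))
    groups <- rep(c("copiotroph", "oligotroph", "unassigned"),
                  c(n_c, n_o, n_u))
    # within-group taxon weights vary; group read shares stay as specified
    w <- runif(n_taxa, 0.2, 1)
    prob <- numeric(n_taxa)
    share <- c(copiotroph = p_copiotroph, oligotroph = p_oligotroph,
               unassigned = 1 - p_copiotroph - p_oligotroph)
    for (g in names(share)) {
      sel <- groups == g
      if (any(sel) && share[[g]] > 0) prob[sel] <- share[[g]] * w[sel] / sum(w[sel])
    }
    prob <- prob / sum(prob)
    depths <- sample(depth_range[1]:depth_range[2], n_samples, replace = TRUE)
    counts <- vapply(depths, function(d) rmultinom(1, d, prob)[, 1],
                     integer(n_taxa))
    rownames(counts) <- paste0("ASV", seq_len(n_taxa))
    colnames(counts) <- paste0("S", seq_len(n_samples))
    list(asv = asvTable(counts, lineage), groups = groups,
         true_ratio = p_copiotroph / p_oligotroph, rules = rules)
  })
}

#' Synthetic observed mass loss from a reference model run
#'
#' Produces the observation side of a self-consistent calibration demo: runs
#' the litterbag design under a known reference multiplier set, perturbs each
#' run's mass loss with plot-level noise, and summarises per-site envelopes
#' (min / mean / max at each timepoint) together with the observed relative
#' effect sizes fitted on the noisy table.
#'
#' @param sites Rows of [siteTable()].
#' @param ref_mults Named multipliers of the generating "truth" run.
#' @param params Default parameter set the multipliers act on.
#' @param noise_sd SD of the plot-level observation noise (% mass loss).
#' @param seed Integer seed.
#' @param forcing_seed Seed of the daily climatologies (shared with the
#'   calibration runs so the comparison is apples-to-apples).
#' @return List: `means` and `envelope` (site x timepoint data.frames),
#'   `effects` (observed relative effect sizes), `obs_table`, and `truth`
#'   (the generating multipliers).
#' @export
syntheticObservedMassLoss <- function(sites = siteTable("calibration"),
                                      ref_mults = c(m_tau_r = 1.33,
                                                    m_beta = 0.76,
                                                    m_vmod_m = 1.76,
                                                    m_vmod_s = 0.93),
                                      params = mimicsParams(),
                                      noise_sd = 2, seed = 1L,
                                      forcing_seed = 1L) {
  truth_par <- applyMultipliers(params, ref_mults)
  runs <- litterbagDesign(sites, truth_par, forcing_seed = forcing_seed)
  obs <- .withSeed(seed, {
    runs$mass_loss_pct <- pmin(pmax(
      runs$mass_loss_pct + rnorm(nrow(runs), 0, noise_sd), 0), 100)
    runs
  })
  means <- aggregate(mass_loss_pct ~ site_id + timepoint, obs, mean)
  env_min <- aggregate(mass_loss_pct ~ site_id + timepoint, obs, min)
  env_max <- aggregate(mass_loss_pct ~ site_id + timepoint, obs, max)
  envelope <- merge(env_min, env_max, by = c("site_id", "timepoint"),
                    suffixes = c("_min", "_max"))
  eff <- fitMassLossModel(preparePredictors(runsToObservations(obs)))
  list(means = means, envelope = envelope, effects = eff$relative,
       obs_table = runsToObservations(obs), truth = ref_mults)
}

#' Generate a synthetic SSP-like monthly climate anomaly
#'
#' Monthly deltas that ramp linearly from zero at the start of the historical
#' record to site-wide targets in the projection window, with a seasonal
#' shape (stronger winter warming, wetter winters / drier summers) and a
#' litterfall multiplier; the kind of smooth anomaly an Earth-system-model
#' SSP3-7.0 run yields after subtracting its baseline climatology.
#'
#' @param dT_mean Annual-mean warming (degrees C) reached in the target
#'   window.
#' @param dT_seasonal Amplitude of the seasonal modulation of the warming.
#' @param dMoist_amp Seasonal moisture delta amplitude (+ in winter, - in
#'   summer).
#' @param litterfall_mult Litterfall multiplier reached in the target window.
#' @param years Calendar years the anomaly covers.
#' @param ramp_from,ramp_to Years between which deltas ramp from 0 to full.
#' @return `climate_anomaly` data.frame: `year`, `month`, `d_temp`,
#'   `d_moisture`, `litterfall_mult`.
#' @export
syntheticAnomaly <- function(dT_mean = 3.0, dT_seasonal = 1.0,
                             dMoist_amp = 0.04, litterfall_mult = 1.10,
                             years = 2072:2074, ramp_from = 2022,
                             ramp_to = 2072) {
  grid <- expand.grid(month = 1:12, year = years)
  ramp <- pmin(pmax((grid$year - ramp_from) / (ramp_to - ramp_from), 0), 1)
  season <- cos(2 * pi * (grid$month - 1) / 12)   # peaks in January
  out <- data.frame(
    year = grid$year, month = grid$month,
    d_temp = ramp * (dT_mean + dT_seasonal * season),
    d_moisture = ramp * dMoist_amp * season,
    litterfall_mult = 1 + ramp * (litterfall_mult - 1))
  class(out) <- c("climate_anomaly", "data.frame")
  out
}

#' Write every synthetic fixture the pipeline stages read
#'
#' One entry point materialising the synthetic inputs as the CSV/TSV dialects
#' the analysis stages consume.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
makeFixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  obs <- generateObservations(observationConfig(seed = seed))
  p <- file.path(dir, "observations.csv"); write.csv(obs, p, row.names = FALSE)
  paths <- c(paths, p)
  gen <- generateAsvTable(seed = seed)
  tab <- data.frame(taxon_id = rownames(gen$asv$counts),
                    lineage = gen$asv$lineage, gen$asv$counts,
                    check.names = FALSE)
  p <- file.path(dir, "asv_table.tsv")
  utils::write.table(tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  anom <- syntheticAnomaly()
  p <- file.path(dir, "anomaly.csv"); write.csv(anom, p, row.names = FALSE)
  paths <- c(paths, p)
  forc <- do.call(rbind, lapply(seq_len(nrow(siteTable("all"))), function(i) {
    site <- siteTable("all")[i, ]
    cbind(site_id = site$site_id,
          generateDailyForcing(site, seed = seed))
  }))
  p <- file.path(dir, "daily_forcing.csv"); write.csv(forc, p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
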