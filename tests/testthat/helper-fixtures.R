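# shared fixtures: parameter set and site rows are deterministic, so build
# them once per test run
the <- new.env()

defaultParams <- function() {
  if (is.null(the$params)) the$params <- mimicsParams()
  the$params
}

calSites <- function() {
  if (is.null(the$sites)) the$sites <- siteTable("calibration")
  the$sites
}

treeSite <- function() calSites()[calSites()$site_id == "TREE", , drop = FALSE]

# deSolve forward integration of the reference (pure-R) derivative function;
# the independent route against which the Newton solver is checked
integrateToSteady <- function(site, moisture_variant, lignin_n, params,
                              years = 500) {
  mult <- switch(moisture_variant, mean = 1, min = site$mult_min,
                 max = site$mult_max)
  parms <- list(temp = site$soil_t_mean,
                moisture = min(max(site$moisture_mean * mult, 0), 1),
                input = site$litterfall * 1000 / (1e4 * getPar(params, "depth_cm")) / 8760,
                lignin_n = lignin_n, clay = site$clay_pct / 100)
  rhs <- function(t, y, pr) {
    d <- mimicsDerivatives(pmax(y, 0), pr$temp, pr$moisture, pr$input,
                           pr$lignin_n, pr$clay, params, use_compiled = FALSE)
    list(d[1:7])
  }
  out <- deSolve::lsoda(stats::setNames(c(0.2, 2, 0.05, 0.05, 2, 2, 0.2),
                                        poolNames()),
                        times = c(0, years * 8760), rhs, parms,
                        rtol = 1e-9, atol = 1e-12)
  out[2, 2:8]
}

# random admissible state/forcing draws for property-style sweeps
randomStateForcing <- function() {
  list(state = stats::runif(7, 0, 20),
       temp = stats::runif(1, -5, 30),
       moisture = stats::runif(1, 0, 1),
       input = stats::runif(1, 0, 2e-3),
       lignin_n = stats::runif(1, 5, 120),
       clay = stats::runif(1, 0, 0.5))
}

# a small hand-buildable eval_record for calibration filter/selection tests
fakeRecord <- function(rmse, effects, viable = TRUE, site_means = NULL,
                       mults = c(m_tau_r = 1, m_beta = 1, m_vmod_m = 1,
                                 m_vmod_s = 1)) {
  if (is.null(site_means)) {
    site_means <- data.frame(site_id = rep(c("A", "B"), each = 2),
                             timepoint = rep(1:2, 2),
                             mass_loss_pct = c(30, 60, 35, 65))
  }
  structure(list(mults = mults, site_means = site_means, rmse = rmse,
                 effects = c(moisture = effects[1], lignin_n = effects[2],
                             co_ratio = effects[3]),
                 viable_all = viable, failed = FALSE),
            class = "eval_record")
}

fakeEnvelope <- function(width = 10) {
  data.frame(site_id = rep(c("A", "B"), each = 2), timepoint = rep(1:2, 2),
             mass_loss_pct_min = c(30, 60, 35, 65) - width,
             mass_loss_pct_max = c(30, 60, 35, 65) + width)
}
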