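#' Pool names of the seven-pool model
#' @return Character vector: two litter pools (`lit_m`, `lit_s`), two
#'   microbial pools (`mic_r` copiotrophic, `mic_k` oligotrophic), and three
#'   SOM pools (`som_p` physically protected, `som_c` chemically protected,
#'   `som_a` available).
#' @export
poolNames <- function() .POOL_NAMES

.checkState <- function(state) {
  if (length(state) != 7) stop("state must have length 7")
  if (any(!is.finite(state))) stop("state contains non-finite values")
  if (any(state < 0)) stop("pool values must be non-negative")
  setNames(as.numeric(state), .POOL_NAMES)
}

# temperature-resolved Vmax and Km for the six uptake fluxes
.kinetics <- function(temp, clay, p) {
  vmod <- c(p$v_mod_r_m, p$v_mod_r_s, p$v_mod_r_a,
            p$v_mod_k_m, p$v_mod_k_s, p$v_mod_k_a)
  kslope <- c(p$k_slope_r_m, p$k_slope_r_s, p$k_slope_r_a,
              p$k_slope_k_m, p$k_slope_k_s, p$k_slope_k_a)
  kmod <- c(p$k_mod_r_m, p$k_mod_r_s, p$k_mod_r_a,
            p$k_mod_k_m, p$k_mod_k_s, p$k_mod_k_a)
  pscal <- p$p_scalar_a * exp(p$p_scalar_b * sqrt(clay))
  kmod[c(3, 6)] <- kmod[c(3, 6)] * pscal
  list(vmax = exp(p$v_slope * temp + p$v_int) * p$a_v * p$vmax_scale * vmod,
       km = exp(kslope * temp + p$k_int) * p$a_k / kmod)
}

#' Microbial substrate uptake flux
#'
#' Reverse Michaelis-Menten uptake: `mic * Vmax(T) * S / (Km(T) + S)`,
#' multiplied by the 0-1 soil-moisture scalar. `Vmax` and `Km` are exponential
#' functions of temperature with flux-specific modifiers; the global
#' `vmax_scale` (default 0.6, i.e. a 40% reduction of catabolic capacity) is
#' folded into `Vmax`.
#'
#' @param mic Microbial biomass carbon (mgC cm-3, >= 0).
#' @param substrate Substrate carbon (mgC cm-3, >= 0).
#' @param temp Soil temperature (degrees C).
#' @param moisture Soil-moisture scalar in `[0, 1]`.
#' @param flux Which of the six flux channels, e.g. `"r_m"` (copiotroph on
#'   metabolic litter) ... `"k_a"` (oligotroph on available SOM).
#' @param params A [MimicsParams-class] object.
#' @param clay Clay fraction (affects the available-SOM half-saturation).
#' @return Flux in mgC cm-3 h-1.
#' @export
uptakeFlux <- function(mic, substrate, temp, moisture,
                       flux = c("r_m", "r_s", "r_a", "k_m", "k_s", "k_a"),
                       params = mimicsParams(), clay = 0) {
  flux <- match.arg(flux)
  if (mic < 0 || substrate < 0) stop("pools must be non-negative")
  if (moisture < 0 || moisture > 1) stop("moisture must lie in [0, 1]")
  j <- match(flux, c("r_m", "r_s", "r_a", "k_m", "k_s", "k_a"))
  kin <- .kinetics(temp, clay, params@pars)
  mic * kin$vmax[j] * substrate / (kin$km[j] + substrate) * moisture
}

#' Density-dependent microbial turnover to one SOM pool
#'
#' `mic^beta * tau * f_s`: with `beta = 1` this is ordinary linear turnover;
#' `beta > 1` makes per-capita turnover increase with biomass, damping
#' microbial oscillations.
#'
#' @param mic Microbial biomass carbon (>= 0).
#' @param beta Density-dependence exponent.
#' @param tau Baseline turnover rate (> 0, h-1 at unit biomass).
#' @param f_s Fraction of turnover routed to the receiving SOM pool.
#' @return Turnover flux (mgC cm-3 h-1).
#' @export
microbialTurnover <- function(mic, beta, tau, f_s = 1) {
  if (any(mic < 0)) stop("mic must be non-negative")
  stopifnot(tau > 0, f_s >= 0, f_s <= 1)
  mic^beta * tau * f_s
}

#' Model derivatives for one forcing configuration
#'
#' Pure-R evaluation of the seven pool derivatives plus respiration. Litter
#' inputs are split by [fmetFraction()] between the metabolic and structural
#' pools (a fraction `f_i` routed directly to SOM); each microbial group takes
#' up its substrates by [uptakeFlux()] kinetics, assimilating `cue * flux` and
#' respiring the rest; turnover (`mic^beta * tau`) is partitioned among the
#' three SOM pools; physically protected SOM desorbs to available SOM; and
#' chemically protected SOM is oxidised to available SOM with an amplified
#' half-saturation. Carbon balance holds by construction:
#' `input - respiration - d(total)/dt = 0`.
#'
#' @param state Named or plain numeric vector of the seven pools
#'   (see [poolNames()]).
#' @param temp Soil temperature (degrees C).
#' @param moisture Soil-moisture scalar in `[0, 1]`.
#' @param litter_input Total litter input (mgC cm-3 h-1).
#' @param lignin_n Litter lignin:N ratio.
#' @param clay Clay fraction in `[0, 1]`.
#' @param params A [MimicsParams-class] object.
#' @param use_compiled Use the compiled kernel (default) or the reference R
#'   implementation.
#' @return Named numeric vector: seven derivatives (mgC cm-3 h-1) and
#'   `respiration`.
#' @export
mimicsDerivatives <- function(state, temp, moisture, litter_input, lignin_n,
                              clay, params = mimicsParams(),
                              use_compiled = TRUE) {
  state <- .checkState(state)
  if (!is.finite(temp) || !is.finite(moisture) || !is.finite(litter_input) ||
      moisture < 0 || moisture > 1 || litter_input < 0) {
    stop("invalid forcing (need finite temp, moisture in [0,1], input >= 0)")
  }
  fmet <- fmetFraction(lignin_n, params)
  if (use_compiled) {
    return(.mimicsRhsCpp(state, temp, moisture, litter_input, fmet, clay,
                         .paramVector(params)))
  }
  p <- params@pars
  kin <- .kinetics(temp, clay, p)
  v <- kin$vmax; km <- kin$km
  x <- state
  l1r <- x["mic_r"] * v[1] * x["lit_m"] / (km[1] + x["lit_m"]) * moisture
  l2r <- x["mic_r"] * v[2] * x["lit_s"] / (km[2] + x["lit_s"]) * moisture
  ar  <- x["mic_r"] * v[3] * x["som_a"] / (km[3] + x["som_a"]) * moisture
  l1k <- x["mic_k"] * v[4] * x["lit_m"] / (km[4] + x["lit_m"]) * moisture
  l2k <- x["mic_k"] * v[5] * x["lit_s"] / (km[5] + x["lit_s"]) * moisture
  ak  <- x["mic_k"] * v[6] * x["som_a"] / (km[6] + x["som_a"]) * moisture
  oxr <- x["mic_r"] * v[2] * x["som_c"] / (p$k_o_r * km[2] + x["som_c"]) * moisture
  oxk <- x["mic_k"] * v[5] * x["som_c"] / (p$k_o_k * km[5] + x["som_c"]) * moisture
  tau_r <- p$tau_base_r * exp(p$tau_mod_r * fmet)
  tau_k <- p$tau_base_k * exp(p$tau_mod_k * fmet)
  trn_r <- microbialTurnover(x[["mic_r"]], p$beta, tau_r)
  trn_k <- microbialTurnover(x[["mic_k"]], p$beta, tau_k)
  fphys_r <- p$f_phys_r_a * exp(p$f_phys_r_b * clay)
  fphys_k <- p$f_phys_k_a * exp(p$f_phys_k_b * clay)
  fchem_r <- p$f_chem_r_a * exp(p$f_chem_r_b * fmet)
  fchem_k <- p$f_chem_k_a * exp(p$f_chem_k_b * fmet)
  des <- x["som_p"] * p$d_base * exp(p$d_clay * clay)
  i_m <- litter_input * fmet
  i_s <- litter_input * (1 - fmet)
  d <- c(
    lit_m = i_m * (1 - p$f_i_m) - l1r - l1k,
    lit_s = i_s * (1 - p$f_i_s) - l2r - l2k,
    mic_r = p$cue_r_m * (l1r + ar) + p$cue_r_s * l2r - trn_r,
    mic_k = p$cue_k_m * (l1k + ak) + p$cue_k_s * l2k - trn_k,
    som_p = i_m * p$f_i_m + trn_r * fphys_r + trn_k * fphys_k - des,
    som_c = i_s * p$f_i_s + trn_r * fchem_r + trn_k * fchem_k - oxr - oxk,
    som_a = trn_r * (1 - fphys_r - fchem_r) + trn_k * (1 - fphys_k - fchem_k) +
      des + oxr + oxk - ar - ak
  )
  resp <- (1 - p$cue_r_m) * (l1r + ar) + (1 - p$cue_r_s) * l2r +
    (1 - p$cue_k_m) * (l1k + ak) + (1 - p$cue_k_s) * l2k
  out <- c(d, respiration = unname(resp))
  names(out) <- c(.POOL_NAMES, "respiration")
  out
}

#' Steady-state pools for one site configuration
#'
#' Solves the seven-pool model for the state at which all derivatives vanish
#' under constant annual-mean forcing: a damped Newton iteration on
#' log-transformed pools (which keeps them positive), warm-started from
#' `init` when given and falling back to a long forward integration when the
#' Newton iteration stalls.
#'
#' @param site One row of [siteTable()].
#' @param moisture_variant `"min"`, `"mean"` or `"max"`: the site moisture
#'   scalar times the corresponding multiplier.
#' @param lignin_n Litter lignin:N ratio of the simulated litter type.
#' @param params A [MimicsParams-class] object.
#' @param init Optional warm-start state (length 7).
#' @param tol Relative residual tolerance (derivative norm over total input).
#' @param viability_floor Microbial biomass (mgC cm-3) below which a group is
#'   flagged non-viable.
#' @return Named numeric state vector with attributes `residual_rel`,
#'   `viable` (named logical for `mic_r`, `mic_k`), `converged`, and the
#'   resolved constant `forcing`.
#' @export
steadyState <- function(site, moisture_variant = c("mean", "min", "max"),
                        lignin_n, params = mimicsParams(), init = NULL,
                        tol = 1e-8, viability_floor = 1e-6) {
  moisture_variant <- match.arg(moisture_variant)
  mult <- switch(moisture_variant, mean = 1, min = site$mult_min,
                 max = site$mult_max)
  moisture <- min(max(site$moisture_mean * mult, 0), 1)
  forcing <- list(temp = site$soil_t_mean, moisture = moisture,
                  litter_input = .inputRate(site$litterfall,
                                            getPar(params, "depth_cm")),
                  lignin_n = lignin_n, clay = site$clay_pct / 100)
  st <- steadyStateForcing(forcing, params, init = init, tol = tol,
                           viability_floor = viability_floor)
  attr(st, "site_id") <- site$site_id
  st
}

#' Steady state under explicit constant forcing
#'
#' Workhorse behind [steadyState()]; takes a fully resolved constant forcing
#' list rather than a site row.
#'
#' @inheritParams steadyState
#' @param forcing List with `temp`, `moisture`, `litter_input`, `lignin_n`,
#'   `clay`.
#' @export
steadyStateForcing <- function(forcing, params = mimicsParams(), init = NULL,
                               tol = 1e-8, viability_floor = 1e-6) {
  if (forcing$litter_input == 0) {
    st <- setNames(numeric(7), .POOL_NAMES)
    attr(st, "residual_rel") <- 0
    attr(st, "converged") <- TRUE
    attr(st, "viable") <- c(mic_r = FALSE, mic_k = FALSE)
    attr(st, "forcing") <- forcing
    return(st)
  }
  fmet <- fmetFraction(forcing$lignin_n, params)
  pv <- .paramVector(params)
  sol <- .solveSteady(init, forcing, fmet, pv, tol)
  if (is.null(sol)) {
    stop(sprintf(paste0("steady-state solver failed to converge ",
                        "(T=%.1f, moisture=%.2f, input=%.2e, lignin:N=%.1f)"),
                 forcing$temp, forcing$moisture, forcing$litter_input,
                 forcing$lignin_n))
  }
  st <- sol$state
  attr(st, "residual_rel") <- sol$residual_rel
  attr(st, "converged") <- TRUE
  attr(st, "viable") <- c(mic_r = st[["mic_r"]] >= viability_floor,
                          mic_k = st[["mic_k"]] >= viability_floor)
  attr(st, "forcing") <- forcing
  st
}

# standard initial state the spin-up departs from; the spin pulls the pools
# onto the attracting branch (a direct Newton solve can land on a spurious,
# non-invasible-violating extinction root), after which Newton polishes the
# residual below tolerance
.STD_INIT <- c(0.2, 2, 0.05, 0.05, 2, 2, 0.2)
.SPIN_YEARS <- 20

.solveSteady <- function(init, forcing, fmet, pv, tol) {
  with(forcing, {
    if (is.null(init)) {
      init <- .mimicsIntegrateCpp(.STD_INIT, temp, moisture, litter_input,
                                  fmet, clay, pv,
                                  hours = .SPIN_YEARS * 8760, dt = 96)
    }
    sol <- .mimicsSteadyNewtonCpp(pmax(init, 1e-30), temp, moisture,
                                  litter_input, fmet, clay, pv, tol = tol,
                                  maxit = 300)
    if (!sol$converged) {
      spun <- .mimicsIntegrateCpp(.STD_INIT, temp, moisture, litter_input,
                                  fmet, clay, pv, hours = 300 * 8760, dt = 24)
      sol <- .mimicsSteadyNewtonCpp(pmax(spun, 1e-30), temp, moisture,
                                    litter_input, fmet, clay, pv, tol = tol,
                                    maxit = 300)
      if (!sol$converged) return(NULL)
    }
    sol
  })
}

#' Steady states for a whole experimental design
#'
#' Enumerates site x litter type x moisture variant and solves each steady
#' state, optionally warm-starting every configuration from a previous
#' solution table (used heavily by the calibration stage).
#'
#' @param sites Rows of [siteTable()].
#' @param params A [MimicsParams-class] object.
#' @param warm Optional result of a previous call with the same design and
#'   the same parameterisation, whose states seed the Newton iteration
#'   directly (skipping the spin-up); do not reuse across parameterisations,
#'   where the attracting branch may differ.
#' @param viability_floor Microbial biomass (mgC cm-3) below which a group is
#'   flagged non-viable.
#' @param moisture_variants Character subset of `c("min", "mean", "max")`.
#' @return data.frame with one row per configuration: identifiers, forcing,
#'   the seven pools, `co_ratio` (`mic_r`/`mic_k`), viability flags and the
#'   relative residual.
#' @export
steadyStateTable <- function(sites, params = mimicsParams(), warm = NULL,
                             moisture_variants = c("min", "mean", "max"),
                             viability_floor = 1e-6) {
  grid <- .designGrid(sites, moisture_variants)
  n <- nrow(grid)
  warm_ok <- !is.null(warm) && nrow(warm) == n &&
    identical(warm$site_id, grid$site_id) &&
    identical(warm$litter_id, grid$litter_id) &&
    identical(warm$moisture_variant, grid$moisture_variant)
  pv <- .paramVector(params)
  depth <- getPar(params, "depth_cm")
  pools <- matrix(NA_real_, n, 7, dimnames = list(NULL, .POOL_NAMES))
  resid_rel <- numeric(n)
  for (i in seq_len(n)) {
    input <- .inputRate(grid$litterfall[i], depth)
    if (input == 0) {
      pools[i, ] <- 0; resid_rel[i] <- 0
      next
    }
    fmet <- fmetFraction(grid$lignin_n[i], params)
    forcing <- list(temp = grid$temp[i], moisture = grid$moisture[i],
                    litter_input = input, clay = grid$clay[i])
    init <- if (warm_ok) pmax(as.numeric(warm[i, .POOL_NAMES]), 1e-30)
            else NULL
    sol <- .solveSteady(init, forcing, fmet, pv, tol = 1e-8)
    if (is.null(sol)) {
      stop(sprintf("steady-state solver failed for %s litter %d (%s)",
                   grid$site_id[i], grid$litter_id[i],
                   grid$moisture_variant[i]))
    }
    pools[i, ] <- sol$state
    resid_rel[i] <- sol$residual_rel
  }
  out <- cbind(grid[c("site_id", "litter_id", "moisture_variant", "lignin_n",
                      "moisture", "temp")],
               as.data.frame(pools),
               co_ratio = pools[, "mic_r"] / pmax(pools[, "mic_k"], 1e-300),
               viable_r = pools[, "mic_r"] >= viability_floor,
               viable_k = pools[, "mic_k"] >= viability_floor,
               residual_rel = resid_rel)
  rownames(out) <- NULL
  out
}

# one row per site x litter x moisture-variant configuration, fixed order
.designGrid <- function(sites, moisture_variants = c("min", "mean", "max")) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    site <- sites[i, ]
    lig <- siteLigninN(site)
    g <- expand.grid(moisture_variant = moisture_variants,
                     litter_id = seq_along(lig), stringsAsFactors = FALSE)
    data.frame(site_id = site$site_id, litter_id = g$litter_id,
               moisture_variant = g$moisture_variant,
               lignin_n = lig[g$litter_id],
               mult = ifelse(g$moisture_variant == "min", site$mult_min,
                             ifelse(g$moisture_variant == "max",
                                    site$mult_max, 1)),
               temp = site$soil_t_mean,
               litterfall = site$litterfall,
               clay = site$clay_pct / 100,
               site_row = i)
  })
  g <- do.call(rbind, rows)
  g$moisture <- pmin(pmax(sites$moisture_mean[g$site_row] * g$mult, 0), 1)
  rownames(g) <- NULL
  g
}
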