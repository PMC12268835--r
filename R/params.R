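#' @useDynLib mimicsLitter, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rmultinom sd qt quantile setNames aggregate
#'   as.formula coef lm resid var vcov complete.cases
#' @importFrom utils read.csv read.delim write.csv head
NULL

.PAR_NAMES <- c(
  "v_slope", "v_int", "a_v",
  "v_mod_r_m", "v_mod_r_s", "v_mod_r_a", "v_mod_k_m", "v_mod_k_s", "v_mod_k_a",
  "vmax_scale",
  "k_slope_r_m", "k_slope_r_s", "k_slope_r_a",
  "k_slope_k_m", "k_slope_k_s", "k_slope_k_a",
  "k_int", "a_k",
  "k_mod_r_m", "k_mod_r_s", "k_mod_r_a", "k_mod_k_m", "k_mod_k_s", "k_mod_k_a",
  "p_scalar_a", "p_scalar_b", "k_o_r", "k_o_k",
  "cue_r_m", "cue_r_s", "cue_k_m", "cue_k_s",
  "tau_base_r", "tau_base_k", "tau_mod_r", "tau_mod_k", "beta",
  "f_phys_r_a", "f_phys_r_b", "f_phys_k_a", "f_phys_k_b",
  "f_chem_r_a", "f_chem_r_b", "f_chem_k_a", "f_chem_k_b",
  "f_i_m", "f_i_s", "d_base", "d_clay",
  "f_met0", "f_met_slope", "f_met_min", "f_met_max", "depth_cm"
)

.POOL_NAMES <- c("lit_m", "lit_s", "mic_r", "mic_k", "som_p", "som_c", "som_a")

#' Kinetic parameter set for the seven-pool litter/SOM model
#'
#' Holds every rate, efficiency, partitioning and turnover constant of the
#' model, including the four calibratable microbial parameters (the litter
#' quality multiplier on copiotrophic turnover, the density-dependence
#' exponent beta, and the metabolic / structural Vmax modifiers). Construct
#' with [mimicsParams()]; never instantiate directly.
#'
#' @slot pars Named list of parameter values (see the packaged
#'   `mimics_params.yaml` for names, meaning and units).
#' @export
setClass("MimicsParams", representation(pars = "list"))

setValidity("MimicsParams", function(object) {
  p <- object@pars
  msgs <- character()
  missing <- setdiff(.PAR_NAMES, names(p))
  if (length(missing)) {
    return(paste("missing parameters:", paste(missing, collapse = ", ")))
  }
  num <- vapply(p[.PAR_NAMES], function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (!all(num)) {
    return(paste("non-scalar or non-finite:",
                 paste(.PAR_NAMES[!num], collapse = ", ")))
  }
  pos <- c("a_v", "a_k", "vmax_scale", "tau_base_r", "tau_base_k", "beta",
           "d_base", "depth_cm",
           grep("^(v_mod|k_mod|k_o)", .PAR_NAMES, value = TRUE))
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad)) msgs <- c(msgs, paste("must be > 0:", paste(bad, collapse = ", ")))
  cues <- unlist(p[c("cue_r_m", "cue_r_s", "cue_k_m", "cue_k_s")])
  if (any(cues <= 0 | cues >= 1)) {
    msgs <- c(msgs, "carbon-use efficiencies must lie in (0, 1)")
  }
  if (p$f_i_m < 0 || p$f_i_m > 1 || p$f_i_s < 0 || p$f_i_s > 1) {
    msgs <- c(msgs, "f_i fractions must lie in [0, 1]")
  }
  # turnover partition fractions must stay a partition of unity over the
  # admissible clay and litter-quality range
  for (clay in c(0, 0.5)) {
    for (fm in c(p$f_met_min, p$f_met_max)) {
      fr <- p$f_phys_r_a * exp(p$f_phys_r_b * clay) +
        p$f_chem_r_a * exp(p$f_chem_r_b * fm)
      fk <- p$f_phys_k_a * exp(p$f_phys_k_b * clay) +
        p$f_chem_k_a * exp(p$f_chem_k_b * fm)
      if (fr >= 1 || fk >= 1) {
        msgs <- c(msgs, "turnover partition fractions exceed 1 within the admissible clay/quality range")
      }
    }
  }
  if (length(msgs)) paste(unique(msgs), collapse = "; ") else TRUE
})

#' Build a kinetic parameter set
#'
#' Reads the packaged default configuration (or a user-supplied YAML file of
#' the same shape) and applies any overrides given as named arguments.
#'
#' @param file Path to a YAML parameter file; `NULL` uses the packaged
#'   defaults.
#' @param ... Named scalar overrides using flat parameter names (see
#'   [paramNames()]).
#' @return A [MimicsParams-class] object.
#' @examples
#' p <- mimicsParams()
#' getPar(p, "beta")
#' mimicsParams(beta = 1)  # linear microbial turnover
#' @export
mimicsParams <- function(file = NULL, ...) {
  if (is.null(file)) {
    file <- system.file("extdata", "mimics_params.yaml",
                        package = "mimicsLitter", mustWork = TRUE)
  }
  y <- yaml::read_yaml(file)
  p <- list(
    v_slope = y$v_slope, v_int = y$v_int, a_v = y$a_v,
    v_mod_r_m = y$v_mod_m$r, v_mod_r_s = y$v_mod_s$r, v_mod_r_a = y$v_mod_a$r,
    v_mod_k_m = y$v_mod_m$k, v_mod_k_s = y$v_mod_s$k, v_mod_k_a = y$v_mod_a$k,
    vmax_scale = y$vmax_scale,
    k_slope_r_m = y$k_slope$m, k_slope_r_s = y$k_slope$s,
    k_slope_r_a = y$k_slope$a, k_slope_k_m = y$k_slope$m,
    k_slope_k_s = y$k_slope$s, k_slope_k_a = y$k_slope$a,
    k_int = y$k_int, a_k = y$a_k,
    k_mod_r_m = y$k_mod_m$r, k_mod_r_s = y$k_mod_s$r, k_mod_r_a = y$k_mod_a$r,
    k_mod_k_m = y$k_mod_m$k, k_mod_k_s = y$k_mod_s$k, k_mod_k_a = y$k_mod_a$k,
    p_scalar_a = y$p_scalar_a, p_scalar_b = y$p_scalar_b,
    k_o_r = y$k_o$r, k_o_k = y$k_o$k,
    cue_r_m = y$cue$r_m, cue_r_s = y$cue$r_s,
    cue_k_m = y$cue$k_m, cue_k_s = y$cue$k_s,
    tau_base_r = y$tau_base$r, tau_base_k = y$tau_base$k,
    tau_mod_r = y$tau_mod_r, tau_mod_k = y$tau_mod_k, beta = y$beta,
    f_phys_r_a = y$f_phys_r[1], f_phys_r_b = y$f_phys_r[2],
    f_phys_k_a = y$f_phys_k[1], f_phys_k_b = y$f_phys_k[2],
    f_chem_r_a = y$f_chem_r[1], f_chem_r_b = y$f_chem_r[2],
    f_chem_k_a = y$f_chem_k[1], f_chem_k_b = y$f_chem_k[2],
    f_i_m = y$f_i$m, f_i_s = y$f_i$s,
    d_base = y$d_base, d_clay = y$d_clay,
    f_met0 = y$f_met0, f_met_slope = y$f_met_slope,
    f_met_min = y$f_met_min, f_met_max = y$f_met_max,
    depth_cm = y$depth_cm
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), .PAR_NAMES)
    if (length(unknown)) {
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  new("MimicsParams", pars = p)
}

#' Names of the flat kinetic parameters
#' @return Character vector of parameter names accepted by [mimicsParams()]
#'   and [getPar()].
#' @export
paramNames <- function() .PAR_NAMES

#' Extract one parameter value
#' @param object A [MimicsParams-class] object.
#' @param name Flat parameter name.
#' @return Numeric scalar.
#' @export
getPar <- function(object, name) {
  stopifnot(is(object, "MimicsParams"))
  if (!name %in% .PAR_NAMES) stop("unknown parameter: ", name)
  object@pars[[name]]
}

#' Replace parameter values
#' @param object A [MimicsParams-class] object.
#' @param ... Named scalar replacements.
#' @return A new, validated [MimicsParams-class] object.
#' @export
setPars <- function(object, ...) {
  stopifnot(is(object, "MimicsParams"))
  dots <- list(...)
  unknown <- setdiff(names(dots), .PAR_NAMES)
  if (length(unknown)) stop("unknown parameter name(s): ",
                            paste(unknown, collapse = ", "))
  p <- object@pars
  p[names(dots)] <- dots
  new("MimicsParams", pars = p)
}

setMethod("show", "MimicsParams", function(object) {
  p <- object@pars
  cat("MimicsParams (seven-pool litter/SOM kinetics)\n")
  cat(sprintf("  Vmax: exp(%.3f T + %.2f) x %.1e, global scale %.2f\n",
              p$v_slope, p$v_int, p$a_v, p$vmax_scale))
  cat(sprintf("  v_mod metabolic {r=%.2f, k=%.2f}  structural {r=%.2f, k=%.2f}\n",
              p$v_mod_r_m, p$v_mod_k_m, p$v_mod_r_s, p$v_mod_k_s))
  cat(sprintf("  turnover: tau {r=%.1e, k=%.1e} x exp({%.2f, %.2f} fmet), beta = %.2f\n",
              p$tau_base_r, p$tau_base_k, p$tau_mod_r, p$tau_mod_k, p$beta))
  cat(sprintf("  CUE {r_m=%.2f, r_s=%.2f, k_m=%.2f, k_s=%.2f}; depth %.0f cm\n",
              p$cue_r_m, p$cue_r_s, p$cue_k_m, p$cue_k_s, p$depth_cm))
  invisible(object)
})

# flat numeric vector consumed by the compiled kernels
.paramVector <- function(object) {
  unlist(object@pars[.PAR_NAMES], use.names = FALSE)
}

#' Metabolic fraction of litter inputs
#'
#' Linear decreasing function of the litter lignin:N ratio, clipped to the
#' configured bounds. Controls the split of litterfall (and of litterbag
#' carbon) between the metabolic and structural litter pools.
#'
#' @param lignin_n Litter lignin:N ratio (> 0; length any).
#' @param params A [MimicsParams-class] object.
#' @return Fraction(s) in `[f_met_min, f_met_max]`.
#' @export
fmetFraction <- function(lignin_n, params = mimicsParams()) {
  if (any(!is.finite(lignin_n)) || any(lignin_n <= 0)) {
    stop("lignin_n must be positive and finite")
  }
  p <- params@pars
  pmin(pmax(p$f_met0 - p$f_met_slope * lignin_n, p$f_met_min), p$f_met_max)
}

#' Apply calibration multipliers to a parameter set
#'
#' The four calibratable parameters are scaled by their multipliers: the
#' litter-quality coefficient on copiotrophic turnover (`tau_mod_r`), the
#' density-dependence exponent (`beta`), and the metabolic and structural
#' Vmax modifiers (each applied to both microbial groups). All other
#' parameters are unchanged.
#'
#' @param defaults A [MimicsParams-class] object.
#' @param mults Named numeric vector or one-row data.frame with
#'   `m_tau_r`, `m_beta`, `m_vmod_m`, `m_vmod_s`.
#' @param ranges Admissible multiplier ranges, as from [multiplierRanges()];
#'   `NULL` skips range checking.
#' @return A new [MimicsParams-class] object.
#' @export
applyMultipliers <- function(defaults, mults,
                             ranges = multiplierRanges()) {
  stopifnot(is(defaults, "MimicsParams"))
  if (is.data.frame(mults)) mults <- unlist(mults[1, intersect(
    c("m_tau_r", "m_beta", "m_vmod_m", "m_vmod_s"), names(mults))])
  need <- c("m_tau_r", "m_beta", "m_vmod_m", "m_vmod_s")
  if (!all(need %in% names(mults))) {
    stop("mults must name ", paste(need, collapse = ", "))
  }
  if (!is.null(ranges)) {
    for (nm in need) {
      r <- ranges[[nm]]
      if (mults[[nm]] < r[1] || mults[[nm]] > r[2]) {
        stop(sprintf("multiplier %s = %.3f outside its range [%g, %g]",
                     nm, mults[[nm]], r[1], r[2]))
      }
    }
  }
  p <- defaults@pars
  p$tau_mod_r <- p$tau_mod_r * mults[["m_tau_r"]]
  p$beta <- p$beta * mults[["m_beta"]]
  p$v_mod_r_m <- p$v_mod_r_m * mults[["m_vmod_m"]]
  p$v_mod_k_m <- p$v_mod_k_m * mults[["m_vmod_m"]]
  p$v_mod_r_s <- p$v_mod_r_s * mults[["m_vmod_s"]]
  p$v_mod_k_s <- p$v_mod_k_s * mults[["m_vmod_s"]]
  new("MimicsParams", pars = p)
}

#' Admissible ranges of the four calibration multipliers
#' @return Named list of length-2 numeric ranges.
#' @export
multiplierRanges <- function() {
  list(m_tau_r = c(0.3, 2), m_beta = c(0.67, 1.33),
       m_vmod_m = c(0.5, 2), m_vmod_s = c(0.5, 2))
}

#' The three calibrated multiplier sets shipped with the package
#' @return data.frame with columns `set_id`, `m_tau_r`, `m_beta`,
#'   `m_vmod_m`, `m_vmod_s`.
#' @export
calibratedSets <- function() {
  read.csv(system.file("extdata", "calibrated_sets.csv",
                       package = "mimicsLitter", mustWork = TRUE))
}
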