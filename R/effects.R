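#' Prepare standardized predictors for the mass-loss model
#'
#' Log-transforms soil moisture (to meet linearity assumptions) and
#' standardizes all three predictors - log moisture, lignin:N and the
#' copiotroph:oligotroph ratio - to mean 0, SD 1 within the table.
#'
#' @param table Observation table with columns `site`, `plot`, `timepoint`,
#'   `mass_loss`, `moisture`, `lignin_n`, `co_ratio`.
#' @return The table with added columns `z_moisture`, `z_lignin_n`,
#'   `z_co_ratio`.
#' @export
preparePredictors <- function(table) {
  need <- c("site", "plot", "timepoint", "mass_loss", "moisture", "lignin_n",
            "co_ratio")
  missing <- setdiff(need, names(table))
  if (length(missing)) stop("observation table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (any(table$moisture <= 0)) stop("moisture must be positive")
  z <- function(x, nm) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) stop("zero-variance predictor: ", nm)
    (x - mean(x)) / s
  }
  table$z_moisture <- z(log(table$moisture), "moisture")
  table$z_lignin_n <- z(table$lignin_n, "lignin_n")
  table$z_co_ratio <- z(table$co_ratio, "co_ratio")
  table
}

#' Fit the mixed-effects model of litter mass loss
#'
#' Linear mixed model of percent mass loss on the three standardized
#' predictors, with random intercepts for site and plot-within-site (REML).
#' A singular plot-level fit falls back to a site-only random intercept,
#' recorded in the result.
#'
#' @param design Output of [preparePredictors()].
#' @return An `effect_size_fit` list: `coefficients` (the three fixed
#'   effects), `relative` (signed percentages summing to 100 in absolute
#'   value), `vif`, `fit` (the lme4 fit), `fallback`, `singular`.
#' @export
fitMassLossModel <- function(design) {
  need <- c("z_moisture", "z_lignin_n", "z_co_ratio")
  if (!all(need %in% names(design))) {
    stop("design lacks standardized predictors; call preparePredictors() first")
  }
  if (length(unique(design$site)) < 2) stop("need at least 2 sites")
  design$plot_in_site <- interaction(design$site, design$plot, drop = TRUE)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(mass_loss ~ z_moisture + z_lignin_n + z_co_ratio +
                 (1 | site) + (1 | plot_in_site),
               data = design, REML = TRUE, control = ctrl)))
  fallback <- FALSE
  if (lme4::isSingular(fit, tol = 1e-5)) {
    fit2 <- suppressMessages(suppressWarnings(
      lme4::lmer(mass_loss ~ z_moisture + z_lignin_n + z_co_ratio +
                   (1 | site), data = design, REML = TRUE, control = ctrl)))
    fit <- fit2
    fallback <- TRUE
  }
  coefs <- lme4::fixef(fit)[c("z_moisture", "z_lignin_n", "z_co_ratio")]
  names(coefs) <- c("moisture", "lignin_n", "co_ratio")
  out <- list(coefficients = coefs,
              relative = relativeEffectSizes(coefs),
              vif = varianceInflation(design),
              vcov = as.matrix(vcov(fit))[2:4, 2:4],
              fit = fit, fallback = fallback,
              singular = lme4::isSingular(fit, tol = 1e-5))
  class(out) <- "effect_size_fit"
  out
}

#' @export
print.effect_size_fit <- function(x, ...) {
  cat("Mixed-effects mass-loss model (site / plot-in-site random intercepts",
      if (x$fallback) "- fell back to site-only)" else ")", "\n")
  tab <- rbind(coefficient = x$coefficients, `relative (%)` = x$relative,
               VIF = x$vif)
  print(round(tab, 3))
  invisible(x)
}

#' Relativize coefficients to 100%
#'
#' Expresses each fixed-effect coefficient as a signed percentage of the sum
#' of absolute coefficients, so the absolute relative effect sizes total
#' exactly 100.
#'
#' @param coefs Named numeric vector of coefficients (intercept excluded).
#' @return Signed percentages with the input's names.
#' @export
relativeEffectSizes <- function(coefs) {
  tot <- sum(abs(coefs))
  if (tot == 0) stop("all coefficients are zero; relative sizes undefined")
  100 * coefs / tot
}

#' Variance inflation factors of the three predictors
#'
#' `VIF_i = 1 / (1 - R^2_i)` where `R^2_i` is from regressing predictor `i`
#' on the other two. Values below 5 are conventionally taken as acceptable
#' collinearity.
#'
#' @param design Output of [preparePredictors()] (or any data.frame holding
#'   the three `z_` columns).
#' @return Named numeric vector of VIFs with a `pass` attribute
#'   (all VIF < 5).
#' @export
varianceInflation <- function(design) {
  cols <- c("z_moisture", "z_lignin_n", "z_co_ratio")
  if (!all(cols %in% names(design))) stop("design lacks standardized predictors")
  X <- as.matrix(design[, cols])
  if (nrow(X) < 4) stop("need at least 4 rows")
  if (qr(cbind(1, X))$rank < ncol(X) + 1) stop("rank-deficient design")
  vif <- vapply(seq_along(cols), function(i) {
    r2 <- summary(lm(X[, i] ~ X[, -i]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  names(vif) <- c("moisture", "lignin_n", "co_ratio")
  attr(vif, "pass") <- all(vif < 5)
  vif
}

#' Build a fast repeated-fit function for one design structure
#'
#' The Monte Carlo calibration refits the mass-loss mixed model thousands of
#' times on tables whose grouping structure (site, plot, timepoint) is fixed
#' and only the numeric columns change. This factory prebuilds the lme4
#' model structure once and returns a function fitting new tables via the
#' modular interface, falling back to [fitMassLossModel()] whenever the
#' grouping differs from the template. Estimates agree with
#' [fitMassLossModel()] to optimizer tolerance.
#'
#' @param template A design (from [preparePredictors()]) defining the
#'   grouping structure.
#' @return `function(design)` returning a list with `coefficients`,
#'   `relative` and `fallback`.
#' @export
makeEffectFitter <- function(template) {
  template$plot_in_site <- interaction(template$site, template$plot,
                                       drop = TRUE)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  lf_full <- lme4::lFormula(
    mass_loss ~ z_moisture + z_lignin_n + z_co_ratio + (1 | site) +
      (1 | plot_in_site), data = template, REML = TRUE, control = ctrl)
  lf_site <- lme4::lFormula(
    mass_loss ~ z_moisture + z_lignin_n + z_co_ratio + (1 | site),
    data = template, REML = TRUE, control = ctrl)
  zcols <- c("z_moisture", "z_lignin_n", "z_co_ratio")
  run_one <- function(lf, design) {
    lf$fr$mass_loss <- design$mass_loss
    for (cc in zcols) lf$fr[[cc]] <- design[[cc]]
    lf$X[, zcols] <- as.matrix(design[, zcols])
    devfun <- do.call(lme4::mkLmerDevfun, lf)
    opt <- lme4::optimizeLmer(devfun, control = ctrl$optCtrl)
    lme4::mkMerMod(environment(devfun), opt, lf$reTrms, fr = lf$fr)
  }
  function(design) {
    if (!identical(design$site, template$site) ||
        !identical(design$plot, template$plot) ||
        !identical(design$timepoint, template$timepoint)) {
      fit <- fitMassLossModel(design)
      return(list(coefficients = fit$coefficients, relative = fit$relative,
                  fallback = fit$fallback))
    }
    fit <- run_one(lf_full, design)
    fallback <- FALSE
    if (lme4::isSingular(fit, tol = 1e-5)) {
      fit <- run_one(lf_site, design)
      fallback <- TRUE
    }
    coefs <- lme4::fixef(fit)[zcols]
    names(coefs) <- c("moisture", "lignin_n", "co_ratio")
    list(coefficients = coefs, relative = relativeEffectSizes(coefs),
         fallback = fallback)
  }
}

#' Model-output observation table from a litterbag design run
#'
#' Reshapes a [litterbagDesign()] result into the observation-table layout
#' the effect-size stage consumes: "plot" is each litter type x moisture
#' variant combination, the moisture predictor is the temporally averaged
#' scalar of that variant, and the community predictor is the steady-state
#' copiotroph:oligotroph biomass ratio.
#'
#' @param runs Result of [litterbagDesign()].
#' @return Observation table ready for [preparePredictors()].
#' @export
runsToObservations <- function(runs) {
  data.frame(site = runs$site_id,
             plot = paste(runs$litter_id, runs$moisture_variant, sep = "."),
             timepoint = runs$timepoint,
             mass_loss = runs$mass_loss_pct,
             moisture = runs$moisture,
             lignin_n = runs$lignin_n,
             co_ratio = runs$co_ratio)
}
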