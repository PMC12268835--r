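#' Site forcing table
#'
#' Returns the packaged table of site-level forcing statistics: annual
#' litterfall (gC m-2 yr-1), mean and SD of soil temperature (degrees C) and of
#' the 0-1 soil-moisture scalar, the min/max soil-moisture multipliers, percent
#' clay, and the three litter lignin:N ratios per site (columns `lignin_n_1-3`,
#' ascending, i.e. decreasing litter quality). Seven calibration sites and
#' three validation sites.
#'
#' @param role `"calibration"`, `"validation"` or `"all"`.
#' @param file Optional path to a CSV with the same columns.
#' @return data.frame, one row per site.
#' @export
siteTable <- function(role = c("calibration", "validation", "all"),
                      file = NULL) {
  role <- match.arg(role)
  if (is.null(file)) {
    file <- system.file("extdata", "site_table.csv", package = "mimicsLitter",
                        mustWork = TRUE)
  }
  tab <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("site_id", "role", "litterfall", "soil_t_mean", "soil_t_sd",
            "moisture_mean", "moisture_sd", "mult_max", "mult_min",
            "clay_pct", "lignin_n_1", "lignin_n_2", "lignin_n_3")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("site table lacks columns: ",
                            paste(missing, collapse = ", "))
  .validateSites(tab)
  if (role != "all") tab <- tab[tab$role == role, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

.validateSites <- function(tab) {
  with(tab, {
    if (any(moisture_mean < 0 | moisture_mean > 1)) {
      stop("moisture_mean must lie in [0, 1]")
    }
    if (any(mult_min > 1) || any(mult_max < 1)) {
      stop("moisture multipliers must bracket 1")
    }
    if (any(clay_pct < 0 | clay_pct > 100)) stop("clay_pct must lie in [0, 100]")
    lig <- cbind(lignin_n_1, lignin_n_2, lignin_n_3)
    if (any(lig <= 0)) stop("lignin:N values must be positive")
    if (any(litterfall < 0)) stop("litterfall must be non-negative")
  })
  invisible(tab)
}

#' Lignin:N values of one site in long form
#' @param site One row of [siteTable()].
#' @return Numeric vector of the three litter lignin:N ratios.
#' @export
siteLigninN <- function(site) {
  as.numeric(site[1, c("lignin_n_1", "lignin_n_2", "lignin_n_3")])
}

# annual litterfall (gC m-2 yr-1) -> volumetric hourly input (mgC cm-3 h-1)
.inputRate <- function(litterfall, depth_cm) {
  litterfall * 1000 / (1e4 * depth_cm) / 8760
}

#' Moisture multipliers from field soil-moisture samples
#'
#' Divides the lower and upper bounds of the t-based 95% confidence interval
#' of the mean by the mean itself, yielding the min and max soil-moisture
#' multipliers used to span within-site moisture variability.
#'
#' @param samples Numeric vector of field soil-moisture measurements
#'   (at least 3, positive mean).
#' @return Named numeric vector `c(mult_min =, mult_max =)`.
#' @export
computeMoistureMultipliers <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 3) stop("need at least 3 samples")
  m <- mean(samples)
  if (m <= 0) stop("sample mean must be positive")
  se <- sd(samples) / sqrt(length(samples))
  tq <- qt(0.975, df = length(samples) - 1)
  c(mult_min = (m - tq * se) / m, mult_max = (m + tq * se) / m)
}

#' Generate a daily forcing climatology for one site
#'
#' Builds a 365-day climatology of soil temperature, soil-moisture scalar and
#' daily litterfall that emulates what a land-model climatology would provide:
#' a seasonal sinusoid plus seeded day-to-day noise, affinely adjusted so the
#' annual mean reproduces the site statistic and the annual SD its stated
#' spread; the moisture scalar is clipped to \eqn{[0, 1]}; daily litterfall is
#' an autumn-peaked pulse normalised to the annual total.
#'
#' @param site One row of [siteTable()].
#' @param seed Integer seed making the climatology reproducible.
#' @param moisture_mult Multiplier applied to the moisture series (and its
#'   target mean), e.g. the site `mult_min`/`mult_max`.
#' @return data.frame with columns `doy`, `soil_t`, `moisture`, `litterfall`
#'   (gC m-2 day-1); attribute `"site_id"`.
#' @export
generateDailyForcing <- function(site, seed = 1L, moisture_mult = 1) {
  stopifnot(nrow(site) == 1)
  doy <- 1:365
  rs <- .withSeed(seed, {
    list(tn = rnorm(365), mn = rnorm(365))
  })
  # temperature: winter trough around mid-January (day 15), noise ~30% of SD
  sd_t <- site$soil_t_sd
  noise_t <- 0.3 * sd_t
  amp_t <- sqrt(2 * max(sd_t^2 - noise_t^2, 0))
  soil_t <- site$soil_t_mean - amp_t * cos(2 * pi * (doy - 15) / 365) +
    noise_t * rs$tn
  soil_t <- .matchMoments(soil_t, site$soil_t_mean, sd_t)

  # moisture: wetter in winter/spring, drier in late summer
  m_target <- site$moisture_mean * moisture_mult
  sd_m <- site$moisture_sd * moisture_mult
  noise_m <- 0.3 * sd_m
  amp_m <- sqrt(2 * max(sd_m^2 - noise_m^2, 0))
  moisture <- m_target + amp_m * cos(2 * pi * (doy - 46) / 365) +
    noise_m * rs$mn
  moisture <- .matchMoments(moisture, m_target, sd_m)
  # clipping perturbs the mean; recentre once and clip again so the annual
  # mean stays within tolerance of the target
  for (i in 1:4) {
    moisture <- pmin(pmax(moisture, 0), 1)
    drift <- m_target - mean(moisture)
    if (abs(drift) < 1e-9 * max(m_target, 1e-12)) break
    moisture <- moisture + drift
  }
  moisture <- pmin(pmax(moisture, 0), 1)

  # litterfall pulse centred on mid-October, sigma 15 days, cyclic
  w <- exp(-0.5 * ((doy - 288) / 15)^2) + 1e-6
  litterfall <- site$litterfall * w / sum(w)

  out <- data.frame(doy = doy, soil_t = soil_t, moisture = moisture,
                    litterfall = litterfall)
  attr(out, "site_id") <- site$site_id
  out
}

.matchMoments <- function(x, mean_target, sd_target) {
  s <- sd(x)
  if (s > 0 && sd_target > 0) x <- (x - mean(x)) / s * sd_target + mean_target
  else x <- x - mean(x) + mean_target
  x
}

# evaluate an expression under a temporary RNG state
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
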