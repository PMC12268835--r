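toyTable <- function(n_sites = 4, plots = 6, seed = 21, b = c(6, -5, -3),
                     sd_site = 2, sd_plot = 1, sd_resid = 2) {
  cfg <- observationConfig(b_moisture = b[1], b_lignin_n = b[2],
                           b_co_ratio = b[3], sd_site = sd_site,
                           sd_plot = sd_plot, sd_resid = sd_resid,
                           plots_per_site = setNames(
                             rep(plots, n_sites),
                             siteTable("calibration")$site_id[seq_len(n_sites)]),
                           seed = seed)
  generateObservations(cfg)
}

test_that("predictors are logged where stated and standardized to z-scores", {
  tab <- toyTable()
  des <- preparePredictors(tab)
  for (cc in c("z_moisture", "z_lignin_n", "z_co_ratio")) {
    expect_lt(abs(mean(des[[cc]])), 1e-12)
    expect_equal(sd(des[[cc]]), 1, tolerance = 1e-12)
  }
  # hand-computed z-scores on a 5-row toy
  t5 <- data.frame(site = "A", plot = letters[1:5], timepoint = 1,
                   mass_loss = 1:5, moisture = c(0.2, 0.3, 0.5, 0.4, 0.6),
                   lignin_n = c(10, 20, 30, 40, 50),
                   co_ratio = c(1, 2, 3, 2, 1))
  d5 <- preparePredictors(t5)
  lm5 <- log(t5$moisture)
  expect_equal(d5$z_moisture, (lm5 - mean(lm5)) / sd(lm5))
  expect_equal(d5$z_lignin_n, (t5$lignin_n - 30) / sd(t5$lignin_n))
  # rescaling raw moisture is absorbed by the log and centering
  t5b <- t5; t5b$moisture <- t5$moisture * 37.5
  expect_equal(preparePredictors(t5b)$z_moisture, d5$z_moisture)
  # zero variance is refused by name
  t5c <- t5; t5c$lignin_n <- 20
  expect_error(preparePredictors(t5c), "lignin_n")
  t5d <- t5; t5d$moisture[1] <- 0
  expect_error(preparePredictors(t5d), "positive")
})

test_that("noiseless data identify the generating coefficients exactly", {
  tab <- toyTable(seed = 31, sd_site = 0, sd_plot = 0, sd_resid = 0)
  fit <- fitMassLossModel(preparePredictors(tab))
  truth <- attr(tab, "truth")$b
  # generator builds the response from per-plot z-scores; the fitted design
  # standardizes over rows (two timepoints per plot), so coefficients match
  # up to that constant rescaling of each column
  ratio <- fit$coefficients / truth
  expect_equal(unname(ratio / ratio[1]), rep(1, 3), tolerance = 1e-6)
  expect_equal(sum(abs(fit$relative)), 100)
})

test_that("row order does not affect the fitted model", {
  tab <- toyTable(seed = 5)
  des <- preparePredictors(tab)
  f1 <- fitMassLossModel(des)
  set.seed(1)
  f2 <- fitMassLossModel(des[sample(nrow(des)), ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("relativization preserves signs and totals 100 in absolute value", {
  # any positive rescaling of the same coefficient pattern gives the same
  # relative sizes
  for (c0 in c(0.01, 1, 250)) {
    rel <- relativeEffectSizes(c(moisture = 0.479 * c0,
                                 lignin_n = -0.190 * c0,
                                 co_ratio = 0.331 * c0))
    expect_equal(unname(rel), c(47.9, -19.0, 33.1))
    expect_equal(sum(abs(rel)), 100)
  }
  expect_equal(unname(relativeEffectSizes(c(1, -1, 2))), c(25, -25, 50))
  expect_equal(unname(relativeEffectSizes(c(0, 0, 5))), c(0, 0, 100))
  expect_error(relativeEffectSizes(c(0, 0, 0)), "zero")
})

test_that("variance inflation factors follow the 1/(1 - R^2) closed form", {
  # orthogonal predictors
  z <- function(x) (x - mean(x)) / sd(x)
  n <- 32
  x1 <- z(rep(c(-1, 1), each = n / 2))
  x2 <- z(rep(c(-1, 1), times = n / 2))
  x3 <- z(rep(c(-1, 1, 1, -1), times = n / 4))
  d <- data.frame(z_moisture = x1, z_lignin_n = x2, z_co_ratio = x3)
  v <- varianceInflation(d)
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(attr(v, "pass"))

  # exact correlation 0.8 between two predictors: R^2 = 0.64, VIF = 1/0.36
  e <- z(stats::residuals(lm(x2 ~ x1)))
  x2c <- 0.8 * x1 + sqrt(1 - 0.64) * e
  d2 <- data.frame(z_moisture = x1, z_lignin_n = z(x2c), z_co_ratio = x3)
  v2 <- varianceInflation(d2)
  expect_equal(unname(v2[1:2]), rep(1 / (1 - 0.64), 2), tolerance = 1e-8)

  # duplicated predictor blows up and fails the check
  d3 <- data.frame(z_moisture = x1, z_lignin_n = x1 + 1e-6 * x2,
                   z_co_ratio = x3)
  v3 <- varianceInflation(d3)
  expect_gt(v3[["moisture"]], 1e6)
  expect_false(attr(v3, "pass"))
  expect_error(varianceInflation(d3[1:3, ]), "at least 4")
})

test_that("the fast refit path agrees with the reference fit", {
  tab <- toyTable(seed = 13)
  des <- preparePredictors(tab)
  fitter <- makeEffectFitter(des)
  fast <- fitter(des)
  full <- fitMassLossModel(des)
  expect_equal(fast$coefficients, full$coefficients, tolerance = 1e-6)
  expect_identical(fast$fallback, full$fallback)
  # and on perturbed responses
  des2 <- des; des2$mass_loss <- des$mass_loss + rnorm(nrow(des), 0, 2)
  expect_equal(fitter(des2)$coefficients,
               fitMassLossModel(des2)$coefficients, tolerance = 1e-6)
  # different grouping falls back to the reference path transparently
  des3 <- des[des$site != des$site[1], ]
  expect_equal(fitter(des3)$coefficients,
               fitMassLossModel(des3)$coefficients, tolerance = 1e-6)
})

test_that("interval coverage: generator truth is recovered across replicates", {
  # moderately sized simulation; the full 200-replicate sweep lives in the
  # acceptance suite
  covered <- matrix(FALSE, 25, 3)
  for (r in 1:25) {
    tab <- generateObservations(observationConfig(seed = 400 + r))
    fit <- fitMassLossModel(preparePredictors(tab))
    expect_identical(nrow(tab), 124L)
    se <- sqrt(diag(fit$vcov))
    truth <- attr(tab, "truth")$b
    covered[r, ] <- abs(fit$coefficients - truth) <= 1.96 * se
  }
  # nominal 95% Wald intervals: each coefficient covered in >= 80% of reps
  expect_true(all(colMeans(covered) >= 0.8))
})
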