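test_that("multiplier draws are uniform within ranges and reproducible", {
  rng <- multiplierRanges()
  d <- sampleParameterSets(5000, rng, seed = 77)
  expect_identical(nrow(d), 5000L)
  for (nm in names(rng)) {
    expect_true(all(d[[nm]] >= rng[[nm]][1] & d[[nm]] <= rng[[nm]][2]))
    # extreme order statistics of 5000 uniforms sit within 1% of the ends
    span <- diff(rng[[nm]])
    expect_lt(min(d[[nm]]) - rng[[nm]][1], 0.01 * span)
    expect_lt(rng[[nm]][2] - max(d[[nm]]), 0.01 * span)
  }
  expect_identical(sampleParameterSets(5000, rng, seed = 77), d)
  expect_false(identical(sampleParameterSets(5000, rng, seed = 78), d))
  expect_error(sampleParameterSets(10, list(m_tau_r = c(2, 1)), seed = 1),
               "invalid range")
})

test_that("the four filters apply their thresholds individually", {
  ok <- fakeRecord(rmse = 3, effects = c(40, -20, -40))
  obs_eff <- c(moisture = 40, lignin_n = -20, co_ratio = -40)
  env <- fakeEnvelope()

  recs <- list(ok,
               fakeRecord(rmse = 6.0, effects = c(40, -20, -40)),     # rmse
               fakeRecord(rmse = 3, effects = c(40, -32, -40)),       # effects
               fakeRecord(rmse = 3, effects = c(40, -20, -40),
                          viable = FALSE),                            # viability
               fakeRecord(rmse = 3, effects = c(40, -20, -40),
                          site_means = data.frame(
                            site_id = rep(c("A", "B"), each = 2),
                            timepoint = rep(1:2, 2),
                            mass_loss_pct = c(55, 60, 35, 65))))      # envelope
  flt <- filterSets(recs, env, obs_eff)
  expect_identical(flt$survivors, 1L)
  expect_false(flt$verdicts[2, "rmse"])
  expect_false(flt$verdicts[3, "effects"])
  expect_false(flt$verdicts[4, "viability"])
  expect_false(flt$verdicts[5, "envelope"])
  expect_identical(unname(flt$failure_counts),
                   c(1, 1, 1, 1))
  # an effect deviation of exactly 10 units still passes; 12 does not
  r10 <- fakeRecord(rmse = 3, effects = c(50, -20, -40))
  r12 <- fakeRecord(rmse = 3, effects = c(52, -20, -40))
  flt2 <- filterSets(list(r10, r12), env, obs_eff)
  expect_identical(flt2$survivors, 1L)
  # rmse exactly at 5.4 is rejected (strictly less than)
  expect_length(filterSets(list(fakeRecord(5.4, c(40, -20, -40))), env,
                           obs_eff)$survivors, 0)
})

test_that("filtering is monotone in its thresholds", {
  set.seed(9)
  recs <- lapply(1:40, function(i)
    fakeRecord(rmse = runif(1, 0, 8),
               effects = c(40, -20, -40) + rnorm(3, 0, 8),
               viable = runif(1) > 0.2))
  env <- fakeEnvelope()
  obs_eff <- c(moisture = 40, lignin_n = -20, co_ratio = -40)
  s1 <- filterSets(recs, env, obs_eff, rmse_max = 4, effect_tol = 6)$survivors
  s2 <- filterSets(recs, env, obs_eff, rmse_max = 5.4,
                   effect_tol = 10)$survivors
  s3 <- filterSets(recs, env, obs_eff, rmse_max = 8,
                   effect_tol = 20)$survivors
  expect_true(all(s1 %in% s2))
  expect_true(all(s2 %in% s3))
})

test_that("selection ranks by RMSE with the effect-size tie-break", {
  obs_eff <- c(moisture = 40, lignin_n = -20, co_ratio = -40)
  recs <- list(fakeRecord(5.3, c(40, -20, -40)),
               fakeRecord(3, c(45, -20, -40)),
               fakeRecord(4, c(40, -20, -40)),
               fakeRecord(5, c(40, -20, -40)),
               fakeRecord(3, c(41, -20, -40)))
  sel <- selectBest(recs, seq_along(recs), obs_eff, k = 3)
  # RMSE 3, 3, 4 win; within the RMSE tie the smaller deviation leads
  expect_identical(sel$index, c(5L, 2L, 3L))
  expect_warning(s2 <- selectBest(recs, c(1L, 2L), obs_eff, k = 3),
                 "survivors")
  expect_identical(nrow(s2), 2L)
  expect_error(selectBest(recs, integer(0), obs_eff), "loosening")
})

test_that("selection is stable under holdout when an optimum dominates", {
  obs_eff <- c(moisture = 40, lignin_n = -20, co_ratio = -40)
  set.seed(4)
  # three dominant records, the rest clearly worse
  recs <- c(lapply(1:3, function(i) fakeRecord(0.5 + 0.1 * i,
                                               c(40, -20, -40))),
            lapply(1:37, function(i) fakeRecord(runif(1, 3, 5),
                                                c(40, -20, -40))))
  env <- fakeEnvelope()
  st <- stabilityCheck(recs, env, obs_eff, replicates = 100, seed = 2)
  expect_identical(st$full_selection, 1:3)
  # available full-data selections are always re-selected
  expect_equal(st$mean_overlap, 1.0)
  # holdout 0: identical selection always
  st0 <- stabilityCheck(recs, env, obs_eff, holdout = 0, replicates = 10,
                        seed = 2)
  expect_true(all(st0$overlap == 1))
  expect_error(stabilityCheck(recs[1:5], env, obs_eff), "at least 10")
})

test_that("identity multipliers reproduce the default model exactly", {
  p <- defaultParams()
  sites <- calSites()
  runs <- litterbagDesign(sites, p)
  obs <- list(means = aggregate(mass_loss_pct ~ site_id + timepoint, runs,
                                mean))
  r <- evaluateSet(c(m_tau_r = 1, m_beta = 1, m_vmod_m = 1, m_vmod_s = 1),
                   sites, obs, p)
  expect_false(r$failed)
  # RMSE of the default model against its own site means is zero
  expect_lt(r$rmse, 1e-10)
  expect_equal(r$runs$mass_loss_pct, runs$mass_loss_pct, tolerance = 1e-10)
})

test_that("RMSE follows the quadratic-mean formula on a 2-site toy", {
  sim <- data.frame(site_id = c("A", "A", "B", "B"), timepoint = c(1, 2, 1, 2),
                    mass_loss_pct = c(30, 60, 40, 70))
  obs <- data.frame(site_id = c("A", "A", "B", "B"), timepoint = c(1, 2, 1, 2),
                    mass_loss_pct = c(32, 57, 40, 74))
  m <- merge(sim, obs, by = c("site_id", "timepoint"),
             suffixes = c("_sim", "_obs"))
  rmse <- sqrt(mean((m$mass_loss_pct_sim - m$mass_loss_pct_obs)^2))
  expect_equal(rmse, sqrt((4 + 9 + 0 + 16) / 4))
})

test_that("failed evaluations are recorded, not dropped", {
  p <- defaultParams()
  sites <- calSites()[1, , drop = FALSE]
  bad <- sites; bad$moisture_mean <- NA
  obs <- list(means = data.frame(site_id = "TREE", timepoint = 1:2,
                                 mass_loss_pct = c(30, 60)))
  r <- evaluateSet(c(m_tau_r = 1, m_beta = 1, m_vmod_m = 1, m_vmod_s = 1),
                   bad, obs, p)
  expect_true(r$failed)
  expect_true(is.na(r$rmse))
  expect_false(r$viable_all)
})
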