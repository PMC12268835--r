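test_that("uptake flux follows moisture-scaled Michaelis-Menten kinetics", {
  p <- defaultParams()
  expect_equal(uptakeFlux(1, 0, 10, 0.5, "r_m", p), 0)
  expect_equal(uptakeFlux(0, 5, 10, 0.5, "r_m", p), 0)
  expect_equal(uptakeFlux(1, 5, 10, 0, "r_m", p), 0)
  expect_error(uptakeFlux(-1, 5, 10, 0.5, "r_m", p), "non-negative")
  expect_error(uptakeFlux(1, 5, 10, 1.5, "r_m", p), "moisture")

  # half-saturation identity: flux at S = Km is half the saturating rate
  kin <- mimicsLitter:::.kinetics(10, 0.1, p@pars)
  for (j in 1:6) {
    fl <- c("r_m", "r_s", "r_a", "k_m", "k_s", "k_a")[j]
    half <- uptakeFlux(2, kin$km[j], 10, 0.7, fl, p, clay = 0.1)
    expect_equal(half, 2 * kin$vmax[j] * 0.7 / 2, tolerance = 1e-12)
  }

  # the 40% catabolic-capacity reduction is a pure scaling of Vmax
  p_full <- setPars(p, vmax_scale = 1)
  expect_equal(uptakeFlux(1, 5, 10, 0.5, "r_m", p),
               0.6 * uptakeFlux(1, 5, 10, 0.5, "r_m", p_full))

  # monotone in moisture
  fx <- vapply(seq(0, 1, by = 0.1), function(m)
    uptakeFlux(1, 5, 10, m, "k_s", p), numeric(1))
  expect_true(all(diff(fx) >= 0))
})

test_that("density-dependent turnover reduces to the linear law at beta = 1", {
  expect_equal(microbialTurnover(0, 1.5, 0.1), 0)
  expect_equal(microbialTurnover(3, 1, 0.1, 1), 0.3)
  expect_equal(microbialTurnover(2, 1.5, 0.1, 1), 2^1.5 * 0.1)
  expect_equal(microbialTurnover(2, 1.5, 0.1, 1), 0.2828427, tolerance = 1e-6)
  expect_error(microbialTurnover(-1, 1.5, 0.1), "non-negative")
  # beta = 1 is exactly linear in biomass
  mic <- seq(0, 10, by = 0.5)
  expect_equal(microbialTurnover(mic, 1, 2e-4), mic * 2e-4)
})

test_that("derivatives vanish for an empty system and conserve carbon", {
  p <- defaultParams()
  d0 <- mimicsDerivatives(rep(0, 7), 10, 0.5, 0, 30, 0.1, p)
  expect_equal(unname(d0), rep(0, 8))
  expect_error(mimicsDerivatives(rep(-1, 7), 10, 0.5, 0, 30, 0.1, p),
               "non-negative")
  expect_error(mimicsDerivatives(rep(1, 7), NA, 0.5, 1e-4, 30, 0.1, p),
               "invalid forcing")

  set.seed(7)
  for (i in 1:50) {
    sf <- randomStateForcing()
    d <- mimicsDerivatives(sf$state, sf$temp, sf$moisture, sf$input,
                           sf$lignin_n, sf$clay, p)
    scale <- max(abs(d), sf$input, 1e-12)
    expect_lt(abs(sum(d[1:7]) + d[["respiration"]] - sf$input) / scale, 1e-10)
  }
})

test_that("compiled and reference derivative implementations agree", {
  p <- defaultParams()
  set.seed(11)
  for (i in 1:25) {
    sf <- randomStateForcing()
    dc <- mimicsDerivatives(sf$state, sf$temp, sf$moisture, sf$input,
                            sf$lignin_n, sf$clay, p, use_compiled = TRUE)
    dr <- mimicsDerivatives(sf$state, sf$temp, sf$moisture, sf$input,
                            sf$lignin_n, sf$clay, p, use_compiled = FALSE)
    expect_equal(dc, dr, tolerance = 1e-13)
  }
})

test_that("one Euler step matches a manual flux-by-flux evaluation", {
  # every flux written out independently with its own arithmetic
  p <- defaultParams()
  x <- c(lit_m = 1.2, lit_s = 6.5, mic_r = 0.7, mic_k = 0.9,
         som_p = 14, som_c = 6, som_a = 3.5)
  temp <- 12; moist <- 0.6; input <- 4e-4; lign <- 25; clay <- 0.12
  fmet <- 0.85 - 0.013 * 25
  vb <- exp(0.063 * temp + 5.47) * 8e-6 * 0.6
  v <- vb * c(10, 2, 10, 3, 3, 2)
  pscal <- 2 * exp(-2 * sqrt(clay))
  km <- exp(c(0.017, 0.027, 0.017, 0.017, 0.027, 0.017) * temp + 3.19) * 10 /
    c(8, 2, 4 * pscal, 2, 4, 6 * pscal)
  l1r <- 0.7 * v[1] * 1.2 / (km[1] + 1.2) * 0.6
  l2r <- 0.7 * v[2] * 6.5 / (km[2] + 6.5) * 0.6
  ar <- 0.7 * v[3] * 3.5 / (km[3] + 3.5) * 0.6
  l1k <- 0.9 * v[4] * 1.2 / (km[4] + 1.2) * 0.6
  l2k <- 0.9 * v[5] * 6.5 / (km[5] + 6.5) * 0.6
  ak <- 0.9 * v[6] * 3.5 / (km[6] + 3.5) * 0.6
  oxr <- 0.7 * v[2] * 6 / (6 * km[2] + 6) * 0.6
  oxk <- 0.9 * v[5] * 6 / (6 * km[5] + 6) * 0.6
  trn_r <- 0.7^1.5 * 5.2e-4 * exp(0.3 * fmet)
  trn_k <- 0.9^1.5 * 2.4e-4 * exp(0.1 * fmet)
  fp_r <- 0.3 * exp(1.3 * clay); fp_k <- 0.2 * exp(0.8 * clay)
  fc_r <- 0.1 * exp(-3 * fmet); fc_k <- 0.3 * exp(-3 * fmet)
  des <- 14 * 1.5e-5 * exp(-1.5 * clay)
  expected <- c(
    input * fmet * 0.95 - l1r - l1k,
    input * (1 - fmet) * 0.95 - l2r - l2k,
    0.55 * (l1r + ar) + 0.25 * l2r - trn_r,
    0.75 * (l1k + ak) + 0.35 * l2k - trn_k,
    input * fmet * 0.05 + trn_r * fp_r + trn_k * fp_k - des,
    input * (1 - fmet) * 0.05 + trn_r * fc_r + trn_k * fc_k - oxr - oxk,
    trn_r * (1 - fp_r - fc_r) + trn_k * (1 - fp_k - fc_k) + des + oxr + oxk -
      ar - ak)
  d <- mimicsDerivatives(x, temp, moist, input, lign, clay, p)
  expect_equal(unname(d[1:7]), expected, tolerance = 1e-12)
  # one Euler update stays consistent
  expect_equal(unname(x + 24 * d[1:7]), unname(x + 24 * expected),
               tolerance = 1e-12)
})

test_that("steady state has vanishing derivatives and honest viability flags", {
  p <- defaultParams()
  site <- treeSite()
  st <- steadyState(site, "mean", lignin_n = 30, params = p)
  expect_true(attr(st, "converged"))
  expect_lt(attr(st, "residual_rel"), 1e-8)
  expect_true(all(st >= 0))
  fo <- attr(st, "forcing")
  d <- mimicsDerivatives(st, fo$temp, fo$moisture, fo$litter_input,
                         fo$lignin_n, fo$clay, p)
  expect_lt(max(abs(d[1:7])) / fo$litter_input, 1e-8)
  expect_true(all(attr(st, "viable")))

  # no inputs, no standing stocks
  site0 <- site; site0$litterfall <- 0
  st0 <- steadyState(site0, "mean", 30, p)
  expect_equal(unname(st0[1:7]), rep(0, 7))
  expect_false(any(attr(st0, "viable")))
})

test_that("steady-state table enumerates the design and accepts warm starts", {
  p <- defaultParams()
  sites <- calSites()
  tab <- steadyStateTable(sites, p)
  expect_identical(nrow(tab), 63L)   # 7 sites x 3 litters x 3 moistures
  expect_true(all(tab$residual_rel < 1e-8))
  expect_true(all(tab[, poolNames()] >= 0))
  # same-parameterisation warm start reproduces the same solution
  tab2 <- steadyStateTable(sites, p, warm = tab)
  expect_equal(tab2[, poolNames()], tab[, poolNames()], tolerance = 1e-6)
})

test_that("moisture monotonicity: wetter never slows any uptake flux", {
  p <- defaultParams()
  set.seed(3)
  for (i in 1:10) {
    sf <- randomStateForcing()
    m2 <- min(sf$moisture + 0.2, 1)
    for (fl in c("r_m", "r_s", "r_a", "k_m", "k_s", "k_a")) {
      f1 <- uptakeFlux(sf$state[3], sf$state[1], sf$temp, sf$moisture, fl, p,
                       clay = sf$clay)
      f2 <- uptakeFlux(sf$state[3], sf$state[1], sf$temp, m2, fl, p,
                       clay = sf$clay)
      expect_gte(f2, f1)
    }
  }
})
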