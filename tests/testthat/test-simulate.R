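test_that("identical configurations yield identical lineage tables", {
  cfg <- SimulationConfig(n_founders = 8, seed = 123)
  a <- simulateLineages(cfg)
  b <- simulateLineages(cfg)
  expect_identical(cells(a), cells(b))
  expect_identical(volumeSeries(a), volumeSeries(b))
  c2 <- simulateLineages(SimulationConfig(n_founders = 8, seed = 124))
  expect_false(identical(volumeSeries(a), volumeSeries(c2)))
})

test_that("division conserves volume exactly", {
  lt <- simulateLineages(SimulationConfig(n_founders = 10, seed = 2))
  cc <- cells(lt)
  kids <- cc[!is.na(cc$parent_id), ]
  sums <- tapply(kids$birth_volume, kids$parent_id, sum)
  mothers <- cc[match(names(sums), cc$cell_id), ]
  expect_equal(as.numeric(sums), mothers$division_volume, tolerance = 1e-12)
})

test_that("the noise-free limit is a perfectly symmetric fully viable tree", {
  cfg <- SimulationConfig(n_founders = 4, n_generations = 3,
                          sigma_g = 0, sigma_s = 0, cv_dV = 0,
                          founder_cv = 0, seed = 31)
  lt <- simulateLineages(cfg)
  cc <- cells(lt)
  expect_equal(nrow(cc), 4 * (2^4 - 1))          # complete binary trees
  expect_equal(survivalProbability(lt, generation = 1)$p, 1)
  s <- asymmetrySummary(extractSisterPairs(lt))
  expect_equal(s$Cg, 0, tolerance = 1e-12)
  expect_equal(s$Cs, 0, tolerance = 1e-12)
})

test_that("asymmetry calibration inverts the expected pair statistics", {
  expect_equal(calibrateSigmaG(0), 0)
  expect_equal(calibrateSigmaS(0), 0)
  for (tgt in c(0.05, 0.2, 0.55, 0.8)) {
    expect_equal(expectedCg(calibrateSigmaG(tgt)), tgt, tolerance = 1e-6)
  }
  for (tgt in c(0.05, 0.194, 0.4)) {
    expect_equal(expectedCs(calibrateSigmaS(tgt)), tgt, tolerance = 1e-6)
  }
  expect_error(calibrateSigmaG(1), "domain error")
  expect_error(calibrateSigmaG(-0.1), "domain error")
  expect_error(calibrateSigmaS(0.45), "domain error")
})

test_that("invalid configurations fail before any simulation", {
  expect_error(SimulationConfig(r0 = -1), "r0")
  expect_error(SimulationConfig(sigma_s = 0.6), "sigma_s")
  expect_error(SimulationConfig(survival = c(V_lo = 5, V_hi = 1,
                                             p_mid = 1, steepness = 1)),
               "V_lo")
  expect_error(SimulationConfig(survival = c(V_lo = 1, V_hi = 5,
                                             p_mid = 2, steepness = 1)),
               "p_mid")
})

test_that("simulator configurations round-trip through JSON", {
  cfg <- SimulationConfig(n_founders = 12, sigma_g = calibrateSigmaG(0.55),
                          seed = 77)
  path <- withr::local_tempfile(fileext = ".json")
  writeSimulationConfig(cfg, path)
  back <- readSimulationConfig(path)
  expect_equal(back@sigma_g, cfg@sigma_g)
  expect_equal(back@seed, cfg@seed)
  expect_identical(cells(simulateLineages(back)),
                   cells(simulateLineages(cfg)))

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"r0": 0.01, "bogus_knob": 3}', bad)
  expect_error(readSimulationConfig(bad), "config error")
})

test_that("mean birth volume drifts down when founders start far above the adder target", {
  cfg <- SimulationConfig(n_founders = 20, n_generations = 4,
                          founder_volume = 4 * 3.3, founder_cv = 0,
                          seed = 21)
  lt <- simulateLineages(cfg)
  cc <- cells(lt)
  byGen <- tapply(cc$birth_volume, cc$generation, mean)
  expect_true(all(diff(byGen) < 0))              # monotone decline
  # and the septation rate exceeds elongation while volume is shrinking
  pairs <- extractSisterPairs(lt)
  r <- mean(c(pairs$r_a, pairs$r_b), na.rm = TRUE)
  expect_equal(homeostasisCheck(r, septationRate(lt), tol = 0.05)$regime,
               "shrinking")
})

test_that("balanced fully viable runs keep birth volume at the adder fixed point", {
  cfg <- SimulationConfig(n_founders = 6, n_generations = 6,
                          founder_volume = 3.3, seed = 22)
  lt <- simulateLineages(cfg)
  cc <- cells(lt)
  byGen <- tapply(cc$birth_volume, cc$generation, mean)
  av <- addedVolume(lt)
  expect_lt(abs(byGen[["6"]] - av$mean) / av$mean, 0.15)
})

test_that("log cell counts grow at the branching rate r0 * log2(2 * pbar) when p < 1", {
  r0 <- 0.01
  slopes <- numeric(4); pbars <- numeric(4)
  for (i in 1:4) {
    cfg <- SimulationConfig(r0 = r0, n_founders = 12, n_generations = 7,
                            survival = c(V_lo = -50, V_hi = 1e4,
                                         p_mid = 0.85, steepness = 1),
                            seed = 400 + i)
    lt <- simulateLineages(cfg)
    pbars[i] <- survivalProbability(lt)$p
    cc <- cells(lt)
    tEnd <- min(cc$birth_time[cc$generation == max(cc$generation)])
    times <- seq(2 * log(2) / r0, tEnd, by = 10)
    n <- countCells(lt, times)
    slopes[i] <- unname(coef(lm(log(n) ~ times))[2])
  }
  expected <- r0 * log2(2 * mean(pbars))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - expected), max(3 * se, 0.1 * expected))
})

test_that("growth-curve fixtures expose their generating parameters", {
  gc <- simulateGrowthCurve(r = 0.008, lag = 0, K = 1e5, od0 = 0.02,
                            tMax = 500)
  expect_equal(identifyPhases(gc$time, gc$od)$k, 0.008, tolerance = 4e-4)
  gc2 <- simulateGrowthCurve(r = 0.01, lag = 120, K = 1e5, od0 = 0.02,
                             noiseSd = 0.005, seed = 6, tMax = 700)
  expect_equal(identifyPhases(gc2$time, gc2$od)$lag, 120, tolerance = 25)
  expect_identical(simulateGrowthCurve(0.01, noiseSd = 0.01, seed = 9),
                   simulateGrowthCurve(0.01, noiseSd = 0.01, seed = 9))
})
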