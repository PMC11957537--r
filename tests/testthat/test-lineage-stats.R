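test_that("elongation-rate fit recovers a noiseless exponential exactly", {
  t <- seq(0, 30, 5)
  fit <- fitElongationRate(t, 2 * exp(0.01 * t))
  expect_equal(fit$r, 0.01, tolerance = 1e-10)
  expect_equal(fit$V0, 2, tolerance = 1e-10)
  expect_equal(fit$n_points, 7L)
  expect_lt(fit$rss, 1e-20)

  flat <- fitElongationRate(t, rep(3, 7))
  expect_equal(flat$r, 0, tolerance = 1e-12)

  expect_error(fitElongationRate(c(0, 5), c(1, 2)), "insufficient data")
  expect_error(fitElongationRate(t, c(-1, rep(1, 6))), "domain error")
})

test_that("noisy rate fits agree with a brute-force RSS grid search", {
  set.seed(7)
  t <- seq(0, 95, by = 5)
  v <- 2 * exp(0.01 * t) * exp(rnorm(length(t), 0, 0.01))
  fit <- fitElongationRate(t, v)
  oracle <- gridSearchRate(t, v)
  expect_lt(abs(fit$r - oracle), 1e-4)          # within grid resolution
  # and within 3 standard errors of the truth
  se <- summary(lm(log(v) ~ t))$coefficients["t", "Std. Error"]
  expect_lt(abs(fit$r - 0.01), 3 * se)
})

test_that("septation rate is ln2 over the mean division time", {
  expect_equal(septationRate(rep(69.3, 5)), log(2) / 69.3)
  expect_equal(septationRate(c(60, 80)), log(2) / 70)
  expect_equal(round(septationRate(c(60, 80)), 5), 0.0099)
  expect_equal(septationRate(100), log(2) / 100)
  lt <- fateForest(nDiv = 4, nArr = 0, tau = 60)
  expect_equal(septationRate(lt), log(2) / 60)
  expect_error(septationRate(numeric(0)), "insufficient data")
})

test_that("asymmetry statistics are zero for identical sisters and match hand values", {
  pairs <- data.frame(mother_id = "M", generation = 1L,
                      cell_a = "a", cell_b = "b",
                      fate_a = "divided", fate_b = "divided",
                      r_a = 0.01, r_b = 0.01, T_a = 60, T_b = 60,
                      Vb_a = 2, Vb_b = 2, stringsAsFactors = FALSE)
  s <- asymmetrySummary(pairs)
  expect_equal(c(s$Cg, s$CT, s$Cs), c(0, 0, 0))

  pairs$r_a <- 3; pairs$r_b <- 1
  expect_equal(asymmetrySummary(pairs)$Cg, 0.5)   # |3-1|/(3+1)
})

test_that("a pair with one arrested sister is excluded from Cg/CT but kept for Cs", {
  pairs <- data.frame(mother_id = "M", generation = 1L,
                      cell_a = "a", cell_b = "b",
                      fate_a = "divided", fate_b = "arrested",
                      r_a = 0.01, r_b = 0, T_a = 60, T_b = NA,
                      Vb_a = 3, Vb_b = 1, stringsAsFactors = FALSE)
  expect_warning(expect_warning(s <- asymmetrySummary(pairs), "Cg"), "CT")
  expect_true(is.na(s$Cg) && is.na(s$CT))
  expect_equal(s$Cs, 0.5)
  expect_equal(s$n_Cs, 1L)
  expect_error(asymmetrySummary(pairs, strict = TRUE), "Cg")
  expect_error(asymmetrySummary(pairs[0, ]), "no sister pairs")
})

test_that("asymmetry statistics are invariant under sister relabelling", {
  set.seed(3)
  lt <- simulateLineages(SimulationConfig(n_founders = 15, seed = 3))
  pairs <- extractSisterPairs(lt)
  sw <- pairs
  sw[, c("cell_a", "cell_b", "fate_a", "fate_b", "r_a", "r_b",
         "T_a", "T_b", "Vb_a", "Vb_b")] <-
    pairs[, c("cell_b", "cell_a", "fate_b", "fate_a", "r_b", "r_a",
              "T_b", "T_a", "Vb_b", "Vb_a")]
  expect_equal(unclass(asymmetrySummary(sw)), unclass(asymmetrySummary(pairs)))
  s <- asymmetrySummary(pairs)
  expect_true(all(c(s$Cg, s$CT, s$Cs) >= 0 & c(s$Cg, s$CT, s$Cs) <= 1))
})

test_that("survival probability counts divided over non-censored cells with a Wald CI", {
  expect_equal(survivalProbability(fateForest(10, 0), generation = 1)$p, 1)

  est <- survivalProbability(fateForest(120, 21), generation = 1)
  expect_equal(est$N, 141L)
  expect_equal(est$p, 120 / 141)
  expect_equal(round(est$p, 3), 0.851)
  expect_equal(est$ci_halfwidth, 1.96 * sqrt(est$p * (1 - est$p) / 141))

  expect_equal(waldHalfwidth(0.5, 100), 0.098)

  # censored cells are excluded from the denominator
  lt <- tinyForest()   # both daughters censored
  expect_error(survivalProbability(lt, generation = 1), "insufficient data")
})

test_that("Wald half-width is maximal at p = 0.5 and shrinks as 1/sqrt(N)", {
  p <- seq(0.05, 0.95, by = 0.05)
  hw <- waldHalfwidth(p, 100)
  expect_equal(p[which.max(hw)], 0.5)
  expect_equal(waldHalfwidth(0.3, 400), waldHalfwidth(0.3, 100) / 2)
})

test_that("survival-vs-volume flags thin bins and keeps empty bins visible", {
  lt <- fateForest(12, 4, vb = 2)
  prof <- survivalVsVolume(lt, bins = c(0, 1, 3, 10), generation = 1,
                           minCount = 5)
  expect_equal(nrow(prof), 3L)
  expect_equal(prof$N, c(0L, 16L, 0L))         # all daughters born at 2 um^3
  expect_true(is.na(prof$p[1]) && prof$flagged[1])
  expect_equal(prof$p[2], 12 / 16)
  expect_error(survivalVsVolume(lt, bins = c(3, 1)), "domain error")
})

test_that("uniform survival yields volume bins that agree within their CIs", {
  lt <- simulateLineages(SimulationConfig(n_founders = 120, n_generations = 2,
                                          seed = 5))
  prof <- survivalVsVolume(lt, generation = 1, minCount = 5)
  ok <- prof$N > 0
  expect_true(all(abs(prof$p[ok] - 1) <= pmax(prof$ci_halfwidth[ok], 1e-12)))
})

test_that("U-tailed survival produces lower survival in the volume tails", {
  cfg <- SimulationConfig(n_founders = 250, n_generations = 2,
                          sigma_s = calibrateSigmaS(0.25),
                          survival = c(V_lo = 2.2, V_hi = 4.4, p_mid = 0.95,
                                       steepness = 2.5),
                          seed = 9)
  lt <- simulateLineages(cfg)
  prof <- survivalVsVolume(lt, bins = c(0, 2.2, 4.4, 50), generation = 1,
                           minCount = 5)
  expect_true(prof$p[1] < prof$p[2])
  expect_true(prof$p[3] < prof$p[2])
})

test_that("added volume matches division minus birth and its adder summary", {
  df <- rbind(frameRows("F1", NA, c(0, 30, 60), c(2, 3, 5)),
              frameRows("F1.1", "F1", c(60, 80, 100), c(2.5, 2.6, 2.7)),
              frameRows("F1.2", "F1", c(60, 80, 100), c(2.5, 2.6, 2.7)))
  lt <- makeLineageTable(df, metadata = list(frame_dt = 20))
  av <- addedVolume(lt)
  expect_equal(av$perCell$dV, 3)               # 5 - 2
  expect_equal(av$n, 1L)
  expect_error(addedVolume(tinyForest(), generation = 1),
               "insufficient data")
})

test_that("homeostasis regime follows the sign of septation minus elongation", {
  expect_equal(homeostasisCheck(0.01, 0.01)$regime, "balanced")
  expect_equal(homeostasisCheck(0.01, 0.015, tol = 0.1)$regime, "shrinking")
  expect_equal(homeostasisCheck(0.01, 0.005, tol = 0.1)$regime, "growing")
  expect_error(homeostasisCheck(-1, 1), "domain error")
})

test_that("effective growth rate scales elongation by viability", {
  expect_equal(effectiveGrowthRate(1, 0.02), 0.02)
  expect_equal(effectiveGrowthRate(0.5, 0.02), 0.01)
  expect_error(effectiveGrowthRate(1.2, 0.02), "domain error")
})
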