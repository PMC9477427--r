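test_that("acetylation fit recovers generating parameters from the closed form", {
  lat <- chromLattice()
  pk <- gaussianPeak(0.1196, 0.1666, -0.5438, 5.1875)
  p <- modelParams()
  mkObs <- function(kAc, aBg) {
    psi <- evaluateGaussianProfile(gaussianPeak(aBg * pk@psiB, pk@psiM,
                                                pk@i0, pk@sigma0), lat)
    kAc * psi / (kAc * psi + p@gammaAc + p@gammaTurn + log(2) / p@cellCycle)
  }
  ## noiseless recovery is exact up to optimizer tolerance
  fit <- fitAcetylation(mkObs(1.03, 0.6), pk, p, lat)
  expect_equal(fit$kAc, 1.03, tolerance = 0.02)
  expect_equal(fit$backgroundCorrection, 0.6, tolerance = 0.02)
  expect_lt(fit$chi2, 1e-6)
  ## nested model: data generated with no background correction
  fit1 <- fitAcetylation(mkObs(0.9, 1.0), pk, p, lat)
  expect_equal(fit1$kAc, 0.9, tolerance = 0.02)
  expect_equal(fit1$backgroundCorrection, 1.0, tolerance = 0.02)
  ## zero observed signal (flat, hence ill-posed) drives the rate to the
  ## lower boundary
  expect_warning(fit0 <- fitAcetylation(rep(0, 200), pk, p, lat), "ill-posed")
  expect_lt(fit0$kAc, 1e-3)
  expect_warning(fitAcetylation(rep(0.25, 200), pk, p, lat), "ill-posed")
})

test_that("synthetic targets carry the observation-scale conventions", {
  targets <- makeSyntheticTargets(nTraj = 8L, burnInCycles = 5,
                                  sampleCycles = 2, seed = 3)
  expect_s3_class(targets, "TargetData")
  expect_true(all(targets$utxkdMe3 >= 0 & targets$utxkdMe3 <= 1))
  expect_true(all(targets$dkoAc >= 0 & targets$dkoAc <= 1))
  ## observed no-spreading valency at the promoter: me2 > me3 > me1
  sel <- abs(positionsKbp(targets$profile)) <= 2.5
  m <- vapply(targets$ezh2ko, function(v) mean(v[sel]), numeric(1))
  expect_gt(m[["me2"]], m[["me3"]])
  expect_gt(m[["me3"]], m[["me1"]])
  expect_error(targetData(targets$dkoAc, targets$ezh2ko, targets$wt,
                          targets$utxkdMe3 + 2, targets$profile,
                          targets$p300Peak), "probability")
})

test_that("demethylation-rate scan brackets the generating value", {
  targets <- makeSyntheticTargets(nTraj = 24L, burnInCycles = 10,
                                  sampleCycles = 3, seed = 5)
  cfg <- testInferenceConfig()
  fit <- fitGammaMe(targets, modelParams(), cfg)
  expect_equal(fit$status, "ok")
  expect_gte(1.5, fit$interval[1])
  expect_lte(1.5, fit$interval[2])
  ## a grid of huge demethylation rates admits nothing
  cfgBad <- testInferenceConfig()
  cfgBad$gammaGrid <- c(8, 10, 12)
  fitBad <- fitGammaMe(targets, modelParams(), cfgBad)
  expect_equal(fitBad$status, "failed_valency")
  ## targets whose own valency is wrong fail before simulating
  t2 <- targets
  t2$ezh2ko$me1 <- t2$ezh2ko$me2 * 2
  expect_equal(fitGammaMe(t2, modelParams(), cfg)$status, "failed_valency")
})

test_that("nucleation-rate fit responds to degenerate targets", {
  targets <- makeSyntheticTargets(nTraj = 8L, burnInCycles = 5,
                                  sampleCycles = 2, seed = 6)
  cfg <- testInferenceConfig()
  cfg$kGrid <- c(0.3, 0.6, 0.9, 1.2)
  ## saturated observation drives the fit to the upper grid edge
  tHi <- targets; tHi$utxkdMe3 <- rep(1, 200)
  fitHi <- fitKme3(tHi, modelParams(), cfg)
  expect_gte(fitHi$kMe3, max(cfg$kGrid))
  expect_true(fitHi$boundary)
  ## empty observation drives it to the lower edge
  tLo <- targets; tLo$utxkdMe3 <- rep(0, 200)
  fitLo <- fitKme3(tLo, modelParams(), cfg)
  expect_lte(fitLo$kMe3, cfg$kGrid[1])
  expect_true(fitLo$boundary)
})

test_that("degenerate tolerance returns after one iteration", {
  targets <- makeSyntheticTargets(nTraj = 8L, burnInCycles = 5,
                                  sampleCycles = 2, seed = 6)
  cfg <- testInferenceConfig(tolRel = Inf)
  cfg$gammaGrid <- seq(1, 2, by = 0.5)
  cfg$RGrid <- seq(0.6, 1.0, by = 0.1)
  cfg$kGrid <- c(0.6, 0.8, 1.0)
  res <- iterateInference(targets, cfg)
  expect_s4_class(res, "InferenceResult")
  expect_equal(res@status, "converged")
  expect_equal(nrow(res@trace), 1L)
})

test_that("inference at badly wrong ratios fails or misfits", {
  targets <- makeSyntheticTargets(nTraj = 24L, burnInCycles = 10,
                                  sampleCycles = 3, seed = 5)
  cfg <- testInferenceConfig(r13 = 9, r23 = 9)
  res <- iterateInference(targets, cfg)
  misfit <- res@status != "converged" ||
    abs(res@kMe3 - 0.81) / 0.81 > 0.2 ||
    abs(res@gammaMe - 1.5) / 1.5 > 0.2
  expect_true(misfit)
})

test_that("a single-pair ratio grid equals plain iteration", {
  targets <- makeSyntheticTargets(nTraj = 8L, burnInCycles = 5,
                                  sampleCycles = 2, seed = 6)
  cfg <- testInferenceConfig(tolRel = Inf)
  cfg$gammaGrid <- seq(1, 2, by = 0.5)
  cfg$RGrid <- seq(0.6, 1.0, by = 0.2)
  cfg$kGrid <- c(0.6, 0.8, 1.0)
  scan <- ratioGridScan(targets, cfg, r13Values = 3, r23Values = 3,
                        kMe3Inits = 1.0)
  expect_equal(nrow(scan$summary), 1L)
  cfgSingle <- cfg
  cfgSingle$seed <- chromK27:::.subSeed(cfg$seed, 1L * 100L + 1L)
  direct <- iterateInference(targets, cfgSingle)
  one <- scan$results[[1]]
  expect_equal(one@kMe3, direct@kMe3)
  expect_equal(one@gammaMe, direct@gammaMe)
  expect_equal(one@R, direct@R)
})
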