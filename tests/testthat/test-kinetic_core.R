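test_that("power-law contact kernel has the stated entries", {
  lat <- chromLattice()
  K <- contactKernel(lat, 1)
  expect_equal(K[101, 102], 1)
  expect_equal(K[101, 111], 0.1)
  expect_true(all(diag(K) == 0))
  expect_identical(K, t(K))
  K2 <- contactKernel(lat, 2)
  expect_equal(K2[101, 111], 0.01)
  expect_error(contactKernel(lat, 0))
})

test_that("reaction propensities follow the rate equations", {
  lat <- chromLattice()
  n <- nSites(lat)
  psiS <- rep(0.1, n); psiU <- rep(0.2, n); psiP <- rep(0.15, n)
  prof <- hmeProfile(lat, psiS, psiP, psiU)
  p <- modelParams()  # kMe3 = 0.81, R = 0.85, gammaMe = 1.5 ...
  cfgStates <- rep("me2", n)
  tab <- propensities(cfgStates, prof, p)
  i <- 50
  demeth <- tab$rate[tab$site == i & tab$to == "me1"]
  expect_equal(demeth, 1.5 * 0.2)
  ## no trimethylated site anywhere: nucleation term only
  nuc <- tab$rate[tab$site == i & tab$to == "me3"]
  expect_equal(nuc, 0.81 * 0.1)
  ## one me3 site at distance 10 with psiS = 0.2 adds the spreading term
  psiS2 <- psiS; psiS2[i + 10] <- 0.2
  prof2 <- hmeProfile(lat, psiS2, psiP, psiU)
  cfg2 <- cfgStates; cfg2[i + 10] <- "me3"
  tab2 <- propensities(cfg2, prof2, p)
  nuc2 <- tab2$rate[tab2$site == i & tab2$to == "me3"]
  expect_equal(nuc2, 0.081 + 0.85 * 0.81 * (1 / 10) * 0.2)
  expect_equal(nuc2, 0.09477)
})

test_that("the reaction table respects the methylation ladder", {
  lat <- chromLattice(nSites = 10)
  n <- 10L
  prof <- hmeProfile(lat, runif(n), runif(n), runif(n))
  p <- modelParams()
  allowed <- c("u>me1", "u>ac", "ac>u", "me1>me2", "me1>u",
               "me2>me3", "me2>me1", "me2>u", "me3>me2", "me3>u")
  set.seed(3)
  for (rep in 1:5) {
    cfg <- sample(0:4, n, replace = TRUE)
    tab <- propensities(cfg, prof, p)
    expect_true(all(paste0(tab$from, ">", tab$to) %in% allowed))
    ## no direct ac <-> me transitions, no skipped methylation level
    expect_false(any(tab$from == "ac" & tab$to != "u"))
    expect_false(any(tab$from == "u" & tab$to %in% c("me2", "me3")))
    ## every listed rate is non-negative and finite
    expect_true(all(is.finite(tab$rate) & tab$rate >= 0))
  }
})

test_that("spreading vanishes identically at R = 0", {
  lat <- chromLattice(nSites = 20)
  n <- 20L
  prof <- hmeProfile(lat, rep(0.3, n), rep(0, n), rep(0, n))
  p0 <- modelParams(R = 0)
  cfgA <- rep("me2", n)
  cfgB <- cfgA; cfgB[c(2, 19)] <- "me3"
  tabA <- propensities(cfgA, prof, p0)
  rateAt <- function(tab, i) tab$rate[tab$site == i & tab$to == "me3"]
  tabB <- propensities(cfgB, prof, p0)
  for (i in c(5, 10, 15))
    expect_equal(rateAt(tabB, i), rateAt(tabA, i))
})

test_that("closed-form acetylation probability and its monotonicity", {
  p <- modelParams()
  expect_equal(closedFormAc(0, p), 0)
  ## methyltransferase-null peak density 0.1666 + 0.6 * 0.1196
  psi <- 0.23836
  expected <- 1.03 * psi / (1.03 * psi + 0.6 + 0.03 + log(2) / 13.5)
  expect_equal(closedFormAc(psi, p), expected)
  expect_equal(closedFormAc(psi, p), 0.265, tolerance = 2e-3)
  expect_equal(closedFormAc(1e9, p), 1, tolerance = 1e-6)
  ## strict monotonicity in each parameter
  psis <- seq(0, 2, by = 0.1)
  expect_true(all(diff(closedFormAc(psis, p)) > 0))
  expect_gt(closedFormAc(0.2, modelParams(kAc = 2)),
            closedFormAc(0.2, modelParams(kAc = 1)))
  expect_lt(closedFormAc(0.2, modelParams(gammaAc = 1)),
            closedFormAc(0.2, modelParams(gammaAc = 0.5)))
  expect_lt(closedFormAc(0.2, modelParams(gammaTurn = 0.5)),
            closedFormAc(0.2, modelParams(gammaTurn = 0.1)))
  expect_gt(closedFormAc(0.2, modelParams(cellCycle = 30)),
            closedFormAc(0.2, modelParams(cellCycle = 5)))
})

test_that("single-site periodic oracle: degenerate and acetylation-only cases", {
  ## absorbing unmodified state when nothing acts
  pz <- frozenParams()
  res <- singleSitePeriodicSteadyState(0, 0, 0, pz, phaseGrid = 64L)
  expect_equal(unname(res$phaseAverage), c(1, 0, 0, 0, 0), tolerance = 1e-9)
  ## acetylation-only: the phase-averaged probability agrees with the
  ## effective-rate closed form within the documented approximation error
  p <- modelParams(kMe3 = 0, R = 0, gammaMe = 0)
  for (psi in c(0.05, 0.2386, 0.6)) {
    res <- singleSitePeriodicSteadyState(0, psi, 0, p)
    expect_lt(abs(res$phaseAverage[["ac"]] - closedFormAc(psi, p)), 0.02)
  }
  ## distributions are proper at every phase
  expect_true(all(abs(rowSums(res$p) - 1) < 1e-9))
})

test_that("allostery fold change follows the contact-geometry formula", {
  expect_equal(allosteryFoldChange(0), 0)
  expect_equal(allosteryFoldChange(0.5, a = 22, d0 = 22), 0.5 * pi / 6)
  expect_equal(allosteryFoldChange(0.85, 10, 22),
               0.85 / ((6 / pi) * (10 / 22)^3))
  expect_equal(allosteryFoldChange(0.85, 10, 22), 4.74, tolerance = 1e-2)
})

test_that("kinetic parameters serialize to a flat config and back", {
  p <- modelParams(kMe3 = 0.77, r13 = 4, r23 = 2, R = 1.1, gammaMe = 0.9)
  f <- tempfile(fileext = ".yaml")
  writeParams(p, f)
  q <- readParams(f)
  for (nm in slotNames("ModelParams"))
    expect_identical(slot(q, nm), slot(p, nm))
  ## derived rates
  expect_equal(kMe1(p), 4 * 0.77)
  expect_equal(kMe2(p), 2 * 0.77)
  expect_equal(unname(epsMe(p)), 1.1 * c(4, 2, 1) * 0.77)
})
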