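#!/usr/bin/env Rscript
## One-time calibration of the packaged SUZ12/UTX Gaussian preset constants.
##
## The p300 constants are the published wild-type Gaussian fit (with the
## active-gene amplitude defined as the PcG amplitude / 0.3, so the
## PcG-target preset at beta = 0.3 reproduces that fit exactly). The SUZ12
## and UTX peak constants are free choices; this script documents how the
## shipped values were selected, by scoring candidate constant sets against
## the properties the presets must reproduce under the wild-type kinetic
## parameters:
##
##   1. (alpha, beta) = (1, 0.3) is PcG-target-like with a me3/me2 crossover
##      at ~5 kbp from the TSS, and (alpha, beta) = (0, 1) is active-like;
##   2. with spreading off (R = 0), the admissible demethylation-rate window
##      (me2 > me3 > me1 valency at the TSS) is centred near 1.5/h, and the
##      admissible spreading-ratio window (PcG valency + crossover within
##      5.0 +/- 0.5 kbp) is centred near 0.85 -- so the inference scheme,
##      which returns admissible-interval midpoints, is unbiased at the
##      wild-type parameter values;
##   3. dynamic tempo: after re-enabling spreading from the no-spreading
##      steady state, the region-averaged me3 level recovers to 90% of its
##      wild-type value within roughly two cell cycles, and after an
##      active-to-PcG profile switch the near-TSS me3 level is established
##      within roughly one cycle.
##
## The amplitude scale is only weakly constrained by the static valencies
## (property 1-2 mostly fix amplitude ratios); property 3 pins it.
##
## Shipped values (the last candidate below):
##   SUZ12 (PcG):  psiB = 0.005, psiM = 0.22, i0 = 0, sigma0 = 1.7 kbp
##   UTX (active): psiB = 0.030, psiM = 0.12, i0 = 0, sigma0 = 2.0 kbp
##
## Usage: Rscript scripts/calibrate_presets.R   (several minutes)

library(chromK27)

lat <- chromLattice()
pos <- positionsKbp(lat)
gauss <- function(psiB, psiM, i0, s) psiM * exp(-(pos - i0)^2 / (2 * s^2)) + psiB
T <- 13.5
prot <- simulationProtocol(duration = 3 * T, burnInCycles = 12,
                           recordInterval = 1)

scoreCandidate <- function(c6, nTraj = 100) {
  ## c6 = (psiB_suz, psiM_suz, sigma_suz, psiB_utx, psiM_utx, sigma_utx)
  mk <- function(a, b) hmeProfile(lat,
    gauss(c6[1], a * c6[2], 0, c6[3]),
    gauss(0.1196, b * 0.1666 / 0.3, -0.5438, 5.1875),
    gauss(c6[4], b * c6[5], 0, c6[6]))
  prof <- mk(1, 0.3); act <- mk(0, 1)

  ## demethylation-rate admissible window under R = 0
  gs <- seq(0.75, 2.5, by = 0.25)
  okG <- vapply(seq_along(gs), function(i) {
    m <- valencyCall(runEnsemble(prof, modelParams(R = 0, gammaMe = gs[i]),
                                 prot, 8, seed = 1000 + i))$means
    m[["me2"]] > m[["me3"]] && m[["me3"]] > m[["me1"]]
  }, logical(1))
  gMid <- if (any(okG)) mean(range(gs[okG])) else NA_real_

  ## spreading-ratio admissible window
  Rs <- seq(0.55, 1.25, by = 0.1)
  okR <- vapply(seq_along(Rs), function(i) {
    ens <- runEnsemble(prof, modelParams(R = Rs[i]), prot, 10, seed = 2000 + i)
    P <- meanProfiles(ens)
    xo <- crossoverDistance(P["me3", ], P["me2", ], lat)
    valencyCall(ens)$label == "pcg_like" && !is.na(xo) && abs(xo - 5) <= 0.5
  }, logical(1))
  rMid <- if (any(okR)) mean(range(Rs[okR])) else NA_real_

  ## wild-type statics
  ensWT <- runEnsemble(prof, modelParams(), prot, 16, seed = 77)
  P <- meanProfiles(ensWT)
  xo <- crossoverDistance(P["me3", ], P["me2", ], lat)
  labWT <- valencyCall(ensWT)$label
  labAct <- valencyCall(runEnsemble(act, modelParams(), prot, 8, seed = 78))$label
  wtLevel <- mean(regionMeanSeries(ensWT)$P_me3)
  wtNear <- mean(regionMeanSeries(ensWT, 2.5)$P_me3)

  ## washout tempo: no-spreading steady state -> wild type at t = 0
  protW <- washoutProtocol(0, modelParams(), duration = 60,
                           burnInCycles = 12, recordInterval = 0.5)
  ensW <- runEnsemble(prof, modelParams(R = 0), protW, nTraj, seed = 12)
  rs <- regionMeanSeries(ensW)
  t90w <- rs$time[which(rs$P_me3 >= 0.9 * wtLevel)[1]]

  ## profile-switch tempo: active -> PcG at t = 0, near-TSS me3
  protS <- switchProtocol(0, prof, duration = 60, burnInCycles = 12,
                          recordInterval = 0.5)
  ensS <- runEnsemble(act, modelParams(), protS, nTraj, seed = 13)
  rsS <- regionMeanSeries(ensS, 2.5)
  t90s <- rsS$time[which(rsS$P_me3 >= 0.9 * wtNear)[1]]

  cat(sprintf(paste0(
    "c6=[%s]\n  WT=%s xo=%.2f | active=%s | gammaWindowMid=%.2f | ",
    "RWindowMid=%.2f | washout t90=%.2fT | switch t90=%.2fT\n"),
    paste(c6, collapse = ","), labWT, xo, labAct, gMid, rMid,
    t90w / T, t90s / T))
}

candidates <- list(
  c(0.005, 0.30, 2.4, 0.040, 0.40, 2.0), # initial guess: me3 saturates, no crossover
  c(0.005, 0.48, 1.5, 0.100, 0.40, 2.0), # statics all pass, but tempo ~0.8T (too fast)
  c(0.005, 0.20, 1.5, 0.045, 0.17, 2.0), # tempo ok, gamma window centred too low
  c(0.005, 0.22, 1.7, 0.030, 0.12, 2.0)  # shipped: all properties hold
)
for (c6 in candidates) scoreCandidate(c6)
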