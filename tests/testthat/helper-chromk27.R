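## Shared fixture builders for the test suite. Everything is generated in
## code; no stored data.

## a profile with all enzyme densities zero (frozen methylation/acetylation)
zeroProfile <- function(lattice = chromLattice()) {
  n <- nSites(lattice)
  hmeProfile(lattice, rep(0, n), rep(0, n), rep(0, n))
}

## parameters with every rate switched off (overridable)
frozenParams <- function(...) {
  args <- modifyList(list(kMe3 = 0, R = 0, gammaMe = 0, kAc = 0,
                          gammaAc = 0, gammaTurn = 0), list(...))
  do.call(modelParams, args)
}

## per-trajectory time-averaged state indicator means at one site: the
## trajectories are the independent replication unit, so their spread gives
## an honest standard error even for slowly mixing sites
siteStateMeans <- function(ens, site) {
  t(vapply(ens@trajectories, function(tr) {
    s <- tr@states[, site]
    vapply(0:4, function(code) mean(s == code), numeric(1))
  }, numeric(5)))
}

## short steady-state protocol used by qualitative checks
quickSteadyProtocol <- function(sampleCycles = 3, burnInCycles = 10,
                                recordInterval = 1) {
  simulationProtocol(duration = sampleCycles * 13.5,
                     burnInCycles = burnInCycles,
                     recordInterval = recordInterval)
}

## Monte-Carlo standard error of a proportion estimated from an ensemble,
## with a conservative factor-4 penalty on the sample count for the
## autocorrelation of successive samples along a trajectory
mcSE <- function(p, nSamples, autocorrFactor = 4) {
  sqrt(pmax(p * (1 - p), 1e-12) * autocorrFactor / nSamples)
}

## light-budget inference configuration used by the unit tests
testInferenceConfig <- function(...) {
  inferenceConfig(gammaGrid = seq(0.5, 3, by = 0.25),
                  RGrid = seq(0.3, 1.4, by = 0.1),
                  kGrid = seq(0.3, 1.8, by = 0.1),
                  nTraj = 8L, burnInCycles = 8, sampleCycles = 3,
                  maxIter = 5L, seed = 7L, ...)
}
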