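## Multi-step parameter inference: closed-form acetylation fit, then the
## iterative loop fixing gammaMe (methyltransferase-null valency), R
## (wild-type valency + me3/me2 crossover) and kMe3 (absolute me3 profile of
## the demethylase-null condition), scanned over the nucleation-rate ratios.

#' Inference configuration
#'
#' Search grids, tolerances and the simulation budget used by the inference
#' scheme. Defaults: gammaMe scanned over [0, 5] by 0.1, R over [0, 2] by
#' 0.05, kMe3 over (0, 3] by 0.05 (each with one local bisection
#' refinement); relative convergence tolerance 0.05; crossover target
#' 5.0 +/- 0.5 kbp; valency window +/- 2.5 kbp.
#'
#' @param r13,r23 nucleation-rate ratios (positive, r13 >= r23).
#' @param kMe3Init initial nucleation rate (1/h).
#' @param gammaGrid,RGrid,kGrid search grids (strictly increasing, >= 0).
#' @param tolRel relative convergence tolerance.
#' @param maxIter maximum number of outer iterations.
#' @param crossoverTargetKbp,crossoverTolKbp target me3/me2 crossover
#'   distance and tolerance (kbp).
#' @param windowKbp valency window half-width (kbp).
#' @param nTraj,burnInCycles,sampleCycles,recordInterval simulation budget of
#'   each internal steady-state ensemble.
#' @param seed master seed for the internal simulations.
#' @return A list with class \code{"InferenceConfig"}.
#' @export
inferenceConfig <- function(r13 = 3, r23 = 3, kMe3Init = 1.0,
                            gammaGrid = seq(0, 5, by = 0.1),
                            RGrid = seq(0, 2, by = 0.05),
                            kGrid = seq(0.05, 3, by = 0.05),
                            tolRel = 0.05, maxIter = 20L,
                            crossoverTargetKbp = 5.0, crossoverTolKbp = 0.5,
                            windowKbp = 2.5,
                            nTraj = 8L, burnInCycles = 10, sampleCycles = 3,
                            recordInterval = 1, seed = 1L) {
  stopifnot(r13 > 0, r23 > 0, r13 >= r23,
            all(diff(gammaGrid) > 0), all(diff(RGrid) > 0), all(diff(kGrid) > 0),
            all(kGrid > 0), tolRel > 0)
  structure(list(r13 = r13, r23 = r23, kMe3Init = kMe3Init,
                 gammaGrid = gammaGrid, RGrid = RGrid, kGrid = kGrid,
                 tolRel = tolRel, maxIter = as.integer(maxIter),
                 crossoverTargetKbp = crossoverTargetKbp,
                 crossoverTolKbp = crossoverTolKbp, windowKbp = windowKbp,
                 nTraj = as.integer(nTraj), burnInCycles = burnInCycles,
                 sampleCycles = sampleCycles, recordInterval = recordInterval,
                 seed = as.integer(seed)),
            class = "InferenceConfig")
}

#' Observed target profiles for inference
#'
#' Bundles the per-condition observed profiles the inference scheme fits:
#' the acetylation profile of the methyltransferase-null (EZH1/2 DKO)
#' condition, relative methylation profiles of the no-spreading (EZH2 KO)
#' and wild-type conditions, and the absolute (calibrated, probability-scale)
#' me3 profile of the demethylase-null (UTX KD) condition. \code{profile} is
#' the enzyme-occupancy input shared by the simulated conditions, and
#' \code{p300Peak} the Gaussian fit of the wild-type p300 profile used by the
#' acetylation fit.
#'
#' @param dkoAc,utxkdMe3 numeric per-site profiles (utxkdMe3 in [0, 1]).
#' @param ezh2ko,wt lists with numeric elements \code{me1, me2, me3}.
#' @param profile an \linkS4class{HMEProfile}.
#' @param p300Peak a \linkS4class{GaussianPeak}.
#' @return A list with class \code{"TargetData"}.
#' @export
targetData <- function(dkoAc, ezh2ko, wt, utxkdMe3, profile, p300Peak) {
  n <- nSites(profile)
  chk <- function(v, nm) {
    if (length(v) != n || any(!is.finite(v)))
      stop(nm, " must be a finite length-", n, " profile")
  }
  chk(dkoAc, "dkoAc"); chk(utxkdMe3, "utxkdMe3")
  if (any(utxkdMe3 < 0 | utxkdMe3 > 1))
    stop("utxkdMe3 must be on the absolute probability scale (in [0, 1])")
  for (cond in list(ezh2ko = ezh2ko, wt = wt))
    for (m in c("me1", "me2", "me3")) chk(cond[[m]], m)
  structure(list(dkoAc = dkoAc, ezh2ko = ezh2ko, wt = wt,
                 utxkdMe3 = utxkdMe3, profile = profile, p300Peak = p300Peak),
            class = "TargetData")
}

## one internal steady-state ensemble -> 5 x n mean profile matrix
.steadyProfiles <- function(profile, params, cfg, seedOffset) {
  prot <- simulationProtocol(duration = cfg$sampleCycles * params@cellCycle,
                             burnInCycles = cfg$burnInCycles,
                             recordInterval = cfg$recordInterval)
  ens <- runEnsemble(profile, params, prot, nTraj = cfg$nTraj,
                     seed = .subSeed(cfg$seed, seedOffset))
  meanProfiles(ens)
}

.windowMeans <- function(P, windowKbp) {
  sel <- abs(attr(P, "positionsKbp")) <= windowKbp
  rowMeans(P[, sel, drop = FALSE])
}

#' Fit the acetylation rate from the methyltransferase-null condition
#'
#' In the absence of methylation the model is a two-state u/ac system with
#' the closed-form steady state of \code{\link{closedFormAc}}. The p300
#' density of the null condition is modeled as the wild-type Gaussian peak
#' with its background scaled by a correction factor alphaBg < 1; (kAc,
#' alphaBg) minimize the unweighted sum of squared differences between the
#' closed-form prediction and the observed acetylation profile (coarse grid
#' search, then local refinement).
#'
#' @param dkoAc observed acetylation profile on the lattice.
#' @param p300Peak \linkS4class{GaussianPeak} fit of the wild-type p300
#'   profile.
#' @param params a \linkS4class{ModelParams} supplying gammaAc, gammaTurn, T.
#' @param lattice the \linkS4class{ChromLattice}.
#' @return A list with \code{kAc}, \code{backgroundCorrection} and the
#'   residual \code{chi2}.
#' @export
fitAcetylation <- function(dkoAc, p300Peak, params = modelParams(),
                           lattice = chromLattice()) {
  gaussPart <- evaluateGaussianProfile(
    gaussianPeak(0, p300Peak@psiM, p300Peak@i0, p300Peak@sigma0), lattice)
  psiB <- p300Peak@psiB
  pred <- function(kAc, aBg) {
    psi <- gaussPart + aBg * psiB
    num <- kAc * psi
    num / (num + params@gammaAc + params@gammaTurn + log(2) / params@cellCycle)
  }
  obj <- function(par) sum((pred(par[1], par[2]) - dkoAc)^2)
  if (max(dkoAc) - min(dkoAc) < 1e-12)
    warning("flat observed acetylation profile: fit is ill-posed")
  grid <- expand.grid(kAc = seq(0.05, 5, by = 0.05),
                      aBg = seq(0.05, 1, by = 0.05))
  sc <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(sc), ])
  opt <- optim(best, obj, method = "L-BFGS-B",
               lower = c(1e-6, 1e-6), upper = c(20, 1))
  list(kAc = opt$par[1], backgroundCorrection = opt$par[2], chi2 = opt$value)
}

## midpoint of the longest contiguous admissible run: with independent
## Monte-Carlo noise per grid point, isolated spurious (in)admissible points
## near the window edges would otherwise drag range-based midpoints around
.admissibleRun <- function(grid, ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  grid[starts[best]:ends[best]]
}

#' Fit the demethylation rate from the no-spreading condition
#'
#' Simulates the no-spreading (EZH2 KO-like, R = 0) system over a grid of
#' gammaMe values and retains those whose steady state reproduces the
#' qualitative methylation valency observed at the promoter in that
#' condition: mean(me2) > mean(me3) > mean(me1) in the TSS window. Returns
#' the midpoint of the admissible interval.
#'
#' @param targets a \code{\link{targetData}} bundle (its \code{ezh2ko}
#'   profiles are checked for the expected ordering).
#' @param params current \linkS4class{ModelParams} (R is forced to 0).
#' @param cfg an \code{\link{inferenceConfig}}.
#' @return A list with \code{gammaMe}, the admissible \code{interval}, the
#'   admissible \code{values}, and \code{status}.
#' @export
fitGammaMe <- function(targets, params, cfg = inferenceConfig()) {
  pos <- positionsKbp(targets$profile)
  sel <- abs(pos) <= cfg$windowKbp
  obs <- vapply(targets$ezh2ko, function(v) mean(v[sel]), numeric(1))
  if (!(obs[["me2"]] > obs[["me3"]] && obs[["me3"]] > obs[["me1"]]))
    return(list(gammaMe = NA_real_, interval = c(NA_real_, NA_real_),
                values = numeric(0), status = "failed_valency"))
  p0 <- params; p0@R <- 0
  ok <- logical(length(cfg$gammaGrid))
  for (gi in seq_along(cfg$gammaGrid)) {
    p0@gammaMe <- cfg$gammaGrid[gi]
    P <- .steadyProfiles(targets$profile, p0, cfg, 1000L + gi)
    m <- .windowMeans(P, cfg$windowKbp)
    ok[gi] <- m[["me2"]] > m[["me3"]] && m[["me3"]] > m[["me1"]]
  }
  if (!any(ok))
    return(list(gammaMe = NA_real_, interval = c(NA_real_, NA_real_),
                values = numeric(0), status = "failed_valency"))
  adm <- .admissibleRun(cfg$gammaGrid, ok)
  list(gammaMe = (min(adm) + max(adm)) / 2, interval = range(adm),
       values = adm, status = "ok")
}

#' Fit the spreading-to-nucleation ratio from the wild-type condition
#'
#' Simulates the full model over a grid of R values and retains those whose
#' steady state shows (i) the PcG-target-like valency in the TSS window
#' (per \code{\link{classifyValency}}) and (ii) a me3/me2 crossover distance
#' within the configured target (default 5.0 +/- 0.5 kbp from the TSS).
#' Returns the midpoint of the admissible values.
#'
#' @param targets a \code{\link{targetData}} bundle.
#' @param params current \linkS4class{ModelParams} (gammaMe, kMe3 fixed).
#' @param cfg an \code{\link{inferenceConfig}}.
#' @return A list with \code{R}, \code{interval}, \code{values},
#'   \code{status}.
#' @export
fitR <- function(targets, params, cfg = inferenceConfig()) {
  lat <- lattice(targets$profile)
  p0 <- params
  ok <- logical(length(cfg$RGrid))
  for (ri in seq_along(cfg$RGrid)) {
    p0@R <- cfg$RGrid[ri]
    P <- .steadyProfiles(targets$profile, p0, cfg, 2000L + ri)
    m <- .windowMeans(P, cfg$windowKbp)
    lab <- classifyValency(m[["me1"]], m[["me2"]], m[["me3"]])
    if (lab != "pcg_like") next
    ## crossover on lightly smoothed profiles: the raw per-site Monte-Carlo
    ## noise otherwise jitters the crossover point by +/- a few bins
    bp <- lat@bpPerSite
    xo <- crossoverDistance(smoothProfile(P["me3", ], 3 * bp, bp),
                            smoothProfile(P["me2", ], 3 * bp, bp), lat)
    ok[ri] <- !is.na(xo) &&
      abs(xo - cfg$crossoverTargetKbp) <= cfg$crossoverTolKbp
  }
  if (!any(ok))
    return(list(R = NA_real_, interval = c(NA_real_, NA_real_),
                values = numeric(0), status = "failed_valency"))
  adm <- .admissibleRun(cfg$RGrid, ok)
  list(R = (min(adm) + max(adm)) / 2, interval = range(adm), values = adm,
       status = "ok")
}

#' Fit the nucleation rate from the demethylase-null condition
#'
#' The demethylase-null (UTX KD-like) condition is simulated with gammaMe =
#' 0 and the acetylation pathway off (kAc = 0); its me3 profile is on the
#' absolute probability scale and is compared directly to the calibrated
#' observed profile by an unweighted chi-squared score over the lattice.
#' Scans the kMe3 grid and applies one local bisection refinement (half-step
#' evaluations around the grid minimum).
#'
#' @param targets a \code{\link{targetData}} bundle.
#' @param params current \linkS4class{ModelParams} (R, r13, r23 fixed).
#' @param cfg an \code{\link{inferenceConfig}}.
#' @return A list with \code{kMe3}, its \code{chi2}, a \code{boundary} flag
#'   (fit driven to a grid edge), and \code{status}.
#' @export
fitKme3 <- function(targets, params, cfg = inferenceConfig()) {
  p0 <- params; p0@gammaMe <- 0; p0@kAc <- 0
  ## common random numbers across candidate k values: every evaluation uses
  ## the same sub-seed, so the Monte-Carlo noise is strongly correlated
  ## between candidates and largely cancels in the argmin comparison
  chi2 <- function(k) {
    p0@kMe3 <- k
    P <- .steadyProfiles(targets$profile, p0, cfg, 3000L)
    sum((P["me3", ] - targets$utxkdMe3)^2)
  }
  sc <- vapply(cfg$kGrid, chi2, numeric(1))
  bi <- which.min(sc)
  kBest <- cfg$kGrid[bi]; scBest <- sc[bi]
  step <- if (length(cfg$kGrid) > 1) diff(cfg$kGrid)[max(1, bi - 1)] else kBest / 2
  for (kCand in c(kBest - step / 2, kBest + step / 2)) {
    if (kCand <= 0) next
    s <- chi2(kCand)
    if (s < scBest) { kBest <- kCand; scBest <- s }
  }
  list(kMe3 = kBest, chi2 = scBest,
       boundary = bi %in% c(1L, length(cfg$kGrid)), status = "ok")
}

#' Iterative inference of the methylation-related parameters
#'
#' Starting from \code{kMe3Init} and fixed ratios (r13, r23), repeats
#' \code{\link{fitGammaMe}} (no-spreading condition) ->
#' \code{\link{fitR}} (wild type) -> \code{\link{fitKme3}}
#' (demethylase-null condition) until gammaMe, R and kMe3 all change by less
#' than \code{tolRel} relative, or a step fails, or \code{maxIter} is
#' reached. The acetylation parameters are fit once up front from the
#' methyltransferase-null profile.
#'
#' @param targets a \code{\link{targetData}} bundle.
#' @param cfg an \code{\link{inferenceConfig}}.
#' @param baseParams fixed structural parameters (gammaAc, gammaTurn, T,
#'   lambda).
#' @return An \linkS4class{InferenceResult}.
#' @export
iterateInference <- function(targets, cfg = inferenceConfig(),
                             baseParams = modelParams()) {
  acFit <- fitAcetylation(targets$dkoAc, targets$p300Peak, baseParams,
                          lattice(targets$profile))
  par <- baseParams
  par@r13 <- cfg$r13; par@r23 <- cfg$r23
  par@kMe3 <- cfg$kMe3Init
  par@kAc <- acFit$kAc
  prev <- c(gammaMe = NA_real_, R = NA_real_, kMe3 = par@kMe3)
  trace <- list()
  status <- "failed_max_iter"
  score <- NA_real_
  ## goodness score of a converged fit: absolute chi-squared of the
  ## demethylase-null me3 profile plus scale-fitted chi-squared of the
  ## relative me1/me2/me3 profiles of the no-spreading and wild-type
  ## conditions (one free common scale per condition, since normalized
  ## tracks are only proportional to modification probabilities)
  relChi2 <- function(P, obs) {
    sim <- c(P["me1", ], P["me2", ], P["me3", ])
    o <- c(obs$me1, obs$me2, obs$me3)
    sc <- sum(sim * o) / sum(sim * sim)
    sum((sc * sim - o)^2)
  }
  finalScore <- function() {
    ## score-only ensembles use a tripled trajectory budget: the score
    ## compares pairs whose differences are smaller than the scan noise
    cfg3 <- cfg; cfg3$nTraj <- 3L * cfg$nTraj
    pKO <- par; pKO@R <- 0
    pUK <- par; pUK@gammaMe <- 0; pUK@kAc <- 0
    sum((.steadyProfiles(targets$profile, pUK, cfg3, 4002L)["me3", ] -
           targets$utxkdMe3)^2) +
      relChi2(.steadyProfiles(targets$profile, pKO, cfg3, 4000L),
              targets$ezh2ko) +
      relChi2(.steadyProfiles(targets$profile, par, cfg3, 4001L), targets$wt)
  }
  finish <- function(status, score) {
    new("InferenceResult", kAc = acFit$kAc,
        backgroundCorrection = acFit$backgroundCorrection,
        gammaMe = par@gammaMe, R = par@R, kMe3 = par@kMe3,
        r13 = cfg$r13, r23 = cfg$r23, status = status,
        trace = if (length(trace)) do.call(rbind, trace) else
          data.frame(gammaMe = numeric(0), R = numeric(0), kMe3 = numeric(0),
                     chi2 = numeric(0)),
        score = score)
  }
  for (it in seq_len(cfg$maxIter)) {
    g <- fitGammaMe(targets, par, cfg)
    if (g$status != "ok") return(finish("failed_valency", Inf))
    par@gammaMe <- g$gammaMe
    r <- fitR(targets, par, cfg)
    if (r$status != "ok") return(finish("failed_valency", Inf))
    par@R <- r$R
    k <- fitKme3(targets, par, cfg)
    par@kMe3 <- k$kMe3
    score <- k$chi2
    trace[[it]] <- data.frame(gammaMe = par@gammaMe, R = par@R,
                              kMe3 = par@kMe3, chi2 = k$chi2)
    cur <- c(gammaMe = par@gammaMe, R = par@R, kMe3 = par@kMe3)
    if (!any(is.na(prev))) {
      rel <- abs(cur - prev) / pmax(abs(prev), 1e-12)
      if (all(rel < cfg$tolRel) || !is.finite(cfg$tolRel)) {
        status <- "converged"
        break
      }
    }
    if (!is.finite(cfg$tolRel)) { status <- "converged"; break }
    prev <- cur
  }
  if (status == "converged") score <- finalScore()
  finish(status, score)
}

#' Scan the nucleation-rate ratio grid
#'
#' Runs \code{\link{iterateInference}} for each (r13, r23) pair (integers,
#' r13 >= r23) and each initial kMe3 value, and reports which pairs converge
#' and which is best-scoring (lowest chi-squared of the absolute me3 fit,
#' among converged pairs whose runs from different initializations agree).
#'
#' @param targets a \code{\link{targetData}} bundle.
#' @param cfg base \code{\link{inferenceConfig}} (its r13/r23 are overridden
#'   per pair).
#' @param r13Values,r23Values integer grids.
#' @param kMe3Inits initial nucleation-rate values tried per pair.
#' @param baseParams fixed structural parameters.
#' @return A list with \code{results} (one \linkS4class{InferenceResult} per
#'   pair and init), \code{summary} (data.frame with per-pair status and
#'   score), and \code{best} (the best-scoring converged pair, or NULL).
#' @export
ratioGridScan <- function(targets, cfg = inferenceConfig(),
                          r13Values = 1:9, r23Values = 1:9,
                          kMe3Inits = c(0.4, 1.2),
                          baseParams = modelParams()) {
  pairs <- expand.grid(r13 = r13Values, r23 = r23Values)
  pairs <- pairs[pairs$r13 >= pairs$r23, , drop = FALSE]
  results <- list()
  rows <- list()
  for (pi in seq_len(nrow(pairs))) {
    r13 <- pairs$r13[pi]; r23 <- pairs$r23[pi]
    fits <- list()
    for (ii in seq_along(kMe3Inits)) {
      c2 <- cfg
      c2$r13 <- r13; c2$r23 <- r23; c2$kMe3Init <- kMe3Inits[ii]
      c2$seed <- .subSeed(cfg$seed, pi * 100L + ii)
      fits[[ii]] <- iterateInference(targets, c2, baseParams)
      results[[sprintf("r13=%d,r23=%d,init=%g", r13, r23, kMe3Inits[ii])]] <-
        fits[[ii]]
    }
    conv <- vapply(fits, function(f) f@status == "converged", logical(1))
    agree <- TRUE
    if (sum(conv) >= 2) {
      ks <- vapply(fits[conv], function(f) f@kMe3, numeric(1))
      gs <- vapply(fits[conv], function(f) f@gammaMe, numeric(1))
      rs <- vapply(fits[conv], function(f) f@R, numeric(1))
      relSpread <- function(v) (max(v) - min(v)) / max(abs(v), 1e-12)
      agree <- relSpread(ks) < 2 * cfg$tolRel &&
        relSpread(gs) < 2 * cfg$tolRel && relSpread(rs) < 2 * cfg$tolRel
    }
    score <- if (any(conv)) min(vapply(fits[conv], function(f) f@score,
                                       numeric(1))) else Inf
    rows[[pi]] <- data.frame(r13 = r13, r23 = r23,
                             converged = any(conv), initAgreement = agree,
                             score = score)
  }
  summary <- do.call(rbind, rows)
  okRows <- summary$converged & summary$initAgreement & is.finite(summary$score)
  best <- if (any(okRows)) {
    b <- summary[okRows, , drop = FALSE]
    b[which.min(b$score), c("r13", "r23", "score")]
  } else NULL
  list(results = results, summary = summary, best = best)
}

#' Generate synthetic inference targets from known parameters
#'
#' Simulates the four observation conditions of the inference scheme at known
#' ("true") parameter values and perturbs them with independent truncated-
#' Gaussian noise per site, for parameter-recovery testing. The
#' methyltransferase-null acetylation profile is generated from the closed
#' form; the no-spreading and wild-type methylation profiles are simulated
#' and exported on a relative scale (multiplied by \code{relScale}; only
#' their valency is used downstream); the demethylase-null me3 profile is
#' simulated on the absolute probability scale.
#'
#' @param trueParams the generating \linkS4class{ModelParams}.
#' @param profile the shared \linkS4class{HMEProfile} (default: the
#'   PcG-target preset).
#' @param backgroundCorrection the p300 background correction of the
#'   methyltransferase-null condition (default 0.6).
#' @param noiseCV coefficient of variation of the per-site noise (default
#'   0.05).
#' @param relScale arbitrary scale factor of the relative profiles.
#' @param nTraj,burnInCycles,sampleCycles simulation budget per condition.
#' @param seed RNG seed.
#' @return A \code{\link{targetData}} bundle.
#' @export
makeSyntheticTargets <- function(trueParams = modelParams(),
                                 profile = makePresetProfile("pcg_target"),
                                 backgroundCorrection = 0.6,
                                 noiseCV = 0.05, relScale = 0.8,
                                 nTraj = 64L, burnInCycles = 15,
                                 sampleCycles = 5, seed = 1L) {
  lat <- lattice(profile)
  pk <- .presetPeaks()$p300
  p300Peak <- gaussianPeak(pk@psiB, 0.3 * pk@psiM, pk@i0, pk@sigma0)
  cfg <- list(nTraj = as.integer(nTraj), burnInCycles = burnInCycles,
              sampleCycles = sampleCycles, recordInterval = 1, seed = seed)
  noisy <- function(v, upper = Inf) {
    pmin(pmax(v * (1 + noiseCV * rnorm(length(v))), 0), upper)
  }
  set.seed(seed)
  ## methyltransferase-null: closed-form two-state acetylation
  psiDko <- evaluateGaussianProfile(
    gaussianPeak(backgroundCorrection * p300Peak@psiB, p300Peak@psiM,
                 p300Peak@i0, p300Peak@sigma0), lat)
  dkoAc <- noisy(closedFormAc(psiDko, trueParams), upper = 1)
  ## no-spreading condition
  pKO <- trueParams; pKO@R <- 0
  Pko <- .steadyProfiles(profile, pKO, cfg, 11L)
  ezh2ko <- lapply(c(me1 = "me1", me2 = "me2", me3 = "me3"),
                   function(m) noisy(relScale * Pko[m, ]))
  ## wild type
  Pwt <- .steadyProfiles(profile, trueParams, cfg, 12L)
  wt <- lapply(c(me1 = "me1", me2 = "me2", me3 = "me3"),
               function(m) noisy(relScale * Pwt[m, ]))
  ## demethylase-null, acetylation off: absolute me3
  pUK <- trueParams; pUK@gammaMe <- 0; pUK@kAc <- 0
  Puk <- .steadyProfiles(profile, pUK, cfg, 13L)
  utxkdMe3 <- noisy(Puk["me3", ], upper = 1)
  targetData(dkoAc, ezh2ko, wt, utxkdMe3, profile, p300Peak)
}
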