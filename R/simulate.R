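## Driving the compiled Gillespie engine: single trajectories, ensembles,
## replication operator, washout / profile-switch protocols.

.rateVector <- function(params) {
  eps <- epsMe(params)
  c(kMe1(params), kMe2(params), params@kMe3,
    eps[["me1"]], eps[["me2"]], eps[["me3"]],
    params@gammaMe, params@kAc, params@gammaAc, params@gammaTurn)
}

#' Replication dilution operator
#'
#' Applies one replication event to a lattice configuration: each site is
#' independently reset to the unmodified state with probability 1/2 (the
#' random partition of parental histones between sister chromatids); reset
#' sites are relabeled as new. Uses the R random number stream, so results
#' are reproducible under \code{set.seed}.
#'
#' @param config integer vector of per-site states.
#' @param pools optional integer vector of pool labels (0 old / 1 new).
#' @param prob loss probability per site (1/2 for symmetric replication).
#' @return A list with \code{config}, \code{pools} and the logical reset
#'   \code{mask}.
#' @export
replicateConfig <- function(config, pools = NULL, prob = 0.5) {
  n <- length(config)
  mask <- runif(n) < prob
  config[mask] <- .STATE_U
  if (!is.null(pools)) pools[mask] <- 1L
  list(config = config, pools = pools, mask = mask)
}

## Deterministic sub-seed rule: trajectory j of a run with master seed s gets
## sub-seed (s * 1000003 + j * 7919) mod 2147483647, independent of execution
## order.
.subSeed <- function(seed, j) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(j) * 7919) %% 2147483647)
}

#' Simulate one stochastic trajectory
#'
#' Runs the exact continuous-time simulation of the lattice model under a
#' protocol: burn-in of \code{burnInCycles} cell cycles starting from a fully
#' unmodified lattice, then \code{duration} hours of protocol time with any
#' scheduled parameter/profile change events applied at their exact times.
#' Replication events occur every T hours at the trajectory's phase;
#' propensities are recomputed after every state change (the spreading sum
#' depends on the global set of trimethylated sites).
#'
#' @param profile an \linkS4class{HMEProfile} (initial profile).
#' @param params a \linkS4class{ModelParams} (initial parameters).
#' @param protocol a \linkS4class{SimulationProtocol}.
#' @param seed integer seed for this trajectory (set before simulation);
#'   \code{NULL} uses the current RNG state.
#' @param phase replication phase in [0, T); default 0 if synchronized, else
#'   drawn uniformly.
#' @param initConfig initial per-site states (default all unmodified).
#' @return A \linkS4class{Trajectory}; samples at exactly a scheduled event
#'   time show the pre-event state.
#' @export
simulateTrajectory <- function(profile, params, protocol = simulationProtocol(),
                               seed = NULL, phase = NULL, initConfig = NULL) {
  stopifnot(is(profile, "HMEProfile"), is(params, "ModelParams"),
            is(protocol, "SimulationProtocol"))
  if (!is.null(seed)) set.seed(seed)
  n <- nSites(profile)
  T <- params@cellCycle
  burnIn <- protocol@burnInCycles * T
  total <- burnIn + protocol@duration
  if (is.null(phase))
    phase <- if (protocol@synchronized) 0 else runif(1, 0, T)
  if (is.null(initConfig)) initConfig <- rep(.STATE_U, n)

  ## absolute schedule
  repTimes <- seq(phase, total + T, by = T)
  repTimes <- repTimes[repTimes > 0 & repTimes <= total]
  recTimes <- burnIn + seq(protocol@recordFrom, protocol@duration,
                           by = protocol@recordInterval)
  recTimes <- recTimes[recTimes >= 0 & recTimes <= total]
  labelEpoch <- burnIn + protocol@labelEpoch

  ## epochs bounded by protocol events
  evTimes <- vapply(protocol@events, function(e) burnIn + e$time, numeric(1))
  bounds <- c(0, evTimes, total)
  curParams <- params; curProfile <- profile
  kernel <- contactKernel(lattice(profile), params@lambdaExp)

  state <- as.integer(initConfig)
  pool <- rep(0L, n)
  incorp <- rep(NA_real_, n)
  recS <- matrix(NA_integer_, length(recTimes), n)
  recP <- matrix(NA_integer_, length(recTimes), n)

  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    if (k > 1L) { # apply event k-1 at its exact time
      ev <- protocol@events[[k - 1L]]
      if (!is.null(ev$params)) {
        if (ev$params@lambdaExp != curParams@lambdaExp)
          kernel <- contactKernel(lattice(curProfile), ev$params@lambdaExp)
        curParams <- ev$params
      }
      if (!is.null(ev$profile)) curProfile <- ev$profile
    }
    if (t1 <= t0) next
    selRec <- which(recTimes > t0 & recTimes <= t1)
    if (k == 1L) selRec <- which(recTimes >= t0 & recTimes <= t1)
    selRep <- repTimes[repTimes > t0 & repTimes <= t1]
    res <- .gillespie_epoch(state, pool, incorp,
                            psiSuz12(curProfile), psiP300(curProfile),
                            psiUtx(curProfile), kernel,
                            .rateVector(curParams), t0, t1,
                            selRep, recTimes[selRec], labelEpoch)
    if (length(selRec)) {
      recS[selRec, ] <- res$states
      recP[selRec, ] <- res$pools
    }
    state <- res$finalState; pool <- res$finalPool; incorp <- res$incorporation
  }

  new("Trajectory", times = recTimes - burnIn, states = recS, pools = recP,
      phase = phase, incorporation = incorp - burnIn)
}

#' Simulate an ensemble of independent trajectories
#'
#' Trajectories share the protocol, profile and parameters; each gets a
#' deterministic sub-seed derived from the master seed (so ensembles are
#' reproducible independent of execution order) and, if unsynchronized, its
#' own uniform replication phase.
#'
#' @param profile,params,protocol as in \code{\link{simulateTrajectory}}.
#' @param nTraj number of trajectories (>= 1).
#' @param seed master seed.
#' @return An \linkS4class{Ensemble}.
#' @export
#' @examples
#' prot <- simulationProtocol(duration = 10, burnInCycles = 1)
#' ens <- runEnsemble(makePresetProfile("pcg_target"), modelParams(),
#'                    prot, nTraj = 2, seed = 1)
runEnsemble <- function(profile, params, protocol = simulationProtocol(),
                        nTraj = 32L, seed = 1L) {
  stopifnot(nTraj >= 1)
  trajs <- vector("list", nTraj)
  for (j in seq_len(nTraj)) {
    trajs[[j]] <- simulateTrajectory(profile, params, protocol,
                                     seed = .subSeed(seed, j))
  }
  new("Ensemble", trajectories = trajs, protocol = protocol,
      profile = profile, params = params, seed = as.integer(seed))
}

#' Inhibitor-washout protocol
#'
#' Builds the protocol for an enzymatic-inhibition washout experiment: the
#' population is evolved to steady state under one parameter set (by default
#' an EZH2-inhibited state, spreading ratio R = 0), then at protocol time
#' \code{t0} the parameters switch (washout) and mark dynamics are tracked in
#' all histones and in the pool of histones incorporated after \code{t0}.
#'
#' @param t0 protocol time of the switch (>= 0; the burn-in ends at 0).
#' @param paramsAfter \linkS4class{ModelParams} applied from \code{t0} on.
#' @param duration,burnInCycles,recordInterval,recordFrom see
#'   \code{\link{simulationProtocol}}.
#' @return A \linkS4class{SimulationProtocol} (unsynchronized) whose pool
#'   label epoch is \code{t0}. Simulate it with the pre-washout parameters,
#'   e.g. \code{runEnsemble(profile, modelParams(R = 0), protocol, ...)}.
#' @export
washoutProtocol <- function(t0 = 0, paramsAfter = modelParams(),
                            duration = 100, burnInCycles = 25,
                            recordInterval = 0.5, recordFrom = 0) {
  if (t0 < 0) stop("t0 must be >= 0 (the burn-in ends at protocol time 0)")
  simulationProtocol(duration = duration, burnInCycles = burnInCycles,
                     synchronized = FALSE,
                     events = list(list(time = t0, params = paramsAfter)),
                     recordInterval = recordInterval, recordFrom = recordFrom,
                     labelEpoch = t0)
}

#' Enzyme-profile switch protocol
#'
#' As \code{\link{washoutProtocol}} but replacing the enzyme occupancy
#' profile at \code{t0} (e.g. an active-gene to Polycomb-target-gene
#' recruitment switch) while the kinetic parameters stay fixed.
#'
#' @param t0 protocol time of the switch (>= 0).
#' @param profileAfter \linkS4class{HMEProfile} applied from \code{t0} on.
#' @param duration,burnInCycles,recordInterval,recordFrom see
#'   \code{\link{simulationProtocol}}.
#' @return A \linkS4class{SimulationProtocol}; simulate it with the
#'   pre-switch profile.
#' @export
switchProtocol <- function(t0 = 0, profileAfter,
                           duration = 100, burnInCycles = 25,
                           recordInterval = 0.5, recordFrom = 0) {
  if (t0 < 0) stop("t0 must be >= 0 (the burn-in ends at protocol time 0)")
  simulationProtocol(duration = duration, burnInCycles = burnInCycles,
                     synchronized = FALSE,
                     events = list(list(time = t0, profile = profileAfter)),
                     recordInterval = recordInterval, recordFrom = recordFrom,
                     labelEpoch = t0)
}
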