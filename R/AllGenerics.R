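#' @rdname ChromLattice-class
#' @param object,x a package object.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname ChromLattice-class
#' @export
setGeneric("positionsKbp", function(x) standardGeneric("positionsKbp"))

#' @rdname HMEProfile-class
#' @export
setGeneric("psiSuz12", function(x) standardGeneric("psiSuz12"))
#' @rdname HMEProfile-class
#' @export
setGeneric("psiP300", function(x) standardGeneric("psiP300"))
#' @rdname HMEProfile-class
#' @export
setGeneric("psiUtx", function(x) standardGeneric("psiUtx"))
#' @rdname HMEProfile-class
#' @export
setGeneric("lattice", function(x) standardGeneric("lattice"))

#' @rdname ModelParams-class
#' @export
setGeneric("kMe1", function(x) standardGeneric("kMe1"))
#' @rdname ModelParams-class
#' @export
setGeneric("kMe2", function(x) standardGeneric("kMe2"))
#' @rdname ModelParams-class
#' @export
setGeneric("epsMe", function(x) standardGeneric("epsMe"))

#' @rdname Ensemble-class
#' @export
setGeneric("nTrajectories", function(x) standardGeneric("nTrajectories"))

setMethod("nSites", "ChromLattice", function(x) x@nSites)
setMethod("nSites", "HMEProfile", function(x) x@lattice@nSites)

setMethod("positionsKbp", "ChromLattice", function(x)
  (seq_len(x@nSites) - x@tssIndex) * x@bpPerSite / 1000)
setMethod("positionsKbp", "HMEProfile", function(x) positionsKbp(x@lattice))

setMethod("lattice", "HMEProfile", function(x) x@lattice)
setMethod("psiSuz12", "HMEProfile", function(x) x@psiSuz12)
setMethod("psiP300", "HMEProfile", function(x) x@psiP300)
setMethod("psiUtx", "HMEProfile", function(x) x@psiUtx)

## derived rates: kMe1 = r13 * kMe3, kMe2 = r23 * kMe3; spreading rates are
## R * kMex for every level x (level-independent ratio R).
setMethod("kMe1", "ModelParams", function(x) x@r13 * x@kMe3)
setMethod("kMe2", "ModelParams", function(x) x@r23 * x@kMe3)
setMethod("epsMe", "ModelParams", function(x)
  c(me1 = x@R * x@r13 * x@kMe3, me2 = x@R * x@r23 * x@kMe3, me3 = x@R * x@kMe3))

setMethod("nTrajectories", "Ensemble", function(x) length(x@trajectories))

setMethod("show", "ChromLattice", function(object) {
  pos <- positionsKbp(object)
  cat(sprintf("ChromLattice: %d H3 tails, %d bp/site, window [%.1f, %.1f] kbp (TSS at site %d)\n",
              object@nSites, object@bpPerSite, min(pos), max(pos), object@tssIndex))
})

setMethod("show", "GaussianPeak", function(object) {
  cat(sprintf("GaussianPeak: psiB=%.4g psiM=%.4g i0=%.4g kbp sigma0=%.4g kbp\n",
              object@psiB, object@psiM, object@i0, object@sigma0))
})

setMethod("show", "HMEProfile", function(object) {
  cat("HMEProfile on ", object@lattice@nSites, " sites\n", sep = "")
  for (nm in c("psiSuz12", "psiP300", "psiUtx")) {
    v <- slot(object, nm)
    cat(sprintf("  %-9s range [%.4g, %.4g], TSS value %.4g\n", nm,
                min(v), max(v), v[object@lattice@tssIndex]))
  }
})

setMethod("show", "ModelParams", function(object) {
  e <- epsMe(object)
  cat("ModelParams (rates in 1/h):\n")
  cat(sprintf("  kMe1=%.3g kMe2=%.3g kMe3=%.3g (r13=%g, r23=%g)\n",
              kMe1(object), kMe2(object), object@kMe3, object@r13, object@r23))
  cat(sprintf("  R=%.3g (epsMe1=%.3g epsMe2=%.3g epsMe3=%.3g)\n",
              object@R, e[["me1"]], e[["me2"]], e[["me3"]]))
  cat(sprintf("  gammaMe=%.3g kAc=%.3g gammaAc=%.3g gammaTurn=%.3g\n",
              object@gammaMe, object@kAc, object@gammaAc, object@gammaTurn))
  cat(sprintf("  cell cycle T=%.3g h, kernel exponent lambda=%g\n",
              object@cellCycle, object@lambdaExp))
})

setMethod("show", "SimulationProtocol", function(object) {
  cat(sprintf("SimulationProtocol: burn-in %g cycles, duration %g h, %s, dt=%g h, %d event(s)\n",
              object@burnInCycles, object@duration,
              if (object@synchronized) "synchronized" else "unsynchronized",
              object@recordInterval, length(object@events)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d samples x %d sites, t in [%.2f, %.2f] h, phase %.3f h\n",
              nrow(object@states), ncol(object@states),
              min(object@times), max(object@times), object@phase))
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble of %d trajectories (seed %d)\n",
              length(object@trajectories), object@seed))
  show(object@protocol)
})

setMethod("show", "InferenceResult", function(object) {
  cat(sprintf("InferenceResult [%s] (r13=%g, r23=%g)\n",
              object@status, object@r13, object@r23))
  cat(sprintf("  kAc=%.3g bgCorrection=%.3g gammaMe=%.3g R=%.3g kMe3=%.3g score=%.4g\n",
              object@kAc, object@backgroundCorrection, object@gammaMe,
              object@R, object@kMe3, object@score))
  if (nrow(object@trace)) cat("  iterations:", nrow(object@trace), "\n")
})
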