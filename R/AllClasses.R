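#' @import methods
#' @importFrom stats aggregate cor optim optimize quantile runif rnorm setNames
#' @importFrom utils modifyList read.table write.table packageVersion
#' @useDynLib chromK27, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The five H3K27 states
#'
#' Each histone tail carries exactly one of five mutually exclusive H3K27
#' states: unmodified (\code{u}), acetylated (\code{ac}), or mono-, di- or
#' tri-methylated (\code{me1}, \code{me2}, \code{me3}). The methylation ladder
#' is strictly sequential (u <-> me1 <-> me2 <-> me3, one methyl group at a
#' time) and acetylation is only reachable from, and only returns to, the
#' unmodified state.
#'
#' Internally states are encoded as integers 0:4 in the order returned here.
#'
#' @return Character vector of the five state names, in internal encoding order.
#' @export
#' @examples
#' h3k27States()
h3k27States <- function() c("u", "ac", "me1", "me2", "me3")

## internal integer codes
.STATE_U <- 0L; .STATE_AC <- 1L; .STATE_ME1 <- 2L; .STATE_ME2 <- 3L; .STATE_ME3 <- 4L

#' ChromLattice: the histone lattice around a TSS
#'
#' A 1D array of H3 tails covering a genomic window centred on a transcription
#' start site. Two consecutive sites are the two independent H3 tails of one
#' nucleosome; with the defaults (200 sites, 100 bp per site) the lattice
#' spans [-10, +10) kbp around the TSS.
#'
#' @slot nSites integer, number of H3 tails (even, >= 2).
#' @slot bpPerSite integer, genomic footprint of one tail in bp.
#' @slot tssIndex integer, 1-based index of the site at the TSS.
#' @export
setClass("ChromLattice",
  representation(nSites = "integer", bpPerSite = "integer", tssIndex = "integer"),
  validity = function(object) {
    if (length(object@nSites) != 1L || object@nSites < 2L)
      return("nSites must be a single integer >= 2")
    if (object@nSites %% 2L != 0L)
      return("nSites must be even (two H3 tails per nucleosome)")
    if (object@bpPerSite < 1L) return("bpPerSite must be positive")
    if (object@tssIndex < 1L || object@tssIndex > object@nSites)
      return("tssIndex out of range")
    TRUE
  })

#' Construct a histone lattice
#'
#' @param nSites number of H3 tails (default 200, i.e. 100 nucleosomes).
#' @param bpPerSite bp covered by one tail (default 100).
#' @param tssIndex 1-based index of the TSS site; default \code{nSites/2 + 1}
#'   places position 0 so that the window spans [-10, +10) kbp at defaults.
#' @return A \linkS4class{ChromLattice}.
#' @export
#' @examples
#' lat <- chromLattice()
#' range(positionsKbp(lat))
chromLattice <- function(nSites = 200L, bpPerSite = 100L,
                         tssIndex = as.integer(nSites / 2L) + 1L) {
  new("ChromLattice", nSites = as.integer(nSites),
      bpPerSite = as.integer(bpPerSite), tssIndex = as.integer(tssIndex))
}

#' GaussianPeak: a Gaussian-plus-background occupancy peak
#'
#' Parametric form of an average enzyme binding profile around the TSS:
#' \deqn{\psi(x) = \psi_m \exp(-(x - i_0)^2 / (2\sigma_0^2)) + \psi_b}
#' with \eqn{x} the genomic position in kbp relative to the TSS.
#'
#' @slot psiB background (non-specific) occupancy, dimensionless, >= 0.
#' @slot psiM peak height above background, dimensionless, >= 0.
#' @slot i0 peak centre, kbp relative to TSS.
#' @slot sigma0 peak width, kbp, > 0.
#' @export
setClass("GaussianPeak",
  representation(psiB = "numeric", psiM = "numeric", i0 = "numeric", sigma0 = "numeric"),
  validity = function(object) {
    if (object@psiB < 0) return("psiB must be >= 0")
    if (object@psiM < 0) return("psiM must be >= 0")
    if (object@sigma0 <= 0) return("sigma0 must be > 0")
    TRUE
  })

#' @rdname GaussianPeak-class
#' @param psiB,psiM,i0,sigma0 see slot documentation.
#' @return A \linkS4class{GaussianPeak}.
#' @export
gaussianPeak <- function(psiB, psiM, i0, sigma0) {
  new("GaussianPeak", psiB = as.numeric(psiB), psiM = as.numeric(psiM),
      i0 = as.numeric(i0), sigma0 = as.numeric(sigma0))
}

#' HMEProfile: per-site histone-modifying-enzyme occupancy densities
#'
#' Normalized occupancy densities of the three enzymes driving H3K27 dynamics,
#' sampled on the histone lattice: SUZ12 (a proxy for bound PRC2, the
#' methyltransferase complex), p300 (acetyltransferase) and UTX (demethylase).
#'
#' @slot lattice a \linkS4class{ChromLattice}.
#' @slot psiSuz12,psiP300,psiUtx numeric vectors of length \code{nSites},
#'   all entries >= 0.
#' @export
setClass("HMEProfile",
  representation(lattice = "ChromLattice", psiSuz12 = "numeric",
                 psiP300 = "numeric", psiUtx = "numeric"),
  validity = function(object) {
    n <- object@lattice@nSites
    for (nm in c("psiSuz12", "psiP300", "psiUtx")) {
      v <- slot(object, nm)
      if (length(v) != n) return(sprintf("%s must have length nSites (%d)", nm, n))
      if (any(!is.finite(v))) return(sprintf("%s has non-finite entries", nm))
      if (any(v < 0)) return(sprintf("%s has negative entries", nm))
    }
    TRUE
  })

#' @rdname HMEProfile-class
#' @param lattice a \linkS4class{ChromLattice}.
#' @param psiSuz12,psiP300,psiUtx per-site densities (length \code{nSites}).
#' @return An \linkS4class{HMEProfile}.
#' @export
hmeProfile <- function(lattice, psiSuz12, psiP300, psiUtx) {
  new("HMEProfile", lattice = lattice, psiSuz12 = as.numeric(psiSuz12),
      psiP300 = as.numeric(psiP300), psiUtx = as.numeric(psiUtx))
}

#' ModelParams: kinetic parameters of the H3K27 model
#'
#' All rates are in 1/h. Methylation nucleation rates are parameterized by the
#' me2->me3 rate \code{kMe3} and the dimensionless ratios \code{r13} (=
#' kMe1/kMe3) and \code{r23} (= kMe2/kMe3); allosteric spreading rates are
#' \code{R * kMex} for every level x, i.e. the spreading-to-nucleation ratio
#' R is independent of the methylation level.
#'
#' Defaults are the wild-type mESC best-fit values: kMe3 = 0.81/h, r13 = r23 =
#' 3, R = 0.85, gammaMe = 1.5/h, kAc = 1.03/h, gammaAc = 0.6/h, gammaTurn =
#' 0.03/h, cell cycle T = 13.5 h, contact-kernel exponent lambda = 1.
#'
#' @slot kMe3 nucleation rate me2 -> me3 (1/h).
#' @slot r13,r23 dimensionless ratios kMe1/kMe3 and kMe2/kMe3.
#' @slot R spreading-to-nucleation ratio (dimensionless).
#' @slot gammaMe UTX-mediated demethylation rate coefficient (1/h).
#' @slot kAc p300-mediated acetylation rate coefficient (1/h).
#' @slot gammaAc deacetylation rate (1/h).
#' @slot gammaTurn histone turnover rate (1/h).
#' @slot cellCycle cell-cycle length T (h).
#' @slot lambdaExp exponent of the power-law contact kernel.
#' @export
setClass("ModelParams",
  representation(kMe3 = "numeric", r13 = "numeric", r23 = "numeric", R = "numeric",
                 gammaMe = "numeric", kAc = "numeric", gammaAc = "numeric",
                 gammaTurn = "numeric", cellCycle = "numeric", lambdaExp = "numeric"),
  validity = function(object) {
    for (nm in c("kMe3", "r13", "r23", "R", "gammaMe", "kAc", "gammaAc", "gammaTurn")) {
      v <- slot(object, nm)
      if (length(v) != 1L || !is.finite(v) || v < 0)
        return(sprintf("%s must be a single finite value >= 0", nm))
    }
    if (object@cellCycle <= 0) return("cellCycle must be > 0")
    if (object@lambdaExp <= 0) return("lambdaExp must be > 0")
    TRUE
  })

#' @rdname ModelParams-class
#' @param kMe3,r13,r23,R,gammaMe,kAc,gammaAc,gammaTurn,cellCycle,lambdaExp see
#'   slot documentation; defaults are the wild-type best-fit values.
#' @return A \linkS4class{ModelParams}.
#' @export
#' @examples
#' p <- modelParams()
#' kMe1(p)  # = r13 * kMe3
modelParams <- function(kMe3 = 0.81, r13 = 3, r23 = 3, R = 0.85,
                        gammaMe = 1.5, kAc = 1.03, gammaAc = 0.6,
                        gammaTurn = 0.03, cellCycle = 13.5, lambdaExp = 1) {
  new("ModelParams", kMe3 = kMe3, r13 = r13, r23 = r23, R = R,
      gammaMe = gammaMe, kAc = kAc, gammaAc = gammaAc, gammaTurn = gammaTurn,
      cellCycle = cellCycle, lambdaExp = lambdaExp)
}

#' SimulationProtocol: timing and scheduling of a simulation run
#'
#' Protocol time t = 0 is the end of the burn-in; the burn-in itself covers
#' \code{burnInCycles} cell cycles before t = 0. \code{events} is a list of
#' parameter/profile changes applied at given protocol times (strictly
#' increasing), each a list with elements \code{time} and at least one of
#' \code{params}, \code{profile}.
#'
#' @slot duration simulated time after t = 0 (h).
#' @slot burnInCycles number of cell cycles of burn-in before t = 0.
#' @slot synchronized logical; TRUE = common replication phase 0 (a replication
#'   occurs exactly at every multiple of T, including t = 0), FALSE = one
#'   uniform random phase per trajectory.
#' @slot events list of scheduled changes (possibly empty).
#' @slot recordInterval sampling interval of the state (h).
#' @slot recordFrom first recorded protocol time (may be negative to record
#'   during burn-in).
#' @slot labelEpoch protocol time from which histone replacement (turnover or
#'   replication loss) flips a site's pool label from old to new.
#' @export
setClass("SimulationProtocol",
  representation(duration = "numeric", burnInCycles = "numeric",
                 synchronized = "logical", events = "list",
                 recordInterval = "numeric", recordFrom = "numeric",
                 labelEpoch = "numeric"),
  validity = function(object) {
    if (object@duration < 0) return("duration must be >= 0")
    if (object@burnInCycles < 0) return("burnInCycles must be >= 0")
    if (object@recordInterval <= 0) return("recordInterval must be > 0")
    if (length(object@events)) {
      tms <- vapply(object@events, function(e) e$time, numeric(1))
      if (any(diff(tms) <= 0)) return("event times must be strictly increasing")
      ok <- vapply(object@events, function(e)
        is.list(e) && !is.null(e$time) && (!is.null(e$params) || !is.null(e$profile)),
        logical(1))
      if (!all(ok)) return("each event needs $time and $params and/or $profile")
    }
    TRUE
  })

#' @rdname SimulationProtocol-class
#' @param duration,burnInCycles,synchronized,events,recordInterval,recordFrom,labelEpoch
#'   see slot documentation.
#' @return A \linkS4class{SimulationProtocol}.
#' @export
simulationProtocol <- function(duration = 100, burnInCycles = 25,
                               synchronized = FALSE, events = list(),
                               recordInterval = 0.5, recordFrom = 0,
                               labelEpoch = 0) {
  new("SimulationProtocol", duration = duration, burnInCycles = burnInCycles,
      synchronized = synchronized, events = events,
      recordInterval = recordInterval, recordFrom = recordFrom,
      labelEpoch = labelEpoch)
}

#' Trajectory: one sampled stochastic trajectory
#'
#' States and pool labels sampled on the protocol's recording grid. Rows of
#' \code{states}/\code{pools} correspond to \code{times} (protocol time, h),
#' columns to lattice sites. States use the integer encoding of
#' \code{\link{h3k27States}} (0 = u ... 4 = me3); pools are 0 (old: present
#' since the label epoch) or 1 (new: incorporated after it).
#'
#' @slot times numeric vector of sample times (protocol time, h).
#' @slot states integer matrix, samples x sites.
#' @slot pools integer matrix, samples x sites.
#' @slot phase replication phase of this trajectory in [0, T).
#' @slot incorporation numeric vector: last incorporation (replacement) time of
#'   each site, NA_real_ if never replaced after the label epoch.
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix", pools = "matrix",
                 phase = "numeric", incorporation = "numeric"),
  validity = function(object) {
    if (nrow(object@states) != length(object@times)) return("states/times mismatch")
    if (!identical(dim(object@states), dim(object@pools)))
      return("states/pools dimension mismatch")
    TRUE
  })

#' Ensemble: a population of independent trajectories
#'
#' @slot trajectories list of \linkS4class{Trajectory}.
#' @slot protocol the shared \linkS4class{SimulationProtocol}.
#' @slot profile the (initial) \linkS4class{HMEProfile}.
#' @slot params the (initial) \linkS4class{ModelParams}.
#' @slot seed master seed of the run.
#' @export
setClass("Ensemble",
  representation(trajectories = "list", protocol = "SimulationProtocol",
                 profile = "HMEProfile", params = "ModelParams", seed = "integer"))

#' InferenceResult: outcome of the iterative parameter-inference scheme
#'
#' @slot kAc fitted acetylation rate (1/h).
#' @slot backgroundCorrection fitted p300 background correction factor for the
#'   methyltransferase-null condition (dimensionless, in (0, 1]).
#' @slot gammaMe,R,kMe3 fitted methylation-related parameters.
#' @slot r13,r23 the (fixed) nucleation-rate ratios used.
#' @slot status one of "converged", "failed_valency", "failed_max_iter".
#' @slot trace data.frame with one row per iteration (gammaMe, R, kMe3, chi2).
#' @slot score goodness score of the converged fit: chi-squared of the
#'   absolute demethylase-null me3 profile plus scale-fitted chi-squared of
#'   the relative methylation profiles of the no-spreading and wild-type
#'   conditions.
#' @export
setClass("InferenceResult",
  representation(kAc = "numeric", backgroundCorrection = "numeric",
                 gammaMe = "numeric", R = "numeric", kMe3 = "numeric",
                 r13 = "numeric", r23 = "numeric", status = "character",
                 trace = "data.frame", score = "numeric"))
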