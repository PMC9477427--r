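## Steady-state observables: mark profiles, valency calls, crossover distance,
## correlation maps, recruitment phase diagram.

.trajWindow <- function(traj, from, to) {
  sel <- traj@times >= from & traj@times <= to
  if (!any(sel)) stop("no recorded samples in the requested time window")
  sel
}

#' Mean mark profiles of an ensemble
#'
#' Per-site probability of each H3K27 state, averaged over trajectories and
#' over recorded samples in a protocol-time window (the steady-state profile
#' of an asynchronous population when the window covers the post-burn-in
#' record).
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param from,to protocol-time window over which to average (h).
#' @return A \code{5 x nSites} matrix of probabilities (rows named as
#'   \code{\link{h3k27States}}, columns summing to 1), with the per-site kbp
#'   positions in attribute \code{"positionsKbp"}.
#' @export
meanProfiles <- function(ensemble, from = 0, to = Inf) {
  n <- nSites(ensemble@profile)
  counts <- matrix(0, 5, n)
  total <- 0
  for (traj in ensemble@trajectories) {
    sel <- .trajWindow(traj, from, to)
    m <- traj@states[sel, , drop = FALSE]
    for (s in 0:4) counts[s + 1L, ] <- counts[s + 1L, ] + colSums(m == s)
    total <- total + sum(sel)
  }
  P <- counts / total
  rownames(P) <- h3k27States()
  attr(P, "positionsKbp") <- positionsKbp(ensemble@profile)
  P
}

#' Region-averaged state proportions over time
#'
#' Ensemble-mean fraction of sites in each state within a window around the
#' TSS, at every recorded time.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param windowKbp half-width of the TSS window in kbp (Inf = whole lattice).
#' @return A data.frame with \code{time} and one probability column per state.
#' @export
regionMeanSeries <- function(ensemble, windowKbp = Inf) {
  pos <- positionsKbp(ensemble@profile)
  sites <- which(abs(pos) <= windowKbp)
  times <- ensemble@trajectories[[1L]]@times
  acc <- matrix(0, length(times), 5)
  for (traj in ensemble@trajectories) {
    m <- traj@states[, sites, drop = FALSE]
    for (s in 0:4) acc[, s + 1L] <- acc[, s + 1L] + rowSums(m == s)
  }
  P <- acc / (length(ensemble@trajectories) * length(sites))
  out <- data.frame(time = times, P)
  names(out) <- c("time", paste0("P_", h3k27States()))
  out
}

#' Classify methylation valency
#'
#' Applies the threshold rules defining gene-class-like methylation
#' valencies from window-averaged mark proportions: PcG-target-like requires
#' mean(me2) > mean(me1) and mean(me3) > 1.5 mean(me2); active-like requires
#' mean(me1) > mean(me2) and mean(me2) > 1.5 mean(me3); everything else is
#' intermediate (which includes bivalent-like valencies).
#'
#' @param pMe1,pMe2,pMe3 window-averaged methylation proportions, in [0, 1].
#' @return One of \code{"pcg_like"}, \code{"active_like"},
#'   \code{"intermediate"}.
#' @export
#' @examples
#' classifyValency(0.10, 0.20, 0.35)  # pcg_like
classifyValency <- function(pMe1, pMe2, pMe3) {
  stopifnot(pMe1 >= 0, pMe1 <= 1, pMe2 >= 0, pMe2 <= 1, pMe3 >= 0, pMe3 <= 1)
  if (pMe2 > pMe1 && pMe3 > 1.5 * pMe2) "pcg_like"
  else if (pMe1 > pMe2 && pMe2 > 1.5 * pMe3) "active_like"
  else "intermediate"
}

#' Valency call of an ensemble around the TSS
#'
#' @param ensemble an \linkS4class{Ensemble} (or a profile matrix as returned
#'   by \code{\link{meanProfiles}}).
#' @param windowKbp half-width of the TSS window (default 2.5 kbp).
#' @param from,to averaging window in protocol time, passed to
#'   \code{\link{meanProfiles}}.
#' @return A list with \code{label} and the window-averaged proportions
#'   \code{means} (named by state).
#' @export
valencyCall <- function(ensemble, windowKbp = 2.5, from = 0, to = Inf) {
  P <- if (is.matrix(ensemble)) ensemble else meanProfiles(ensemble, from, to)
  pos <- attr(P, "positionsKbp")
  sel <- abs(pos) <= windowKbp
  means <- rowMeans(P[, sel, drop = FALSE])
  list(label = classifyValency(means[["me1"]], means[["me2"]], means[["me3"]]),
       means = means)
}

#' Distance from the TSS at which me2 overtakes me3
#'
#' Scans outward from the TSS independently on each side for the smallest
#' distance at which P(me2) > P(me3) and remains so for at least
#' \code{persist} consecutive sites (guarding against single-bin noise
#' flips), and returns the mean of the two side distances. Returns \code{NA}
#' if neither side has a crossover; if only one side has one, that side's
#' distance is returned.
#'
#' @param pMe3,pMe2 per-site probabilities on the lattice.
#' @param lattice the \linkS4class{ChromLattice}.
#' @param persist number of consecutive sites required (default 3).
#' @return Crossover distance in kbp, or \code{NA_real_}.
#' @export
crossoverDistance <- function(pMe3, pMe2, lattice = chromLattice(), persist = 3L) {
  n <- nSites(lattice); tss <- lattice@tssIndex
  pos <- positionsKbp(lattice)
  sideCross <- function(idx) { # idx: site indices ordered outward from TSS
    ok <- pMe2[idx] > pMe3[idx]
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hit <- which(runs$values & runs$lengths >= persist)
    ## a crossover run reaching the lattice edge counts even if shorter
    lastRun <- length(runs$values)
    if (runs$values[lastRun] && !(lastRun %in% hit)) hit <- c(hit, lastRun)
    if (!length(hit)) return(NA_real_)
    abs(pos[idx[starts[min(hit)]]])
  }
  right <- sideCross(tss:n)
  left <- sideCross(tss:1)
  both <- c(left, right)
  if (all(is.na(both))) return(NA_real_)
  mean(both, na.rm = TRUE)
}

#' Correlation map of the local epigenomic state
#'
#' Pearson correlations between the indicator variables of (site, state)
#' pairs, pooled over trajectories and recorded samples:
#' \deqn{C_{i,j}(x,y) = \frac{\langle\delta_i(x)\delta_j(y)\rangle -
#'   \langle\delta_i(x)\rangle\langle\delta_j(y)\rangle}{\sqrt{
#'   \langle\delta_i(x)\rangle(1-\langle\delta_i(x)\rangle)
#'   \langle\delta_j(y)\rangle(1-\langle\delta_j(y)\rangle)}}}
#' with \eqn{\delta_i(x) = 1} if site i is in state x. Degenerate indicators
#' (mean occupancy 0 or 1) have undefined correlations and are reported as
#' \code{NA}, with the affected (site, state) pairs flagged.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param sites site indices to include (default: every 4th site).
#' @param states character vector of states to include (default all five).
#' @param from,to pooling window in protocol time.
#' @return A square correlation matrix with dimnames \code{"<site>:<state>"}
#'   and a logical attribute \code{"degenerate"} marking undefined rows.
#' @export
correlationMap <- function(ensemble, sites = NULL, states = h3k27States(),
                           from = 0, to = Inf) {
  n <- nSites(ensemble@profile)
  if (is.null(sites)) sites <- seq(1L, n, by = 4L)
  codes <- match(states, h3k27States()) - 1L
  blocks <- lapply(ensemble@trajectories, function(traj) {
    sel <- .trajWindow(traj, from, to)
    traj@states[sel, sites, drop = FALSE]
  })
  M <- do.call(rbind, blocks)
  ind <- matrix(0L, nrow(M), length(sites) * length(codes))
  cn <- character(ncol(ind))
  k <- 0L
  for (x in seq_along(codes)) for (s in seq_along(sites)) {
    k <- k + 1L
    ind[, k] <- as.integer(M[, s] == codes[x])
    cn[k] <- paste0(sites[s], ":", states[x])
  }
  colnames(ind) <- cn
  mu <- colMeans(ind)
  degenerate <- mu <= 0 | mu >= 1
  C <- suppressWarnings(cor(ind))
  C[degenerate, ] <- NA_real_
  C[, degenerate] <- NA_real_
  attr(C, "degenerate") <- setNames(degenerate, cn)
  C
}

#' Long-format export of a correlation map
#'
#' @param C matrix from \code{\link{correlationMap}}.
#' @return A data.frame with columns \code{i, x, j, y, C}.
#' @export
correlationTable <- function(C) {
  parts <- strsplit(rownames(C), ":", fixed = TRUE)
  site <- as.integer(vapply(parts, `[`, "", 1L))
  state <- vapply(parts, `[`, "", 2L)
  idx <- which(upper.tri(C, diag = TRUE), arr.ind = TRUE)
  data.frame(i = site[idx[, 1]], x = state[idx[, 1]],
             j = site[idx[, 2]], y = state[idx[, 2]],
             C = C[idx])
}

#' Recruitment phase diagram
#'
#' Scans a grid of recruitment scales (alpha for PRC2/SUZ12, beta jointly for
#' p300 and UTX), simulates each condition to periodic steady state, and
#' classifies the methylation valency in a window around the TSS. The default
#' grid is alpha in 0..1.4 by 0.2 and beta in 0..2 by 0.2.
#'
#' @param alphaGrid,betaGrid numeric grids of non-negative scales.
#' @param params kinetic parameters (wild-type defaults).
#' @param nTraj trajectories per grid cell.
#' @param burnInCycles,sampleCycles burn-in and averaging lengths, in cell
#'   cycles.
#' @param windowKbp valency window half-width (default 2.5 kbp).
#' @param seed master seed; each cell derives its own sub-seed.
#' @param lattice the \linkS4class{ChromLattice}.
#' @return A data.frame with columns \code{alpha, beta, P_u, P_ac, P_me1,
#'   P_me2, P_me3, label}.
#' @export
phaseDiagram <- function(alphaGrid = seq(0, 1.4, by = 0.2),
                         betaGrid = seq(0, 2, by = 0.2),
                         params = modelParams(), nTraj = 12L,
                         burnInCycles = 20, sampleCycles = 5,
                         windowKbp = 2.5, seed = 1L,
                         lattice = chromLattice()) {
  stopifnot(all(alphaGrid >= 0), all(betaGrid >= 0))
  grid <- expand.grid(alpha = alphaGrid, beta = betaGrid,
                      KEEP.OUT.ATTRS = FALSE)
  prot <- simulationProtocol(duration = sampleCycles * params@cellCycle,
                             burnInCycles = burnInCycles,
                             recordInterval = 1)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    prof <- makePresetProfile("pcg_target",
                              recruitmentScales(grid$alpha[g], grid$beta[g]),
                              lattice)
    ens <- runEnsemble(prof, params, prot, nTraj = nTraj,
                       seed = .subSeed(seed, g))
    vc <- valencyCall(ens, windowKbp = windowKbp)
    rows[[g]] <- data.frame(alpha = grid$alpha[g], beta = grid$beta[g],
                            P_u = vc$means[["u"]], P_ac = vc$means[["ac"]],
                            P_me1 = vc$means[["me1"]], P_me2 = vc$means[["me2"]],
                            P_me3 = vc$means[["me3"]], label = vc$label)
  }
  do.call(rbind, rows)
}
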