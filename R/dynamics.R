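## Time-resolved analyses: synchronized cell-cycle averages, old/new histone
## pools, effective histone decay time, time normalization.

#' Intra-cell-cycle average of a synchronized population
#'
#' For a synchronized ensemble at periodic steady state (common replication
#' phase 0, so a replication occurs at every multiple of T), folds the
#' recorded protocol times modulo T and averages state proportions over
#' trajectories and cycles as a function of the time since the last
#' replication.
#'
#' @param ensemble a synchronized \linkS4class{Ensemble}.
#' @param windowKbp half-width of the TSS window to average over (Inf = whole
#'   lattice).
#' @param from earliest protocol time to include (h).
#' @return A data.frame with \code{tSinceRep} (h), \code{tOverT} and one
#'   probability column per state.
#' @export
cellCycleAverage <- function(ensemble, windowKbp = Inf, from = 0) {
  if (!ensemble@protocol@synchronized)
    stop("cellCycleAverage requires a synchronized ensemble")
  T <- ensemble@params@cellCycle
  series <- regionMeanSeries(ensemble, windowKbp)
  series <- series[series$time >= from, , drop = FALSE]
  ph <- round(series$time %% T, 9)
  ## a sample at exactly t = k*T shows the pre-replication state: fold it to T
  ph[ph == 0 & series$time > min(series$time)] <- T
  agg <- aggregate(series[paste0("P_", h3k27States())], list(tSinceRep = ph), mean)
  agg <- agg[order(agg$tSinceRep), , drop = FALSE]
  rownames(agg) <- NULL
  cbind(agg[1], tOverT = agg$tSinceRep / T, agg[-1])
}

#' Mark dynamics in the old and new histone pools
#'
#' From the pool labels of an (unsynchronized) ensemble whose label epoch is
#' the protocol time t0, computes at each recorded time the mark proportions
#' within the pool of remaining (old) histones and within the pool of
#' histones incorporated after t0 (new, via turnover or replication loss),
#' together with each pool's share of all sites.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @param windowKbp restrict to sites within this distance of the TSS.
#' @return A data.frame with columns \code{time, pool, P_u, P_ac, P_me1,
#'   P_me2, P_me3, poolFraction}; proportions are \code{NA} while a pool is
#'   empty.
#' @export
trackPools <- function(ensemble, windowKbp = Inf) {
  pos <- positionsKbp(ensemble@profile)
  sites <- which(abs(pos) <= windowKbp)
  times <- ensemble@trajectories[[1L]]@times
  nT <- length(times)
  cnt <- array(0, dim = c(nT, 5, 2)) # time x state x pool
  for (traj in ensemble@trajectories) {
    st <- traj@states[, sites, drop = FALSE]
    pl <- traj@pools[, sites, drop = FALSE]
    for (p in 0:1) for (s in 0:4)
      cnt[, s + 1L, p + 1L] <- cnt[, s + 1L, p + 1L] + rowSums(st == s & pl == p)
  }
  out <- list()
  totalSites <- length(sites) * length(ensemble@trajectories)
  for (p in 1:2) {
    poolN <- rowSums(cnt[, , p, drop = FALSE][, , 1])
    P <- cnt[, , p] / ifelse(poolN > 0, poolN, NA_real_)
    df <- data.frame(time = times, pool = c("old", "new")[p], P,
                     poolFraction = poolN / totalSites)
    names(df) <- c("time", "pool", paste0("P_", h3k27States()), "poolFraction")
    out[[p]] <- df
  }
  do.call(rbind, out)
}

#' Old-histone fraction over time
#'
#' @param ensemble an \linkS4class{Ensemble} with pool labeling.
#' @return A data.frame with \code{time} and \code{fraction} (share of sites
#'   still carrying their pre-label-epoch histone).
#' @export
oldFraction <- function(ensemble) {
  times <- ensemble@trajectories[[1L]]@times
  acc <- numeric(length(times)); tot <- 0
  for (traj in ensemble@trajectories) {
    acc <- acc + rowSums(traj@pools == 0L)
    tot <- tot + ncol(traj@pools)
  }
  data.frame(time = times, fraction = acc / tot)
}

#' Closed-form old-histone fraction (unsynchronized population)
#'
#' A site keeps its old histone until turnover (rate gammaTurn) or a
#' replication coin-flip loss (probability 1/2 per replication). With a
#' uniformly distributed replication phase, the expected old fraction at time
#' t after the label epoch is
#' \deqn{f(t) = e^{-\gamma_{turn} t}\; 2^{-m}\,(1 - r/(2T)),}
#' where m = floor(t/T) and r = t - mT. At t = mT this decays with the
#' asymptotic log-slope gammaTurn + ln(2)/T.
#'
#' @param t time since the label epoch (h), scalar or vector.
#' @param gammaTurn turnover rate (1/h).
#' @param T cell-cycle length (h).
#' @return Expected old-histone fraction.
#' @export
oldFractionClosedForm <- function(t, gammaTurn = 0.03, T = 13.5) {
  m <- floor(t / T)
  r <- t - m * T
  exp(-gammaTurn * t) * 2^(-m) * (1 - r / (2 * T))
}

#' Effective histone decay time
#'
#' Fits exp(-t / t_e) to the old-histone fraction curve and returns the
#' effective decay time t_e, which lumps direct turnover and replication
#' dilution in an unsynchronized population. The default fit is unweighted
#' least squares on the linear scale over the full recorded window; a
#' log-scale fit (weighting the tail more heavily, and equal to the
#' asymptotic log-slope 1/(gammaTurn + ln2/T) for the ideal curve sampled at
#' cycle multiples) is available via \code{scale = "log"}.
#'
#' @param times sample times (h), starting at the label epoch.
#' @param fraction old-histone fraction at \code{times}, decreasing from 1.
#' @param scale \code{"linear"} (default) or \code{"log"}.
#' @return A list with \code{te} (h) and \code{residual} (residual sum of
#'   squares on the fitted scale).
#' @export
effectiveDecayTime <- function(times, fraction, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  stopifnot(length(times) == length(fraction), length(times) >= 2)
  if (all(diff(fraction) >= 0)) stop("old fraction must decrease over time")
  if (scale == "log") {
    keep <- fraction > 0 & times > 0
    x <- times[keep]; y <- -log(fraction[keep])
    te <- sum(x^2) / sum(x * y) # least squares through the origin
    return(list(te = te, residual = sum((y - x / te)^2)))
  }
  sse <- function(te) sum((exp(-times / te) - fraction)^2)
  opt <- optimize(sse, interval = c(max(times) * 1e-4, max(times) * 100),
                  tol = 1e-8)
  list(te = opt$minimum, residual = opt$objective)
}

#' Normalize a time axis
#'
#' @param times numeric times (h).
#' @param mode \code{"cycle"} (divide by the cell-cycle length) or
#'   \code{"decay"} (divide by the effective histone decay time).
#' @param by the normalizer (T or t_e, in h; must be positive).
#' @return \code{times / by}.
#' @export
normalizeTime <- function(times, mode = c("cycle", "decay"), by) {
  mode <- match.arg(mode)
  stopifnot(by > 0)
  times / by
}
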