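## Kinetic core: contact kernel, reaction propensities, closed-form acetylation
## steady state, exact single-site periodic oracle, allostery bookkeeping.

#' Power-law 3D contact kernel
#'
#' Contact probability between lattice sites i and j, taken proportional to
#' the polymer-physics power law |i - j|^(-lambda). The diagonal is zero: the
#' on-site enzyme action is the nucleation term, so self-contact would
#' double-count it. The kernel is not normalized; any constant factor is
#' absorbed into the spreading rates.
#'
#' @param lattice a \linkS4class{ChromLattice}.
#' @param lambdaExp positive decay exponent (default 1, the value consistent
#'   with average Hi-C contact decay).
#' @return A symmetric \code{nSites x nSites} matrix with zero diagonal.
#' @export
contactKernel <- function(lattice = chromLattice(), lambdaExp = 1) {
  stopifnot(lambdaExp > 0)
  n <- nSites(lattice)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  P <- ifelse(d == 0, 0, d^(-lambdaExp))
  dim(P) <- c(n, n)
  P
}

#' Per-site reaction propensities
#'
#' Reference implementation of the reaction table for a given lattice
#' configuration. For site i in state me_{x-1} the methylation propensity is
#' \deqn{k_{mex}\,\psi_{suz12}(i) + \epsilon_{mex} \sum_{j \ne i} P(i,j)\,
#'   \psi_{suz12}(j)\, [\mathrm{state}(j) = me3]}
#' (local nucleation plus allosteric long-range spreading from trimethylated
#' PRC2-bound sites); demethylation of me_x (x >= 1) proceeds at
#' \eqn{\gamma_{me}\,\psi_{UTX}(i)}, acetylation of u at
#' \eqn{k_{ac}\,\psi_{p300}(i)}, deacetylation at \eqn{\gamma_{ac}} and
#' turnover of any modified state at \eqn{\gamma_{turn}}.
#'
#' This pure-R builder is the reference against which the compiled simulation
#' engine is validated; it is not used in the hot simulation loop.
#'
#' @param config integer vector of per-site states (encoding of
#'   \code{\link{h3k27States}}) or character vector of state names.
#' @param profile an \linkS4class{HMEProfile}.
#' @param params a \linkS4class{ModelParams}.
#' @param kernel contact matrix; default the power-law kernel with the
#'   exponent stored in \code{params}.
#' @return A data.frame with columns \code{site}, \code{from}, \code{to},
#'   \code{rate} listing every reaction with nonzero structural rate.
#' @export
propensities <- function(config, profile, params,
                         kernel = contactKernel(lattice(profile), params@lambdaExp)) {
  n <- nSites(profile)
  if (is.character(config)) config <- match(config, h3k27States()) - 1L
  if (length(config) != n) stop("config length does not match the profile lattice")
  if (!identical(dim(kernel), c(n, n))) stop("kernel dimension mismatch")
  psiS <- psiSuz12(profile); psiP <- psiP300(profile); psiU <- psiUtx(profile)
  eps <- epsMe(params)
  kx <- c(kMe1(params), kMe2(params), params@kMe3)
  ## spreading sum S(i) = sum_j P(i,j) psiS(j) [state(j) = me3]
  me3 <- as.numeric(config == .STATE_ME3)
  S <- as.vector(kernel %*% (psiS * me3))
  rows <- list()
  add <- function(site, from, to, rate)
    rows[[length(rows) + 1L]] <<- data.frame(site = site, from = from, to = to,
                                             rate = rate)
  st <- h3k27States()
  for (i in seq_len(n)) {
    s <- config[i]
    if (s == .STATE_U) {
      add(i, "u", "me1", kx[1] * psiS[i] + eps[["me1"]] * S[i])
      add(i, "u", "ac", params@kAc * psiP[i])
    } else if (s == .STATE_AC) {
      add(i, "ac", "u", params@gammaAc)
      add(i, "ac", "u", params@gammaTurn)
    } else if (s == .STATE_ME1) {
      add(i, "me1", "me2", kx[2] * psiS[i] + eps[["me2"]] * S[i])
      add(i, "me1", "u", params@gammaMe * psiU[i])
      add(i, "me1", "u", params@gammaTurn)
    } else if (s == .STATE_ME2) {
      add(i, "me2", "me3", kx[3] * psiS[i] + eps[["me3"]] * S[i])
      add(i, "me2", "me1", params@gammaMe * psiU[i])
      add(i, "me2", "u", params@gammaTurn)
    } else {
      add(i, "me3", "me2", params@gammaMe * psiU[i])
      add(i, "me3", "u", params@gammaTurn)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Closed-form acetylation steady state
#'
#' In the absence of methylation the model reduces to a two-state (u <-> ac)
#' system. Treating replication dilution as an effective first-order decay
#' ln(2)/T, the steady-state acetylation probability at a site with p300
#' density psi is
#' \deqn{P_{ac} = \frac{k_{ac}\psi}{k_{ac}\psi + \gamma_{ac} + \gamma_{turn}
#'   + \ln 2 / T}.}
#'
#' @param psiP300 p300 density (scalar or vector), >= 0.
#' @param params a \linkS4class{ModelParams}.
#' @return Acetylation probability, same length as \code{psiP300}.
#' @export
#' @examples
#' closedFormAc(0.23836, modelParams())  # ~0.265
closedFormAc <- function(psiP300, params = modelParams()) {
  stopifnot(all(psiP300 >= 0))
  num <- params@kAc * psiP300
  num / (num + params@gammaAc + params@gammaTurn + log(2) / params@cellCycle)
}

## 5x5 generator (columns = from, rows = to convention: dp/dt = Q p) for one
## decoupled site (no spreading). Order: u, ac, me1, me2, me3.
.siteGenerator <- function(psiS, psiP, psiU, params) {
  kx <- c(kMe1(params), kMe2(params), params@kMe3)
  gme <- params@gammaMe * psiU
  Q <- matrix(0, 5, 5)
  rate <- function(from, to, r) {
    Q[to, from] <<- Q[to, from] + r
    Q[from, from] <<- Q[from, from] - r
  }
  rate(1, 3, kx[1] * psiS)          # u -> me1
  rate(3, 4, kx[2] * psiS)          # me1 -> me2
  rate(4, 5, kx[3] * psiS)          # me2 -> me3
  rate(3, 1, gme); rate(4, 3, gme); rate(5, 4, gme)  # demethylation
  rate(1, 2, params@kAc * psiP)     # u -> ac
  rate(2, 1, params@gammaAc)        # ac -> u
  for (s in 2:5) rate(s, 1, params@gammaTurn)        # turnover
  Q
}

#' Exact periodic steady state of one decoupled site
#'
#' Solves the 5-state master equation of a single histone site over one cell
#' cycle with the replication dilution map p -> p/2 + e_u/2 applied at each
#' cycle boundary, and returns the unique periodic fixed point. Valid as an
#' exact oracle for the full lattice model when the spreading ratio R = 0,
#' where sites decouple.
#'
#' @param psiS,psiP,psiU enzyme densities at the site.
#' @param params a \linkS4class{ModelParams} (its R is ignored; the oracle has
#'   no spreading by construction).
#' @param phaseGrid number of equally spaced phases within the cycle at which
#'   the distribution is returned.
#' @return A list with \code{phases} (times since replication, h),
#'   \code{p} (a \code{phaseGrid x 5} matrix of state probabilities, columns
#'   named after \code{\link{h3k27States}}), and \code{phaseAverage} (the
#'   cycle-averaged distribution, i.e. what an unsynchronized population
#'   shows).
#' @export
singleSitePeriodicSteadyState <- function(psiS, psiP, psiU,
                                          params = modelParams(),
                                          phaseGrid = 512L) {
  Q <- .siteGenerator(psiS, psiP, psiU, params)
  T <- params@cellCycle
  dt <- T / phaseGrid
  Estep <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
  ET <- diag(5)
  props <- vector("list", phaseGrid)
  for (k in seq_len(phaseGrid)) { props[[k]] <- ET; ET <- Estep %*% ET }
  ## replication map M p = p/2 + e_u/2
  eu <- c(1, 0, 0, 0, 0)
  M <- diag(5) / 2 + outer(eu, rep(1, 5)) / 2
  ## periodic fixed point just after replication: p = M ET p, sum(p) = 1
  A <- diag(5) - M %*% ET
  A <- rbind(A, rep(1, 5))
  b <- c(rep(0, 5), 1)
  p0 <- qr.solve(A, b)
  p0 <- pmax(p0, 0); p0 <- p0 / sum(p0)
  P <- t(vapply(props, function(E) as.vector(E %*% p0), numeric(5)))
  colnames(P) <- h3k27States()
  list(phases = (seq_len(phaseGrid) - 1L) * dt, p = P,
       phaseAverage = colMeans(P))
}

#' Allosteric fold change implied by the spreading ratio
#'
#' The spreading rate is the allosterically boosted PRC2 activity F * kMex
#' times the 3D contact probability; with contact probability
#' (6/pi) (a / d0)^3 at the reference separation, the spreading-to-nucleation
#' ratio is R = F (6/pi) (a/d0)^3, so
#' \deqn{F = R \,/\, [(6/\pi)(a/d_0)^3].}
#'
#' @param R spreading-to-nucleation ratio.
#' @param a PRC2 capture distance, nm (default 10).
#' @param d0 spatial prefactor of the inter-locus distance, nm (default 22).
#' @return The fold change F (dimensionless).
#' @export
allosteryFoldChange <- function(R, a = 10, d0 = 22) {
  stopifnot(a > 0, d0 > 0)
  R / ((6 / pi) * (a / d0)^3)
}

#' Read/write kinetic parameters as a flat key-value config
#'
#' @param params a \linkS4class{ModelParams}.
#' @param path file path (YAML, flat keys named as the ModelParams fields).
#' @return \code{writeParams} returns \code{path} invisibly;
#'   \code{readParams} returns a \linkS4class{ModelParams}.
#' @export
writeParams <- function(params, path) {
  fields <- c("kMe3", "r13", "r23", "R", "gammaMe", "kAc", "gammaAc",
              "gammaTurn", "cellCycle", "lambdaExp")
  vals <- lapply(fields, function(f) slot(params, f))
  names(vals) <- fields
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(modelParams, vals)
}
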