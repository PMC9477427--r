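## Delimited-text exports and JSON run manifests.

#' Long-format ensemble summary
#'
#' Per-time, per-site state probabilities (fraction of trajectories in each
#' state), the standard exchange format of the simulator.
#'
#' @param ensemble an \linkS4class{Ensemble}.
#' @return A data.frame with columns \code{time_h, site, position_kbp, P_u,
#'   P_ac, P_me1, P_me2, P_me3}.
#' @export
ensembleSummary <- function(ensemble) {
  times <- ensemble@trajectories[[1L]]@times
  n <- nSites(ensemble@profile)
  pos <- positionsKbp(ensemble@profile)
  counts <- array(0, dim = c(length(times), n, 5))
  for (traj in ensemble@trajectories)
    for (s in 0:4)
      counts[, , s + 1L] <- counts[, , s + 1L] + (traj@states == s)
  P <- counts / length(ensemble@trajectories)
  out <- data.frame(time_h = rep(times, times = n),
                    site = rep(seq_len(n), each = length(times)),
                    position_kbp = rep(pos, each = length(times)))
  for (s in 1:5) out[[paste0("P_", h3k27States()[s])]] <- as.vector(P[, , s])
  out
}

#' Write a data.frame as a TSV file
#'
#' @param df a data.frame.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the resolved configuration of a run (parameters, protocol, seed)
#' plus the package version, so the run can be reproduced from the manifest
#' alone.
#'
#' @param config named list of resolved settings.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeManifest <- function(config, path) {
  config$package <- "chromK27"
  config$version <- as.character(packageVersion("chromK27"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.paramsToList <- function(params) {
  fields <- c("kMe3", "r13", "r23", "R", "gammaMe", "kAc", "gammaAc",
              "gammaTurn", "cellCycle", "lambdaExp")
  setNames(lapply(fields, function(f) slot(params, f)), fields)
}
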