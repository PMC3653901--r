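# Evaluation pipeline: run the heuristic over a simulated dataset and
# compare inferred against simulated distances.

#' Run a simulation study
#'
#' Simulates \code{count} data points, infers G_dup from each G_obs with
#' \code{\link{aliquot}}, and tabulates simulated vs inferred DCJ distances.
#' The disagreement between the simulated and the inferred G_dup is
#' reported as r times the DCJ distance of their single-copy quotients (a
#' well-defined surrogate for the distance between two differently
#' copy-labelled perfectly duplicated genomes).
#'
#' @inheritParams simulateDataset
#' @param alpha,depth heuristic parameters (see \code{\link{aliquot}}).
#' @param verbose print one progress line per point.
#' @return list with \code{rows} (one data.frame row per point: simulated
#'   and inferred distance, their relative forms, \code{delta} = inferred -
#'   simulated, and the relative G_dup-vs-G_dup distance) and
#'   \code{summary} (exceedance fraction and maximum delta among points
#'   with relative simulated distance < 0.4, and the mean relative
#'   G_dup-vs-G_dup distance per 0.1-wide bin of the relative simulated
#'   distance).
#' @export
runStudy <- function(count, n = 100L, m0 = 2L, r = 3L, dN = "uniform",
                     seed = NULL, alpha = 0.5, depth = 1L, verbose = FALSE) {
  ds <- simulateDataset(count, n = n, m0 = m0, r = r, dN = dN, seed = seed)
  rows <- ds$table
  rows$infD <- NA_integer_
  rows$infRel <- NA_real_
  rows$gdupD <- NA_integer_
  rows$gdupRel <- NA_real_
  for (i in seq_len(count)) {
    rec <- ds$records[[i]]
    res <- aliquot(rec$gobs, r, alpha = alpha, depth = depth)
    rows$infD[i] <- as.integer(res@distance)
    rows$infRel[i] <- res@relativeDistance
    qSim <- quotientGenome(rec$gdup, r)
    qInf <- res@ganc
    gd <- r * dcjDistance(qSim, qInf)
    rows$gdupD[i] <- gd
    rows$gdupRel[i] <- relativeDistance(gd, r, n)
    if (verbose)
      message(sprintf("point %d/%d: D_N=%d simD=%d infD=%d gdupD=%d",
                      i, count, rec$dN, rec$simD, rows$infD[i], gd))
  }
  rows$delta <- rows$infD - rows$simD
  low <- rows$simRel < 0.4
  bins <- cut(rows$simRel, breaks = seq(0, 1, by = 0.1),
              include.lowest = TRUE)
  summary <- list(
    nLow = sum(low),
    exceedFraction = if (any(low)) mean(rows$delta[low] > 0) else NA_real_,
    maxDeltaLow = if (any(low)) max(rows$delta[low]) else NA_integer_,
    gdupRelByBin = tapply(rows$gdupRel, bins, mean))
  list(rows = rows, summary = summary)
}
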