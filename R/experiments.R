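#' Extrapolate per-unit output to ribosomes per generation
#'
#' Scales full-length transcript counts from \code{n} parallel simulated
#' units to the per-generation output of the cell's ~75 transcriptionally
#' active rDNA repeats (50% of 150). For the paper-style 16-unit design the
#' multiplier is the stated x4.7; for other unit counts it is
#' \code{activeRepeats / n}. Runs shorter than a generation are extrapolated
#' linearly in time over \code{simTime - burnIn} seconds of steady state.
#'
#' @param perUnitCounts numeric vector of full-length (productive) counts,
#'   one entry per simulated unit, accumulated after the burn-in
#' @param demand a \code{\link{DemandModel}}
#' @param simTime simulated seconds the counts cover (including burn-in)
#' @param burnIn seconds excluded from the counts
#' @return estimated ribosomes per generation
#' @examples
#' ribosomeOutput(rep(1000 / 16, 16))   # 4700
#' @export
ribosomeOutput <- function(perUnitCounts, demand = DemandModel(),
                           simTime = demand@generationTime, burnIn = 0) {
  stopifnot(is(demand, "DemandModel"))
  n <- length(perUnitCounts)
  if (n == 0) stop("no units supplied")
  effective <- simTime - burnIn
  if (effective <= 0) stop("simTime must exceed burnIn")
  scale <- if (n == 16L) demand@scaleFactor else demand@activeRepeats / n
  sum(perUnitCounts) * (demand@generationTime / effective) * scale
}

#' 5' occupancy bias of a profile
#'
#' Mean occupancy over the first \code{boundary} nt divided by the mean over
#' the remainder of the unit, the region where excess polymerase density is
#' observed in vivo. A 1e-12 pseudocount on both means guards the ratio.
#'
#' @param profile numeric occupancy vector over the unit (or a
#'   \code{\link{SimOutput}})
#' @param boundary nt boundary of the 5' region
#' @return ratio (1 for a uniform profile)
#' @export
fivePrimeBias <- function(profile, boundary = 2000L) {
  if (is(profile, "SimOutput")) profile <- occupancyProfile(profile)
  if (length(profile) < boundary + 1L)
    stop("profile must extend beyond the boundary")
  if (all(profile == 0)) stop("all-zero profile")
  eps <- 1e-12
  (mean(profile[seq_len(boundary)]) + eps) /
    (mean(profile[(boundary + 1L):length(profile)]) + eps)
}

#' Run a premature-termination parameter grid
#'
#' Simulates every combination of \code{pPtValues} and \code{ptDistances}
#' with \code{replicates} independently seeded units per cell and aggregates
#' per-generation ribosome output, processivity, polymerase load and the 5'
#' occupancy bias. Deterministic given the seeds; a failed cell is recorded
#' in the \code{error} column rather than dropped.
#'
#' @param baseParams \code{\link{SimParams}} shared by all cells
#' @param pPtValues premature-termination probabilities to sweep
#' @param ptDistances nt ranges over which the hazard applies
#' @param replicates units per cell
#' @param seeds one seed per replicate (default \code{baseParams@seed + 0:(replicates-1)})
#' @param simTime per-unit simulated seconds (default \code{baseParams@simTime});
#'   shorter desk-scale runs are extrapolated linearly after the burn-in
#' @param burnIn seconds excluded as start-up transient (default one
#'   transit, \code{geneLength / vBar})
#' @param demand a \code{\link{DemandModel}}
#' @param folding optional bias track passed to \code{\link{simulateUnit}}
#' @param biasBoundary nt boundary for \code{\link{fivePrimeBias}}
#' @return data.frame with one row per cell: pPt, ptDistance, n, mean/sd of
#'   productive counts, processivity and polymerase load,
#'   ribosomesPerGeneration (mean and sd), fivePrimeBias, error
#' @export
runGrid <- function(baseParams, pPtValues, ptDistances = baseParams@ptDistance,
                    replicates = 4L, seeds = NULL,
                    simTime = baseParams@simTime,
                    burnIn = baseParams@geneLength / baseParams@vBar,
                    demand = DemandModel(), folding = NULL,
                    biasBoundary = 2000L) {
  stopifnot(is(baseParams, "SimParams"), is(demand, "DemandModel"))
  if (length(pPtValues) == 0 || length(ptDistances) == 0)
    stop("empty parameter sweep")
  if (any(pPtValues < 0 | pPtValues > 1)) stop("pPt values must be in [0, 1]")
  if (is.null(seeds)) seeds <- baseParams@seed + seq_len(replicates) - 1L
  if (length(seeds) != replicates)
    stop("need one seed per replicate")
  cells <- expand.grid(pPt = pPtValues, ptDistance = ptDistances)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    pPt <- cells$pPt[i]
    ptd <- cells$ptDistance[i]
    cell <- tryCatch({
      reps <- lapply(seeds, function(s) {
        p <- baseParams
        p@pPt <- pPt
        p@ptDistance <- as.integer(ptd)
        p@simTime <- simTime
        p@seed <- as.integer(s)
        simulateUnit(p, folding = folding, burnIn = burnIn)
      })
      prod <- vapply(reps, function(r) counters(r, steadyState = TRUE)[["productive"]],
                     numeric(1))
      proc <- vapply(reps, function(r) {
        cts <- counters(r)
        tot <- cts[["productive"]] + cts[["nonProductive"]]
        if (tot > 0) cts[["productive"]] / tot else NA_real_
      }, numeric(1))
      pol <- vapply(reps, function(r) r@meanPolCount, numeric(1))
      occ <- Reduce(`+`, lapply(reps, occupancyProfile, raw = TRUE))
      perRep <- vapply(prod, function(x)
        x / (simTime - burnIn) * demand@generationTime * demand@activeRepeats,
        numeric(1))
      data.frame(
        pPt = pPt, ptDistance = ptd, n = length(reps),
        productiveMean = mean(prod), productiveSd = stats::sd(prod),
        processivityMean = mean(proc, na.rm = TRUE),
        processivitySd = stats::sd(proc),
        meanPolCount = mean(pol), meanPolSd = stats::sd(pol),
        ribosomesPerGeneration = ribosomeOutput(prod, demand,
                                                simTime = simTime,
                                                burnIn = burnIn),
        ribosomesSd = stats::sd(perRep),
        fivePrimeBias = fivePrimeBias(occ, biasBoundary),
        error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(pPt = pPt, ptDistance = ptd, n = 0L,
                 productiveMean = NA_real_, productiveSd = NA_real_,
                 processivityMean = NA_real_, processivitySd = NA_real_,
                 meanPolCount = NA_real_, meanPolSd = NA_real_,
                 ribosomesPerGeneration = NA_real_, ribosomesSd = NA_real_,
                 fivePrimeBias = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    cell
  })
  do.call(rbind, rows)
}

#' Smallest grid P_PT below the demand-compatible range
#'
#' Finds the smallest swept premature-termination probability whose mean
#' per-generation ribosome output falls below the "decreased" boundary
#' (150,000 per generation by default).
#'
#' @param result a grid result from \code{\link{runGrid}} (or any data.frame
#'   with \code{pPt} and \code{ribosomesPerGeneration} columns)
#' @param demand a \code{\link{DemandModel}}
#' @return the smallest such pPt, or NA if every cell meets demand
#' @export
pptThreshold <- function(result, demand = DemandModel()) {
  if (!all(c("pPt", "ribosomesPerGeneration") %in% names(result)))
    stop("result needs pPt and ribosomesPerGeneration columns")
  if (nrow(result) == 0) stop("empty sweep")
  means <- tapply(result$ribosomesPerGeneration, result$pPt, mean,
                  na.rm = TRUE)
  pp <- as.numeric(names(means))
  ord <- order(pp)
  pp <- pp[ord]; means <- means[ord]
  below <- which(means < demand@decreasedThreshold)
  if (length(below) == 0) NA_real_ else pp[below[1]]
}

#' Scaling from parallel simulated units to active rDNA repeats
#'
#' @param activeRepeats transcriptionally active repeats per cell
#' @param nUnits parallel simulated units
#' @param digits rounding of the reported factor
#' @return the multiplier (4.7 for 75 repeats over 16 units)
#' @examples
#' repeatScaleFactor()   # 4.7
#' @export
repeatScaleFactor <- function(activeRepeats = 75, nUnits = 16, digits = 1) {
  round(activeRepeats / nUnits, digits)
}
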