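#' Premature-termination hazard rate
#'
#' Converts the total per-transit premature-termination probability into a
#' per-second hazard by scaling over the estimated time spent in the
#' termination-competent region: \code{pPt * vBar / ptDistance}. The stepper
#' applies \code{hazard * dt} per time step to every polymerase whose
#' position is at most \code{ptDistance}, so that the cumulative
#' termination probability over one transit of the region approximates
#' \code{pPt} (exactly \code{1 - exp(-pPt)} in the constant-velocity limit).
#'
#' @param params a \code{\link{SimParams}} object
#' @return hazard rate in events per second
#' @examples
#' ptHazard(SimParams(pPt = 0.1))            # 0.0025 /s
#' ptHazard(SimParams(pPt = 1, ptDistance = 6750L))
#' @export
ptHazard <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  params@pPt * params@vBar / params@ptDistance
}

#' Torsional entrainment factor of a polymerase
#'
#' Short nascent transcripts near the TSS leave the polymerase free to
#' rotate around the DNA, decoupling it from the torsion built up by its
#' neighbours. The factor ramps linearly from 0 (no transcript, free
#' rotation) to 1 at \code{lerLength} nt; with \code{lerLength = 0} the
#' low-entrainment region is disabled and the factor is 1 everywhere.
#'
#' @param transcriptLength nascent transcript length, nt (>= 0)
#' @param params a \code{\link{SimParams}} (only \code{lerLength} is used)
#' @return factor in [0, 1], monotone non-decreasing in length
#' @export
entrainmentFactor <- function(transcriptLength, params) {
  if (any(transcriptLength < 0)) stop("transcriptLength must be >= 0")
  ler <- params@lerLength
  if (ler <= 0L) return(rep(1, length(transcriptLength)))
  pmin(1, transcriptLength / ler)
}

#' Single-step translocation probabilities
#'
#' Probabilities of a forward step, a backward step, or no movement for one
#' polymerase in a unit, under the exponential-bias Brownian ratchet. The
#' baseline bias is calibrated so that on a neutral template with no
#' neighbours \code{p_forward - p_backward = vBar * dt}. Steric exclusion
#' zeroes the blocked direction; paired nascent RNA within
#' \code{structureWindow} (weight \code{dgStructure}) and the RNA:DNA hybrid
#' (weight \code{dgHybridRatio * dgStructure}) suppress backward steps;
#' accumulated twist with each neighbour, scaled by \code{torsionC} and both
#' partners' entrainment factors, biases the polymerase toward its convoy.
#'
#' @param unit a \code{\link{UnitState}}
#' @param index which polymerase (1 = most downstream)
#' @param folding numeric bias track in [0, 1] over the gene, or NULL
#' @param params a \code{\link{SimParams}}
#' @return named vector \code{p_forward}, \code{p_backward}, \code{p_stay},
#'   \code{clamped} (1 if the biases had to be clamped into [0, 1])
#' @export
stepProbabilities <- function(unit, index, folding = NULL, params) {
  stopifnot(is(unit, "UnitState"), is(params, "SimParams"))
  p <- unit@polymerases
  if (index < 1 || index > nrow(p)) stop("no polymerase at index ", index)
  folding <- .foldingVector(folding, params@geneLength)
  .cpp_step_probabilities(
    as.integer(p$position), as.numeric(p$twistUp), as.integer(index), folding,
    params@geneLength, params@footprint, params@hybridLength, params@dt,
    params@vBar, params@dgStructure, params@dgHybridRatio,
    params@structureWindow, params@torsionC, params@lerLength)
}

.foldingVector <- function(folding, geneLength) {
  if (is.null(folding)) return(numeric(0))
  if (is(folding, "FoldingTrack")) folding <- foldingBias(folding)
  folding <- as.numeric(folding)
  if (length(folding) < geneLength)
    stop("folding track must cover the gene (", geneLength, " nt)")
  folding[seq_len(geneLength)]
}

#' Advance a transcription unit in time
#'
#' Runs \code{nSteps} time steps of \code{params@dt} seconds. Per step, in
#' order: an initiation attempt if due (every \code{initiationInterval}
#' seconds, succeeding with \code{initiationProb} when positions
#' 1..footprint are free), one translocation draw per polymerase iterated
#' downstream to upstream, premature-termination draws for polymerases at
#' positions <= \code{ptDistance}, and run-off completion at
#' \code{geneLength}. Occupancy accumulates \code{dt} at every engaged
#' position.
#'
#' @param unit a \code{\link{UnitState}}
#' @param params a \code{\link{SimParams}}
#' @param folding optional bias track (numeric in [0,1] over the gene, or a
#'   \code{FoldingTrack}); NULL means a neutral template
#' @param nSteps number of dt steps to advance
#' @param stochastic FALSE selects the constant-velocity control (one
#'   deterministic forward step every \code{1/(vBar*dt)} steps, no
#'   backtracking) used to test the constant-hazard limit
#' @param debug check the steric invariant after every step (slow)
#' @return the advanced \code{UnitState}
#' @export
advanceUnit <- function(unit, params, folding = NULL, nSteps = 1L,
                        stochastic = TRUE, debug = FALSE) {
  stopifnot(is(unit, "UnitState"), is(params, "SimParams"))
  validObject(unit)
  p <- unit@polymerases
  res <- .cpp_advance(
    as.integer(p$position), as.integer(p$maxPosition),
    as.numeric(p$birthTime), as.numeric(p$twistUp),
    unit@time, as.integer(nSteps),
    params@geneLength, params@footprint, params@hybridLength, params@dt,
    params@initiationProb, params@initiationInterval, params@vBar,
    params@dgStructure, params@dgHybridRatio, params@structureWindow,
    params@torsionC, params@pPt, params@ptDistance, params@lerLength,
    .foldingVector(folding, params@geneLength),
    burn_in = 0, stochastic = stochastic, debug_steric = debug)
  occ <- unit@occupancy
  if (length(occ) != params@geneLength) occ <- numeric(params@geneLength)
  new("UnitState",
      polymerases = data.frame(position = res$positions,
                               maxPosition = res$max_positions,
                               birthTime = res$births,
                               twistUp = res$twists),
      time = res$time,
      counters = unit@counters + c(initiations = res$initiations,
                                   productive = res$productive,
                                   nonProductive = res$nonproductive),
      occupancy = occ + res$occupancy)
}

#' Simulate one transcription unit
#'
#' Runs the full stochastic simulation for \code{params@simTime} seconds
#' from an empty template and summarizes counters, the occupancy profile,
#' the time-averaged polymerase load and the processivity. The run is
#' reproducible: the RNG is seeded from \code{params@seed}.
#'
#' @param params a \code{\link{SimParams}}
#' @param folding optional bias track as in \code{\link{advanceUnit}}
#' @param burnIn seconds excluded from the steady-state counters and the
#'   mean polymerase count (occupancy and whole-run counters keep the full
#'   run); default one transit, \code{geneLength / vBar}
#' @param stochastic FALSE selects the constant-velocity control
#' @param debug check the steric invariant every step
#' @return a \code{\link{SimOutput}}
#' @examples
#' out <- simulateUnit(SimParams(simTime = 50, seed = 7))
#' counters(out)
#' @export
simulateUnit <- function(params, folding = NULL,
                         burnIn = params@geneLength / params@vBar,
                         stochastic = TRUE, debug = FALSE) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  nSteps <- params@simTime / params@dt
  if (abs(nSteps - round(nSteps)) > 1e-9) {
    warning("simTime is not an integral number of time steps; rounding down")
    nSteps <- floor(nSteps)
  }
  nSteps <- as.integer(round(nSteps))
  set.seed(params@seed)
  res <- .cpp_advance(
    integer(0), integer(0), numeric(0), numeric(0),
    0, nSteps,
    params@geneLength, params@footprint, params@hybridLength, params@dt,
    params@initiationProb, params@initiationInterval, params@vBar,
    params@dgStructure, params@dgHybridRatio, params@structureWindow,
    params@torsionC, params@pPt, params@ptDistance, params@lerLength,
    .foldingVector(folding, params@geneLength),
    burn_in = burnIn, stochastic = stochastic, debug_steric = debug)
  occ <- res$occupancy
  tot <- sum(occ)
  left <- res$productive + res$nonproductive
  new("SimOutput",
      counters = c(initiations = res$initiations,
                   productive = res$productive,
                   nonProductive = res$nonproductive),
      ssCounters = c(initiations = res$initiations_ss,
                     productive = res$productive_ss,
                     nonProductive = res$nonproductive_ss),
      occupancy = occ,
      occupancyProfile = if (tot > 0) occ / tot else occ,
      meanPolCount = res$mean_engaged_ss,
      processivity = if (left > 0) res$productive / left else NA_real_,
      meanTransit = if (res$n_transit > 0)
        res$sum_transit / res$n_transit else NA_real_,
      engagedEnd = length(res$positions),
      burnIn = burnIn,
      clampWarnings = as.integer(res$warnings),
      params = params)
}

#' @rdname counters
#' @export
setGeneric("counters", function(object, ...) standardGeneric("counters"))

#' Event counters of a simulation
#'
#' @param object a \code{\link{SimOutput}} or \code{\link{UnitState}}
#' @param steadyState for \code{SimOutput}, return the post-burn-in counters
#' @param ... unused
#' @return named numeric vector: initiations, productive, nonProductive
#' @export
setMethod("counters", "SimOutput", function(object, steadyState = FALSE, ...) {
  if (steadyState) object@ssCounters else object@counters
})

#' @rdname counters
#' @export
setMethod("counters", "UnitState", function(object, ...) object@counters)

#' @rdname processivity
#' @export
setGeneric("processivity", function(object, ...) standardGeneric("processivity"))

#' Processivity: fraction of departing polymerases that ran off the 3' end
#'
#' \code{productive / (productive + nonProductive)}. Errors when no
#' polymerase has yet left the template (both counts zero), e.g. when the
#' simulated time is shorter than one transit.
#'
#' @param object a \code{\link{SimOutput}}, or a named counter vector as
#'   returned by \code{\link{counters}}, or the productive count
#' @param nonProductive the prematurely terminated count (numeric method)
#' @param ... unused
#' @return fraction in [0, 1]
#' @examples
#' processivity(90, 10)
#' @export
setMethod("processivity", "SimOutput", function(object, ...) {
  processivity(object@counters[["productive"]],
               object@counters[["nonProductive"]])
})

#' @rdname processivity
#' @export
setMethod("processivity", "numeric", function(object, nonProductive, ...) {
  if (missing(nonProductive)) {
    if (!all(c("productive", "nonProductive") %in% names(object)))
      stop("supply (productive, nonProductive) counts")
    nonProductive <- object[["nonProductive"]]
    object <- object[["productive"]]
  }
  if (object < 0 || nonProductive < 0) stop("counts must be non-negative")
  if (object + nonProductive == 0)
    stop("processivity undefined: no polymerase has left the template")
  object / (object + nonProductive)
})

#' @rdname occupancyProfile
#' @export
setGeneric("occupancyProfile",
           function(object, ...) standardGeneric("occupancyProfile"))

#' Occupancy profile of a simulation
#'
#' @param object a \code{\link{SimOutput}}
#' @param raw return accumulated residence times (seconds) instead of the
#'   normalized profile
#' @param ... unused
#' @return numeric vector over the gene
#' @export
setMethod("occupancyProfile", "SimOutput", function(object, raw = FALSE, ...) {
  if (raw) object@occupancy else object@occupancyProfile
})

#' DNA rotation bookkeeping
#'
#' One full rotation of the DNA is required per ~10.3 nt synthesized, so a
#' 7000-nt unit takes ~680 rotations per transcript, and at 40 nt/s the
#' template spins at ~230 rpm.
#'
#' @param geneLength transcript length, nt
#' @param pitch nt per DNA turn
#' @return number of complete rotations per transcript
#' @examples
#' round(rotationsPerTranscript() / 10) * 10   # ~680
#' round(rotationRpm() / 10) * 10              # ~230 rpm
#' @export
rotationsPerTranscript <- function(geneLength = 7000, pitch = 10.3) {
  geneLength / pitch
}

#' @param vBar elongation rate, nt/s
#' @rdname rotationsPerTranscript
#' @return \code{rotationRpm}: rotation rate in revolutions per minute
#' @export
rotationRpm <- function(vBar = 40, pitch = 10.3) {
  vBar / pitch * 60
}
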