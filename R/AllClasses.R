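#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib polterm, .registration = TRUE
NULL

#' Simulation parameters for one rDNA transcription unit
#'
#' Full parameterization of the lattice simulator: a Brownian-ratchet
#' elongation model with steric exclusion, nascent-RNA structure bias,
#' torsional entrainment between neighbouring polymerases, and a
#' position-limited premature-termination hazard.
#'
#' @slot geneLength length of the transcription unit in nt
#' @slot footprint polymerase footprint in nt (minimum spacing)
#' @slot hybridLength RNA:DNA hybrid length within the bubble, nt
#' @slot dt time step in seconds
#' @slot simTime total simulated time in seconds
#' @slot initiationProb success probability of one initiation attempt
#' @slot initiationInterval seconds between initiation attempts
#' @slot vBar mean elongation velocity in nt/s (calibration target)
#' @slot dgStructure weight of the nascent-RNA structure term
#' @slot dgHybridRatio hybrid term weight as a ratio to \code{dgStructure}
#' @slot structureWindow nt of nascent RNA behind the polymerase whose
#'   pairing state blocks reverse translocation
#' @slot torsionC torsional stiffness constant coupling neighbours
#' @slot pPt total premature-termination probability per transit, in [0,1]
#' @slot ptDistance nt from the TSS over which the hazard applies
#' @slot lerLength nt of the low-entrainment ramp at the TSS (0 disables it,
#'   i.e. full entrainment everywhere)
#' @slot nReplicates number of parallel units in a replicate design
#' @slot seed integer RNG seed
#' @export
setClass("SimParams", representation(
  geneLength = "integer", footprint = "integer", hybridLength = "integer",
  dt = "numeric", simTime = "numeric",
  initiationProb = "numeric", initiationInterval = "numeric",
  vBar = "numeric", dgStructure = "numeric", dgHybridRatio = "numeric",
  structureWindow = "integer", torsionC = "numeric",
  pPt = "numeric", ptDistance = "integer", lerLength = "integer",
  nReplicates = "integer", seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@geneLength < 1L) msg <- c(msg, "geneLength must be positive")
  if (object@footprint < 1L) msg <- c(msg, "footprint must be positive")
  if (object@footprint >= object@geneLength)
    msg <- c(msg, "footprint must be smaller than geneLength")
  if (object@hybridLength < 1L) msg <- c(msg, "hybridLength must be positive")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@simTime <= 0) msg <- c(msg, "simTime must be positive")
  if (object@initiationProb < 0 || object@initiationProb > 1)
    msg <- c(msg, "initiationProb must be in [0, 1]")
  if (object@initiationInterval <= 0)
    msg <- c(msg, "initiationInterval must be positive")
  if (object@vBar <= 0) msg <- c(msg, "vBar must be positive")
  if (object@pPt < 0 || object@pPt > 1) msg <- c(msg, "pPt must be in [0, 1]")
  if (object@ptDistance < 1L || object@ptDistance > object@geneLength)
    msg <- c(msg, "ptDistance must be in [1, geneLength]")
  if (object@lerLength < 0L) msg <- c(msg, "lerLength must be non-negative")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be positive")
  if (length(msg)) msg else TRUE
})

#' @param geneLength,footprint,hybridLength,dt,simTime,initiationProb,initiationInterval,vBar,dgStructure,dgHybridRatio,structureWindow,torsionC,pPt,ptDistance,lerLength,nReplicates,seed see slots
#' @return a validated \code{SimParams} object
#' @rdname SimParams-class
#' @examples
#' p <- SimParams(pPt = 0.1)
#' ptHazard(p)
#' @export
SimParams <- function(geneLength = 7000L, footprint = 38L, hybridLength = 11L,
                      dt = 0.004, simTime = 6000,
                      initiationProb = 0.8, initiationInterval = 2.0,
                      vBar = 50, dgStructure = 1.25, dgHybridRatio = 0.48,
                      structureWindow = 11L, torsionC = 0.5,
                      pPt = 0, ptDistance = 2000L, lerLength = 2000L,
                      nReplicates = 16L, seed = 1L) {
  new("SimParams",
      geneLength = as.integer(geneLength), footprint = as.integer(footprint),
      hybridLength = as.integer(hybridLength), dt = dt, simTime = simTime,
      initiationProb = initiationProb,
      initiationInterval = initiationInterval, vBar = vBar,
      dgStructure = dgStructure, dgHybridRatio = dgHybridRatio,
      structureWindow = as.integer(structureWindow), torsionC = torsionC,
      pPt = pPt, ptDistance = as.integer(ptDistance),
      lerLength = as.integer(lerLength), nReplicates = as.integer(nReplicates),
      seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams: gene", object@geneLength, "nt, footprint",
      object@footprint, "nt, v_bar", object@vBar, "nt/s, dt", object@dt,
      "s, sim", object@simTime, "s\n")
  cat("  P_PT =", object@pPt, "over first", object@ptDistance,
      "nt; LER", object@lerLength, "nt; torsion c =", object@torsionC, "\n")
  invisible(NULL)
})

#' State of one transcription unit
#'
#' Positions and ages of the engaged polymerases (ordered downstream to
#' upstream, strictly decreasing positions with pairwise gaps of at least
#' one footprint), the simulation clock, event counters and the accumulated
#' per-nucleotide residence time.
#'
#' @slot polymerases data.frame with columns \code{position},
#'   \code{maxPosition}, \code{birthTime}, \code{twistUp} (relative twist in
#'   turns with the upstream neighbour)
#' @slot time seconds elapsed
#' @slot counters named numeric vector: \code{initiations},
#'   \code{productive}, \code{nonProductive}
#' @slot occupancy per-nt accumulated residence time, seconds
#' @export
setClass("UnitState", representation(
  polymerases = "data.frame", time = "numeric", counters = "numeric",
  occupancy = "numeric"))

setValidity("UnitState", function(object) {
  p <- object@polymerases
  msg <- character()
  need <- c("position", "maxPosition", "birthTime", "twistUp")
  if (!all(need %in% names(p))) return("polymerases lacks required columns")
  if (nrow(p) > 1 && any(diff(p$position) >= 0))
    msg <- c(msg, "positions must strictly decrease downstream -> upstream")
  if (any(p$position > p$maxPosition) || any(p$position < 1))
    msg <- c(msg, "require 1 <= position <= maxPosition")
  if (any(object@occupancy < 0)) msg <- c(msg, "occupancy must be >= 0")
  if (any(object@counters < 0)) msg <- c(msg, "counters must be >= 0")
  if (object@counters[["initiations"]] <
      object@counters[["productive"]] + object@counters[["nonProductive"]])
    msg <- c(msg, "initiations must be >= productive + nonProductive")
  if (length(msg)) msg else TRUE
})

#' @param geneLength template length for the occupancy vector
#' @return an empty \code{UnitState}
#' @rdname UnitState-class
#' @export
UnitState <- function(geneLength) {
  new("UnitState",
      polymerases = data.frame(position = integer(), maxPosition = integer(),
                               birthTime = numeric(), twistUp = numeric()),
      time = 0,
      counters = c(initiations = 0, productive = 0, nonProductive = 0),
      occupancy = numeric(geneLength))
}

setMethod("show", "UnitState", function(object) {
  cat("UnitState: t =", object@time, "s,", nrow(object@polymerases),
      "engaged polymerase(s);",
      paste(names(object@counters), object@counters, collapse = ", "), "\n")
  invisible(NULL)
})

#' Result of a full simulation run
#'
#' @slot counters named numeric: initiations, productive, nonProductive over
#'   the whole run
#' @slot ssCounters same counters restricted to times at or after the burn-in
#' @slot occupancy raw per-nt residence time (seconds) over the whole run
#' @slot occupancyProfile occupancy normalized to sum to 1 (all-zero when no
#'   signal)
#' @slot meanPolCount time-averaged engaged polymerase count after burn-in
#' @slot processivity productive / (productive + nonProductive); NA when no
#'   polymerase has left the template
#' @slot meanTransit mean transit time (s) of completed transcripts; NA if none
#' @slot engagedEnd polymerases still engaged at the end
#' @slot burnIn burn-in used, seconds
#' @slot clampWarnings count of bias clamping events in the stepper
#' @slot params the \code{SimParams} used
#' @export
setClass("SimOutput", representation(
  counters = "numeric", ssCounters = "numeric", occupancy = "numeric",
  occupancyProfile = "numeric", meanPolCount = "numeric",
  processivity = "numeric", meanTransit = "numeric", engagedEnd = "integer",
  burnIn = "numeric", clampWarnings = "integer", params = "SimParams"))

setMethod("show", "SimOutput", function(object) {
  cat("SimOutput:", object@counters[["productive"]], "productive,",
      object@counters[["nonProductive"]], "prematurely terminated,",
      object@engagedEnd, "still engaged\n")
  cat("  processivity:", signif(object@processivity, 4),
      " mean polymerases (post burn-in):", signif(object@meanPolCount, 4), "\n")
  invisible(NULL)
})

#' Per-nucleotide signal track over the reference
#'
#' @slot values numeric vector, one value per reference position
#' @slot chrom reference sequence name
#' @slot unitStart,unitEnd 1-based bounds of the transcription unit within
#'   the reference (normalization and readthrough statistics use this window)
#' @slot normalized whether \code{normalizeUnit} has been applied
#' @slot smoothing descriptor of any smoothing applied ("none" initially)
#' @export
setClass("ProfileTrack", representation(
  values = "numeric", chrom = "character", unitStart = "integer",
  unitEnd = "integer", normalized = "logical", smoothing = "character"))

setValidity("ProfileTrack", function(object) {
  msg <- character()
  if (object@unitStart < 1L || object@unitEnd > length(object@values) ||
      object@unitStart > object@unitEnd)
    msg <- c(msg, "unit window must lie within the track")
  if (length(msg)) msg else TRUE
})

#' @param values,chrom,unitStart,unitEnd,normalized,smoothing see slots
#' @return a \code{ProfileTrack}
#' @rdname ProfileTrack-class
#' @export
ProfileTrack <- function(values, chrom = "synthetic_rDNA",
                         unitStart = 1L, unitEnd = length(values),
                         normalized = FALSE, smoothing = "none") {
  new("ProfileTrack", values = as.numeric(values), chrom = chrom,
      unitStart = as.integer(unitStart), unitEnd = as.integer(unitEnd),
      normalized = normalized, smoothing = smoothing)
}

setMethod("show", "ProfileTrack", function(object) {
  cat("ProfileTrack on", object@chrom, ":", length(object@values),
      "nt (unit", object@unitStart, "-", object@unitEnd, "),",
      if (object@normalized) "normalized," else "raw,",
      "smoothing:", object@smoothing, "\n")
  invisible(NULL)
})

setMethod("length", "ProfileTrack", function(x) length(x@values))

#' Called peaks on a smoothed track
#'
#' @slot positions 1-based track coordinates of the called peaks, sorted
#' @slot scores smoothed track value at each peak
#' @slot order local-maximum comparator half-width used
#' @slot window pre-smoothing moving-average window used
#' @export
setClass("PeakSet", representation(
  positions = "integer", scores = "numeric", order = "integer",
  window = "integer"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@scores))
    msg <- c(msg, "positions and scores must have the same length")
  if (is.unsorted(object@positions, strictly = TRUE) &&
      length(object@positions) > 1)
    msg <- c(msg, "positions must be sorted increasing")
  if (length(object@positions) > 1 &&
      any(diff(object@positions) <= object@order))
    msg <- c(msg, "pairwise peak distance must exceed the comparator order")
  if (any(object@scores <= 0)) msg <- c(msg, "scores must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet:", length(object@positions), "peak(s), order",
      object@order, ", window", object@window, "\n")
  if (length(object@positions))
    cat("  positions:", paste(utils::head(object@positions, 10),
                              collapse = ", "),
        if (length(object@positions) > 10) "..." else "", "\n")
  invisible(NULL)
})

setMethod("length", "PeakSet", function(x) length(x@positions))

#' Landmark coordinates of the synthetic rDNA-like unit
#'
#' 1-based unit coordinates (TSS = 1) for the processing and termination
#' elements of the 3' ETS: the 25S 3' end (B2), the two co-transcriptional
#' stem cleavage sites at +14 and +49 downstream of B2 (B0-1/B0-2), the
#' T-rich terminator ~93 nt downstream of B2 (T1), and the roadblock factor
#' binding site 12-20 nt past T1.
#'
#' @slot tss,a0,boundary2kb,b2,b01,b02,t1,nsi1Start,nsi1End,unitLength,flank
#'   integer positions / lengths (see Description)
#' @export
setClass("ElementMap", representation(
  tss = "integer", a0 = "integer", boundary2kb = "integer", b2 = "integer",
  b01 = "integer", b02 = "integer", t1 = "integer", nsi1Start = "integer",
  nsi1End = "integer", unitLength = "integer", flank = "integer"))

setValidity("ElementMap", function(object) {
  msg <- character()
  pos <- c(object@tss, object@a0, object@boundary2kb, object@b2, object@b01,
           object@b02, object@t1, object@nsi1Start, object@nsi1End)
  if (any(diff(pos) <= 0)) msg <- c(msg, "landmarks must strictly increase")
  if (object@nsi1End > object@unitLength + object@flank)
    msg <- c(msg, "elements must fit within the reference")
  if (object@b01 - object@b2 != 14L) msg <- c(msg, "B0-1 must sit at B2 + 14")
  if (object@b02 - object@b2 != 49L) msg <- c(msg, "B0-2 must sit at B2 + 49")
  if (object@t1 - object@b2 != 93L) msg <- c(msg, "T1 must sit at B2 + 93")
  if (length(msg)) msg else TRUE
})

#' @param b2 1-based unit coordinate of the 25S 3' end; the other 3' ETS
#'   elements are placed at their fixed offsets from it
#' @param unitLength,flank unit length and per-side flank, nt
#' @param a0 boundary of the 5' ETS A0 region
#' @return an \code{ElementMap}
#' @rdname ElementMap-class
#' @export
elementMap <- function(b2 = 6858L, unitLength = 7000L, flank = 1300L,
                       a0 = 610L) {
  b2 <- as.integer(b2)
  new("ElementMap", tss = 1L, a0 = as.integer(a0), boundary2kb = 2000L,
      b2 = b2, b01 = b2 + 14L, b02 = b2 + 49L, t1 = b2 + 93L,
      nsi1Start = b2 + 93L + 12L, nsi1End = b2 + 93L + 20L,
      unitLength = as.integer(unitLength), flank = as.integer(flank))
}

setMethod("show", "ElementMap", function(object) {
  cat("ElementMap: unit", object@unitLength, "nt +", object@flank,
      "nt flanks; B2 =", object@b2, ", B0-2 = B2+49, T1 = B2+93\n")
  invisible(NULL)
})

#' Cellular demand model for ribosome output
#'
#' Literature-derived bookkeeping used to translate per-unit simulated
#' output into per-generation ribosome numbers: 75 transcriptionally active
#' repeats out of 150, a 100-min generation, a demand of 200,000 ribosomes
#' per generation, with "decreased" and "insufficient" classification
#' boundaries at 150,000 and 100,000. The x4.7 factor scales the paper-style
#' 16-unit replicate design to 75 active repeats.
#'
#' @slot activeRepeats,totalRepeats counts of rDNA repeats
#' @slot generationTime seconds per generation
#' @slot demand,decreasedThreshold,insufficientThreshold ribosomes/generation
#' @slot scaleFactor multiplier from 16 parallel units to 75 repeats
#' @export
setClass("DemandModel", representation(
  activeRepeats = "integer", totalRepeats = "integer",
  generationTime = "numeric", demand = "numeric",
  decreasedThreshold = "numeric", insufficientThreshold = "numeric",
  scaleFactor = "numeric"))

setValidity("DemandModel", function(object) {
  msg <- character()
  if (!(object@insufficientThreshold < object@decreasedThreshold &&
        object@decreasedThreshold < object@demand + 1e-9))
    msg <- c(msg, "thresholds must be ordered: insufficient < decreased <= demand")
  if (object@activeRepeats > object@totalRepeats)
    msg <- c(msg, "activeRepeats cannot exceed totalRepeats")
  if (length(msg)) msg else TRUE
})

#' @param activeRepeats,totalRepeats,generationTime,demand,decreasedThreshold,insufficientThreshold,scaleFactor see slots
#' @return a \code{DemandModel}
#' @rdname DemandModel-class
#' @export
DemandModel <- function(activeRepeats = 75L, totalRepeats = 150L,
                        generationTime = 6000, demand = 2e5,
                        decreasedThreshold = 1.5e5,
                        insufficientThreshold = 1e5, scaleFactor = 4.7) {
  new("DemandModel", activeRepeats = as.integer(activeRepeats),
      totalRepeats = as.integer(totalRepeats),
      generationTime = generationTime, demand = demand,
      decreasedThreshold = decreasedThreshold,
      insufficientThreshold = insufficientThreshold,
      scaleFactor = scaleFactor)
}

#' Specification of a synthetic CRAC read set
#'
#' Statistical structure of the generated aligned reads: a mixture of
#' Gaussian 3'-end peaks over a uniform background, a cleavage class whose
#' 5' ends are pinned at the B0-2 stem cleavage site with a planted read
#' length median, read lengths from a shifted negative binomial, and
#' position-dependent non-templated oligo(A) tailing that is enriched near
#' the planted peaks.
#'
#' @slot nReads reads per replicate
#' @slot peakMixture data.frame(center, width, weight) in unit coordinates;
#'   weights sum to 1
#' @slot backgroundWeight fraction of non-cleavage reads drawn uniformly
#' @slot cleavage5pFraction fraction of reads whose 5' end is pinned at B0-2
#' @slot cleavedLengthMedian target median length (nt) of the cleavage class
#' @slot lengthSize,lengthMu negative-binomial size and mean for read
#'   lengths; the shift is chosen so the distribution median equals
#'   \code{cleavedLengthMedian}
#' @slot polyABaseRate,polyAPeakRate oligo(A) tailing probability far from /
#'   at a planted peak
#' @slot polyAGeomProb geometric parameter for tail length beyond 3 nt
#' @slot junkTailRate probability of an uninformative non-A-terminal tail on
#'   a non-adenylated read
#' @slot nReplicates,seed replicate count and base seed
#' @export
setClass("ReadSimSpec", representation(
  nReads = "integer", peakMixture = "data.frame", backgroundWeight = "numeric",
  cleavage5pFraction = "numeric", cleavedLengthMedian = "integer",
  lengthSize = "numeric", lengthMu = "numeric",
  polyABaseRate = "numeric", polyAPeakRate = "numeric",
  polyAGeomProb = "numeric", junkTailRate = "numeric",
  nReplicates = "integer", seed = "integer"))

setValidity("ReadSimSpec", function(object) {
  msg <- character()
  pm <- object@peakMixture
  if (!all(c("center", "width", "weight") %in% names(pm)))
    return("peakMixture needs columns center, width, weight")
  if (nrow(pm) > 0 && abs(sum(pm$weight) - 1) > 1e-8)
    msg <- c(msg, "peak weights must sum to 1")
  fr <- c(object@backgroundWeight, object@cleavage5pFraction,
          object@polyABaseRate, object@polyAPeakRate, object@junkTailRate)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must be in [0, 1]")
  if (object@cleavedLengthMedian < 1L) msg <- c(msg, "median must be >= 1")
  if (object@nReads < 0L) msg <- c(msg, "nReads must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param nReads,peakMixture,backgroundWeight,cleavage5pFraction,cleavedLengthMedian,lengthSize,lengthMu,polyABaseRate,polyAPeakRate,polyAGeomProb,junkTailRate,nReplicates,seed see slots
#' @return a \code{ReadSimSpec}
#' @rdname ReadSimSpec-class
#' @export
readSimSpec <- function(nReads = 20000L,
                        peakMixture = data.frame(
                          center = c(437L, 647L, 6932L),
                          width = c(15, 15, 10),
                          weight = c(0.25, 0.25, 0.5)),
                        backgroundWeight = 0.2, cleavage5pFraction = 0.3,
                        cleavedLengthMedian = 25L,
                        lengthSize = 20, lengthMu = 7,
                        polyABaseRate = 0.02, polyAPeakRate = 0.25,
                        polyAGeomProb = 0.5, junkTailRate = 0.02,
                        nReplicates = 3L, seed = 1L) {
  new("ReadSimSpec", nReads = as.integer(nReads), peakMixture = peakMixture,
      backgroundWeight = backgroundWeight,
      cleavage5pFraction = cleavage5pFraction,
      cleavedLengthMedian = as.integer(cleavedLengthMedian),
      lengthSize = lengthSize, lengthMu = lengthMu,
      polyABaseRate = polyABaseRate, polyAPeakRate = polyAPeakRate,
      polyAGeomProb = polyAGeomProb, junkTailRate = junkTailRate,
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Rolling-window nascent-RNA folding-energy track
#'
#' @slot values per-nt score (kcal/mol by convention, <= 0); NA where the
#'   window is incomplete
#' @slot window,offset window length and offset behind the polymerase, nt
#' @slot engine descriptor of the folding engine used
#' @export
setClass("FoldingTrack", representation(
  values = "numeric", window = "integer", offset = "integer",
  engine = "character"))

setValidity("FoldingTrack", function(object) {
  ok <- is.na(object@values) | object@values <= 0
  if (!all(ok)) "all defined values must be <= 0" else TRUE
})

setMethod("show", "FoldingTrack", function(object) {
  cat("FoldingTrack:", length(object@values), "nt, window", object@window,
      "nt offset", object@offset, "nt, engine:", object@engine, "\n")
  invisible(NULL)
})

setMethod("length", "FoldingTrack", function(x) length(x@values))
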