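#' Per-nucleotide end or coverage profile of aligned reads
#'
#' Counts read 5' ends, 3' ends, or full coverage per reference position,
#' weighted by read multiplicity. On the plus strand the 5' end is the
#' interval start and the 3' end the interval end; on the minus strand the
#' two are swapped.
#'
#' @param reads a \code{GRanges} of reads with optional metadata column
#'   \code{count} (multiplicity, default 1)
#' @param refLength reference length in nt
#' @param mode one of "five_prime", "three_prime", "coverage"
#' @param chrom reference name for the resulting track
#' @param unitStart,unitEnd 1-based unit window within the reference
#' @return a raw \code{\link{ProfileTrack}}
#' @export
endProfile <- function(reads, refLength,
                       mode = c("three_prime", "five_prime", "coverage"),
                       chrom = "synthetic_rDNA",
                       unitStart = 1L, unitEnd = refLength) {
  mode <- match.arg(mode)
  stopifnot(is(reads, "GRanges"))
  st <- GenomicRanges::start(reads)
  en <- GenomicRanges::end(reads)
  if (length(reads) > 0 && (any(st < 1L) || any(en > refLength))) {
    bad <- which(st < 1L | en > refLength)[1]
    nm <- if (!is.null(names(reads))) names(reads)[bad] else as.character(bad)
    stop("read off reference: ", nm, " [", st[bad], ", ", en[bad], "]")
  }
  cnt <- S4Vectors::mcols(reads)$count
  if (is.null(cnt)) cnt <- rep(1, length(reads))
  minus <- as.character(GenomicRanges::strand(reads)) == "-"
  values <- numeric(refLength)
  if (length(reads) > 0) {
    if (mode == "coverage") {
      for (i in seq_along(reads))
        values[st[i]:en[i]] <- values[st[i]:en[i]] + cnt[i]
    } else {
      pos <- if (mode == "five_prime") ifelse(minus, en, st)
             else ifelse(minus, st, en)
      agg <- tapply(cnt, pos, sum)
      values[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  ProfileTrack(values, chrom = chrom, unitStart = unitStart,
               unitEnd = unitEnd)
}

#' Normalize a track to unit fractions
#'
#' Divides the whole track by the total signal within the unit window, then
#' adds a pseudocount to every position, so the sum over the unit becomes
#' \code{1 + unitLength * pseudo}. Refuses to run twice on the same track.
#'
#' @param track a \code{\link{ProfileTrack}}
#' @param pseudo pseudocount added after normalization
#' @return the normalized track
#' @export
normalizeUnit <- function(track, pseudo = 1e-7) {
  stopifnot(is(track, "ProfileTrack"))
  if (track@normalized) stop("track is already normalized")
  unit <- track@unitStart:track@unitEnd
  total <- sum(track@values[unit])
  if (total <= 0) stop("zero total signal over the unit")
  track@values <- track@values / total + pseudo
  track@normalized <- TRUE
  track
}

.blackmanKernel <- function(window) {
  n <- 0:(window - 1)
  k <- 0.42 - 0.5 * cos(2 * pi * n / (window - 1)) +
    0.08 * cos(4 * pi * n / (window - 1))
  k / sum(k)
}

.convSame <- function(x, kernel) {
  # centered same-length convolution; truncated renormalized kernel at edges
  n <- length(x)
  w <- length(kernel)
  left <- (w - 1L) %/% 2L
  num <- as.numeric(stats::convolve(x, rev(kernel), type = "open"))
  den <- as.numeric(stats::convolve(rep(1, n), rev(kernel), type = "open"))
  idx <- (1L + left):(n + left)
  num[idx] / den[idx]
}

#' Smooth a track with a centered Blackman window
#'
#' Convolution with a Blackman kernel normalized to sum 1, same-length
#' output; at the edges the kernel is truncated and renormalized. Away from
#' the edges the total signal is conserved.
#'
#' @param track a \code{\link{ProfileTrack}} or numeric vector
#' @param window kernel length in nt (>= 3; the Blackman window is zero at
#'   its two endpoints)
#' @return the smoothed track (same class as the input)
#' @export
smoothBlackman <- function(track, window = 10L) {
  vals <- if (is(track, "ProfileTrack")) track@values else as.numeric(track)
  if (window < 3) stop("window must be >= 3")
  if (window > length(vals)) stop("window exceeds track length")
  sm <- .convSame(vals, .blackmanKernel(window))
  if (is(track, "ProfileTrack")) {
    track@values <- sm
    track@smoothing <- paste0("blackman:", window)
    track
  } else sm
}

#' Summarize replicate tracks per position
#'
#' @param tracks list of \code{\link{ProfileTrack}}s (or numeric vectors) on
#'   identical coordinates
#' @return data.frame with columns position, median, q25, q75, min, max
#'   (quartiles by linear interpolation)
#' @export
aggregateReplicates <- function(tracks) {
  if (length(tracks) < 1) stop("need at least one track")
  vals <- lapply(tracks, function(t)
    if (is(t, "ProfileTrack")) t@values else as.numeric(t))
  lens <- vapply(vals, length, integer(1))
  if (length(unique(lens)) != 1) stop("tracks have mismatched lengths")
  m <- do.call(cbind, vals)
  q <- apply(m, 1, stats::quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(position = seq_len(nrow(m)),
             median = q[2, ], q25 = q[1, ], q75 = q[3, ],
             min = apply(m, 1, min), max = apply(m, 1, max))
}

#' Difference and cumulative maps between two replicate summaries
#'
#' @param a,b summaries from \code{\link{aggregateReplicates}} on the same
#'   coordinates
#' @return list with \code{difference} (median a - median b),
#'   \code{cumulativeA}, \code{cumulativeB}, \code{cumulativeDifference}
#'   (running sums of the medians and of the difference) and
#'   \code{significant} (TRUE where the interquartile bands of a and b are
#'   disjoint)
#' @export
differenceAndCumulative <- function(a, b) {
  need <- c("position", "median", "q25", "q75")
  if (!all(need %in% names(a)) || !all(need %in% names(b)))
    stop("inputs must be replicate summaries")
  if (nrow(a) != nrow(b) || any(a$position != b$position))
    stop("mismatched coordinates")
  diffMed <- a$median - b$median
  list(difference = diffMed,
       cumulativeA = cumsum(a$median),
       cumulativeB = cumsum(b$median),
       cumulativeDifference = cumsum(diffMed),
       significant = a$q75 < b$q25 | b$q75 < a$q25)
}

#' Fraction of signal downstream of a site
#'
#' Transcriptional readthrough statistic: the fraction of (3'-end) signal
#' within the unit that lies strictly downstream of the terminator site.
#'
#' @param track a \code{\link{ProfileTrack}}
#' @param site 1-based unit coordinate of the termination site
#' @return fraction in [0, 1]
#' @seealso \code{\link{readthroughTest}} for the replicate-level comparison
#' @export
readthroughFraction <- function(track, site) {
  stopifnot(is(track, "ProfileTrack"))
  unit <- track@unitStart:track@unitEnd
  vals <- track@values[unit]
  total <- sum(vals)
  if (total <= 0) stop("zero total signal over the unit")
  unitLen <- length(vals)
  if (site < 1 || site > unitLen) stop("site outside the unit")
  if (site == unitLen) return(0)
  sum(vals[(site + 1L):unitLen]) / total
}

#' Compare readthrough fractions between two replicate groups
#'
#' Two-sided Wilcoxon rank-sum test on per-replicate readthrough fractions
#' (normal approximation with continuity correction for larger samples, as
#' in \code{stats::wilcox.test}).
#'
#' @param fractionsA,fractionsB per-replicate readthrough fractions
#' @return the \code{htest} object
#' @export
readthroughTest <- function(fractionsA, fractionsB) {
  ties <- anyDuplicated(c(fractionsA, fractionsB)) > 0
  stats::wilcox.test(fractionsA, fractionsB, alternative = "two.sided",
                     exact = !ties && length(fractionsA) <= 25 &&
                       length(fractionsB) <= 25,
                     correct = TRUE)
}

.terminalARun <- function(tail) {
  m <- regexpr("A+$", tail)
  ifelse(m > 0, attr(m, "match.length"), 0L)
}

#' Select oligo-adenylated reads
#'
#' A read is selected when its non-templated 3' tail ends in a run of at
#' least \code{minA} consecutive adenosines ("AAA or longer" by default) --
#' the signature of TRAMP-mediated tailing at the transcript's extreme 3'
#' end. A tail ending in a non-A base disqualifies the read unless
#' \code{minA = 0}. With \code{tailAllA = TRUE} the whole tail must be
#' adenosines (the stricter reading).
#'
#' @param reads \code{GRanges} with a \code{tail} metadata column
#' @param minA minimum terminal A-run length
#' @param tailAllA require the entire tail to be A
#' @param refLength reference length for the fraction track
#' @param chrom,unitStart,unitEnd passed to the fraction track
#' @return list with \code{reads} (the selected subset) and
#'   \code{fractionTrack} (per-position adenylated 3'-end fraction, 0 where
#'   no reads end)
#' @export
selectPolyA <- function(reads, minA = 3L, tailAllA = FALSE,
                        refLength = NULL, chrom = "synthetic_rDNA",
                        unitStart = 1L, unitEnd = refLength) {
  stopifnot(is(reads, "GRanges"))
  tails <- S4Vectors::mcols(reads)$tail
  if (is.null(tails)) stop("reads carry no tail metadata column")
  tails[is.na(tails) | tails == "."] <- ""
  sel <- if (tailAllA)
    nchar(tails) >= minA & grepl("^A*$", tails)
  else
    .terminalARun(tails) >= minA
  out <- list(reads = reads[sel], fractionTrack = NULL)
  if (!is.null(refLength)) {
    all3 <- endProfile(reads, refLength, mode = "three_prime", chrom = chrom,
                       unitStart = unitStart, unitEnd = unitEnd)
    sel3 <- endProfile(reads[sel], refLength, mode = "three_prime",
                       chrom = chrom, unitStart = unitStart,
                       unitEnd = unitEnd)
    frac <- ifelse(all3@values > 0, sel3@values / all3@values, 0)
    out$fractionTrack <- ProfileTrack(frac, chrom = chrom,
                                      unitStart = unitStart,
                                      unitEnd = unitEnd)
  }
  out
}

#' Read-length distribution, optionally anchored at a 5' position
#'
#' @param reads \code{GRanges} of reads (metadata column \code{count} used
#'   as multiplicity)
#' @param anchor5p optional 1-based reference coordinate; only reads whose
#'   5' end sits exactly there are kept
#' @param breaks histogram breaks passed to \code{hist}
#' @return list with \code{median}, \code{n} and \code{histogram} (counts
#'   per length)
#' @export
readLengthStats <- function(reads, anchor5p = NULL, breaks = "Sturges") {
  stopifnot(is(reads, "GRanges"))
  if (!is.null(anchor5p)) {
    minus <- as.character(GenomicRanges::strand(reads)) == "-"
    p5 <- ifelse(minus, GenomicRanges::end(reads),
                 GenomicRanges::start(reads))
    reads <- reads[p5 == anchor5p]
  }
  if (length(reads) == 0) stop("no reads match the anchor")
  cnt <- S4Vectors::mcols(reads)$count
  if (is.null(cnt)) cnt <- rep(1L, length(reads))
  lens <- rep(GenomicRanges::width(reads), cnt)
  list(median = stats::median(lens), n = length(lens),
       histogram = graphics::hist(lens, breaks = breaks, plot = FALSE))
}
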