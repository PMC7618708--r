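#' Build the synthetic rDNA-like reference
#'
#' Generates a random-composition reference of
#' \code{unitLength + 2 * flank} nt with two planted features: a
#' palindromic cassette spanning the B0-1..B0-2 interval, so that any
#' pairing-based folding engine scores a stable stem there (the Rnt1
#' substrate geometry), and a T-rich run at the T1 terminator. The stand-in
#' is synthetic: composition outside the planted elements carries no
#' biological signal.
#'
#' @param map an \code{\link{ElementMap}}
#' @param seed RNG seed
#' @param chrom reference sequence name
#' @return list with \code{sequence} (a named \code{DNAStringSet}) and
#'   \code{annotation} (a \code{GRanges} of the landmark elements, reference
#'   coordinates)
#' @examples
#' ref <- makeReference(elementMap(), seed = 1)
#' length(ref$sequence[[1]])   # 9600
#' @export
makeReference <- function(map = elementMap(), seed = 1L,
                          chrom = "synthetic_rDNA") {
  stopifnot(is(map, "ElementMap"))
  validObject(map)
  refLen <- map@unitLength + 2L * map@flank
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), refLen, replace = TRUE)

  toRef <- function(unitPos) map@flank + unitPos
  # palindromic stem cassette across B0-1..B0-2 (36 nt: 16 + 4 loop + 16)
  armLen <- 16L
  arm <- sample(c("G", "C", "A", "T"), armLen, replace = TRUE,
                prob = c(0.4, 0.4, 0.1, 0.1))
  loop <- c("T", "T", "C", "G")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cassette <- c(arm, loop, rev(unname(comp[arm])))
  cs <- toRef(map@b01)
  bases[cs:(cs + length(cassette) - 1L)] <- cassette
  # T-rich terminator run at T1
  t1 <- toRef(map@t1)
  bases[t1:(t1 + 11L)] <- "T"

  if (toRef(map@nsi1End) > refLen) stop("elements out of reference bounds")
  seq <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(seq) <- chrom

  anno <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(
      start = toRef(c(map@tss, map@a0, map@boundary2kb, map@b2, map@b01,
                      map@b02, map@t1, map@nsi1Start)),
      end = toRef(c(map@tss, map@a0, map@boundary2kb, map@b2, map@b01,
                    map@b02, map@t1, map@nsi1End))),
    strand = "+",
    name = c("TSS", "A0", "boundary_2kb", "B2", "B0_1", "B0_2", "T1",
             "NSI1_site"))
  list(sequence = seq, annotation = anno)
}

#' Simulate CRAC-like aligned reads over the synthetic reference
#'
#' Draws per-replicate read sets with the statistical structure of nascent
#' transcript profiling data: 3' ends from a mixture of Gaussian peaks plus
#' uniform background; a cleavage class whose 5' ends are pinned at the
#' B0-2 stem cleavage site with the planted read-length median; read lengths
#' from a shifted negative binomial; and non-templated oligo(A) tails (3 nt
#' plus a geometric excess) attached with a probability that interpolates
#' from \code{polyABaseRate} to \code{polyAPeakRate} with proximity to the
#' planted peaks. Replicates differ only by seed.
#'
#' @param spec a \code{\link{ReadSimSpec}}
#' @param map the \code{\link{ElementMap}} used for the reference
#' @param strand "+" (default; the rDNA is transcribed from one strand) or
#'   "-" (mirror-image mode used to test coordinate handling)
#' @param chrom reference name
#' @return list of \code{GRanges} (one per replicate) with metadata columns
#'   \code{tail} (non-templated 3' sequence, "" when absent) and
#'   \code{count}
#' @export
simulateReads <- function(spec, map = elementMap(), strand = "+",
                          chrom = "synthetic_rDNA") {
  stopifnot(is(spec, "ReadSimSpec"), is(map, "ElementMap"))
  validObject(spec)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  pm <- spec@peakMixture
  if (nrow(pm) > 0 && (any(pm$center < 1) || any(pm$center > map@unitLength)))
    stop("planted peaks must lie within the unit")
  refLen <- map@unitLength + 2L * map@flank
  shift <- spec@cleavedLengthMedian -
    stats::qnbinom(0.5, size = spec@lengthSize, mu = spec@lengthMu)

  lapply(seq_len(spec@nReplicates), function(rep) {
    set.seed(spec@seed + rep - 1L)
    n <- spec@nReads
    if (n == 0L) {
      gr <- GenomicRanges::GRanges(seqnames = character(),
                                   ranges = IRanges::IRanges(),
                                   strand = character())
      S4Vectors::mcols(gr)$tail <- character()
      S4Vectors::mcols(gr)$count <- integer()
      return(gr)
    }
    len <- pmax(5L, shift + stats::rnbinom(n, size = spec@lengthSize,
                                           mu = spec@lengthMu))
    cleaved <- stats::runif(n) < spec@cleavage5pFraction

    # 3'-end positions (unit coordinates) for the non-cleavage classes
    end3 <- integer(n)
    bg <- stats::runif(n) < spec@backgroundWeight
    end3[bg] <- sample.int(map@unitLength, sum(bg), replace = TRUE)
    npk <- sum(!bg)
    if (npk > 0 && nrow(pm) > 0) {
      comp <- sample.int(nrow(pm), npk, replace = TRUE, prob = pm$weight)
      end3[!bg] <- pmin(map@unitLength, pmax(
        1L, as.integer(round(stats::rnorm(npk, pm$center[comp],
                                          pm$width[comp])))))
    } else if (npk > 0) {
      end3[!bg] <- sample.int(map@unitLength, npk, replace = TRUE)
    }
    # cleavage class: 5' pinned at B0-2, 3' end set by the drawn length
    end3[cleaved] <- map@b02 + len[cleaved] - 1L

    # oligo(A) tailing, enriched near the planted peaks
    prox <- rep(0, n)
    if (nrow(pm) > 0) {
      for (k in seq_len(nrow(pm)))
        prox <- pmax(prox, exp(-(end3 - pm$center[k])^2 /
                                 (2 * pm$width[k]^2)))
    }
    pA <- spec@polyABaseRate + (spec@polyAPeakRate - spec@polyABaseRate) * prox
    tailed <- stats::runif(n) < pA
    tail <- rep("", n)
    if (any(tailed)) {
      aLen <- 3L + stats::rgeom(sum(tailed), spec@polyAGeomProb)
      tail[tailed] <- strrep("A", aLen)
    }
    junk <- !tailed & stats::runif(n) < spec@junkTailRate
    if (any(junk)) {
      nj <- sum(junk)
      jl <- sample(1:3, nj, replace = TRUE)
      tail[junk] <- vapply(seq_len(nj), function(i)
        paste0(paste(sample(c("A", "C", "G", "T"), jl[i] - 1, replace = TRUE),
                     collapse = ""),
               sample(c("C", "G", "T"), 1)), character(1))
    }

    # unit -> reference coordinates; the biological 3' end is the interval
    # end on "+" and the interval start on "-" (where the 5' pin at B0-2
    # becomes the interval end)
    if (strand == "+") {
      refEnd <- map@flank + end3
      refStart <- refEnd - len + 1L
    } else {
      refStart <- map@flank + end3
      refEnd <- refStart + len - 1L
      refEnd[cleaved] <- map@flank + map@b02
      refStart[cleaved] <- refEnd[cleaved] - len[cleaved] + 1L
    }
    keep <- refStart >= 1L & refEnd <= refLen
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = refStart[keep], end = refEnd[keep]),
      strand = strand)
    S4Vectors::mcols(gr)$tail <- tail[keep]
    S4Vectors::mcols(gr)$count <- rep(1L, sum(keep))
    names(gr) <- sprintf("read_%d_%d", rep, seq_len(sum(keep)))
    gr
  })
}
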