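# small parameter sets and hand-built unit states shared across tests

shortParams <- function(simTime = 60, ...) {
  SimParams(simTime = simTime, seed = 101L, ...)
}

# a UnitState with polymerases at the given (decreasing) positions
unitWithPols <- function(positions, geneLength = 7000L, twists = NULL) {
  n <- length(positions)
  if (is.null(twists)) twists <- numeric(n)
  new("UnitState",
      polymerases = data.frame(position = as.integer(positions),
                               maxPosition = as.integer(positions),
                               birthTime = numeric(n), twistUp = twists),
      time = 0,
      counters = c(initiations = n, productive = 0, nonProductive = 0),
      occupancy = numeric(geneLength))
}

# reads as a GRanges in one call: list of c(start, end), strands, tails
makeReads <- function(intervals, strand = "+", tail = "", count = 1L,
                      chrom = "synthetic_rDNA") {
  st <- vapply(intervals, `[`, numeric(1), 1)
  en <- vapply(intervals, `[`, numeric(1), 2)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = st, end = en),
    strand = rep(strand, length.out = length(intervals)))
  S4Vectors::mcols(gr)$tail <- rep(tail, length.out = length(intervals))
  S4Vectors::mcols(gr)$count <- rep(as.integer(count),
                                    length.out = length(intervals))
  names(gr) <- sprintf("r%d", seq_along(gr))
  gr
}

# independent brute-force scanner for the oligo(A) selection rule:
# walk the tail backwards counting consecutive A
bruteTerminalARun <- function(tail) {
  if (is.na(tail) || tail == "" || tail == ".") return(0L)
  chars <- rev(strsplit(tail, "")[[1]])
  run <- 0L
  for (ch in chars) {
    if (ch == "A") run <- run + 1L else break
  }
  run
}
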