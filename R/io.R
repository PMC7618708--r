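#' Read aligned reads from a BED6+1 file
#'
#' Tab-separated BED6 with a 7th column holding the non-templated 3' tail
#' sequence ("." for none). Multiplicity is taken from the score column when
#' it is an integer >= 1, otherwise 1. Malformed lines raise an error naming
#' the line number.
#'
#' @param path file path (plain or gzip)
#' @return \code{GRanges} with metadata columns \code{tail} and \code{count}
#' @export
readBedReads <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$tail <- character()
    S4Vectors::mcols(gr)$count <- integer()
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 6)) stop("malformed BED line ", which(n < 6)[1],
                       ": fewer than 6 fields")
  chrom <- vapply(fields, `[`, character(1), 1)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  name <- vapply(fields, `[`, character(1), 4)
  score <- vapply(fields, `[`, character(1), 5)
  strand <- vapply(fields, `[`, character(1), 6)
  tail <- vapply(seq_along(fields), function(i)
    if (n[i] >= 7) fields[[i]][7] else ".", character(1))
  if (anyNA(start0) || anyNA(end0))
    stop("malformed BED line ", which(is.na(start0) | is.na(end0))[1],
         ": non-numeric interval")
  bad <- which(start0 >= end0)
  if (length(bad)) stop("malformed BED line ", bad[1],
                        ": start must be < end (inverted interval)")
  if (any(!strand %in% c("+", "-")))
    stop("malformed BED line ", which(!strand %in% c("+", "-"))[1],
         ": strand must be + or -")
  tail[tail == "."] <- ""
  if (any(grepl("[^ACGTN]", tail)))
    stop("malformed BED line ", which(grepl("[^ACGTN]", tail))[1],
         ": tail may contain only ACGTN")
  cnt <- suppressWarnings(as.numeric(score))
  count <- ifelse(!is.na(cnt) & cnt >= 1 & cnt == round(cnt),
                  as.integer(cnt), 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand)
  S4Vectors::mcols(gr)$tail <- tail
  S4Vectors::mcols(gr)$count <- count
  names(gr) <- name
  gr
}

#' Write reads to a BED6+1 file
#'
#' @param reads \code{GRanges} with \code{tail} and \code{count} metadata
#' @param path destination (".gz" suffix gzips)
#' @export
writeBedReads <- function(reads, path) {
  stopifnot(is(reads, "GRanges"))
  tails <- S4Vectors::mcols(reads)$tail
  if (is.null(tails)) tails <- rep("", length(reads))
  tails[is.na(tails) | tails == ""] <- "."
  cnt <- S4Vectors::mcols(reads)$count
  if (is.null(cnt)) cnt <- rep(1L, length(reads))
  nm <- names(reads)
  if (is.null(nm)) nm <- sprintf("read_%d", seq_along(reads))
  lines <- paste(as.character(GenomicRanges::seqnames(reads)),
                 GenomicRanges::start(reads) - 1L,
                 GenomicRanges::end(reads), nm, cnt,
                 as.character(GenomicRanges::strand(reads)), tails,
                 sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a track as bedGraph
#'
#' 0-based half-open intervals; adjacent equal values are run-length merged;
#' NA and zero positions are omitted. Round-trips bit-exactly through
#' \code{\link{readBedGraph}} for finite values.
#'
#' @param track a \code{\link{ProfileTrack}} (or numeric vector)
#' @param path destination path
#' @param chrom reference name when \code{track} is a bare vector
#' @export
writeBedGraph <- function(track, path, chrom = "synthetic_rDNA") {
  if (is(track, "ProfileTrack")) {
    vals <- track@values
    chrom <- track@chrom
  } else vals <- as.numeric(track)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  keep <- !is.na(vals) & vals != 0
  if (any(keep)) {
    r <- rle(paste0(ifelse(keep, format(vals, digits = 17), "SKIP")))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    use <- r$values != "SKIP"
    writeLines(paste(chrom, starts[use] - 1L, ends[use],
                     format(vals[starts[use]], digits = 17, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a track
#'
#' @param path bedGraph path
#' @param refLength reference length for the resulting track
#' @param chrom,unitStart,unitEnd passed to the \code{\link{ProfileTrack}}
#' @return a \code{ProfileTrack}; positions absent from the file are 0
#' @export
readBedGraph <- function(path, refLength, chrom = "synthetic_rDNA",
                         unitStart = 1L, unitEnd = refLength) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  vals <- numeric(refLength)
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    for (f in fields) {
      s <- as.integer(f[2]); e <- as.integer(f[3])
      vals[(s + 1L):e] <- as.numeric(f[4])
    }
  }
  ProfileTrack(vals, chrom = chrom, unitStart = unitStart, unitEnd = unitEnd)
}

#' Run the synthetic-data / profiling pipeline from a configuration
#'
#' Executes the requested stages in dependency order: \code{synth}
#' (reference + reads), \code{fold} (folding-energy track), \code{profile}
#' (3'-end profile, unit-normalized and Blackman-smoothed), \code{peaks},
#' \code{metaplot}, \code{polya} and \code{readthrough}. All randomness
#' derives from the single top-level seed. A manifest (stages, parameters,
#' seed, output checksums) is written to the output directory; a rerun with
#' the same configuration yields identical checksums.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognized keys: \code{stages} (character vector), \code{out_dir},
#'   \code{seed}, \code{smooth_window}, \code{peak_order},
#'   \code{peak_window}, \code{metaplot_flank}, \code{min_a},
#'   \code{reads_file} (use existing BED6+1 instead of the synth stage),
#'   plus optional sub-lists \code{elements} and \code{reads} overriding
#'   \code{\link{elementMap}} / \code{\link{readSimSpec}} defaults
#' @return (invisibly) the manifest list
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  known <- c("stages", "out_dir", "seed", "smooth_window", "peak_order",
             "peak_window", "metaplot_flank", "min_a", "reads_file",
             "elements", "reads")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  stages <- config[["stages"]] %||% c("synth", "profile", "peaks")
  outDir <- config[["out_dir"]] %||% stop("config needs out_dir")
  seed <- as.integer(config[["seed"]] %||% 1L)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  map <- do.call(elementMap, config[["elements"]] %||% list())
  spec <- do.call(readSimSpec, c(config[["reads"]] %||% list(), list(seed = seed)))
  refLen <- map@unitLength + 2L * map@flank
  unitStart <- map@flank + 1L
  unitEnd <- map@flank + map@unitLength
  manifest <- list(seed = seed, stages = list(), outputs = character())
  paths <- character()
  ref <- NULL; reads <- NULL; smoothed <- NULL; pk <- NULL

  addOut <- function(p) { paths <<- c(paths, p); p }

  for (stage in stages) {
    if (stage == "synth") {
      ref <- makeReference(map, seed = seed)
      Biostrings::writeXStringSet(ref$sequence,
                                  addOut(file.path(outDir, "reference.fa")))
      anno <- ref$annotation
      writeLines(paste(as.character(GenomicRanges::seqnames(anno)),
                       GenomicRanges::start(anno) - 1L,
                       GenomicRanges::end(anno),
                       S4Vectors::mcols(anno)$name, 0L,
                       as.character(GenomicRanges::strand(anno)),
                       sep = "\t"),
                 addOut(file.path(outDir, "annotation.bed")))
      readSets <- simulateReads(spec, map)
      for (i in seq_along(readSets))
        writeBedReads(readSets[[i]],
                      addOut(file.path(outDir,
                                       sprintf("reads_rep%d.bed", i))))
      reads <- readSets[[1]]
      manifest$stages$synth <- list(nReplicates = spec@nReplicates,
                                    nReads = spec@nReads)
    } else if (stage == "fold") {
      if (is.null(ref)) ref <- makeReference(map, seed = seed)
      ft <- windowDg(ref$sequence[[1]])
      writeBedGraph(ProfileTrack(ft@values), addOut(
        file.path(outDir, "folding.bedgraph")))
      manifest$stages$fold <- list(window = ft@window, offset = ft@offset,
                                   engine = ft@engine)
    } else if (stage == "profile") {
      if (is.null(reads)) {
        if (!is.null(config[["reads_file"]])) {
          if (!file.exists(config[["reads_file"]]))
            stop("missing input file: ", config[["reads_file"]])
          reads <- readBedReads(config[["reads_file"]])
        } else stop("profile stage needs the synth stage or reads_file")
      }
      tr <- endProfile(reads, refLen, mode = "three_prime",
                       unitStart = unitStart, unitEnd = unitEnd)
      tr <- normalizeUnit(tr)
      smoothed <- smoothBlackman(tr, as.integer(config[["smooth_window"]] %||% 10L))
      writeBedGraph(smoothed, addOut(file.path(outDir,
                                               "profile_3p.bedgraph")))
      manifest$stages$profile <- list(mode = "three_prime",
                                      smoothing = smoothed@smoothing)
    } else if (stage == "peaks") {
      if (is.null(smoothed)) stop("peaks stage needs the profile stage")
      pk <- findPeaks(smoothed, order = as.integer(config[["peak_order"]] %||% 45L),
                      window = as.integer(config[["peak_window"]] %||% 80L))
      writeLines(paste(smoothed@chrom, pk@positions - 1L, pk@positions,
                       sprintf("peak_%d", seq_along(pk@positions)),
                       format(pk@scores, digits = 6),
                       "+", sep = "\t"),
                 addOut(file.path(outDir, "peaks.bed")))
      manifest$stages$peaks <- list(n = length(pk@positions))
    } else if (stage == "metaplot") {
      if (is.null(pk)) stop("metaplot stage needs the peaks stage")
      mp <- metaplot(smoothed, pk,
                     flank = as.integer(config[["metaplot_flank"]] %||% 200L))
      utils::write.table(mp, addOut(file.path(outDir, "metaplot.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$metaplot <- list(nPeaksUsed = length(pk@positions) -
                                         attr(mp, "dropped"))
    } else if (stage == "polya") {
      if (is.null(reads)) stop("polya stage needs reads")
      pa <- selectPolyA(reads, minA = as.integer(config[["min_a"]] %||% 3L),
                        refLength = refLen, unitStart = unitStart,
                        unitEnd = unitEnd)
      writeBedGraph(pa$fractionTrack,
                    addOut(file.path(outDir, "polya_fraction.bedgraph")))
      manifest$stages$polya <- list(nSelected = length(pa$reads))
    } else if (stage == "readthrough") {
      if (is.null(smoothed)) stop("readthrough stage needs the profile stage")
      rt <- readthroughFraction(smoothed, site = map@t1)
      writeLines(format(rt, digits = 10),
                 addOut(file.path(outDir, "readthrough.txt")))
      manifest$stages$readthrough <- list(site = map@t1, fraction = rt)
    } else stop("unknown stage: ", stage)
  }

  manifest$outputs <- as.list(tools::md5sum(paths))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
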