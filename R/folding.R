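.baseCodes <- function(sequence) {
  s <- toupper(as.character(sequence))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  codes <- match(chars, c("A", "C", "G", "U")) - 1L
  tIdx <- chars == "T"
  codes[tIdx] <- 3L
  codes[is.na(codes)] <- -1L
  codes
}

#' Bundled folding engine: maximum base-pairing score
#'
#' A Nussinov-style dynamic program over Watson-Crick plus G:U pairs with a
#' minimum loop of 3 unpaired nt, scoring each pair at -1 kcal/mol. It is
#' deterministic and dependency-free but not thermodynamically exact; a
#' production folding engine can be plugged into \code{\link{windowDg}} in
#' its place. The simulator consumes only the relative (min-max normalized)
#' bias, so engine units do not matter there.
#'
#' @param sequence a character string, \code{DNAString}/\code{RNAString},
#'   or anything coercible via \code{as.character}
#' @return minimum free-energy proxy, <= 0
#' @examples
#' nussinovDg("AAAAAAAAAA")      # 0: no pairing possible
#' nussinovDg("GGGGGAAAACCCCC")  # a stem scores negative
#' @export
nussinovDg <- function(sequence) {
  -1 * .cpp_max_pairs(.baseCodes(sequence))  # -1 kcal/mol per pair
}

#' Rolling-window nascent-RNA folding-energy track
#'
#' For each template position the folding score of the \code{window} nt of
#' extruded nascent RNA ending \code{offset} nt behind the polymerase (the
#' region still inside the enzyme is skipped): position \code{i} scores the
#' subsequence ending at \code{i - offset}. Positions whose window is
#' incomplete are NA.
#'
#' @param sequence template sequence (character or \code{DNAString}-like)
#' @param engine NULL for the bundled \code{\link{nussinovDg}} fast path, or
#'   any function mapping a sequence string to a score <= 0
#' @param window window length, nt
#' @param offset nt between the polymerase position and the window end
#' @return a \code{\link{FoldingTrack}}
#' @export
windowDg <- function(sequence, engine = NULL, window = 65L, offset = 15L) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (is.null(engine)) {
    vals <- .cpp_window_dg(.baseCodes(s), as.integer(window),
                           as.integer(offset))
    engName <- "nussinov"
  } else {
    vals <- rep(NA_real_, n)
    if (n >= window + offset) {
      for (i in (window + offset):n) {
        sub <- substr(s, i - offset - window + 1L, i - offset)
        vals[i] <- tryCatch({
          v <- engine(sub)
          if (!is.finite(v) || v > 0) stop("engine returned invalid score")
          v
        }, error = function(e) {
          warning("folding engine failed at position ", i, ": ",
                  conditionMessage(e))
          NA_real_
        })
      }
    }
    engName <- "custom"
  }
  new("FoldingTrack", values = vals, window = as.integer(window),
      offset = as.integer(offset), engine = engName)
}

#' Min-max normalized folding bias for the simulator
#'
#' Rescales a folding-energy track to [0, 1] with 1 at the strongest folding
#' (most negative score) and 0 at the weakest; undefined positions map to 0.
#' This decouples the folding engine's units from the ratchet's force units.
#'
#' @param track a \code{\link{FoldingTrack}} (or numeric vector of scores)
#' @return numeric bias vector in [0, 1]
#' @export
foldingBias <- function(track) {
  vals <- if (is(track, "FoldingTrack")) track@values else as.numeric(track)
  def <- !is.na(vals)
  out <- numeric(length(vals))
  if (!any(def)) return(out)
  lo <- min(vals[def]); hi <- max(vals[def])
  if (hi > lo) out[def] <- (hi - vals[def]) / (hi - lo)
  out
}
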