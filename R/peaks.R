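#' Call peaks on a profile track
#'
#' The track is first smoothed with a centered moving average of length
#' \code{window}; a position is then called a peak when its smoothed value
#' strictly exceeds every position within \code{order} nt on both sides
#' (plateau ties resolve to the leftmost position) and reaches at least
#' \code{minHeight} times the smoothed track mean. Positions within
#' \code{order} of either boundary are not callable.
#'
#' @param track a \code{\link{ProfileTrack}} or numeric vector
#' @param order local-maximum comparator half-width, nt
#' @param window moving-average pre-smoothing window, nt
#' @param minHeight height floor as a multiple of the smoothed track mean
#' @return a \code{\link{PeakSet}} (positions are 1-based track coordinates)
#' @export
findPeaks <- function(track, order = 45L, window = 80L, minHeight = 1.0) {
  vals <- if (is(track, "ProfileTrack")) track@values else as.numeric(track)
  order <- as.integer(order)
  window <- as.integer(window)
  n <- length(vals)
  if (order >= n) stop("order must be smaller than the track length")
  if (n <= window) stop("track must be longer than the smoothing window")
  sm <- .convSame(vals, rep(1 / window, window))
  floorVal <- minHeight * mean(sm)
  pos <- integer(0)
  i <- order + 1L
  lastPeak <- -order - 1L
  while (i <= n - order) {
    left <- sm[(i - order):(i - 1L)]
    right <- sm[(i + 1L):(i + order)]
    if (sm[i] > max(left) && sm[i] >= max(right) && sm[i] >= floorVal &&
        i - lastPeak > order) {
      pos <- c(pos, i)
      lastPeak <- i
      i <- i + order + 1L   # no second peak within the comparator width
    } else i <- i + 1L
  }
  new("PeakSet", positions = pos, scores = sm[pos],
      order = as.integer(order), window = as.integer(window))
}

#' Drop designated peaks from a peak set
#'
#' Supports excluding individual features (e.g. a dominant position) from a
#' metaplot without recalling peaks.
#'
#' @param peaks a \code{\link{PeakSet}}
#' @param exclude track coordinates to drop
#' @param tol match tolerance in nt
#' @return the filtered \code{PeakSet}
#' @export
excludePeaks <- function(peaks, exclude, tol = 0L) {
  stopifnot(is(peaks, "PeakSet"))
  keep <- vapply(peaks@positions, function(p)
    all(abs(p - exclude) > tol), logical(1))
  new("PeakSet", positions = peaks@positions[keep],
      scores = peaks@scores[keep], order = peaks@order,
      window = peaks@window)
}

#' Peak-anchored metaplot
#'
#' Superimposes a two-sided window around every peak and averages the track
#' values at each offset. Peaks whose window would exceed the track bounds
#' are dropped (their count is reported in the \code{dropped} attribute).
#'
#' @param track a \code{\link{ProfileTrack}} or numeric vector
#' @param peaks a \code{\link{PeakSet}} (or integer positions)
#' @param flank half-width of the window, nt
#' @return data.frame with columns \code{offset} (-flank..flank) and
#'   \code{mean}
#' @export
metaplot <- function(track, peaks, flank = 200L) {
  vals <- if (is(track, "ProfileTrack")) track@values else as.numeric(track)
  pos <- if (is(peaks, "PeakSet")) peaks@positions else as.integer(peaks)
  usable <- pos[pos - flank >= 1L & pos + flank <= length(vals)]
  if (length(usable) == 0) stop("no peak with a full window inside the track")
  windows <- vapply(usable, function(p) vals[(p - flank):(p + flank)],
                    numeric(2L * flank + 1L))
  out <- data.frame(offset = -flank:flank, mean = rowMeans(windows))
  attr(out, "dropped") <- length(pos) - length(usable)
  out
}

#' Average a second track around anchor peaks
#'
#' Metaplot of \code{otherTrack} anchored on the peaks of another signal
#' (e.g. a termination factor around polymerase peaks), reporting the offset
#' of the secondary track's maximum; negative offsets are upstream of the
#' anchor.
#'
#' @param anchorPeaks a \code{\link{PeakSet}} called on the anchor track
#' @param otherTrack a \code{\link{ProfileTrack}} or numeric vector on the
#'   same coordinates
#' @param flank half-width of the window, nt
#' @return list with \code{metaplot} (offset, mean) and \code{offsetOfMax}
#' @export
alignTracksAtPeaks <- function(anchorPeaks, otherTrack, flank = 200L) {
  mp <- metaplot(otherTrack, anchorPeaks, flank = flank)
  list(metaplot = mp, offsetOfMax = mp$offset[which.max(mp$mean)])
}
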