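#' Windowed GC skew along a sequence
#'
#' GC skew is the strand asymmetry `(G - C) / (G + C)` counted on the
#' forward strand of each window. Windows are placed from position 0 every
#' `step` bp; windows extending past the sequence end are discarded.
#' Windows with `G + C = 0` yield a missing value.
#'
#' @param seq A single A/C/G/T/N string.
#' @param window Window size in bp (>= 1). Default 100 bp with a 50 bp
#'   step resolves a ~1 kb skewed promoter footprint with >= 10 windows.
#' @param step Step between window starts in bp (>= 1).
#' @param chrom Optional chromosome name stored as an attribute.
#' @return A `data.frame` of class `"skew_track"` with columns `start`
#'   (0-based window start) and `skew` in `[-1, 1]` or `NA`; attributes
#'   `window`, `step`, `chrom`.
#' @examples
#' gc_skew("GGGGCCAA", window = 4, step = 2)
#' @export
gc_skew <- function(seq, window = 100L, step = 50L, chrom = NA_character_) {
  stopifnot(length(seq) == 1L, is.character(seq))
  if (window < 1L) stop("window must be >= 1")
  if (step < 1L) stop("step must be >= 1")
  seq <- toupper(seq)
  L <- nchar(seq)
  if (window > L) {
    starts <- numeric()
  } else {
    starts <- seq.int(0L, L - window, by = step)
  }
  if (!length(starts)) {
    out <- data.frame(start = numeric(), skew = numeric())
  } else {
    v <- charToRaw(seq)
    cg <- c(0, cumsum(v == charToRaw("G")))
    cc <- c(0, cumsum(v == charToRaw("C")))
    G <- cg[starts + window + 1] - cg[starts + 1]
    C <- cc[starts + window + 1] - cc[starts + 1]
    skew <- ifelse(G + C == 0, NA_real_, (G - C) / (G + C))
    out <- data.frame(start = starts, skew = skew)
  }
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "chrom") <- chrom
  class(out) <- c("skew_track", "data.frame")
  out
}

#' Call positively GC-skewed regions from a skew track
#'
#' A simple run-length rule: maximal runs of at least `min_run`
#' consecutive non-missing windows with skew `>= threshold` are merged
#' into one interval spanning the first window's start to the last
#' window's end. (This replaces HMM-based skew segmentation with an
#' explicit thresholded statistic.)
#'
#' @param track A `"skew_track"` from [gc_skew].
#' @param threshold Skew threshold in `(0, 1]` (default 0.2).
#' @param min_run Minimum number of consecutive qualifying windows.
#' @return A [gintervals] table of called regions (chrom taken from the
#'   track attribute).
#' @export
call_skewed_regions <- function(track, threshold = 0.2, min_run = 2L) {
  stopifnot(inherits(track, "skew_track"))
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  if (min_run < 1L) stop("min_run must be >= 1")
  window <- attr(track, "window")
  chrom <- attr(track, "chrom") %||% NA_character_
  if (!nrow(track)) return(gintervals())
  ok <- !is.na(track$skew) & track$skew >= threshold
  r <- rle(ok)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(gintervals())
  gintervals(
    chrom = chrom,
    start = track$start[starts_i[keep]],
    end = track$start[ends_i[keep]] + window
  )
}
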