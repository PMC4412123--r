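#' Scan a sequence for G-quadruplex motifs
#'
#' Detects Quadparser-style motifs: `n_tracts` tracts of exactly
#' `tract_len` guanines (default 4 tracts of `GGG`) separated by loops of
#' `loop_min`..`loop_max` nucleotides (default 1-7). Plus-strand motifs
#' come from the G-pattern on the given sequence; minus-strand motifs are
#' found by running the same G-pattern on the reverse complement and
#' mapping coordinates back, which is equivalent to a `CCC`-tract pattern
#' on the forward strand and keeps the scan exactly strand-symmetric.
#'
#' Tracts are matched as exactly-`tract_len` runs that may sit inside
#' longer G runs (leftmost feasible placement wins); loops are length-only
#' constraints, so any base including `N` may appear in a loop, while `N`
#' never participates in a tract.
#'
#' @param seq A single A/C/G/T/N string.
#' @param tract_len Tract length in bp (default 3, i.e. `GGG`).
#' @param n_tracts Number of tracts (default 4).
#' @param loop_min,loop_max Loop length bounds in bp (defaults 1 and 7).
#' @param policy `"greedy_nonoverlapping"` (default) reports motifs
#'   left-to-right, each starting at or after the previous motif's end,
#'   choosing at every step the leftmost feasible tract placement;
#'   `"all"` reports every tract combination with valid loops.
#' @param chrom Optional chromosome name attached to the output.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open motif span), `strand`, `tract_starts` (comma-separated
#'   0-based forward-strand tract starts) and `loop_lengths`
#'   (comma-separated, in forward orientation).
#' @examples
#' scan_g4("GGGAGGGAGGGAGGG")
#' @export
scan_g4 <- function(seq, tract_len = 3L, n_tracts = 4L,
                    loop_min = 1L, loop_max = 7L,
                    policy = c("greedy_nonoverlapping", "all"),
                    chrom = NA_character_) {
  policy <- match.arg(policy)
  stopifnot(length(seq) == 1L, is.character(seq))
  if (loop_min < 1L) stop("loop_min must be >= 1")
  if (loop_max < loop_min) stop("loop_max must be >= loop_min")
  seq <- toupper(seq)
  L <- nchar(seq)
  plus <- g4_tract_scan(seq, tract_len, n_tracts, loop_min, loop_max, policy)
  minus <- g4_tract_scan(revcomp(seq), tract_len, n_tracts, loop_min, loop_max, policy)
  res <- list()
  if (nrow(plus)) {
    res$plus <- data.frame(
      chrom = chrom, start = plus$start, end = plus$end, strand = "+",
      tract_starts = plus$tract_starts, loop_lengths = plus$loop_lengths,
      stringsAsFactors = FALSE
    )
  }
  if (nrow(minus)) {
    # reflect reverse-complement coordinates back to the forward strand
    ts <- lapply(strsplit(minus$tract_starts, ","), as.numeric)
    fwd_ts <- lapply(ts, function(p) sort(L - p - tract_len))
    ll <- lapply(fwd_ts, function(p) diff(p) - tract_len)
    res$minus <- data.frame(
      chrom = chrom,
      start = L - minus$end,
      end = L - minus$start,
      strand = "-",
      tract_starts = vapply(fwd_ts, paste, "", collapse = ","),
      loop_lengths = vapply(ll, paste, "", collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               strand = character(), tract_starts = character(),
               loop_lengths = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# Core single-strand scan: all 0-based starts of exactly-tract_len G runs
# (placements may overlap inside longer runs), then a chain DP over
# admissible loop windows.
g4_tract_scan <- function(seq, tract_len, n_tracts, loop_min, loop_max, policy) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      tract_starts = character(), loop_lengths = character(),
                      stringsAsFactors = FALSE)
  L <- nchar(seq)
  if (L < n_tracts * tract_len + (n_tracts - 1L) * loop_min) return(empty)
  m <- gregexpr(sprintf("(?=G{%d})", tract_len), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  tpos <- as.numeric(m) - 1  # 0-based tract starts, sorted
  n <- length(tpos)
  if (n < n_tracts) return(empty)
  # successor index window of each tract: next tract start within
  # [pos + tract_len + loop_min, pos + tract_len + loop_max]
  lo <- findInterval(tpos + tract_len + loop_min - 0.5, tpos) + 1L
  hi <- findInterval(tpos + tract_len + loop_max + 0.5, tpos)
  # ok[[k]][i]: tract i can begin a chain of k tracts
  ok <- vector("list", n_tracts)
  ok[[1L]] <- rep(TRUE, n)
  if (n_tracts > 1L) {
    for (k in 2:n_tracts) {
      cs <- cumsum(ok[[k - 1L]])
      cnt <- ifelse(hi >= lo, cs[pmin(hi, n)] - ifelse(lo > 1L, cs[lo - 1L], 0), 0)
      ok[[k]] <- cnt > 0
    }
  }
  emit <- function(idx_list) {
    if (!length(idx_list)) return(empty)
    starts <- vapply(idx_list, function(ix) tpos[ix[1L]], 0)
    ends <- vapply(idx_list, function(ix) tpos[ix[length(ix)]] + tract_len, 0)
    data.frame(
      start = starts, end = ends,
      tract_starts = vapply(idx_list, function(ix) paste(tpos[ix], collapse = ","), ""),
      loop_lengths = vapply(idx_list, function(ix) {
        paste(diff(tpos[ix]) - tract_len, collapse = ",")
      }, ""),
      stringsAsFactors = FALSE
    )
  }
  if (policy == "greedy_nonoverlapping") {
    motifs <- list()
    cursor <- 0
    okn <- ok[[n_tracts]]
    repeat {
      cand <- which(okn & tpos >= cursor)
      if (!length(cand)) break
      ix <- integer(n_tracts)
      ix[1L] <- cand[1L]
      if (n_tracts > 1L) {
        for (k in 2:n_tracts) {
          prev <- ix[k - 1L]
          js <- seq.int(lo[prev], min(hi[prev], n))
          js <- js[ok[[n_tracts - k + 1L]][js]]
          ix[k] <- js[1L]
        }
      }
      motifs[[length(motifs) + 1L]] <- ix
      cursor <- tpos[ix[n_tracts]] + tract_len
    }
    emit(motifs)
  } else {
    # exhaustive: every admissible tract combination
    frontier <- lapply(which(ok[[n_tracts]]), function(i) i)
    if (n_tracts > 1L) {
      for (k in 2:n_tracts) {
        nxt <- list()
        okk <- ok[[n_tracts - k + 1L]]
        for (ix in frontier) {
          prev <- ix[length(ix)]
          if (hi[prev] < lo[prev]) next
          js <- seq.int(lo[prev], min(hi[prev], n))
          js <- js[okk[js]]
          for (j in js) nxt[[length(nxt) + 1L]] <- c(ix, j)
        }
        frontier <- nxt
        if (length(frontier) > 2e6) stop("motif explosion under policy='all'")
      }
    }
    emit(frontier)
  }
}

#' Scan every chromosome of a genome for G4 motifs
#'
#' @inheritParams scan_g4
#' @param g A [genome].
#' @return Combined motif table across chromosomes (see [scan_g4]).
#' @export
scan_g4_genome <- function(g, tract_len = 3L, n_tracts = 4L,
                           loop_min = 1L, loop_max = 7L,
                           policy = c("greedy_nonoverlapping", "all")) {
  policy <- match.arg(policy)
  out <- lapply(names(g), function(ch) {
    scan_g4(unclass(g)[[ch]], tract_len, n_tracts, loop_min, loop_max,
            policy, chrom = ch)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert a G4 motif table to intervals
#'
#' @param motifs Output of [scan_g4] / [scan_g4_genome].
#' @return A [gintervals] table (name `"G4"`, score = motif length).
#' @export
g4_to_intervals <- function(motifs) {
  gintervals(motifs$chrom, motifs$start, motifs$end,
             name = "G4", score = motifs$end - motifs$start,
             strand = motifs$strand, label = "G4")
}
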