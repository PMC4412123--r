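#' Build the TSS-associated CpG island promoter universe
#'
#' The transcription start site (TSS) of each gene is its 5' end: `start`
#' for `+` genes, `end - 1` for `-` genes. A gene enters the universe
#' when its TSS lies inside, or within `max_distance` bp of, a CpG
#' island. When several islands qualify the nearest (by TSS-to-interval
#' distance) wins, ties broken by leftmost island.
#'
#' Distance convention: 0 when the TSS falls inside the island; otherwise
#' the number of bases the TSS would have to move to enter it
#' (`start - tss` to the left edge, `tss - end + 1` past the right edge).
#'
#' @param genes Stranded [gintervals] (strand `+`/`-` required; unstranded
#'   genes are dropped with a warning). Gene ids come from the `name`
#'   column, or `gene<i>` when absent.
#' @param cgis CpG islands as (unstranded) [gintervals].
#' @param max_distance Maximum TSS-to-island distance in bp (default 0:
#'   the TSS must sit inside the island, the conventional reading of
#'   "CpG island promoter").
#' @return A `data.frame` of class `"promoter_universe"` with columns
#'   `gene_id`, `chrom`, `tss`, `strand`, `cgi_start`, `cgi_end`,
#'   `gc_skewed` (`NA` until [flag_gc_skew] is run); one row per
#'   `(gene_id, tss)`, ordered by `(chrom, tss, gene_id)`.
#' @export
build_promoter_universe <- function(genes, cgis, max_distance = 0) {
  validate_intervals(genes)
  validate_intervals(cgis)
  stopifnot(max_distance >= 0)
  unstranded <- genes$strand == "."
  if (any(unstranded)) {
    warning(sum(unstranded), " unstranded gene(s) dropped from the promoter universe")
    genes <- genes[!unstranded, , drop = FALSE]
  }
  if (!nrow(genes) || !nrow(cgis)) {
    return(empty_universe())
  }
  gene_id <- ifelse(is.na(genes$name), paste0("gene", seq_len(nrow(genes))), genes$name)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  # candidate islands within max_distance of each TSS via windowed overlap
  tss_win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = tss + 1 - max_distance, end = tss + 1 + max_distance)
  )
  hits <- GenomicRanges::findOverlaps(tss_win, as_granges0(cgis))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- tss_cgi_distance(tss[qi], cgis$start[si], cgis$end[si])
  keep <- d <= max_distance
  qi <- qi[keep]; si <- si[keep]; d <- d[keep]
  if (!length(qi)) return(empty_universe())
  # nearest island per gene, ties broken by leftmost (start, then end)
  o <- order(qi, d, cgis$start[si], cgis$end[si])
  qi <- qi[o]; si <- si[o]
  first <- !duplicated(qi)
  gi <- qi[first]; ci <- si[first]
  out <- data.frame(
    gene_id = gene_id[gi],
    chrom = genes$chrom[gi],
    tss = tss[gi],
    strand = genes$strand[gi],
    cgi_start = cgis$start[ci],
    cgi_end = cgis$end[ci],
    gc_skewed = NA,
    stringsAsFactors = FALSE
  )
  out <- out[!duplicated(paste(out$gene_id, out$tss)), , drop = FALSE]
  out <- out[order(out$chrom, out$tss, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("promoter_universe", "data.frame")
  attr(out, "max_distance") <- max_distance
  out
}

empty_universe <- function() {
  out <- data.frame(gene_id = character(), chrom = character(), tss = numeric(),
                    strand = character(), cgi_start = numeric(), cgi_end = numeric(),
                    gc_skewed = logical(), stringsAsFactors = FALSE)
  class(out) <- c("promoter_universe", "data.frame")
  out
}

# Point-to-interval distance under the convention documented in
# build_promoter_universe (0-based half-open interval, 0 if inside).
tss_cgi_distance <- function(tss, start, end) {
  ifelse(tss < start, start - tss, ifelse(tss >= end, tss - end + 1, 0))
}

#' Associate peaks with promoters
#'
#' Two association geometries are supported. `cgi_overlap` (default): a
#' peak associates with a promoter when it shares at least one base with
#' the promoter's CpG island. `upstream_window`: when it shares at least
#' one base with the `upstream` bp immediately 5' of the TSS in oriented
#' coordinates — `[tss - upstream, tss)` for `+` promoters, reflected to
#' `[tss + 1, tss + 1 + upstream)` for `-` promoters.
#'
#' @param peaks A [gintervals] table.
#' @param universe A `"promoter_universe"` from [build_promoter_universe].
#' @param mode `"cgi_overlap"` or `"upstream_window"`.
#' @param upstream Width of the upstream window in bp (default 1000).
#' @return A `data.frame` with columns `promoter` and `peak` (row indices
#'   into `universe` and `peaks`) and `overlap` (shared bases).
#' @seealso [promoter_positive] for the per-promoter indicator.
#' @export
associate_peaks_to_promoters <- function(peaks, universe,
                                         mode = c("cgi_overlap", "upstream_window"),
                                         upstream = 1000) {
  mode <- match.arg(mode)
  validate_intervals(peaks)
  stopifnot(inherits(universe, "promoter_universe"))
  if (!nrow(peaks) || !nrow(universe)) {
    return(data.frame(promoter = integer(), peak = integer(), overlap = numeric()))
  }
  win <- promoter_windows(universe, mode, upstream)
  res <- intersect_intervals(win$intervals, peaks, min_overlap = 1L)
  out <- data.frame(promoter = win$row[res$a], peak = res$b, overlap = res$overlap)
  out[order(out$promoter, out$peak), , drop = FALSE]
}

# The association geometry of each promoter as an interval table plus the
# universe row each interval belongs to (degenerate windows, e.g. a TSS at
# the chromosome start in upstream mode, are dropped).
promoter_windows <- function(universe, mode, upstream = 1000) {
  if (mode == "cgi_overlap") {
    start <- universe$cgi_start
    end <- universe$cgi_end
  } else {
    stopifnot(upstream >= 1)
    start <- ifelse(universe$strand == "+", pmax(universe$tss - upstream, 0),
                    universe$tss + 1)
    end <- ifelse(universe$strand == "+", universe$tss, universe$tss + 1 + upstream)
  }
  keep <- which(start < end)
  list(
    intervals = gintervals(universe$chrom[keep], start[keep], end[keep],
                           name = universe$gene_id[keep]),
    row = keep
  )
}

#' Per-promoter peak positivity
#'
#' @param peaks,universe,mode,upstream As in [associate_peaks_to_promoters].
#' @return Logical vector over `universe` rows: `TRUE` when at least one
#'   peak associates with the promoter.
#' @export
promoter_positive <- function(peaks, universe,
                              mode = c("cgi_overlap", "upstream_window"),
                              upstream = 1000) {
  mode <- match.arg(mode)
  assoc <- associate_peaks_to_promoters(peaks, universe, mode, upstream)
  seq_len(nrow(universe)) %in% assoc$promoter
}

#' Flag promoters with a positively GC-skewed footprint
#'
#' Measures GC skew on the non-template strand over the `footprint` bp
#' immediately downstream of the TSS (forward strand for `+` genes,
#' reverse complement for `-` genes) and flags promoters whose mean
#' windowed skew reaches `threshold`.
#'
#' @param universe A `"promoter_universe"`.
#' @param g A [genome].
#' @param footprint Footprint width in bp (default 1000).
#' @param window,step Passed to [gc_skew] (defaults 100/50).
#' @param threshold Mean-skew threshold (default 0.1).
#' @return The universe with `gc_skewed` filled in.
#' @export
flag_gc_skew <- function(universe, g, footprint = 1000, window = 100L,
                         step = 50L, threshold = 0.1) {
  stopifnot(inherits(universe, "promoter_universe"))
  flags <- vapply(seq_len(nrow(universe)), function(i) {
    tss <- universe$tss[i]
    if (universe$strand[i] == "+") {
      s <- get_seq(g, universe$chrom[i], tss, tss + footprint)
    } else {
      s <- revcomp(get_seq(g, universe$chrom[i], tss - footprint + 1, tss + 1))
    }
    if (!nzchar(s)) return(NA)
    tr <- gc_skew(s, window = window, step = step)
    mu <- mean(tr$skew, na.rm = TRUE)
    !is.na(mu) && mu >= threshold
  }, logical(1))
  universe$gc_skewed <- flags
  universe
}

#' Write a promoter universe as a tab-separated table
#'
#' @param universe A `"promoter_universe"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_universe <- function(universe, path) {
  utils::write.table(universe, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a promoter universe written by [write_universe]
#' @param path Path to the table.
#' @return A `"promoter_universe"`.
#' @export
read_universe <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("promoter_universe", "data.frame")
  out
}
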