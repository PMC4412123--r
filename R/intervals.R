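#' Construct a set of genomic intervals
#'
#' Intervals follow the BED convention throughout the package: coordinates
#' are 0-based, half-open `[start, end)`, so book-ended intervals share no
#' base. Strand is one of `"+"`, `"-"`, or `"."` (unstranded); unstranded
#' intervals match either strand in stranded queries.
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Numeric vectors of 0-based half-open coordinates with
#'   `0 <= start < end`.
#' @param name Optional labels (`NA` allowed).
#' @param score Optional numeric scores; used as fold enrichment above
#'   input by [filter_by_fold_enrichment()].
#' @param strand `"+"`, `"-"` or `"."`.
#' @param label Free-text label for the set (e.g. `"DRIP"`, `"ORC1"`,
#'   `"SNS"`), stored as an attribute.
#' @return A `data.frame` of class `"gintervals"` with columns `chrom`,
#'   `start`, `end`, `name`, `score`, `strand`.
#' @examples
#' gintervals("chr1", c(0, 50), c(10, 80), strand = c("+", "."))
#' @export
gintervals <- function(chrom = character(), start = numeric(), end = numeric(),
                       name = NA_character_, score = NA_real_, strand = ".",
                       label = NULL) {
  n <- max(length(chrom), length(start), length(end))
  if (length(start) == 0L || length(end) == 0L || length(chrom) == 0L) n <- 0L
  x <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  class(x) <- c("gintervals", "data.frame")
  if (!is.null(label)) attr(x, "label") <- label
  validate_intervals(x)
  x
}

#' Validate genomic intervals
#'
#' Checks the interval invariants: integral coordinates, `0 <= start < end`,
#' known strand symbols, and (when a genome is supplied) that every `chrom`
#' exists and no interval extends past its sequence end.
#'
#' @param x A `gintervals` data frame.
#' @param genome Optional [genome] against which chromosome names and
#'   bounds are checked.
#' @return `x`, invisibly. Errors describe the first offending row.
#' @export
validate_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end", "strand")
  if (!all(req %in% names(x))) {
    stop("interval table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 x$start != floor(x$start) | x$end != floor(x$end))
  if (length(bad)) stop("non-integer coordinates at row ", bad[1L])
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad)) {
    stop(sprintf("invalid interval at row %d: start=%s end=%s (need 0 <= start < end)",
                 bad[1L], format(x$start[bad[1L]]), format(x$end[bad[1L]])))
  }
  bad <- which(!x$strand %in% c("+", "-", "."))
  if (length(bad)) stop("unknown strand symbol at row ", bad[1L])
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    miss <- setdiff(unique(x$chrom), names(lens))
    if (length(miss)) stop("chromosome(s) not in genome: ", paste(miss, collapse = ", "))
    over <- which(x$end > lens[x$chrom])
    if (length(over)) stop("interval beyond chromosome end at row ", over[1L])
  }
  invisible(x)
}

# 1-based closed GRanges view of a 0-based half-open interval table.
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Read a BED file
#'
#' Reads BED3 to BED6 (tab-separated, optional `track`/`browser`/`#`
#' lines, no header required). Columns 4-6 (name, score, strand) are
#' honored when present; `"."` scores parse as `NA`; an unknown strand
#' symbol is treated as unstranded with a warning.
#'
#' @param path Path to the BED file.
#' @param label Optional set label (`"DRIP"`, `"ORC1"`, `"SNS"`, ...).
#' @return A [gintervals] table. Malformed lines (fewer than 3 columns,
#'   non-integer coordinates, `start >= end`) abort with the line number.
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(gintervals(label = label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    stop("line ", lineno[which(ncols < 3L)[1L]], ": fewer than 3 tab-separated columns")
  }
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- get_col(1L)
  start <- suppressWarnings(as.numeric(get_col(2L)))
  end <- suppressWarnings(as.numeric(get_col(3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) stop("line ", lineno[bad[1L]], ": non-integer coordinates")
  bad <- which(start < 0 | start >= end)
  if (length(bad)) stop("line ", lineno[bad[1L]], ": start >= end or negative start")
  name <- get_col(4L)
  name[name %in% "."] <- NA_character_
  score_raw <- get_col(5L)
  score <- suppressWarnings(as.numeric(ifelse(score_raw %in% ".", NA, score_raw)))
  strand <- get_col(6L)
  strand[is.na(strand)] <- "."
  unknown <- !strand %in% c("+", "-", ".")
  if (any(unknown)) {
    warning("unknown strand symbol(s) treated as unstranded (line ",
            lineno[which(unknown)[1L]], ")")
    strand[unknown] <- "."
  }
  gintervals(chrom, start, end, name = name, score = score, strand = strand,
             label = label)
}

#' Write intervals as BED
#'
#' Emits sorted BED (by `chrom`, then `start`, `end`, `name`) with Unix
#' line endings. The number of columns defaults to 6 when any name, score
#' or strand is informative, 3 otherwise.
#'
#' @param x A [gintervals] table.
#' @param path Output path.
#' @param ncol 3..6, or `NULL` to choose automatically.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, ncol = NULL) {
  validate_intervals(x)
  x <- sort_intervals(x)
  if (is.null(ncol)) {
    ncol <- if (nrow(x) && (any(!is.na(x$name)) || any(!is.na(x$score)) ||
                            any(x$strand != "."))) 6L else 3L
  }
  stopifnot(ncol >= 3L, ncol <= 6L)
  cols <- list(
    x$chrom,
    format(x$start, scientific = FALSE, trim = TRUE),
    format(x$end, scientific = FALSE, trim = TRUE)
  )
  if (ncol >= 4L) cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  if (ncol >= 5L) {
    cols <- c(cols, list(ifelse(is.na(x$score), ".",
                                format(x$score, scientific = FALSE, trim = TRUE))))
  }
  if (ncol >= 6L) cols <- c(cols, list(x$strand))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(x)) {
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' Sort intervals deterministically
#'
#' Orders by `(chrom, start, end, name)`; the name column breaks residual
#' ties so output order never depends on input order.
#'
#' @param x A [gintervals] table.
#' @return The sorted table.
#' @export
sort_intervals <- function(x) {
  if (!nrow(x)) return(x)
  out <- x[order(x$chrom, x$start, x$end, x$name, method = "radix",
                 na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge overlapping and book-ended intervals
#'
#' Collapses touching or overlapping intervals on the same chromosome into
#' maximal runs. Under the half-open convention `[0,10)` and `[10,20)` are
#' book-ended and merge into `[0,20)`. Strand, name and score are dropped
#' (merged intervals are unstranded). The operation is idempotent and
#' preserves the per-base coverage footprint.
#'
#' @param x A [gintervals] table.
#' @return A sorted, non-overlapping [gintervals] table.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (!nrow(x)) return(gintervals(label = attr(x, "label")))
  gr <- as_granges0(x)
  red <- GenomicRanges::reduce(gr)  # default min.gapwidth=1 merges book-ends
  out <- gintervals(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = GenomicRanges::end(red),
    label = attr(x, "label")
  )
  sort_intervals(out)
}

#' Intersect two interval sets
#'
#' Reports every pair of intervals (one from `a`, one from `b`) on the
#' same chromosome sharing at least `min_overlap` bases. Content is
#' symmetric under swapping `a` and `b`.
#'
#' @param a,b [gintervals] tables.
#' @param min_overlap Minimum shared bases (default 1; must be >= 1).
#' @return A `data.frame` with columns `a` and `b` (row indices into the
#'   inputs) and `overlap` (shared bases), ordered by `(a, b)`.
#' @export
intersect_intervals <- function(a, b, min_overlap = 1L) {
  validate_intervals(a)
  validate_intervals(b)
  if (!is.numeric(min_overlap) || length(min_overlap) != 1L || min_overlap < 1) {
    stop("min_overlap must be a single number >= 1")
  }
  if (!nrow(a) || !nrow(b)) {
    return(data.frame(a = integer(), b = integer(), overlap = numeric()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(a), as_granges0(b),
                                      minoverlap = as.integer(min_overlap))
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j])
  out <- data.frame(a = i, b = j, overlap = ov)
  out[order(out$a, out$b), , drop = FALSE]
}

#' Filter peaks by fold enrichment above input
#'
#' Retains exactly the intervals whose score, interpreted as fold
#' enrichment above input, is strictly greater than `threshold`. The
#' default reproduces a "greater than fivefold above input" peak filter,
#' read literally as `> 5` rather than `>= 5`.
#'
#' @param x A [gintervals] table; every row must carry a score.
#' @param threshold Fold-enrichment cutoff (default 5).
#' @return The filtered table.
#' @export
filter_by_fold_enrichment <- function(x, threshold = 5) {
  validate_intervals(x)
  if (any(is.na(x$score))) {
    i <- which(is.na(x$score))[1L]
    stop(sprintf("interval %s:%s-%s (%s) has no fold-enrichment score",
                 x$chrom[i], format(x$start[i]), format(x$end[i]),
                 ifelse(is.na(x$name[i]), "unnamed", x$name[i])))
  }
  out <- x[x$score > threshold, , drop = FALSE]
  attr(out, "label") <- attr(x, "label")
  class(out) <- class(x)
  out
}

#' Total bases covered by an interval set
#'
#' Counts each base once regardless of how many intervals cover it.
#'
#' @param x A [gintervals] table.
#' @return Number of distinct covered bases.
#' @export
covered_bases <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}
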