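#' TSS-centered composite density profile
#'
#' For every anchor (an oriented TSS), each base covered by a hit inside
#' the `[-halfwidth, +halfwidth)` window increments the count at its
#' offset; minus-strand windows are reflected so upstream is always
#' leftward. Counts are averaged over the anchors actually covering each
#' offset (windows truncated at chromosome ends contribute to neither
#' numerator nor denominator at the missing positions) and then divided
#' by the genome-wide hit density, so a uniformly distributed hit set has
#' expected profile value 1 everywhere.
#'
#' @param hits A [gintervals] table of hits (peaks or motifs).
#' @param anchors A `data.frame` with columns `chrom`, `tss`, `strand`
#'   (`+`/`-`); e.g. a `"promoter_universe"`.
#' @param g A [genome].
#' @param halfwidth Window half-width in bp (default 3000, i.e. a 6 kb
#'   span).
#' @param mode `"coverage"` (default): hits contribute every covered
#'   base, and the normalizer is total hit-covered bases (with
#'   multiplicity) per genome base. `"midpoint"`: each hit contributes
#'   only its midpoint, normalized by hits per genome base.
#' @return A list of class `"composite_profile"`: `offset`
#'   (`-halfwidth .. halfwidth-1`), `values` (normalized density),
#'   `counts` (raw per-offset hit-base counts), `nvalid` (anchors
#'   covering each offset), `n_regions`, `genome_density`, `halfwidth`,
#'   `mode`.
#' @export
composite_profile <- function(hits, anchors, g, halfwidth = 3000L,
                              mode = c("coverage", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(halfwidth >= 1L, nrow(anchors) >= 1L)
  validate_intervals(hits, g)
  core <- profile_core(hits, anchors, g, halfwidth, mode)
  density <- hit_density(hits, g, mode)
  if (density == 0) stop("no hits: genome-wide density is zero")
  values <- ifelse(core$nvalid > 0, core$counts / core$nvalid / density, NA_real_)
  out <- list(
    offset = seq.int(-halfwidth, halfwidth - 1L),
    values = values,
    counts = core$counts,
    nvalid = core$nvalid,
    n_regions = nrow(anchors),
    genome_density = density,
    halfwidth = halfwidth,
    mode = mode
  )
  class(out) <- "composite_profile"
  out
}

# Raw per-offset counts and per-offset anchor coverage.
profile_core <- function(hits, anchors, g, halfwidth, mode = "coverage") {
  lens <- genome_lengths(g)
  width <- 2L * halfwidth
  counts <- numeric(width)
  nvalid <- numeric(width)
  offs <- seq.int(-halfwidth, halfwidth - 1L)
  cov <- list()
  for (ch in unique(anchors$chrom)) {
    L <- lens[[ch]]
    hh <- hits[hits$chrom == ch, , drop = FALSE]
    if (nrow(hh)) {
      if (mode == "coverage") {
        s <- pmax(hh$start, 0) + 1L
        e <- pmin(hh$end, L) + 1L
        keep <- s < e
        d <- tabulate(s[keep], nbins = L + 1L) - tabulate(e[keep], nbins = L + 1L)
        cov[[ch]] <- cumsum(d)[seq_len(L)]
      } else {
        mid <- pmin(pmax(floor((hh$start + hh$end) / 2), 0), L - 1)
        cov[[ch]] <- numeric(L)
        tb <- table(mid + 1L)
        cov[[ch]][as.integer(names(tb))] <- as.numeric(tb)
      }
    } else {
      cov[[ch]] <- numeric(L)
    }
  }
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    L <- lens[[ch]]
    tss <- anchors$tss[i]
    pos <- if (anchors$strand[i] == "+") tss + offs else tss - offs
    valid <- pos >= 0 & pos < L
    idx <- which(valid)
    counts[idx] <- counts[idx] + cov[[ch]][pos[idx] + 1L]
    nvalid[idx] <- nvalid[idx] + 1
  }
  list(counts = counts, nvalid = nvalid)
}

hit_density <- function(hits, g, mode) {
  lens <- genome_lengths(g)
  if (!nrow(hits)) return(0)
  if (mode == "coverage") {
    clipped <- pmin(hits$end, lens[hits$chrom]) - pmax(hits$start, 0)
    sum(pmax(clipped, 0)) / sum(lens)
  } else {
    nrow(hits) / sum(lens)
  }
}

#' TSS-centered profile of G4 motifs with strand filtering
#'
#' Motif spans are treated as hits; `strand_mode` selects which motif
#' strand counts at each anchor: `"both"` keeps all motifs,
#' `"nontemplate"` keeps motifs on the anchor gene's own strand (the
#' displaced, non-template strand of transcription), `"template"` the
#' opposite strand. Under strand filtering each anchor-strand group is
#' normalized by its own motif density and the groups are combined
#' weighted by anchor count, so a uniform motif set still profiles at 1.
#'
#' @param motifs Output of [scan_g4_genome] (needs a `chrom` column).
#' @param anchors,g,halfwidth As in [composite_profile].
#' @param strand_mode `"both"`, `"template"` or `"nontemplate"`.
#' @return A `"composite_profile"`.
#' @export
profile_g4 <- function(motifs, anchors, g, halfwidth = 3000L,
                       strand_mode = c("both", "template", "nontemplate")) {
  strand_mode <- match.arg(strand_mode)
  hits_all <- g4_to_intervals(motifs)
  if (strand_mode == "both") {
    return(composite_profile(hits_all, anchors, g, halfwidth))
  }
  width <- 2L * halfwidth
  counts <- numeric(width)       # raw hit-base counts
  norm_counts <- numeric(width)  # density-normalized numerator
  nvalid <- numeric(width)
  n_total <- nrow(anchors)
  for (anchor_strand in c("+", "-")) {
    an <- anchors[anchors$strand == anchor_strand, , drop = FALSE]
    if (!nrow(an)) next
    motif_strand <- if (strand_mode == "nontemplate") anchor_strand else
      setdiff(c("+", "-"), anchor_strand)
    hh <- hits_all[hits_all$strand == motif_strand, , drop = FALSE]
    density <- hit_density(hh, g, "coverage")
    if (density == 0) {
      warning("no ", motif_strand, " strand motifs; skipping ",
              anchor_strand, " strand anchors")
      next
    }
    core <- profile_core(hh, an, g, halfwidth)
    counts <- counts + core$counts
    norm_counts <- norm_counts + core$counts / density
    nvalid <- nvalid + core$nvalid
  }
  values <- ifelse(nvalid > 0, norm_counts / nvalid, NA_real_)
  out <- list(
    offset = seq.int(-halfwidth, halfwidth - 1L),
    values = values,
    counts = counts,
    nvalid = nvalid,
    n_regions = n_total,
    genome_density = NA_real_,
    halfwidth = halfwidth,
    mode = "coverage"
  )
  class(out) <- "composite_profile"
  out
}

#' Smooth a composite profile with a centered moving average
#'
#' @param p A `"composite_profile"`.
#' @param width Odd window width in bp (default 51).
#' @return The profile with smoothed `values` (edges become `NA`).
#' @export
smooth_profile <- function(p, width = 51L) {
  stopifnot(inherits(p, "composite_profile"), width %% 2L == 1L, width >= 1L)
  p$values <- as.numeric(stats::filter(p$values, rep(1 / width, width),
                                       sides = 2))
  p
}

#' Offset of the profile maximum
#'
#' @param p A `"composite_profile"`.
#' @return The offset (bp relative to the TSS) at which `values` attains
#'   its maximum; ties resolve to the smallest offset.
#' @export
profile_argmax <- function(p) {
  stopifnot(inherits(p, "composite_profile"))
  p$offset[which.max(p$values)]
}

#' Write a profile as a two-column table
#'
#' @param p A `"composite_profile"`.
#' @param path Output path (tab-separated `offset`, `value`).
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  utils::write.table(
    data.frame(offset = p$offset, value = p$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
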