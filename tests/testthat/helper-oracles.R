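# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (GRanges, chain DP): masks, quadratic scans and exhaustive
# enumeration only.

random_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

random_interval_set <- function(n, chroms = c("chrA", "chrB", "chrC"),
                                chrom_len = 1e5, max_len = 2000) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, chrom_len - max_len))
  len <- floor(runif(n, 1, max_len))
  gintervals(chrom, start, start + len,
             name = sprintf("iv%04d", seq_len(n)),
             score = round(runif(n, 0, 20), 2),
             strand = sample(c("+", "-", "."), n, replace = TRUE))
}

# Per-base boolean mask: distinct covered bases per chromosome.
oracle_covered_bases <- function(x, chrom_len) {
  total <- 0
  for (ch in unique(x$chrom)) {
    mask <- logical(chrom_len)
    xx <- x[x$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(xx))) {
      mask[(xx$start[i] + 1):xx$end[i]] <- TRUE
    }
    total <- total + sum(mask)
  }
  total
}

# Quadratic all-pairs overlap scan.
oracle_intersect <- function(a, b, min_overlap = 1) {
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) {
        rows[[length(rows) + 1L]] <- c(i, j, ov)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(a = integer(), b = integer(), overlap = numeric()))
  }
  m <- do.call(rbind, rows)
  out <- data.frame(a = m[, 1], b = m[, 2], overlap = m[, 3])
  out[order(out$a, out$b), , drop = FALSE]
}

# --- G4 oracle -------------------------------------------------------------
# All 0-based starts of exactly-len runs of `ch` found by direct substring
# comparison (no regex).
oracle_tract_starts <- function(seq, ch = "G", len = 3) {
  run <- strrep(ch, len)
  n <- nchar(seq)
  if (n < len) return(numeric())
  idx <- seq_len(n - len + 1L)
  which(substring(seq, idx, idx + len - 1L) == run) - 1
}

# Exhaustive enumeration of every admissible tract quadruple (n_tracts
# generalized) by nested expansion; returns a data.frame of tract-start
# combinations sorted lexicographically.
oracle_g4_all_onestrand <- function(seq, ch = "G", tract_len = 3,
                                    n_tracts = 4, loop_min = 1, loop_max = 7) {
  tp <- oracle_tract_starts(seq, ch, tract_len)
  combos <- lapply(tp, function(p) p)
  for (k in seq_len(n_tracts - 1L)) {
    nxt <- list()
    for (cmb in combos) {
      last <- cmb[length(cmb)]
      succ <- tp[tp >= last + tract_len + loop_min &
                   tp <= last + tract_len + loop_max]
      for (s in succ) nxt[[length(nxt) + 1L]] <- c(cmb, s)
    }
    combos <- nxt
  }
  if (!length(combos)) {
    return(matrix(numeric(), ncol = n_tracts))
  }
  m <- do.call(rbind, combos)
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# Greedy leftmost-first selection on top of the exhaustive set: repeatedly
# take the lexicographically smallest admissible combination starting at or
# after the cursor.
oracle_g4_greedy_onestrand <- function(seq, ch = "G", tract_len = 3,
                                       n_tracts = 4, loop_min = 1,
                                       loop_max = 7) {
  all <- oracle_g4_all_onestrand(seq, ch, tract_len, n_tracts,
                                 loop_min, loop_max)
  picked <- list()
  cursor <- 0
  while (nrow(all)) {
    ok <- all[, 1] >= cursor
    if (!any(ok)) break
    row <- all[which(ok)[1L], ]
    picked[[length(picked) + 1L]] <- row
    cursor <- row[n_tracts] + tract_len
  }
  if (!length(picked)) matrix(numeric(), ncol = n_tracts) else do.call(rbind, picked)
}

# Full two-strand oracle mirroring the scan_g4 output columns. Minus-strand
# motifs come from the G-pattern on the reverse complement, coordinates
# reflected (the definition that makes greedy scanning strand-symmetric).
oracle_rc <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

oracle_scan_g4 <- function(seq, tract_len = 3, n_tracts = 4, loop_min = 1,
                           loop_max = 7, policy = "greedy_nonoverlapping") {
  fn <- if (policy == "greedy_nonoverlapping") {
    oracle_g4_greedy_onestrand
  } else {
    oracle_g4_all_onestrand
  }
  L <- nchar(seq)
  plus <- fn(seq, "G", tract_len, n_tracts, loop_min, loop_max)
  minus_rc <- fn(oracle_rc(seq), "G", tract_len, n_tracts, loop_min, loop_max)
  rows <- list()
  if (nrow(plus)) {
    rows$p <- data.frame(
      start = plus[, 1], end = plus[, n_tracts] + tract_len, strand = "+",
      tract_starts = apply(plus, 1, paste, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(minus_rc)) {
    fwd <- t(apply(minus_rc, 1, function(p) sort(L - p - tract_len)))
    rows$m <- data.frame(
      start = fwd[, 1], end = fwd[, n_tracts] + tract_len, strand = "-",
      tract_starts = apply(fwd, 1, paste, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(start = numeric(), end = numeric(), strand = character(),
               tract_starts = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# Canonical comparable form of a scan_g4 result.
g4_key <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(df$strand, df$tract_starts, sep = ":"))
}

# Direct per-anchor, per-hit scan of in-window hit-base totals (profile
# conservation oracle; no coverage vectors).
oracle_window_hit_bases <- function(hits, anchors, chrom_len, halfwidth) {
  total <- 0
  for (i in seq_len(nrow(anchors))) {
    tss <- anchors$tss[i]
    if (anchors$strand[i] == "+") {
      lo <- tss - halfwidth; hi <- tss + halfwidth
    } else {
      lo <- tss - halfwidth + 1; hi <- tss + halfwidth + 1
    }
    lo <- max(lo, 0); hi <- min(hi, chrom_len[[anchors$chrom[i]]])
    hh <- hits[hits$chrom == anchors$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(hh))) {
      total <- total + max(0, min(hh$end[j], hi) - max(hh$start[j], lo))
    }
  }
  total
}

# All-pairs TSS <-> CpG-island association oracle (nearest island within
# max_distance, ties leftmost), mirroring the documented distance rule.
oracle_promoter_universe <- function(genes, cgis, max_distance = 0) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    if (!genes$strand[i] %in% c("+", "-")) next
    tss <- if (genes$strand[i] == "+") genes$start[i] else genes$end[i] - 1
    best <- NULL
    for (j in seq_len(nrow(cgis))) {
      if (cgis$chrom[j] != genes$chrom[i]) next
      d <- if (tss < cgis$start[j]) {
        cgis$start[j] - tss
      } else if (tss >= cgis$end[j]) {
        tss - cgis$end[j] + 1
      } else {
        0
      }
      if (d > max_distance) next
      cand <- c(d, cgis$start[j], cgis$end[j], j)
      if (is.null(best) || cand[1] < best[1] ||
          (cand[1] == best[1] && (cand[2] < best[2] ||
                                  (cand[2] == best[2] && cand[3] < best[3])))) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = i, tss = tss, cgi = best[4], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = integer(), tss = numeric(), cgi = integer()))
  }
  do.call(rbind, rows)
}
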