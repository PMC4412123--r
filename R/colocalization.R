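#' Build the CpG-island-origin set
#'
#' Origins are defined as promoters positive for BOTH short-nascent-strand
#' (SNS) peaks and ORC1 binding under the chosen association geometry —
#' the intersection of two independent origin-mapping assays.
#'
#' @param universe A `"promoter_universe"` (must be non-empty).
#' @param sns,orc1 Peak tables ([gintervals]).
#' @param mode,upstream Association geometry, see
#'   [associate_peaks_to_promoters].
#' @return A list of class `"origin_set"`: `records` (universe rows
#'   positive for both), `sns_pos`/`orc1_pos` (logical vectors over the
#'   universe), and `counts` = `(n_universe, n_sns, n_orc1, n_both)`.
#' @export
build_origin_set <- function(universe, sns, orc1,
                             mode = c("cgi_overlap", "upstream_window"),
                             upstream = 1000) {
  mode <- match.arg(mode)
  stopifnot(inherits(universe, "promoter_universe"))
  if (!nrow(universe)) stop("empty promoter universe")
  sns_pos <- promoter_positive(sns, universe, mode, upstream)
  orc1_pos <- promoter_positive(orc1, universe, mode, upstream)
  both <- sns_pos & orc1_pos
  out <- list(
    records = universe[both, , drop = FALSE],
    sns_pos = sns_pos,
    orc1_pos = orc1_pos,
    counts = c(n_universe = nrow(universe), n_sns = sum(sns_pos),
               n_orc1 = sum(orc1_pos), n_both = sum(both)),
    mode = mode, upstream = upstream
  )
  class(out) <- "origin_set"
  out
}

#' Observed co-occurrence of a query promoter set with a target
#'
#' Counts how many promoters in the query set (e.g. CpG islands with
#' R-loop/DRIP peaks) are also positive for the target (e.g. ORC1
#' binding or origin-set membership). Counting is at island/promoter
#' granularity: a promoter counts once however many peaks it holds.
#'
#' @param query Logical vector over the universe (the query set), with at
#'   least one `TRUE`.
#' @param target Logical vector over the universe (target positivity).
#' @return A list `(n_query, n_hit, observed_fraction)`.
#' @export
coloc_observed <- function(query, target) {
  stopifnot(is.logical(query), is.logical(target), length(query) == length(target))
  n_query <- sum(query)
  if (n_query == 0L) stop("empty query set")
  n_hit <- sum(query & target)
  list(n_query = n_query, n_hit = n_hit, observed_fraction = n_hit / n_query)
}

#' Permutation null for promoter-level co-localization
#'
#' The primary null model: each permutation draws `query_size` promoters
#' uniformly without replacement from the universe and records the
#' target-positive fraction, making "expected by chance" explicit as the
#' mean target rate of random promoter sets of the same size. The
#' empirical p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`, so it is never zero.
#'
#' @param query Logical query-set indicator over the universe.
#' @param target Logical target indicator over the universe.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (required for reproducibility).
#' @return A list of class `"coloc_result"`: `n_query`, `n_hit`,
#'   `observed_fraction`, `null_fractions`, `expected_fraction`,
#'   `empirical_p`, `fold` (`NA` when the expected fraction is 0),
#'   `n_perm`, `seed`, `null_type = "permute"`.
#' @export
coloc_permutation <- function(query, target, n_perm = 1000L, seed) {
  stopifnot(n_perm >= 1L)
  obs <- coloc_observed(query, target)
  n <- length(target)
  k <- obs$n_query
  stopifnot(k <= n)
  null_frac <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(target[sample.int(n, k)]) / k,
           0)
  })
  finish_coloc(obs, null_frac, n_perm, seed, "permute")
}

finish_coloc <- function(obs, null_frac, n_perm, seed, null_type) {
  expected <- mean(null_frac)
  res <- list(
    n_query = obs$n_query,
    n_hit = obs$n_hit,
    observed_fraction = obs$observed_fraction,
    null_fractions = null_frac,
    expected_fraction = expected,
    empirical_p = (1 + sum(null_frac >= obs$observed_fraction)) / (n_perm + 1),
    fold = if (expected > 0) obs$observed_fraction / expected else NA_real_,
    n_perm = n_perm,
    seed = seed,
    null_type = null_type
  )
  class(res) <- "coloc_result"
  res
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "co-localization (%s null): %d/%d = %.1f%% observed vs %.1f%% expected (fold %s, p = %.4g, %d perms, seed %s)\n",
    x$null_type, x$n_hit, x$n_query, 100 * x$observed_fraction,
    100 * x$expected_fraction,
    ifelse(is.na(x$fold), "NA", sprintf("%.2f", x$fold)),
    x$empirical_p, x$n_perm, format(x$seed)))
  invisible(x)
}

#' Randomly re-place intervals on their chromosomes
#'
#' A bedtools-shuffle-like randomization: every interval is moved to a
#' uniformly random position on its own chromosome, preserving its
#' length and avoiding `excluded` regions (rejection sampling with
#' `max_tries` attempts per interval).
#'
#' @param peaks A [gintervals] table.
#' @param g A [genome].
#' @param excluded Optional [gintervals] of forbidden regions.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap per interval (default 1000).
#' @return A [gintervals] table of shuffled peaks (name/score/strand
#'   preserved).
#' @export
shuffle_intervals <- function(peaks, g, excluded = NULL, seed = NULL,
                              max_tries = 1000L) {
  validate_intervals(peaks, g)
  lens <- genome_lengths(g)
  excl <- if (!is.null(excluded) && nrow(excluded)) merge_intervals(excluded) else NULL
  with_seed(seed, {
    new_start <- numeric(nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      w <- peaks$end[i] - peaks$start[i]
      L <- lens[[peaks$chrom[i]]]
      if (w > L) stop("interval longer than its chromosome")
      ex <- if (!is.null(excl)) excl[excl$chrom == peaks$chrom[i], , drop = FALSE] else NULL
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        s <- floor(stats::runif(1, min = 0, max = L - w + 1))
        if (s > L - w) s <- L - w  # guard the runif right edge
        if (is.null(ex) || !nrow(ex) ||
            !any(pmin(ex$end, s + w) - pmax(ex$start, s) > 0)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place interval ", i, " after ", max_tries, " tries")
      new_start[i] <- s
    }
    out <- peaks
    out$start <- new_start
    out$end <- new_start + (peaks$end - peaks$start)
    out
  })
}

#' Genomic-shuffling null for co-localization
#'
#' Sensitivity-check null: instead of permuting promoter labels, each
#' permutation re-places the target peak set at random genomic positions
#' ([shuffle_intervals]) and recomputes the fraction of query promoters
#' that are target-positive under the same association geometry.
#'
#' @param query Logical query indicator over `universe` rows.
#' @param universe A `"promoter_universe"`.
#' @param target_peaks The target peak set ([gintervals]).
#' @param g A [genome].
#' @param excluded Optional excluded regions for the shuffle.
#' @param mode,upstream Association geometry.
#' @param n_perm Number of shuffles (default 200; each shuffle pays a
#'   full re-association, so the default is smaller than for label
#'   permutation).
#' @param seed Integer seed.
#' @return A `"coloc_result"` with `null_type = "shuffle"`.
#' @export
coloc_shuffle <- function(query, universe, target_peaks, g, excluded = NULL,
                          mode = c("cgi_overlap", "upstream_window"),
                          upstream = 1000, n_perm = 200L, seed) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1L)
  target <- promoter_positive(target_peaks, universe, mode, upstream)
  obs <- coloc_observed(query, target)
  null_frac <- vapply(seq_len(n_perm), function(i) {
    shuf <- shuffle_intervals(target_peaks, g, excluded,
                              seed = child_seed(seed, i))
    tgt <- promoter_positive(shuf, universe, mode, upstream)
    sum(query & tgt) / obs$n_query
  }, 0)
  finish_coloc(obs, null_frac, n_perm, seed, "shuffle")
}
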