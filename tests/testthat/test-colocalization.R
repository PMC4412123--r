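test_that("origin set is the SNS AND ORC1 intersection", {
  u <- make_universe(c(5000, 15000, 25000, 35000), rep("+", 4),
                     c(4400, 14400, 24400, 34400),
                     c(5600, 15600, 25600, 35600))
  peak_at <- function(idx) {
    gintervals("chr1", u$tss[idx] - 200, u$tss[idx] + 200)
  }
  sns <- peak_at(1:3)
  orc1 <- peak_at(2:4)
  os <- build_origin_set(u, sns, orc1)
  expect_equal(unname(os$counts), c(4, 3, 3, 2))
  expect_equal(sort(os$records$gene_id), sort(u$gene_id[2:3]))

  # disjoint assays: empty origin set
  os2 <- build_origin_set(u, peak_at(1), peak_at(4))
  expect_equal(os2$counts[["n_both"]], 0)
  expect_equal(nrow(os2$records), 0L)
  expect_error(build_origin_set(empty_universe_for_test(), sns, orc1), "empty")
})

empty_universe_for_test <- function() {
  u <- make_universe(5000, "+", 4400, 5600)
  u[0, , drop = FALSE]
}

test_that("observed fractions and degenerate nulls behave", {
  expect_equal(
    coloc_observed(c(rep(TRUE, 10), rep(FALSE, 5)),
                   c(rep(TRUE, 3), rep(FALSE, 12)))$observed_fraction,
    0.3
  )
  expect_error(coloc_observed(rep(FALSE, 5), rep(TRUE, 5)), "empty query")

  # saturated target: every null fraction 1, p = 1
  q <- c(rep(TRUE, 5), rep(FALSE, 15))
  res <- coloc_permutation(q, rep(TRUE, 20), n_perm = 50, seed = 1)
  expect_equal(res$observed_fraction, 1)
  expect_true(all(res$null_fractions == 1))
  expect_equal(res$empirical_p, 1)

  # empty target: expected 0, fold reported as missing
  res0 <- coloc_permutation(q, rep(FALSE, 20), n_perm = 50, seed = 1)
  expect_equal(res0$expected_fraction, 0)
  expect_true(is.na(res0$fold))
  expect_equal(res0$observed_fraction, 0)
})

test_that("permutation null is deterministic given seed and p is valid", {
  q <- c(rep(TRUE, 30), rep(FALSE, 70))
  t <- rep(c(TRUE, FALSE), c(20, 80))[sample.int(100)]
  r1 <- coloc_permutation(q, t, n_perm = 200, seed = 99)
  r2 <- coloc_permutation(q, t, n_perm = 200, seed = 99)
  expect_identical(r1$null_fractions, r2$null_fractions)
  expect_gte(r1$empirical_p, 1 / 201)
  expect_lte(r1$empirical_p, 1)
  expect_equal(r1$expected_fraction, mean(r1$null_fractions))
})

test_that("expected fraction estimates the target rate (small calibration)", {
  set.seed(8)
  target <- logical(500); target[sample.int(500, 100)] <- TRUE  # rate 0.2
  q <- logical(500); q[sample.int(500, 50)] <- TRUE
  res <- coloc_permutation(q, target, n_perm = 1000, seed = 17)
  expect_lt(abs(res$expected_fraction - 0.2), 0.02)
})

test_that("shuffle preserves lengths, chromosome and exclusions", {
  g <- genome(c(chrS = random_dna(10000)))
  pk <- gintervals("chrS", c(0, 4000), c(2500, 6000), name = c("a", "b"))
  sh <- shuffle_intervals(pk, g, seed = 4)
  expect_equal(sh$end - sh$start, pk$end - pk$start)
  expect_equal(sh$chrom, pk$chrom)
  expect_true(all(sh$start >= 0 & sh$end <= 10000))

  # a 1 kb peak on a 10 kb chromosome with 5 kb excluded never lands on it
  excl <- gintervals("chrS", 2500, 7500)
  one <- gintervals("chrS", 0, 1000)
  for (s in 1:200) {
    sh <- shuffle_intervals(one, g, excluded = excl, seed = s)
    expect_lte(max(0, min(sh$end, 7500) - max(sh$start, 2500)), 0)
  }
  # infeasible: exclusion covers everything
  expect_error(
    shuffle_intervals(one, g, excluded = gintervals("chrS", 0, 10000),
                      seed = 1, max_tries = 50),
    "could not place"
  )
})

test_that("peak-set load order does not change co-occurrence counts", {
  set.seed(44)
  u <- make_universe(seq(5000, 95000, by = 3000),
                     sample(c("+", "-"), 31, TRUE),
                     seq(5000, 95000, by = 3000) - 600,
                     seq(5000, 95000, by = 3000) + 600)
  pk <- random_interval_set(60, chroms = "chr1", chrom_len = 1e5)
  shuffled <- pk[sample.int(nrow(pk)), , drop = FALSE]
  expect_equal(sum(promoter_positive(pk, u)),
               sum(promoter_positive(shuffled, u)))
})

test_that("shuffle and permutation nulls agree on an unstructured genome", {
  set.seed(66)
  g <- genome(c(chr1 = random_dna(2e5)))
  tss <- seq(5000, 195000, by = 5000)
  n <- length(tss)
  u <- make_universe(tss, rep("+", n), tss - 500, tss + 500)
  # unstructured target peaks: uniform positions
  tstart <- floor(runif(40, 0, 2e5 - 400))
  target_peaks <- gintervals("chr1", tstart, tstart + 400)
  query <- logical(n); query[sample.int(n, 15)] <- TRUE
  target <- promoter_positive(target_peaks, u)
  rp <- coloc_permutation(query, target, n_perm = 400, seed = 5)
  rs <- coloc_shuffle(query, u, target_peaks, g, n_perm = 150, seed = 6)
  # error budget: MC error of both null means plus the binomial error of
  # the one realized target draw the permutation null conditions on
  p <- mean(target)
  se <- sqrt(stats::var(rp$null_fractions) / rp$n_perm +
               stats::var(rs$null_fractions) / rs$n_perm +
               p * (1 - p) / n)
  expect_lt(abs(rp$expected_fraction - rs$expected_fraction), 2 * se)
})
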