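toy_genome <- function(len = 20000, chrom = "chr1") {
  g <- stats::setNames(strrep("A", len), chrom)
  genome(g)
}

test_that("single hit at the TSS lands at the right offsets on both strands", {
  g <- toy_genome()
  hit <- gintervals("chr1", 10000, 10010)
  anch_p <- data.frame(chrom = "chr1", tss = 10000, strand = "+")
  p <- composite_profile(hit, anch_p, g, halfwidth = 100)
  expect_equal(p$counts[p$offset %in% 0:9], rep(1, 10))
  expect_equal(sum(p$counts), 10)

  anch_m <- data.frame(chrom = "chr1", tss = 10000, strand = "-")
  pm <- composite_profile(hit, anch_m, g, halfwidth = 100)
  expect_equal(pm$counts[pm$offset %in% -9:0], rep(1, 10))
  expect_equal(sum(pm$counts), 10)
})

test_that("hits tiling the genome normalize to exactly 1 everywhere", {
  g <- toy_genome(5000)
  tile <- gintervals("chr1", seq(0, 4900, by = 100), seq(100, 5000, by = 100))
  anch <- data.frame(chrom = "chr1", tss = c(1000, 2500), strand = c("+", "-"))
  p <- composite_profile(tile, anch, g, halfwidth = 500)
  expect_equal(unique(p$values), 1)
})

test_that("window truncation drops out-of-chromosome positions from both sums", {
  g <- toy_genome(1000)
  hit <- gintervals("chr1", 0, 1000)  # full coverage
  anch <- data.frame(chrom = "chr1", tss = 50, strand = "+")
  p <- composite_profile(hit, anch, g, halfwidth = 200)
  expect_true(all(is.na(p$values[p$offset < -50])))
  expect_equal(unique(p$values[p$offset >= -50]), 1)
  expect_equal(unname(p$nvalid[p$offset < -50]), rep(0, 150))
})

test_that("unnormalized counts conserve total in-window hit bases (oracle)", {
  set.seed(12)
  g <- toy_genome(50000)
  hs <- floor(runif(200, 0, 49800))
  hits <- gintervals("chr1", hs, hs + floor(runif(200, 1, 200)))
  anch <- data.frame(chrom = "chr1",
                     tss = sample(seq(500, 49500, by = 37), 40),
                     strand = sample(c("+", "-"), 40, TRUE))
  p <- composite_profile(hits, anch, g, halfwidth = 400)
  expect_equal(sum(p$counts),
               oracle_window_hit_bases(hits, anch, genome_lengths(g), 400))
})

test_that("reflection invariance: flipping genome and strands preserves profile", {
  set.seed(18)
  L <- 30000
  g <- toy_genome(L)
  hs <- floor(runif(100, 0, L - 300))
  hits <- gintervals("chr1", hs, hs + floor(runif(100, 50, 300)))
  anch <- data.frame(chrom = "chr1", tss = c(8000, 15000, 22000),
                     strand = c("+", "-", "+"))
  p1 <- composite_profile(hits, anch, g, halfwidth = 1000)
  # reflect everything: position x -> L - 1 - x
  hits_r <- gintervals("chr1", L - hits$end, L - hits$start)
  anch_r <- data.frame(chrom = "chr1", tss = L - 1 - anch$tss,
                       strand = chartr("+-", "-+", anch$strand))
  p2 <- composite_profile(hits_r, anch_r, g, halfwidth = 1000)
  expect_equal(p1$values, p2$values)
})

test_that("uniform random hits profile to ~1 (Monte-Carlo null)", {
  set.seed(99)
  L <- 1e6
  g <- toy_genome(L)
  hs <- floor(runif(2000, 0, L - 100))
  hits <- gintervals("chr1", hs, hs + 100)
  anch <- data.frame(chrom = "chr1",
                     tss = sample(seq(5000, L - 5000, by = 101), 100),
                     strand = sample(c("+", "-"), 100, TRUE))
  p <- composite_profile(hits, anch, g, halfwidth = 1000)
  m <- mean(p$values)
  n_eff <- sum(p$counts) / 100  # hits contributing, each ~100 bases
  expect_lt(abs(m - 1), 3 / sqrt(n_eff))
})

test_that("midpoint mode counts one base per hit", {
  g <- toy_genome(2000)
  hit <- gintervals("chr1", c(900, 1100), c(1000, 1200))
  anch <- data.frame(chrom = "chr1", tss = 1000, strand = "+")
  p <- composite_profile(hit, anch, g, halfwidth = 500, mode = "midpoint")
  expect_equal(sum(p$counts), 2)
  expect_equal(p$counts[p$offset %in% c(-50, 150)], c(1, 1))
})

test_that("profile_g4 strand modes filter motifs relative to the gene", {
  g <- toy_genome(20000)
  motifs <- data.frame(chrom = "chr1", start = 9900, end = 9915, strand = "+")
  anch_p <- data.frame(chrom = "chr1", tss = 10000, strand = "+")
  # nontemplate: motif strand equals gene strand -> counted at -100..-86
  p <- profile_g4(motifs, anch_p, g, halfwidth = 200,
                  strand_mode = "nontemplate")
  expect_true(all(p$counts[p$offset %in% -100:-86] == 1))
  expect_equal(sum(p$counts), 15)
  # template mode: excluded (no opposite-strand motifs at all)
  expect_warning(
    pt <- profile_g4(motifs, anch_p, g, halfwidth = 200,
                     strand_mode = "template"),
    "no . strand motifs"
  )
  expect_equal(sum(pt$counts), 0)
  # both: same counts as nontemplate here
  pb <- profile_g4(motifs, anch_p, g, halfwidth = 200, strand_mode = "both")
  expect_equal(sum(pb$counts), 15)
})

test_that("smoothing and argmax behave", {
  g <- toy_genome(4000)
  hit <- gintervals("chr1", 1950, 1960)
  anch <- data.frame(chrom = "chr1", tss = 2000, strand = "+")
  p <- composite_profile(hit, anch, g, halfwidth = 300)
  expect_equal(profile_argmax(p), -50)
  sm <- smooth_profile(p, 11)
  expect_equal(length(sm$values), length(p$values))
  expect_error(smooth_profile(p, 10), "width")
})
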