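test_that("TSS derivation and containment association", {
  genes <- gintervals("chr1", 1000, 5000, name = "gA", strand = "+")
  cgis <- gintervals("chr1", 800, 1400)
  u <- build_promoter_universe(genes, cgis, max_distance = 0)
  expect_equal(nrow(u), 1L)
  expect_equal(u$tss, 1000)
  expect_equal(c(u$cgi_start, u$cgi_end), c(800, 1400))

  # minus strand: TSS = end - 1
  genes <- gintervals("chr1", 1000, 5000, name = "gB", strand = "-")
  cgis <- gintervals("chr1", 4800, 5200)
  u <- build_promoter_universe(genes, cgis)
  expect_equal(u$tss, 4999)
  expect_equal(u$gene_id, "gB")

  # TSS outside island, max_distance 0: no association
  cgis <- gintervals("chr1", 5100, 5400)
  expect_equal(nrow(build_promoter_universe(genes, cgis, 0)), 0L)
  # ... but reachable with max_distance
  expect_equal(nrow(build_promoter_universe(genes, cgis, 200)), 1L)
})

test_that("unstranded genes are rejected with a warning", {
  genes <- gintervals("chr1", c(100, 500), c(400, 900),
                      name = c("a", "b"), strand = c("+", "."))
  cgis <- gintervals("chr1", 0, 1000)
  expect_warning(u <- build_promoter_universe(genes, cgis), "unstranded")
  expect_equal(u$gene_id, "a")
})

test_that("universe construction matches the all-pairs distance oracle", {
  set.seed(31)
  for (rep in 1:5) {
    genes <- random_interval_set(50, chroms = "chrT", chrom_len = 5e4,
                                 max_len = 5000)
    genes$strand[genes$strand == "."] <- "+"
    cgis <- random_interval_set(30, chroms = "chrT", chrom_len = 5e4,
                                max_len = 1500)
    cgis$strand <- "."
    for (md in c(0, 250)) {
      u <- build_promoter_universe(genes, cgis, md)
      o <- oracle_promoter_universe(genes, cgis, md)
      expect_equal(nrow(u), nrow(o))
      key_u <- sort(paste(u$tss, u$cgi_start, u$cgi_end))
      key_o <- sort(paste(o$tss, cgis$start[o$cgi], cgis$end[o$cgi]))
      expect_identical(key_u, key_o)
    }
  }
})

test_that("peak association honors both geometries and orientation", {
  u <- make_universe(5000, "+", 4500, 5600)
  pk <- gintervals("chr1", 4200, 4600)
  # upstream window [4000, 5000): associated
  expect_true(promoter_positive(pk, u, "upstream_window", 1000))
  # island [4500, 5600): also overlaps
  expect_true(promoter_positive(pk, u, "cgi_overlap"))
  pk2 <- gintervals("chr1", 5700, 5900)
  expect_false(promoter_positive(pk2, u, "cgi_overlap"))
  expect_false(promoter_positive(pk2, u, "upstream_window", 1000))

  # minus strand: upstream is rightward, [tss+1, tss+1+upstream)
  um <- make_universe(5000, "-", 4500, 5600)
  pk3 <- gintervals("chr1", 5200, 5600)
  expect_true(promoter_positive(pk3, um, "upstream_window", 1000))
  pk4 <- gintervals("chr1", 4200, 4600)
  expect_false(promoter_positive(pk4, um, "upstream_window", 1000))
})

test_that("association matches a quadratic oracle and is monotone in upstream", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 30
    tss <- sort(sample(seq(5000, 95000, by = 50), n))
    strand <- sample(c("+", "-"), n, TRUE)
    u <- make_universe(tss, strand, tss - 600, tss + 600)
    peaks <- random_interval_set(100, chroms = "chr1", chrom_len = 1e5,
                                 max_len = 800)
    for (mode in c("cgi_overlap", "upstream_window")) {
      assoc <- associate_peaks_to_promoters(peaks, u, mode, upstream = 500)
      # re-check every reported pair against the stated geometric predicate
      for (r in seq_len(nrow(assoc))) {
        i <- assoc$promoter[r]; j <- assoc$peak[r]
        if (mode == "cgi_overlap") {
          lo <- u$cgi_start[i]; hi <- u$cgi_end[i]
        } else if (u$strand[i] == "+") {
          lo <- u$tss[i] - 500; hi <- u$tss[i]
        } else {
          lo <- u$tss[i] + 1; hi <- u$tss[i] + 501
        }
        expect_true(min(peaks$end[j], hi) - max(peaks$start[j], lo) >= 1)
      }
      # exhaustive count cross-check
      n_pairs <- 0
      for (i in seq_len(nrow(u))) {
        for (j in seq_len(nrow(peaks))) {
          if (peaks$chrom[j] != u$chrom[i]) next
          if (mode == "cgi_overlap") {
            lo <- u$cgi_start[i]; hi <- u$cgi_end[i]
          } else if (u$strand[i] == "+") {
            lo <- u$tss[i] - 500; hi <- u$tss[i]
          } else {
            lo <- u$tss[i] + 1; hi <- u$tss[i] + 501
          }
          if (min(peaks$end[j], hi) - max(peaks$start[j], lo) >= 1) {
            n_pairs <- n_pairs + 1
          }
        }
      }
      expect_equal(nrow(assoc), n_pairs)
    }
    # doubling upstream never loses associations
    a1 <- nrow(associate_peaks_to_promoters(peaks, u, "upstream_window", 500))
    a2 <- nrow(associate_peaks_to_promoters(peaks, u, "upstream_window", 1000))
    expect_gte(a2, a1)
  }
})

test_that("flag_gc_skew flags G-biased promoter footprints strand-awarely", {
  set.seed(21)
  # + promoter with G-rich downstream footprint; - promoter with C-rich
  # (forward) footprint, i.e. G-rich on its own non-template strand
  fp_plus <- random_dna(1000, c(0.25, 0.1, 0.4, 0.25))
  fp_minus <- random_dna(1000, c(0.25, 0.4, 0.1, 0.25))
  neutral <- random_dna(3000)
  seq1 <- paste0(neutral, fp_plus, random_dna(2000), fp_minus, neutral)
  g <- genome(c(chr1 = seq1))
  # tss of + gene at 3000 (footprint [3000,4000)); tss of - gene at 6999
  genes <- gintervals("chr1", c(3000, 4000), c(6000, 7000),
                      name = c("gp", "gm"), strand = c("+", "-"))
  cgis <- gintervals("chr1", c(2800, 6800), c(3400, 7200))
  u <- build_promoter_universe(genes, cgis)
  u <- flag_gc_skew(u, g)
  expect_identical(u$gc_skewed[match(c("gp", "gm"), u$gene_id)], c(TRUE, TRUE))
  # a neutral promoter is not flagged
  genes2 <- gintervals("chr1", 500, 2500, name = "gn", strand = "+")
  cgis2 <- gintervals("chr1", 300, 900)
  u2 <- flag_gc_skew(build_promoter_universe(genes2, cgis2), g)
  expect_false(u2$gc_skewed)
})
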