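#' Simulation configuration
#'
#' Describes the synthetic world the generator emits: a toy genome whose
#' CpG island promoters carry a positively GC-skewed ~1 kb footprint on
#' the non-template strand, G4 motifs concentrated upstream of the TSS,
#' and three peak sets (DRIP, ORC1, SNS) whose promoter-level
#' co-positivity follows configurable marginal and conditional
#' probabilities. Identical config + seed gives byte-identical output.
#'
#' The default co-localization block mirrors the structure of the real
#' analysis this package emulates: roughly 16% of promoters R-loop
#' positive, an ORC1 marginal of 6% (the "expected by chance" baseline),
#' and a conditional P(ORC1 | DRIP) of 30%; 75% of promoters are
#' GC-skewed.
#'
#' @param seed Master integer seed; all randomness derives from it.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Total genes, spread evenly across chromosomes.
#' @param cgi_length CpG island width (bp), centered on the TSS.
#' @param skew_footprint Width (bp) of the G-biased footprint downstream
#'   of skewed TSSs on the non-template strand.
#' @param p_skewed Fraction of promoters carrying the skewed footprint.
#' @param base_comp,cgi_comp,skew_comp Named base probabilities
#'   (`A`,`C`,`G`,`T`) for background, CpG island and skewed-footprint
#'   sequence.
#' @param cpg_rate Extra CpG dinucleotides planted per island base.
#' @param g4_rate_upstream Mean planted G4 motifs per promoter in the
#'   1 kb upstream of the TSS (Poisson).
#' @param g4_rate_background Mean background G4 motifs per Mb.
#' @param g4_offset_mean,g4_offset_sd Oriented offset (bp, negative =
#'   upstream) distribution of planted upstream motifs.
#' @param coloc List of promoter-label probabilities: `p_drip`, `p_orc1`,
#'   `p_sns` (marginals) and optional `p_orc1_given_drip`,
#'   `p_sns_given_orc1` (conditionals; marginals are preserved by
#'   adjusting the complementary stratum).
#' @param peak_specs Per-label list (`DRIP`, `ORC1`, `SNS`) of
#'   `length_mean`, `length_sd`, `center` (oriented bp relative to TSS),
#'   `center_sd`, `fold_meanlog`, `fold_sdlog`.
#' @param background_peaks Decoy peaks per label scattered uniformly.
#' @param background_fold_meanlog,background_fold_sdlog Decoy
#'   fold-enrichment distribution (lognormal).
#' @param restriction_site Optional recognition sequence (e.g. `"GATC"`);
#'   when set, DRIP peak boundaries are snapped outward to the nearest
#'   flanking site occurrence, emulating restriction-fragment resolution.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L,
                       chrom_length = 2e6,
                       n_genes = 300L,
                       cgi_length = 1200L,
                       skew_footprint = 1000L,
                       p_skewed = 0.75,
                       base_comp = c(A = 0.295, C = 0.205, G = 0.205, T = 0.295),
                       cgi_comp = c(A = 0.175, C = 0.325, G = 0.325, T = 0.175),
                       cpg_rate = 0.04,
                       skew_comp = c(A = 0.26, C = 0.14, G = 0.34, T = 0.26),
                       g4_rate_upstream = 2,
                       g4_rate_background = 5,
                       g4_offset_mean = -500,
                       g4_offset_sd = 100,
                       coloc = list(p_drip = 0.16, p_orc1 = 0.06, p_sns = 0.35,
                                    p_orc1_given_drip = 0.30,
                                    p_sns_given_orc1 = 0.85),
                       peak_specs = list(
                         DRIP = list(length_mean = 600, length_sd = 100,
                                     center = -450, center_sd = 100,
                                     fold_meanlog = log(12), fold_sdlog = 0.35),
                         ORC1 = list(length_mean = 300, length_sd = 50,
                                     center = -350, center_sd = 80,
                                     fold_meanlog = log(10), fold_sdlog = 0.35),
                         SNS = list(length_mean = 400, length_sd = 80,
                                    center = -300, center_sd = 100,
                                    fold_meanlog = log(8), fold_sdlog = 0.35)
                       ),
                       background_peaks = 150L,
                       background_fold_meanlog = log(2.5),
                       background_fold_sdlog = 0.5,
                       restriction_site = NULL) {
  cfg <- as.list(environment())
  probs <- c(p_skewed, unlist(coloc), cpg_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  for (cmp in list(base_comp, cgi_comp, skew_comp)) {
    if (!setequal(names(cmp), c("A", "C", "G", "T")) ||
        abs(sum(cmp) - 1) > 1e-8) {
      stop("base compositions need names A,C,G,T and must sum to 1")
    }
  }
  if (n_chroms < 1 || chrom_length < 1e4 || n_genes < 0 || cgi_length < 100 ||
      skew_footprint < 1) {
    stop("invalid simulation geometry")
  }
  # derived complementary-stratum rates; validated here so an infeasible
  # conditional/marginal combination fails fast
  label_rates(cfg$coloc)
  class(cfg) <- "sim_config"
  cfg
}

# Bernoulli rates per stratum implied by the coloc block.
label_rates <- function(coloc) {
  p_drip <- coloc$p_drip
  p_orc1 <- coloc$p_orc1
  p_sns <- coloc$p_sns
  orc1_given_drip <- coloc$p_orc1_given_drip %||% p_orc1
  orc1_given_nodrip <- if (p_drip < 1) {
    (p_orc1 - p_drip * orc1_given_drip) / (1 - p_drip)
  } else {
    0
  }
  sns_given_orc1 <- coloc$p_sns_given_orc1 %||% p_sns
  sns_given_noorc1 <- if (p_orc1 < 1) {
    (p_sns - p_orc1 * sns_given_orc1) / (1 - p_orc1)
  } else {
    0
  }
  rates <- c(orc1_given_drip = orc1_given_drip,
             orc1_given_nodrip = orc1_given_nodrip,
             sns_given_orc1 = sns_given_orc1,
             sns_given_noorc1 = sns_given_noorc1)
  if (any(rates < -1e-12 | rates > 1 + 1e-12)) {
    stop("conditional/marginal probabilities are inconsistent: ",
         paste(names(rates), round(rates, 4), sep = "=", collapse = ", "))
  }
  pmin(pmax(rates, 0), 1)
}

#' Simulate a toy genome with promoter structure
#'
#' Generates background sequence, places genes, overlays CpG islands on
#' each TSS, G-biases the non-template strand of the skewed footprint,
#' and plants G4 motifs (upstream of promoters at the configured rate and
#' genome-wide at the background rate). Planted motifs are flanked by
#' non-G bases and never overlap each other, so their coordinates are
#' exact ground truth for the scanner.
#'
#' @param config A [sim_config].
#' @return A list: `genome` ([genome]), `genes` ([gintervals], stranded),
#'   `cgis` ([gintervals]), `promoters` (truth table: `gene_id`, `chrom`,
#'   `tss`, `strand`, `cgi_start`, `cgi_end`, `skewed`), `g4_truth`
#'   (planted motifs with `class` `"upstream"`/`"background"`), and the
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 11L), simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  bases <- c("A", "C", "G", "T")
  n_chrom <- config$n_chroms
  L <- config$chrom_length
  chrom_names <- paste0("chr", seq_len(n_chrom))
  # genes per chromosome, as even as possible
  per <- diff(floor(seq(0, config$n_genes, length.out = n_chrom + 1)))
  seqs <- vector("list", n_chrom)
  promoters <- list()
  g4_rows <- list()
  half_cgi <- floor(config$cgi_length / 2)
  edge <- max(config$cgi_length, config$skew_footprint, 2000) + 500
  for (ci in seq_len(n_chrom)) {
    chars <- sample(bases, L, replace = TRUE, prob = config$base_comp)
    k <- per[ci]
    if (k > 0) {
      slot <- L / k
      if (slot < 2 * edge + 2000) stop("genes too dense for chromosome length")
      lo <- (seq_len(k) - 1) * slot + pmax(0.3 * slot, edge)
      hi <- seq_len(k) * slot - pmax(0.3 * slot, edge)
      tss <- floor(stats::runif(k, lo, hi))
      strand <- sample(c("+", "-"), k, replace = TRUE)
      glen <- floor(stats::runif(k, 2000, 10000))
      skewed <- stats::runif(k) < config$p_skewed
      gene_id <- sprintf("g%02d_%03d", ci, seq_len(k))
      for (j in seq_len(k)) {
        t0 <- tss[j]
        # CpG island centered on the TSS
        cs <- t0 - half_cgi
        ce <- cs + config$cgi_length
        idx <- (cs + 1):ce
        chars[idx] <- sample(bases, length(idx), replace = TRUE,
                             prob = config$cgi_comp)
        n_cpg <- round(config$cgi_length * config$cpg_rate)
        if (n_cpg > 0) {
          at <- sample(seq.int(cs, ce - 2L), n_cpg)
          chars[at + 1L] <- "C"
          chars[at + 2L] <- "G"
        }
        # skewed footprint downstream of the TSS on the non-template strand
        if (skewed[j]) {
          fp <- config$skew_footprint
          if (strand[j] == "+") {
            fidx <- (t0 + 1):(t0 + fp)
            chars[fidx] <- sample(bases, fp, replace = TRUE,
                                  prob = config$skew_comp)
          } else {
            fidx <- (t0 - fp + 2):(t0 + 1)
            comp <- config$skew_comp[c("T", "G", "C", "A")]
            names(comp) <- bases
            chars[fidx] <- sample(bases, fp, replace = TRUE, prob = comp)
          }
        }
      }
      promoters[[ci]] <- data.frame(
        gene_id = gene_id, chrom = chrom_names[ci], tss = tss, strand = strand,
        gene_start = ifelse(strand == "+", tss, pmax(tss - glen + 1, 0)),
        gene_end = ifelse(strand == "+", pmin(tss + glen, L), tss + 1),
        cgi_start = tss - half_cgi, cgi_end = tss - half_cgi + config$cgi_length,
        skewed = skewed, stringsAsFactors = FALSE
      )
    }
    seqs[[ci]] <- chars
  }
  promoters <- if (length(promoters)) do.call(rbind, promoters) else NULL
  # ---- G4 planting (after all composition edits, so planted coordinates
  # stay exact truth) ----
  occupied <- vector("list", n_chrom)  # planted spans per chrom, for collision checks
  plant <- function(ci, fwd_start, motif_fwd) {
    mlen <- nchar(motif_fwd)
    span <- c(fwd_start - 1, fwd_start + mlen + 1)  # incl. flanks
    if (span[1] < 0 || span[2] > L) return(FALSE)
    occ <- occupied[[ci]]
    if (!is.null(occ) &&
        any(pmin(occ[, 2], span[2]) - pmax(occ[, 1], span[1]) > 0)) {
      return(FALSE)
    }
    occupied[[ci]] <<- rbind(occ, span)
    s <- strsplit(motif_fwd, "", fixed = TRUE)[[1L]]
    seqs[[ci]][(fwd_start):(fwd_start + mlen + 1)] <<- c("A", s, "A")
    TRUE
  }
  random_motif <- function() {
    loops <- sample.int(7L, 3L, replace = TRUE)
    loop_seqs <- vapply(loops, function(l) {
      paste(sample(c("A", "T"), l, replace = TRUE), collapse = "")
    }, "")
    paste0("GGG", paste(loop_seqs, "GGG", sep = "", collapse = ""))
  }
  if (!is.null(promoters) && config$g4_rate_upstream > 0) {
    for (i in seq_len(nrow(promoters))) {
      n_m <- stats::rpois(1L, config$g4_rate_upstream)
      ci <- match(promoters$chrom[i], chrom_names)
      for (m in seq_len(n_m)) {
        motif <- random_motif()
        mlen <- nchar(motif)
        off <- round(stats::rnorm(1, config$g4_offset_mean, config$g4_offset_sd))
        off <- min(max(off, -1000L), -mlen - 1L)  # keep span inside [-1000, 0)
        t0 <- promoters$tss[i]
        if (promoters$strand[i] == "+") {
          fs <- t0 + off
          ok <- plant(ci, fs, motif)
          st <- "+"
        } else {
          fs <- t0 - off - mlen + 1
          ok <- plant(ci, fs, revcomp(motif))
          st <- "-"
        }
        if (ok) {
          g4_rows[[length(g4_rows) + 1L]] <- data.frame(
            chrom = promoters$chrom[i], start = fs, end = fs + mlen,
            strand = st, class = "upstream", gene_id = promoters$gene_id[i],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  n_bg <- stats::rpois(1L, config$g4_rate_background * n_chrom * L / 1e6)
  for (m in seq_len(n_bg)) {
    motif <- random_motif()
    mlen <- nchar(motif)
    ci <- sample.int(n_chrom, 1L)
    fs <- floor(stats::runif(1, 1, L - mlen - 1))
    st <- sample(c("+", "-"), 1L)
    ok <- plant(ci, fs, if (st == "+") motif else revcomp(motif))
    if (ok) {
      g4_rows[[length(g4_rows) + 1L]] <- data.frame(
        chrom = chrom_names[ci], start = fs, end = fs + mlen, strand = st,
        class = "background", gene_id = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  gnm <- genome(stats::setNames(
    vapply(seqs, paste, "", collapse = ""), chrom_names))
  g4_truth <- if (length(g4_rows)) do.call(rbind, g4_rows) else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               strand = character(), class = character(),
               gene_id = character(), stringsAsFactors = FALSE)
  }
  genes <- if (!is.null(promoters)) {
    gintervals(promoters$chrom, promoters$gene_start, promoters$gene_end,
               name = promoters$gene_id, strand = promoters$strand,
               label = "genes")
  } else {
    gintervals(label = "genes")
  }
  cgis <- if (!is.null(promoters)) {
    gintervals(promoters$chrom, promoters$cgi_start, promoters$cgi_end,
               name = paste0("cgi_", promoters$gene_id), label = "CGI")
  } else {
    gintervals(label = "CGI")
  }
  if (is.null(promoters)) {
    promoters <- data.frame(gene_id = character(), chrom = character(),
                            tss = numeric(), strand = character(),
                            gene_start = numeric(), gene_end = numeric(),
                            cgi_start = numeric(), cgi_end = numeric(),
                            skewed = logical(), stringsAsFactors = FALSE)
  }
  rownames(promoters) <- NULL
  list(genome = gnm, genes = genes, cgis = cgis, promoters = promoters,
       g4_truth = g4_truth, config = config)
}

#' Simulate DRIP, ORC1 and SNS peak sets over a simulated genome
#'
#' Promoter labels are drawn first (DRIP, then ORC1 conditioned on DRIP,
#' then SNS conditioned on ORC1, preserving the configured marginals);
#' each positive label then receives one peak placed in oriented
#' coordinates upstream of / across the TSS, with lognormal fold
#' enrichment. Decoy peaks are scattered uniformly. When
#' `restriction_site` is set, DRIP peak boundaries snap outward to the
#' nearest flanking occurrence of the site (or the chromosome end).
#'
#' @param sim Output of [simulate_genome].
#' @param config A [sim_config]; defaults to the one inside `sim`.
#' @return A list: `peaks` (named list of DRIP/ORC1/SNS [gintervals]) and
#'   `labels` (truth table `gene_id`, `drip`, `orc1`, `sns`).
#' @export
simulate_peaks <- function(sim, config = sim$config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 23L), simulate_peaks_impl(sim, config))
}

simulate_peaks_impl <- function(sim, config) {
  pr <- sim$promoters
  n <- nrow(pr)
  rates <- label_rates(config$coloc)
  drip <- stats::runif(n) < config$coloc$p_drip
  orc1 <- stats::runif(n) < ifelse(drip, rates[["orc1_given_drip"]],
                                   rates[["orc1_given_nodrip"]])
  sns <- stats::runif(n) < ifelse(orc1, rates[["sns_given_orc1"]],
                                  rates[["sns_given_noorc1"]])
  labels <- data.frame(gene_id = pr$gene_id, drip = drip, orc1 = orc1,
                       sns = sns, stringsAsFactors = FALSE)
  lens <- genome_lengths(sim$genome)
  make_label_peaks <- function(label, pos) {
    spec <- config$peak_specs[[label]]
    rows <- list()
    for (i in which(pos)) {
      len <- max(50, round(stats::rnorm(1, spec$length_mean, spec$length_sd)))
      ctr <- round(stats::rnorm(1, spec$center, spec$center_sd))
      a <- ctr - floor(len / 2)
      b <- a + len
      t0 <- pr$tss[i]
      if (pr$strand[i] == "+") {
        s <- t0 + a; e <- t0 + b
      } else {
        s <- t0 - b + 1; e <- t0 - a + 1
      }
      L <- lens[[pr$chrom[i]]]
      s <- max(0, s); e <- min(L, e)
      if (s >= e) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = pr$chrom[i], start = s, end = e,
        name = paste0(label, "_p_", pr$gene_id[i]),
        score = stats::rlnorm(1, spec$fold_meanlog, spec$fold_sdlog),
        stringsAsFactors = FALSE
      )
    }
    n_bg <- config$background_peaks
    for (i in seq_len(n_bg)) {
      ch <- sample(names(lens), 1L, prob = lens / sum(lens))
      len <- max(50, round(stats::rnorm(1, spec$length_mean, spec$length_sd)))
      L <- lens[[ch]]
      s <- floor(stats::runif(1, 0, max(L - len, 1)))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s, end = min(s + len, L),
        name = paste0(label, "_bg_", i),
        score = stats::rlnorm(1, config$background_fold_meanlog,
                              config$background_fold_sdlog),
        stringsAsFactors = FALSE
      )
    }
    df <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 name = character(), score = numeric(), stringsAsFactors = FALSE)
    }
    sort_intervals(gintervals(df$chrom, df$start, df$end, name = df$name,
                              score = round(df$score, 2), label = label))
  }
  peaks <- list(
    DRIP = make_label_peaks("DRIP", drip),
    ORC1 = make_label_peaks("ORC1", orc1),
    SNS = make_label_peaks("SNS", sns)
  )
  if (!is.null(config$restriction_site)) {
    peaks$DRIP <- snap_to_restriction_sites(peaks$DRIP, sim$genome,
                                            config$restriction_site)
  }
  list(peaks = peaks, labels = labels)
}

#' Snap peak boundaries outward to restriction-site occurrences
#'
#' Emulates the restriction-fragment resolution of DRIP-seq: each peak's
#' start moves left to the nearest occurrence of `site` at or before it
#' (or the chromosome start), and its end moves right so it terminates at
#' the end of the nearest occurrence at or after it (or the chromosome
#' end).
#'
#' @param peaks A [gintervals] table.
#' @param g A [genome].
#' @param site Recognition sequence, e.g. `"GATC"`.
#' @return The snapped peaks (merged where snapping makes them overlap is
#'   NOT applied; duplicates may arise for nearby peaks).
#' @export
snap_to_restriction_sites <- function(peaks, g, site) {
  stopifnot(nchar(site) >= 1L)
  lens <- genome_lengths(g)
  site_pos <- lapply(names(g), function(ch) {
    m <- gregexpr(site, unclass(g)[[ch]], fixed = TRUE)[[1L]]
    if (m[1L] == -1L) numeric() else as.numeric(m) - 1
  })
  names(site_pos) <- names(g)
  w <- nchar(site)
  out <- peaks
  for (i in seq_len(nrow(peaks))) {
    sp <- site_pos[[peaks$chrom[i]]]
    L <- lens[[peaks$chrom[i]]]
    left <- sp[sp <= peaks$start[i]]
    out$start[i] <- if (length(left)) max(left) else 0
    right <- sp[sp + w >= peaks$end[i]]
    out$end[i] <- if (length(right)) min(right) + w else L
  }
  out
}

#' Simulate a complete dataset (genome + annotations + peaks)
#'
#' @param config A [sim_config].
#' @return The union of [simulate_genome] and [simulate_peaks] outputs.
#' @export
simulate_dataset <- function(config = sim_config()) {
  sim <- simulate_genome(config)
  pk <- simulate_peaks(sim, config)
  c(sim, pk)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `genes.bed` (BED6), `cgis.bed`,
#' `{drip,orc1,sns}_peaks.bed` (BED6 with fold-enrichment scores),
#' `truth_promoters.tsv`, `truth_g4.tsv` and `truth_labels.tsv`.
#'
#' @param sim Output of [simulate_dataset].
#' @param dir Output directory (created if missing).
#' @return Named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.bed"),
    cgis = file.path(dir, "cgis.bed"),
    drip = file.path(dir, "drip_peaks.bed"),
    orc1 = file.path(dir, "orc1_peaks.bed"),
    sns = file.path(dir, "sns_peaks.bed"),
    promoters = file.path(dir, "truth_promoters.tsv"),
    g4 = file.path(dir, "truth_g4.tsv"),
    labels = file.path(dir, "truth_labels.tsv")
  )
  write_fasta(sim$genome, paths[["genome"]])
  write_bed(sim$genes, paths[["genes"]], ncol = 6L)
  write_bed(sim$cgis, paths[["cgis"]], ncol = 4L)
  write_bed(sim$peaks$DRIP, paths[["drip"]], ncol = 6L)
  write_bed(sim$peaks$ORC1, paths[["orc1"]], ncol = 6L)
  write_bed(sim$peaks$SNS, paths[["sns"]], ncol = 6L)
  utils::write.table(sim$promoters, paths[["promoters"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$g4_truth, paths[["g4"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$labels, paths[["labels"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
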