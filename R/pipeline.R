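#' Run the full co-localization analysis
#'
#' Orchestrates the pipeline end to end: simulate (or load) a dataset,
#' build the TSS-associated CpG island promoter universe, flag GC-skewed
#' promoters, filter DRIP peaks by fold enrichment, construct the
#' CpG-island-origin set (SNS AND ORC1 positive), test DRIP/ORC1
#' co-localization against the permutation and/or shuffling null, scan G4
#' motifs, and compute TSS-centered composite profiles for ORC1, DRIP
#' and G4 at the co-localized promoter set. Writes per-stage outputs and
#' a machine-readable JSON report that records every parameter and seed
#' needed to reproduce the numbers (the timestamp is isolated in a single
#' field so the rest of the report is reproducible byte for byte).
#'
#' @param config A [sim_config] describing the synthetic dataset, or a
#'   list of real input paths with elements `genome_fa`, `genes_bed`,
#'   `cgis_bed`, `drip_bed`, `orc1_bed`, `sns_bed` plus a `seed`.
#' @param out_dir Output directory.
#' @param n_perm Permutations for the label-permutation null.
#' @param null `"permute"`, `"shuffle"` or `"both"`.
#' @param mode,upstream Association geometry
#'   (see [associate_peaks_to_promoters]).
#' @param fold_threshold DRIP fold-enrichment filter (strictly greater
#'   than; default 5).
#' @param halfwidth Profile half-width in bp.
#' @param n_shuffle Shuffles for the genomic-shuffling null.
#' @return The report, invisibly (also written as `report.json`).
#' @export
run_all <- function(config = sim_config(), out_dir,
                    n_perm = 1000L,
                    null = c("both", "permute", "shuffle"),
                    mode = c("cgi_overlap", "upstream_window"),
                    upstream = 1000, fold_threshold = 5,
                    halfwidth = 3000L, n_shuffle = 100L) {
  null <- match.arg(null)
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- stage 1: inputs ----
  if (inherits(config, "sim_config")) {
    sim <- simulate_dataset(config)
    paths <- write_simulation(sim, out_dir)
    seed <- config$seed
  } else {
    need <- c("genome_fa", "genes_bed", "cgis_bed", "drip_bed", "orc1_bed",
              "sns_bed", "seed")
    if (!all(need %in% names(config))) {
      stop("stage inputs: config must be a sim_config or name ",
           paste(need, collapse = ", "))
    }
    paths <- c(genome = config$genome_fa, genes = config$genes_bed,
               cgis = config$cgis_bed, drip = config$drip_bed,
               orc1 = config$orc1_bed, sns = config$sns_bed)
    seed <- config$seed
  }
  # read everything back through the parsers so real and simulated inputs
  # take the identical path
  g <- read_fasta(paths[["genome"]])
  genes <- read_bed(paths[["genes"]], label = "genes")
  cgis <- read_bed(paths[["cgis"]], label = "CGI")
  drip <- read_bed(paths[["drip"]], label = "DRIP")
  orc1 <- read_bed(paths[["orc1"]], label = "ORC1")
  sns <- read_bed(paths[["sns"]], label = "SNS")

  # ---- stage 2: promoter universe ----
  universe <- build_promoter_universe(genes, cgis, max_distance = 0)
  if (!nrow(universe)) stop("stage annotate: empty promoter universe")
  universe <- flag_gc_skew(universe, g)
  write_universe(universe, file.path(out_dir, "universe.tsv"))

  # ---- stage 3: peak filtering + association ----
  drip_f <- filter_by_fold_enrichment(drip, fold_threshold)
  drip_pos <- promoter_positive(drip_f, universe, mode, upstream)
  orc1_pos <- promoter_positive(orc1, universe, mode, upstream)
  origin <- build_origin_set(universe, sns, orc1, mode, upstream)
  write_bed(gintervals(origin$records$chrom, origin$records$cgi_start,
                       origin$records$cgi_end, name = origin$records$gene_id),
            file.path(out_dir, "origin_set.bed"), ncol = 4L)

  # ---- stage 4: co-localization ----
  if (!any(drip_pos)) stop("stage coloc: no DRIP-positive promoters")
  coloc <- list()
  if (null %in% c("permute", "both")) {
    coloc$permute <- coloc_permutation(drip_pos, orc1_pos, n_perm = n_perm,
                                       seed = child_seed(seed, 101L))
  }
  if (null %in% c("shuffle", "both")) {
    coloc$shuffle <- coloc_shuffle(drip_pos, universe, orc1, g,
                                   mode = mode, upstream = upstream,
                                   n_perm = n_shuffle,
                                   seed = child_seed(seed, 202L))
  }

  # ---- stage 5: G4 scan + composite profiles ----
  motifs <- scan_g4_genome(g)
  anchors <- universe[drip_pos & orc1_pos, , drop = FALSE]
  if (!nrow(anchors)) anchors <- origin$records
  if (!nrow(anchors)) anchors <- universe
  profiles <- list(
    ORC1 = composite_profile(orc1, anchors, g, halfwidth),
    DRIP = composite_profile(drip_f, anchors, g, halfwidth),
    G4 = profile_g4(motifs, anchors, g, halfwidth, strand_mode = "both")
  )
  for (nm in names(profiles)) {
    write_profile(profiles[[nm]],
                  file.path(out_dir, paste0("profile_", tolower(nm), ".tsv")))
  }

  # ---- report ----
  coloc_report <- lapply(coloc, function(x) {
    x$null_fractions <- NULL
    unclass(x)
  })
  report <- list(
    package = "rloopcoloc",
    version = as.character(utils::packageVersion("rloopcoloc")),
    parameters = list(
      seed = seed, n_perm = n_perm, n_shuffle = n_shuffle, null = null,
      mode = mode, upstream = upstream, fold_threshold = fold_threshold,
      halfwidth = halfwidth,
      simulation = if (inherits(config, "sim_config")) {
        config[!vapply(config, is.function, TRUE)]
      } else {
        NULL
      }
    ),
    input_checksums = as.list(tools::md5sum(unname(paths[
      c("genome", "genes", "cgis", "drip", "orc1", "sns")]))),
    universe = list(
      n_promoters = nrow(universe),
      n_gc_skewed = sum(universe$gc_skewed, na.rm = TRUE)
    ),
    origin_set = as.list(origin$counts),
    n_drip_filtered = nrow(drip_f),
    n_drip_positive_promoters = sum(drip_pos),
    colocalization = coloc_report,
    g4 = list(n_motifs = nrow(motifs)),
    profiles = lapply(profiles, function(p) {
      list(argmax_offset = profile_argmax(p),
           max_value = max(p$values, na.rm = TRUE),
           n_regions = p$n_regions)
    }),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
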