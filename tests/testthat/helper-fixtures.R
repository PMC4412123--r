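# Shared fixture builders.

make_universe <- function(tss, strand, cgi_start, cgi_end, chrom = "chr1") {
  genes <- gintervals(chrom,
                      ifelse(strand == "+", tss, tss - 3000),
                      ifelse(strand == "+", tss + 3000, tss + 1),
                      name = paste0("g", seq_along(tss)), strand = strand)
  cgis <- gintervals(chrom, cgi_start, cgi_end)
  build_promoter_universe(genes, cgis)
}
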