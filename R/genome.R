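#' Construct a genome from named sequences
#'
#' A genome is an ordered, uniquely named set of nucleotide sequences over
#' the alphabet A/C/G/T/N, stored as an upper-cased named character
#' vector of class `"genome"`.
#'
#' @param seqs Named character vector of sequences.
#' @return A `"genome"` object.
#' @export
genome <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) stop("all sequences must be named")
  if (anyDuplicated(nm)) stop("duplicate sequence names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence")
  if (any(grepl("[^ACGTN]", seqs))) stop("sequence contains characters outside A/C/G/T/N")
  class(seqs) <- "genome"
  seqs
}

#' Per-sequence lengths of a genome
#' @param g A [genome].
#' @return Named numeric vector of sequence lengths (bp).
#' @export
genome_lengths <- function(g) {
  stats::setNames(as.numeric(nchar(unclass(g))), names(g))
}

#' Read a FASTA file into a genome
#'
#' Sequence names are the first whitespace-delimited token of each header;
#' sequences are upper-cased. Empty files and duplicate names are
#' rejected.
#'
#' @param path Path to a FASTA file.
#' @return A [genome].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  genome(stats::setNames(toupper(as.character(ss)), nm))
}

#' Write a genome as FASTA
#'
#' @param g A [genome].
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(g))
  names(ss) <- names(g)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' Vectorized over its input; `N` maps to `N`. Applying it twice is the
#' identity.
#'
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a genomic subsequence
#'
#' @param g A [genome].
#' @param chrom Sequence name.
#' @param start,end 0-based half-open span, clipped to the sequence.
#' @return The subsequence (forward strand).
#' @export
get_seq <- function(g, chrom, start, end) {
  if (!chrom %in% names(g)) stop("chromosome not in genome: ", chrom)
  L <- nchar(g[[chrom]])
  start <- max(0, start)
  end <- min(L, end)
  if (start >= end) return("")
  substr(unclass(g)[[chrom]], start + 1, end)
}
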