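# Reference genome access. The genome is held as a Biostrings::DNAStringSet;
# all interface coordinates are 1-based inclusive.

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig (first whitespace
#'   token of each header).
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract wild-type and mutant sequence context around an SNV
#'
#' Returns the reference (wild-type) window `pos +/- radius` and the mutant
#' window obtained by substituting the alternate allele at the SNV, both
#' uppercase. Windows running off a contig end are truncated and flagged. The
#' reference base at the SNV must equal `ref_allele`; a mismatch signals stale
#' coordinates or the wrong assembly and is an error.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param snv One-row somatic SNV data.frame (or list) with `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`.
#' @param radius Window half-width in bp (default 30).
#' @return List with `wt_context`, `mut_context`, `snv_offset` (1-based
#'   position of the SNV inside the window), `ctx_start` (genome coordinate of
#'   window position 1), `chrom`, and `truncated`.
#' @export
extract_context <- function(genome, snv, radius = 30L) {
  chrom <- as.character(snv$chrom)
  pos <- as.integer(snv$pos)
  if (!chrom %in% names(genome)) stop("contig not in genome: ", chrom)
  contig_len <- Biostrings::width(genome[chrom])
  if (pos < 1 || pos > contig_len) {
    stop("SNV position ", pos, " outside contig ", chrom,
         " (length ", contig_len, ")")
  }
  start <- max(1L, pos - radius)
  end <- min(contig_len, pos + radius)
  wt <- toupper(as.character(Biostrings::subseq(genome[[chrom]], start, end)))
  offset <- pos - start + 1L
  ref_base <- substr(wt, offset, offset)
  if (ref_base != toupper(snv$ref_allele)) {
    stop("reference mismatch at ", chrom, ":", pos, " — genome has ",
         ref_base, " but ref_allele is ", snv$ref_allele,
         " (stale coordinates or wrong assembly?)")
  }
  mut <- wt
  substr(mut, offset, offset) <- toupper(snv$alt_allele)
  list(
    wt_context = wt, mut_context = mut, snv_offset = offset,
    ctx_start = start, chrom = chrom,
    truncated = (start > pos - radius) || (end < pos + radius)
  )
}
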