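# The pipeline's unit of flow is a somatic SNV table: one row per somatic
# single-nucleotide variant with sample, coordinate, allele, AF, gene and
# zygosity columns. All readers normalize into this shape.

SNV_COLUMNS <- c(
  "sample_id", "cancer_type", "chrom", "pos", "ref_allele", "alt_allele",
  "allele_frequency", "alt_read_count", "gene_symbol", "variant_class",
  "zygosity", "flags"
)

#' Construct an empty somatic SNV table
#'
#' @return A zero-row data.frame with the canonical SNV columns: `sample_id`,
#'   `cancer_type`, `chrom`, `pos` (1-based), `ref_allele`, `alt_allele`,
#'   `allele_frequency`, `alt_read_count`, `gene_symbol`, `variant_class`
#'   (missense/synonymous/nonsense/splice/other), `zygosity`
#'   (heterozygous/homozygous/unknown) and `flags` (semicolon-separated set).
#' @export
empty_snv_table <- function() {
  data.frame(
    sample_id = character(0), cancer_type = character(0),
    chrom = character(0), pos = integer(0),
    ref_allele = character(0), alt_allele = character(0),
    allele_frequency = numeric(0), alt_read_count = integer(0),
    gene_symbol = character(0), variant_class = character(0),
    zygosity = character(0), flags = character(0),
    stringsAsFactors = FALSE
  )
}

#' Validate a somatic SNV table
#'
#' Checks the structural invariants every pipeline stage relies on: canonical
#' columns present, single-base ACGT alleles with ref != alt, allele
#' frequencies in \[0, 1\], positive 1-based positions, and admissible
#' zygosity/variant-class labels.
#'
#' @param snvs A data.frame of somatic SNVs.
#' @return `snvs`, invisibly, after normalizing column order; errors describe
#'   the first violated invariant.
#' @export
validate_snvs <- function(snvs) {
  missing <- setdiff(SNV_COLUMNS, names(snvs))
  if (length(missing) > 0) {
    stop("SNV table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(snvs) == 0) return(invisible(snvs[, SNV_COLUMNS, drop = FALSE]))
  if (!all(snvs$ref_allele %in% DNA_BASES) || !all(snvs$alt_allele %in% DNA_BASES)) {
    stop("ref_allele/alt_allele must be single bases in {A,C,G,T}")
  }
  if (any(snvs$ref_allele == snvs$alt_allele)) {
    stop("ref_allele must differ from alt_allele")
  }
  af <- snvs$allele_frequency
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    stop("allele_frequency must lie in [0, 1]")
  }
  if (any(snvs$pos < 1)) stop("pos must be >= 1 (1-based coordinates)")
  if (!all(snvs$zygosity %in% c("heterozygous", "homozygous", "unknown"))) {
    stop("zygosity must be heterozygous, homozygous or unknown")
  }
  if (!all(snvs$variant_class %in%
             c("missense", "synonymous", "nonsense", "splice", "other"))) {
    stop("variant_class must be one of missense/synonymous/nonsense/splice/other")
  }
  invisible(snvs[, union(SNV_COLUMNS, names(snvs)), drop = FALSE])
}

# Split a semicolon-separated flag string into a character set.
parse_flags <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}
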