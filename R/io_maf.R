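# GDC-style MAF reader/writer. Only the minimal column set is required; extra
# columns are ignored. Coordinates are 1-based inclusive throughout.

MAF_REQUIRED <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                  "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Type",
                  "Tumor_Sample_Barcode")

VARIANT_CLASS_MAP <- c(
  Missense_Mutation = "missense",
  Silent = "synonymous",
  Nonsense_Mutation = "nonsense",
  Splice_Site = "splice",
  Splice_Region = "splice"
)

#' Read somatic SNVs from a MAF file
#'
#' Parses a GDC-style mutation annotation format (MAF) table into the
#' canonical somatic SNV table. Only `Variant_Type == "SNP"` rows are kept;
#' InDels and MNPs are skipped and counted (attribute `"n_skipped"`). Allele
#' frequency is taken from an `allele_frequency` column when present,
#' otherwise computed as `t_alt_count / t_depth`. Zygosity is never inferred
#' by the reader: every record comes back `"unknown"` (see [call_zygosity()]).
#'
#' @param path Path to a tab-separated MAF file; lines starting `#` ignored.
#' @param dialect MAF dialect; only `"gdc"` is currently defined.
#' @param strict If `TRUE` (default), an unparsable row aborts with its line
#'   number; if `FALSE` such rows are skipped with a warning.
#' @return A somatic SNV data.frame (see [empty_snv_table()]) with attribute
#'   `n_skipped`, the number of non-SNP rows dropped.
#' @export
read_maf <- function(path, dialect = c("gdc"), strict = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("MAF file not found: ", path)
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  missing <- setdiff(MAF_REQUIRED, names(raw))
  if (length(missing) > 0) {
    stop("MAF is missing required column(s): ", paste(missing, collapse = ", "))
  }
  n_skipped <- sum(raw$Variant_Type != "SNP")
  rows <- raw[raw$Variant_Type == "SNP", , drop = FALSE]

  getcol <- function(nm) if (nm %in% names(rows)) rows[[nm]] else rep(NA_character_, nrow(rows))

  pos <- suppressWarnings(as.integer(rows$Start_Position))
  af_col <- suppressWarnings(as.numeric(getcol("allele_frequency")))
  alt_ct <- suppressWarnings(as.integer(getcol("t_alt_count")))
  depth <- suppressWarnings(as.integer(getcol("t_depth")))
  af <- ifelse(!is.na(af_col), af_col,
               ifelse(!is.na(alt_ct) & !is.na(depth) & depth > 0,
                      alt_ct / depth, NA_real_))

  bad <- which(is.na(pos) | is.na(af) |
                 !(rows$Reference_Allele %in% DNA_BASES) |
                 !(rows$Tumor_Seq_Allele2 %in% DNA_BASES) |
                 rows$Reference_Allele == rows$Tumor_Seq_Allele2)
  if (length(bad) > 0) {
    if (strict) {
      stop("Unparsable MAF SNP row (missing position/AF or bad alleles) at data row ",
           bad[1])
    }
    warning(length(bad), " unparsable MAF row(s) skipped")
    keep <- setdiff(seq_len(nrow(rows)), bad)
    rows <- rows[keep, , drop = FALSE]
    pos <- pos[keep]; af <- af[keep]; alt_ct <- alt_ct[keep]
  }

  vc <- VARIANT_CLASS_MAP[getcol("Variant_Classification")]
  vc[is.na(vc)] <- "other"

  snvs <- data.frame(
    sample_id = rows$Tumor_Sample_Barcode,
    cancer_type = getcol("cancer_type"),
    chrom = rows$Chromosome,
    pos = pos,
    ref_allele = rows$Reference_Allele,
    alt_allele = rows$Tumor_Seq_Allele2,
    allele_frequency = af,
    alt_read_count = alt_ct,
    gene_symbol = rows$Hugo_Symbol,
    variant_class = unname(vc),
    zygosity = rep("unknown", nrow(rows)),
    flags = ifelse(is.na(getcol("flags")), "", getcol("flags")),
    stringsAsFactors = FALSE
  )
  validate_snvs(snvs)
  attr(snvs, "n_skipped") <- n_skipped
  snvs
}

#' Write somatic SNVs as a GDC-style MAF file
#'
#' Inverse of [read_maf()]: emits the minimal GDC column set plus read counts.
#' When `alt_read_count` is present, `t_depth` is reconstructed so that
#' `t_alt_count / t_depth` reproduces the stored allele frequency exactly;
#' otherwise counts are synthesized at depth 1000.
#'
#' @param snvs Somatic SNV table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(snvs, path) {
  validate_snvs(snvs)
  alt_ct <- snvs$alt_read_count
  depth <- ifelse(!is.na(alt_ct) & snvs$allele_frequency > 0,
                  as.integer(round(alt_ct / snvs$allele_frequency)),
                  1000L)
  alt_ct <- ifelse(!is.na(alt_ct), alt_ct,
                   as.integer(round(snvs$allele_frequency * 1000)))
  inv_class <- c(missense = "Missense_Mutation", synonymous = "Silent",
                 nonsense = "Nonsense_Mutation", splice = "Splice_Site",
                 other = "Other")
  out <- data.frame(
    Hugo_Symbol = snvs$gene_symbol,
    Chromosome = snvs$chrom,
    Start_Position = snvs$pos,
    End_Position = snvs$pos,
    Variant_Classification = unname(inv_class[snvs$variant_class]),
    Variant_Type = rep("SNP", nrow(snvs)),
    Reference_Allele = snvs$ref_allele,
    Tumor_Seq_Allele1 = snvs$ref_allele,
    Tumor_Seq_Allele2 = snvs$alt_allele,
    Tumor_Sample_Barcode = snvs$sample_id,
    t_depth = depth,
    t_alt_count = alt_ct,
    cancer_type = ifelse(is.na(snvs$cancer_type), "", snvs$cancer_type),
    flags = ifelse(is.na(snvs$flags), "", snvs$flags),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
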