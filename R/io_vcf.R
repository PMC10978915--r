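# VCF 4.x reader/writer (alternate input format). Parsing is delegated to
# vcfR; this layer normalizes biallelic SNV records into the SNV table,
# decomposing multiallelic sites into per-alt records.

#' Read somatic SNVs from a VCF file
#'
#' Keeps SNV records only (single-base ref and alt); multiallelic sites are
#' decomposed into one record per alternate allele. Allele frequency is taken
#' from the per-sample `AF` (or `VAF`) FORMAT field when present, else from
#' `AD` (alt / total), else from the INFO `AF` field. A genotype, when
#' present, sets zygosity (`1/1` homozygous, `0/1` heterozygous); records
#' whose genotype does not carry the alternate allele are skipped for that
#' sample. Gene symbols are read from the INFO key `GENE` when present.
#'
#' @param path Path to an uncompressed or bgzipped VCF 4.x file.
#' @param sample_id Sample name used for sites-only VCFs (no genotype
#'   columns); ignored otherwise.
#' @return A somatic SNV data.frame (see [empty_snv_table()]).
#' @export
read_vcf <- function(path, sample_id = "sample1") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_snv_table())
  info_gene <- tryCatch(vcfR::extract.info(vcf, "GENE"),
                        error = function(e) rep(NA_character_, nrow(fix)))
  info_af <- tryCatch(suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, "AF"))),
    error = function(e) rep(NA_real_, nrow(fix)))
  if (is.null(info_gene)) info_gene <- rep(NA_character_, nrow(fix))
  if (is.null(info_af) || length(info_af) == 0) info_af <- rep(NA_real_, nrow(fix))

  has_gt <- ncol(vcf@gt) > 1
  gt <- ad <- afm <- NULL
  samples <- sample_id
  if (has_gt) {
    samples <- colnames(vcf@gt)[-1]
    gt <- tryCatch(vcfR::extract.gt(vcf, "GT"), error = function(e) NULL)
    ad <- tryCatch(vcfR::extract.gt(vcf, "AD"), error = function(e) NULL)
    afm <- tryCatch(vcfR::extract.gt(vcf, "AF"), error = function(e) NULL)
    if (is.null(afm)) {
      afm <- tryCatch(vcfR::extract.gt(vcf, "VAF"), error = function(e) NULL)
    }
  }

  recs <- list()
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[i])
    alts <- strsplit(toupper(fix$ALT[i]), ",", fixed = TRUE)[[1]]
    if (!(ref %in% DNA_BASES)) next
    for (k in seq_along(alts)) {
      alt <- alts[k]
      if (!(alt %in% DNA_BASES) || alt == ref) next
      for (s in seq_along(samples)) {
        zyg <- "unknown"
        af <- NA_real_
        if (has_gt) {
          g <- if (!is.null(gt)) gt[i, s] else NA_character_
          if (!is.na(g)) {
            alleles <- strsplit(g, "[/|]")[[1]]
            if (!all(alleles == ".")) {  # "./." stays unknown but is kept
              if (!any(alleles == as.character(k))) next  # sample lacks this alt
              zyg <- if (all(alleles == as.character(k))) "homozygous" else "heterozygous"
            }
          }
          if (!is.null(afm) && !is.na(afm[i, s])) {
            af <- suppressWarnings(as.numeric(
              strsplit(afm[i, s], ",", fixed = TRUE)[[1]][k]))
          }
          if (is.na(af) && !is.null(ad) && !is.na(ad[i, s])) {
            counts <- suppressWarnings(as.numeric(
              strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
            if (length(counts) >= k + 1 && sum(counts) > 0) {
              af <- counts[k + 1] / sum(counts)
            }
          }
        }
        if (is.na(af)) af <- info_af[i]
        recs[[length(recs) + 1]] <- data.frame(
          sample_id = samples[s], cancer_type = NA_character_,
          chrom = fix$CHROM[i],
          pos = as.integer(fix$POS[i]),
          ref_allele = ref, alt_allele = alt,
          allele_frequency = af, alt_read_count = NA_integer_,
          gene_symbol = if (is.na(info_gene[i])) "" else info_gene[i],
          variant_class = "other", zygosity = zyg, flags = "",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(recs) == 0) return(empty_snv_table())
  out <- do.call(rbind, recs)
  validate_snvs(out)
  out
}

#' Write somatic SNVs as a single-sample VCF 4.2 file
#'
#' Minimal writer used for format round trips: one genotype column, `GT:AD:AF`
#' FORMAT, gene symbol in the INFO `GENE` key. All SNVs must belong to one
#' sample.
#'
#' @param snvs Somatic SNV table for a single sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snvs, path) {
  validate_snvs(snvs)
  sm <- unique(snvs$sample_id)
  if (length(sm) > 1) stop("write_vcf handles a single sample; got ", length(sm))
  if (length(sm) == 0) sm <- "sample1"
  gt <- c(heterozygous = "0/1", homozygous = "1/1", unknown = "./.")[snvs$zygosity]
  alt_ct <- ifelse(is.na(snvs$alt_read_count),
                   as.integer(round(snvs$allele_frequency * 1000)),
                   snvs$alt_read_count)
  depth <- ifelse(snvs$allele_frequency > 0,
                  as.integer(round(alt_ct / snvs$allele_frequency)), 1000L)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sm, sep = "\t")
  )
  body <- if (nrow(snvs) == 0) character(0) else {
    ord <- order(snvs$chrom, snvs$pos, snvs$alt_allele)
    s <- snvs[ord, , drop = FALSE]
    gt <- gt[ord]; alt_ct <- alt_ct[ord]; depth <- depth[ord]
    paste(s$chrom, s$pos, ".", s$ref_allele, s$alt_allele, ".", "PASS",
          paste0("GENE=", s$gene_symbol), "GT:AD:AF",
          sprintf("%s:%d,%d:%.6g", gt, depth - alt_ct, alt_ct,
                  s$allele_frequency),
          sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
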