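# Variant-level filters: QC, cohort recurrence, zygosity calling, gene-class,
# the per-sample clonality threshold AF_cut, and the expression filter.

#' Quality-control filter
#'
#' Retains SNVs supported by at least `qc_min_alt_reads` alt reads (records
#' with no read count pass this check vacuously), with allele frequency at or
#' above `qc_min_af`, and carrying none of the excluded flags (segmental
#' duplication, tandem repeat, germline database hits by default). Both read
#' and AF thresholds are inclusive ("at least").
#'
#' @param snvs Somatic SNV table.
#' @param config A [pipeline_config()].
#' @return The retained subset of `snvs`.
#' @export
qc_filter <- function(snvs, config = pipeline_config()) {
  validate_snvs(snvs)
  if (nrow(snvs) == 0) return(snvs)
  reads_ok <- is.na(snvs$alt_read_count) |
    snvs$alt_read_count >= config$qc_min_alt_reads
  af_ok <- !is.na(snvs$allele_frequency) &
    snvs$allele_frequency >= config$qc_min_af
  flags_ok <- vapply(snvs$flags, function(f) {
    length(intersect(parse_flags(f), config$exclude_flags)) == 0
  }, logical(1), USE.NAMES = FALSE)
  snvs[reads_ok & af_ok & flags_ok, , drop = FALSE]
}

#' Cohort-recurrence filter
#'
#' Keeps exactly the SNVs whose (chrom, pos, ref, alt) appears in a catalog of
#' known somatic mutations (e.g. variants seen in at least one cohort
#' patient). This stage is optional: with a `NULL` catalog the input passes
#' through untouched.
#'
#' @param snvs Somatic SNV table.
#' @param catalog Data.frame with `chrom`, `pos`, `ref_allele`, `alt_allele`
#'   (see [read_recurrence_catalog()]), or `NULL` to skip.
#' @return The retained subset.
#' @export
recurrence_filter <- function(snvs, catalog = NULL) {
  validate_snvs(snvs)
  if (is.null(catalog)) return(snvs)
  if (nrow(snvs) == 0) return(snvs)
  key <- function(d) paste(d$chrom, d$pos, d$ref_allele, d$alt_allele, sep = "\r")
  snvs[key(snvs) %in% key(catalog), , drop = FALSE]
}

#' Call zygosity from allele frequency
#'
#' Genotype-derived zygosity (heterozygous/homozygous) is never overwritten.
#' Records of unknown zygosity are called homozygous when their allele
#' frequency is at least `hom_af_min` (default 0.9, a loss-of-heterozygosity
#' tolerant heuristic), heterozygous otherwise. The decision path is recorded
#' in a `zygosity_source` column (`"genotype"` or `"af_rule"`).
#'
#' @param snvs Somatic SNV table.
#' @param config A [pipeline_config()].
#' @return `snvs` with `zygosity` resolved and `zygosity_source` added.
#' @export
call_zygosity <- function(snvs, config = pipeline_config()) {
  validate_snvs(snvs)
  src <- ifelse(snvs$zygosity == "unknown", "af_rule", "genotype")
  unknown <- snvs$zygosity == "unknown"
  snvs$zygosity[unknown] <- ifelse(
    snvs$allele_frequency[unknown] >= config$hom_af_min,
    "homozygous", "heterozygous")
  snvs$zygosity_source <- src
  snvs
}

#' Gene-class filter
#'
#' Implements the viability logic: SNVs in haploinsufficient genes are kept at
#' any zygosity (single-copy disruption suffices), SNVs in essential genes
#' only when homozygous (only a homozygous knockout eliminates the gene's
#' function), and everything else is dropped. Retained records are annotated
#' with their `gene_class`.
#'
#' @param snvs Somatic SNV table with zygosity resolved.
#' @param catalog A `gene_catalog` from [read_gene_catalog()].
#' @return The retained, annotated subset.
#' @export
filter_by_gene_class <- function(snvs, catalog) {
  validate_snvs(snvs)
  stopifnot(inherits(catalog, "gene_catalog"))
  if (nrow(snvs) == 0) { snvs$gene_class <- character(0); return(snvs) }
  if (any(snvs$zygosity == "unknown")) {
    stop("gene-class filter requires resolved zygosity; run call_zygosity() first")
  }
  cls <- gene_class_of(catalog, snvs$gene_symbol)
  keep <- (cls == "haploinsufficient") |
    (cls == "essential" & snvs$zygosity == "homozygous")
  out <- snvs[keep, , drop = FALSE]
  out$gene_class <- cls[keep]
  out
}

#' Compute the per-sample clonality threshold AF_cut
#'
#' `AF_cut = AF_M + MAD(hetAF)`, where `AF_M` is the median allele frequency
#' over the configured population (heterozygous SNVs by default, optionally
#' all SNVs) and `MAD(hetAF)` is `mad_constant * median(|AF_i - median(hetAF)|)`
#' over the heterozygous SNVs. Computed on a sample's complete (QC-passed) SNV
#' list, before gene-class filtering, so the threshold reflects the sample's
#' overall clonal structure.
#'
#' @param snvs All SNVs of one sample, zygosity resolved.
#' @param config A [pipeline_config()].
#' @return Object of class `af_threshold`: list with `sample_id`, `af_median`,
#'   `mad_het`, `af_cut` (= `af_median + mad_het` exactly), `n_snvs_used`,
#'   `n_het_used`.
#' @export
compute_af_cut <- function(snvs, config = pipeline_config()) {
  validate_snvs(snvs)
  sample_id <- unique(snvs$sample_id)
  if (length(sample_id) > 1) {
    stop("compute_af_cut expects SNVs of a single sample; got ",
         length(sample_id))
  }
  het <- snvs$allele_frequency[snvs$zygosity == "heterozygous"]
  het <- het[!is.na(het)]
  if (length(het) == 0) {
    stop(structure(
      class = c("af_cut_undefined", "error", "condition"),
      list(message = paste0("no heterozygous SNVs for sample ",
                            if (length(sample_id)) sample_id else "<none>",
                            "; AF_cut undefined"),
           call = sys.call())))
  }
  pop <- if (config$af_median_population == "het") het else {
    snvs$allele_frequency[!is.na(snvs$allele_frequency)]
  }
  af_median <- stats::median(pop)
  mad_het <- config$mad_constant * stats::median(abs(het - stats::median(het)))
  out <- list(
    sample_id = if (length(sample_id)) sample_id else NA_character_,
    af_median = af_median,
    mad_het = mad_het,
    af_cut = af_median + mad_het,
    n_snvs_used = length(pop),
    n_het_used = length(het)
  )
  class(out) <- "af_threshold"
  out
}

#' @export
print.af_threshold <- function(x, ...) {
  cat(sprintf(
    "AF threshold for %s: AF_cut = %.4f (median %.4f + MAD %.4f; %d het of %d SNVs)\n",
    x$sample_id, x$af_cut, x$af_median, x$mad_het, x$n_het_used, x$n_snvs_used))
  invisible(x)
}

#' Clonality filter on the AF threshold
#'
#' Keeps SNVs whose allele frequency surpasses the sample's `AF_cut`. The
#' comparison is strict (`>`) by default; set `af_strict = FALSE` in the
#' config for `>=`.
#'
#' @param snvs SNVs of the threshold's sample.
#' @param threshold An `af_threshold` from [compute_af_cut()].
#' @param config A [pipeline_config()].
#' @return The retained subset.
#' @export
filter_by_af <- function(snvs, threshold, config = pipeline_config()) {
  validate_snvs(snvs)
  stopifnot(inherits(threshold, "af_threshold"))
  if (nrow(snvs) == 0) return(snvs)
  af <- snvs$allele_frequency
  keep <- if (config$af_strict) af > threshold$af_cut else af >= threshold$af_cut
  snvs[!is.na(af) & keep, , drop = FALSE]
}

#' Expression filter
#'
#' Keeps SNVs whose gene is expressed above `expression_min` log2(FPKM+1)
#' (strict `>`) in the same sample. A missing expression value is missing —
#' not zero — and drops the SNV unless `keep_missing_expression` is set.
#'
#' @param snvs Somatic SNV table.
#' @param expr An `expression_table`.
#' @param config A [pipeline_config()].
#' @return The retained subset.
#' @export
filter_by_expression <- function(snvs, expr, config = pipeline_config()) {
  validate_snvs(snvs)
  if (nrow(snvs) == 0) return(snvs)
  v <- expression_value(expr, snvs$sample_id, snvs$gene_symbol)
  keep <- ifelse(is.na(v), config$keep_missing_expression,
                 v > config$expression_min)
  snvs[keep, , drop = FALSE]
}

#' Does a sample carry a cataloged hotspot mutation?
#'
#' Matches a sample's SNVs against a hotspot catalog on (gene, position), and
#' additionally on (ref, alt) for entries that specify alleles.
#'
#' @param snvs_of_sample SNVs of one sample.
#' @param hotspots Data.frame from [read_hotspots()].
#' @return `TRUE` iff at least one SNV matches a hotspot entry.
#' @export
annotate_hotspot_carrier <- function(snvs_of_sample, hotspots) {
  validate_snvs(snvs_of_sample)
  if (nrow(snvs_of_sample) == 0 || is.null(hotspots) || nrow(hotspots) == 0) {
    return(FALSE)
  }
  for (i in seq_len(nrow(hotspots))) {
    h <- hotspots[i, ]
    m <- snvs_of_sample$gene_symbol == h$gene_symbol &
      snvs_of_sample$pos == h$pos
    if (!is.na(h$ref_allele) && !is.na(h$alt_allele)) {
      m <- m & snvs_of_sample$ref_allele == h$ref_allele &
        snvs_of_sample$alt_allele == h$alt_allele
    }
    if (any(m)) return(TRUE)
  }
  FALSE
}
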