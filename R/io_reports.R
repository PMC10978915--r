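# Guide report (TSV) and eligibility report (JSON) writers. Row and column
# order are fixed so repeat runs are byte-identical.

GUIDE_REPORT_COLUMNS <- c(
  "sample_id", "cancer_type", "chrom", "pos", "ref_allele", "alt_allele",
  "gene_symbol", "gene_class", "zygosity", "allele_frequency",
  "spacer", "pam", "strand", "design_class", "snv_spacer_position",
  "context30", "on_target_score", "n_off_targets", "max_off_target_cfd",
  "wt_allele_cfd", "qualified"
)

# %.10g keeps full working precision for scores/AFs while staying stable.
fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))

#' Write the guide candidate report
#'
#' One row per guide candidate, sorted deterministically by (sample, chrom,
#' pos, strand, spacer). Columns (fixed order): sample, SNV coordinate
#' (1-based) and alleles, gene and class, zygosity, allele frequency, spacer
#' (5'->3'), PAM, strand, design class, SNV position in the spacer (0 = SNV in
#' PAM), 30-nt scoring context, on-target score, off-target count, maximum
#' off-target CFD, wild-type-allele CFD, and the qualification verdict.
#'
#' @param candidates Guide candidate table from the design/scoring stages (an
#'   empty or `NULL` table yields a header-only file).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_guide_report <- function(candidates, path) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    writeLines(paste(GUIDE_REPORT_COLUMNS, collapse = "\t"), path)
    return(invisible(path))
  }
  x <- candidates
  if (!"context30" %in% names(x) && "context30_mut" %in% names(x)) {
    x$context30 <- x$context30_mut
  }
  if (!"spacer" %in% names(x)) x$spacer <- x$spacer_mut
  if (!"pam" %in% names(x)) x$pam <- x$pam_mut
  missing <- setdiff(GUIDE_REPORT_COLUMNS, names(x))
  if (length(missing) > 0) {
    stop("candidate table missing report column(s): ",
         paste(missing, collapse = ", "))
  }
  x <- x[order(x$sample_id, x$chrom, x$pos, x$strand, x$spacer),
         GUIDE_REPORT_COLUMNS, drop = FALSE]
  for (col in c("allele_frequency", "on_target_score", "max_off_target_cfd",
                "wt_allele_cfd")) {
    x[[col]] <- fmt_num(x[[col]])
  }
  x$qualified <- ifelse(is.na(x$qualified), "NA",
                        ifelse(x$qualified, "TRUE", "FALSE"))
  x$cancer_type <- ifelse(is.na(x$cancer_type), "NA", x$cancer_type)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guide candidate report back
#'
#' @param path TSV written by [write_guide_report()].
#' @return Data.frame with the report columns and native types.
#' @export
read_guide_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  missing <- setdiff(GUIDE_REPORT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("guide report missing column(s): ", paste(missing, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  df$snv_spacer_position <- as.integer(df$snv_spacer_position)
  df$n_off_targets <- as.integer(df$n_off_targets)
  for (col in c("allele_frequency", "on_target_score", "max_off_target_cfd",
                "wt_allele_cfd")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$qualified <- as.logical(df$qualified)
  df
}

#' Write an eligibility summary as JSON
#'
#' Percentages are carried at full precision in the JSON; one-decimal rounding
#' is applied only in the printed summary.
#'
#' @param summary An `eligibility_summary` from [summarize_eligibility()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eligibility_json <- function(summary, path) {
  stopifnot(inherits(summary, "eligibility_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a per-group attrition table
#'
#' @param attrition Data.frame from [step_attrition_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_attrition <- function(attrition, path) {
  utils::write.table(attrition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
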