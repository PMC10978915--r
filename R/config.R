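#' Pipeline configuration
#'
#' Bundles every tunable cutoff of the guide-selection workflow. Defaults
#' reproduce the published analysis conditions; each is a plain argument so a
#' config can be built partially and audited by printing.
#'
#' @param hom_af_min Allele-frequency at or above which an SNV of unknown
#'   genotype is called homozygous (default 0.9; genotype-derived zygosity
#'   always wins, see [call_zygosity()]).
#' @param expression_min Minimum `log2(FPKM+1)` expression; the filter is a
#'   strict `>` (default 1.0).
#' @param mad_constant Scale factor applied to the median absolute deviation in
#'   the AF threshold. 1.0 is the literal MAD; set 1.4826 for R's
#'   normal-consistent convention.
#' @param af_median_population Which SNVs feed the AF median of the clonality
#'   threshold: `"het"` (heterozygous only, default) or `"all"`.
#' @param af_strict Logical; `TRUE` (default) keeps SNVs with AF strictly
#'   greater than `af_cut`, `FALSE` uses `>=`.
#' @param on_target_min On-target score cutoff, strict `>` (default 0.5).
#' @param off_target_max_cfd Maximum tolerated off-target CFD score; a guide is
#'   disqualified when any off-target scores strictly above this (default
#'   0.175, i.e. a score of exactly 0.175 is kept).
#' @param max_mismatches Mismatch budget of the off-target scan (default 3).
#' @param seed_window Number of PAM-proximal spacer positions in which the SNV
#'   must fall for a seed design (default 12, i.e. spacer positions 9-20).
#' @param pam_motifs Character vector of IUPAC PAM motifs (default `"NGG"`).
#' @param exclude_flags SNV flags that disqualify a variant at QC.
#' @param qc_min_alt_reads Minimum alt-supporting reads (default 5, inclusive).
#' @param qc_min_af Minimum allele frequency at QC (default 0.20, inclusive).
#' @param keep_missing_expression Keep SNVs whose gene has no expression value
#'   (default `FALSE`: missing is dropped, never treated as zero).
#' @param count_wt_as_offtarget Treat the wild-type allele at the guide's own
#'   locus as a disqualifying off-target (default `FALSE`: it is reported as
#'   `wt_allele_cfd` but does not disqualify).
#' @param scorer Name of the registered on-target scorer (default
#'   `"gc_surrogate"`).
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config(seed_window = 10)
#' cfg$seed_window
#' @export
pipeline_config <- function(hom_af_min = 0.9,
                            expression_min = 1.0,
                            mad_constant = 1.0,
                            af_median_population = c("het", "all"),
                            af_strict = TRUE,
                            on_target_min = 0.5,
                            off_target_max_cfd = 0.175,
                            max_mismatches = 3L,
                            seed_window = 12L,
                            pam_motifs = "NGG",
                            exclude_flags = c("segdup", "tandem_repeat", "germline_db"),
                            qc_min_alt_reads = 5L,
                            qc_min_af = 0.20,
                            keep_missing_expression = FALSE,
                            count_wt_as_offtarget = FALSE,
                            scorer = "gc_surrogate") {
  af_median_population <- match.arg(af_median_population)
  stopifnot(
    is.numeric(hom_af_min), hom_af_min >= 0, hom_af_min <= 1,
    is.numeric(mad_constant), mad_constant > 0,
    is.numeric(on_target_min), on_target_min >= 0, on_target_min <= 1,
    is.numeric(off_target_max_cfd), off_target_max_cfd >= 0, off_target_max_cfd <= 1,
    is.numeric(max_mismatches), max_mismatches >= 0,
    is.numeric(seed_window), seed_window >= 1, seed_window <= 20,
    is.character(pam_motifs), length(pam_motifs) >= 1, all(nchar(pam_motifs) == 3),
    is.numeric(qc_min_alt_reads), qc_min_alt_reads >= 0,
    is.numeric(qc_min_af), qc_min_af >= 0, qc_min_af <= 1,
    is.logical(af_strict), is.logical(keep_missing_expression),
    is.logical(count_wt_as_offtarget)
  )
  cfg <- list(
    hom_af_min = hom_af_min,
    expression_min = expression_min,
    mad_constant = mad_constant,
    af_median_population = af_median_population,
    af_strict = af_strict,
    on_target_min = on_target_min,
    off_target_max_cfd = off_target_max_cfd,
    max_mismatches = as.integer(max_mismatches),
    seed_window = as.integer(seed_window),
    pam_motifs = toupper(pam_motifs),
    exclude_flags = exclude_flags,
    qc_min_alt_reads = as.integer(qc_min_alt_reads),
    qc_min_af = qc_min_af,
    keep_missing_expression = keep_missing_expression,
    count_wt_as_offtarget = count_wt_as_offtarget,
    scorer = scorer
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("snvguide pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
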