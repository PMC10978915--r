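# End-to-end orchestration: QC -> zygosity -> AF_cut -> gene class -> AF ->
# expression -> design -> on-target -> off-target -> qualification ->
# eligibility, with per-sample filter traces and a run manifest.

#' Run the full guide-selection pipeline
#'
#' Executes every stage in the published order on a cohort MAF, a reference
#' genome, a gene-class catalog and an expression table. Inputs may be given
#' as file paths or as the already-loaded objects. The per-sample clonality
#' threshold is computed on the sample's complete QC-passed SNV list, before
#' gene-class filtering. Samples without a single heterozygous SNV have an
#' undefined threshold and are skipped (logged in `skipped_samples`) but stay
#' in the eligibility denominator. Off-target scanning is only spent on
#' candidates that already pass the on-target cutoff.
#'
#' @param maf Path to a MAF file, or a somatic SNV data.frame.
#' @param genome Path to a FASTA file, or a `DNAStringSet`.
#' @param gene_catalog Path(s) to gene-class catalog files, or a
#'   `gene_catalog`.
#' @param expression Path to an expression TSV, or an `expression_table`.
#' @param hotspots Optional path or data.frame of hotspot entries.
#' @param recurrence Optional path or data.frame of a cohort-recurrence
#'   catalog; when given, SNVs absent from it are dropped after QC.
#' @param config A [pipeline_config()].
#' @param cfd_model A `cfd_model` (default the bundled synthetic model).
#' @param output_dir Optional directory; when given, writes
#'   `guide_report.tsv`, `eligibility.json`, `attrition.tsv` and
#'   `manifest.json`.
#' @return List of class `snvguide_run`: `candidates` (guide report table),
#'   `eligibility` (an `eligibility_summary`), `traces` (per-sample
#'   step counts), `thresholds` (list of `af_threshold`), `skipped_samples`,
#'   and `manifest`.
#' @export
run_pipeline <- function(maf, genome, gene_catalog, expression,
                         hotspots = NULL, recurrence = NULL,
                         config = pipeline_config(),
                         cfd_model = cfd_default_model(),
                         output_dir = NULL) {
  input_paths <- character(0)
  note_path <- function(x, nm) {
    if (is.character(x)) input_paths[nm] <<- x
  }
  note_path(maf, "maf"); note_path(genome, "genome")
  note_path(expression, "expression"); note_path(hotspots, "hotspots")
  note_path(recurrence, "recurrence")
  if (is.character(gene_catalog)) {
    input_paths[paste0("gene_catalog", seq_along(gene_catalog))] <- gene_catalog
  }

  snvs <- if (is.character(maf)) read_maf(maf) else maf
  validate_snvs(snvs)
  genome <- if (is.character(genome)) read_genome(genome) else genome
  catalog <- if (is.character(gene_catalog)) read_gene_catalog(gene_catalog)
             else gene_catalog
  expr <- if (is.character(expression)) read_expression(expression)
          else expression
  hotspots <- if (is.character(hotspots)) read_hotspots(hotspots) else hotspots
  recurrence <- if (is.character(recurrence)) read_recurrence_catalog(recurrence)
                else recurrence
  scorer <- resolve_scorer(config$scorer)

  samples <- unique(data.frame(sample_id = snvs$sample_id,
                               cancer_type = ifelse(is.na(snvs$cancer_type),
                                                    "unknown", snvs$cancer_type),
                               stringsAsFactors = FALSE))
  samples <- samples[order(samples$sample_id), , drop = FALSE]

  all_candidates <- list()
  traces <- list()
  thresholds <- list()
  skipped <- character(0)
  hotspot_flags <- stats::setNames(logical(nrow(samples)), samples$sample_id)

  for (sm in samples$sample_id) {
    s_all <- snvs[snvs$sample_id == sm, , drop = FALSE]
    s_qc <- qc_filter(s_all, config)
    s_qc <- call_zygosity(s_qc, config)
    s_qc <- recurrence_filter(s_qc, recurrence)
    if (!is.null(hotspots)) {
      hotspot_flags[sm] <- annotate_hotspot_carrier(s_qc, hotspots)
    }
    trace <- c(input = nrow(s_qc), after_gene_class = 0L, after_af = 0L,
               after_expression = 0L, after_design = 0L, after_on_target = 0L,
               after_off_target = 0L)
    thr <- tryCatch(compute_af_cut(s_qc, config),
                    af_cut_undefined = function(e) NULL)
    if (is.null(thr)) {
      skipped <- c(skipped, sm)
      traces[[sm]] <- trace
      next
    }
    thresholds[[sm]] <- thr
    s1 <- filter_by_gene_class(s_qc, catalog)
    trace["after_gene_class"] <- nrow(s1)
    s2 <- filter_by_af(s1, thr, config)
    trace["after_af"] <- nrow(s2)
    s3 <- filter_by_expression(s2, expr, config)
    trace["after_expression"] <- nrow(s3)

    snv_design <- snv_on <- snv_off <- character(0)
    if (nrow(s3) > 0) {
      for (i in seq_len(nrow(s3))) {
        snv_key <- paste(s3$chrom[i], s3$pos[i], s3$alt_allele[i])
        cand <- build_candidates(genome, s3[i, ], config)
        if (nrow(cand) == 0) next
        snv_design <- union(snv_design, snv_key)
        cand <- score_on_target(cand, scorer)
        cand_on <- cand[cand$on_target_score > config$on_target_min, ,
                        drop = FALSE]
        cand_fail <- cand[cand$on_target_score <= config$on_target_min, ,
                          drop = FALSE]
        if (nrow(cand_fail) > 0) {
          cand_fail$n_off_targets <- NA_integer_
          cand_fail$max_off_target_cfd <- NA_real_
          cand_fail$wt_allele_cfd <- NA_real_
          cand_fail$qualified <- FALSE
          all_candidates[[length(all_candidates) + 1L]] <- cand_fail
        }
        if (nrow(cand_on) == 0) next
        snv_on <- union(snv_on, snv_key)
        cand_on <- score_off_targets(cand_on, genome, config, cfd_model)
        cand_on <- qualify_guides(cand_on, config)
        attr(cand_on, "off_target_hits") <- NULL
        all_candidates[[length(all_candidates) + 1L]] <- cand_on
        if (any(cand_on$qualified)) snv_off <- union(snv_off, snv_key)
      }
    }
    trace["after_design"] <- length(snv_design)
    trace["after_on_target"] <- length(snv_on)
    trace["after_off_target"] <- length(snv_off)
    traces[[sm]] <- trace
  }

  candidates <- if (length(all_candidates) > 0) {
    do.call(rbind, all_candidates)
  } else {
    NULL
  }
  if (!is.null(candidates)) {
    candidates <- candidates[order(candidates$sample_id, candidates$chrom,
                                   candidates$pos, candidates$strand,
                                   candidates$spacer), , drop = FALSE]
    rownames(candidates) <- NULL
  }

  if (length(traces) == 0) {
    trace_df <- cbind(
      data.frame(sample_id = character(0), cancer_type = character(0),
                 stringsAsFactors = FALSE),
      as.data.frame(stats::setNames(
        rep(list(integer(0)), length(FILTER_STEPS)), FILTER_STEPS)))
  } else
  trace_df <- do.call(rbind, lapply(names(traces), function(sm)
    cbind(data.frame(sample_id = sm,
                     cancer_type = samples$cancer_type[match(sm, samples$sample_id)],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(traces[[sm]])))))

  eligibility <- summarize_eligibility(
    candidates, samples,
    hotspot_flags = if (is.null(hotspots)) NULL else hotspot_flags)

  result <- list(candidates = candidates, eligibility = eligibility,
                 traces = trace_df, thresholds = thresholds,
                 skipped_samples = skipped)

  manifest <- list(
    tool = "snvguide",
    version = as.character(utils::packageVersion("snvguide")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    scorer = scorer$name,
    inputs = as.list(input_paths[file.exists(input_paths)]),
    input_digests = as.list(unname(tools::md5sum(
      input_paths[file.exists(input_paths)]))),
    n_samples = nrow(samples),
    skipped_samples = skipped,
    stage_counts = trace_df
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- c(
      guide_report = file.path(output_dir, "guide_report.tsv"),
      eligibility = file.path(output_dir, "eligibility.json"),
      attrition = file.path(output_dir, "attrition.tsv")
    )
    write_guide_report(candidates, out["guide_report"])
    write_eligibility_json(eligibility, out["eligibility"])
    write_attrition(step_attrition_table(trace_df, "cancer_type"),
                    out["attrition"])
    manifest$outputs <- as.list(out)
    manifest$output_digests <- as.list(unname(tools::md5sum(out)))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  }
  result$manifest <- manifest
  class(result) <- "snvguide_run"
  result
}

#' @export
print.snvguide_run <- function(x, ...) {
  cat("snvguide pipeline run:", x$eligibility$overall$n_samples, "samples,",
      if (is.null(x$candidates)) 0L else nrow(x$candidates),
      "guide candidates,",
      if (is.null(x$candidates)) 0L else sum(x$candidates$qualified),
      "qualified\n")
  print(x$eligibility)
  invisible(x)
}
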