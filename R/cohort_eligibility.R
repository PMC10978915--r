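# Cohort-level aggregation: eligibility counts per sample and cancer type,
# the hotspot-strategy comparison, attrition tables and AF-distribution
# summaries. An applicable (eligible) patient has >= 1 qualified guide.

#' Summarize cohort eligibility
#'
#' Aggregates qualified guide candidates into per-sample, per-cancer-type and
#' overall eligibility statistics, together with the comparison against the
#' hotspot-mutation strategy (Venn partition of eligible-by-passenger vs
#' hotspot-carrier). Samples with zero candidates are counted as ineligible —
#' they stay in every denominator. Percentages are kept at full precision;
#' rounding happens only when printing.
#'
#' @param candidates Guide candidate table with a `qualified` column (may be
#'   empty/`NULL`).
#' @param samples Data.frame with `sample_id` and `cancer_type`, one row per
#'   analyzed sample. Every candidate's sample must appear here.
#' @param hotspot_flags Optional named logical vector, sample -> carries a
#'   cataloged hotspot mutation (see [annotate_hotspot_carrier()]).
#' @return Object of class `eligibility_summary`: list with `per_sample`
#'   (data.frame), `per_type` (data.frame) and `overall` (list, including the
#'   pooled and type-averaged eligible percentages and the Venn counts
#'   `n_both`, `n_only_passenger`, `n_only_hotspot`, `n_neither`).
#' @export
summarize_eligibility <- function(candidates, samples, hotspot_flags = NULL) {
  stopifnot(all(c("sample_id", "cancer_type") %in% names(samples)))
  samples <- unique(samples[, c("sample_id", "cancer_type")])
  if (anyDuplicated(samples$sample_id)) {
    stop("samples table maps a sample_id to more than one cancer_type")
  }
  if (!is.null(candidates) && nrow(candidates) > 0) {
    orphan <- setdiff(unique(candidates$sample_id), samples$sample_id)
    if (length(orphan) > 0) {
      stop("candidate sample(s) absent from the sample table: ",
           paste(orphan, collapse = ", "))
    }
    nq <- tapply(candidates$qualified, candidates$sample_id, sum)
  } else {
    nq <- integer(0)
  }
  n_qualified <- as.integer(nq[samples$sample_id])
  n_qualified[is.na(n_qualified)] <- 0L
  hot <- if (is.null(hotspot_flags)) rep(FALSE, nrow(samples)) else {
    h <- hotspot_flags[samples$sample_id]
    h[is.na(h)] <- FALSE
    as.logical(h)
  }
  per_sample <- data.frame(
    sample_id = samples$sample_id,
    cancer_type = samples$cancer_type,
    n_qualified_guides = n_qualified,
    eligible = n_qualified >= 1L,
    hotspot_carrier = hot,
    stringsAsFactors = FALSE
  )
  per_sample <- per_sample[order(per_sample$sample_id), , drop = FALSE]
  rownames(per_sample) <- NULL

  types <- sort(unique(per_sample$cancer_type))
  if (length(types) == 0) {
    per_type <- data.frame(cancer_type = character(0), n_samples = integer(0),
                           n_eligible = integer(0), pct_eligible = numeric(0),
                           n_hotspot = integer(0), pct_hotspot = numeric(0),
                           stringsAsFactors = FALSE)
  } else
  per_type <- do.call(rbind, lapply(types, function(ct) {
    s <- per_sample[per_sample$cancer_type == ct, ]
    data.frame(cancer_type = ct, n_samples = nrow(s),
               n_eligible = sum(s$eligible),
               pct_eligible = 100 * mean(s$eligible),
               n_hotspot = sum(s$hotspot_carrier),
               pct_hotspot = 100 * mean(s$hotspot_carrier),
               stringsAsFactors = FALSE)
  }))
  rownames(per_type) <- NULL

  n <- nrow(per_sample)
  overall <- list(
    n_samples = n,
    n_eligible = sum(per_sample$eligible),
    pct_eligible = 100 * mean(per_sample$eligible),
    pct_eligible_type_averaged =
      if (nrow(per_type) > 0) mean(per_type$pct_eligible) else NA_real_,
    n_hotspot = sum(per_sample$hotspot_carrier),
    pct_hotspot = 100 * mean(per_sample$hotspot_carrier),
    n_both = sum(per_sample$eligible & per_sample$hotspot_carrier),
    n_only_passenger = sum(per_sample$eligible & !per_sample$hotspot_carrier),
    n_only_hotspot = sum(!per_sample$eligible & per_sample$hotspot_carrier),
    n_neither = sum(!per_sample$eligible & !per_sample$hotspot_carrier)
  )
  structure(list(per_sample = per_sample, per_type = per_type,
                 overall = overall),
            class = "eligibility_summary")
}

#' @export
print.eligibility_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "Cohort eligibility: %d/%d samples eligible (%.1f%% pooled, %.1f%% type-averaged); %d (%.1f%%) hotspot carriers\n",
    o$n_eligible, o$n_samples, o$pct_eligible,
    o$pct_eligible_type_averaged, o$n_hotspot, o$pct_hotspot))
  cat(sprintf("Venn: both=%d only-passenger=%d only-hotspot=%d neither=%d\n",
              o$n_both, o$n_only_passenger, o$n_only_hotspot, o$n_neither))
  invisible(x)
}

FILTER_STEPS <- c("input", "after_gene_class", "after_af", "after_expression",
                  "after_design", "after_on_target", "after_off_target")

#' Per-group step attrition table
#'
#' Sums per-step SNV counts across samples or cancer types. Counts are
#' non-increasing along the step order by construction of the traces.
#'
#' @param traces Data.frame of per-sample filter traces (one row per sample,
#'   columns `sample_id`, `cancer_type`, then the step counts `input`,
#'   `after_gene_class`, `after_af`, `after_expression`, `after_design`,
#'   `after_on_target`, `after_off_target`).
#' @param group_by `"sample"` or `"cancer_type"`.
#' @return Data.frame with one row per group and summed step counts.
#' @export
step_attrition_table <- function(traces, group_by = c("sample", "cancer_type")) {
  group_by <- match.arg(group_by)
  missing <- setdiff(FILTER_STEPS, names(traces))
  if (length(missing) > 0) {
    stop("traces missing step column(s): ", paste(missing, collapse = ", "))
  }
  key <- if (group_by == "sample") traces$sample_id else traces$cancer_type
  groups <- sort(unique(key))
  if (length(groups) == 0) {
    out <- cbind(data.frame(g = character(0), stringsAsFactors = FALSE),
                 as.data.frame(stats::setNames(
                   rep(list(integer(0)), length(FILTER_STEPS)), FILTER_STEPS)))
    names(out)[1] <- group_by
    return(out)
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    rows <- traces[key == g, FILTER_STEPS, drop = FALSE]
    cbind(data.frame(group = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(colSums(rows))))
  }))
  names(out)[1] <- group_by
  rownames(out) <- NULL
  out
}

#' Compare allele-frequency distributions across selection groups
#'
#' Descriptive statistics (n, median, quartiles) for the selected passenger
#' SNVs, the hotspot mutations, and the pre-selection SNV pool, plus a
#' two-sample Wilcoxon rank-sum test between the selected and pre-selection
#' AFs (descriptive only — no p-value gates any filtering decision). Empty
#' groups are dropped with a warning.
#'
#' @param selected,hotspot_snvs,all_snvs SNV tables or bare numeric AF
#'   vectors.
#' @return List with `stats` (data.frame: group, n, median, q25, q75) and,
#'   when both are non-empty, `test` (list: name, statistic, p_value) for
#'   selected vs all.
#' @export
compare_af_distributions <- function(selected, hotspot_snvs = NULL,
                                     all_snvs = NULL) {
  afs <- function(x) {
    if (is.null(x)) return(numeric(0))
    v <- if (is.data.frame(x)) x$allele_frequency else as.numeric(x)
    v[!is.na(v)]
  }
  groups <- list(selected = afs(selected), hotspot = afs(hotspot_snvs),
                 all = afs(all_snvs))
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0]
  if (length(empty) > 0) {
    warning("empty AF group(s) dropped: ", paste(empty, collapse = ", "))
  }
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  stats_df <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), median = q[2], q25 = q[1], q75 = q[3],
               stringsAsFactors = FALSE)
  }))
  out <- list(stats = stats_df)
  if (all(c("selected", "all") %in% names(groups))) {
    wt <- suppressWarnings(stats::wilcox.test(groups$selected, groups$all))
    out$test <- list(name = "Wilcoxon rank-sum (selected vs pre-selection)",
                     statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  out
}
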