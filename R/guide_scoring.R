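# On-target scoring (pluggable), exhaustive off-target enumeration, wild-type
# allele scoring, and final qualification.

#' Construct an on-target scorer
#'
#' A scorer is a named, deterministic function from a 30-nt sequence context
#' (4 nt upstream + 20-nt protospacer + 3-nt PAM + 3 nt downstream) to a
#' score in \[0, 1\]. The interface is the adapter slot for external
#' efficiency models (e.g. an Azimuth implementation); the package bundles a
#' documented GC surrogate for self-contained runs.
#'
#' @param name Scorer name (recorded in reports/manifests).
#' @param score_fn Function `character(1) -> numeric(1)`.
#' @return Object of class `on_target_scorer`.
#' @export
on_target_scorer <- function(name, score_fn) {
  stopifnot(is.character(name), is.function(score_fn))
  structure(list(name = name, score = score_fn), class = "on_target_scorer")
}

#' Bundled GC-content surrogate on-target scorer
#'
#' `score = clamp(1 - 2 * |GC20 - 0.55|, 0, 1)` where `GC20` is the GC
#' fraction of the 20-nt spacer (context positions 5-24). Deterministic and
#' defined for every ACGT 30-mer; it rewards the mid-high GC content typical
#' of efficient guides and is a documented surrogate, not a trained
#' efficiency model.
#'
#' @return An `on_target_scorer` named `"gc_surrogate"`.
#' @export
gc_surrogate_scorer <- function() {
  on_target_scorer("gc_surrogate", function(context30) {
    if (nchar(context30) != 30 || !is_acgt(context30)) {
      stop("on-target scoring requires a 30-nt ACGT context, got: ", context30)
    }
    spacer <- substr(context30, 5, 24)
    gc <- sum(strsplit(spacer, "")[[1]] %in% c("G", "C")) / 20
    max(0, min(1, 1 - 2 * abs(gc - 0.55)))
  })
}

# Named scorer registry for config-driven selection.
resolve_scorer <- function(scorer) {
  if (inherits(scorer, "on_target_scorer")) return(scorer)
  switch(scorer,
         gc_surrogate = gc_surrogate_scorer(),
         stop("unknown on-target scorer: ", scorer))
}

#' Attach on-target scores to guide candidates
#'
#' @param candidates Candidate table from [build_candidates()].
#' @param scorer An `on_target_scorer` or registered scorer name.
#' @return `candidates` with an `on_target_score` column.
#' @export
score_on_target <- function(candidates, scorer = gc_surrogate_scorer()) {
  scorer <- resolve_scorer(scorer)
  candidates$on_target_score <- if (nrow(candidates) == 0) numeric(0) else {
    vapply(candidates$context30_mut, scorer$score, numeric(1), USE.NAMES = FALSE)
  }
  attr(candidates, "scorer") <- scorer$name
  candidates
}

#' Exhaustive mismatch-tolerant off-target scan
#'
#' Finds every placement on both strands of the genome whose 20-nt sequence
#' matches the spacer with at most `max_mismatches` mismatches *and* whose
#' adjacent 3-nt PAM matches a configured motif. The search is exact and
#' exhaustive (Biostrings pattern matching over every contig; no heuristic
#' pruning). Ambiguous genomic bases (N) never match, in the spacer or the
#' PAM. Placements overlapping `exclude` (normally the candidate's own locus,
#' which would otherwise self-match) are removed. Hits are sorted by
#' (chrom, start, strand) and carry their CFD score.
#'
#' @param spacer 20-nt spacer (5'->3').
#' @param genome A `DNAStringSet`.
#' @param config A [pipeline_config()] (mismatch budget, PAM motifs).
#' @param exclude Optional list/one-row data.frame with `chrom`, `start`,
#'   `end`: protospacer interval to exclude (1-based inclusive).
#' @param model `cfd_model` used to score hits.
#' @return Data.frame of hits: `chrom`, `start`, `end` (protospacer span,
#'   1-based inclusive, plus strand), `strand`, `site_seq`, `pam_seq` (both
#'   5'->3' on the protospacer strand), `n_mismatches`, `mismatch_positions`
#'   (comma-separated, 1 = PAM-distal) and `cfd`.
#' @export
enumerate_off_targets <- function(spacer, genome, config = pipeline_config(),
                                  exclude = NULL,
                                  model = cfd_default_model()) {
  stopifnot(nchar(spacer) == 20, is_acgt(spacer))
  spacer <- toupper(spacer)
  pat_fwd <- Biostrings::DNAString(spacer)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  rows <- list()
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    clen <- length(subject)
    # plus strand: protospacer then PAM to the right
    m <- Biostrings::matchPattern(pat_fwd, subject,
                                  max.mismatch = config$max_mismatches,
                                  with.indels = FALSE, fixed = TRUE)
    for (k in seq_along(m)) {
      s <- Biostrings::start(m)[k]; e <- Biostrings::end(m)[k]
      if (e + 3L > clen) next
      pam <- toupper(as.character(Biostrings::subseq(subject, e + 1L, e + 3L)))
      if (!is_acgt(pam) || !matches_any_motif(pam, config$pam_motifs)) next
      site <- toupper(as.character(Biostrings::subseq(subject, s, e)))
      mm <- mismatch_positions(spacer, site)
      if (length(mm) > config$max_mismatches || !is_acgt(site)) next
      rows[[length(rows) + 1L]] <- list(chrom = chrom, start = s, end = e,
                                        strand = "+", site = site, pam = pam,
                                        mm = mm)
    }
    # minus strand: reverse-complement spacer, PAM to the left (plus frame)
    m <- Biostrings::matchPattern(pat_rev, subject,
                                  max.mismatch = config$max_mismatches,
                                  with.indels = FALSE, fixed = TRUE)
    for (k in seq_along(m)) {
      s <- Biostrings::start(m)[k]; e <- Biostrings::end(m)[k]
      if (s - 3L < 1L) next
      pam <- revcomp_chr(toupper(as.character(
        Biostrings::subseq(subject, s - 3L, s - 1L))))
      if (!is_acgt(pam) || !matches_any_motif(pam, config$pam_motifs)) next
      site <- revcomp_chr(toupper(as.character(Biostrings::subseq(subject, s, e))))
      mm <- mismatch_positions(spacer, site)
      if (length(mm) > config$max_mismatches || !is_acgt(site)) next
      rows[[length(rows) + 1L]] <- list(chrom = chrom, start = s, end = e,
                                        strand = "-", site = site, pam = pam,
                                        mm = mm)
    }
  }
  if (!is.null(exclude)) {
    rows <- Filter(function(r) {
      !(r$chrom == exclude$chrom && r$start <= exclude$end &&
          r$end >= exclude$start)
    }, rows)
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      site_seq = character(0), pam_seq = character(0),
                      n_mismatches = integer(0),
                      mismatch_positions = character(0), cfd = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    site_seq = vapply(rows, `[[`, character(1), "site"),
    pam_seq = vapply(rows, `[[`, character(1), "pam"),
    n_mismatches = vapply(rows, function(r) length(r$mm), integer(1)),
    mismatch_positions = vapply(rows, function(r)
      paste(r$mm, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  out$cfd <- vapply(seq_len(nrow(out)), function(i)
    cfd_score(spacer, out$site_seq[i], out$pam_seq[i], model), numeric(1))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CFD of a guide against its wild-type cognate allele
#'
#' Reports how strongly the mutant-specific guide would cut the *wild-type*
#' allele at its own locus: for `snv_in_pam` designs the wild-type placement
#' lacks a canonical PAM and the score is 0; for `snv_in_seed` designs it is
#' the CFD of the spacer against the wild-type protospacer. Reported as
#' `wt_allele_cfd`; by default it does *not* enter qualification (see
#' `count_wt_as_offtarget`). A degenerate identical mutant/wild-type placement
#' scores 1 with an integrity warning.
#'
#' @param spacer_mut,spacer_wt 20-nt mutant/wild-type spacers.
#' @param pam_wt Wild-type 3-nt PAM triplet at the placement.
#' @param model A `cfd_model`.
#' @param pam_motifs PAM motifs considered cleavage-competent.
#' @return CFD score in \[0, 1\].
#' @export
score_wt_allele <- function(spacer_mut, spacer_wt, pam_wt,
                            model = cfd_default_model(), pam_motifs = "NGG") {
  if (!matches_any_motif(toupper(pam_wt), pam_motifs)) return(0.0)
  if (identical(toupper(spacer_mut), toupper(spacer_wt))) {
    warning("mutant and wild-type placements are identical; ",
            "guide cannot discriminate alleles")
    return(1.0)
  }
  cfd_score(spacer_mut, spacer_wt, pam_wt, model)
}

#' Enumerate and attach off-target evidence for each candidate
#'
#' Runs [enumerate_off_targets()] per candidate with the candidate's own
#' protospacer locus excluded, records `n_off_targets` and
#' `max_off_target_cfd` (`NA` when no hits), and computes `wt_allele_cfd`
#' via [score_wt_allele()]. With `count_wt_as_offtarget` set, the wild-type
#' allele CFD participates in `max_off_target_cfd`.
#'
#' @param candidates Candidate table (scored or not).
#' @param genome A `DNAStringSet`.
#' @param config A [pipeline_config()].
#' @param model A `cfd_model`.
#' @return `candidates` with off-target columns; the per-candidate hit tables
#'   are attached as attribute `off_target_hits` (a list).
#' @export
score_off_targets <- function(candidates, genome, config = pipeline_config(),
                              model = cfd_default_model()) {
  n <- nrow(candidates)
  hits_list <- vector("list", n)
  n_hits <- integer(n); max_cfd <- rep(NA_real_, n); wt_cfd <- numeric(n)
  for (i in seq_len(n)) {
    cand <- candidates[i, ]
    hits <- enumerate_off_targets(
      cand$spacer, genome, config,
      exclude = list(chrom = cand$chrom, start = cand$proto_start,
                     end = cand$proto_end),
      model = model)
    hits_list[[i]] <- hits
    n_hits[i] <- nrow(hits)
    wt_cfd[i] <- score_wt_allele(cand$spacer, cand$spacer_wt, cand$pam_wt,
                                 model, config$pam_motifs)
    cfds <- hits$cfd
    if (config$count_wt_as_offtarget) cfds <- c(cfds, wt_cfd[i])
    if (length(cfds) > 0) max_cfd[i] <- max(cfds)
  }
  candidates$n_off_targets <- n_hits
  candidates$max_off_target_cfd <- max_cfd
  candidates$wt_allele_cfd <- wt_cfd
  attr(candidates, "off_target_hits") <- hits_list
  candidates
}

#' Final guide qualification
#'
#' A guide qualifies iff its on-target score is strictly greater than
#' `on_target_min` (default 0.5) *and* it has either no off-target hits or a
#' maximum off-target CFD at or below `off_target_max_cfd` (default 0.175;
#' guides are filtered only when an off-target scores strictly above the
#' cutoff). A pure function of the attached scores — hit order is irrelevant.
#'
#' @param candidates Candidate table with `on_target_score`, `n_off_targets`
#'   and `max_off_target_cfd` populated.
#' @param config A [pipeline_config()].
#' @return `candidates` with a logical `qualified` column.
#' @export
qualify_guides <- function(candidates, config = pipeline_config()) {
  if (nrow(candidates) == 0) {
    candidates$qualified <- logical(0)
    return(candidates)
  }
  on_ok <- !is.na(candidates$on_target_score) &
    candidates$on_target_score > config$on_target_min
  off_ok <- is.na(candidates$max_off_target_cfd) |
    candidates$max_off_target_cfd <= config$off_target_max_cfd
  candidates$qualified <- on_ok & off_ok
  candidates
}
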