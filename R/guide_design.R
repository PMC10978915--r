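# Allele-discriminating protospacer/PAM enumeration. Spacer positions are
# numbered 1 (PAM-distal) to 20 (PAM-proximal); position 0 marks an SNV inside
# the PAM. Two design classes exist:
#   snv_in_seed — the SNV lies in the PAM-proximal seed of an existing
#                 protospacer (default spacer positions 9-20, i.e. within 12
#                 bp of the PAM), so the guide mismatches the wild-type allele
#                 where Cas9 is least tolerant;
#   snv_in_pam  — the SNV itself creates a new NGG PAM (at PAM position 2 or
#                 3); the wild-type allele has no cleavage-competent site at
#                 all. An SNV at PAM position 1 (the N) cannot discriminate
#                 alleles and is rejected.

# Scan one strand of a (mut, wt) context pair. Returns sites in the scanned
# orientation: i = protospacer start, PAM at i+20..i+22.
scan_strand <- function(mut_chars, wt_chars, snv_offset, config) {
  L <- length(mut_chars)
  out <- list()
  if (L < 23) return(out)
  seed_lo <- 21L - config$seed_window
  for (i in seq_len(L - 22L)) {
    pam_mut <- paste(mut_chars[(i + 20L):(i + 22L)], collapse = "")
    if (!matches_any_motif(pam_mut, config$pam_motifs)) next
    spacer_mut <- paste(mut_chars[i:(i + 19L)], collapse = "")
    if (!is_acgt(spacer_mut) || !is_acgt(pam_mut)) next
    rel <- snv_offset - i + 1L  # 1..20 spacer, 21..23 PAM
    if (rel >= 1L && rel <= 20L) {
      if (rel < seed_lo) next  # PAM-distal: mismatch too tolerated
      design_class <- "snv_in_seed"
      snv_pos <- rel
    } else if (rel == 22L || rel == 23L) {
      # SNV sits on a constrained PAM base: mutant has the motif, the
      # wild-type triplet must lack it (new-PAM design).
      pam_wt <- paste(wt_chars[(i + 20L):(i + 22L)], collapse = "")
      if (matches_any_motif(pam_wt, config$pam_motifs)) next
      design_class <- "snv_in_pam"
      snv_pos <- 0L
    } else {
      next  # SNV outside the window, or on the unconstrained PAM N
    }
    out[[length(out) + 1L]] <- list(
      i = i,
      spacer_mut = spacer_mut,
      spacer_wt = paste(wt_chars[i:(i + 19L)], collapse = ""),
      pam_mut = pam_mut,
      pam_wt = paste(wt_chars[(i + 20L):(i + 22L)], collapse = ""),
      snv_position_in_spacer = snv_pos,
      design_class = design_class
    )
  }
  out
}

#' Enumerate allele-discriminating protospacer placements around an SNV
#'
#' Scans every 23-nt protospacer+PAM window on both strands of the mutant
#' context and returns the placements that discriminate the mutant from the
#' wild-type allele: either the SNV falls in the PAM-proximal seed
#' (`snv_in_seed`, spacer positions `21 - seed_window` to 20) of a window
#' whose PAM is intact on the mutant haplotype, or the SNV creates a new PAM
#' at PAM position 2 or 3 that the wild-type triplet lacks (`snv_in_pam`).
#' Windows containing non-ACGT characters are excluded; an SNV on the
#' unconstrained PAM N is rejected.
#'
#' @param wt_context,mut_context Equal-length wild-type/mutant sequences from
#'   [extract_context()].
#' @param snv_offset 1-based position of the SNV within the contexts.
#' @param config A [pipeline_config()].
#' @return Data.frame of sites with context coordinates
#'   (`ctx_proto_start`/`ctx_proto_end`, plus-strand 1-based inclusive),
#'   `strand`, mutant/wild-type spacer and PAM strings (5'->3' on the
#'   protospacer strand), `snv_position_in_spacer` (0 for PAM designs) and
#'   `design_class`. Zero rows when no placement qualifies.
#' @export
find_design_sites <- function(wt_context, mut_context, snv_offset,
                              config = pipeline_config()) {
  stopifnot(nchar(wt_context) == nchar(mut_context))
  L <- nchar(mut_context)
  mut_chars <- strsplit(toupper(mut_context), "")[[1]]
  wt_chars <- strsplit(toupper(wt_context), "")[[1]]

  rows <- list()
  add <- function(s, strand) {
    if (strand == "+") {
      ps <- s$i; pe <- s$i + 19L
    } else {
      # scanned on the reverse complement: map back to plus coordinates
      ps <- L - (s$i + 19L) + 1L; pe <- L - s$i + 1L
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      strand = strand, ctx_proto_start = ps, ctx_proto_end = pe,
      spacer_mut = s$spacer_mut, spacer_wt = s$spacer_wt,
      pam_mut = s$pam_mut, pam_wt = s$pam_wt,
      snv_position_in_spacer = s$snv_position_in_spacer,
      design_class = s$design_class,
      stringsAsFactors = FALSE
    )
  }
  for (s in scan_strand(mut_chars, wt_chars, snv_offset, config)) add(s, "+")
  rc_mut <- rev(chartr("ACGTN", "TGCAN", mut_chars))
  rc_wt <- rev(chartr("ACGTN", "TGCAN", wt_chars))
  rc_offset <- L - snv_offset + 1L
  for (s in scan_strand(rc_mut, rc_wt, rc_offset, config)) add(s, "-")

  if (length(rows) == 0) {
    return(data.frame(
      strand = character(0), ctx_proto_start = integer(0),
      ctx_proto_end = integer(0), spacer_mut = character(0),
      spacer_wt = character(0), pam_mut = character(0),
      pam_wt = character(0), snv_position_in_spacer = integer(0),
      design_class = character(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("ctx_proto_start", "strand")]), , drop = FALSE]
  out <- out[order(out$ctx_proto_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build scored-ready guide candidates for one SNV
#'
#' Runs [extract_context()] and [find_design_sites()], converts site
#' coordinates to genome coordinates, and assembles the 30-nt scoring context
#' (4 nt upstream + 20-nt protospacer + 3-nt PAM + 3 nt downstream, on the
#' protospacer strand, mutant allele). Reverse-strand candidates are reported
#' reverse-complemented so spacers always read 5'->3' with the PAM 3'.
#' Placements that cannot supply the full 30-nt context (contig edge) are
#' dropped; the number dropped is recorded in attribute `n_context_dropped`.
#'
#' @param genome A `DNAStringSet`.
#' @param snv One-row SNV data.frame.
#' @param config A [pipeline_config()].
#' @param radius Context half-width passed to [extract_context()].
#' @return Data.frame of guide candidates: SNV annotation columns plus
#'   `proto_start`/`proto_end` (genome, 1-based inclusive, plus strand),
#'   `strand`, spacer/PAM strings, `design_class`, `snv_spacer_position` and
#'   `context30_mut`.
#' @export
build_candidates <- function(genome, snv, config = pipeline_config(),
                             radius = 30L) {
  ctx <- extract_context(genome, snv, radius = radius)
  sites <- find_design_sites(ctx$wt_context, ctx$mut_context, ctx$snv_offset,
                             config)
  n_dropped <- 0L
  rows <- list()
  L <- nchar(ctx$mut_context)
  rc_mut <- revcomp_chr(ctx$mut_context)
  for (j in seq_len(nrow(sites))) {
    s <- sites[j, ]
    if (s$strand == "+") {
      i <- s$ctx_proto_start
      lo <- i - 4L; hi <- i + 25L
      ctx_str <- ctx$mut_context
    } else {
      i <- L - s$ctx_proto_end + 1L  # start in the reverse-complement frame
      lo <- i - 4L; hi <- i + 25L
      ctx_str <- rc_mut
    }
    if (lo < 1L || hi > L) {
      n_dropped <- n_dropped + 1L
      next
    }
    context30 <- substr(ctx_str, lo, hi)
    if (nchar(context30) != 30L || !is_acgt(context30)) {
      n_dropped <- n_dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = snv$sample_id,
      cancer_type = if ("cancer_type" %in% names(snv)) snv$cancer_type else NA_character_,
      chrom = ctx$chrom, pos = as.integer(snv$pos),
      ref_allele = snv$ref_allele, alt_allele = snv$alt_allele,
      gene_symbol = snv$gene_symbol,
      gene_class = if ("gene_class" %in% names(snv)) snv$gene_class else NA_character_,
      zygosity = snv$zygosity,
      allele_frequency = snv$allele_frequency,
      proto_start = ctx$ctx_start + s$ctx_proto_start - 1L,
      proto_end = ctx$ctx_start + s$ctx_proto_end - 1L,
      strand = s$strand,
      spacer = s$spacer_mut, spacer_wt = s$spacer_wt,
      pam = s$pam_mut, pam_wt = s$pam_wt,
      design_class = s$design_class,
      snv_spacer_position = s$snv_position_in_spacer,
      context30_mut = context30,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) == 0) NULL else do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      sample_id = character(0), cancer_type = character(0),
      chrom = character(0), pos = integer(0), ref_allele = character(0),
      alt_allele = character(0), gene_symbol = character(0),
      gene_class = character(0), zygosity = character(0),
      allele_frequency = numeric(0), proto_start = integer(0),
      proto_end = integer(0), strand = character(0), spacer = character(0),
      spacer_wt = character(0), pam = character(0), pam_wt = character(0),
      design_class = character(0), snv_spacer_position = integer(0),
      context30_mut = character(0), stringsAsFactors = FALSE
    )
  }
  attr(out, "n_context_dropped") <- n_dropped
  out
}
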