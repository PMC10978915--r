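# Deterministic synthetic-cohort generator. Emulates the pipeline's real
# inputs (reference genome, MAF cohort, expression table, gene-class and
# hotspot catalogs) with planted ground truth: chosen samples carry an
# engineered SNV in an essential or haploinsufficient gene that is guaranteed
# to survive every pipeline stage, and all other (background) mutations are
# confined to oncogene/other genes so they can never produce a qualified
# guide. The truth JSON is therefore exact by construction.

#' Specification of a synthetic cohort
#'
#' Defaults are the package's reference study conditions: a 5 x 50 kb genome
#' carrying 30 gene models (8 essential, 8 haploinsufficient, 4 oncogene, 10
#' other), 20 samples over 4 cancer-type labels, ~25 background somatic SNVs
#' per sample, tumor purity 0.95 and 70% clonal mutations. Heterozygous
#' clonal allele frequencies are drawn from a Beta centered at
#' `0.5 * purity`, homozygous clonal AFs near `purity`, subclonal AFs from a
#' Beta centered at 0.15. Read depth is fixed at 1000 so each AF is exactly
#' `alt_count / 1000` and files round-trip byte-identically. Three samples
#' are planted eligible; planted heterozygous SNVs get AF 0.80 (above any
#' realized AF_cut, below the 0.9 homozygosity rule) and planted homozygous
#' SNVs AF 0.95.
#'
#' @param seed Integer seed; every stochastic draw flows from it.
#' @param n_contigs,contig_length Genome geometry.
#' @param n_samples Cohort size.
#' @param cancer_types Labels recycled over samples.
#' @param muts_per_sample Background somatic SNVs per sample.
#' @param purity Tumor purity driving the AF model.
#' @param clonal_fraction Fraction of background SNVs that are clonal.
#' @param n_planted_eligible Number of samples planted to be eligible.
#' @param planted_design_classes Design classes cycled over planted guides
#'   (`"snv_in_seed"`/`"snv_in_pam"`).
#' @param n_hotspot_carriers Samples planted with a cataloged hotspot
#'   mutation.
#' @param gene_length Length of each gene model (bp).
#' @return Object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(seed = 1L,
                                  n_contigs = 5L,
                                  contig_length = 50000L,
                                  n_samples = 20L,
                                  cancer_types = c("COAD", "BRCA", "LUAD", "HNSC"),
                                  muts_per_sample = 25L,
                                  purity = 0.95,
                                  clonal_fraction = 0.7,
                                  n_planted_eligible = 3L,
                                  planted_design_classes = c("snv_in_seed",
                                                             "snv_in_pam",
                                                             "snv_in_seed"),
                                  n_hotspot_carriers = 5L,
                                  gene_length = 1200L) {
  stopifnot(n_contigs >= 1, contig_length >= 5000, n_samples >= 1,
            purity > 0, purity <= 1, clonal_fraction >= 0, clonal_fraction <= 1,
            n_planted_eligible <= n_samples,
            all(planted_design_classes %in% c("snv_in_seed", "snv_in_pam")))
  spec <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_samples = as.integer(n_samples), cancer_types = cancer_types,
    muts_per_sample = as.integer(muts_per_sample), purity = purity,
    clonal_fraction = clonal_fraction,
    n_planted_eligible = as.integer(n_planted_eligible),
    planted_design_classes = planted_design_classes,
    n_hotspot_carriers = as.integer(n_hotspot_carriers),
    gene_length = as.integer(gene_length),
    het_af_planted = 0.80, hom_af_planted = 0.95, depth = 1000L
  )
  class(spec) <- "synthetic_cohort_spec"
  spec
}

# AF model draws (exposed so distributional realism is testable directly).
# Heterozygous clonal AFs: Beta with mean 0.5*purity, concentration 60.
draw_het_clonal_af <- function(n, purity) {
  m <- 0.5 * purity
  stats::rbeta(n, m * 60, (1 - m) * 60)
}
draw_hom_clonal_af <- function(n, purity) {
  stats::rbeta(n, purity * 200, (1 - purity) * 200)
}
draw_subclonal_af <- function(n) {
  stats::rbeta(n, 0.15 * 40, 0.85 * 40)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# 20-mer with exactly `gc` G/C bases (spacer backbone for planted guides).
random_spacer <- function(gc = 11L) {
  bases <- c(sample(c("G", "C"), gc, replace = TRUE),
             sample(c("A", "T"), 20L - gc, replace = TRUE))
  paste(sample(bases), collapse = "")
}

substr_assign <- function(s, start, value) {
  substr(s, start, start + nchar(value) - 1L) <- value
  s
}

#' Generate a synthetic cohort bundle
#'
#' Writes `genome.fa`, `cohort.maf`, `expression.tsv`, `gene_catalog.tsv`,
#' `hotspots.tsv` and `truth.json` into `dir`. The same spec and seed always
#' produce byte-identical files. The generator verifies its own planting by
#' running the actual filter and design stages on each planted SNV and aborts
#' (rather than emitting a wrong truth file) if a planted guide would not
#' survive; accidental genome near-matches to a planted spacer are scrubbed
#' so the truth is exhaustive.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param config The [pipeline_config()] the planted truth must hold under.
#' @return List with `paths` (named file paths), `truth` (the planted facts,
#'   as written to JSON) and `spec`.
#' @export
generate_cohort <- function(spec = synthetic_cohort_spec(), dir,
                            config = pipeline_config()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  ## --- genome and gene models ------------------------------------------
  contigs <- paste0("ctg", seq_len(spec$n_contigs))
  genome_chr <- stats::setNames(
    vapply(seq_len(spec$n_contigs), function(i) random_dna(spec$contig_length),
           character(1)),
    contigs)

  class_counts <- c(essential = 8L, haploinsufficient = 8L, oncogene = 4L,
                    other = 10L)
  gene_classes <- rep(names(class_counts), class_counts)
  n_genes <- length(gene_classes)
  prefix <- c(essential = "ESS", haploinsufficient = "HAP",
              oncogene = "ONC", other = "OTH")
  idx_within <- stats::setNames(rep(0L, 4), names(class_counts))
  symbols <- character(n_genes)
  for (g in seq_len(n_genes)) {
    cl <- gene_classes[g]
    idx_within[cl] <- idx_within[cl] + 1L
    symbols[g] <- sprintf("%s%02d", prefix[cl], idx_within[cl])
  }
  per_contig <- ceiling(n_genes / spec$n_contigs)
  spacing <- (spec$contig_length - 4000L) %/% per_contig
  if (spacing < spec$gene_length + 500L) {
    stop("planting infeasible: contigs too short for ", n_genes,
         " gene models of length ", spec$gene_length)
  }
  genes <- data.frame(
    gene_symbol = symbols, gene_class = gene_classes,
    chrom = contigs[((seq_len(n_genes) - 1L) %% spec$n_contigs) + 1L],
    stringsAsFactors = FALSE
  )
  slot <- (seq_len(n_genes) - 1L) %/% spec$n_contigs
  genes$start <- 2000L + slot * spacing
  genes$end <- genes$start + spec$gene_length - 1L

  ## --- samples and planted structure -----------------------------------
  sample_ids <- sprintf("S%02d", seq_len(spec$n_samples))
  sample_types <- rep(spec$cancer_types,
                      length.out = spec$n_samples)
  planted_samples <- sort(sample(spec$n_samples, spec$n_planted_eligible))
  hotspot_carriers <- sort(sample(spec$n_samples, spec$n_hotspot_carriers))

  ess_genes <- genes[genes$gene_class == "essential", ]
  hap_genes <- genes[genes$gene_class == "haploinsufficient", ]
  planted <- list()
  for (j in seq_along(planted_samples)) {
    cls <- spec$planted_design_classes[((j - 1L) %% length(spec$planted_design_classes)) + 1L]
    use_essential <- (j %% 2L) == 1L
    gene <- if (use_essential) ess_genes[((j - 1L) %/% 2L) + 1L, ]
            else hap_genes[((j - 1L) %/% 2L) + 1L, ]
    p <- gene$start + 400L
    chrom <- gene$chrom
    spacer_wt <- random_spacer(11L)
    if (cls == "snv_in_seed") {
      # protospacer at p-19..p (SNV at spacer position 20), PAM at p+1..p+3
      genome_chr[chrom] <- substr_assign(genome_chr[chrom], p - 19L, spacer_wt)
      genome_chr[chrom] <- substr_assign(genome_chr[chrom], p + 1L, "TGG")
      ref <- substr(spacer_wt, 20L, 20L)
      alt <- c(A = "T", T = "A", G = "C", C = "G")[[ref]]  # keep GC count
      spacer_mut <- substr_assign(spacer_wt, 20L, alt)
      proto_start <- p - 19L; proto_end <- p
    } else {
      # protospacer at p-22..p-3, wild-type PAM TGC at p-2..p; the SNV
      # converts PAM position 3 (C -> G), creating TGG on the mutant allele
      genome_chr[chrom] <- substr_assign(genome_chr[chrom], p - 22L, spacer_wt)
      genome_chr[chrom] <- substr_assign(genome_chr[chrom], p - 2L, "TGC")
      ref <- "C"; alt <- "G"
      spacer_mut <- spacer_wt
      proto_start <- p - 22L; proto_end <- p - 3L
    }
    af <- if (use_essential) spec$hom_af_planted else spec$het_af_planted
    planted[[j]] <- list(
      sample_id = sample_ids[planted_samples[j]],
      gene_symbol = gene$gene_symbol, gene_class = gene$gene_class,
      chrom = chrom, pos = p, ref_allele = ref, alt_allele = alt,
      allele_frequency = af,
      zygosity_expected = if (use_essential) "homozygous" else "heterozygous",
      design_class = cls, spacer_mut = spacer_mut,
      proto_start = proto_start, proto_end = proto_end
    )
  }

  ## --- hotspot catalog ---------------------------------------------------
  onc <- genes[genes$gene_class == "oncogene", ][1L, ]
  hs_pos <- onc$start + c(300L, 500L, 700L)
  hotspots <- data.frame(
    gene_symbol = onc$gene_symbol, chrom = onc$chrom, pos = hs_pos,
    ref_allele = substring(genome_chr[onc$chrom], hs_pos, hs_pos),
    alt_allele = NA_character_, stringsAsFactors = FALSE
  )
  hotspots$alt_allele <- vapply(hotspots$ref_allele, function(r)
    sample(setdiff(DNA_BASES, r), 1L), character(1))

  ## --- background mutations ---------------------------------------------
  # Background SNVs live only in oncogene/other genes, so the gene-class
  # filter removes them all and eligibility truth stays exact.
  bg_genes <- genes[genes$gene_class %in% c("oncogene", "other"), ]
  recs <- list()
  add_rec <- function(sample_i, gene_row, pos, ref, alt, af, vclass) {
    alt_ct <- as.integer(round(af * spec$depth))
    alt_ct <- max(1L, min(spec$depth, alt_ct))
    recs[[length(recs) + 1L]] <<- data.frame(
      sample_id = sample_ids[sample_i],
      cancer_type = sample_types[sample_i],
      chrom = gene_row$chrom, pos = as.integer(pos),
      ref_allele = ref, alt_allele = alt,
      allele_frequency = alt_ct / spec$depth,
      alt_read_count = alt_ct,
      gene_symbol = gene_row$gene_symbol,
      variant_class = vclass, zygosity = "unknown", flags = "",
      stringsAsFactors = FALSE
    )
  }
  vclasses <- c("missense", "synonymous", "nonsense", "other")
  for (si in seq_len(spec$n_samples)) {
    for (k in seq_len(spec$muts_per_sample)) {
      gr <- bg_genes[sample(nrow(bg_genes), 1L), ]
      pos <- gr$start + sample.int(spec$gene_length, 1L) - 1L
      ref <- substring(genome_chr[gr$chrom], pos, pos)
      alt <- sample(setdiff(DNA_BASES, ref), 1L)
      clonal <- stats::runif(1) < spec$clonal_fraction
      af <- if (!clonal) draw_subclonal_af(1L)
            else if (stats::runif(1) < 0.1) draw_hom_clonal_af(1L, spec$purity)
            else draw_het_clonal_af(1L, spec$purity)
      af <- min(max(af, 0.02), 0.99)
      add_rec(si, gr, pos, ref, alt, af, sample(vclasses, 1L))
    }
    if (si %in% hotspot_carriers) {
      h <- hotspots[1L, ]
      gr <- onc
      add_rec(si, gr, h$pos, h$ref_allele, h$alt_allele,
              draw_het_clonal_af(1L, spec$purity), "missense")
    }
  }
  for (pl in planted) {
    si <- match(pl$sample_id, sample_ids)
    gr <- genes[genes$gene_symbol == pl$gene_symbol, ]
    add_rec(si, gr, pl$pos, pl$ref_allele, pl$alt_allele,
            pl$allele_frequency, "missense")
  }
  snvs <- do.call(rbind, recs)
  # collapse accidental duplicate (sample, site) draws; planted/hotspot
  # records were appended last and take precedence
  snvs <- snvs[!duplicated(snvs[, c("sample_id", "chrom", "pos")],
                           fromLast = TRUE), ]
  rownames(snvs) <- NULL

  ## --- scrub accidental near-matches to planted spacers ------------------
  protected <- lapply(planted, function(pl)
    list(chrom = pl$chrom, start = pl$pos - 30L, end = pl$pos + 10L))
  genome <- Biostrings::DNAStringSet(genome_chr)
  for (pl in planted) {
    for (iter in 1:20) {
      hits <- enumerate_off_targets(
        pl$spacer_mut, genome, config,
        exclude = list(chrom = pl$chrom, start = pl$proto_start,
                       end = pl$proto_end))
      if (nrow(hits) == 0) break
      h <- hits[1L, ]
      # break the hit's PAM: the middle G (plus strand) / C (minus strand)
      pam_pos <- if (h$strand == "+") h$end + 2L else h$start - 2L
      in_protected <- any(vapply(protected, function(w)
        w$chrom == h$chrom && pam_pos >= w$start && pam_pos <= w$end,
        logical(1)))
      if (in_protected) {
        stop("planting infeasible: accidental near-match overlaps a planted ",
             "guide at ", h$chrom, ":", h$start)
      }
      newbase <- if (h$strand == "+") "A" else "T"
      genome_chr[h$chrom] <- substr_assign(genome_chr[h$chrom], pam_pos, newbase)
      genome <- Biostrings::DNAStringSet(genome_chr)
      if (iter == 20L) stop("planting infeasible: could not scrub near-matches")
    }
  }

  ## --- expression table --------------------------------------------------
  expr_rows <- expand.grid(sample_id = sample_ids,
                           gene_symbol = genes$gene_symbol,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expr_rows <- expr_rows[order(expr_rows$sample_id, expr_rows$gene_symbol), ]
  expr_rows$log2_fpkm_plus1 <- round(stats::runif(nrow(expr_rows), 0, 4), 3)
  for (pl in planted) {
    i <- expr_rows$sample_id == pl$sample_id &
      expr_rows$gene_symbol == pl$gene_symbol
    expr_rows$log2_fpkm_plus1[i] <- 5.0
  }
  rownames(expr_rows) <- NULL

  ## --- verify the planting against the real pipeline stages --------------
  expr_tab <- expression_table(expr_rows)
  catalog <- merge_gene_catalog(
    data.frame(gene_symbol = genes$gene_symbol, gene_class = genes$gene_class,
               source = "synthetic", stringsAsFactors = FALSE))
  for (pl in planted) {
    s_snvs <- snvs[snvs$sample_id == pl$sample_id, , drop = FALSE]
    s_snvs <- call_zygosity(qc_filter(s_snvs, config), config)
    thr <- compute_af_cut(s_snvs, config)
    mine <- s_snvs[s_snvs$chrom == pl$chrom & s_snvs$pos == pl$pos, ]
    ok <- nrow(mine) == 1 &&
      mine$zygosity == pl$zygosity_expected &&
      mine$allele_frequency > thr$af_cut &&
      expression_value(expr_tab, pl$sample_id, pl$gene_symbol) > config$expression_min
    if (ok) {
      cand <- build_candidates(genome, mine, config)
      cand <- score_on_target(cand, resolve_scorer(config$scorer))
      cand <- cand[cand$design_class == pl$design_class &
                     cand$spacer == pl$spacer_mut, , drop = FALSE]
      ok <- nrow(cand) >= 1
      if (ok) {
        cand <- score_off_targets(cand[1L, , drop = FALSE], genome, config)
        cand <- qualify_guides(cand, config)
        ok <- isTRUE(cand$qualified[1L]) &&
          cand$on_target_score[1L] > config$on_target_min
      }
    }
    if (!ok) {
      stop("planting infeasible: planted guide for ", pl$sample_id, "/",
           pl$gene_symbol, " would not survive the pipeline (AF_cut ",
           sprintf("%.3f", thr$af_cut), ")")
    }
  }

  ## --- write the bundle ---------------------------------------------------
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    maf = file.path(dir, "cohort.maf"),
    expression = file.path(dir, "expression.tsv"),
    gene_catalog = file.path(dir, "gene_catalog.tsv"),
    hotspots = file.path(dir, "hotspots.tsv"),
    truth = file.path(dir, "truth.json")
  )
  Biostrings::writeXStringSet(genome, paths["genome"], width = 70L)
  ord <- order(snvs$sample_id, snvs$chrom, snvs$pos)
  write_maf(snvs[ord, ], paths["maf"])
  expr_out <- expr_rows
  expr_out$log2_fpkm_plus1 <- sprintf("%.3f", expr_out$log2_fpkm_plus1)
  utils::write.table(expr_out, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(genes[, c("gene_symbol", "gene_class")],
                     paths["gene_catalog"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(hotspots, paths["hotspots"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- list(
    seed = spec$seed,
    n_samples = spec$n_samples,
    samples = data.frame(sample_id = sample_ids, cancer_type = sample_types,
                         stringsAsFactors = FALSE),
    eligible_samples = sample_ids[planted_samples],
    hotspot_carriers = sample_ids[hotspot_carriers],
    planted_guides = do.call(rbind, lapply(planted, function(pl)
      data.frame(sample_id = pl$sample_id, gene_symbol = pl$gene_symbol,
                 gene_class = pl$gene_class, chrom = pl$chrom, pos = pl$pos,
                 ref_allele = pl$ref_allele, alt_allele = pl$alt_allele,
                 allele_frequency = pl$allele_frequency,
                 zygosity = pl$zygosity_expected,
                 design_class = pl$design_class, spacer = pl$spacer_mut,
                 stringsAsFactors = FALSE)))
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  list(paths = as.list(paths), truth = truth, spec = spec)
}

#' Plant an off-target copy of a spacer into a genome
#'
#' Inserts, on the plus strand of a chosen contig, a 20-nt site matching
#' `spacer` at exactly `n_mismatches` positions followed by an instance of
#' the PAM motif, and returns the modified genome plus the planted-locus
#' record. Fails rather than overwriting a window in `avoid`.
#'
#' @param genome A `DNAStringSet`.
#' @param spacer 20-nt spacer.
#' @param n_mismatches Exact number of mismatches to engineer (0-20).
#' @param pam PAM to write after the site; IUPAC `N`s are drawn at random.
#' @param at Optional list `(chrom, start)` fixing the placement; default: a
#'   random position on the first contig.
#' @param avoid Optional list of `(chrom, start, end)` windows that must not
#'   be overwritten.
#' @return List with `genome` (modified) and `record` (chrom, start, end,
#'   strand, site_seq, pam_seq, n_mismatches, mismatch_positions).
#' @export
plant_off_target_copy <- function(genome, spacer, n_mismatches, pam = "TGG",
                                  at = NULL, avoid = list()) {
  stopifnot(nchar(spacer) == 20, n_mismatches >= 0, n_mismatches <= 20)
  spacer <- toupper(spacer)
  pam_chars <- strsplit(toupper(pam), "")[[1]]
  pam_chars[pam_chars == "N"] <- sample(DNA_BASES, sum(pam_chars == "N"),
                                        replace = TRUE)
  pam_seq <- paste(pam_chars, collapse = "")
  chrom <- if (is.null(at)) names(genome)[1] else at$chrom
  clen <- Biostrings::width(genome[chrom])
  overlaps_avoid <- function(s, e) {
    any(vapply(avoid, function(w)
      w$chrom == chrom && s <= w$end && e >= w$start, logical(1)))
  }
  for (try in 1:50) {
    start <- if (is.null(at)) sample.int(clen - 30L, 1L) else at$start
    end <- start + 19L
    if (!overlaps_avoid(start, end + 3L)) break
    if (!is.null(at) || try == 50L) {
      stop("cannot place off-target copy without colliding with an ",
           "avoided window")
    }
  }
  site_chars <- strsplit(spacer, "")[[1]]
  mm_pos <- if (n_mismatches > 0) sort(sample(20L, n_mismatches)) else integer(0)
  for (p in mm_pos) {
    site_chars[p] <- sample(setdiff(DNA_BASES, site_chars[p]), 1L)
  }
  site <- paste(site_chars, collapse = "")
  contig <- as.character(genome[[chrom]])
  contig <- substr_assign(contig, start, paste0(site, pam_seq))
  chr_list <- as.character(genome)
  chr_list[chrom] <- contig
  list(
    genome = Biostrings::DNAStringSet(chr_list),
    record = list(chrom = chrom, start = start, end = end, strand = "+",
                  site_seq = site, pam_seq = pam_seq,
                  n_mismatches = as.integer(n_mismatches),
                  mismatch_positions = mm_pos)
  )
}
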