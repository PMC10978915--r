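# Shared fixtures and independent brute-force oracles. The oracles here are
# deliberately written from the rule statements (plain loops over substrings /
# embed() windows) and share no code with the implementation they check.

make_snv <- function(sample_id = "S1", chrom = "ctg1", pos = 100L,
                     ref = "G", alt = "A", af = 0.5, alt_reads = NA_integer_,
                     gene = "GENE1", zygosity = "unknown", flags = "",
                     cancer_type = "COAD", variant_class = "missense") {
  data.frame(sample_id = sample_id, cancer_type = cancer_type, chrom = chrom,
             pos = as.integer(pos), ref_allele = ref, alt_allele = alt,
             allele_frequency = af, alt_read_count = alt_reads,
             gene_symbol = gene, variant_class = variant_class,
             zygosity = zygosity, flags = flags, stringsAsFactors = FALSE)
}

make_snvs <- function(...) do.call(rbind, list(...))

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
                        collapse = "")

make_catalog <- function(...) {
  entries <- data.frame(...)
  entries$source <- "test"
  snvguide:::merge_gene_catalog(entries)
}

make_expr <- function(sample_id, gene_symbol, value) {
  expression_table(data.frame(sample_id = sample_id, gene_symbol = gene_symbol,
                              log2_fpkm_plus1 = value, stringsAsFactors = FALSE))
}

# --- sort-based median/MAD oracle (literal definitions) ---------------------
oracle_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
oracle_af_cut <- function(het_afs, all_afs = het_afs, population = "het",
                          mad_constant = 1) {
  m <- oracle_median(if (population == "het") het_afs else all_afs)
  mad <- mad_constant * oracle_median(abs(het_afs - oracle_median(het_afs)))
  list(af_median = m, mad_het = mad, af_cut = m + mad)
}

# --- exhaustive 23-nt window design-site oracle -----------------------------
# Enumerates every window on both strands and applies the two rules verbatim:
# (a) SNV at spacer positions [21 - seed_window, 20] of a window whose mutant
#     PAM is NGG; (b) SNV at PAM position 2 or 3, mutant NGG, wild-type not.
oracle_design_sites <- function(wt, mut, snv_offset, seed_window = 12) {
  L <- nchar(mut)
  keys <- character(0)
  for (strand in c("+", "-")) {
    m <- if (strand == "+") mut else rc(mut)
    w <- if (strand == "+") wt else rc(wt)
    off <- if (strand == "+") snv_offset else L - snv_offset + 1
    if (L < 23) next
    for (i in 1:(L - 22)) {
      win <- substr(m, i, i + 22)
      if (!grepl("^[ACGT]{23}$", win)) next
      if (substr(win, 22, 22) != "G" || substr(win, 23, 23) != "G") next
      relpos <- off - i + 1
      cls <- NULL; snvpos <- NULL
      if (relpos >= 21 - seed_window && relpos <= 20) {
        cls <- "snv_in_seed"; snvpos <- relpos
      } else if (relpos == 22 || relpos == 23) {
        wt_pam <- substr(w, i + 20, i + 22)
        if (!(substr(wt_pam, 2, 2) == "G" && substr(wt_pam, 3, 3) == "G")) {
          cls <- "snv_in_pam"; snvpos <- 0
        }
      }
      if (is.null(cls)) next
      plus_start <- if (strand == "+") i else L - (i + 19) + 1
      keys <- c(keys, paste(strand, plus_start, cls, snvpos,
                            substr(win, 1, 20)))
    }
  }
  sort(keys)
}

site_keys <- function(sites) {
  if (nrow(sites) == 0) return(character(0))
  sort(paste(sites$strand, sites$ctx_proto_start, sites$design_class,
             sites$snv_position_in_spacer, sites$spacer_mut))
}

# --- naive full-scan off-target oracle --------------------------------------
# Literal mismatch counting over every placement of both strands, vectorized
# with embed() windows; independent of Biostrings.
oracle_offtargets <- function(spacer, contigs, max_mm = 3, exclude = NULL) {
  sp <- strsplit(spacer, "")[[1]]
  out <- list()
  scan <- function(seq_str) {
    ch <- strsplit(seq_str, "")[[1]]
    L <- length(ch)
    if (L < 23) return(NULL)
    M <- embed(ch, 23)[, 23:1, drop = FALSE]  # row i = window starting at i
    ok_pam <- M[, 22] == "G" & M[, 23] == "G"
    ok_acgt <- apply(M, 1, function(r) all(r %in% c("A", "C", "G", "T")))
    mm <- rowSums(M[, 1:20, drop = FALSE] !=
                    matrix(sp, nrow(M), 20, byrow = TRUE))
    idx <- which(ok_pam & ok_acgt & mm <= max_mm)
    if (length(idx) == 0) return(NULL)
    data.frame(i = idx, mm = mm[idx],
               site = apply(M[idx, 1:20, drop = FALSE], 1, paste, collapse = ""),
               pam = apply(M[idx, 21:23, drop = FALSE], 1, paste, collapse = ""),
               stringsAsFactors = FALSE)
  }
  for (chrom in names(contigs)) {
    s <- contigs[[chrom]]
    L <- nchar(s)
    plus <- scan(s)
    if (!is.null(plus)) {
      plus$chrom <- chrom; plus$strand <- "+"
      plus$start <- plus$i; plus$end <- plus$i + 19
      out[[length(out) + 1]] <- plus
    }
    minus <- scan(rc(s))
    if (!is.null(minus)) {
      minus$chrom <- chrom; minus$strand <- "-"
      # window start i in the reverse-complement frame: protospacer occupies
      # plus coordinates [L - i - 18, L - i + 1] minus the PAM offset
      minus$start <- L - (minus$i + 19) + 1
      minus$end <- L - minus$i + 1
      out[[length(out) + 1]] <- minus
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      site = character(0), mm = integer(0)))
  }
  res <- do.call(rbind, out)[, c("chrom", "start", "end", "strand", "site",
                                 "pam", "mm")]
  if (!is.null(exclude)) {
    keep <- !(res$chrom == exclude$chrom & res$start <= exclude$end &
                res$end >= exclude$start)
    res <- res[keep, , drop = FALSE]
  }
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

hit_keys <- function(df) {
  if (nrow(df) == 0) return(character(0))
  n_mm <- if ("n_mismatches" %in% names(df)) df$n_mismatches else df$mm
  site <- if ("site_seq" %in% names(df)) df$site_seq else df$site
  sort(paste(df$chrom, df$start, df$end, df$strand, site, n_mm))
}
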