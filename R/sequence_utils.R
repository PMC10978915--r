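# Small sequence helpers shared by the design and scoring modules.
# Sequences are plain uppercase character strings in the DNA alphabet; the
# genome itself is a Biostrings::DNAStringSet.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> admissible bases (genome side must be a concrete ACGT base;
# ambiguous genomic bases never match).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Does a concrete triplet match an IUPAC motif? Vectorized over `seqs`.
matches_motif <- function(seqs, motif) {
  motif_chars <- strsplit(motif, "")[[1]]
  vapply(seqs, function(s) {
    if (is.na(s) || nchar(s) != length(motif_chars)) return(FALSE)
    sc <- strsplit(s, "")[[1]]
    for (i in seq_along(motif_chars)) {
      adm <- IUPAC_SETS[[motif_chars[i]]]
      if (is.null(adm) || !(sc[i] %in% adm)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

matches_any_motif <- function(seqs, motifs) {
  out <- rep(FALSE, length(seqs))
  for (m in motifs) out <- out | matches_motif(seqs, m)
  out
}

is_acgt <- function(s) {
  !is.na(s) & grepl("^[ACGT]+$", s)
}

# Positions (1-based) at which two equal-length strings differ.
mismatch_positions <- function(a, b) {
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
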