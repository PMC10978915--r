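# Cutting Frequency Determination (CFD) scoring. The score of an off-target
# site is the product, over mismatched spacer positions, of a
# (position, spacer base, genomic base)-specific activity penalty, multiplied
# by a PAM-dinucleotide penalty (positions 2-3 of the NGG). A perfect match
# with a canonical NGG PAM scores exactly 1.

#' Build the bundled synthetic CFD penalty model
#'
#' A deterministic, fully documented *synthetic* penalty table with the
#' structural properties of published CFD tables: matched bases have penalty
#' 1; mismatch penalties decay from PAM-distal (position 1, tolerated) to
#' PAM-proximal (position 20, near-abolishing); transversions are penalized
#' more than transitions; `pam_penalty("GG") = 1`. The mismatch penalty is
#' `((20 - p)/19 * 0.85 + 0.05) * f` with `f = 1` for transitions and
#' `f = 0.8` for transversions, rounded to 4 decimals. This is a stand-in
#' surrogate, not the empirically trained table; load a published table with
#' [read_cfd_model()] for production scoring.
#'
#' @return Object of class `cfd_model`: list with `mismatch` (named numeric,
#'   keys `"pos:spacer_base:genomic_base"`) and `pam` (named numeric, keys =
#'   PAM dinucleotides).
#' @export
cfd_default_model <- function() {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  mk <- character(0); mv <- numeric(0)
  for (p in 1:20) {
    for (sb in DNA_BASES) {
      for (gb in DNA_BASES) {
        key <- paste(p, sb, gb, sep = ":")
        val <- if (sb == gb) 1.0 else {
          f <- if (transitions[[sb]] == gb) 1.0 else 0.8
          round(((20 - p) / 19 * 0.85 + 0.05) * f, 4)
        }
        mk <- c(mk, key); mv <- c(mv, val)
      }
    }
  }
  pam_din <- apply(expand.grid(DNA_BASES, DNA_BASES), 1, paste, collapse = "")
  pam <- stats::setNames(rep(0.0, length(pam_din)), pam_din)
  pam["GG"] <- 1.0
  pam["AG"] <- 0.25
  pam["GA"] <- 0.10
  pam["CG"] <- 0.10
  pam["TG"] <- 0.10
  pam["GT"] <- 0.05
  structure(list(mismatch = stats::setNames(mv, mk), pam = pam),
            class = "cfd_model")
}

#' Read a CFD penalty model from TSV files
#'
#' The mismatch table has columns `position` (1-20, 1 = PAM-distal),
#' `spacer_base`, `genomic_base`, `penalty`; the PAM table has `pam_dinuc`
#' (PAM positions 2-3) and `penalty`. Tables keyed on RNA bases (U) are
#' re-keyed to DNA (U -> T) at load time. Matched-base entries default to 1
#' when absent.
#'
#' @param mismatch_path,pam_path Paths to the two TSV files.
#' @return A `cfd_model`.
#' @export
read_cfd_model <- function(mismatch_path, pam_path) {
  mm <- utils::read.delim(mismatch_path, stringsAsFactors = FALSE)
  need <- c("position", "spacer_base", "genomic_base", "penalty")
  if (!all(need %in% names(mm))) {
    stop("CFD mismatch table needs columns: ", paste(need, collapse = ", "))
  }
  mm$spacer_base <- chartr("Uu", "Tt", toupper(mm$spacer_base))
  mm$genomic_base <- chartr("Uu", "Tt", toupper(mm$genomic_base))
  if (any(mm$penalty < 0 | mm$penalty > 1)) stop("CFD penalties must lie in [0,1]")
  keys <- paste(mm$position, mm$spacer_base, mm$genomic_base, sep = ":")
  mismatch <- stats::setNames(mm$penalty, keys)
  # fill matched-base entries at 1.0 where not given
  for (p in 1:20) for (b in DNA_BASES) {
    k <- paste(p, b, b, sep = ":")
    if (!k %in% names(mismatch)) mismatch[k] <- 1.0
  }
  pm <- utils::read.delim(pam_path, stringsAsFactors = FALSE)
  if (!all(c("pam_dinuc", "penalty") %in% names(pm))) {
    stop("CFD PAM table needs columns: pam_dinuc, penalty")
  }
  if (any(pm$penalty < 0 | pm$penalty > 1)) stop("CFD penalties must lie in [0,1]")
  pam <- stats::setNames(pm$penalty, toupper(pm$pam_dinuc))
  if (is.na(pam["GG"]) || pam["GG"] != 1.0) {
    stop("CFD PAM table must assign penalty 1.0 to GG")
  }
  structure(list(mismatch = mismatch, pam = pam), class = "cfd_model")
}

#' Write a CFD model back to TSV (round-trip companion of [read_cfd_model()])
#'
#' @param model A `cfd_model`.
#' @param mismatch_path,pam_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cfd_model <- function(model, mismatch_path, pam_path) {
  parts <- do.call(rbind, strsplit(names(model$mismatch), ":", fixed = TRUE))
  mm <- data.frame(position = as.integer(parts[, 1]), spacer_base = parts[, 2],
                   genomic_base = parts[, 3], penalty = unname(model$mismatch),
                   stringsAsFactors = FALSE)
  mm <- mm[order(mm$position, mm$spacer_base, mm$genomic_base), ]
  utils::write.table(mm, mismatch_path, sep = "\t", quote = FALSE, row.names = FALSE)
  pm <- data.frame(pam_dinuc = names(model$pam), penalty = unname(model$pam),
                   stringsAsFactors = FALSE)
  pm <- pm[order(pm$pam_dinuc), ]
  utils::write.table(pm, pam_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mismatch_path, pam_path))
}

#' CFD score of a spacer against a genomic site
#'
#' @param spacer 20-nt spacer (5'->3', DNA alphabet).
#' @param site_seq 20-nt genomic protospacer sequence, same orientation.
#' @param pam 3-nt PAM adjacent to the site.
#' @param model A `cfd_model` (default [cfd_default_model()]).
#' @return Score in \[0, 1\]: the product of per-mismatch penalties times the
#'   PAM-dinucleotide penalty. A perfect match with an NGG PAM scores 1.
#' @export
cfd_score <- function(spacer, site_seq, pam, model = cfd_default_model()) {
  stopifnot(nchar(spacer) == 20, nchar(site_seq) == 20, nchar(pam) == 3)
  spacer <- toupper(spacer); site_seq <- toupper(site_seq); pam <- toupper(pam)
  score <- 1.0
  sc <- strsplit(spacer, "")[[1]]
  tc <- strsplit(site_seq, "")[[1]]
  for (p in which(sc != tc)) {
    key <- paste(p, sc[p], tc[p], sep = ":")
    pen <- model$mismatch[key]
    if (is.na(pen)) {
      stop("CFD model has no penalty for (position=", p, ", spacer=", sc[p],
           ", genomic=", tc[p], ")")
    }
    score <- score * pen
  }
  din <- substr(pam, 2, 3)
  ppen <- model$pam[din]
  if (is.na(ppen)) stop("CFD model has no PAM penalty for dinucleotide ", din)
  unname(score * ppen)
}
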