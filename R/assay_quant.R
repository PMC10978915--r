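# Editing-readout arithmetic for the T7 endonuclease 1 (T7E1) assay and
# targeted-sequencing InDel bookkeeping.

#' NHEJ percentage from T7E1 band densities
#'
#' The T7E1 enzyme cleaves heteroduplexes formed between edited and unedited
#' amplicons. With
#' `fraction_cleaved = digested / (digested + parent)`, the estimated
#' non-homologous end joining rate is
#' `NHEJ(%) = 100 * (1 - (1 - fraction_cleaved)^(1/2))` — the square root
#' accounts for heteroduplexes requiring only one edited strand. The result
#' is scale-invariant in the densities and strictly increasing in the
#' cleaved fraction.
#'
#' @param density_digested Summed band densities of the cleavage products
#'   (non-negative).
#' @param density_parent Density of the undigested parental band
#'   (non-negative).
#' @return Object of class `t7e1_measurement`: list with `density_digested`,
#'   `density_parent`, `fraction_cleaved` and `nhej_percent` (in \[0, 100\]).
#' @examples
#' nhej_percent(60, 40)   # fraction 0.6 -> ~36.75%
#' @export
nhej_percent <- function(density_digested, density_parent) {
  stopifnot(is.numeric(density_digested), is.numeric(density_parent),
            length(density_digested) == 1, length(density_parent) == 1)
  if (density_digested < 0 || density_parent < 0) {
    stop("band densities must be non-negative")
  }
  total <- density_digested + density_parent
  if (total == 0) {
    stop("undefined measurement: both band densities are zero")
  }
  fraction <- density_digested / total
  out <- list(
    density_digested = density_digested,
    density_parent = density_parent,
    fraction_cleaved = fraction,
    nhej_percent = 100 * (1 - sqrt(1 - fraction))
  )
  class(out) <- "t7e1_measurement"
  out
}

#' @export
print.t7e1_measurement <- function(x, ...) {
  cat(sprintf("T7E1: fraction cleaved %.4f -> NHEJ %.3f%%\n",
              x$fraction_cleaved, x$nhej_percent))
  invisible(x)
}

#' InDel read fraction
#'
#' Bookkeeping ratio for targeted-sequencing editing readouts: the fraction
#' of reads classified as carrying an insertion or deletion.
#'
#' @param n_indel_reads Number of InDel-containing reads.
#' @param n_total_reads Total reads (> 0, >= `n_indel_reads`).
#' @return Fraction in \[0, 1\].
#' @examples
#' indel_fraction(377, 1000)
#' @export
indel_fraction <- function(n_indel_reads, n_total_reads) {
  stopifnot(length(n_indel_reads) == 1, length(n_total_reads) == 1)
  if (n_total_reads <= 0) stop("undefined: zero total reads")
  if (n_indel_reads < 0 || n_indel_reads > n_total_reads) {
    stop("n_indel_reads must lie in [0, n_total_reads]")
  }
  n_indel_reads / n_total_reads
}
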