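# Gene-class, hotspot, expression and recurrence catalogs. All are small local
# TSV (or JSON) files; nothing is fetched from the network.

GENE_CLASSES <- c("essential", "haploinsufficient", "oncogene", "other")

#' Read and merge gene-class catalogs
#'
#' Each file is either a two-column TSV/JSON (`gene_symbol`, `gene_class`) or
#' a bare one-column gene list whose class is supplied via `classes`.
#' Viability classes merge with haploinsufficient taking precedence over
#' essential (haploinsufficiency imposes the weaker zygosity requirement, so
#' it retains more candidates); oncogene labels are kept in a separate lookup
#' and never override a viability class. Conflicting assignments are logged in
#' the `conflicts` element.
#'
#' @param paths Character vector of catalog files.
#' @param classes Optional character vector, one class per file, for bare gene
#'   lists.
#' @return An object of class `gene_catalog`: list with `classes` (named
#'   character vector gene -> essential/haploinsufficient), `oncogenes`
#'   (character vector), `conflicts` (data.frame) and `entries` (all rows as
#'   read).
#' @export
read_gene_catalog <- function(paths, classes = NULL) {
  entries <- list()
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (!file.exists(p)) stop("gene catalog file not found: ", p)
    if (tolower(tools::file_ext(p)) == "json") {
      lst <- jsonlite::read_json(p, simplifyVector = TRUE)
      df <- data.frame(gene_symbol = names(lst),
                       gene_class = unname(unlist(lst)),
                       stringsAsFactors = FALSE)
    } else {
      df <- utils::read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
      if (!"gene_symbol" %in% names(df)) {
        # bare list: single column of symbols
        df <- data.frame(gene_symbol = df[[1]], stringsAsFactors = FALSE)
      }
      if (!"gene_class" %in% names(df)) {
        if (is.null(classes) || is.na(classes[i])) {
          stop("file ", p, " has no gene_class column and no class was supplied")
        }
        df$gene_class <- classes[i]
      }
    }
    bad <- setdiff(unique(df$gene_class), GENE_CLASSES)
    if (length(bad) > 0) {
      stop("unknown gene class label(s) ", paste(bad, collapse = ", "),
           "; admissible labels: ", paste(GENE_CLASSES, collapse = ", "))
    }
    df$source <- basename(p)
    entries[[length(entries) + 1]] <- df[, c("gene_symbol", "gene_class", "source")]
  }
  if (length(entries) == 0) {
    warning("empty gene catalog file set")
    entries_df <- data.frame(gene_symbol = character(0), gene_class = character(0),
                             source = character(0), stringsAsFactors = FALSE)
  } else {
    entries_df <- unique(do.call(rbind, entries))
  }
  merge_gene_catalog(entries_df)
}

# Deterministic merge of catalog entries: haploinsufficient > essential >
# other among viability classes; oncogene kept aside.
merge_gene_catalog <- function(entries_df) {
  onc <- sort(unique(entries_df$gene_symbol[entries_df$gene_class == "oncogene"]))
  via <- entries_df[entries_df$gene_class != "oncogene", , drop = FALSE]
  rank <- c(haploinsufficient = 1, essential = 2, other = 3)
  classes <- character(0)
  conflicts <- data.frame(gene_symbol = character(0), classes = character(0),
                          resolved = character(0), stringsAsFactors = FALSE)
  if (nrow(via) > 0) {
    sp <- split(via$gene_class, via$gene_symbol)
    resolved <- vapply(sp, function(cl) {
      names(rank)[min(rank[unique(cl)])]
    }, character(1))
    classes <- resolved
    multi <- vapply(sp, function(cl) length(unique(cl)) > 1, logical(1))
    if (any(multi)) {
      conflicts <- data.frame(
        gene_symbol = names(sp)[multi],
        classes = vapply(sp[multi], function(cl)
          paste(sort(unique(cl)), collapse = "+"), character(1)),
        resolved = resolved[multi],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- list(classes = classes, oncogenes = onc, conflicts = conflicts,
              entries = entries_df)
  class(out) <- "gene_catalog"
  out
}

#' @export
print.gene_catalog <- function(x, ...) {
  tab <- table(x$classes)
  cat("gene_catalog:", length(x$classes), "viability-classed genes (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "),",
      length(x$oncogenes), "oncogenes,",
      nrow(x$conflicts), "conflicts resolved\n")
  invisible(x)
}

# Viability class for a vector of gene symbols ("other" when uncataloged).
gene_class_of <- function(catalog, genes) {
  cls <- catalog$classes[genes]
  cls[is.na(cls)] <- "other"
  unname(cls)
}

#' Read a hotspot mutation catalog
#'
#' @param path TSV with columns `gene_symbol`, `chrom`, `pos` and optionally
#'   `ref_allele`, `alt_allele`. Positions are 1-based.
#' @return A data.frame of hotspot entries.
#' @export
read_hotspots <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_symbol", "chrom", "pos")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("hotspot catalog missing column(s): ", paste(missing, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  if (any(df$pos < 1)) stop("hotspot pos must be >= 1")
  if (!"ref_allele" %in% names(df)) df$ref_allele <- NA_character_
  if (!"alt_allele" %in% names(df)) df$alt_allele <- NA_character_
  df
}

#' Read a cohort-recurrence catalog
#'
#' @param path TSV with columns `chrom`, `pos`, `ref_allele`, `alt_allele`:
#'   somatic mutations previously observed in the reference cohort.
#' @return A data.frame usable by [recurrence_filter()].
#' @export
read_recurrence_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref_allele", "alt_allele")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("recurrence catalog missing column(s): ", paste(missing, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  df
}

#' Read a gene-expression table
#'
#' Accepts either long format (columns `sample_id`, `gene_symbol`,
#' `log2_fpkm_plus1`) or a genes-by-samples matrix whose first column holds
#' gene symbols; the layout is auto-detected from the header. Values are
#' log2(FPKM + 1) and must be non-negative. A missing (sample, gene) pair is
#' *missing*, never zero.
#'
#' @param path Path to a TSV file.
#' @return An object of class `expression_table`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  long_cols <- c("sample_id", "gene_symbol", "log2_fpkm_plus1")
  if (all(long_cols %in% names(df))) {
    long <- df[, long_cols]
  } else {
    genes <- df[[1]]
    samples <- names(df)[-1]
    long <- data.frame(
      sample_id = rep(samples, each = length(genes)),
      gene_symbol = rep(genes, times = length(samples)),
      log2_fpkm_plus1 = as.numeric(unlist(df[-1], use.names = FALSE)),
      stringsAsFactors = FALSE
    )
    long <- long[!is.na(long$log2_fpkm_plus1), , drop = FALSE]
  }
  expression_table(long)
}

#' Build an expression lookup from a long-format data.frame
#'
#' @param long Data.frame with `sample_id`, `gene_symbol`, `log2_fpkm_plus1`.
#' @return Object of class `expression_table`.
#' @export
expression_table <- function(long) {
  if (any(long$log2_fpkm_plus1 < 0, na.rm = TRUE)) {
    stop("expression values (log2(FPKM+1)) must be non-negative")
  }
  values <- stats::setNames(long$log2_fpkm_plus1,
                            paste(long$sample_id, long$gene_symbol, sep = "\r"))
  structure(list(values = values), class = "expression_table")
}

#' Look up expression values
#'
#' @param expr An `expression_table`.
#' @param sample_id,gene_symbol Vectors (recycled to common length).
#' @return Numeric vector of log2(FPKM+1) values; `NA` marks a missing
#'   (sample, gene) pair — distinguishable from a stored zero.
#' @export
expression_value <- function(expr, sample_id, gene_symbol) {
  stopifnot(inherits(expr, "expression_table"))
  unname(expr$values[paste(sample_id, gene_symbol, sep = "\r")])
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", length(x$values), "(sample, gene) values\n")
  invisible(x)
}
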