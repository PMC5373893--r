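#' Construct a spectral-count matrix
#'
#' Container for replicated label-free proteomics data quantified by spectral
#' counting: an integer count matrix (proteins in rows, samples in columns)
#' together with the protein lengths needed for NSAF normalization, a
#' two-level group label per sample, and an extraction-fraction tag.
#'
#' @param counts Numeric matrix of non-negative integer spectral counts,
#'   proteins x samples. Row names (or `protein_ids`) identify proteins,
#'   column names identify samples.
#' @param lengths Positive integer vector of protein lengths (amino acids),
#'   one per row of `counts`.
#' @param groups Character or factor vector assigning each sample column to
#'   one of exactly two groups.
#' @param fraction Single string tagging the extraction fraction
#'   (e.g. `"NaCl"`, `"GuHCl"`).
#' @param protein_ids Optional character vector of protein identifiers;
#'   defaults to `rownames(counts)`.
#'
#' @return An object of class `spectral_counts`: a list with elements
#'   `counts`, `lengths`, `groups` (factor), `fraction`, `protein_ids`.
#' @export
#' @examples
#' m <- matrix(c(10L, 20L, 5L, 8L), nrow = 2,
#'             dimnames = list(c("MMP9", "FN1"), c("s1", "s2")))
#' spectral_count_matrix(m, lengths = c(707L, 2386L),
#'                       groups = c("sym", "asym"), fraction = "NaCl")
spectral_count_matrix <- function(counts, lengths, groups, fraction = "NaCl",
                                  protein_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(protein_ids)) {
    protein_ids <- paste0("P", seq_len(nrow(counts)))
  }
  assert_that(length(protein_ids) == nrow(counts),
              "`protein_ids` must match the number of rows of `counts`")
  assert_that(!anyDuplicated(protein_ids),
              "duplicate protein ids are not allowed")
  assert_that(all(is.finite(counts)), "counts must be finite")
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(length(lengths) == nrow(counts),
              "`lengths` must have one entry per protein")
  assert_that(all(is.finite(lengths)) && all(lengths > 0),
              "protein lengths must be positive")
  assert_that(length(groups) == ncol(counts),
              "`groups` must have one entry per sample")
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  assert_that(nlevels(groups) == 2L,
              "`groups` must have exactly two levels")
  assert_that(is.character(fraction) && length(fraction) == 1L,
              "`fraction` must be a single string")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  rownames(counts) <- protein_ids
  structure(
    list(counts = counts, lengths = as.numeric(lengths), groups = groups,
         fraction = fraction, protein_ids = protein_ids),
    class = "spectral_counts"
  )
}

#' @export
print.spectral_counts <- function(x, ...) {
  cat("<spectral_counts> ", nrow(x$counts), " proteins x ", ncol(x$counts),
      " samples, fraction ", x$fraction, "\n", sep = "")
  cat("groups: ", paste(sprintf("%s (n=%d)", levels(x$groups),
                                tabulate(x$groups)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
as_tibble.spectral_counts <- function(x, ...) {
  tibble::as_tibble(x$counts, rownames = "protein_id") |>
    dplyr::mutate(length = x$lengths, .after = "protein_id")
}

#' Construct an expression matrix
#'
#' Container for log-scale expression values (genes x samples) with a
#' two-level group label, as produced by microarray preprocessing.
#'
#' @param values Numeric matrix of log-scale intensities, genes x samples.
#' @param groups Two-level sample label vector.
#' @param gene_ids Optional gene identifiers; defaults to `rownames(values)`.
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups, gene_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(values)))
  assert_that(!anyDuplicated(gene_ids), "duplicate gene ids are not allowed")
  assert_that(all(is.finite(values)), "expression values must be finite")
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  assert_that(nlevels(groups) == 2L, "`groups` must have exactly two levels")
  assert_that(all(tabulate(groups) >= 2L),
              "each group needs at least 2 samples")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  }
  rownames(values) <- gene_ids
  structure(list(values = values, groups = groups, gene_ids = gene_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  invisible(x)
}
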