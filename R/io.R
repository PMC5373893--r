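split_fields <- function(lines, sep = "\t") {
  strsplit(lines, sep, fixed = TRUE)
}

parse_error <- function(path, line_no, msg) {
  plaq_abort(sprintf("%s:%d: %s", path, line_no, msg),
             class = "plaqomics_parse_error")
}

#' Write / read a spectral-count matrix (TSV)
#'
#' Tab-separated with `#`-prefixed metadata lines (`#fraction` and
#' `#groups`), a header row (`protein_id`, `length`, sample ids) and one
#' row per protein. Write-then-read reproduces integer counts exactly.
#'
#' @param matrix A [spectral_count_matrix()].
#' @param path File path.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` returns a `spectral_counts` object.
#' @export
write_count_matrix <- function(matrix, path) {
  assert_that(inherits(matrix, "spectral_counts"),
              "`matrix` must be a spectral_count_matrix()")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#fraction\t", matrix$fraction), con)
  writeLines(paste0("#groups\t",
                    paste(colnames(matrix$counts), as.character(matrix$groups),
                          sep = "=", collapse = "\t")), con)
  writeLines(paste(c("protein_id", "length", colnames(matrix$counts)),
                   collapse = "\t"), con)
  body <- cbind(matrix$protein_ids, format(matrix$lengths, trim = TRUE),
                apply(matrix$counts, 2, format, trim = TRUE))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path)
  meta <- grepl("^#", lines)
  fraction <- "unknown"
  groups_map <- NULL
  for (i in which(meta)) {
    f <- split_fields(lines[i])[[1]]
    if (f[1] == "#fraction") fraction <- f[2]
    if (f[1] == "#groups") {
      kv <- strsplit(f[-1], "=", fixed = TRUE)
      groups_map <- stats::setNames(vapply(kv, `[`, "", 2),
                                    vapply(kv, `[`, "", 1))
    }
  }
  body_idx <- which(!meta)
  if (length(body_idx) < 2) parse_error(path, length(lines), "no data rows")
  header <- split_fields(lines[body_idx[1]])[[1]]
  if (header[1] != "protein_id" || header[2] != "length") {
    parse_error(path, body_idx[1],
                "header must start with 'protein_id\\tlength'")
  }
  samples <- header[-(1:2)]
  n_col <- length(header)
  rows <- split_fields(lines[body_idx[-1]])
  ids <- character(length(rows))
  lens <- numeric(length(rows))
  counts <- matrix(0L, nrow = length(rows), ncol = length(samples))
  for (k in seq_along(rows)) {
    ln <- body_idx[-1][k]
    f <- rows[[k]]
    if (length(f) != n_col) {
      parse_error(path, ln, sprintf("expected %d fields, found %d",
                                    n_col, length(f)))
    }
    ids[k] <- f[1]
    num <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(num)) {
      bad <- f[-1][which(is.na(num))[1]]
      parse_error(path, ln, sprintf("non-numeric value '%s'", bad))
    }
    lens[k] <- num[1]
    counts[k, ] <- num[-1]
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    parse_error(path, body_idx[-1][which(duplicated(ids))[1]],
                sprintf("duplicate protein id '%s'", dup[1]))
  }
  if (all(counts == round(counts))) storage.mode(counts) <- "integer"
  colnames(counts) <- samples
  groups <- if (!is.null(groups_map)) unname(groups_map[samples]) else
    plaq_abort("count matrix file lacks a #groups line")
  spectral_count_matrix(counts, lengths = lens, groups = groups,
                        fraction = fraction, protein_ids = ids)
}

#' Write / read an expression matrix (TSV)
#'
#' Tab-separated with a `#groups` metadata line, a header (`gene_id`,
#' sample ids) and one row per gene; values round-trip to 12 significant
#' digits.
#'
#' @param matrix An [expression_matrix()].
#' @param path File path.
#' @export
write_expression_matrix <- function(matrix, path) {
  assert_that(inherits(matrix, "expression_matrix"),
              "`matrix` must be an expression_matrix()")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#groups\t",
                    paste(colnames(matrix$values), as.character(matrix$groups),
                          sep = "=", collapse = "\t")), con)
  writeLines(paste(c("gene_id", colnames(matrix$values)), collapse = "\t"),
             con)
  body <- cbind(matrix$gene_ids,
                apply(matrix$values, 2, formatC, digits = 12, format = "g"))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  meta <- grepl("^#", lines)
  groups_map <- NULL
  for (i in which(meta)) {
    f <- split_fields(lines[i])[[1]]
    if (f[1] == "#groups") {
      kv <- strsplit(f[-1], "=", fixed = TRUE)
      groups_map <- stats::setNames(vapply(kv, `[`, "", 2),
                                    vapply(kv, `[`, "", 1))
    }
  }
  body_idx <- which(!meta)
  header <- split_fields(lines[body_idx[1]])[[1]]
  if (header[1] != "gene_id") {
    parse_error(path, body_idx[1], "header must start with 'gene_id'")
  }
  samples <- header[-1]
  rows <- split_fields(lines[body_idx[-1]])
  ids <- vapply(rows, `[`, "", 1)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(samples))
  for (k in seq_along(rows)) {
    ln <- body_idx[-1][k]
    f <- rows[[k]]
    if (length(f) != length(header)) {
      parse_error(path, ln, sprintf("expected %d fields, found %d",
                                    length(header), length(f)))
    }
    num <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(num)) parse_error(path, ln, "non-numeric expression value")
    vals[k, ] <- num
  }
  if (anyDuplicated(ids)) {
    parse_error(path, body_idx[-1][which(duplicated(ids))[1]],
                sprintf("duplicate gene id '%s'", ids[duplicated(ids)][1]))
  }
  colnames(vals) <- samples
  if (is.null(groups_map)) {
    plaq_abort("expression matrix file lacks a #groups line")
  }
  expression_matrix(vals, groups = unname(groups_map[samples]),
                    gene_ids = ids)
}

#' Write / read a cohort table (CSV)
#'
#' Plain CSV with one row per subject. Reading validates that subject ids
#' are unique and that every subject with `event_status = 1` carries an
#' `event_time`.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("subject_id" %in% names(cohort) && anyDuplicated(cohort$subject_id)) {
    plaq_abort(sprintf("%s: duplicate subject id '%s'", path,
                       cohort$subject_id[duplicated(cohort$subject_id)][1]),
               class = "plaqomics_parse_error")
  }
  if (all(c("event_status", "event_time") %in% names(cohort))) {
    bad <- which(cohort$event_status == 1 & !is.finite(cohort$event_time))
    if (length(bad) > 0) {
      plaq_abort(sprintf("%s: subject at row %d has an event but no event_time",
                         path, bad[1]),
                 class = "plaqomics_parse_error")
    }
  }
  cohort
}

#' Write / read a one-symbol-per-line gene list
#'
#' @param symbols Character vector.
#' @param path File path.
#' @export
write_gene_list <- function(symbols, path) {
  writeLines(as.character(symbols), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !grepl("^#", x)]
}

#' Protein concentration from UV absorbance (Groves formula)
#'
#' `concentration (mg/ml) = 1.55 * A280 - 0.76 * A260`, correcting the
#' 280 nm protein absorbance for nucleic-acid interference at 260 nm.
#' Negative results are floored at zero with a warning.
#'
#' @param a280,a260 Absorbance readings (non-negative, vectorized).
#' @return Concentration in mg/ml.
#' @export
#' @examples
#' groves_concentration(0.8, 0.5)  # 0.86 mg/ml
groves_concentration <- function(a280, a260) {
  if (any(a280 < 0) || any(a260 < 0)) {
    plaq_abort("absorbances must be non-negative")
  }
  conc <- 1.55 * a280 - 0.76 * a260
  if (any(conc < 0)) {
    rlang::warn("negative concentration floored at 0 (A260 exceeds protein signal)")
    conc <- pmax(conc, 0)
  }
  conc
}
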