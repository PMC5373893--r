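#' Union of per-fraction differential-expression lists
#'
#' Deduplicated union of the DE protein symbol lists from the extraction
#' fractions, with per-fraction provenance and a flag for members found in
#' at least two fractions. Symbols are upper-cased before comparison.
#'
#' @param fraction_lists Named list of character vectors of DE symbols
#'   (one per fraction).
#' @return Tibble: `symbol`, one logical column per fraction, `n_fractions`,
#'   `shared` (present in two or more fractions). Order follows first
#'   appearance.
#' @export
#' @examples
#' de_union(list(NaCl = c("MMP9", "APOA1"), GuHCl = c("APOA1", "FMOD")))
de_union <- function(fraction_lists) {
  assert_that(is.list(fraction_lists), "`fraction_lists` must be a list")
  if (is.null(names(fraction_lists))) {
    names(fraction_lists) <- paste0("fraction", seq_along(fraction_lists))
  }
  norm <- purrr::map(fraction_lists, ~ unique(toupper(.x)))
  all_sym <- unique(unlist(norm, use.names = FALSE))
  out <- tibble::tibble(symbol = all_sym)
  for (nm in names(norm)) {
    out[[nm]] <- all_sym %in% norm[[nm]]
  }
  out$n_fractions <- rowSums(as.matrix(out[names(norm)]))
  out$shared <- out$n_fractions >= 2
  out
}

#' Intersection of protein and transcript DE lists
#'
#' Case-normalized set intersection, order-stable by the first list.
#'
#' @param protein_union Character vector (or [de_union()] tibble) of DE
#'   protein symbols.
#' @param transcript_list Character vector of DE transcript symbols.
#' @return Character vector of shared symbols.
#' @export
intersect_de <- function(protein_union, transcript_list) {
  if (is.data.frame(protein_union)) protein_union <- protein_union$symbol
  p <- unique(toupper(protein_union))
  t_ <- unique(toupper(transcript_list))
  p[p %in% t_]
}

#' Select cross-omics candidate biomarkers
#'
#' A symbol is a candidate when it is detected by plaque proteomics *and*
#' by at least one of the two other approaches (plaque transcriptomics or
#' the SMC secretome):
#' `proteomics_union` intersected with the union of `transcript_overlap`
#' and `secretome_hits`. The selection is monotone: enlarging any evidence
#' list never removes a member.
#'
#' @param proteomics_union Character vector (or [de_union()] tibble) of DE
#'   proteins across fractions.
#' @param transcript_overlap Character vector of symbols DE at the
#'   transcript level (typically [intersect_de()] output).
#' @param secretome_hits Character vector of secretome hits.
#' @param directions Optional named numeric vector (+1/-1) of DE directions
#'   per symbol and source, as `list(proteomics = ..., transcriptomics =
#'   ..., secretome = ...)`.
#' @return Tibble of class `candidate_set`: `symbol`, logical evidence
#'   flags `proteomics`, `transcriptomics`, `secretome`, `n_evidence`.
#' @export
select_candidates <- function(proteomics_union, transcript_overlap,
                              secretome_hits, directions = NULL) {
  if (is.data.frame(proteomics_union)) {
    proteomics_union <- proteomics_union$symbol
  }
  p <- unique(toupper(proteomics_union))
  tr <- unique(toupper(transcript_overlap))
  se <- unique(toupper(secretome_hits))
  members <- p[p %in% union(tr, se)]
  out <- tibble::tibble(
    symbol = members,
    proteomics = TRUE,
    transcriptomics = members %in% tr,
    secretome = members %in% se
  )
  out$n_evidence <- 1L + out$transcriptomics + out$secretome
  if (!is.null(directions)) {
    for (src in names(directions)) {
      out[[paste0("direction_", src)]] <-
        unname(directions[[src]][out$symbol])
    }
  }
  structure(out, class = c("candidate_set", class(out)))
}

#' Protein-transcript correlation and sign concordance
#'
#' Pearson correlation between matched protein abundances and transcript
#' levels per shared symbol, with a concordance flag: positive correlation
#' and agreeing DE directions.
#'
#' @param protein_values Numeric matrix or tibble, symbols x observations
#'   (e.g. per-sample NSAF values).
#' @param transcript_values Numeric matrix of the same symbols x matched
#'   observations.
#' @param de_directions Optional list with numeric vectors `protein` and
#'   `transcript` (+1/-1 per symbol) for the direction-agreement part of
#'   the flag; when absent the flag reduces to `r > 0`.
#' @return Tibble: `symbol`, `r`, `p_value`, `n`, `concordant`.
#' @export
protein_transcript_correlation <- function(protein_values, transcript_values,
                                           de_directions = NULL) {
  protein_values <- as.matrix(protein_values)
  transcript_values <- as.matrix(transcript_values)
  shared <- intersect(rownames(protein_values), rownames(transcript_values))
  assert_that(length(shared) > 0, "no shared symbols")
  assert_that(ncol(protein_values) == ncol(transcript_values),
              "matched observation counts differ")
  assert_that(ncol(protein_values) >= 3L,
              "need at least 3 matched observations")
  purrr::map_dfr(shared, function(s) {
    x <- protein_values[s, ]
    y <- transcript_values[s, ]
    ct <- stats::cor.test(x, y, method = "pearson")
    agree <- TRUE
    if (!is.null(de_directions)) {
      agree <- isTRUE(sign(de_directions$protein[[s]]) ==
                        sign(de_directions$transcript[[s]]))
    }
    tibble::tibble(symbol = s, r = unname(ct$estimate),
                   p_value = ct$p.value, n = length(x),
                   concordant = unname(ct$estimate) > 0 & agree)
  })
}
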