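#' Collapse probe-level rows to genes
#'
#' When several probes map to one gene, keeps the probe with the largest
#' average intensity across all samples, so downstream differential
#' expression is reported per gene.
#'
#' @param values Numeric probes x samples matrix.
#' @param gene_map Character vector, gene symbol per probe row.
#' @return Numeric matrix with one row per gene (rownames = gene symbols).
#' @export
collapse_probes <- function(values, gene_map) {
  values <- as.matrix(values)
  assert_that(length(gene_map) == nrow(values),
              "`gene_map` must have one symbol per probe row")
  avg <- rowMeans(values)
  keep <- tibble::tibble(row = seq_len(nrow(values)),
                         gene = as.character(gene_map), avg = avg) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$avg, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- values[keep$row, , drop = FALSE]
  rownames(out) <- keep$gene
  out
}

# Newton inversion of the trigamma function (for the moments estimator of
# the prior degrees of freedom); trigamma is convex decreasing on (0, Inf)
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated two-group differential expression
#'
#' Per-gene two-group linear model with empirical-Bayes variance
#' moderation. Residual variances \eqn{s_g^2} (df \eqn{d}) are assumed to
#' follow a scaled inverse chi-square prior with scale \eqn{s_0^2} and
#' degrees of freedom \eqn{d_0}, estimated by the method of moments from
#' the log residual variances: with \eqn{z_g = \log s_g^2},
#' \eqn{Var(z) \approx \psi'(d/2) + \psi'(d_0/2)} determines \eqn{d_0} via
#' trigamma inversion and \eqn{E(z)} determines \eqn{s_0^2}. The moderated
#' t uses the posterior variance \eqn{(d_0 s_0^2 + d s_g^2)/(d_0 + d)} with
#' \eqn{d + d_0} degrees of freedom, followed by Benjamini-Hochberg FDR.
#'
#' @param matrix An [expression_matrix()].
#' @param fdr_threshold Significance threshold (default 0.10).
#' @param prior_df Optional override of the prior degrees of freedom:
#'   0 recovers the ordinary two-sample t, `Inf` pools all genes to the
#'   common prior variance.
#' @return A tibble of class `expression_de`: `gene_id`, `mean_a`,
#'   `mean_b` (first factor level = group A), `effect` (A - B),
#'   `statistic`, `p_value`, `fdr`, `significant`. Attributes `prior_df`,
#'   `prior_var`, `residual_df`.
#' @export
moderated_two_group_de <- function(matrix, fdr_threshold = 0.10,
                                   prior_df = NULL) {
  assert_that(inherits(matrix, "expression_matrix"),
              "`matrix` must be an expression_matrix()")
  g <- matrix$groups
  vals <- matrix$values
  n1 <- sum(g == levels(g)[1])
  n2 <- sum(g == levels(g)[2])
  assert_that(n1 >= 2 && n2 >= 2, "each group needs at least 2 samples")
  m_a <- rowMeans(vals[, g == levels(g)[1], drop = FALSE])
  m_b <- rowMeans(vals[, g == levels(g)[2], drop = FALSE])
  d <- n1 + n2 - 2
  ss <- (n1 - 1) * apply(vals[, g == levels(g)[1], drop = FALSE], 1,
                         stats::var) +
    (n2 - 1) * apply(vals[, g == levels(g)[2], drop = FALSE], 1, stats::var)
  s2 <- ss / d
  # method-of-moments fit of the variance prior on the log scale
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(d / 2) + log(d / 2)
  if (is.null(prior_df)) {
    excess <- stats::var(e) - trigamma(d / 2)
    d0 <- if (excess > 0) 2 * trigamma_inverse(excess) else Inf
  } else {
    d0 <- prior_df
  }
  if (is.infinite(d0)) {
    s0_2 <- exp(mean(e))
    post_var <- rep(s0_2, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s0_2 <- NA_real_
    post_var <- s2
    df_total <- d
  } else {
    s0_2 <- exp(mean(e) + log(d0 / 2) - digamma(d0 / 2))
    post_var <- (d0 * s0_2 + d * s2) / (d0 + d)
    df_total <- d + d0
  }
  se <- sqrt(post_var * (1 / n1 + 1 / n2))
  t_stat <- (m_a - m_b) / se
  p <- 2 * stats::pt(abs(t_stat), df = df_total, lower.tail = FALSE)
  fdr <- adjust_fdr(p)
  out <- tibble::tibble(
    gene_id = matrix$gene_ids,
    mean_a = unname(m_a), mean_b = unname(m_b),
    effect = unname(m_a - m_b),
    statistic = unname(t_stat), p_value = unname(p), fdr = unname(fdr),
    significant = unname(fdr < fdr_threshold)
  )
  structure(out, class = c("expression_de", class(out)),
            prior_df = d0, prior_var = s0_2, residual_df = d,
            fdr_threshold = fdr_threshold)
}

#' @export
glance.expression_de <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x), n_significant = sum(x$significant),
                 fdr_threshold = attr(x, "fdr_threshold"),
                 prior_df = attr(x, "prior_df"),
                 prior_var = attr(x, "prior_var"),
                 residual_df = attr(x, "residual_df"))
}

#' @export
tidy.expression_de <- function(x, ...) tibble::as_tibble(x)

#' Paired t-tests with Bonferroni family-wise control
#'
#' Per-protein two-sided paired t-test of condition differences (lipid
#' minus control within donor), Bonferroni-adjusted across the tested
#' family; a protein is significant at a 5% family-wise error rate when
#' `bonferroni_p < 0.05`. Proteins whose paired differences are all zero
#' are flagged degenerate and reported with p = 1.
#'
#' @param paired Long tibble with columns `protein_id`, `donor`,
#'   `condition` (`"control"`/`"lipid"`), `value`, e.g. from
#'   [simulate_secretome()].
#' @param family_size Bonferroni family size; default the number of tested
#'   proteins.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Tibble of class `paired_de`: `protein_id`,
#'   `mean_paired_difference`, `t_statistic`, `p_value`, `bonferroni_p`,
#'   `significant`, `degenerate`, `n_pairs`.
#' @export
paired_bonferroni_test <- function(paired, family_size = NULL, alpha = 0.05) {
  needed <- c("protein_id", "donor", "condition", "value")
  assert_that(all(needed %in% names(paired)),
              "paired table must have protein_id, donor, condition, value")
  wide <- paired |>
    tidyr::pivot_wider(id_cols = c("protein_id", "donor"),
                       names_from = "condition", values_from = "value") |>
    dplyr::filter(!is.na(.data$control) & !is.na(.data$lipid))
  m <- family_size %||% dplyr::n_distinct(wide$protein_id)
  out <- wide |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_paired_difference = mean(.data$lipid - .data$control),
      sd_diff = stats::sd(.data$lipid - .data$control),
      .groups = "drop"
    )
  assert_that(all(out$n_pairs >= 2), "need at least 2 complete pairs per protein")
  out <- out |>
    dplyr::mutate(
      degenerate = .data$sd_diff == 0,
      t_statistic = ifelse(.data$degenerate, NA_real_,
                           .data$mean_paired_difference /
                             (.data$sd_diff / sqrt(.data$n_pairs))),
      p_value = ifelse(.data$degenerate, 1,
                       2 * stats::pt(abs(.data$t_statistic),
                                     df = .data$n_pairs - 1,
                                     lower.tail = FALSE)),
      bonferroni_p = pmin(1, m * .data$p_value),
      significant = .data$bonferroni_p < alpha & !.data$degenerate
    ) |>
    dplyr::select("protein_id", "n_pairs", "mean_paired_difference",
                  "t_statistic", "p_value", "bonferroni_p", "significant",
                  "degenerate")
  structure(out, class = c("paired_de", class(out)), family_size = m,
            alpha = alpha)
}

#' @export
autoplot.expression_de <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$effect,
                               y = -log10(pmax(.data$fdr, 1e-300)),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "seagreen4")) +
    ggplot2::labs(x = "log-expression difference", y = "-log10 FDR",
                  colour = "significant",
                  title = "Transcript-level moderated-t DE") +
    ggplot2::theme_minimal()
}
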