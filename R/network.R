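#' All-pairs Pearson correlations with p-values
#'
#' Pearson r from centered cross-products for every feature pair, with
#' two-sided p-values from the t-transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}}
#' on n - 2 degrees of freedom. Constant features (zero variance) are
#' excluded and reported.
#'
#' @param values Numeric features x samples matrix (at least 3 samples).
#' @return Tibble with one row per unordered pair: `feature_1`,
#'   `feature_2`, `r`, `p_value`. Attribute `excluded` lists constant
#'   features.
#' @export
pearson_with_p <- function(values) {
  values <- as.matrix(values)
  assert_that(ncol(values) >= 3L, "need at least 3 samples")
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("F", seq_len(nrow(values)))
  }
  v <- apply(values, 1, stats::var)
  excluded <- rownames(values)[v == 0]
  values <- values[v > 0, , drop = FALSE]
  n_f <- nrow(values)
  n <- ncol(values)
  if (n_f < 2L) plaq_abort("fewer than 2 variable features")
  r <- stats::cor(t(values))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[idx]
  rv <- pmin(pmax(rv, -1), 1)
  tv <- rv * sqrt((n - 2) / pmax(1 - rv^2, 1e-300))
  p <- 2 * stats::pt(abs(tv), df = n - 2, lower.tail = FALSE)
  p[abs(rv) >= 1] <- 0
  f1 <- rownames(values)[idx[, 1]]
  f2 <- rownames(values)[idx[, 2]]
  # canonical orientation so the undirected pair set does not depend on the
  # input row order
  swap <- f1 > f2
  out <- tibble::tibble(
    feature_1 = ifelse(swap, f2, f1),
    feature_2 = ifelse(swap, f1, f2),
    r = rv, p_value = p
  )
  attr(out, "excluded") <- excluded
  out
}

#' Storey q-values
#'
#' Estimates the proportion of true nulls \eqn{\pi_0} by the median-lambda
#' rule over \eqn{\lambda \in \{0.05, 0.10, \ldots, 0.95\}}
#' (\eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (n(1-\lambda))}, median
#' across the grid, clipped to (0, 1]) and computes
#' \eqn{q_i = \hat\pi_0 \cdot \min_{ranks \ge i} (n p / rank)}, monotone in
#' the p-value ranking and capped at 1. With fewer than 10 p-values the
#' \eqn{\pi_0} estimate is unstable and the function falls back to
#' \eqn{\pi_0 = 1} (Benjamini-Hochberg) with a warning.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @return Numeric q-values in the input order; attribute `pi0`.
#' @export
storey_qvalues <- function(p_values) {
  if (length(p_values) == 0) plaq_abort("empty p-value vector")
  assert_that(all(p_values >= 0 & p_values <= 1),
              "p-values must lie in [0, 1]")
  n <- length(p_values)
  if (n < 10L) {
    rlang::warn("fewer than 10 p-values: falling back to pi0 = 1 (BH)")
    pi0 <- 1
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p_values > l) / (1 - l),
                    numeric(1))
    pi0 <- min(max(stats::median(pi0_l), 1 / n), 1)
  }
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * n * p_values[o] / rank(p_values, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)[ro]
  structure(q, pi0 = pi0)
}

#' Build a protein coexpression network
#'
#' Nodes are the analyzed proteins, sized by differential-expression
#' confidence (-log10 FDR); edges are protein pairs whose Pearson
#' correlation (computed across all samples pooled, after NSAF
#' normalization) passes the q-value FDR threshold (default 20%).
#'
#' @param nsaf Numeric NSAF matrix (proteins x samples).
#' @param de_result Optional `spectral_de` result supplying node sizes;
#'   its features must cover the matrix rows it annotates.
#' @param q_threshold Edge q-value threshold (default 0.20).
#' @param node_classes Optional named character vector of protein
#'   categories (e.g. collagen, protease) used as a node attribute.
#' @return Object of class `coexpression_network`: list with `nodes`
#'   (tibble: `feature`, `node_size`, `node_class`) and `edges` (tibble:
#'   `feature_1`, `feature_2`, `r`, `p_value`, `q_value`), plus the
#'   threshold and the estimated `pi0`.
#' @export
build_network <- function(nsaf, de_result = NULL, q_threshold = 0.20,
                          node_classes = NULL) {
  nsaf <- as.matrix(nsaf)
  if (nrow(nsaf) == 0) plaq_abort("empty matrix")
  pairs <- pearson_with_p(nsaf)
  q <- storey_qvalues(pairs$p_value)
  pairs$q_value <- as.numeric(q)
  edges <- pairs[pairs$q_value < q_threshold, , drop = FALSE]
  feats <- setdiff(rownames(nsaf), attr(pairs, "excluded"))
  node_size <- rep(NA_real_, length(feats))
  if (!is.null(de_result)) {
    idx <- match(feats, de_result$protein_id)
    node_size <- -log10(pmax(de_result$fdr[idx], 1e-300))
  }
  node_class <- rep(NA_character_, length(feats))
  if (!is.null(node_classes)) {
    node_class <- unname(node_classes[feats])
  }
  structure(
    list(nodes = tibble::tibble(feature = feats, node_size = node_size,
                                node_class = node_class),
         edges = tibble::as_tibble(edges),
         q_threshold = q_threshold,
         pi0 = attr(q, "pi0")),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d nodes, %d edges (q < %.2f, pi0 = %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$q_threshold, x$pi0))
  invisible(x)
}

#' @export
glance.coexpression_network <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 q_threshold = x$q_threshold, pi0 = x$pi0)
}

#' Convert a coexpression network to an igraph object
#'
#' @param network A [build_network()] result.
#' @return An undirected `igraph` graph with node and edge attributes.
#' @export
as_igraph <- function(network) {
  assert_that(inherits(network, "coexpression_network"),
              "`network` must be a coexpression_network")
  igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = as.data.frame(network$nodes)
  )
}

#' @export
autoplot.coexpression_network <- function(object, ...) {
  g <- as_igraph(object)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    feature = igraph::V(g)$name,
    x = lay[, 1], y = lay[, 2],
    node_size = igraph::V(g)$node_size
  )
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, feature, x1 = "x", y1 = "y"),
                     by = c(feature_1 = "feature")) |>
    dplyr::left_join(dplyr::select(nodes, feature, x2 = "x", y2 = "y"),
                     by = c(feature_2 = "feature"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2,
                                       alpha = abs(.data$r)),
                          colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$node_size),
                        colour = "steelblue") +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Protein coexpression network",
                  size = "-log10 FDR", alpha = "|r|")
}
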