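#' Normalized spectral abundance factors
#'
#' NSAF for protein i in sample j is the length-normalized count divided by
#' the sample total of length-normalized counts:
#' \deqn{NSAF_{ij} = (c_{ij}/L_i) / \sum_k (c_{kj}/L_k),}
#' so each sample column sums to one.
#'
#' @param matrix A [spectral_count_matrix()], or a numeric matrix if
#'   `lengths` is supplied.
#' @param lengths Protein lengths when `matrix` is a plain matrix.
#' @return Numeric NSAF matrix with the input dimnames; every column sums
#'   to 1.
#' @export
#' @examples
#' m <- spectral_count_matrix(
#'   matrix(c(10, 20, 10, 20), 2, dimnames = list(c("A", "B"), NULL)),
#'   lengths = c(100, 200), groups = c("sym", "asym"))
#' colSums(compute_nsaf(m))
compute_nsaf <- function(matrix, lengths = NULL) {
  if (inherits(matrix, "spectral_counts")) {
    lengths <- matrix$lengths
    counts <- matrix$counts
  } else {
    counts <- as.matrix(matrix)
    assert_that(!is.null(lengths), "`lengths` required for a plain matrix")
  }
  assert_that(all(lengths > 0), "protein lengths must be positive")
  saf <- counts / lengths
  tot <- colSums(saf)
  if (any(tot <= 0)) {
    plaq_abort("sample column with all-zero counts: NSAF undefined")
  }
  sweep(saf, 2, tot, "/")
}

# Shapiro-Wilk W; for > 5000 values an evenly spaced order-statistic
# subsample keeps the test defined while preserving the distribution shape
shapiro_w <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) plaq_abort("need at least 3 values for Shapiro-Wilk")
  if (length(x) > 5000L) {
    x <- sort(x)[round(seq(1L, length(x), length.out = 5000L))]
  }
  if (stats::sd(x) == 0) return(NA_real_)
  unname(stats::shapiro.test(x)$statistic)
}

#' Impute zero spectral counts with an empirical fractional value
#'
#' Zero counts are replaced by a single fractional value
#' \eqn{\epsilon \in (0,1)} chosen empirically: every candidate on the grid
#' `grid_step, 2*grid_step, ..., 1 - grid_step` is substituted for all
#' zeros, the resulting matrix is NSAF-normalized, and the pooled natural-log
#' NSAF values are scored by the Shapiro-Wilk W statistic. The chosen
#' \eqn{\epsilon} maximizes W; ties break toward the smallest value.
#'
#' @param matrix A [spectral_count_matrix()].
#' @param grid_step Grid resolution in (0, 1); default 0.01.
#' @return An object of class `imputation_result`: list with `epsilon`,
#'   `w_statistic`, `grid` (tibble of epsilon and w), `imputed_matrix`
#'   (a `spectral_counts` object with zeros replaced), and `applied`
#'   (FALSE when the input had no zeros and is returned unchanged).
#' @export
impute_zeros <- function(matrix, grid_step = 0.01) {
  assert_that(inherits(matrix, "spectral_counts"),
              "`matrix` must be a spectral_count_matrix()")
  assert_that(grid_step > 0 && grid_step < 1, "`grid_step` must be in (0,1)")
  counts <- matrix$counts
  if (!any(counts == 0)) {
    return(structure(
      list(epsilon = NA_real_, w_statistic = NA_real_,
           grid = tibble::tibble(epsilon = numeric(), w = numeric()),
           imputed_matrix = matrix, applied = FALSE),
      class = "imputation_result"
    ))
  }
  if (sum(counts != 0) < 3L) {
    plaq_abort("need at least 3 nonzero counts to score normality")
  }
  grid <- seq(grid_step, 1 - grid_step / 2, by = grid_step)
  grid <- grid[grid < 1]
  w <- vapply(grid, function(eps) {
    imp <- counts
    imp[imp == 0] <- eps
    shapiro_w(log(compute_nsaf(imp, matrix$lengths)))
  }, numeric(1))
  best <- which(w == max(w, na.rm = TRUE))[1]  # ties -> smallest epsilon
  imp <- counts
  imp[imp == 0] <- grid[best]
  imputed <- matrix
  imputed$counts <- imp
  structure(
    list(epsilon = grid[best], w_statistic = w[best],
         grid = tibble::tibble(epsilon = grid, w = w),
         imputed_matrix = imputed, applied = TRUE),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  if (!x$applied) {
    cat("<imputation_result> no zeros present; matrix unchanged\n")
  } else {
    cat(sprintf("<imputation_result> epsilon = %.2f (Shapiro-Wilk W = %.4f over %d grid points)\n",
                x$epsilon, x$w_statistic, nrow(x$grid)))
  }
  invisible(x)
}

#' Fit the power-law global error model
#'
#' Ordinary least squares of log replicate standard deviation on log
#' replicate mean across proteins, within the replicates of one condition:
#' \eqn{\ln SD_i = b + a \ln \mu_i}. The fitted \eqn{(a, b)} provide
#' modelled standard deviations for the signal-to-noise statistic, which
#' stabilizes variance estimates in small-n spectral-count designs.
#'
#' @param nsaf Numeric abundance matrix (typically NSAF after imputation).
#' @param groups Two-level sample label vector.
#' @param condition Group level to fit on; default the group with more
#'   replicates (tie broken toward the first level).
#' @return Object of class `plgem_fit`: `slope`, `intercept`, `r_squared`,
#'   `n_points`, `fit_condition`.
#' @export
fit_plgem <- function(nsaf, groups, condition = NULL) {
  nsaf <- as.matrix(nsaf)
  groups <- if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
  assert_that(ncol(nsaf) == length(groups),
              "`groups` must have one entry per sample")
  if (is.null(condition)) {
    sizes <- tabulate(groups)
    condition <- levels(groups)[which.max(sizes)]  # tie -> first level
  }
  assert_that(condition %in% levels(groups), "unknown `condition` level")
  cols <- which(groups == condition)
  if (length(cols) < 3L) {
    plaq_abort("need at least 3 replicates in the fitting condition")
  }
  sub <- nsaf[, cols, drop = FALSE]
  mu <- rowMeans(sub)
  sd_ <- apply(sub, 1, stats::sd)
  keep <- mu > 0 & sd_ > 0
  if (sum(sd_ > 0) == 0) plaq_abort("degenerate variance: all replicate SDs are zero")
  if (sum(keep) < 10L) {
    plaq_abort("need at least 10 proteins with positive mean and SD")
  }
  fit <- stats::lm(log(sd_[keep]) ~ log(mu[keep]))
  # noiseless inputs trigger lm's "essentially perfect fit" note; r^2 = 1
  # is the intended answer there
  r2 <- withCallingHandlers(
    summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_points = sum(keep),
         fit_condition = condition),
    class = "plgem_fit"
  )
}

#' @export
print.plgem_fit <- function(x, ...) {
  cat(sprintf("<plgem_fit> ln SD = %.4f + %.4f ln mean (r^2 = %.3f, %d proteins, condition '%s')\n",
              x$intercept, x$slope, x$r_squared, x$n_points, x$fit_condition))
  invisible(x)
}

#' @export
tidy.plgem_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.plgem_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_points = x$n_points,
                 fit_condition = x$fit_condition)
}

#' Power-law signal-to-noise statistic
#'
#' Per-protein STN with modelled (not empirical) standard deviations in the
#' denominator:
#' \deqn{STN_i = (\mu_{A,i} - \mu_{B,i}) /
#'   (e^{b}\mu_{A,i}^{a} + e^{b}\mu_{B,i}^{a}).}
#'
#' @param nsaf Numeric abundance matrix.
#' @param fit A [fit_plgem()] result.
#' @param groups Two-level sample labels; group A is the first factor level.
#' @return Named numeric vector of STN values (positive = higher in A).
#' @export
plgem_stn <- function(nsaf, fit, groups) {
  nsaf <- as.matrix(nsaf)
  groups <- if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
  assert_that(inherits(fit, "plgem_fit"), "`fit` must be a plgem_fit")
  assert_that(nlevels(groups) == 2L, "need exactly two groups")
  m_a <- rowMeans(nsaf[, groups == levels(groups)[1], drop = FALSE])
  m_b <- rowMeans(nsaf[, groups == levels(groups)[2], drop = FALSE])
  if (any(m_a <= 0) || any(m_b <= 0)) {
    plaq_abort("non-positive group mean: power-law model inapplicable (impute zeros first)")
  }
  denom <- exp(fit$intercept) * (m_a^fit$slope + m_b^fit$slope)
  stats::setNames((m_a - m_b) / denom, rownames(nsaf))
}

#' Resampling null distribution and p-values for STN
#'
#' Builds a pooled null by repeatedly splitting the replicates of the
#' fitting condition into two pseudo-groups, recomputing STN for every
#' protein. The two-sided p-value of protein i is the fraction of pooled
#' null |STN| at least |STN_i|, with the +1/(N+1) small-sample correction.
#' Deterministic given `seed`.
#'
#' @inheritParams plgem_stn
#' @param n_iter Number of resampling iterations (default 500).
#' @param seed Integer seed.
#' @return List with `statistic` (observed STN), `p_values`, and
#'   `null_abs_stn` (pooled null |STN| values).
#' @export
resampling_null <- function(nsaf, fit, groups, n_iter = 500L, seed = 1L) {
  if (!is_count(n_iter, 1L)) plaq_abort("`n_iter` must be a positive count")
  nsaf <- as.matrix(nsaf)
  groups <- if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
  assert_that(all(tabulate(groups) >= 2L),
              "need at least 2 replicates per group")
  stn <- plgem_stn(nsaf, fit, groups)
  cols <- which(groups == fit$fit_condition)
  m <- length(cols)
  sizes <- tabulate(groups)
  a <- fit$slope
  b <- fit$intercept
  with_seed(seed, {
    null_abs <- matrix(NA_real_, nrow = nrow(nsaf), ncol = n_iter)
    sub <- nsaf[, cols, drop = FALSE]
    for (it in seq_len(n_iter)) {
      # pseudo-groups of the real group sizes, drawn with replacement from
      # the replicates of the fitting condition
      g1 <- sub[, sample.int(m, sizes[1], replace = TRUE), drop = FALSE]
      g2 <- sub[, sample.int(m, sizes[2], replace = TRUE), drop = FALSE]
      mu1 <- rowMeans(g1)
      mu2 <- rowMeans(g2)
      null_abs[, it] <- abs((mu1 - mu2) / (exp(b) * (mu1^a + mu2^a)))
    }
    null_abs <- as.vector(null_abs)
    null_abs <- null_abs[is.finite(null_abs)]
    sorted <- sort(null_abs)
    n_null <- length(sorted)
    # count of null values >= |stn| via binary search on the sorted vector
    n_ge <- n_null - findInterval(abs(stn) - 1e-15, sorted)
    p <- (n_ge + 1) / (n_null + 1)
    list(statistic = stn, p_values = stats::setNames(pmin(p, 1), names(stn)),
         null_abs_stn = null_abs)
  })
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values, monotone in the p-value ranking and capped
#' at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param method Adjustment method passed to [stats::p.adjust()].
#' @return Adjusted values in the input order.
#' @export
adjust_fdr <- function(p_values, method = "BH") {
  if (length(p_values) == 0) plaq_abort("empty p-value vector")
  assert_that(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = method)
}

#' Spectral-count differential expression (NSAF + power-law error model)
#'
#' Full engine for one extraction fraction: drops proteins with zero counts
#' in every sample, imputes remaining zeros ([impute_zeros()]),
#' NSAF-normalizes, fits the power-law error model on the condition with
#' more replicates ([fit_plgem()]), computes signal-to-noise statistics
#' ([plgem_stn()]), derives resampling p-values ([resampling_null()]), and
#' applies Benjamini-Hochberg FDR. Proteins with `fdr < fdr_threshold`
#' form the significant set.
#'
#' @param matrix A [spectral_count_matrix()].
#' @param fdr_threshold Significance threshold on the FDR (default 0.10).
#' @param seed Integer seed for the resampling null.
#' @param n_iter Resampling iterations.
#' @param grid_step Imputation grid resolution.
#' @return A tibble of class `spectral_de` with columns `protein_id`,
#'   `mean_a`, `mean_b` (group NSAF means; group A is the first factor
#'   level), `log2_fold_change`, `statistic`, `p_value`, `fdr`,
#'   `significant`. Attributes: `fit` (`plgem_fit`), `imputation`,
#'   `fraction`, `groups`, `fdr_threshold`, `dropped` (all-zero proteins).
#' @export
run_spectral_de <- function(matrix, fdr_threshold = 0.10, seed = 1L,
                            n_iter = 500L, grid_step = 0.01) {
  assert_that(inherits(matrix, "spectral_counts"),
              "`matrix` must be a spectral_count_matrix()")
  assert_that(is_prop(fdr_threshold), "`fdr_threshold` must be in [0, 1]")
  all_zero <- rowSums(matrix$counts) == 0
  dropped <- matrix$protein_ids[all_zero]
  if (any(all_zero)) {
    matrix <- spectral_count_matrix(
      matrix$counts[!all_zero, , drop = FALSE],
      lengths = matrix$lengths[!all_zero],
      groups = matrix$groups, fraction = matrix$fraction,
      protein_ids = matrix$protein_ids[!all_zero]
    )
  }
  imp <- impute_zeros(matrix, grid_step = grid_step)
  nsaf <- compute_nsaf(imp$imputed_matrix)
  fit <- fit_plgem(nsaf, matrix$groups)
  res <- resampling_null(nsaf, fit, matrix$groups, n_iter = n_iter,
                         seed = seed)
  fdr <- adjust_fdr(res$p_values)
  g <- factor(matrix$groups)
  m_a <- rowMeans(nsaf[, g == levels(g)[1], drop = FALSE])
  m_b <- rowMeans(nsaf[, g == levels(g)[2], drop = FALSE])
  out <- tibble::tibble(
    protein_id = matrix$protein_ids,
    mean_a = m_a, mean_b = m_b,
    log2_fold_change = log2(m_a / m_b),
    statistic = unname(res$statistic),
    p_value = unname(res$p_values),
    fdr = unname(fdr),
    significant = unname(fdr < fdr_threshold)
  )
  structure(out,
            class = c("spectral_de", class(out)),
            fit = fit, imputation = imp, fraction = matrix$fraction,
            groups = g, fdr_threshold = fdr_threshold, dropped = dropped)
}

#' @export
glance.spectral_de <- function(x, ...) {
  fit <- attr(x, "fit")
  imp <- attr(x, "imputation")
  tibble::tibble(
    fraction = attr(x, "fraction"),
    n_proteins = nrow(x),
    n_significant = sum(x$significant),
    fdr_threshold = attr(x, "fdr_threshold"),
    epsilon = imp$epsilon,
    plgem_slope = fit$slope,
    plgem_intercept = fit$intercept,
    plgem_r_squared = fit$r_squared
  )
}

#' @export
tidy.spectral_de <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `spectral_de` or `expression_de` result.
#' @param ... Unused.
#' @return A ggplot object: log2 fold change against -log10 FDR, with the
#'   significant set highlighted.
#' @export
autoplot.spectral_de <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$log2_fold_change,
                               y = -log10(pmax(.data$fdr, 1e-300)),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (NSAF)", y = "-log10 FDR",
                  colour = "significant",
                  title = paste0("Spectral-count DE (",
                                 attr(object, "fraction"), " fraction)")) +
    ggplot2::theme_minimal()
}
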