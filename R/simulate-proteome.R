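#' Configuration for spectral-count simulation
#'
#' Describes a two-group spectral-counting experiment with a power-law
#' mean-variance relationship: replicate counts for a protein with mean
#' \eqn{\mu} have standard deviation \eqn{e^{b}\mu^{a}}, the structure the
#' power-law global error model (PLGEM) assumes. Differentially abundant
#' proteins have their group-B mean multiplied by `fold_change`. Structural
#' zeros are injected preferentially into low-abundance proteins.
#'
#' The defaults mirror a 6-versus-6 endarterectomy comparison. The power-law
#' parameters are free simulation parameters (within-group dispersion of the
#' motivating data set is not published), chosen to give replicate
#' coefficients of variation around 25--50% at typical count levels.
#'
#' @param seed Integer seed; the simulation is a pure function of the config.
#' @param n_proteins Number of proteins.
#' @param n_per_group Replicates per group (default 6).
#' @param de_fraction Proportion of proteins that are differentially abundant.
#' @param fold_change Multiplicative group-B/group-A mean ratio for DE
#'   proteins; must be positive.
#' @param plgem_slope,plgem_intercept Power-law exponent \eqn{a} and
#'   intercept \eqn{b} of \eqn{\log SD = b + a \log \mu}.
#' @param zero_rate Average per-cell probability of a structural zero.
#' @param length_range Integer pair, range of protein lengths (amino acids).
#' @param mean_log,sd_log Log-normal parameters of the across-protein
#'   abundance distribution.
#'
#' @return A `proteome_sim_config` list.
#' @export
proteome_sim_config <- function(seed = 1L, n_proteins = 200L, n_per_group = 6L,
                                de_fraction = 0, fold_change = 1,
                                plgem_slope = 0.7, plgem_intercept = -0.5,
                                zero_rate = 0.05,
                                length_range = c(100L, 2000L),
                                mean_log = 3, sd_log = 1.2) {
  assert_that(is_count(n_proteins, 1L), "`n_proteins` must be a positive count")
  assert_that(is_count(n_per_group, 0L), "`n_per_group` must be a count")
  if (n_per_group < 2L) {
    plaq_abort("`n_per_group` must be at least 2 (replicate SD undefined)")
  }
  assert_that(is_prop(de_fraction), "`de_fraction` must be in [0, 1]")
  if (!is.numeric(fold_change) || length(fold_change) != 1L ||
      !is.finite(fold_change) || fold_change <= 0) {
    plaq_abort("`fold_change` must be a positive number")
  }
  assert_that(is_prop(zero_rate), "`zero_rate` must be in [0, 1]")
  assert_that(length(length_range) == 2L && all(length_range > 0) &&
                length_range[1] <= length_range[2],
              "`length_range` must be an increasing pair of positive integers")
  structure(
    list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
         n_per_group = as.integer(n_per_group), de_fraction = de_fraction,
         fold_change = fold_change, plgem_slope = plgem_slope,
         plgem_intercept = plgem_intercept, zero_rate = zero_rate,
         length_range = as.integer(length_range),
         mean_log = mean_log, sd_log = sd_log),
    class = "proteome_sim_config"
  )
}

#' Simulate a two-group spectral-count experiment
#'
#' Draws per-protein abundance means from a log-normal distribution, adds
#' replicate noise with the power-law standard deviation
#' \eqn{e^{b}\mu^{a}}, rounds to non-negative integer counts, multiplies
#' group-B means of the selected DE proteins by the configured fold change,
#' and injects structural zeros with per-cell probability proportional to
#' `zero_rate / rank(abundance)` (normalized so the average equals
#' `zero_rate`), so zeros concentrate in low-abundance proteins as they do in
#' real spectral counting.
#'
#' @param config A [proteome_sim_config()].
#' @param fraction Fraction tag stored on the output matrix.
#'
#' @return A list with elements `matrix` (a [spectral_count_matrix()] with
#'   groups `"sym"`/`"asym"`) and `truth`, a tibble with columns
#'   `protein_id`, `is_de`, `direction` (+1/-1/0, sign of the group-A minus
#'   group-B log difference), `mean_a`, `mean_b`.
#' @export
#' @examples
#' sim <- simulate_spectral_counts(proteome_sim_config(seed = 7,
#'   n_proteins = 50, de_fraction = 0.1, fold_change = 3))
#' sim$matrix
#' sum(sim$truth$is_de)
simulate_spectral_counts <- function(config, fraction = "NaCl") {
  assert_that(inherits(config, "proteome_sim_config"),
              "`config` must be a proteome_sim_config")
  with_seed(config$seed, {
    n <- config$n_proteins
    k <- config$n_per_group
    mu_a <- stats::rlnorm(n, meanlog = config$mean_log, sdlog = config$sd_log)
    n_de <- round(config$de_fraction * n)
    de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
    is_de <- seq_len(n) %in% de_idx & config$fold_change != 1
    # DE directions are mixed (half up, half down in group B) so the
    # compositional sum-to-one constraint of NSAF stays centred
    up <- rep(FALSE, n)
    if (n_de > 0) up[de_idx] <- stats::runif(n_de) < 0.5
    mu_b <- mu_a
    mu_b[de_idx] <- mu_a[de_idx] *
      ifelse(up[de_idx], config$fold_change, 1 / config$fold_change)

    sd_of <- function(mu) exp(config$plgem_intercept) * mu^config$plgem_slope
    draw <- function(mu) {
      raw <- matrix(stats::rnorm(n * k, mean = rep(mu, k),
                                 sd = rep(sd_of(mu), k)), nrow = n)
      pmax(round(raw), 0)
    }
    counts <- cbind(draw(mu_a), draw(mu_b))

    if (config$zero_rate > 0) {
      rk <- rank(mu_a, ties.method = "first")
      w <- (1 / rk) / mean(1 / rk)
      p_zero <- pmin(1, config$zero_rate * w)
      zero_mask <- matrix(stats::runif(n * 2 * k) <
                            rep(p_zero, times = 2 * k), nrow = n)
      counts[zero_mask] <- 0
    }
    storage.mode(counts) <- "integer"

    lengths <- sample(seq(config$length_range[1], config$length_range[2]), n,
                      replace = TRUE)
    ids <- sprintf("P%04d", seq_len(n))
    rownames(counts) <- ids
    colnames(counts) <- c(paste0("sym", seq_len(k)), paste0("asym", seq_len(k)))
    groups <- rep(c("sym", "asym"), each = k)

    truth <- tibble::tibble(
      protein_id = ids,
      is_de = is_de,
      direction = ifelse(is_de, sign(log(mu_a / mu_b)), 0),
      mean_a = mu_a,
      mean_b = mu_b
    )
    list(
      matrix = spectral_count_matrix(counts, lengths = lengths,
                                     groups = groups, fraction = fraction),
      truth = truth
    )
  })
}

#' Simulate a two-group expression array experiment
#'
#' Per-gene Gaussian log-intensities with gene-specific residual variances
#' drawn from a scaled inverse chi-square distribution (the hierarchical
#' structure that empirical-Bayes variance moderation assumes). DE genes are
#' shifted upward by `effect_size` in group 1. Default group sizes mirror an
#' 84-versus-37 symptomatic/asymptomatic plaque contrast.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param n_group1,n_group2 Samples per group (each must be at least 2).
#' @param de_fraction Proportion of DE genes.
#' @param effect_size Log-scale shift added in group 1 for DE genes; must be
#'   finite.
#' @param baseline_mean Mean log-intensity level.
#' @param s0,d0 Prior scale and degrees of freedom of the gene-variance
#'   distribution: residual variances are \eqn{s_0^2 d_0 / \chi^2_{d_0}}.
#'
#' @return List with `matrix` (an [expression_matrix()] with groups
#'   `"sym"`/`"asym"`) and `truth` tibble (`gene_id`, `is_de`, `shift`).
#' @export
simulate_transcriptome <- function(seed = 1L, n_genes = 1000L,
                                   n_group1 = 84L, n_group2 = 37L,
                                   de_fraction = 0, effect_size = 1,
                                   baseline_mean = 7, s0 = 0.5, d0 = 4) {
  assert_that(is_count(n_group1, 2L) && is_count(n_group2, 2L),
              "both groups need at least 2 samples")
  if (!is.finite(effect_size)) plaq_abort("`effect_size` must be finite")
  assert_that(is_prop(de_fraction), "`de_fraction` must be in [0, 1]")
  with_seed(seed, {
    n_s <- n_group1 + n_group2
    gene_var <- s0^2 * d0 / stats::rchisq(n_genes, df = d0)
    base <- stats::rnorm(n_genes, baseline_mean, 1.5)
    vals <- matrix(stats::rnorm(n_genes * n_s, sd = rep(sqrt(gene_var), n_s)),
                   nrow = n_genes) + base
    n_de <- round(de_fraction * n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    is_de <- seq_len(n_genes) %in% de_idx & effect_size != 0
    vals[de_idx, seq_len(n_group1)] <-
      vals[de_idx, seq_len(n_group1), drop = FALSE] + effect_size
    ids <- sprintf("G%05d", seq_len(n_genes))
    rownames(vals) <- ids
    colnames(vals) <- c(paste0("sym", seq_len(n_group1)),
                        paste0("asym", seq_len(n_group2)))
    groups <- rep(c("sym", "asym"), c(n_group1, n_group2))
    list(
      matrix = expression_matrix(vals, groups = groups),
      truth = tibble::tibble(gene_id = ids, is_de = is_de,
                             shift = ifelse(is_de, effect_size, 0))
    )
  })
}

#' Simulate a paired secretome experiment
#'
#' Donor-paired control versus lipid-loaded protein levels with a shared
#' donor random effect (which the paired t-test removes) and independent
#' residual noise per measurement. Proteins listed in `shifted_proteins` are
#' elevated by `shift` in the lipid-loaded condition. Defaults mirror a
#' 6-donor experiment over 9 proteins shared between the secretome and the
#' plaque proteome.
#'
#' @param seed Integer seed.
#' @param n_donors Number of donors (at least 2).
#' @param n_proteins Number of proteins; ids are `"SEC1"`, ... unless
#'   `protein_ids` is given.
#' @param shifted_proteins Character vector of protein ids elevated under
#'   lipid loading; must be a subset of the protein ids.
#' @param shift Additive elevation in the loaded condition.
#' @param donor_sd SD of the donor random effect.
#' @param residual_sd SD of the per-measurement residual; the paired
#'   difference then has SD `sqrt(2) * residual_sd`.
#' @param protein_ids Optional protein id vector of length `n_proteins`.
#'
#' @return A tibble with columns `protein_id`, `donor`, `condition`
#'   (`"control"`/`"lipid"`), `value`, carrying attribute `truth` (tibble of
#'   `protein_id`, `shifted`, `shift`).
#' @export
simulate_secretome <- function(seed = 1L, n_donors = 6L, n_proteins = 9L,
                               shifted_proteins = character(), shift = 0,
                               donor_sd = 1, residual_sd = 0.3,
                               protein_ids = NULL) {
  if (n_donors < 2L) plaq_abort("`n_donors` must be at least 2")
  if (is.null(protein_ids)) protein_ids <- paste0("SEC", seq_len(n_proteins))
  assert_that(length(protein_ids) == n_proteins,
              "`protein_ids` must have length `n_proteins`")
  assert_that(all(shifted_proteins %in% protein_ids),
              "`shifted_proteins` must be a subset of the protein set")
  with_seed(seed, {
    base <- stats::rnorm(n_proteins, 10, 2)
    grid <- tidyr::expand_grid(protein_id = protein_ids,
                               donor = paste0("D", seq_len(n_donors)))
    donor_eff <- stats::rnorm(n_donors * n_proteins, 0, donor_sd)
    out <- grid |>
      dplyr::mutate(
        .base = rep(base, each = n_donors),
        .donor_eff = donor_eff
      ) |>
      tidyr::expand_grid(condition = c("control", "lipid")) |>
      dplyr::mutate(
        value = .data$.base + .data$.donor_eff +
          ifelse(.data$condition == "lipid" &
                   .data$protein_id %in% shifted_proteins, shift, 0) +
          stats::rnorm(dplyr::n(), 0, residual_sd)
      ) |>
      dplyr::select("protein_id", "donor", "condition", "value")
    attr(out, "truth") <- tibble::tibble(
      protein_id = protein_ids,
      shifted = protein_ids %in% shifted_proteins,
      shift = ifelse(protein_ids %in% shifted_proteins, shift, 0)
    )
    out
  })
}
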