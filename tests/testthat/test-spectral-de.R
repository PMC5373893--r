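test_that("NSAF matches hand evaluation and conserves column sums", {
  m <- spectral_count_matrix(
    matrix(c(10, 20, 10, 20), 2, 2, dimnames = list(c("P1", "P2"), NULL)),
    lengths = c(100, 200), groups = c("sym", "asym"))
  nsaf <- compute_nsaf(m)
  expect_equal(unname(nsaf[, 1]), c(0.5, 0.5))

  sim <- toy_counts(seed = 5, zero_rate = 0)
  expect_equal(unname(colSums(compute_nsaf(sim))),
               rep(1, ncol(sim$counts)), tolerance = 1e-12)

  one <- spectral_count_matrix(matrix(c(3, 7), 1, 2), lengths = 500,
                               groups = c("sym", "asym"),
                               protein_ids = "ONLY")
  expect_equal(unname(compute_nsaf(one)[1, ]), c(1, 1))

  zc <- matrix(c(0, 0, 5, 3), 2, 2)
  expect_error(compute_nsaf(zc, lengths = c(100, 100)), "all-zero")
})

test_that("zero imputation returns a zero-free matrix and honors the grid argmax", {
  m <- toy_counts(seed = 6, zero_rate = 0.1)
  expect_true(any(m$counts == 0))
  imp <- impute_zeros(m)
  expect_true(imp$applied)
  expect_true(all(imp$imputed_matrix$counts > 0))
  expect_true(imp$epsilon %in% imp$grid$epsilon)
  expect_equal(imp$w_statistic, max(imp$grid$w, na.rm = TRUE))

  # independent brute-force re-evaluation of W over the same grid
  grid <- imp$grid$epsilon
  w_oracle <- vapply(grid, function(eps) {
    counts <- m$counts
    counts[counts == 0] <- eps
    saf <- counts / m$lengths
    nsaf <- sweep(saf, 2, colSums(saf), "/")
    vals <- log(as.vector(nsaf))
    unname(stats::shapiro.test(vals)$statistic)
  }, numeric(1))
  expect_equal(grid[which.max(w_oracle)], imp$epsilon)
  expect_equal(max(w_oracle), imp$w_statistic, tolerance = 1e-12)
})

test_that("zero-free matrices pass through imputation unchanged", {
  m <- toy_counts(seed = 7, zero_rate = 0)
  m$counts[m$counts == 0] <- 1L
  imp <- impute_zeros(m)
  expect_false(imp$applied)
  expect_identical(imp$imputed_matrix$counts, m$counts)
})

test_that("power-law fit recovers exact parameters from noiseless data", {
  # replicates (mu - d, mu, mu + d) have sample SD exactly d
  mu <- exp(seq(log(5), log(500), length.out = 50))
  d <- exp(-1) * mu^0.5
  vals <- cbind(mu - d, mu, mu + d, mu - d, mu, mu + d)
  groups <- rep(c("sym", "asym"), each = 3)
  fit <- fit_plgem(vals, groups, condition = "sym")
  expect_equal(fit$slope, 0.5, tolerance = 1e-9)
  expect_equal(fit$intercept, -1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  expect_error(fit_plgem(vals[, c(1, 2, 4, 5)], rep(c("a", "b"), each = 2)),
               "at least 3 replicates")
  const <- matrix(5, 20, 6)
  expect_error(fit_plgem(const, groups), "degenerate|positive mean")
})

test_that("power-law fit recovers simulation parameters within tolerance", {
  sim <- simulate_spectral_counts(proteome_sim_config(
    seed = 19, n_proteins = 500, plgem_slope = 0.7, plgem_intercept = -0.5,
    zero_rate = 0))
  fit <- fit_plgem(sim$matrix$counts, sim$matrix$groups, condition = "sym")
  expect_lt(abs(fit$slope - 0.7), 0.07)
})

test_that("signal-to-noise statistic behaves at its degeneracies", {
  nsaf <- matrix(c(rep(2, 6), rep(c(1, 3), each = 3)), 2, 6, byrow = TRUE)
  groups <- rep(c("sym", "asym"), each = 3)
  fit <- structure(list(slope = 0, intercept = 0, r_squared = 1,
                        n_points = 10, fit_condition = "sym"),
                   class = "plgem_fit")
  stn <- plgem_stn(nsaf, fit, groups)
  expect_equal(unname(stn[1]), 0)              # equal means
  expect_equal(unname(stn[2]), (1 - 3) / 2)    # a = 0, b = 0 -> denom 2

  neg <- matrix(c(0, 0, 0, 1, 1, 1), 1, 6)
  expect_error(plgem_stn(neg, fit, groups), "non-positive")
})

test_that("true DE proteins dominate null proteins in |STN|", {
  sim <- simulate_spectral_counts(proteome_sim_config(
    seed = 3, n_proteins = 500, de_fraction = 0.1, fold_change = 3))
  de <- run_spectral_de(sim$matrix, seed = 1, n_iter = 100)
  tt <- sim$truth[match(de$protein_id, sim$truth$protein_id), ]
  w <- stats::wilcox.test(abs(de$statistic[tt$is_de]),
                          abs(de$statistic[!tt$is_de]),
                          alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("resampling p-values are seed-deterministic and maximal at STN zero", {
  sim <- toy_counts(seed = 9, zero_rate = 0)
  nsaf <- compute_nsaf(sim)
  nsaf <- rbind(nsaf, CONST = rep(1 / nrow(nsaf), ncol(nsaf)))
  nsaf <- sweep(nsaf, 2, colSums(nsaf), "/")
  fit <- fit_plgem(nsaf, sim$groups, condition = "sym")
  r1 <- resampling_null(nsaf, fit, sim$groups, n_iter = 100, seed = 4)
  r2 <- resampling_null(nsaf, fit, sim$groups, n_iter = 100, seed = 4)
  expect_identical(r1$p_values, r2$p_values)
  expect_equal(unname(r1$statistic["CONST"]), 0)
  expect_gte(unname(r1$p_values["CONST"]), 0.999)
  expect_error(resampling_null(nsaf, fit, sim$groups, n_iter = 0), "positive")
})

test_that("Benjamini-Hochberg adjustment matches the step-up rule", {
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.3, 0.001, 0.2, 0.05, 0.9)
  perm <- c(4, 1, 5, 2, 3)
  expect_equal(adjust_fdr(p)[perm], adjust_fdr(p[perm]))
  expect_error(adjust_fdr(numeric(0)), "empty")
})

test_that("label swap negates STN and leaves p-values and FDR unchanged", {
  sim <- simulate_spectral_counts(proteome_sim_config(
    seed = 12, n_proteins = 80, de_fraction = 0.1, fold_change = 2,
    zero_rate = 0))
  nsaf <- compute_nsaf(sim$matrix)
  g <- sim$matrix$groups
  g_sw <- factor(as.character(g), levels = rev(levels(g)))
  fit <- fit_plgem(nsaf, g, condition = "sym")
  stn <- plgem_stn(nsaf, fit, g)
  stn_sw <- plgem_stn(nsaf, fit, g_sw)
  expect_equal(stn_sw, -stn)
  p <- resampling_null(nsaf, fit, g, n_iter = 200, seed = 2)$p_values
  p_sw <- resampling_null(nsaf, fit, g_sw, n_iter = 200, seed = 2)$p_values
  expect_equal(p, p_sw)
  expect_equal(adjust_fdr(p), adjust_fdr(p_sw))
})

test_that("full engine detects planted fold changes with controlled FDP", {
  sens <- fdp <- numeric(0)
  for (s in 1:10) {
    sim <- simulate_spectral_counts(proteome_sim_config(
      seed = s, n_proteins = 300, de_fraction = 0.1, fold_change = 3))
    de <- run_spectral_de(sim$matrix, seed = s + 100, n_iter = 300)
    tt <- sim$truth[match(de$protein_id, sim$truth$protein_id), ]
    sens <- c(sens, mean(de$significant[tt$is_de]))
    fdp <- c(fdp, sum(de$significant & !tt$is_de) /
               max(1, sum(de$significant)))
  }
  expect_gte(mean(sens), 0.6)
  expect_lte(mean(fdp), 0.2)
})

test_that("threshold zero yields an empty significant set and all-zero proteins are dropped", {
  m <- toy_counts(seed = 14, zero_rate = 0.1)
  m$counts[3, ] <- 0L
  de <- run_spectral_de(m, fdr_threshold = 0, seed = 1, n_iter = 50)
  expect_equal(sum(de$significant), 0)
  expect_false(m$protein_ids[3] %in% de$protein_id)
  expect_true(m$protein_ids[3] %in% attr(de, "dropped"))
})
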