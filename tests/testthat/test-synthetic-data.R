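test_that("generators are pure functions of config and seed", {
  cfg <- proteome_sim_config(seed = 7, n_proteins = 60, de_fraction = 0.1,
                             fold_change = 2)
  s1 <- simulate_spectral_counts(cfg)
  s2 <- simulate_spectral_counts(cfg)
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  expect_identical(s1$truth, s2$truth)

  t1 <- simulate_transcriptome(seed = 3, n_genes = 50)
  t2 <- simulate_transcriptome(seed = 3, n_genes = 50)
  expect_identical(t1$matrix$values, t2$matrix$values)

  e1 <- simulate_secretome(seed = 5, shift = 1, shifted_proteins = "SEC2")
  e2 <- simulate_secretome(seed = 5, shift = 1, shifted_proteins = "SEC2")
  expect_identical(e1$value, e2$value)

  c1 <- simulate_cohort(cohort_sim_config(seed = 9, n_subjects = 60))
  c2 <- simulate_cohort(cohort_sim_config(seed = 9, n_subjects = 60))
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$exams, c2$exams)
})

test_that("null proteome configuration carries no DE flags and invalid configs error", {
  sim <- simulate_spectral_counts(proteome_sim_config(
    seed = 1, n_proteins = 50, de_fraction = 0, fold_change = 1))
  expect_equal(sum(sim$truth$is_de), 0)
  # fold_change = 1 means no effect even when a fraction is nominated
  sim2 <- simulate_spectral_counts(proteome_sim_config(
    seed = 1, n_proteins = 50, de_fraction = 0.2, fold_change = 1))
  expect_equal(sum(sim2$truth$is_de), 0)

  expect_error(proteome_sim_config(fold_change = 0), "positive")
  expect_error(proteome_sim_config(fold_change = -2), "positive")
  expect_error(proteome_sim_config(n_per_group = 1), "at least 2")
})

test_that("generated counts follow the requested power-law mean-SD structure", {
  sim <- simulate_spectral_counts(proteome_sim_config(
    seed = 21, n_proteins = 500, plgem_slope = 0.5, plgem_intercept = -1,
    zero_rate = 0))
  counts <- sim$matrix$counts
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  g <- sim$matrix$groups
  sub <- counts[, g == "sym", drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, sd)
  keep <- mu > 0 & sdv > 0
  slope <- unname(coef(lm(log(sdv[keep]) ~ log(mu[keep])))[2])
  expect_lt(abs(slope - 0.5), 0.05)
})

test_that("zeros concentrate in low-abundance proteins", {
  sim <- simulate_spectral_counts(proteome_sim_config(
    seed = 8, n_proteins = 400, zero_rate = 0.15))
  zr <- rowMeans(sim$matrix$counts == 0)
  abund <- sim$truth$mean_a
  low <- abund <= median(abund)
  expect_gt(mean(zr[low]), mean(zr[!low]))
})

test_that("null transcriptome gives uniform two-sample t p-values", {
  sim <- simulate_transcriptome(seed = 13, n_genes = 2000, de_fraction = 0)
  g <- sim$matrix$groups
  v <- sim$matrix$values
  a <- v[, g == levels(g)[1]]
  b <- v[, g == levels(g)[2]]
  p <- vapply(seq_len(nrow(v)), function(i) {
    stats::t.test(a[i, ], b[i, ], var.equal = TRUE)$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  expect_error(simulate_transcriptome(n_group2 = 1), "at least 2")
  expect_error(simulate_transcriptome(effect_size = Inf), "finite")
})

test_that("secretome pairing removes the donor effect", {
  sec <- simulate_secretome(seed = 2, shift = 0)
  wide <- tidyr::pivot_wider(sec, id_cols = c(protein_id, donor),
                             names_from = condition, values_from = value)
  diffs <- wide$lipid - wide$control
  expect_lt(abs(mean(diffs)), 0.2)
  # large donor effect: paired t beats unpaired t on the same data
  sec2 <- simulate_secretome(seed = 4, n_proteins = 1,
                             shifted_proteins = "SEC1", shift = 0.8,
                             donor_sd = 2, residual_sd = 0.2)
  w2 <- tidyr::pivot_wider(sec2, id_cols = c(protein_id, donor),
                           names_from = condition, values_from = value)
  p_paired <- stats::t.test(w2$lipid, w2$control, paired = TRUE)$p.value
  p_unpaired <- stats::t.test(w2$lipid, w2$control)$p.value
  expect_lt(p_paired, p_unpaired)
  expect_error(simulate_secretome(n_donors = 1), "at least 2")
})

test_that("cohort marginals match the configured rates", {
  cfg <- cohort_sim_config(seed = 31, n_subjects = 685,
                           baseline_event_rate = 91 / 685)
  cs <- simulate_cohort(cfg)
  co <- cs$cohort
  # binomial tolerance around the target event rate
  ci <- stats::binom.test(sum(co$event_status), nrow(co))$conf.int
  expect_true(91 / 685 >= ci[1] && 91 / 685 <= ci[2])
  expect_true(all(co$age >= 40 & co$age <= 79))
  expect_true(all(co[paste0("bm", 1:4)] > 0))
  expect_true(all(co$event_time > 0 & co$event_time <= 10))
})

test_that("log-biomarker correlation matches the requested matrix", {
  r_target <- matrix(c(1, 0.5, 0.5, 1), 2)
  frob <- vapply(1:10, function(s) {
    cs <- simulate_cohort(cohort_sim_config(
      seed = s, n_subjects = 685, n_biomarkers = 2,
      biomarker_correlation = r_target, or_per_sd = 1, hr_per_sd = 1))
    r_hat <- cor(log(as.matrix(cs$cohort[paste0("bm", 1:2)])))
    sqrt(sum((r_hat - r_target)^2))
  }, numeric(1))
  expect_lt(mean(frob), 0.1)
  bad <- matrix(c(1, 1, 1, 1), 2)
  expect_error(
    cohort_sim_config(n_biomarkers = 2, biomarker_correlation = bad),
    "positive definite")
})

test_that("null odds and hazard ratios are recovered as null", {
  cover_or <- logical(0)
  cover_hr <- logical(0)
  for (s in 1:20) {
    cs <- simulate_cohort(cohort_sim_config(
      seed = s, n_subjects = 685, or_per_sd = 1, hr_per_sd = 1))
    co <- standardize_biomarkers(cs$cohort, paste0("bm", 1:4))
    tl <- tidy(fit_logistic(co, "advanced",
                            c("age", "sex", paste0("bm", 1:4, "_z"))))
    tl <- tl[grepl("bm", tl$term), ]
    cover_or <- c(cover_or, tl$conf_low <= 1 & tl$conf_high >= 1)
    tc <- tidy(fit_cox(co, c("age", "sex", paste0("bm", 1:4, "_z"))))
    tc <- tc[grepl("bm", tc$term), ]
    cover_hr <- c(cover_hr, tc$conf_low <= 1 & tc$conf_high >= 1)
  }
  expect_gte(mean(cover_or), 0.9)
  expect_gte(mean(cover_hr), 0.9)
})

test_that("noise-free exams reproduce the generator's progression classes", {
  cs <- simulate_cohort(cohort_sim_config(seed = 17, n_subjects = 300,
                                          measurement_error_sd = 0))
  ex <- cs$exams
  calls <- classify_progression(ex[ex$visit == "baseline", ],
                                ex[ex$visit == "followup", ])
  tr <- cs$truth[match(calls$subject_id, cs$truth$subject_id), ]
  agree <- calls$advanced == tr$advanced_true &
    calls$early == tr$early_true &
    calls$incipient == tr$incipient_true
  expect_gte(mean(agree), 0.95)
})

test_that("case-cohort sampling keeps every case and respects the seed", {
  cs <- simulate_cohort(cohort_sim_config(seed = 23, n_subjects = 200))
  co <- cs$cohort
  cc <- draw_case_cohort(co, 50, seed = 11)
  expect_true(all(co$subject_id[co$event_status == 1] %in% cc$subject_id))
  expect_equal(sum(cc$subcohort), 50)
  cc2 <- draw_case_cohort(co, 50, seed = 11)
  expect_identical(cc, cc2)
  # subcohort = full cohort reduces to the full cohort
  full <- draw_case_cohort(co, nrow(co), seed = 1)
  expect_equal(nrow(full), nrow(co))
  expect_true(all(full$subcohort))
  expect_error(draw_case_cohort(co, 0, seed = 1), "positive")
  expect_error(draw_case_cohort(co, nrow(co) + 1, seed = 1), "exceed")
})
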