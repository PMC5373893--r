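test_that("biomarker standardization is a pure log z-score", {
  set.seed(1)
  x <- rlnorm(500, 2, 0.7)
  z <- standardize_biomarker(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  # scale invariance
  expect_equal(as.numeric(standardize_biomarker(10 * x)), as.numeric(z),
               tolerance = 1e-9)
  # the geometric mean maps to zero
  gm <- exp(mean(log(x)))
  z2 <- standardize_biomarker(c(x, gm))
  expect_lt(abs(z2[length(z2)]), 0.01)
  expect_error(standardize_biomarker(c(1, -1)), "positive")
  expect_error(standardize_biomarker(rep(2, 5)), "zero variance")
})

test_that("logistic regression reproduces the 2x2 cross-product odds ratio", {
  d <- tibble::tibble(
    y = c(rep(1, 30), rep(0, 170)),
    x = c(rep(1, 20), rep(0, 10), rep(1, 80), rep(0, 90))
  )
  fit <- fit_logistic(d, "y", "x")
  expect_equal(tidy(fit)$ratio[2], (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_error(fit_logistic(tibble::tibble(y = rep(1, 10), x = rnorm(10)),
                            "y", "x"), "both classes")
  # complete separation is reported, not clipped
  sep <- tibble::tibble(y = rep(c(0, 1), each = 20),
                        x = c(rnorm(20, -5), rnorm(20, 5)))
  expect_error(fit_logistic(sep, "y", "x"), class = "plaqomics_separation")
})

test_that("Cox estimates are invariant to time rescaling and need events", {
  cs <- simulate_cohort(cohort_sim_config(seed = 41, n_subjects = 300))
  co <- standardize_biomarkers(cs$cohort, "bm1")
  f1 <- fit_cox(co, c("age", "bm1_z"))
  co2 <- co
  co2$event_time <- co2$event_time * 2
  f2 <- fit_cox(co2, c("age", "bm1_z"))
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-8)
  none <- co
  none$event_status <- 0
  expect_error(fit_cox(none, "age"), "no events")
  neg <- co
  neg$event_time[1] <- -1
  expect_error(fit_cox(neg, "age"), "non-positive")
})

test_that("stepwise selection honors entry rules and logs its path", {
  cs <- simulate_cohort(cohort_sim_config(seed = 43, n_subjects = 600,
                                          or_per_sd = c(2.5, 1, 1, 1)))
  co <- standardize_biomarkers(cs$cohort, paste0("bm", 1:4))
  # pure-noise candidates never enter
  co$noise1 <- rnorm(nrow(co))
  co$noise2 <- rnorm(nrow(co))
  sw0 <- forward_stepwise(co, "advanced", c("noise1", "noise2"),
                          c("age", "sex"), p_enter = 1e-6)
  expect_length(sw0$selected, 0)
  # a single strong candidate is selected with path length 1
  sw1 <- forward_stepwise(co, "advanced", "bm1_z", c("age", "sex"))
  expect_equal(sw1$selected, "bm1_z")
  expect_equal(nrow(sw1$path), 1)
  expect_equal(sw1$path$action, "add")
  expect_error(forward_stepwise(co, "advanced", "age", "age"), "disjoint")
})

test_that("Prentice case-cohort reduces to the full-cohort Cox fit", {
  cs <- simulate_cohort(cohort_sim_config(seed = 47, n_subjects = 400))
  co <- standardize_biomarkers(cs$cohort, "bm1")
  full_cc <- draw_case_cohort(co, nrow(co), seed = 1)
  m_cc <- prentice_case_cohort(full_cc, c("age", "bm1_z"))
  m_full <- fit_cox(co, c("age", "bm1_z"))
  expect_equal(coef(m_cc$fit), coef(m_full$fit), tolerance = 1e-6)

  # every case contributes even when outside the subcohort
  cc <- draw_case_cohort(co, 80, seed = 3)
  outside <- cc$case & !cc$subcohort
  expect_gt(sum(outside), 0)
  m <- prentice_case_cohort(cc, c("age", "bm1_z"))
  expect_equal(m$n_used, nrow(cc))
  no_sub <- cc
  no_sub$subcohort <- FALSE
  expect_error(prentice_case_cohort(no_sub, "age"), "empty subcohort")
})

test_that("Schoenfeld check passes proportional hazards and flags reversal", {
  cs <- simulate_cohort(cohort_sim_config(seed = 53, n_subjects = 500))
  co <- standardize_biomarkers(cs$cohort, "bm1")
  fit <- fit_cox(co, c("age", "bm1_z"))
  sc <- schoenfeld_check(fit)
  expect_true(all(c("term", "rho", "chisq", "p_value") %in% names(sc)))
  expect_equal(sc$term[nrow(sc)], "GLOBAL")

  # an effect that reverses mid-follow-up is detected
  detected <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 1000
    x <- rnorm(n)
    # piecewise hazard: strong positive effect before t = 5, negative after
    t1 <- rexp(n, rate = 0.05 * exp(1.2 * x))
    t2 <- 5 + rexp(n, rate = 0.05 * exp(-1.2 * x))
    tm <- ifelse(t1 < 5, t1, t2)
    d <- tibble::tibble(event_time = pmin(tm, 10),
                        event_status = as.integer(tm <= 10), x = x)
    f <- fit_cox(d, "x")
    any(schoenfeld_check(f)$p_value[-nrow(schoenfeld_check(f))] < 0.05)
  }, logical(1))
  expect_gte(mean(detected), 0.8)

  two <- tibble::tibble(event_time = c(1, 2, 3, 4),
                        event_status = c(1, 1, 0, 0), x = rnorm(4))
  expect_error(schoenfeld_check(fit_cox(two, "x")), "at least 3 events")
})

test_that("C-statistic equals exhaustive pair counting", {
  set.seed(61)
  for (i in 1:5) {
    n <- sample(20:50, 1)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) y[1:2] <- c(0, 1)
    pred <- round(runif(n), 2)   # rounding forces some ties
    got <- c_statistic(pred, y)
    expect_equal(got$c_statistic, brute_force_c(pred, y), tolerance = 1e-12)
  }
  # survival variant against the pair-enumeration oracle
  for (i in 1:5) {
    n <- 30
    tm <- round(rexp(n, 0.2), 1)
    st <- rbinom(n, 1, 0.6)
    if (sum(st) == 0) st[1] <- 1
    pred <- round(rnorm(n), 1)
    got <- c_statistic(pred, survival = TRUE, times = tm, status = st)
    expect_equal(got$c_statistic,
                 brute_force_c(pred, survival = TRUE, times = tm,
                               status = st),
                 tolerance = 1e-12)
  }
})

test_that("C-statistic edge behavior and agreement with survival::concordance", {
  y <- c(rep(0, 10), rep(1, 10))
  pred <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  expect_equal(c_statistic(pred, y)$c_statistic, 1)

  set.seed(63)
  y2 <- rbinom(1000, 1, 0.3)
  p2 <- runif(1000)
  cr <- c_statistic(p2, y2)$c_statistic
  expect_gt(cr, 0.45)
  expect_lt(cr, 0.55)

  # tie-free survival data: match the survival package implementation
  set.seed(65)
  n <- 80
  tm <- rexp(n)
  st <- rbinom(n, 1, 0.7)
  pred <- rnorm(n)
  ours <- c_statistic(pred, survival = TRUE, times = tm, status = st)
  ref <- survival::concordance(survival::Surv(tm, st) ~ pred, reverse = TRUE)
  expect_equal(ours$c_statistic, unname(ref$concordance), tolerance = 1e-9)
})

test_that("DeLong comparison is internally consistent and matches pROC", {
  set.seed(71)
  y <- rbinom(300, 1, 0.3)
  x1 <- rnorm(300) + y
  x2 <- rnorm(300) + 0.5 * y
  self <- delong_compare(x1, x1, y)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$p_value, 1)

  dl <- delong_compare(x1, x2, y)
  expect_equal(dl$auc_1, c_statistic(x1, y)$c_statistic, tolerance = 1e-9)
  expect_equal(dl$auc_2, c_statistic(x2, y)$c_statistic, tolerance = 1e-9)

  ref <- pROC::roc.test(pROC::roc(y, x1, quiet = TRUE),
                        pROC::roc(y, x2, quiet = TRUE), method = "delong")
  expect_equal(dl$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong p-values are calibrated for equally informative scores", {
  # two pre-specified scores with the same true AUC: H0 holds by symmetry
  pvals <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 400
    truth <- rnorm(n)
    y <- rbinom(n, 1, plogis(truth))
    s1 <- truth + rnorm(n)
    s2 <- truth + rnorm(n)
    delong_compare(s1, s2, y)$p_value
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("NRI reproduces hand-computed values", {
  same <- nri(c(0.02, 0.2, 0.6), c(0.02, 0.2, 0.6), c(0, 1, 1))
  expect_equal(same$nri, c(0, 0))

  # 4 events: 2 up, 0 down; 6 non-events: 1 down, 2 up -> NRI = 1/3
  pred_old <- c(0.02, 0.02, 0.06, 0.06,            # events
                0.06, 0.02, 0.02, 0.02, 0.02, 0.02) # non-events
  pred_new <- c(0.06, 0.09, 0.06, 0.06,            # 2 events up
                0.02, 0.06, 0.09, 0.02, 0.02, 0.02) # 1 down, 2 up
  y <- c(rep(1, 4), rep(0, 6))
  res <- nri(pred_old, pred_new, y)
  expect_equal(res$nri[res$type == "categorical"], 1 / 3, tolerance = 1e-12)

  # continuous variant equals explicit sign counting
  cont <- res[res$type == "continuous", ]
  up <- pred_new > pred_old
  down <- pred_new < pred_old
  ev <- y == 1
  oracle <- (mean(up[ev]) - mean(down[ev])) +
    (mean(down[!ev]) - mean(up[!ev]))
  expect_equal(cont$nri, oracle, tolerance = 1e-12)
  expect_error(nri(pred_old, pred_new, rep(1, 10)), "both events")
  expect_error(nri(pred_old - 1, pred_new, y), "risks")
})

test_that("risk categories are closed on the left", {
  # exactly at the cut-points: 5% belongs to the middle, 7.5% to the top
  expect_equal(plaqomics:::risk_category(c(0.049, 0.05, 0.074, 0.075, 1),
                                         c(0.05, 0.075)),
               c(0L, 1L, 1L, 2L, 2L))
})

test_that("IDI equals the difference of discrimination slopes", {
  expect_equal(idi(c(0.1, 0.5), c(0.1, 0.5), c(0, 1))$idi, 0)
  pred_old <- c(0.2, 0.3, 0.1, 0.4)
  pred_new <- c(0.5, 0.6, 0.1, 0.2)
  y <- c(1, 1, 0, 0)
  hand <- (mean(c(0.5, 0.6)) - mean(c(0.1, 0.2))) -
    (mean(c(0.2, 0.3)) - mean(c(0.1, 0.4)))
  expect_equal(idi(pred_old, pred_new, y)$idi, hand, tolerance = 1e-12)

  # adding pure noise cannot improve the discrimination slope on average
  idis <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 200
    y <- rbinom(n, 1, 0.3)
    p0 <- plogis(qlogis(0.3) + y + rnorm(n))
    p1 <- pmin(pmax(p0 + rnorm(n, 0, 0.1), 0), 1)
    idi(p0, p1, y)$idi
  }, numeric(1))
  expect_lte(mean(idis), 0.005)
})

test_that("estimators are invariant to subject ordering", {
  cs <- simulate_cohort(cohort_sim_config(seed = 81, n_subjects = 300))
  co <- standardize_biomarkers(cs$cohort, paste0("bm", 1:4))
  perm <- sample(nrow(co))
  f1 <- fit_logistic(co, "advanced", c("age", "bm1_z"))
  f2 <- fit_logistic(co[perm, ], "advanced", c("age", "bm1_z"))
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-9)
  r1 <- compare_risk_models(co, "advanced", c("age", "sex"),
                            paste0("bm", 1:4, "_z"))
  r2 <- compare_risk_models(co[perm, ], "advanced", c("age", "sex"),
                            paste0("bm", 1:4, "_z"))
  expect_equal(r1$delta_c, r2$delta_c, tolerance = 1e-9)
  expect_equal(r1$idi, r2$idi, tolerance = 1e-9)
})

test_that("the incremental-value chain responds to informative markers only", {
  # informative markers: positive mean delta-C
  dcs <- vapply(1:5, function(s) {
    cs <- simulate_cohort(cohort_sim_config(seed = s, n_subjects = 685,
                                            or_per_sd = c(1.5, 1.5, 1.3, 1.3)))
    co <- standardize_biomarkers(cs$cohort, paste0("bm", 1:4))
    compare_risk_models(co, "advanced", c("age", "sex"),
                        paste0("bm", 1:4, "_z"))$delta_c
  }, numeric(1))
  expect_gt(mean(dcs), 0)

  # null markers: delta-C near zero
  dcs0 <- vapply(1:5, function(s) {
    cs <- simulate_cohort(cohort_sim_config(seed = s + 50, n_subjects = 685,
                                            or_per_sd = 1))
    co <- standardize_biomarkers(cs$cohort, paste0("bm", 1:4))
    compare_risk_models(co, "advanced", c("age", "sex"),
                        paste0("bm", 1:4, "_z"))$delta_c
  }, numeric(1))
  expect_lt(mean(dcs0), mean(dcs))
  expect_lt(abs(mean(dcs0)), 0.05)
})
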