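#' Configuration for prospective-cohort simulation
#'
#' Describes a community-based cohort with correlated log-normal plasma
#' biomarkers, a logistic advanced-progression outcome whose per-1-SD-log
#' coefficients equal `log(or_per_sd)`, exponential event times with a
#' log-linear hazard in the same standardized markers censored at
#' `followup_years`, and two-visit 8-segment carotid ultrasound exams built
#' to satisfy (or not) the person-based progression rules.
#'
#' Defaults follow the validation setting: 685 subjects aged 40--79 with a
#' 10-year follow-up, four biomarkers with odds ratios on the 1.3--1.5 per
#' SD scale, an overall event rate of 91/685, advanced progression in
#' 102/560, early progression in 371/560, and half the cohort free of
#' carotid atherosclerosis at baseline.
#'
#' @param seed Integer seed.
#' @param n_subjects Cohort size (default 685).
#' @param n_biomarkers Number of plasma biomarkers.
#' @param biomarker_correlation Correlation matrix of log-biomarkers
#'   (default exchangeable with r = 0.3).
#' @param or_per_sd Odds ratios (per 1 SD of the log marker) for advanced
#'   progression; recycled to `n_biomarkers`.
#' @param hr_per_sd Hazard ratios (per 1 SD of the log marker) for incident
#'   events; recycled to `n_biomarkers`.
#' @param baseline_event_rate Target marginal probability of an event within
#'   follow-up.
#' @param followup_years Administrative censoring time (years, default 10).
#' @param measurement_error_sd Gaussian SD (mm) added to every recorded
#'   plaque thickness; 0 gives noise-free exams.
#' @param advanced_rate,early_rate,baseline_free_rate Target marginal rates
#'   of advanced progression, early progression, and baseline freedom from
#'   atherosclerosis.
#'
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(seed = 1L, n_subjects = 685L, n_biomarkers = 4L,
                              biomarker_correlation = NULL,
                              or_per_sd = c(1.3, 1.5, 1.3, 1.3),
                              hr_per_sd = 1.4,
                              baseline_event_rate = 91 / 685,
                              followup_years = 10,
                              measurement_error_sd = 0.1,
                              advanced_rate = 102 / 560,
                              early_rate = 371 / 560,
                              baseline_free_rate = 278 / 560) {
  assert_that(is_count(n_subjects, 10L), "`n_subjects` must be a count >= 10")
  assert_that(is_count(n_biomarkers, 1L), "`n_biomarkers` must be positive")
  if (is.null(biomarker_correlation)) {
    biomarker_correlation <- matrix(0.3, n_biomarkers, n_biomarkers)
    diag(biomarker_correlation) <- 1
  }
  check_correlation_matrix(biomarker_correlation)
  assert_that(nrow(biomarker_correlation) == n_biomarkers,
              "`biomarker_correlation` dimension must equal `n_biomarkers`")
  or_per_sd <- rep_len(or_per_sd, n_biomarkers)
  hr_per_sd <- rep_len(hr_per_sd, n_biomarkers)
  assert_that(all(or_per_sd > 0) && all(hr_per_sd > 0),
              "odds and hazard ratios must be positive")
  assert_that(followup_years > 0, "`followup_years` must be positive")
  assert_that(measurement_error_sd >= 0,
              "`measurement_error_sd` must be non-negative")
  structure(
    list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
         n_biomarkers = as.integer(n_biomarkers),
         biomarker_correlation = biomarker_correlation,
         or_per_sd = or_per_sd, hr_per_sd = hr_per_sd,
         baseline_event_rate = baseline_event_rate,
         followup_years = followup_years,
         measurement_error_sd = measurement_error_sd,
         advanced_rate = advanced_rate, early_rate = early_rate,
         baseline_free_rate = baseline_free_rate),
    class = "cohort_sim_config"
  )
}

# intercept so the marginal mean of plogis(alpha + lp) hits `target`
solve_logit_intercept <- function(lp, target) {
  stats::uniroot(function(a) mean(stats::plogis(a + lp)) - target,
                 lower = -30, upper = 30, tol = 1e-10)$root
}

#' Simulate a prospective cohort with ultrasound follow-up
#'
#' Generates subject demographics and vascular risk factors, correlated
#' log-normal biomarkers, the advanced- and early-progression outcomes, a
#' censored event time, and two-visit ultrasound exams constructed so that
#' subjects labelled advanced satisfy the [classify_progression()] rule
#' (one index plaque grown past the artery-specific threshold in an artery
#' reaching at least 40% narrowing) and early-progression subjects show a
#' new plaque or sub-threshold growth only.
#'
#' @param config A [cohort_sim_config()].
#' @return A list:
#' \describe{
#'   \item{cohort}{Tibble, one row per subject: demographics, risk factors,
#'     biomarkers `bm1`..`bmK`, baseline `atherosclerosis_score` (mm),
#'     `advanced`, `early`, `incipient` flags, `event_time`, `event_status`.}
#'   \item{exams}{Ultrasound exam tibble with both visits for all subjects.}
#'   \item{truth}{Tibble of true linear predictors and progression class.}
#' }
#' @export
simulate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_sim_config"),
              "`config` must be a cohort_sim_config")
  thr <- progression_thresholds()
  with_seed(config$seed, {
    n <- config$n_subjects
    k <- config$n_biomarkers
    id <- sprintf("S%04d", seq_len(n))

    age <- stats::runif(n, 40, 79)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    ldl <- stats::rnorm(n, 130, 30)
    hdl <- stats::rnorm(n, 55, 15)
    crp <- stats::rlnorm(n, 0.3, 0.9)
    diabetes <- stats::rbinom(n, 1, 0.1)
    hypertension <- stats::rbinom(n, 1, 0.5)
    pack_years <- ifelse(stats::rbinom(n, 1, 0.45) == 1,
                         stats::rgamma(n, shape = 2, scale = 10), 0)
    bmi <- stats::rnorm(n, 26, 4)

    z <- rmvnorm_chol(n, config$biomarker_correlation)
    colnames(z) <- paste0("bm", seq_len(k))
    biomarkers <- exp(log(100) + 0.5 * z)  # positive, log-SD 0.5

    # advanced progression: logistic in standardized log markers + age/sex
    lp_adv <- drop(z %*% log(config$or_per_sd)) +
      0.03 * (age - 60) + 0.2 * (sex == "male")
    a_adv <- solve_logit_intercept(lp_adv, config$advanced_rate)
    advanced <- stats::rbinom(n, 1, stats::plogis(a_adv + lp_adv)) == 1

    # early progression: driven by standard risk factors, not the markers
    lp_early <- 0.4 * scale(ldl)[, 1] + 0.5 * hypertension +
      0.3 * scale(pack_years)[, 1] + 0.02 * (age - 60)
    a_early <- solve_logit_intercept(lp_early, config$early_rate)
    early <- stats::rbinom(n, 1, stats::plogis(a_early + lp_early)) == 1

    # incident events: exponential with log-linear hazard, censored
    lp_evt <- drop(z %*% log(config$hr_per_sd)) +
      0.05 * (age - 60) + 0.3 * (sex == "male")
    l0 <- stats::uniroot(function(l) {
      mean(1 - exp(-exp(l + lp_evt) * config$followup_years)) -
        config$baseline_event_rate
    }, lower = -30, upper = 10, tol = 1e-10)$root
    t_raw <- stats::rexp(n, rate = exp(l0 + lp_evt))
    event_status <- as.integer(t_raw <= config$followup_years)
    event_time <- pmax(pmin(t_raw, config$followup_years), 1e-6)

    # baseline plaque burden: advanced subjects always carry a plaque
    free_baseline <- rep(FALSE, n)
    non_adv <- which(!advanced)
    n_free <- min(length(non_adv), round(config$baseline_free_rate * n))
    free_baseline[sample(non_adv, n_free)] <- TRUE

    ex <- build_cohort_exams(id, advanced = advanced, early = early,
                             free_baseline = free_baseline, thr = thr)
    baseline <- ex$baseline
    followup <- ex$followup
    incipient_true <- ex$incipient
    early_true <- ex$early

    if (config$measurement_error_sd > 0) {
      baseline$thickness_mm <- pmax(
        baseline$thickness_mm +
          stats::rnorm(nrow(baseline), 0, config$measurement_error_sd), 0)
      followup$thickness_mm <- pmax(
        followup$thickness_mm +
          stats::rnorm(nrow(followup), 0, config$measurement_error_sd), 0)
    }

    score <- atherosclerosis_score(baseline)
    cohort <- tibble::tibble(
      subject_id = id, age = age, sex = sex, ldl = ldl, hdl = hdl, crp = crp,
      diabetes = diabetes, hypertension = hypertension,
      pack_years = pack_years, bmi = bmi
    )
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(biomarkers))
    cohort <- cohort |>
      dplyr::left_join(dplyr::select(score, "subject_id",
                                     atherosclerosis_score = "score"),
                       by = "subject_id") |>
      dplyr::mutate(advanced = advanced, early = early_true,
                    incipient = incipient_true,
                    event_time = event_time, event_status = event_status)

    truth <- tibble::tibble(
      subject_id = id, lp_advanced = lp_adv, lp_event = lp_evt,
      advanced_true = advanced, early_true = early_true,
      incipient_true = incipient_true
    )
    list(cohort = cohort,
         exams = dplyr::bind_rows(baseline, followup),
         truth = truth)
  })
}

# ultrasound exams for the whole cohort, consistent with the truth flags;
# matrix-based (subjects x 16 sites) for speed at cohort scale
build_cohort_exams <- function(id, advanced, early, free_baseline, thr) {
  tmpl <- blank_exam("x", "baseline")
  side16 <- tmpl$side
  seg16 <- tmpl$segment
  art16 <- paste(side16, segment_artery(seg16))  # 4 distinct arteries
  art_levels <- unique(art16)
  art_idx <- match(art16, art_levels)
  n <- length(id)

  thick_b <- matrix(0, n, 16L)
  narrow_b <- matrix(0, n, 4L)
  has_plaque <- advanced | !free_baseline
  incipient <- logical(n)
  early_done <- logical(n)

  for (i in seq_len(n)) {
    if (has_plaque[i]) {
      np <- min(1L + stats::rpois(1, 1.2), 16L)
      sites <- sample.int(16L, np)
      thick_b[i, sites] <- stats::runif(np, 0.6, 3)
      arts <- unique(art_idx[sites])
      narrow_b[i, arts] <- stats::runif(length(arts), 5, 35)
    }
  }
  thick_f <- thick_b
  narrow_f <- narrow_b

  for (i in seq_len(n)) {
    if (advanced[i]) {
      plaque_sites <- which(thick_b[i, ] >= thr$plaque_min)
      idx <- if (length(plaque_sites) == 1L) plaque_sites else
        sample(plaque_sites, 1L)
      a <- art_idx[idx]
      grow_thr <- if (grepl("ica", art_levels[a])) thr$ica else thr$cca
      rel <- grow_thr * stats::runif(1, 1.3, 2.0)
      thick_f[i, idx] <- thick_b[i, idx] * (1 + rel / 100)
      narrow_f[i, a] <- stats::runif(1, 45, 75)
    }
    if (early[i]) {
      if (!has_plaque[i]) {
        # incipient: first plaque in a subject free of atherosclerosis
        site <- sample.int(16L, 1L)
        thick_f[i, site] <- stats::runif(1, 0.6, 1.2)
        incipient[i] <- TRUE
        early_done[i] <- TRUE
      } else {
        # sub-threshold (non-stenotic) growth of an existing plaque in an
        # artery below the 40% narrowing limit; otherwise a new plaque
        cand <- which(thick_b[i, ] >= thr$plaque_min &
                        narrow_f[i, art_idx] < thr$narrowing &
                        thick_f[i, ] == thick_b[i, ])
        free_sites <- which(thick_b[i, ] < thr$plaque_min)
        if (stats::runif(1) >= 0.5 && length(cand) > 0) {
          site <- if (length(cand) == 1L) cand else sample(cand, 1L)
          a <- art_idx[site]
          grow_thr <- if (grepl("ica", art_levels[a])) thr$ica else thr$cca
          rel <- grow_thr * stats::runif(1, 0.2, 0.8)
          thick_f[i, site] <- thick_b[i, site] * (1 + rel / 100)
          early_done[i] <- TRUE
        } else if (length(free_sites) > 0) {
          site <- if (length(free_sites) == 1L) free_sites else
            sample(free_sites, 1L)
          thick_f[i, site] <- stats::runif(1, 0.6, 1.2)
          early_done[i] <- TRUE
        }
      }
    }
  }

  long_exam <- function(visit, thick, narrow) {
    tibble::tibble(
      subject_id = rep(id, each = 16L),
      visit = visit,
      side = rep(side16, n),
      segment = rep(seg16, n),
      wall = rep(tmpl$wall, n),
      thickness_mm = as.vector(t(thick)),
      narrowing_pct = as.vector(t(narrow[, art_idx, drop = FALSE]))
    )
  }
  list(baseline = long_exam("baseline", thick_b, narrow_b),
       followup = long_exam("followup", thick_f, narrow_f),
       incipient = incipient, early = early_done)
}

#' Draw a case-cohort sample
#'
#' Random subcohort without replacement plus every subject with an event,
#' retaining membership flags for Prentice weighting.
#'
#' @param cohort Cohort tibble with `event_status` (0/1).
#' @param subcohort_size Size of the random subcohort (positive, at most the
#'   cohort size).
#' @param seed Integer seed.
#' @return The sampled rows of `cohort` with logical columns `subcohort`
#'   and `case` added.
#' @export
draw_case_cohort <- function(cohort, subcohort_size, seed = 1L) {
  assert_that("event_status" %in% names(cohort),
              "`cohort` must contain `event_status`")
  if (!is_count(subcohort_size, 1L)) {
    plaq_abort("`subcohort_size` must be a positive count")
  }
  n <- nrow(cohort)
  assert_that(subcohort_size <= n,
              "`subcohort_size` cannot exceed the cohort size")
  with_seed(seed, {
    in_sub <- seq_len(n) %in% sample.int(n, subcohort_size)
    keep <- in_sub | cohort$event_status == 1
    out <- cohort[keep, , drop = FALSE]
    out$subcohort <- in_sub[keep]
    out$case <- out$event_status == 1
    out
  })
}
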