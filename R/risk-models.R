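#' Standardize a biomarker to 1-SD units on the natural-log scale
#'
#' \eqn{z = (\ln x - mean(\ln x)) / SD(\ln x)}, the scale on which odds and
#' hazard ratios "per 1-SD higher log level" are expressed. The transform
#' parameters are stored (and reusable via `center`/`scale`) so new samples
#' can be placed on the same scale.
#'
#' @param values Positive numeric vector.
#' @param center,scale Optional stored log-mean and log-SD from a previous
#'   call.
#' @return Numeric z-scores with attributes `log_mean` and `log_sd`.
#' @export
standardize_biomarker <- function(values, center = NULL, scale = NULL) {
  assert_that(is.numeric(values) && length(values) > 0,
              "`values` must be a non-empty numeric vector")
  if (any(values <= 0, na.rm = TRUE)) {
    plaq_abort("biomarker values must be positive (log-transform undefined)")
  }
  lx <- log(values)
  m <- center %||% mean(lx, na.rm = TRUE)
  s <- scale %||% stats::sd(lx, na.rm = TRUE)
  if (!is.finite(s) || s == 0) plaq_abort("zero variance on the log scale")
  structure((lx - m) / s, log_mean = m, log_sd = s)
}

#' Add standardized log-biomarker columns to a cohort table
#'
#' @param data Cohort tibble.
#' @param cols Character vector of biomarker column names.
#' @param suffix Suffix for the new columns (default `"_z"`).
#' @return `data` with one standardized column per biomarker appended.
#' @export
standardize_biomarkers <- function(data, cols, suffix = "_z") {
  for (cl in cols) {
    data[[paste0(cl, suffix)]] <- as.numeric(standardize_biomarker(data[[cl]]))
  }
  data
}

new_risk_model <- function(fit, type, terms, outcome, data_used) {
  n_used <- if (!is.null(fit$n)) fit$n else stats::nobs(fit)
  structure(list(fit = fit, type = type, terms = terms, outcome = outcome,
                 n_used = n_used, data = data_used),
            class = "risk_model")
}

#' Unconditional logistic regression for a binary outcome
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' [stats::glm()]) with Wald confidence intervals; with standardized log
#' biomarkers among the terms, the exponentiated coefficients are odds
#' ratios per 1 SD. Complete-case analysis; non-convergence and apparent
#' separation are reported as errors rather than silently clipped.
#'
#' @param data Cohort tibble.
#' @param outcome Name of a binary (0/1 or logical) outcome column.
#' @param terms Character vector of predictor column names.
#' @return Object of class `risk_model` (type `"logistic"`); see
#'   [tidy.risk_model()].
#' @export
fit_logistic <- function(data, outcome, terms) {
  assert_that(outcome %in% names(data), "unknown outcome column")
  assert_that(all(terms %in% names(data)),
              paste("unknown terms:",
                    paste(setdiff(terms, names(data)), collapse = ", ")))
  use <- stats::complete.cases(data[c(outcome, terms)])
  d <- data[use, , drop = FALSE]
  y <- as.integer(as.logical(d[[outcome]]))
  assert_that(length(unique(y)) == 2L,
              "outcome must have both classes present")
  f <- stats::reformulate(terms, response = outcome)
  d[[outcome]] <- y
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged ||
      (separated && any(abs(stats::coef(fit)[-1]) > 5, na.rm = TRUE)) ||
      any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
    plaq_abort("apparent separation: logistic estimates unbounded",
               class = "plaqomics_separation")
  }
  qr_rank <- fit$rank
  if (qr_rank < length(stats::coef(fit))) {
    plaq_abort("rank-deficient design matrix")
  }
  new_risk_model(fit, "logistic", terms, outcome, d)
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling via
#' [survival::coxph()]; optional robust (sandwich) standard errors and
#' per-subject, time-fixed weights.
#'
#' @param data Cohort tibble with `event_time` (> 0) and `event_status`
#'   (0/1) columns (names configurable).
#' @param terms Character vector of predictor column names.
#' @param robust Use robust standard errors.
#' @param weights Optional per-subject weight vector (aligned to `data`).
#' @param time_col,status_col Column names of the survival outcome.
#' @return Object of class `risk_model` (type `"cox"`).
#' @export
fit_cox <- function(data, terms, robust = FALSE, weights = NULL,
                    time_col = "event_time", status_col = "event_status") {
  assert_that(all(c(time_col, status_col) %in% names(data)),
              "survival outcome columns not found")
  if (any(data[[time_col]] <= 0, na.rm = TRUE)) {
    plaq_abort("non-positive event time")
  }
  if (sum(data[[status_col]], na.rm = TRUE) < 1) {
    plaq_abort("no events in the data")
  }
  use <- stats::complete.cases(data[c(time_col, status_col, terms)])
  d <- data[use, , drop = FALSE]
  if (!is.null(weights)) d$.w <- weights[use]
  f <- stats::as.formula(paste0("survival::Surv(", time_col, ", ",
                                status_col, ") ~ ",
                                paste(terms, collapse = " + ")))
  fit <- if (is.null(weights)) {
    survival::coxph(f, data = d, ties = "efron", robust = robust, x = TRUE)
  } else {
    survival::coxph(f, data = d, ties = "efron", robust = robust,
                    weights = d$.w, x = TRUE)
  }
  m <- new_risk_model(fit, "cox", terms, paste0("Surv(", time_col, ", ",
                                                status_col, ")"), d)
  m$time_col <- time_col
  m$status_col <- status_col
  m
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s model, %d terms, n = %d\n", x$type,
              length(x$terms), x$n_used))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted risk model
#'
#' @param x A `risk_model`.
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (log scale), `std_error` (robust when
#'   requested at fit time), `ratio` (odds or hazard ratio), `conf_low`,
#'   `conf_high` (on the ratio scale), `p_value`.
#' @export
tidy.risk_model <- function(x, conf_level = 0.95, ...) {
  sm <- summary(x$fit)
  co <- sm$coefficients
  if (x$type == "logistic") {
    est <- co[, "Estimate"]
    se <- co[, "Std. Error"]
    p <- co[, "Pr(>|z|)"]
  } else {
    se_col <- if ("robust se" %in% colnames(co)) "robust se" else "se(coef)"
    est <- co[, "coef"]
    se <- co[, se_col]
    p <- co[, ncol(co)]
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = rownames(co), estimate = unname(est), std_error = unname(se),
    ratio = exp(unname(est)),
    conf_low = exp(unname(est) - zq * unname(se)),
    conf_high = exp(unname(est) + zq * unname(se)),
    p_value = unname(p)
  )
}

#' @export
glance.risk_model <- function(x, ...) {
  ll <- as.numeric(stats::logLik(x$fit))
  tibble::tibble(type = x$type, n_used = x$n_used,
                 n_terms = length(x$terms), log_likelihood = ll)
}

lrt_p <- function(fit0, fit1) {
  ll0 <- as.numeric(stats::logLik(fit0$fit))
  ll1 <- as.numeric(stats::logLik(fit1$fit))
  df <- length(stats::coef(fit1$fit)) - length(stats::coef(fit0$fit))
  if (df <= 0) return(NA_real_)
  stats::pchisq(2 * (ll1 - ll0), df = df, lower.tail = FALSE)
}

fit_generic <- function(data, outcome, terms, type) {
  if (type == "logistic") {
    if (length(terms) == 0) {
      # intercept-only fit via glm directly
      use <- stats::complete.cases(data[outcome])
      d <- data[use, , drop = FALSE]
      d[[outcome]] <- as.integer(as.logical(d[[outcome]]))
      fit <- stats::glm(stats::reformulate("1", response = outcome),
                        data = d, family = stats::binomial())
      return(new_risk_model(fit, "logistic", character(), outcome, d))
    }
    fit_logistic(data, outcome, terms)
  } else {
    if (length(terms) == 0) plaq_abort("Cox model needs at least one term")
    fit_cox(data, terms)
  }
}

#' Forward-stepwise biomarker signature selection
#'
#' Iteratively adds the candidate with the smallest likelihood-ratio
#' p-value below `p_enter`; after each addition, re-tests the included
#' candidates and removes any whose removal p-value exceeds `p_remove`
#' (standard inclusion/exclusion criteria). Forced terms are always kept.
#' Ties break deterministically by candidate order; candidates whose
#' submodel fails to converge are skipped and logged in the path.
#'
#' @param data Cohort tibble.
#' @param outcome Binary outcome column (logistic) — ignored for
#'   `type = "cox"`, which uses `event_time`/`event_status`.
#' @param candidate_terms Candidate predictor columns (disjoint from
#'   `forced_terms`).
#' @param forced_terms Terms always included (e.g. age, sex).
#' @param p_enter,p_remove Entry and removal thresholds (defaults 0.05 and
#'   0.10).
#' @param type `"logistic"` or `"cox"`.
#' @return Object of class `stepwise_result`: list with `selected` (the
#'   chosen candidates in entry order), `model` (final `risk_model`), and
#'   `path` (tibble log of every add/drop/skip decision).
#' @export
forward_stepwise <- function(data, outcome, candidate_terms,
                             forced_terms = character(),
                             p_enter = 0.05, p_remove = 0.10,
                             type = c("logistic", "cox")) {
  type <- match.arg(type)
  assert_that(length(intersect(candidate_terms, forced_terms)) == 0,
              "candidates must be disjoint from forced terms")
  outcome_cols <- if (type == "logistic") outcome else
    c("event_time", "event_status")
  use <- stats::complete.cases(
    data[c(outcome_cols, forced_terms, candidate_terms)])
  d <- data[use, , drop = FALSE]

  selected <- character()
  path <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    base_fit <- tryCatch(
      fit_generic(d, outcome, c(forced_terms, selected), type),
      error = function(e) NULL)
    if (is.null(base_fit)) plaq_abort("base model failed to converge")
    remaining <- setdiff(candidate_terms, selected)
    if (length(remaining) == 0) break
    p_add <- vapply(remaining, function(tm) {
      fit1 <- tryCatch(
        fit_generic(d, outcome, c(forced_terms, selected, tm), type),
        error = function(e) NULL)
      if (is.null(fit1)) return(NA_real_)
      lrt_p(base_fit, fit1)
    }, numeric(1))
    skipped <- remaining[is.na(p_add)]
    for (tm in skipped) {
      path[[length(path) + 1L]] <- tibble::tibble(
        step = step, action = "skip", term = tm, p = NA_real_)
    }
    ok <- !is.na(p_add)
    if (!any(ok) || min(p_add[ok]) >= p_enter) break
    best <- remaining[ok][which.min(p_add[ok])]  # ties -> candidate order
    selected <- c(selected, best)
    path[[length(path) + 1L]] <- tibble::tibble(
      step = step, action = "add", term = best, p = min(p_add[ok]))
    # backward pass over included candidates
    repeat {
      if (length(selected) == 0) break
      full_fit <- fit_generic(d, outcome, c(forced_terms, selected), type)
      p_drop <- vapply(selected, function(tm) {
        fit0 <- tryCatch(
          fit_generic(d, outcome,
                      c(forced_terms, setdiff(selected, tm)), type),
          error = function(e) NULL)
        if (is.null(fit0)) return(NA_real_)
        lrt_p(fit0, full_fit)
      }, numeric(1))
      worst <- which.max(p_drop)
      if (length(worst) == 0 || is.na(p_drop[worst]) ||
          p_drop[worst] <= p_remove) break
      dropped <- selected[worst]
      selected <- setdiff(selected, dropped)
      path[[length(path) + 1L]] <- tibble::tibble(
        step = step, action = "drop", term = dropped, p = p_drop[worst])
    }
  }
  final <- fit_generic(d, outcome, c(forced_terms, selected), type)
  structure(
    list(selected = selected, forced = forced_terms, model = final,
         path = dplyr::bind_rows(path)),
    class = "stepwise_result"
  )
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("<stepwise_result> selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else
        "(forced terms only)", "\n")
  invisible(x)
}

#' Prentice-weighted case-cohort Cox regression
#'
#' Case-cohort partial likelihood with Prentice weighting: subcohort
#' members are at risk from time zero; cases outside the subcohort enter
#' the risk set just before their own event. Implemented as a
#' counting-process Cox model with robust (sandwich) standard errors
#' clustered on subject, which are mandatory for this design.
#'
#' @param sample Case-cohort tibble from [draw_case_cohort()] (columns
#'   `subcohort`, `event_time`, `event_status` plus predictors).
#' @param terms Predictor column names.
#' @return Object of class `risk_model` (type `"cox"`, robust SEs).
#' @export
prentice_case_cohort <- function(sample, terms) {
  assert_that("subcohort" %in% names(sample),
              "`sample` must carry a `subcohort` flag")
  if (!any(sample$subcohort)) plaq_abort("empty subcohort")
  assert_that(all(sample$event_status %in% c(0, 1)),
              "`event_status` must be 0/1")
  if (any(!sample$subcohort & sample$event_status == 0)) {
    plaq_abort("non-subcohort members without events cannot appear in a case-cohort sample")
  }
  d <- sample
  d$.id <- seq_len(nrow(d))
  gaps <- diff(sort(unique(d$event_time)))
  eps <- if (length(gaps)) min(gaps) / 100 else min(d$event_time) / 100
  d$.start <- ifelse(d$subcohort, 0, d$event_time - eps)
  f <- stats::as.formula(paste0(
    "survival::Surv(.start, event_time, event_status) ~ ",
    paste(terms, collapse = " + ")))
  fit <- survival::coxph(f, data = d, ties = "efron", robust = TRUE,
                         cluster = .id, x = TRUE,
                         control = survival::coxph.control(timefix = FALSE))
  m <- new_risk_model(fit, "cox", terms, "Surv(event_time, event_status)", d)
  m$time_col <- "event_time"
  m$status_col <- "event_status"
  m
}

#' Proportional-hazards check via Schoenfeld residuals
#'
#' Per-term test of the scaled Schoenfeld residuals against event time
#' (via [survival::cox.zph()] with the identity time transform), plus the
#' Pearson correlation of residuals with event time for each term.
#'
#' @param model A `risk_model` of type `"cox"`.
#' @return Tibble: `term`, `rho` (correlation with time; `NA` for the
#'   global row), `chisq`, `df`, `p_value`; attribute `violation` flags
#'   any per-term p below 0.05.
#' @export
schoenfeld_check <- function(model) {
  assert_that(inherits(model, "risk_model") && model$type == "cox",
              "`model` must be a fitted Cox risk_model")
  n_events <- sum(model$data[[model$status_col]])
  if (n_events < 3) plaq_abort("need at least 3 events for the Schoenfeld check")
  zph <- survival::cox.zph(model$fit, transform = "identity")
  sch <- stats::resid(model$fit, type = "scaledsch")
  sch <- as.matrix(sch)
  times <- as.numeric(rownames(sch) %||% zph$time)
  if (length(times) != nrow(sch)) times <- zph$time
  rho <- apply(sch, 2, function(col) stats::cor(times, col))
  tab <- zph$table
  terms <- rownames(tab)
  out <- tibble::tibble(
    term = terms,
    rho = c(rho, rep(NA_real_, length(terms) - length(rho))),
    chisq = tab[, "chisq"],
    df = tab[, "df"],
    p_value = tab[, "p"]
  )
  per_term <- out$term != "GLOBAL"
  structure(out, violation = any(out$p_value[per_term] < 0.05))
}
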