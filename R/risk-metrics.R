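# pairwise concordance bookkeeping shared by the C-statistic and its
# jackknife: returns total credit W, usable pairs P, and per-subject sums
concordance_parts <- function(predictions, outcomes, survival = FALSE,
                              times = NULL, status = NULL) {
  n <- length(predictions)
  w_i <- numeric(n)
  p_i <- numeric(n)
  total_w <- 0
  total_p <- 0
  if (!survival) {
    cases <- which(outcomes == 1)
    ctrls <- which(outcomes == 0)
    if (length(cases) == 0 || length(ctrls) == 0) {
      plaq_abort("need at least one case and one non-case")
    }
    pc <- predictions[cases]
    pn <- predictions[ctrls]
    cmp <- outer(pc, pn, function(a, b) (a > b) + 0.5 * (a == b))
    total_w <- sum(cmp)
    total_p <- length(pc) * length(pn)
    w_i[cases] <- rowSums(cmp)
    w_i[ctrls] <- colSums(cmp)
    p_i[cases] <- length(pn)
    p_i[ctrls] <- length(pc)
  } else {
    assert_that(!is.null(times) && !is.null(status),
                "survival concordance needs `times` and `status`")
    # usable pair (i, j): subject i fails strictly before time_j
    ev <- which(status == 1)
    if (length(ev) == 0) plaq_abort("no usable pairs (no events)")
    usable <- outer(times[ev], times, "<")          # i event, t_i < t_j
    credit <- outer(predictions[ev], predictions,
                    function(a, b) (a > b) + 0.5 * (a == b)) * usable
    total_w <- sum(credit)
    total_p <- sum(usable)
    if (total_p == 0) plaq_abort("no usable pairs")
    w_i[ev] <- w_i[ev] + rowSums(credit)
    p_i[ev] <- p_i[ev] + rowSums(usable)
    w_i <- w_i + colSums(credit)
    p_i <- p_i + colSums(usable)
  }
  list(W = total_w, P = total_p, w_i = w_i, p_i = p_i, n = n)
}

#' C-statistic / Harrell's C-index with jackknife standard error
#'
#' Binary outcomes: concordance over all case/non-case pairs with half
#' credit for tied predictions (the probability that a randomly chosen
#' case is ranked above a randomly chosen non-case). Survival outcomes:
#' Harrell's C over usable pairs — subject i failing strictly earlier than
#' subject j is still under observation (event or censoring later). The
#' standard error is the leave-one-subject-out jackknife.
#'
#' @param predictions Numeric risk scores (higher = higher risk).
#' @param outcomes Binary outcome vector (ignored when `survival = TRUE`
#'   and `status` given).
#' @param survival Treat the outcome as time-to-event.
#' @param times Event/censoring times (survival only).
#' @param status Event indicator 0/1 (survival only; defaults to
#'   `outcomes`).
#' @return One-row tibble of class `discrimination_result`: `c_statistic`,
#'   `se_jackknife`, `n`, `n_pairs`; attribute `loo` holds the
#'   leave-one-out values for paired comparisons.
#' @export
c_statistic <- function(predictions, outcomes = NULL, survival = FALSE,
                        times = NULL, status = NULL) {
  if (survival && is.null(status)) status <- outcomes
  parts <- concordance_parts(predictions, outcomes, survival, times, status)
  c_hat <- parts$W / parts$P
  loo <- (parts$W - parts$w_i) / (parts$P - parts$p_i)
  loo[!is.finite(loo)] <- c_hat  # subject involved in every usable pair
  n <- parts$n
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  out <- tibble::tibble(c_statistic = c_hat, se_jackknife = se,
                        n = n, n_pairs = parts$P)
  structure(out, class = c("discrimination_result", class(out)), loo = loo)
}

# DeLong structural components: V10 per case, V01 per control
delong_components <- function(predictions, outcomes) {
  cases <- predictions[outcomes == 1]
  ctrls <- predictions[outcomes == 0]
  assert_that(length(cases) > 0 && length(ctrls) > 0,
              "need both outcome classes")
  psi <- outer(cases, ctrls, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong comparison of two correlated AUCs
#'
#' Paired comparison of the areas under the ROC curves of two models
#' evaluated on the same subjects, using DeLong's structural components to
#' estimate the variance of the AUC difference; two-sided p-value from the
#' normal reference. Identical predictions give a difference of 0 with
#' p = 1.
#'
#' @param pred_model1,pred_model2 Risk scores from the two models for the
#'   same subjects.
#' @param outcomes Binary outcome vector.
#' @return One-row tibble: `auc_1`, `auc_2`, `delta_auc`, `se`, `z`,
#'   `p_value`.
#' @export
delong_compare <- function(pred_model1, pred_model2, outcomes) {
  assert_that(length(pred_model1) == length(pred_model2) &&
                length(pred_model1) == length(outcomes),
              "inputs must have equal length")
  c1 <- delong_components(pred_model1, outcomes)
  c2 <- delong_components(pred_model2, outcomes)
  m <- length(c1$v10)
  n <- length(c1$v01)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  var_d <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- c1$auc - c2$auc
  if (var_d <= 0 || !is.finite(var_d)) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_d)
  }
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(auc_1 = c1$auc, auc_2 = c2$auc, delta_auc = d,
                 se = sqrt(max(var_d, 0)), z = z, p_value = p)
}

risk_category <- function(p, cuts) {
  # left-closed intervals [0, c1), [c1, c2), [c2, 1]
  findInterval(p, c(cuts, Inf), left.open = FALSE)
}

#' Net reclassification improvement
#'
#' Categorical NRI over the 10-year risk categories (defaults <5%,
#' 5 to <7.5%, and at least 7.5%; intervals closed on the left):
#' \deqn{NRI = [P(up|event) - P(down|event)] +
#'   [P(down|nonevent) - P(up|nonevent)].}
#' The continuous NRI uses the same formula with "up" meaning any increase
#' in predicted risk.
#'
#' @param pred_old,pred_new Predicted risks in \[0, 1\] under the old and
#'   new model.
#' @param outcomes Binary outcome vector.
#' @param categories Risk cut-points for the categorical variant (default
#'   `c(0.05, 0.075)`); `NULL` computes the continuous variant only.
#' @return Tibble with one row per variant: `type`
#'   (`"categorical"`/`"continuous"`), `nri`, `nri_event`, `nri_nonevent`,
#'   `p_up_event`, `p_down_event`, `p_up_nonevent`, `p_down_nonevent`.
#' @export
nri <- function(pred_old, pred_new, outcomes, categories = c(0.05, 0.075)) {
  assert_that(all(pred_old >= 0 & pred_old <= 1) &&
                all(pred_new >= 0 & pred_new <= 1),
              "predictions must be risks in [0, 1]")
  ev <- outcomes == 1
  if (!any(ev) || all(ev)) plaq_abort("need both events and non-events")
  one_variant <- function(up, down, type) {
    tibble::tibble(
      type = type,
      nri = (mean(up[ev]) - mean(down[ev])) +
        (mean(down[!ev]) - mean(up[!ev])),
      nri_event = mean(up[ev]) - mean(down[ev]),
      nri_nonevent = mean(down[!ev]) - mean(up[!ev]),
      p_up_event = mean(up[ev]), p_down_event = mean(down[ev]),
      p_up_nonevent = mean(up[!ev]), p_down_nonevent = mean(down[!ev])
    )
  }
  out <- list()
  if (!is.null(categories)) {
    old_cat <- risk_category(pred_old, categories)
    new_cat <- risk_category(pred_new, categories)
    out$cat <- one_variant(new_cat > old_cat, new_cat < old_cat,
                           "categorical")
  }
  out$cont <- one_variant(pred_new > pred_old, pred_new < pred_old,
                          "continuous")
  dplyr::bind_rows(out)
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slopes of the two models:
#' \deqn{IDI = [\bar p_{new|event} - \bar p_{new|nonevent}] -
#'   [\bar p_{old|event} - \bar p_{old|nonevent}],}
#' equivalently the NRI integrated over all possible risk cut-offs.
#'
#' @inheritParams nri
#' @return One-row tibble: `idi`, `slope_new`, `slope_old`.
#' @export
idi <- function(pred_old, pred_new, outcomes) {
  ev <- outcomes == 1
  if (!any(ev) || all(ev)) plaq_abort("need both events and non-events")
  slope_new <- mean(pred_new[ev]) - mean(pred_new[!ev])
  slope_old <- mean(pred_old[ev]) - mean(pred_old[!ev])
  tibble::tibble(idi = slope_new - slope_old, slope_new = slope_new,
                 slope_old = slope_old)
}

#' Predicted risks from a fitted risk model
#'
#' Logistic models return fitted probabilities. Cox models return the
#' `horizon`-year absolute risk `1 - exp(-H0(h) exp(lp))` using the
#' Breslow estimator of the baseline cumulative hazard.
#'
#' @param model A `risk_model`.
#' @param newdata Optional data to predict on (default: the fitting data).
#' @param horizon Prediction horizon in the time units of the Cox fit
#'   (default 10).
#' @return Numeric vector of predicted risks in \[0, 1\].
#' @export
predict_risk <- function(model, newdata = NULL, horizon = 10) {
  assert_that(inherits(model, "risk_model"), "`model` must be a risk_model")
  d <- newdata %||% model$data
  if (model$type == "logistic") {
    return(unname(stats::predict(model$fit, newdata = d,
                                 type = "response")))
  }
  bh <- survival::basehaz(model$fit, centered = FALSE)
  h0 <- if (any(bh$time <= horizon)) {
    max(bh$hazard[bh$time <= horizon])
  } else {
    0
  }
  lp <- stats::predict(model$fit, newdata = d, type = "lp",
                       reference = "zero")
  unname(1 - exp(-h0 * exp(lp)))
}

#' Incremental value of added biomarkers over a base risk model
#'
#' Fits the base and extended models on the same complete cases, derives
#' predicted risks (fitted probabilities for logistic models; `horizon`-
#' year Breslow risks for Cox models), and quantifies the increment:
#' change in the C-statistic / Harrell's C-index with a jackknife standard
#' error of the paired difference, the DeLong test (binary outcomes only;
#' for survival the jackknife z-test is reported instead), categorical and
#' continuous NRI, and IDI.
#'
#' @param data Cohort tibble.
#' @param outcome Binary outcome column (logistic) or `NULL` for Cox.
#' @param base_terms,added_terms Predictor columns of the base model and
#'   the additional markers.
#' @param type `"logistic"` or `"cox"`.
#' @param horizon Risk horizon for Cox models (years).
#' @param categories NRI risk cut-points.
#' @return Object of class `reclassification_result`: one-row tibble with
#'   `c_base`, `c_new`, `delta_c`, `delta_c_se` (jackknife), `delta_c_p`,
#'   `delong_p` (`NA` for survival), `nri_categorical`, `nri_continuous`,
#'   `idi`, `n`, `n_events`; attributes `nri` (component table), `models`.
#' @export
compare_risk_models <- function(data, outcome, base_terms, added_terms,
                                type = c("logistic", "cox"), horizon = 10,
                                categories = c(0.05, 0.075)) {
  type <- match.arg(type)
  outcome_cols <- if (type == "logistic") outcome else
    c("event_time", "event_status")
  use <- stats::complete.cases(data[c(outcome_cols, base_terms, added_terms)])
  d <- data[use, , drop = FALSE]
  m0 <- fit_generic(d, outcome, base_terms, type)
  m1 <- fit_generic(d, outcome, c(base_terms, added_terms), type)
  p0 <- predict_risk(m0, newdata = d, horizon = horizon)
  p1 <- predict_risk(m1, newdata = d, horizon = horizon)
  if (type == "logistic") {
    y <- as.integer(as.logical(d[[outcome]]))
    c0 <- c_statistic(p0, y)
    c1 <- c_statistic(p1, y)
    dl <- delong_compare(p1, p0, y)$p_value
    n_events <- sum(y)
  } else {
    y <- d$event_status
    c0 <- c_statistic(p0, survival = TRUE, times = d$event_time, status = y)
    c1 <- c_statistic(p1, survival = TRUE, times = d$event_time, status = y)
    dl <- NA_real_
    n_events <- sum(y)
  }
  loo_d <- attr(c1, "loo") - attr(c0, "loo")
  n <- nrow(d)
  dc <- c1$c_statistic - c0$c_statistic
  dc_se <- sqrt((n - 1) / n * sum((loo_d - mean(loo_d))^2))
  dc_p <- if (dc_se > 0) 2 * stats::pnorm(-abs(dc / dc_se)) else
    as.numeric(dc == 0)
  nri_tab <- nri(p0, p1, y, categories = categories)
  idi_tab <- idi(p0, p1, y)
  out <- tibble::tibble(
    c_base = c0$c_statistic, c_new = c1$c_statistic,
    delta_c = dc, delta_c_se = dc_se, delta_c_p = dc_p, delong_p = dl,
    nri_categorical = nri_tab$nri[nri_tab$type == "categorical"][1],
    nri_continuous = nri_tab$nri[nri_tab$type == "continuous"][1],
    idi = idi_tab$idi, n = n, n_events = n_events
  )
  structure(out, class = c("reclassification_result", class(out)),
            nri = nri_tab, idi = idi_tab, models = list(base = m0, new = m1))
}

#' @export
autoplot.reclassification_result <- function(object, ...) {
  models <- attr(object, "models")
  d <- models$new$data
  p0 <- predict_risk(models$base, newdata = d)
  p1 <- predict_risk(models$new, newdata = d)
  y <- if (models$new$type == "logistic") {
    as.logical(d[[models$new$outcome]])
  } else {
    d$event_status == 1
  }
  df <- tibble::tibble(old = p0, new = p1,
                       outcome = ifelse(y, "event", "no event"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$old, y = .data$new,
                                   colour = .data$outcome)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "predicted risk, base model",
                  y = "predicted risk, extended model",
                  title = "Risk reclassification") +
    ggplot2::theme_minimal()
}
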