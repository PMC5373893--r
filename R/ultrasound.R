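#' Progression-rule constants
#'
#' Fixed constants of the person-based carotid atherosclerosis progression
#' model: the relative-increase thresholds corresponding to twice the
#' sonographic measurement error (internal carotid artery 24.8%, common
#' carotid artery 17%), the lumen-narrowing requirement for advanced
#' progression (40%), and the minimum wall widening that defines a plaque
#' (0.5 mm). Override only deliberately.
#'
#' @param ica,cca Relative plaque-thickness increase thresholds (percent).
#' @param narrowing Minimum lumen narrowing (percent) for the advanced rule.
#' @param plaque_min Minimum plaque thickness (mm).
#' @return A named list of class `progression_thresholds`.
#' @export
progression_thresholds <- function(ica = 24.8, cca = 17,
                                   narrowing = 40, plaque_min = 0.5) {
  structure(list(ica = ica, cca = cca, narrowing = narrowing,
                 plaque_min = plaque_min),
            class = "progression_thresholds")
}

exam_sides <- c("left", "right")
exam_segments <- c("prox_cca", "dist_cca", "prox_ica", "dist_ica")
exam_walls <- c("near", "far")

#' Build an empty (plaque-free) ultrasound exam
#'
#' One row per side x segment x wall combination (16 rows): the four scanned
#' segments of each carotid artery (proximal/distal common and internal
#' carotid) with near- and far-wall maximum axial plaque thickness, plus the
#' per-artery maximum lumen narrowing.
#'
#' @param subject_id Subject identifier.
#' @param visit `"baseline"` or `"followup"`.
#' @return A tibble with columns `subject_id`, `visit`, `side`, `segment`,
#'   `wall`, `thickness_mm` (all 0), `narrowing_pct` (all 0).
#' @export
blank_exam <- function(subject_id, visit = "baseline") {
  assert_that(length(subject_id) == 1L, "one subject per call")
  tibble::tibble(
    subject_id = subject_id, visit = visit,
    side = rep(exam_sides, each = 8L),
    segment = rep(rep(exam_segments, each = 2L), times = 2L),
    wall = rep(exam_walls, times = 8L),
    thickness_mm = 0, narrowing_pct = 0
  )
}

segment_artery <- function(segment) {
  ifelse(grepl("ica$", segment), "ica", "cca")
}

validate_exam <- function(exam) {
  needed <- c("subject_id", "visit", "side", "segment", "wall",
              "thickness_mm", "narrowing_pct")
  assert_that(all(needed %in% names(exam)),
              paste("exam is missing columns:",
                    paste(setdiff(needed, names(exam)), collapse = ", ")))
  if (any(exam$thickness_mm < 0)) plaq_abort("negative plaque thickness")
  if (any(exam$narrowing_pct < 0 | exam$narrowing_pct > 100)) {
    plaq_abort("lumen narrowing must be within [0, 100] percent")
  }
  n_sites <- exam |>
    dplyr::distinct(.data$subject_id, .data$visit, .data$side,
                    .data$segment, .data$wall) |>
    dplyr::count(.data$subject_id, .data$visit)
  if (any(n_sites$n != 16L)) {
    plaq_abort("each exam must cover exactly 8 segments x 2 walls (16 sites)")
  }
  invisible(exam)
}

#' Carotid atherosclerosis score
#'
#' Sums the maximum axial plaque thickness (mm) on the near and far wall of
#' each of the 8 carotid segments. Only sites qualifying as plaque
#' (thickness of at least `thresholds$plaque_min`, default 0.5 mm)
#' contribute.
#'
#' @param exam Exam tibble as produced by [blank_exam()] /
#'   [simulate_cohort()]; may contain several subjects and visits.
#' @param thresholds A [progression_thresholds()] list.
#' @return Tibble with one row per subject x visit: `subject_id`, `visit`,
#'   `score` (mm).
#' @export
#' @examples
#' e <- blank_exam("s1")
#' e$thickness_mm[e$side == "right" & e$segment == "prox_ica" &
#'                e$wall == "far"] <- 1.2
#' atherosclerosis_score(e)$score
atherosclerosis_score <- function(exam, thresholds = progression_thresholds()) {
  validate_exam(exam)
  exam |>
    dplyr::group_by(.data$subject_id, .data$visit) |>
    dplyr::summarise(
      score = sum(.data$thickness_mm[
        .data$thickness_mm >= thresholds$plaque_min]),
      .groups = "drop"
    )
}


#' Classify atherosclerosis progression between two ultrasound visits
#'
#' Implements the person-based progression model. *Advanced complicated
#' atherogenesis*: the relative increase of an existing plaque's maximum
#' axial thickness exceeds the artery-specific threshold (twice the
#' measurement error: ICA 24.8%, CCA 17%) **and** the same artery reaches a
#' follow-up lumen narrowing of at least 40%. *Early atherogenesis*: any new
#' plaque (follow-up thickness at least 0.5 mm where baseline was below) or
#' any thickness increase of an existing plaque that does not meet the
#' advanced rule at that site (non-stenotic progression). *Incipient
#' atherosclerosis*: early progression in a subject with no plaque at
#' baseline. A subject can be flagged early and advanced at different sites.
#'
#' @param baseline,followup Exam tibbles (same subjects, 16 sites each).
#' @param thresholds A [progression_thresholds()] list.
#' @return Tibble with one row per subject: `subject_id`, `early`,
#'   `advanced`, `incipient`, `index_plaque` (side:segment:wall of the
#'   advanced index plaque or `NA`), `relative_increase` (percent or `NA`).
#' @export
classify_progression <- function(baseline, followup,
                                 thresholds = progression_thresholds()) {
  validate_exam(baseline)
  validate_exam(followup)
  ids_b <- sort(unique(baseline$subject_id))
  ids_f <- sort(unique(followup$subject_id))
  if (!identical(ids_b, ids_f)) {
    plaq_abort("baseline and follow-up exams cover different subjects")
  }
  sites <- dplyr::inner_join(
    dplyr::select(baseline, "subject_id", "side", "segment", "wall",
                  b = "thickness_mm"),
    dplyr::select(followup, "subject_id", "side", "segment", "wall",
                  f = "thickness_mm", fup_narrow = "narrowing_pct"),
    by = c("subject_id", "side", "segment", "wall")
  )
  if (nrow(sites) != 16L * length(ids_b)) {
    plaq_abort("missing segments between visits")
  }
  sites$artery <- segment_artery(sites$segment)
  # follow-up narrowing is a per-artery quantity; use the artery maximum
  art_key <- paste(sites$subject_id, sites$side, sites$artery)
  art_max <- tapply(sites$fup_narrow, art_key, max)
  sites$artery_narrow <- as.numeric(art_max[art_key])

  pm <- thresholds$plaque_min
  thr <- ifelse(sites$artery == "ica", thresholds$ica, thresholds$cca)
  had_plaque <- sites$b >= pm
  rel_inc <- ifelse(had_plaque, 100 * (sites$f - sites$b) / sites$b,
                    NA_real_)
  advanced_site <- had_plaque & !is.na(rel_inc) & rel_inc > thr &
    sites$artery_narrow >= thresholds$narrowing
  new_plaque <- !had_plaque & sites$f >= pm
  growth <- had_plaque & sites$f > sites$b & !advanced_site
  sites$.adv <- advanced_site
  sites$.early <- new_plaque | growth
  sites$.new <- new_plaque
  sites$.rel <- rel_inc
  sites$.site <- paste(sites$side, sites$segment, sites$wall, sep = ":")
  sites$.bscore <- ifelse(had_plaque, sites$b, 0)

  sites |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      early = any(.data$.early),
      advanced = any(.data$.adv),
      incipient = any(.data$.early) && sum(.data$.bscore) == 0 &&
        any(.data$.new),
      index_plaque = if (any(.data$.adv)) {
        .data$.site[.data$.adv][which.max(.data$.rel[.data$.adv])]
      } else NA_character_,
      relative_increase = if (any(.data$.adv)) {
        max(.data$.rel[.data$.adv])
      } else NA_real_,
      .groups = "drop"
    )
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' expected agreement from the marginal products, as used to document the
#' reproducibility of the progression categories.
#'
#' @param calls_a,calls_b Equal-length categorical vectors.
#' @return One-row tibble: `kappa`, `p_observed`, `p_expected`, `n`,
#'   `degenerate` (TRUE when expected agreement is 1 and kappa undefined).
#' @export
cohens_kappa <- function(calls_a, calls_b) {
  assert_that(length(calls_a) == length(calls_b),
              "rating vectors must have equal length")
  assert_that(length(calls_a) > 0, "empty rating vectors")
  lev <- union(unique(as.character(calls_a)), unique(as.character(calls_b)))
  a <- factor(as.character(calls_a), levels = lev)
  b <- factor(as.character(calls_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_obs <- sum(diag(tab)) / n
  p_exp <- sum(rowSums(tab) * colSums(tab)) / n^2
  degenerate <- abs(1 - p_exp) < 1e-12
  kappa <- if (degenerate) NA_real_ else (p_obs - p_exp) / (1 - p_exp)
  tibble::tibble(kappa = kappa, p_observed = p_obs, p_expected = p_exp,
                 n = n, degenerate = degenerate)
}
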