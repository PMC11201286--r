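# Rank-correlation analysis, the surgical-duration regression, and the
# revised ASRM score/stage used for comparison.
#
# Two tie dialects are supported for Spearman's rho. "average" is the
# statistically standard mean-rank treatment. "rank_eq" reproduces the
# spreadsheet idiom of ranking each vector with a minimum-rank function
# (all tied values receive the first rank) and then correlating the rank
# vectors with the ordinary product-moment formula; with many ties the two
# dialects can differ noticeably, so analyses report both when they do.

TIE_MODES <- c("average", "rank_eq")

#' Rank a vector under a tie dialect
#'
#' @param values Numeric vector, length at least 1.
#' @param mode `"average"` (ties share the mean rank) or `"rank_eq"` (ties
#'   share the minimum rank, ascending order — the spreadsheet minimum-rank
#'   dialect).
#' @return Numeric vector of ranks.
#' @export
#' @examples
#' rank_vector(c(10, 20, 20, 30), "average")  # 1 2.5 2.5 4
#' rank_vector(c(10, 20, 20, 30), "rank_eq")  # 1 2 2 4
rank_vector <- function(values, mode = c("average", "rank_eq")) {
  mode <- match.arg(mode)
  if (!length(values)) stop("cannot rank an empty vector", call. = FALSE)
  if (anyNA(values)) stop("cannot rank a vector with missing values",
                          call. = FALSE)
  if (mode == "average") rank(values, ties.method = "average")
  else rank(values, ties.method = "min")
}

#' Spearman rank correlation with explicit tie handling
#'
#' Ranks both vectors under the chosen tie dialect and returns the Pearson
#' product-moment correlation of the rank vectors, with a large-sample
#' t-approximation p-value.
#'
#' @param x,y Equal-length numeric vectors, length at least 3, neither
#'   constant.
#' @param mode Tie dialect; see [rank_vector()].
#' @return An object of class `nmse_corr`: list with `estimate`, `n`,
#'   `tie_mode`, `p_value`.
#' @export
#' @examples
#' spearman_corr(c(1, 2, 3), c(10, 20, 30))$estimate  # 1
spearman_corr <- function(x, y, mode = c("average", "rank_eq")) {
  mode <- match.arg(mode)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("correlation undefined for a constant vector", call. = FALSE)
  rho <- stats::cor(rank_vector(x, mode), rank_vector(y, mode))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(estimate = rho, n = n, tie_mode = mode, p_value = p),
            class = "nmse_corr")
}

#' @export
print.nmse_corr <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, tie mode = %s, p = %.3g)\n",
              x$estimate, x$n, x$tie_mode, x$p_value))
  invisible(x)
}

#' Default score variants for correlation tables
#'
#' The standard rows of a validation analysis: the full E-score and its
#' cyst, adhesion, pain and uterine components as stand-alone scores.
#'
#' @param e_scheme Nodule scheme used for the full E-score and uterine rows.
#' @return Named list of [variant_spec()] objects.
#' @export
default_variants <- function(e_scheme = "flat3") {
  list(
    "E-score" = full_escore_variant(e_scheme),
    "Cyst score" = variant_spec(include_cyst = TRUE),
    "Adhesion score" = variant_spec(include_adhesion = TRUE),
    "Pain score" = variant_spec(include_pain = TRUE),
    "Uterine score" = variant_spec(include_uterine = TRUE,
                                   uterine_elements = c("A", "R", "E"),
                                   e_scheme = e_scheme))
}

outcome_matrix <- function(x) {
  get <- function(field) vapply(x$exams, function(e)
    (e$outcomes %||% outcomes())[[field]], numeric(1))
  cbind(rasrm_score = get("rasrm_score"),
        duration_min = get("duration_min"),
        blood_loss_ml = get("blood_loss_ml"))
}

#' Score-versus-outcome correlation table
#'
#' Computes the Spearman correlation of each score variant (plus, when
#' present, the recorded r-ASRM score) against each outcome column, in the
#' layout of a validation table: one row per score, one column per outcome.
#'
#' @param x An `nmse_cohort` whose exams carry outcomes.
#' @param variants Named list of [variant_spec()] objects;
#'   defaults to [default_variants()].
#' @param outcomes Character vector of outcome fields among
#'   `"rasrm_score"`, `"duration_min"`, `"blood_loss_ml"`.
#' @param mode Tie dialect; see [rank_vector()].
#' @return An object of class `nmse_corr_table`: list with `estimate` and
#'   `p_value` matrices (full precision; `print` rounds to 3 decimals),
#'   `n`, `tie_mode`.
#' @export
correlation_table <- function(x, variants = default_variants(),
                              outcomes = c("rasrm_score", "duration_min",
                                           "blood_loss_ml"),
                              mode = c("average", "rank_eq")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "nmse_cohort"))
  om <- outcome_matrix(x)
  bad <- setdiff(outcomes, colnames(om))
  if (length(bad))
    stop("unknown outcome column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  om <- om[, outcomes, drop = FALSE]
  if (any(colSums(!is.na(om)) < 3))
    stop("need at least 3 patients with each requested outcome",
         call. = FALSE)
  scores <- vapply(variants, function(v)
    vapply(x$exams, variant_score, numeric(1), spec = v),
    numeric(length(x$exams)))
  scores <- matrix(scores, ncol = length(variants),
                   dimnames = list(NULL, names(variants)))
  if ("rasrm_score" %in% colnames(om) && !all(is.na(om[, "rasrm_score"])) &&
      !"r-ASRM score" %in% colnames(scores))
    scores <- cbind(scores, "r-ASRM score" = om[, "rasrm_score"])
  est <- p <- matrix(NA_real_, ncol(scores), ncol(om),
                     dimnames = list(colnames(scores), colnames(om)))
  for (i in seq_len(ncol(scores))) for (j in seq_len(ncol(om))) {
    if (identical(colnames(scores)[i], "r-ASRM score") &&
        identical(colnames(om)[j], "rasrm_score")) next
    keep <- !is.na(scores[, i]) & !is.na(om[, j])
    r <- spearman_corr(scores[keep, i], om[keep, j], mode)
    est[i, j] <- r$estimate
    p[i, j] <- r$p_value
  }
  structure(list(estimate = est, p_value = p, n = nrow(scores),
                 tie_mode = mode),
            class = "nmse_corr_table")
}

#' @export
print.nmse_corr_table <- function(x, ...) {
  cat(sprintf("Spearman correlations (n = %d, tie mode = %s):\n",
              x$n, x$tie_mode))
  print(round(x$estimate, 3))
  invisible(x)
}

#' Surgical-duration model
#'
#' An affine predictor of operation time (minutes) from the E-score:
#' `duration = slope * e_score + intercept`. The canonical defaults are the
#' published coefficients slope 6.2995 min per E-score point and intercept
#' 49.459 min.
#'
#' @param slope Minutes per E-score point.
#' @param intercept Minutes.
#' @return An object of class `nmse_duration_model`.
#' @seealso [fit_duration_model()], [predict_duration()]
#' @export
duration_model <- function(slope = 6.2995, intercept = 49.459) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = as.numeric(slope),
                 intercept = as.numeric(intercept), fit = NULL),
            class = "nmse_duration_model")
}

#' Fit the surgical-duration model by ordinary least squares
#'
#' @param e_scores Numeric vector of E-scores.
#' @param durations Numeric vector of operation times (minutes), same
#'   length.
#' @return An `nmse_duration_model`; the underlying `stats::lm` fit is kept
#'   in the `fit` element.
#' @export
#' @examples
#' m <- fit_duration_model(c(0, 10, 20), 6.2995 * c(0, 10, 20) + 49.459)
#' coef(m)
fit_duration_model <- function(e_scores, durations) {
  if (length(e_scores) != length(durations))
    stop("e_scores and durations must have equal length", call. = FALSE)
  if (length(e_scores) < 2)
    stop("need at least 2 observations", call. = FALSE)
  if (length(unique(e_scores)) < 2L)
    stop("degenerate design: all E-scores equal", call. = FALSE)
  fit <- stats::lm(durations ~ e_scores)
  m <- duration_model(slope = unname(stats::coef(fit)[2]),
                      intercept = unname(stats::coef(fit)[1]))
  m$fit <- fit
  m
}

#' Predict surgical duration from an E-score
#'
#' @param model An `nmse_duration_model`.
#' @param e_score Non-negative E-score value(s).
#' @return Predicted duration(s) in minutes.
#' @export
#' @examples
#' predict_duration(duration_model(), 0)   # 49.459
#' predict_duration(duration_model(), 29)  # 232.1445
predict_duration <- function(model, e_score) {
  stopifnot(inherits(model, "nmse_duration_model"))
  if (any(e_score < 0)) stop("e_score must be non-negative", call. = FALSE)
  model$slope * e_score + model$intercept
}

#' @export
predict.nmse_duration_model <- function(object, e_score, ...) {
  predict_duration(object, e_score)
}

#' @export
coef.nmse_duration_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.nmse_duration_model <- function(x, ...) {
  cat(sprintf("<nmse_duration_model> duration = %.4f * E + %.3f min\n",
              x$slope, x$intercept))
  invisible(x)
}

#' @export
residuals.nmse_duration_model <- function(object, ...) {
  if (is.null(object$fit))
    stop("model was not fitted from data", call. = FALSE)
  stats::residuals(object$fit)
}

RASRM_ADHESION_CATEGORIES <- c(none = 0L, lt_third = 4L,
                               third_to_two_thirds = 8L,
                               gt_two_thirds = 16L)

#' Revised ASRM component findings
#'
#' The intraoperative r-ASRM components at point granularity: peritoneal
#' lesions (up to 6), endometriomas (up to 40), posterior cul-de-sac
#' obliteration (up to 40), per-ovary adhesion extent categories (none,
#' less than a third, a third to two thirds, more than two thirds of the
#' ovary involved), and tubal adhesions (up to 32).
#'
#' @param peritoneal_points Integer 0-6.
#' @param endometrioma_points Integer 0-40.
#' @param culdesac_points Integer 0-40.
#' @param right_ovary_adhesion,left_ovary_adhesion One of `"none"`,
#'   `"lt_third"`, `"third_to_two_thirds"`, `"gt_two_thirds"`.
#' @param tubal_adhesion_points Integer 0-32.
#' @return An object of class `nmse_rasrm`.
#' @export
rasrm_findings <- function(peritoneal_points = 0,
                           endometrioma_points = 0,
                           culdesac_points = 0,
                           right_ovary_adhesion = "none",
                           left_ovary_adhesion = "none",
                           tubal_adhesion_points = 0) {
  chk <- function(x, lo, hi, what) {
    if (!is.finite(x) || x < lo || x > hi || x != floor(x))
      stop(sprintf("%s must be an integer in [%d, %d]", what, lo, hi),
           call. = FALSE)
    as.integer(x)
  }
  right_ovary_adhesion <- match.arg(right_ovary_adhesion,
                                    names(RASRM_ADHESION_CATEGORIES))
  left_ovary_adhesion <- match.arg(left_ovary_adhesion,
                                   names(RASRM_ADHESION_CATEGORIES))
  structure(
    list(peritoneal_points = chk(peritoneal_points, 0, 6, "peritoneal_points"),
         endometrioma_points = chk(endometrioma_points, 0, 40,
                                   "endometrioma_points"),
         culdesac_points = chk(culdesac_points, 0, 40, "culdesac_points"),
         right_ovary_adhesion = right_ovary_adhesion,
         left_ovary_adhesion = left_ovary_adhesion,
         tubal_adhesion_points = chk(tubal_adhesion_points, 0, 32,
                                     "tubal_adhesion_points")),
    class = "nmse_rasrm")
}

#' Total r-ASRM score
#'
#' Sum of the component points, with ovarian adhesion categories mapped to
#' 0 / 4 / 8 / 16 points per ovary, capped at the 150-point maximum.
#'
#' @param findings An [rasrm_findings()].
#' @return Integer 0-150.
#' @export
rasrm_total <- function(findings) {
  stopifnot(inherits(findings, "nmse_rasrm"))
  total <- findings$peritoneal_points + findings$endometrioma_points +
    findings$culdesac_points +
    RASRM_ADHESION_CATEGORIES[[findings$right_ovary_adhesion]] +
    RASRM_ADHESION_CATEGORIES[[findings$left_ovary_adhesion]] +
    findings$tubal_adhesion_points
  as.integer(min(150L, total))
}

#' r-ASRM stage from the total score
#'
#' Stage bins: I for 1-5, II for 6-15, III for 16-40, IV for 41 and above.
#' (Published bin labels leave the value 41 between "16-40" and ">41"; it
#' is assigned to stage IV here, matching the conventional ">40" cut.)
#'
#' @param score Integer total, 1-150.
#' @return Factor level among `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
#' @examples
#' rasrm_stage(10)  # II
#' rasrm_stage(40)  # III
rasrm_stage <- function(score) {
  if (any(!is.finite(score) | score < 1 | score > 150 | score != floor(score)))
    stop("score must be an integer in [1, 150]", call. = FALSE)
  cut(score, breaks = c(0, 5, 15, 40, 150),
      labels = c("I", "II", "III", "IV"))
}

#' Cohort descriptive statistics
#'
#' Per-score mean / min / max (E-score and its components, flat scheme),
#' lesion prevalences (endometriotic nodule E, retroversion R, adenomyosis
#' A, rare-site disease) as counts and percentages, and outcome summaries,
#' in the layout of a severity table.
#'
#' @param x A non-empty `nmse_cohort`.
#' @return An object of class `nmse_descriptives`: list with data frames
#'   `scores`, `prevalence`, `outcomes`.
#' @export
cohort_descriptives <- function(x) {
  stopifnot(inherits(x, "nmse_cohort"))
  if (!length(x$exams)) stop("empty cohort", call. = FALSE)
  br <- lapply(x$exams, e_score, scheme = "flat3")
  comp <- function(f) vapply(br, `[[`, numeric(1), f)
  score_df <- do.call(rbind, lapply(
    c("e_score", "cyst_score", "adhesion_score", "pain_score",
      "uterine_score"),
    function(f) {
      v <- comp(f)
      data.frame(score = f, mean = round(mean(v), 2),
                 min = min(v), max = max(v))
    }))
  n <- length(x$exams)
  has <- function(f) sum(vapply(x$exams, f, logical(1)))
  prev <- data.frame(
    finding = c("endometriotic nodule (E)", "retroverted uterus (R)",
                "adenomyosis (A)", "rare-site disease"),
    n = c(has(function(e) length(e$uterus$nodules_cm) > 0),
          has(function(e) e$uterus$retroverted),
          has(function(e) e$uterus$adenomyosis),
          has(function(e) length(e$rare$sites) > 0)))
  prev$percent <- round(100 * prev$n / n, 1)
  om <- outcome_matrix(x)
  oc_df <- do.call(rbind, lapply(c("duration_min", "blood_loss_ml",
                                   "rasrm_score"), function(f) {
    v <- om[, f]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    data.frame(outcome = f, mean = round(mean(v), 2),
               min = min(v), max = max(v))
  }))
  structure(list(scores = score_df, prevalence = prev, outcomes = oc_df,
                 n = n),
            class = "nmse_descriptives")
}

#' @export
print.nmse_descriptives <- function(x, ...) {
  cat(sprintf("Cohort descriptives (n = %d)\n\nScores:\n", x$n))
  print(x$scores, row.names = FALSE)
  cat("\nPrevalence:\n")
  print(x$prevalence, row.names = FALSE)
  if (!is.null(x$outcomes)) {
    cat("\nOutcomes:\n")
    print(x$outcomes, row.names = FALSE)
  }
  invisible(x)
}
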