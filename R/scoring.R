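# NMS-E component scores and the E-score.
#
# Cyst: per-side endometrioma score = ceiling(diameter), capped at 5; the
# two sides sum to at most 10. Tubal lesions add 3 points per side.
# Adhesion: number of positive sliding-sign sites (0-10).
# Pain: maximum NRS over the seven regions (0-10).
# Uterine: 3 points per lesion type (retroversion R, adenomyosis A,
# nodules E) under the flat scheme; under the size-graded scheme each
# nodule contributes 3/6/10 points by diameter band [1,2)/[2,3)/[3,Inf).
# Rare-site: a flat 10 when any rare site is involved.

E_SCHEMES <- c("flat3", "sized")

check_scheme <- function(scheme) match.arg(scheme, E_SCHEMES)

#' Per-side ovarian cyst score
#'
#' Only endometriomas score: the diameter (total of maximum diameters for a
#' multi-cystic ovary) is rounded up to the next whole centimetre and capped
#' at 5 points. Absent cysts and non-endometrioma cysts score 0.
#'
#' @param finding An [ovary_finding()].
#' @return Integer score 0-5.
#' @export
#' @examples
#' cyst_side_score(ovary_finding("right", 6.5, "endometrioma"))  # 5
#' cyst_side_score(ovary_finding("left", 2.4, "endometrioma"))   # 3
cyst_side_score <- function(finding) {
  d <- finding$cyst_diameter_cm
  if (!is.finite(d) || d < 0) stop("cyst diameter must be non-negative")
  if (finding$cyst_kind != "endometrioma") return(0L)
  as.integer(min(5, ceiling(d)))
}

#' Tubal lesion score
#'
#' Each side with a visible tubal lesion (hydrosalpinx, pyosalpinx, or
#' other) scores 3 points, for a range of 0-6.
#'
#' @param right,left [ovary_finding()] objects.
#' @return Integer score 0, 3 or 6.
#' @export
tubal_score <- function(right, left) {
  3L * ((right$tubal_lesion != "none") + (left$tubal_lesion != "none"))
}

#' Combined cyst score
#'
#' Sum of the two per-side endometrioma scores (capped at 5 each, hence at
#' most 10 for the ovarian part) plus the tubal score (0-6).
#'
#' @inheritParams tubal_score
#' @return Integer score 0-16.
#' @export
#' @examples
#' combined_cyst_score(ovary_finding("right", 6.5, "endometrioma"),
#'                     ovary_finding("left", 2.4, "endometrioma"))  # 8
combined_cyst_score <- function(right, left) {
  ov <- cyst_side_score(right) + cyst_side_score(left)
  stopifnot(ov <= 10L)
  as.integer(ov + tubal_score(right, left))
}

#' Adhesion score
#'
#' The number of sliding-sign-positive sites out of the ten canonical
#' locations.
#'
#' @param map An [adhesion_map()].
#' @return Integer score 0-10.
#' @export
adhesion_score <- function(map) {
  as.integer(sum(unclass(map)))
}

#' Pain score
#'
#' The highest NRS value across the seven pelvic regions.
#'
#' @param map A [pain_map()].
#' @return Integer score 0-10.
#' @export
pain_score <- function(map) {
  as.integer(max(unclass(map)))
}

sized_nodule_points <- function(d) {
  # half-open diameter bands [1,2) -> 3, [2,3) -> 6, [3,Inf) -> 10
  ifelse(d >= 3, 10L, ifelse(d >= 2, 6L, 3L))
}

#' Uterine score
#'
#' Retroversion (R) and adenomyosis (A) score 3 points each. Endometriotic
#' nodules (E) score 3 points once if any are present under the `"flat3"`
#' scheme (regardless of their number), keeping the flat-scheme range 0-9;
#' under the `"sized"` scheme every nodule contributes cumulatively by
#' diameter band: 3 points for \[1, 2) cm, 6 for \[2, 3) cm, 10 for 3 cm
#' and above. Myomas never score.
#'
#' @param findings A [uterine_findings()].
#' @param scheme `"flat3"` (default) or `"sized"`.
#' @return Non-negative integer; at most 9 under `"flat3"`.
#' @export
#' @examples
#' u <- uterine_findings(adenomyosis = TRUE, nodules_cm = 2.6)
#' uterine_score(u)           # 6
#' uterine_score(u, "sized")  # 9
uterine_score <- function(findings, scheme = "flat3") {
  scheme <- check_scheme(scheme)
  base <- 3L * (findings$retroverted + findings$adenomyosis)
  nd <- findings$nodules_cm
  nod <- if (!length(nd)) 0L
         else if (scheme == "flat3") 3L
         else sum(sized_nodule_points(nd))
  as.integer(base + nod)
}

#' Rare-site score
#'
#' A flat 10 points when any rare-site endometriosis (intestinal, bladder,
#' ureteral, vaginal, cutaneous, umbilical, inguinal, ...) is present,
#' otherwise 0. Multiple rare sites still score 10.
#'
#' @param findings A [rare_site_findings()].
#' @return 0 or 10.
#' @export
rare_score <- function(findings) {
  if (length(findings$sites)) 10L else 0L
}

#' E-score with its component breakdown
#'
#' Computes every component score and their total, the E-score, which
#' quantifies overall endometriosis severity and is the predictor of the
#' surgical-duration model (see [predict_duration()]).
#'
#' @param exam A valid [patient_exam()].
#' @param scheme Nodule scheme for the uterine component, `"flat3"` or
#'   `"sized"`; see [uterine_score()].
#' @return An object of class `nmse_score`: list with elements
#'   `cyst_right`, `cyst_left`, `tubal`, `cyst_score`, `adhesion_score`,
#'   `pain_score`, `uterine_score`, `rare_score`, `e_score`, `scheme`.
#' @export
#' @examples
#' e_score(worked_example_exam())            # total 29
#' e_score(worked_example_exam(), "sized")   # total 32
e_score <- function(exam, scheme = "flat3") {
  scheme <- check_scheme(scheme)
  stop_if_invalid(exam)
  cr <- cyst_side_score(exam$right)
  cl <- cyst_side_score(exam$left)
  tb <- tubal_score(exam$right, exam$left)
  ad <- adhesion_score(exam$adhesions)
  pn <- pain_score(exam$pain)
  ut <- uterine_score(exam$uterus, scheme)
  rr <- rare_score(exam$rare)
  cy <- as.integer(cr + cl + tb)
  structure(
    list(cyst_right = cr, cyst_left = cl, tubal = tb, cyst_score = cy,
         adhesion_score = ad, pain_score = pn, uterine_score = ut,
         rare_score = rr,
         e_score = as.integer(cy + ad + pn + ut + rr),
         scheme = scheme),
    class = "nmse_score")
}

#' @export
print.nmse_score <- function(x, ...) {
  cat(sprintf("<nmse_score> scheme = %s\n", x$scheme))
  cat(sprintf("  Cyst     %2d  (right %d + left %d + tubal %d)\n",
              x$cyst_score, x$cyst_right, x$cyst_left, x$tubal))
  cat(sprintf("  Adhesion %2d / 10\n", x$adhesion_score))
  cat(sprintf("  Pain     %2d / 10\n", x$pain_score))
  cat(sprintf("  Uterine  %2d\n", x$uterine_score))
  cat(sprintf("  Rare     %2d\n", x$rare_score))
  cat(sprintf("  E-score  %2d\n", x$e_score))
  invisible(x)
}

#' Variant scoring scheme specification
#'
#' Describes which components enter a score and how uterine nodules are
#' graded, so that reduced scores (adhesion only, adhesion + pain, ...)
#' and the size-graded E-score can all be computed through one interface.
#'
#' @param include_cyst,include_adhesion,include_pain,include_uterine,include_rare
#'   Logical switches for each component.
#' @param uterine_elements Subset of `c("A", "R", "E")` counted in the
#'   uterine term; must be empty when `include_uterine` is `FALSE`.
#' @param e_scheme `"flat3"` or `"sized"` nodule grading.
#' @return An object of class `nmse_variant`.
#' @seealso [variant_score()], [correlation_table()]
#' @export
variant_spec <- function(include_cyst = FALSE, include_adhesion = FALSE,
                         include_pain = FALSE, include_uterine = FALSE,
                         uterine_elements = character(),
                         e_scheme = "flat3", include_rare = FALSE) {
  e_scheme <- check_scheme(e_scheme)
  uterine_elements <- as.character(uterine_elements)
  if (length(setdiff(uterine_elements, c("A", "R", "E"))))
    stop("uterine_elements must be a subset of A, R, E")
  if (!include_uterine && length(uterine_elements))
    stop("uterine_elements must be empty when include_uterine is FALSE")
  structure(
    list(include_cyst = isTRUE(include_cyst),
         include_adhesion = isTRUE(include_adhesion),
         include_pain = isTRUE(include_pain),
         include_uterine = isTRUE(include_uterine),
         uterine_elements = uterine_elements,
         e_scheme = e_scheme,
         include_rare = isTRUE(include_rare)),
    class = "nmse_variant")
}

#' The full E-score as a variant specification
#'
#' @param e_scheme Nodule scheme, `"flat3"` or `"sized"`.
#' @return An `nmse_variant` including every component.
#' @export
full_escore_variant <- function(e_scheme = "flat3") {
  variant_spec(include_cyst = TRUE, include_adhesion = TRUE,
               include_pain = TRUE, include_uterine = TRUE,
               uterine_elements = c("A", "R", "E"),
               e_scheme = e_scheme, include_rare = TRUE)
}

#' Compute a variant score
#'
#' Sums only the components selected by the [variant_spec()]; the uterine
#' term counts only the listed elements under the chosen nodule scheme.
#' With every component included this equals the E-score total.
#'
#' @param exam A valid [patient_exam()].
#' @param spec An [variant_spec()].
#' @return Numeric score.
#' @export
#' @examples
#' variant_score(worked_example_exam(),
#'               variant_spec(include_adhesion = TRUE))  # 7
variant_score <- function(exam, spec) {
  stopifnot(inherits(spec, "nmse_variant"))
  stop_if_invalid(exam)
  s <- 0
  if (spec$include_cyst)
    s <- s + combined_cyst_score(exam$right, exam$left)
  if (spec$include_adhesion)
    s <- s + adhesion_score(exam$adhesions)
  if (spec$include_pain)
    s <- s + pain_score(exam$pain)
  if (spec$include_uterine) {
    u <- exam$uterus
    el <- spec$uterine_elements
    s <- s + 3L * (("R" %in% el) && u$retroverted)
    s <- s + 3L * (("A" %in% el) && u$adenomyosis)
    if ("E" %in% el && length(u$nodules_cm)) {
      s <- s + if (spec$e_scheme == "flat3") 3L
               else sum(sized_nodule_points(u$nodules_cm))
    }
  }
  if (spec$include_rare)
    s <- s + rare_score(exam$rare)
  as.numeric(s)
}
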