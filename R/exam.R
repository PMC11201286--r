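# Domain types for a single NMS-E examination: per-side ovarian findings,
# the 10-site sliding-sign adhesion map, the 7-region pelvic pain map,
# uterine lesions, rare-site disease, and optional surgical outcomes.

CYST_KINDS  <- c("none", "endometrioma", "other")
TUBAL_KINDS <- c("none", "hydrosalpinx", "pyosalpinx", "other")
RARE_SITES  <- c("intestinal", "bladder", "ureteral", "vaginal",
                 "cutaneous", "umbilical", "inguinal", "other")

# cm values are carried to one decimal place; extra precision is rounded
# half-up on ingest (round() would round half-even).
round_cm <- function(x) floor(x * 10 + 0.5) / 10

#' Canonical sliding-sign adhesion sites
#'
#' The ten pelvic locations at which adhesions are assessed by the sliding
#' sign on transvaginal ultrasound, in canonical order: five cross-sectional
#' sites (right ovary to pelvic side wall, right ovary to uterus, between the
#' ovaries, left ovary to uterus, left ovary to side wall) followed by five
#' longitudinal sites on the anterior and posterior uterine surfaces.
#'
#' @return Character vector of length 10, in fixed canonical order.
#' @export
#' @examples
#' canonical_adhesion_sites()
canonical_adhesion_sites <- function() {
  c("Rt.O-side", "Rt.O-Ut.", "Inter O-O", "Lt.O-Ut.", "Lt.O-Side",
    "Upper ant.", "Mid. ant.", "Upper post.", "Mid.post.", "Lower post.")
}

#' Canonical pelvic pain regions
#'
#' The seven pelvic regions, centred on the uterine cervix, at which
#' palpation pain is graded on the 0-10 Numeric Rating Scale during pelvic
#' examination. Regions are numbered I-VII.
#'
#' @return Named character vector of length 7; names are the Roman numerals
#'   `I`..`VII`, values the anatomical region descriptions.
#' @export
#' @examples
#' canonical_pain_regions()[["V"]]
canonical_pain_regions <- function() {
  c(I   = "right adnexal region",
    II  = "right uterosacral ligament area",
    III = "anterior vaginal wall area",
    IV  = "cervical area",
    V   = "pouch of Douglas",
    VI  = "left adnexal region",
    VII = "left uterosacral ligament area")
}

PAIN_NUMERALS <- c("I", "II", "III", "IV", "V", "VI", "VII")

#' Ovarian findings for one side
#'
#' Records the cyst (if any) and tubal lesion (if any) found on one adnexa.
#' For multi-cystic ovaries the diameter is the total of the maximum
#' diameters. Non-endometrioma cysts carry a one-letter label (the initial
#' of the cyst type, e.g. `"d"` for dermoid) which is prefixed before the
#' size in the summary notation; they are recorded but never scored.
#'
#' @param side `"right"` or `"left"`.
#' @param cyst_diameter_cm Maximum diameter in cm; rounded half-up to one
#'   decimal place on ingest. 0 when no cyst.
#' @param cyst_kind `"none"`, `"endometrioma"` or `"other"`.
#' @param cyst_label One-letter label for `cyst_kind = "other"`.
#' @param tubal_lesion `"none"`, `"hydrosalpinx"`, `"pyosalpinx"` or
#'   `"other"`.
#' @param tubal_label Short label for `tubal_lesion = "other"`.
#' @return An object of class `nmse_ovary`.
#' @export
#' @examples
#' ovary_finding("right", 6.5, "endometrioma")
ovary_finding <- function(side = c("right", "left"),
                          cyst_diameter_cm = 0,
                          cyst_kind = "none",
                          cyst_label = NULL,
                          tubal_lesion = "none",
                          tubal_label = NULL) {
  side <- match.arg(side)
  stopifnot(is.numeric(cyst_diameter_cm), length(cyst_diameter_cm) == 1)
  cyst_kind <- match.arg(cyst_kind, CYST_KINDS)
  tubal_lesion <- match.arg(tubal_lesion, TUBAL_KINDS)
  structure(
    list(side = side,
         cyst_diameter_cm = round_cm(cyst_diameter_cm),
         cyst_kind = cyst_kind,
         cyst_label = cyst_label,
         tubal_lesion = tubal_lesion,
         tubal_label = tubal_label),
    class = "nmse_ovary")
}

#' Sliding-sign adhesion map
#'
#' Ten booleans, one per canonical site; `TRUE` means the sliding sign is
#' absent, i.e. an adhesion is present.
#'
#' @param positive Character vector of positive site names (must be drawn
#'   from [canonical_adhesion_sites()]), or a named/unnamed logical vector
#'   of length 10 in canonical order.
#' @return An object of class `nmse_adhesion_map`: named logical vector of
#'   length 10 in canonical order.
#' @export
#' @examples
#' adhesion_map(c("Rt.O-side", "Inter O-O"))
adhesion_map <- function(positive = character()) {
  sites <- canonical_adhesion_sites()
  if (is.logical(positive)) {
    if (length(positive) != 10L)
      stop("logical adhesion map must have exactly 10 entries")
    if (!is.null(names(positive)) && !identical(names(positive), sites))
      stop("adhesion map names must be the canonical sites in canonical order")
    m <- as.logical(positive)
  } else {
    positive <- as.character(positive)
    unknown <- setdiff(positive, sites)
    if (length(unknown))
      stop("unknown adhesion site(s): ", paste(unknown, collapse = ", "))
    m <- sites %in% positive
  }
  names(m) <- sites
  structure(m, class = "nmse_adhesion_map")
}

#' Seven-region pelvic pain map
#'
#' @param values Numeric vector of length 7 of NRS values (0-10, integers)
#'   in region order I-VII, or a named vector with names `I`..`VII`.
#' @return An object of class `nmse_pain_map`: named integer-valued vector,
#'   names `I`..`VII`.
#' @export
#' @examples
#' pain_map(c(3, 1, 0, 5, 8, 2, 1))
pain_map <- function(values = rep(0, 7)) {
  if (length(values) != 7L)
    stop("pain map must have exactly 7 regions")
  if (!is.null(names(values))) {
    if (!setequal(names(values), PAIN_NUMERALS))
      stop("pain map names must be the numerals I-VII")
    values <- values[PAIN_NUMERALS]
  }
  v <- as.numeric(values)
  names(v) <- PAIN_NUMERALS
  structure(v, class = "nmse_pain_map")
}

#' Uterine lesion findings
#'
#' Retroversion (R), adenomyosis (A) and endometriotic nodules (E, deep
#' lesions at least 1 cm in diameter) are the scored uterine conditions;
#' myomas (M) are noted but never scored.
#'
#' @param retroverted Logical; cervix-corpus axis angled < 180 degrees
#'   posteriorly.
#' @param adenomyosis Logical.
#' @param nodules_cm Numeric vector of nodule maximum diameters in cm
#'   (rounded half-up to one decimal); may be empty.
#' @param myoma Logical; recorded only.
#' @return An object of class `nmse_uterus`.
#' @export
uterine_findings <- function(retroverted = FALSE, adenomyosis = FALSE,
                             nodules_cm = numeric(), myoma = FALSE) {
  structure(
    list(retroverted = isTRUE(retroverted),
         adenomyosis = isTRUE(adenomyosis),
         nodules_cm = round_cm(as.numeric(nodules_cm)),
         myoma = isTRUE(myoma)),
    class = "nmse_uterus")
}

#' Rare-site endometriosis findings
#'
#' @param sites Character vector of affected sites, drawn from
#'   `r paste0('"', RARE_SITES, '"', collapse = ", ")`; no duplicates.
#' @param other_label Free-text label when `"other"` is among `sites`.
#' @return An object of class `nmse_rare`.
#' @export
rare_site_findings <- function(sites = character(), other_label = NULL) {
  sites <- as.character(sites)
  structure(list(sites = sites, other_label = other_label),
            class = "nmse_rare")
}

#' Surgical outcomes
#'
#' @param duration_min Operation time in minutes (optional).
#' @param blood_loss_ml Intraoperative blood loss in mL (optional).
#' @param rasrm_score Intraoperative revised ASRM score, 0-150 (optional).
#' @return An object of class `nmse_outcomes`.
#' @export
outcomes <- function(duration_min = NA_real_, blood_loss_ml = NA_real_,
                     rasrm_score = NA_integer_) {
  structure(
    list(duration_min = as.numeric(duration_min),
         blood_loss_ml = as.numeric(blood_loss_ml),
         rasrm_score = as.numeric(rasrm_score)),
    class = "nmse_outcomes")
}

#' Full NMS-E examination record for one patient
#'
#' @param patient_id Character identifier.
#' @param right,left [ovary_finding()] objects for each adnexa.
#' @param adhesions An [adhesion_map()].
#' @param pain A [pain_map()].
#' @param uterus A [uterine_findings()].
#' @param rare A [rare_site_findings()].
#' @param outcomes An [outcomes()] object, or `NULL` when no surgery has
#'   taken place.
#' @return An object of class `nmse_exam`.
#' @seealso [validate_exam()], [e_score()], [serialize_summary()]
#' @export
#' @examples
#' ex <- worked_example_exam()
#' validate_exam(ex)     # character(0): the exam is valid
#' e_score(ex)
patient_exam <- function(patient_id = "anon",
                         right = ovary_finding("right"),
                         left = ovary_finding("left"),
                         adhesions = adhesion_map(),
                         pain = pain_map(),
                         uterus = uterine_findings(),
                         rare = rare_site_findings(),
                         outcomes = NULL) {
  stopifnot(inherits(right, "nmse_ovary"), inherits(left, "nmse_ovary"),
            inherits(adhesions, "nmse_adhesion_map"),
            inherits(pain, "nmse_pain_map"),
            inherits(uterus, "nmse_uterus"),
            inherits(rare, "nmse_rare"))
  if (right$side != "right") stop("`right` must be a right-side finding")
  if (left$side != "left")   stop("`left` must be a left-side finding")
  structure(
    list(patient_id = as.character(patient_id),
         right = right, left = left,
         adhesions = adhesions, pain = pain,
         uterus = uterus, rare = rare,
         outcomes = outcomes),
    class = "nmse_exam")
}

validate_ovary <- function(o, prefix) {
  v <- character()
  d <- o$cyst_diameter_cm
  if (!is.finite(d) || d < 0)
    v <- c(v, sprintf("%s: cyst_diameter_cm must be a non-negative number", prefix))
  else {
    if (d >= 50)
      v <- c(v, sprintf("%s: cyst_diameter_cm must be below 50 cm", prefix))
    if (d == 0 && o$cyst_kind != "none")
      v <- c(v, sprintf("%s: diameter 0 requires cyst_kind 'none'", prefix))
    if (d > 0 && o$cyst_kind == "none")
      v <- c(v, sprintf("%s: cyst_kind 'none' requires diameter 0", prefix))
  }
  if (o$cyst_kind == "other" &&
      (is.null(o$cyst_label) || !nzchar(o$cyst_label)))
    v <- c(v, sprintf("%s: cyst_kind 'other' requires a non-empty one-letter label", prefix))
  if (o$cyst_kind == "other" && !is.null(o$cyst_label) && nchar(o$cyst_label) != 1L)
    v <- c(v, sprintf("%s: cyst label must be a single letter", prefix))
  if (o$tubal_lesion == "other" &&
      (is.null(o$tubal_label) || !nzchar(o$tubal_label)))
    v <- c(v, sprintf("%s: tubal_lesion 'other' requires a non-empty label", prefix))
  v
}

#' Validate an examination record
#'
#' Checks every domain invariant and returns the violations as messages;
#' an empty character vector means the exam is valid. Validation never
#' throws.
#'
#' @param exam A [patient_exam()].
#' @return Character vector of violation messages, each naming the field
#'   and the rule; `character(0)` when the exam is valid.
#' @export
#' @examples
#' bad <- worked_example_exam()
#' bad$pain[["IV"]] <- 11
#' validate_exam(bad)
validate_exam <- function(exam) {
  if (!inherits(exam, "nmse_exam")) return("not an nmse_exam object")
  v <- character()
  v <- c(v, validate_ovary(exam$right, "right"))
  v <- c(v, validate_ovary(exam$left, "left"))
  a <- unclass(exam$adhesions)
  if (length(a) != 10L || !identical(names(a), canonical_adhesion_sites()))
    v <- c(v, "adhesions: must cover exactly the 10 canonical sites in order")
  if (anyNA(a))
    v <- c(v, "adhesions: every site must be strictly TRUE or FALSE")
  p <- unclass(exam$pain)
  if (length(p) != 7L || !identical(names(p), PAIN_NUMERALS))
    v <- c(v, "pain: must cover exactly regions I-VII in order")
  else {
    bad <- !is.finite(p) | p < 0 | p > 10
    if (any(bad))
      v <- c(v, sprintf("pain: region %s NRS must be in [0, 10]",
                        names(p)[bad]))
    nonint <- is.finite(p) & p != floor(p)
    if (any(nonint))
      v <- c(v, sprintf("pain: region %s NRS must be a whole number",
                        names(p)[nonint]))
  }
  nd <- exam$uterus$nodules_cm
  if (length(nd) && any(!is.finite(nd) | nd < 1.0))
    v <- c(v, "uterus: endometriotic nodule diameters must be at least 1 cm")
  rs <- exam$rare$sites
  if (anyDuplicated(rs))
    v <- c(v, "rare: duplicate rare-site entries")
  if (length(setdiff(rs, RARE_SITES)))
    v <- c(v, sprintf("rare: unknown site '%s'", setdiff(rs, RARE_SITES)))
  if ("other" %in% rs &&
      (is.null(exam$rare$other_label) || !nzchar(exam$rare$other_label)))
    v <- c(v, "rare: site 'other' requires a non-empty label")
  oc <- exam$outcomes
  if (!is.null(oc)) {
    if (!is.na(oc$duration_min) && oc$duration_min <= 0)
      v <- c(v, "outcomes: duration_min must be positive")
    if (!is.na(oc$blood_loss_ml) && oc$blood_loss_ml < 0)
      v <- c(v, "outcomes: blood_loss_ml must be non-negative")
    if (!is.na(oc$rasrm_score) &&
        (oc$rasrm_score < 0 || oc$rasrm_score > 150 ||
         oc$rasrm_score != floor(oc$rasrm_score)))
      v <- c(v, "outcomes: rasrm_score must be an integer in [0, 150]")
  }
  v
}

stop_if_invalid <- function(exam) {
  v <- validate_exam(exam)
  if (length(v))
    stop("invalid exam:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  invisible(exam)
}

#' The worked-example examination
#'
#' The teaching case used throughout the documentation: a right
#' endometrioma of 6.5 cm, a left endometrioma of 2.4 cm, seven positive
#' adhesion sites (four cross-sectional, three longitudinal), maximum
#' palpation pain NRS 8 in the pouch of Douglas, adenomyosis together with
#' a 2.6 cm endometriotic nodule, and no rare-site disease. Its flat-scheme
#' E-score is 29 (cyst 8 + adhesion 7 + pain 8 + uterine 6).
#'
#' @return An `nmse_exam`.
#' @export
#' @examples
#' e_score(worked_example_exam())
worked_example_exam <- function() {
  patient_exam(
    patient_id = "example",
    right = ovary_finding("right", 6.5, "endometrioma"),
    left  = ovary_finding("left",  2.4, "endometrioma"),
    adhesions = adhesion_map(c("Rt.O-side", "Rt.O-Ut.", "Inter O-O",
                               "Lt.O-Ut.",
                               "Upper post.", "Mid.post.", "Lower post.")),
    pain = pain_map(c(3, 2, 0, 4, 8, 3, 2)),
    uterus = uterine_findings(adenomyosis = TRUE, nodules_cm = 2.6),
    rare = rare_site_findings())
}

pad_cell <- function(s, width = 12L) {
  s <- substr(s, 1L, width)
  formatC(s, width = width, flag = "-")
}

grid_lines <- function(cells, width = 12L) {
  stopifnot(length(cells) == 9L)
  m <- matrix(vapply(cells, pad_cell, "", width = width), 3, 3, byrow = TRUE)
  apply(m, 1L, paste, collapse = "|")
}

ovary_cell <- function(o) {
  s <- ""
  if (o$cyst_kind != "none") {
    pre <- if (o$cyst_kind == "other") o$cyst_label else ""
    s <- paste0(pre, formatC(o$cyst_diameter_cm, format = "f", digits = 1))
  }
  if (o$tubal_lesion != "none")
    s <- paste0(s, "(", tubal_abbrev(o), ")")
  s
}

tubal_abbrev <- function(o) {
  switch(o$tubal_lesion,
         hydrosalpinx = "h.s", pyosalpinx = "p.s",
         other = o$tubal_label, "")
}

#' Render the Physical Finding Map
#'
#' Draws the three 3x3 grids of the finding map as plain text: the
#' cross-sectional ultrasound view (cyst sizes in the outer cells of the
#' middle row, cross-sectional adhesion sites), the longitudinal view
#' (uterine lesion codes in the central cell, longitudinal adhesion sites),
#' and the pelvic pain map (one NRS value per region). Cells are fixed at
#' 12 characters so the rendering is deterministic.
#'
#' @param exam A valid [patient_exam()].
#' @return A single multi-line character string.
#' @export
#' @examples
#' cat(render_finding_map(worked_example_exam()))
render_finding_map <- function(exam) {
  stop_if_invalid(exam)
  a <- exam$adhesions
  mark <- function(site) if (a[[site]]) paste0(site, " +") else paste0(site, " -")
  ut_codes <- character()
  if (exam$uterus$retroverted) ut_codes <- c(ut_codes, "R")
  if (exam$uterus$adenomyosis) ut_codes <- c(ut_codes, "A")
  for (d in exam$uterus$nodules_cm)
    ut_codes <- c(ut_codes, paste0("E", formatC(d, format = "f", digits = 1)))
  if (exam$uterus$myoma) ut_codes <- c(ut_codes, "M")

  cross <- c("", mark("Inter O-O"), "",
             ovary_cell(exam$right), "Ut.", ovary_cell(exam$left),
             mark("Rt.O-side"), "", mark("Lt.O-Side"))
  cross[1] <- mark("Rt.O-Ut.")
  cross[3] <- mark("Lt.O-Ut.")
  long <- c(mark("Upper ant."), "", mark("Upper post."),
            mark("Mid. ant."), paste(ut_codes, collapse = ","), mark("Mid.post."),
            "", "", mark("Lower post."))
  p <- exam$pain
  painc <- function(r) sprintf("%s:%d", r, as.integer(p[[r]]))
  pgrid <- c(painc("I"), "", painc("VI"),
             painc("II"), painc("IV"), painc("VII"),
             painc("III"), painc("V"), "")
  paste(c("Cross-sectional view:", grid_lines(cross),
          "Longitudinal view:",    grid_lines(long),
          sprintf("Pain map (NRS, regions I-VII; %s):",
                  paste0("V=", canonical_pain_regions()[["V"]])),
          grid_lines(pgrid)),
        collapse = "\n")
}

#' @export
print.nmse_exam <- function(x, ...) {
  cat(sprintf("<nmse_exam> patient %s\n", x$patient_id))
  v <- validate_exam(x)
  if (length(v)) {
    cat("  INVALID:\n")
    cat(paste0("   - ", v, "\n"), sep = "")
  } else {
    cat(" ", serialize_summary(x), "\n")
  }
  invisible(x)
}
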