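# Cohort container and the flat CSV interchange schema.
#
# One row per patient; UTF-8, comma-separated, header required; cm fields
# to one decimal place; booleans as 0/1; multi-valued fields (nodule sizes,
# rare sites) semicolon-separated; missing outcomes empty.

#' Canonical cohort CSV column names
#'
#' @return Character vector with the exact header, in order: patient id,
#'   per-side cyst and tubal fields, the ten canonical adhesion sites, pain
#'   regions I-VII, uterine findings, rare sites, and the three outcome
#'   columns.
#' @export
cohort_columns <- function() {
  c("patient_id",
    "right_cyst_cm", "right_cyst_kind", "right_tubal",
    "left_cyst_cm", "left_cyst_kind", "left_tubal",
    canonical_adhesion_sites(),
    paste0("pain_", PAIN_NUMERALS),
    "ut_retroverted", "ut_adenomyosis", "ut_nodules_cm", "ut_myoma",
    "rare_sites",
    "duration_min", "blood_loss_ml", "rasrm_score")
}

#' Construct a cohort
#'
#' @param exams List of [patient_exam()] objects.
#' @param provenance Optional list recording how the cohort was produced
#'   (e.g. simulator seed and spec digest).
#' @return An object of class `nmse_cohort`.
#' @export
cohort <- function(exams = list(), provenance = NULL) {
  stopifnot(all(vapply(exams, inherits, TRUE, "nmse_exam")))
  structure(list(exams = exams, provenance = provenance),
            class = "nmse_cohort")
}

#' @export
length.nmse_cohort <- function(x) length(x$exams)

#' @export
print.nmse_cohort <- function(x, ...) {
  cat(sprintf("<nmse_cohort> %d patients\n", length(x)))
  if (!is.null(x$provenance$seed))
    cat(sprintf("  simulated (seed %s)\n", x$provenance$seed))
  invisible(x)
}

kind_token <- function(kind, label) {
  if (kind == "other") paste0("other:", label %||% "") else kind
}

parse_kind_token <- function(tok, kinds) {
  tok <- as.character(tok)
  if (is.na(tok) || tok %in% c("", "none")) return(list(kind = "none", label = NULL))
  if (tok %in% kinds) return(list(kind = tok, label = NULL))
  if (startsWith(tok, "other:"))
    return(list(kind = "other", label = substring(tok, 7)))
  stop(sprintf("unrecognised kind token '%s'", tok), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

exam_to_row <- function(exam) {
  ov <- function(o) list(
    cm = o$cyst_diameter_cm,
    kind = kind_token(o$cyst_kind, o$cyst_label),
    tubal = kind_token(o$tubal_lesion, o$tubal_label))
  r <- ov(exam$right); l <- ov(exam$left)
  oc <- exam$outcomes %||% outcomes()
  rare_tok <- vapply(exam$rare$sites, function(s)
    if (s == "other") paste0("other:", exam$rare$other_label %||% "") else s, "")
  row <- c(
    list(patient_id = exam$patient_id,
         right_cyst_cm = r$cm, right_cyst_kind = r$kind, right_tubal = r$tubal,
         left_cyst_cm = l$cm, left_cyst_kind = l$kind, left_tubal = l$tubal),
    as.list(as.integer(unclass(exam$adhesions))),
    as.list(as.integer(unclass(exam$pain))),
    list(ut_retroverted = as.integer(exam$uterus$retroverted),
         ut_adenomyosis = as.integer(exam$uterus$adenomyosis),
         ut_nodules_cm = paste(fmt_cm(exam$uterus$nodules_cm), collapse = ";"),
         ut_myoma = as.integer(exam$uterus$myoma),
         rare_sites = paste(rare_tok, collapse = ";"),
         duration_min = oc$duration_min,
         blood_loss_ml = oc$blood_loss_ml,
         rasrm_score = oc$rasrm_score))
  names(row) <- cohort_columns()
  row
}

row_to_exam <- function(row) {
  ov <- function(side, cm, kind, tubal) {
    k <- parse_kind_token(kind, CYST_KINDS)
    t <- parse_kind_token(tubal, TUBAL_KINDS)
    ovary_finding(side,
                  cyst_diameter_cm = ifelse(is.na(cm), 0, as.numeric(cm)),
                  cyst_kind = k$kind, cyst_label = k$label,
                  tubal_lesion = t$kind, tubal_label = t$label)
  }
  sites <- canonical_adhesion_sites()
  adh <- as.logical(as.integer(unlist(row[sites])))
  names(adh) <- sites
  pain_vals <- as.numeric(unlist(row[paste0("pain_", PAIN_NUMERALS)]))
  nod_tok <- as.character(row[["ut_nodules_cm"]])
  nodules <- if (is.na(nod_tok) || !nzchar(nod_tok)) numeric()
             else as.numeric(strsplit(nod_tok, ";", fixed = TRUE)[[1]])
  rare_txt <- as.character(row[["rare_sites"]])
  rare_sites <- character(); rare_other <- NULL
  if (!is.na(rare_txt) && nzchar(rare_txt)) {
    for (tok in strsplit(rare_txt, ";", fixed = TRUE)[[1]]) {
      if (startsWith(tok, "other:")) {
        rare_sites <- c(rare_sites, "other"); rare_other <- substring(tok, 7)
      } else rare_sites <- c(rare_sites, tok)
    }
  }
  oc_vals <- as.numeric(unlist(row[c("duration_min", "blood_loss_ml",
                                     "rasrm_score")]))
  oc <- if (all(is.na(oc_vals))) NULL
        else outcomes(oc_vals[1], oc_vals[2], oc_vals[3])
  patient_exam(
    patient_id = as.character(row[["patient_id"]]),
    right = ov("right", row[["right_cyst_cm"]], row[["right_cyst_kind"]],
               row[["right_tubal"]]),
    left = ov("left", row[["left_cyst_cm"]], row[["left_cyst_kind"]],
              row[["left_tubal"]]),
    adhesions = adhesion_map(adh),
    pain = pain_map(pain_vals),
    uterus = uterine_findings(as.integer(row[["ut_retroverted"]]) == 1L,
                              as.integer(row[["ut_adenomyosis"]]) == 1L,
                              nodules,
                              as.integer(row[["ut_myoma"]]) == 1L),
    rare = rare_site_findings(rare_sites, rare_other),
    outcomes = oc)
}

#' Convert a cohort to a data frame
#'
#' @param x An `nmse_cohort`.
#' @param ... Unused.
#' @return A `data.frame` in the canonical [cohort_columns()] schema.
#' @export
as.data.frame.nmse_cohort <- function(x, ...) {
  if (!length(x$exams)) {
    df <- as.data.frame(setNames(rep(list(character(0)),
                                     length(cohort_columns())),
                                 cohort_columns()),
                        check.names = FALSE)
    return(df)
  }
  rows <- lapply(x$exams, exam_to_row)
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' Write a cohort CSV
#'
#' @param x An `nmse_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "nmse_cohort"))
  df <- as.data.frame(x)
  cm_cols <- c("right_cyst_cm", "left_cyst_cm")
  for (cc in cm_cols) df[[cc]] <- fmt_cm(as.numeric(df[[cc]]))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Reads a cohort table in the canonical schema. In the default lenient
#' mode, rows whose exam fails validation are dropped with a per-row
#' warning and reported in the `rejected` attribute (row number +
#' violations); in strict mode any invalid row aborts the read. A missing
#' or renamed column is always a schema error naming the column.
#'
#' @param path CSV file path.
#' @param strict If `TRUE`, abort on the first invalid row instead of
#'   skipping it.
#' @return An `nmse_cohort`; attribute `rejected` holds a data frame of
#'   diagnostics for skipped rows (lenient mode).
#' @export
read_cohort_csv <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character",
                        fileEncoding = "UTF-8")
  want <- cohort_columns()
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop("cohort CSV schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), want)
  if (length(extra))
    stop("cohort CSV schema error: unknown column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  exams <- list()
  rejected <- list()
  for (i in seq_len(nrow(df))) {
    exam <- tryCatch(row_to_exam(as.list(df[i, , drop = FALSE])),
                     error = function(e) conditionMessage(e))
    viol <- if (is.character(exam)) exam else validate_exam(exam)
    if (length(viol)) {
      msg <- paste(viol, collapse = "; ")
      if (strict)
        stop(sprintf("row %d invalid: %s", i, msg), call. = FALSE)
      warning(sprintf("skipping row %d: %s", i, msg), call. = FALSE)
      rejected[[length(rejected) + 1L]] <-
        data.frame(row = i, violation = msg, stringsAsFactors = FALSE)
    } else {
      exams[[length(exams) + 1L]] <- exam
    }
  }
  out <- cohort(exams)
  attr(out, "rejected") <- if (length(rejected)) do.call(rbind, rejected)
                           else data.frame(row = integer(),
                                           violation = character())
  out
}
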