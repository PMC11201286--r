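# The one-line NMS-E summary notation (grammar "nmse-summary/1"):
#
#   Cy R<cyst>/L<cyst> | Ad<k>/10 | P<max>@<region> | Ut <elements> | \
#     Rare <sites> | E=<total>
#
# <cyst>     "-" when absent; otherwise the diameter to one decimal place,
#            prefixed by a one-letter initial for non-endometrioma cysts
#            (e.g. "d4.0" for a dermoid); a tubal lesion abbreviation in
#            parentheses may follow (hydrosalpinx "h.s", pyosalpinx "p.s").
# <k>        adhesion-positive site count out of 10.
# <max>      maximal NRS; <region> the numeral I-VII of the first region
#            attaining it ("-" when the maximum is 0).
# <elements> comma list drawn from R, A, E<size>, M (one E entry per
#            nodule); "-" when none.
# <sites>    comma list of rare-site names; "-" when none.
# E=<total>  the flat-scheme E-score, re-derivable from the other fields.
#
# An optional "[nmse-summary/1] " prefix carries the grammar version; the
# parser rejects any other bracketed version tag.

SUMMARY_VERSION <- "nmse-summary/1"

fmt_cm <- function(d) formatC(d, format = "f", digits = 1)

cyst_token <- function(o) {
  tok <- if (o$cyst_kind == "none") "-"
         else paste0(if (o$cyst_kind == "other") o$cyst_label else "",
                     fmt_cm(o$cyst_diameter_cm))
  if (o$tubal_lesion != "none")
    tok <- paste0(tok, "(", tubal_abbrev(o), ")")
  tok
}

#' Serialize an exam to the summary notation
#'
#' Condenses an examination into the canonical one-line summary (grammar
#' `nmse-summary/1`), akin to a TNM string: cyst sizes and tubal lesions
#' per side, adhesion count, maximal pain with its region numeral, uterine
#' lesion codes, rare sites, and the flat-scheme E-score total.
#'
#' @param exam A valid [patient_exam()].
#' @param version_prefix If `TRUE`, prepend the bracketed grammar version
#'   tag `[nmse-summary/1]`. Default `FALSE` (the bare canonical string).
#' @return A single-line character string.
#' @seealso [parse_summary()]
#' @export
#' @examples
#' serialize_summary(worked_example_exam())
#' # "Cy R6.5/L2.4 | Ad7/10 | P8@V | Ut A,E2.6 | Rare - | E=29"
serialize_summary <- function(exam, version_prefix = FALSE) {
  stop_if_invalid(exam)
  cy <- sprintf("Cy R%s/L%s", cyst_token(exam$right), cyst_token(exam$left))
  ad <- sprintf("Ad%d/10", adhesion_score(exam$adhesions))
  pmax <- pain_score(exam$pain)
  preg <- if (pmax == 0) "-" else
    PAIN_NUMERALS[which(unclass(exam$pain) == pmax)[1L]]
  pn <- sprintf("P%d@%s", pmax, preg)
  u <- exam$uterus
  el <- character()
  if (u$retroverted) el <- c(el, "R")
  if (u$adenomyosis) el <- c(el, "A")
  for (d in u$nodules_cm) el <- c(el, paste0("E", fmt_cm(d)))
  if (u$myoma) el <- c(el, "M")
  ut <- paste0("Ut ", if (length(el)) paste(el, collapse = ",") else "-")
  rs <- exam$rare$sites
  rtok <- vapply(rs, function(s)
    if (s == "other") exam$rare$other_label else s, "")
  rare <- paste0("Rare ", if (length(rtok)) paste(rtok, collapse = ",") else "-")
  tot <- sprintf("E=%d", e_score(exam, "flat3")$e_score)
  out <- paste(cy, ad, pn, ut, rare, tot, sep = " | ")
  if (version_prefix) out <- paste0("[", SUMMARY_VERSION, "] ", out)
  out
}

parse_fail <- function(part, what, text) {
  stop(sprintf("summary parse error in part %d (%s): '%s'", part, what, text),
       call. = FALSE)
}

parse_cyst_token <- function(tok, part) {
  out <- list(size = NA_real_, kind = "none", label = NULL,
              tubal = "none", tubal_label = NULL)
  m <- regmatches(tok, regexec("^(.*?)(\\(([^)]+)\\))?$", tok))[[1]]
  if (!length(m)) parse_fail(part, "cyst token", tok)
  body <- m[2]; tube <- m[4]
  if (!is.na(tube) && nzchar(tube)) {
    out$tubal <- switch(tube, "h.s" = "hydrosalpinx", "p.s" = "pyosalpinx",
                        "other")
    if (out$tubal == "other") out$tubal_label <- tube
  }
  if (body == "-") {
    out$size <- 0
  } else if (grepl("^[0-9]+\\.[0-9]$", body)) {
    out$kind <- "endometrioma"
    out$size <- as.numeric(body)
  } else if (grepl("^[A-Za-z][0-9]+\\.[0-9]$", body)) {
    out$kind <- "other"
    out$label <- substr(body, 1, 1)
    out$size <- as.numeric(substring(body, 2))
  } else parse_fail(part, "cyst token", tok)
  out
}

#' Parse a summary string
#'
#' Recovers the fields the summary notation encodes. Because the summary is
#' an aggregate, some information cannot be restored to a full exam: the
#' identity of the adherent sites (only their count is carried) and the full
#' pain map (only the maximum and its region) come back as summary-level
#' aggregates, and the result carries `complete = FALSE` to say so.
#'
#' The embedded `E=` total is recomputed from the parsed fields under the
#' flat scheme; a mismatch raises a consistency error, so tampered strings
#' do not parse.
#'
#' @param text A summary string in the `nmse-summary/1` dialect, with or
#'   without the bracketed version prefix.
#' @return An object of class `nmse_summary`: list with elements `right`,
#'   `left` (size/kind/label/tubal), `adhesion_count`, `pain_max`,
#'   `pain_region`, `uterus` (retroverted/adenomyosis/nodules_cm/myoma),
#'   `rare_sites`, `rare_other_label`, `e_total`, `version`, `complete`.
#' @export
#' @examples
#' parse_summary(serialize_summary(worked_example_exam()))
parse_summary <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  version <- SUMMARY_VERSION
  vm <- regmatches(text, regexec("^\\[([^]]+)\\] ", text))[[1]]
  if (length(vm)) {
    version <- vm[2]
    if (!identical(version, SUMMARY_VERSION))
      stop(sprintf("unknown summary grammar version '%s'", version),
           call. = FALSE)
    text <- sub("^\\[[^]]+\\] ", "", text)
  }
  parts <- strsplit(text, " | ", fixed = TRUE)[[1]]
  if (length(parts) != 6L)
    stop(sprintf("summary parse error: expected 6 ' | '-separated parts, got %d",
                 length(parts)), call. = FALSE)

  m <- regmatches(parts[1], regexec("^Cy R(.+)/L(.+)$", parts[1]))[[1]]
  if (!length(m)) parse_fail(1, "Cy section", parts[1])
  right <- parse_cyst_token(m[2], 1)
  left  <- parse_cyst_token(m[3], 1)

  m <- regmatches(parts[2], regexec("^Ad([0-9]+)/10$", parts[2]))[[1]]
  if (!length(m)) parse_fail(2, "Ad section", parts[2])
  adh <- as.integer(m[2])
  if (adh > 10) parse_fail(2, "adhesion count above 10", parts[2])

  m <- regmatches(parts[3], regexec("^P([0-9]+)@(I{1,3}|IV|V|VI|VII|-)$",
                                    parts[3]))[[1]]
  if (!length(m)) parse_fail(3, "P section", parts[3])
  pmax <- as.integer(m[2]); preg <- m[3]
  if (pmax > 10) parse_fail(3, "NRS above 10", parts[3])
  if ((pmax == 0) != (preg == "-"))
    parse_fail(3, "region '-' allowed iff maximum is 0", parts[3])

  if (!grepl("^Ut ", parts[4])) parse_fail(4, "Ut section", parts[4])
  ut <- list(retroverted = FALSE, adenomyosis = FALSE,
             nodules_cm = numeric(), myoma = FALSE)
  el <- substring(parts[4], 4)
  if (el != "-") {
    for (tok in strsplit(el, ",", fixed = TRUE)[[1]]) {
      if (tok == "R") ut$retroverted <- TRUE
      else if (tok == "A") ut$adenomyosis <- TRUE
      else if (tok == "M") ut$myoma <- TRUE
      else if (grepl("^E[0-9]+\\.[0-9]$", tok))
        ut$nodules_cm <- c(ut$nodules_cm, as.numeric(substring(tok, 2)))
      else parse_fail(4, sprintf("uterine element '%s'", tok), parts[4])
    }
  }

  if (!grepl("^Rare ", parts[5])) parse_fail(5, "Rare section", parts[5])
  rare_sites <- character(); rare_other <- NULL
  rtxt <- substring(parts[5], 6)
  if (rtxt != "-") {
    for (tok in strsplit(rtxt, ",", fixed = TRUE)[[1]]) {
      if (tok %in% setdiff(RARE_SITES, "other")) rare_sites <- c(rare_sites, tok)
      else { rare_sites <- c(rare_sites, "other"); rare_other <- tok }
    }
  }

  m <- regmatches(parts[6], regexec("^E=([0-9]+)$", parts[6]))[[1]]
  if (!length(m)) parse_fail(6, "E= section", parts[6])
  e_total <- as.integer(m[2])

  out <- structure(
    list(version = version, right = right, left = left,
         adhesion_count = adh, pain_max = pmax, pain_region = preg,
         uterus = ut, rare_sites = rare_sites,
         rare_other_label = rare_other,
         e_total = e_total, complete = FALSE),
    class = "nmse_summary")
  recomputed <- summary_flat3_total(out)
  if (recomputed != e_total)
    stop(sprintf(paste0("summary consistency error: E=%d but the encoded ",
                        "findings give %d under the flat scheme"),
                 e_total, recomputed), call. = FALSE)
  out
}

# Flat-scheme E-score recomputed from summary-level aggregates alone.
summary_flat3_total <- function(s) {
  side <- function(x) {
    sc <- if (x$kind == "endometrioma") min(5L, as.integer(ceiling(x$size))) else 0L
    sc + 3L * (x$tubal != "none")
  }
  u <- s$uterus
  ut <- 3L * (u$retroverted + u$adenomyosis + (length(u$nodules_cm) > 0))
  side(s$right) + side(s$left) + s$adhesion_count + s$pain_max + ut +
    10L * (length(s$rare_sites) > 0)
}

#' @export
print.nmse_summary <- function(x, ...) {
  cat(sprintf("<nmse_summary> (%s, aggregate-level)\n", x$version))
  cat(sprintf("  right cyst: %s %.1f cm; left cyst: %s %.1f cm\n",
              x$right$kind, x$right$size, x$left$kind, x$left$size))
  cat(sprintf("  adhesion sites: %d/10; max pain: %d at %s\n",
              x$adhesion_count, x$pain_max, x$pain_region))
  cat(sprintf("  E-score (flat scheme): %d\n", x$e_total))
  invisible(x)
}
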