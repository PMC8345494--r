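# Text normalization and tokenization for paramedic free-text reports.
#
# Reports are short, telegraphic, heavily abbreviated, and frequently typed
# in all caps. Normalization lower-cases, strips every symbol except '%'
# (and, by default, '&', which survives systematically in forms like "a&e"),
# and collapses whitespace. Symbols are replaced by a space, never elided:
# "c/o" must become "c o", not "co", so that whitespace tokenization yields
# the same units a clinician reading the report would.

#' Normalize raw report text
#'
#' Applies Unicode NFKC folding, lower-cases, replaces every character that
#' is not a lower-case letter, digit, `%` or (optionally) `&` with a single
#' space, collapses whitespace runs and trims. Digits are always retained.
#' Idempotent: normalizing already-normalized text is a no-op.
#'
#' @param text character vector of raw report text.
#' @param keep_ampersand keep `&` as a token character (default `TRUE`;
#'   abbreviations such as "a&e" are common in this register). Set `FALSE`
#'   to treat `&` like any other symbol.
#' @return character vector of normalized text; empty input gives `""`.
#' @examples
#' normalize_text("o/a- pt sitting conscious alert.")
#' normalize_text("usual bp @ 115/57")
#' @seealso [tokenize()]
#' @export
normalize_text <- function(text, keep_ampersand = TRUE) {
  x <- stringi::stri_trans_nfkc(as.character(text))
  x <- tolower(x)
  cls <- if (keep_ampersand) "[^a-z0-9%&]" else "[^a-z0-9%]"
  x <- gsub(cls, " ", x, perl = TRUE)
  x <- gsub(" +", " ", x, perl = TRUE)
  x <- trimws(x)
  x[is.na(text)] <- NA_character_
  x
}

#' Tokenize normalized text on single spaces
#'
#' @param normalized a single normalized string (see [normalize_text()]).
#' @return character vector of tokens; `character(0)` for empty input.
#' @examples
#' tokenize("given 300 mg aspirin")
#' @export
tokenize <- function(normalized) {
  stopifnot(length(normalized) == 1L)
  if (is.na(normalized) || !nzchar(normalized)) return(character(0))
  if (grepl("  |^ | $", normalized))
    stop("input is not normalized (stray whitespace); call normalize_text() first")
  strsplit(normalized, " ", fixed = TRUE)[[1L]]
}

#' Normalize and tokenize a set of raw reports
#'
#' Reports whose text is empty after normalization are dropped (mirroring
#' the exclusion of cases with missing text reports at corpus intake).
#'
#' @param reports data.frame with columns `report_id` and `text`.
#' @param keep_ampersand passed to [normalize_text()].
#' @return an [ems_corpus] of tokenized reports (no tags).
#' @export
preprocess_reports <- function(reports, keep_ampersand = TRUE) {
  stopifnot(is.data.frame(reports), all(c("report_id", "text") %in% names(reports)))
  norm <- normalize_text(reports$text, keep_ampersand = keep_ampersand)
  keep <- !is.na(norm) & nzchar(norm)
  if (any(!keep))
    message(sum(!keep), " report(s) empty after normalization; dropped")
  ems_corpus(lapply(which(keep), function(i) {
    list(report_id = as.character(reports$report_id[i]),
         tokens = tokenize(norm[i]), tags = NULL)
  }))
}

#' Filter a case registry down to usable reports
#'
#' Corpus intake step: keeps registry rows that resulted in a patient
#' encounter and whose free-text report is non-blank.
#'
#' @param registry data.frame with columns `report_id`, `text`, and logical
#'   `patient_encounter`.
#' @return the filtered data.frame.
#' @export
filter_registry <- function(registry) {
  stopifnot(is.data.frame(registry),
            all(c("report_id", "text", "patient_encounter") %in% names(registry)))
  txt <- as.character(registry$text)
  keep <- registry$patient_encounter & !is.na(txt) & nzchar(trimws(txt))
  registry[keep, , drop = FALSE]
}

#' Read raw reports from a text file
#'
#' Accepts either a two-column tab-delimited file (`report_id<TAB>text`) or a
#' plain file with one report per line (ids are generated).
#'
#' @param path file path.
#' @return data.frame with columns `report_id`, `text`.
#' @export
read_reports <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && all(grepl("\t", lines, fixed = TRUE))) {
    parts <- regmatches(lines, regexpr("\t", lines, fixed = TRUE), invert = TRUE)
    data.frame(report_id = vapply(parts, `[`, "", 1L),
               text = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(report_id = sprintf("report-%05d", seq_along(lines)),
               text = lines, stringsAsFactors = FALSE)
  }
}

#' Write reports to a two-column tab-delimited file
#'
#' @param reports data.frame with `report_id` and `text`, or an [ems_corpus]
#'   (tokens are joined with single spaces).
#' @param path file path.
#' @export
write_reports <- function(reports, path) {
  if (inherits(reports, "ems_corpus")) {
    reports <- data.frame(
      report_id = vapply(reports, `[[`, "", "report_id"),
      text = vapply(reports, function(r) paste(r$tokens, collapse = " "), ""),
      stringsAsFactors = FALSE)
  }
  writeLines(paste(reports$report_id, reports$text, sep = "\t"), path, useBytes = TRUE)
}
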