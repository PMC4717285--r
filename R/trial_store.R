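#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for the indexed facets.
TRIAL_PHASES <- c("I", "II", "III", "IV", "UNSPECIFIED")
TRIAL_TYPES <- c("TREATMENT", "PREVENTION", "DIAGNOSTIC", "SCREENING",
                 "SUPPORTIVE", "SURVEY")
SEX_ELIGIBILITY <- c("ANY", "FEMALE", "MALE")

## Field order for the JSONL corpus dialect; the writer always emits keys in
## this order so corpora diff cleanly.
TRIAL_FIELDS <- c("trial_id", "full_title", "phase", "trial_type",
                  "cancer_type", "min_age", "max_age", "sex_eligibility",
                  "locations", "uses_investigational_drug", "purpose_text",
                  "procedures_text", "eligibility_text")

#' Construct a clinical-trial record
#'
#' A `trial_record` bundles the seven indexed facets used for eligibility
#' filtering (age range, sex, cancer type, locations, trial type, phase,
#' investigational-drug flag) with the three free-text sections
#' (purpose, procedures, eligibility) used for display and for the
#' word-occurrence classifiers.
#'
#' @param trial_id Unique text identifier within a corpus.
#' @param full_title Full registry title (often long and technical).
#' @param phase One of `"I"`, `"II"`, `"III"`, `"IV"`, `"UNSPECIFIED"`.
#' @param trial_type One of `"TREATMENT"`, `"PREVENTION"`, `"DIAGNOSTIC"`,
#'   `"SCREENING"`, `"SUPPORTIVE"`, `"SURVEY"`.
#' @param cancer_type Display name from the corpus vocabulary, e.g.
#'   `"Lung Cancer"`.
#' @param min_age,max_age Inclusive age bounds in years; `min_age <= max_age`.
#' @param sex_eligibility `"ANY"`, `"FEMALE"` or `"MALE"`.
#' @param locations Character vector of region codes; empty means the trial is
#'   offered anywhere.
#' @param uses_investigational_drug Logical flag.
#' @param purpose_text,procedures_text,eligibility_text Free-text sections.
#' @return An object of class `trial_record`.
#' @examples
#' trial_record("NCT0001", "A Study of X in Lung Cancer", "II", "TREATMENT",
#'              "Lung Cancer", 18, 99)
#' @export
trial_record <- function(trial_id, full_title, phase, trial_type, cancer_type,
                         min_age, max_age, sex_eligibility = "ANY",
                         locations = character(),
                         uses_investigational_drug = FALSE,
                         purpose_text = "", procedures_text = "",
                         eligibility_text = "") {
  rec <- structure(
    list(trial_id = as.character(trial_id),
         full_title = as.character(full_title),
         phase = as.character(phase),
         trial_type = as.character(trial_type),
         cancer_type = as.character(cancer_type),
         min_age = as.integer(min_age),
         max_age = as.integer(max_age),
         sex_eligibility = as.character(sex_eligibility),
         locations = as.character(locations),
         uses_investigational_drug = isTRUE(uses_investigational_drug),
         purpose_text = as.character(purpose_text),
         procedures_text = as.character(procedures_text),
         eligibility_text = as.character(eligibility_text)),
    class = "trial_record")
  validate_trial_record(rec)
}

#' Validate a trial record's invariants
#'
#' @param rec A `trial_record`.
#' @param where Optional context (e.g. a line number) prepended to error
#'   messages.
#' @return `rec`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_trial_record <- function(rec, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(where, ": ")
  fail <- function(msg) stop(ctx, msg, call. = FALSE)
  if (!nzchar(rec$trial_id)) fail("trial_id must be non-empty")
  if (!rec$phase %in% TRIAL_PHASES)
    fail(sprintf("unknown phase '%s'", rec$phase))
  if (!rec$trial_type %in% TRIAL_TYPES)
    fail(sprintf("unknown trial_type '%s'", rec$trial_type))
  if (!rec$sex_eligibility %in% SEX_ELIGIBILITY)
    fail(sprintf("unknown sex_eligibility '%s'", rec$sex_eligibility))
  if (is.na(rec$min_age) || rec$min_age < 0L) fail("min_age must be >= 0")
  if (is.na(rec$max_age) || rec$min_age > rec$max_age)
    fail(sprintf("min_age (%d) exceeds max_age (%d) for trial '%s'",
                 rec$min_age, rec$max_age, rec$trial_id))
  if (!nzchar(rec$cancer_type)) fail("cancer_type must be non-empty")
  rec
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record %s> %s\n", x$trial_id, simplify_title(x)))
  cat(sprintf("  ages %d-%d, sex %s, locations: %s, investigational drug: %s\n",
              x$min_age, x$max_age, x$sex_eligibility,
              if (length(x$locations)) paste(x$locations, collapse = ",")
              else "anywhere",
              if (x$uses_investigational_drug) "yes" else "no"))
  invisible(x)
}

#' Parse a JSONL trial corpus
#'
#' Reads a corpus in the package's JSON Lines dialect: one trial record per
#' line, UTF-8, keys as in [trial_record()]. Records are returned in file
#' order and every record invariant is checked; the error message for a
#' malformed line names its line number.
#'
#' @param path Path to a `.jsonl` file, or a character vector of lines
#'   (anything with more than one element, or containing a newline, is
#'   treated as content rather than a path).
#' @return A list of `trial_record` objects.
#' @seealso [write_corpus()]
#' @export
parse_corpus <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && !grepl("[{]", path)) {
    if (!file.exists(path))
      stop(sprintf("corpus file not found: %s", path), call. = FALSE)
    readLines(path, warn = FALSE, encoding = "UTF-8")
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  seen <- character(0)
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) stop(sprintf("line %d: malformed JSON (%s)",
                                       i, conditionMessage(e)), call. = FALSE))
    missing <- setdiff(setdiff(TRIAL_FIELDS, "locations"), names(obj))
    if (length(missing))
      stop(sprintf("line %d: missing field(s) %s", i,
                   paste(missing, collapse = ", ")), call. = FALSE)
    rec <- tryCatch(
      trial_record(obj$trial_id, obj$full_title, obj$phase, obj$trial_type,
                   obj$cancer_type, obj$min_age, obj$max_age,
                   obj$sex_eligibility,
                   as.character(unlist(obj$locations)),
                   obj$uses_investigational_drug,
                   obj$purpose_text, obj$procedures_text,
                   obj$eligibility_text),
      error = function(e) stop(sprintf("line %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
    if (rec$trial_id %in% seen)
      stop(sprintf("line %d: duplicate trial_id '%s'", i, rec$trial_id),
           call. = FALSE)
    seen <- c(seen, rec$trial_id)
    records[[i]] <- rec
  }
  records
}

#' Write a trial corpus as JSON Lines
#'
#' @param records List of `trial_record` objects.
#' @param path Output path; if `NULL` the JSONL text is returned as a
#'   character vector of lines.
#' @return The path (or the lines when `path` is `NULL`), invisibly.
#' @export
write_corpus <- function(records, path = NULL) {
  lines <- vapply(records, function(rec) {
    stopifnot(inherits(rec, "trial_record"))
    x <- unclass(rec)[TRIAL_FIELDS]
    x$locations <- I(x$locations)  # keep [] even for 0/1 elements
    jsonlite::toJSON(x, auto_unbox = TRUE)
  }, character(1))
  if (is.null(path)) return(invisible(lines))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

titlecase <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' Simplified display title for a trial
#'
#' Registry titles are long and technical; the display title is rebuilt from
#' the phase, trial type and cancer type alone, e.g. a phase II treatment
#' study of a lung-cancer drug becomes `"Phase II Treatment Trial for Lung
#' Cancer"`. When the phase is unspecified the phase prefix is dropped.
#'
#' @param record A `trial_record`.
#' @return A one-line character string.
#' @examples
#' rec <- trial_record("t1", "A Study of BFTZ2252 ...", "II", "TREATMENT",
#'                     "Lung Cancer", 18, 99)
#' simplify_title(rec)
#' @export
simplify_title <- function(record) {
  type <- titlecase(record$trial_type)
  if (record$phase == "UNSPECIFIED") {
    sprintf("%s Trial for %s", type, record$cancer_type)
  } else {
    sprintf("Phase %s %s Trial for %s", record$phase, type,
            record$cancer_type)
  }
}

#' Staged detail view of a trial
#'
#' Trials are disclosed in three cumulative levels to limit reading burden:
#' level 1 shows the simplified title and eligibility criteria only, level 2
#' adds the research purpose, level 3 adds the study procedures. The sections
#' at each level are a prefix of those at the next.
#'
#' @param record A `trial_record`.
#' @param level Integer 1, 2 or 3.
#' @return A `detail_view`: list with `level`, `title` and `sections`
#'   (named list of section texts, in display order).
#' @export
detail_view <- function(record, level) {
  if (length(level) != 1L || !level %in% 1:3)
    stop("level must be 1, 2 or 3", call. = FALSE)
  sections <- list(Eligibility = record$eligibility_text)
  if (level >= 2) sections$Purpose <- record$purpose_text
  if (level >= 3) sections$Procedures <- record$procedures_text
  structure(list(level = as.integer(level),
                 title = simplify_title(record),
                 trial_id = record$trial_id,
                 sections = sections),
            class = "detail_view")
}

#' @export
print.detail_view <- function(x, ...) {
  cat(sprintf("%s  [detail level %d]\n", x$title, x$level))
  for (nm in names(x$sections))
    cat(sprintf("-- %s --\n%s\n", nm, x$sections[[nm]]))
  invisible(x)
}

#' Free text of a trial for classification
#'
#' The three free-text sections concatenated in purpose, procedures,
#' eligibility order — the text the subjective-attribute classifiers see.
#'
#' @param record A `trial_record`.
#' @return A single string.
#' @export
trial_text <- function(record) {
  paste(record$purpose_text, record$procedures_text, record$eligibility_text)
}
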