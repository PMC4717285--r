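## Facets in relaxation priority order: the least clinically constraining
## facets are offered for relaxation first.
RELAXATION_ORDER <- c("phase", "trial_type", "location",
                      "investigational_drug_ok", "cancer_type", "sex", "age")

#' Construct a faceted search query
#'
#' Any subset of the seven indexed facets may be set; an unset (`NULL`)
#' facet matches every trial.
#'
#' @param age Optional age in years of the prospective participant.
#' @param sex Optional `"FEMALE"` or `"MALE"`.
#' @param cancer_type Optional cancer-type display name.
#' @param location Optional region code, or `"ANYWHERE"` (matches all).
#' @param trial_type Optional trial-type enum value.
#' @param phase Optional phase enum value.
#' @param investigational_drug_ok Optional logical; `FALSE` excludes trials
#'   that use an investigational drug.
#' @return A `facet_query`.
#' @examples
#' facet_query(age = 70, cancer_type = "Breast Cancer",
#'             trial_type = "TREATMENT", location = "ANYWHERE")
#' @export
facet_query <- function(age = NULL, sex = NULL, cancer_type = NULL,
                        location = NULL, trial_type = NULL, phase = NULL,
                        investigational_drug_ok = NULL) {
  if (!is.null(sex) && !sex %in% c("FEMALE", "MALE"))
    stop("sex must be FEMALE or MALE", call. = FALSE)
  if (!is.null(phase) && !phase %in% TRIAL_PHASES)
    stop("unknown phase", call. = FALSE)
  if (!is.null(trial_type) && !trial_type %in% TRIAL_TYPES)
    stop("unknown trial_type", call. = FALSE)
  structure(list(age = age, sex = sex, cancer_type = cancer_type,
                 location = location, trial_type = trial_type, phase = phase,
                 investigational_drug_ok = investigational_drug_ok),
            class = "facet_query")
}

#' @export
print.facet_query <- function(x, ...) {
  set <- set_facets(x)
  if (!length(set)) {
    cat("<facet_query> (no facets set)\n")
  } else {
    cat("<facet_query>\n")
    for (f in set) cat(sprintf("  %s: %s\n", f, format(x[[f]])))
  }
  invisible(x)
}

#' Names of the facets set in a query
#' @param query A `facet_query`.
#' @return Character vector (possibly empty), in relaxation priority order.
#' @export
set_facets <- function(query) {
  RELAXATION_ORDER[!vapply(RELAXATION_ORDER, function(f)
    is.null(query[[f]]), logical(1))]
}

#' Does a trial match a faceted query?
#'
#' Every set facet must match: the age lies within the trial's inclusive
#' bounds; the sex matches when the trial accepts any sex or the same sex;
#' cancer type, trial type and phase match by equality; the location matches
#' when the query says anywhere, the trial is offered anywhere (empty
#' location set), or the code is among the trial's locations; and
#' `investigational_drug_ok = FALSE` excludes trials using an
#' investigational drug.
#'
#' @param record A `trial_record`.
#' @param query A `facet_query`.
#' @return Logical scalar.
#' @export
matches <- function(record, query) {
  q <- query
  if (!is.null(q$age) &&
      !(record$min_age <= q$age && q$age <= record$max_age)) return(FALSE)
  if (!is.null(q$sex) &&
      !(record$sex_eligibility == "ANY" || record$sex_eligibility == q$sex))
    return(FALSE)
  if (!is.null(q$cancer_type) && record$cancer_type != q$cancer_type)
    return(FALSE)
  if (!is.null(q$location) && q$location != "ANYWHERE" &&
      length(record$locations) > 0 && !q$location %in% record$locations)
    return(FALSE)
  if (!is.null(q$trial_type) && record$trial_type != q$trial_type)
    return(FALSE)
  if (!is.null(q$phase) && record$phase != q$phase) return(FALSE)
  if (isFALSE(q$investigational_drug_ok) && record$uses_investigational_drug)
    return(FALSE)
  TRUE
}

#' Filter a corpus by a faceted query
#'
#' @param corpus List of `trial_record`s.
#' @param query A `facet_query`.
#' @return The matching records, in corpus order.
#' @export
filter_trials <- function(corpus, query) {
  corpus[vapply(corpus, matches, logical(1), query = query)]
}

#' Desired levels of the inferred criteria
#'
#' @param pain,invasiveness,time_burden Optional desired level 0 (low),
#'   1 (medium) or 2 (high); unset preferences are ignored in ranking.
#' @return A `preferences` object.
#' @export
preferences <- function(pain = NULL, invasiveness = NULL, time_burden = NULL) {
  p <- list(pain = pain, invasiveness = invasiveness,
            time_burden = time_burden)
  for (f in names(p))
    if (!is.null(p[[f]]) && !p[[f]] %in% 0:2)
      stop("preference levels must be in 0..2", call. = FALSE)
  structure(p, class = "preferences")
}

#' Preference mismatch score of one trial
#'
#' Sum over the set preferences of the absolute distance between the trial's
#' inferred level and the desired level. Trials with no set preferences score
#' zero.
#'
#' @param inferred An `inferred_criteria` vector for the trial.
#' @param prefs A `preferences` object.
#' @return Non-negative integer.
#' @export
mismatch_score <- function(inferred, prefs) {
  score <- 0L
  for (f in CRITERIA_NAMES)
    if (!is.null(prefs[[f]]))
      score <- score + abs(as.integer(inferred[[f]]) - as.integer(prefs[[f]]))
  score
}

#' Rank trials by inferred-criteria preference fit
#'
#' Stable ascending sort by [mismatch_score()]; ties are broken by
#' `trial_id` ascending, so the ranking is a deterministic permutation of
#' the input.
#'
#' @param trials List of `trial_record`s (e.g. the output of
#'   [filter_trials()]).
#' @param prefs A `preferences` object.
#' @param inferred Named list `trial_id -> inferred_criteria` covering every
#'   listed trial (see [infer_corpus_criteria()]).
#' @return The reordered list of trials.
#' @export
rank_trials <- function(trials, prefs, inferred) {
  if (length(trials) == 0) return(trials)
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  miss <- setdiff(ids, names(inferred))
  if (length(miss))
    stop("missing inferred criteria for trial(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  scores <- vapply(ids, function(id) mismatch_score(inferred[[id]], prefs),
                   integer(1))
  trials[order(scores, ids, method = "radix")]
}

#' Suggest single-facet relaxations of a zero-result query
#'
#' When a search returns no (or no more) trials, each set facet is unset in
#' turn — in the fixed priority order phase, trial type, location,
#' investigational drug, cancer type, sex, age — and the relaxation is
#' suggested iff it yields at least one hit.
#'
#' @param query The current `facet_query`.
#' @param corpus List of `trial_record`s.
#' @return List of relaxations, each `list(dropped_facet, relaxed_query,
#'   hit_count)`.
#' @export
suggest_relaxations <- function(query, corpus) {
  out <- list()
  for (facet in set_facets(query)) {
    relaxed <- query
    relaxed[facet] <- list(NULL)
    hits <- length(filter_trials(corpus, relaxed))
    if (hits >= 1)
      out[[length(out) + 1L]] <- list(dropped_facet = facet,
                                      relaxed_query = relaxed,
                                      hit_count = hits)
  }
  out
}
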