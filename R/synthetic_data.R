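## Default marker-word pools: plausible clinical vocabulary whose occurrence
## in the free text signals the level of each subjective criterion. Pools are
## disjoint across levels (and across criteria, to avoid cross-talk); two
## words per level keeps every marker well represented even in small
## training sets. Purely illustrative and fully configurable.
DEFAULT_MARKER_POOLS <- list(
  pain = list(
    low = c("questionnaire", "telephone"),
    medium = c("injection", "infusion"),
    high = c("biopsy", "surgery")),
  invasiveness = list(
    low = c("survey", "interview"),
    medium = c("imaging", "endoscopy"),
    high = c("transplant", "resection")),
  time_burden = list(
    low = c("brief", "single"),
    medium = c("weekly", "monthly"),
    high = c("daily", "overnight")))

## Neutral filler used when no marker is planted (association draw fails).
NEUTRAL_FILLERS <- c("assessment", "consultation", "checkup", "evaluation")

DEFAULT_CANCER_TYPES <- c("Breast Cancer" = 0.20, "Lung Cancer" = 0.20,
                          "Prostate Cancer" = 0.15, "Colon Cancer" = 0.15,
                          "Leukemia" = 0.15, "Melanoma" = 0.15)
DEFAULT_PHASE_WEIGHTS <- c(I = 0.20, II = 0.30, III = 0.25, IV = 0.10,
                           UNSPECIFIED = 0.15)
DEFAULT_TYPE_WEIGHTS <- c(TREATMENT = 0.40, PREVENTION = 0.15,
                          DIAGNOSTIC = 0.15, SCREENING = 0.10,
                          SUPPORTIVE = 0.10, SURVEY = 0.10)
REGION_CODES <- c("US-NE", "US-SE", "US-MW", "US-SW", "US-W")

## Evaluate expr with the global RNG seeded to `seed`, restoring the prior
## RNG state afterwards, so generators are pure functions of their config.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic trial-corpus generator
#'
#' @param n_trials Number of trials to generate.
#' @param seed Integer seed; the generator is a pure function of its config.
#' @param cancer_types,phase_weights,type_weights Named non-negative weights
#'   over the categorical facets (normalized internally).
#' @param marker_pools Per criterion, a list of `low`/`medium`/`high` word
#'   pools, disjoint across levels of the same criterion.
#' @param association_strength Probability that a trial's text contains a
#'   marker word from the pool of its true level for each criterion.
#' @param label_noise Probability that the emitted gold label is flipped to
#'   a uniformly chosen *other* level (the text keeps its true-level marker).
#' @return A validated `corpus_config`.
#' @export
corpus_config <- function(n_trials = 200L, seed = 1L,
                          cancer_types = DEFAULT_CANCER_TYPES,
                          phase_weights = DEFAULT_PHASE_WEIGHTS,
                          type_weights = DEFAULT_TYPE_WEIGHTS,
                          marker_pools = DEFAULT_MARKER_POOLS,
                          association_strength = 1.0,
                          label_noise = 0.0) {
  if (n_trials < 0) stop("n_trials must be >= 0", call. = FALSE)
  if (association_strength < 0 || association_strength > 1)
    stop("association_strength must be in [0,1]", call. = FALSE)
  if (label_noise < 0 || label_noise > 1)
    stop("label_noise must be in [0,1]", call. = FALSE)
  for (crit in CRITERIA_NAMES) {
    pools <- marker_pools[[crit]]
    if (is.null(pools) || !all(c("low", "medium", "high") %in% names(pools)))
      stop("marker_pools must define low/medium/high pools for ", crit,
           call. = FALSE)
    words <- unlist(pools)
    if (anyDuplicated(words))
      stop("marker pools for ", crit, " must be disjoint across levels",
           call. = FALSE)
  }
  for (w in list(cancer_types, phase_weights, type_weights))
    if (any(w < 0) || sum(w) <= 0)
      stop("categorical weights must be non-negative and sum > 0",
           call. = FALSE)
  structure(list(n_trials = as.integer(n_trials), seed = as.integer(seed),
                 cancer_types = cancer_types / sum(cancer_types),
                 phase_weights = phase_weights / sum(phase_weights),
                 type_weights = type_weights / sum(type_weights),
                 marker_pools = marker_pools,
                 association_strength = association_strength,
                 label_noise = label_noise),
            class = "corpus_config")
}

sample_weighted <- function(values, weights) {
  values[sample.int(length(values), 1L, prob = weights)]
}

## Sentence templates per free-text field; %s receives the embedded word.
## Mixed case, punctuation and hyphens keep tokenization honest.
PURPOSE_TEMPLATES <- c(
  "The purpose of this study is to evaluate a new %s-based protocol.",
  "This trial studies how well a %s approach works; results guide follow-up care.",
  "Researchers want to learn whether a %s component improves outcomes.")
PROCEDURES_TEMPLATES <- c(
  "Participants will undergo a %s at each study visit.",
  "The protocol includes a scheduled %s, with pre-visit preparation.",
  "Study staff will perform a %s during follow-up.")
ELIGIBILITY_TEMPLATES <- c(
  "Eligible patients agree to %s participation requirements.",
  "Enrollment requires consent to %s study contact.",
  "Candidates must accept the %s schedule described by the coordinator.")

## Which free-text field carries each criterion's marker.
CRITERION_FIELD <- c(pain = "procedures", invasiveness = "purpose",
                     time_burden = "eligibility")

make_field_text <- function(field, word) {
  tmpl <- switch(field,
                 purpose = PURPOSE_TEMPLATES,
                 procedures = PROCEDURES_TEMPLATES,
                 eligibility = ELIGIBILITY_TEMPLATES)
  sprintf(sample(tmpl, 1L), word)
}

flip_label <- function(level) {
  others <- setdiff(0:2, level)
  others[sample.int(2L, 1L)]
}

#' Generate a synthetic trial corpus with planted label signals
#'
#' Facets are sampled from the configured categorical weights. For each trial
#' and each criterion a true level is drawn uniformly; with probability
#' `association_strength` a marker word from that level's pool is embedded in
#' the criterion's free-text field (otherwise a neutral filler is used), and
#' with probability `label_noise` the *emitted* gold label is flipped to a
#' random other level. The generator is deterministic given its config and
#' consumes one pseudo-random stream in a fixed per-trial field order.
#'
#' @param config A `corpus_config`.
#' @return List with `records` (list of `trial_record`) and `gold` (data
#'   frame `trial_id`, `pain`, `invasiveness`, `time_burden` of emitted
#'   labels).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  with_local_seed(config$seed, {
    n <- config$n_trials
    records <- vector("list", n)
    gold <- data.frame(trial_id = character(n), pain = integer(n),
                       invasiveness = integer(n), time_burden = integer(n),
                       stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      id <- sprintf("SYN-%05d", i)
      cancer <- sample_weighted(names(config$cancer_types),
                                config$cancer_types)
      phase <- sample_weighted(names(config$phase_weights),
                               config$phase_weights)
      type <- sample_weighted(names(config$type_weights),
                              config$type_weights)
      min_age <- sample(c(18L, 18L, 18L, 30L, 40L, 50L), 1L)
      max_age <- min(99L, min_age + sample(20:60, 1L))
      sex <- sample_weighted(SEX_ELIGIBILITY, c(0.8, 0.1, 0.1))
      locs <- if (stats::runif(1) < 0.3) character(0)
              else sample(REGION_CODES, sample(1:3, 1L))
      drug <- stats::runif(1) < 0.4
      texts <- list(purpose = "", procedures = "", eligibility = "")
      for (crit in CRITERIA_NAMES) {
        true_level <- sample(0:2, 1L)
        pools <- config$marker_pools[[crit]]
        word <- if (stats::runif(1) < config$association_strength)
          sample(pools[[true_level + 1L]], 1L)
        else sample(NEUTRAL_FILLERS, 1L)
        field <- CRITERION_FIELD[[crit]]
        texts[[field]] <- make_field_text(field, word)
        emitted <- if (stats::runif(1) < config$label_noise)
          flip_label(true_level) else true_level
        gold[i, crit] <- emitted
      }
      gold$trial_id[i] <- id
      records[[i]] <- trial_record(
        id, sprintf("A Study of Agent SYN-%d in Subjects With %s", i, cancer),
        phase, type, cancer, min_age, max_age, sex, locs, drug,
        purpose_text = texts$purpose,
        procedures_text = texts$procedures,
        eligibility_text = texts$eligibility)
    }
    list(records = records, gold = gold)
  })
}

#' Generate a labeled training set for one criterion
#'
#' Draws `(text, label)` pairs by the corpus mechanism. The text is the
#' free-text section that carries the criterion's signal (procedures for
#' pain, purpose for invasiveness, eligibility for time burden) — the
#' section a human rater would score for that attribute — and the label is
#' the emitted gold level. Trees trained on these examples apply unchanged
#' to whole trials, since the section's words occur in the concatenated
#' trial text.
#'
#' @param config A `corpus_config` (`n_trials` gives the number of examples).
#' @param criterion `"pain"`, `"invasiveness"` or `"time_burden"`.
#' @return Data frame with columns `text`, `label` (integer 0..2).
#' @export
generate_training_set <- function(config, criterion) {
  stopifnot(criterion %in% CRITERIA_NAMES)
  out <- generate_corpus(config)
  field <- paste0(CRITERION_FIELD[[criterion]], "_text")
  data.frame(text = vapply(out$records, `[[`, character(1), field),
             label = out$gold[[criterion]],
             stringsAsFactors = FALSE)
}

#' Configuration for the simulated two-arm experiment generator
#'
#' Defaults encode a two-arm comparison of a conversational search interface
#' ("agent") against a conventional one ("control") with the analyzable
#' sample sizes and task-2 outcome rates of the motivating experiment:
#' 42 vs 45 participants, completion 0.86/0.80, declared-found 0.48/0.40,
#' found-correct 0.43/0.31, and 7-point satisfaction ratings centered near
#' 4.8 (agent) and 3.2 (control).
#'
#' @param n_per_arm Named integer vector, participants per arm.
#' @param p_completed,p_declared,p_correct Named per-arm success
#'   probabilities.
#' @param rating_probs Named list of per-arm probability vectors over the
#'   1..7 rating scale (normalized internally).
#' @param seed Integer seed.
#' @return A validated `rct_config`.
#' @export
rct_config <- function(n_per_arm = c(agent = 42L, control = 45L),
                       p_completed = c(agent = 0.86, control = 0.80),
                       p_declared = c(agent = 0.48, control = 0.40),
                       p_correct = c(agent = 0.43, control = 0.31),
                       rating_probs = list(
                         agent = c(0.02, 0.04, 0.10, 0.18, 0.26, 0.24, 0.16),
                         control = c(0.14, 0.22, 0.22, 0.18, 0.12, 0.08, 0.04)),
                       seed = 1L) {
  arms <- names(n_per_arm)
  if (is.null(arms) || any(!nzchar(arms)))
    stop("n_per_arm must be a named vector of arm sizes", call. = FALSE)
  for (p in list(p_completed, p_declared, p_correct)) {
    if (!all(arms %in% names(p)))
      stop("success probabilities must name every arm", call. = FALSE)
    if (any(p < 0 | p > 1))
      stop("probabilities must be in [0,1]", call. = FALSE)
  }
  if (!all(arms %in% names(rating_probs)))
    stop("rating_probs must name every arm", call. = FALSE)
  rating_probs <- lapply(rating_probs, function(p) {
    if (length(p) != 7 || any(p < 0) || sum(p) <= 0)
      stop("each rating distribution is 7 non-negative weights",
           call. = FALSE)
    p / sum(p)
  })
  structure(list(n_per_arm = n_per_arm, p_completed = p_completed,
                 p_declared = p_declared, p_correct = p_correct,
                 rating_probs = rating_probs, seed = as.integer(seed)),
            class = "rct_config")
}

#' Simulate per-participant outcomes of a two-arm experiment
#'
#' One row per participant with independent draws: completion, declared
#' trial-found, correct trial-found (Bernoulli at the arm's configured
#' rates) and a 7-point satisfaction rating from the arm's discrete
#' distribution. Deterministic given the config seed.
#'
#' @param config An `rct_config`.
#' @return Data frame with columns `arm`, `completed`, `declared_found`,
#'   `found_correct`, `rating_satisfaction`.
#' @export
generate_rct_outcomes <- function(config) {
  stopifnot(inherits(config, "rct_config"))
  with_local_seed(config$seed, {
    rows <- lapply(names(config$n_per_arm), function(arm) {
      n <- config$n_per_arm[[arm]]
      if (n == 0) return(NULL)
      data.frame(
        arm = rep(arm, n),
        completed = stats::runif(n) < config$p_completed[[arm]],
        declared_found = stats::runif(n) < config$p_declared[[arm]],
        found_correct = stats::runif(n) < config$p_correct[[arm]],
        rating_satisfaction = sample(1:7, n, replace = TRUE,
                                     prob = config$rating_probs[[arm]]),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(arm = character(0), completed = logical(0),
                        declared_found = logical(0),
                        found_correct = logical(0),
                        rating_satisfaction = integer(0),
                        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
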