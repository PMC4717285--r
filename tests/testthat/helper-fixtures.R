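# Shared fixtures, built in code.

# Ten hand-written records covering the facet space.
fixture_corpus <- function() {
  list(
    trial_record("T001", "A Study of BFTZ2252 With Patanobib in NSCLC",
                 "II", "TREATMENT", "Lung Cancer", 18, 99, "ANY",
                 character(0), TRUE,
                 "Tests a new drug combination.",
                 "Participants will undergo a biopsy at each visit.",
                 "Adults with confirmed lung cancer."),
    trial_record("T002", "Mindfulness Survey in Breast Cancer Survivors",
                 "UNSPECIFIED", "SURVEY", "Breast Cancer", 18, 99, "FEMALE",
                 c("US-NE"), FALSE,
                 "Collects quality-of-life data.",
                 "A brief questionnaire by telephone.",
                 "Women previously treated for breast cancer."),
    trial_record("T003", "Phase III Letrozole Extension", "III", "TREATMENT",
                 "Breast Cancer", 40, 80, "ANY", character(0), FALSE,
                 "Compares extended hormone therapy with placebo.",
                 "Daily tablets and monthly blood draws.",
                 "Postmenopausal patients aged 40 to 80."),
    trial_record("T004", "Screening Colonoscopy Intervals", "UNSPECIFIED",
                 "SCREENING", "Colon Cancer", 50, 75, "ANY",
                 c("US-SE", "US-MW"), FALSE,
                 "Compares screening schedules.",
                 "A colonoscopy every five or ten years.",
                 "Adults 50-75 at average risk."),
    trial_record("T005", "Vaccine Prevention Study", "III", "PREVENTION",
                 "Melanoma", 18, 65, "ANY", c("US-W"), TRUE,
                 "Tests a preventive vaccine.",
                 "Monthly injection visits for one year.",
                 "Adults with a family history of melanoma."),
    trial_record("T006", "Imaging Diagnostic Accuracy", "I", "DIAGNOSTIC",
                 "Prostate Cancer", 45, 99, "MALE", character(0), FALSE,
                 "Evaluates a new imaging tracer.",
                 "A single PET-CT imaging session.",
                 "Men with elevated PSA."),
    trial_record("T007", "Supportive Care for Leukemia", "II", "SUPPORTIVE",
                 "Leukemia", 18, 99, "ANY", c("US-NE", "US-SW"), FALSE,
                 "Studies symptom management.",
                 "Weekly counseling by telephone.",
                 "Patients in active leukemia treatment."),
    trial_record("T008", "Phase II Breast Treatment", "II", "TREATMENT",
                 "Breast Cancer", 18, 65, "ANY", character(0), TRUE,
                 "Tests an investigational antibody.",
                 "An infusion every three weeks; surgery if needed.",
                 "Patients aged 18 to 65 with measurable disease."),
    trial_record("T009", "Geriatric Oncology Registry", "UNSPECIFIED",
                 "SURVEY", "Lung Cancer", 70, 99, "ANY", character(0), FALSE,
                 "Observational registry of older adults.",
                 "An interview at enrollment and yearly follow-up.",
                 "Adults 70 and older with lung cancer."),
    trial_record("T010", "Phase IV Safety Follow-up", "IV", "TREATMENT",
                 "Breast Cancer", 18, 99, "ANY", c("US-MW"), FALSE,
                 "Long-term safety follow-up of an approved drug.",
                 "Records review and a yearly checkup.",
                 "Patients who completed the parent study."))
}

# Independent brute-force predicate, written directly from the matching
# rules (the oracle filter_trials is compared against).
oracle_matches <- function(rec, q) {
  ok <- TRUE
  if (!is.null(q$age)) ok <- ok && (q$age >= rec$min_age && q$age <= rec$max_age)
  if (!is.null(q$sex)) ok <- ok && (rec$sex_eligibility %in% c("ANY", q$sex))
  if (!is.null(q$cancer_type)) ok <- ok && (rec$cancer_type == q$cancer_type)
  if (!is.null(q$location) && q$location != "ANYWHERE")
    ok <- ok && (length(rec$locations) == 0 || q$location %in% rec$locations)
  if (!is.null(q$trial_type)) ok <- ok && (rec$trial_type == q$trial_type)
  if (!is.null(q$phase)) ok <- ok && (rec$phase == q$phase)
  if (identical(q$investigational_drug_ok, FALSE))
    ok <- ok && !rec$uses_investigational_drug
  ok
}

# Random facet query with each facet independently set or unset.
random_query <- function(corpus) {
  maybe <- function(x, p = 0.4) if (stats::runif(1) < p) x else NULL
  cancers <- unique(vapply(corpus, `[[`, character(1), "cancer_type"))
  facet_query(
    age = maybe(sample(18:90, 1)),
    sex = maybe(sample(c("FEMALE", "MALE"), 1)),
    cancer_type = maybe(sample(cancers, 1)),
    location = maybe(sample(c("ANYWHERE", "US-NE", "US-SE", "US-MW",
                              "US-SW", "US-W"), 1)),
    trial_type = maybe(sample(c("TREATMENT", "PREVENTION", "DIAGNOSTIC",
                                "SCREENING", "SUPPORTIVE", "SURVEY"), 1)),
    phase = maybe(sample(c("I", "II", "III", "IV"), 1)),
    investigational_drug_ok = maybe(sample(c(TRUE, FALSE), 1)))
}

# Accuracy of a trained tree on a held-out labeled set.
holdout_accuracy <- function(tree, holdout) {
  preds <- vapply(holdout$text, function(t) classify(tree, t), integer(1),
                  USE.NAMES = FALSE)
  mean(preds == holdout$label)
}

# A minimal valid two-state script.
tiny_script_yaml <- function() {
  paste(
    "start: greet",
    "templates:",
    "  greet: 'Hello {name}.'",
    "  bye: 'Goodbye.'",
    "states:",
    "  greet:",
    "    template: greet",
    "    choices:",
    "      - label: Bye",
    "        target: end",
    "  end:",
    "    template: bye",
    "    terminal: true",
    sep = "\n")
}

default_fixture_session <- function(n_trials = 30, seed = 3,
                                    name = "Rosa") {
  script <- load_script(default_script_path())
  gen <- generate_corpus(corpus_config(n_trials = n_trials, seed = seed))
  lex <- read_lexicon(default_lexicon_path())
  new_session(script, gen$records, lexicon = lex, user_name = name)
}

# Random walk helper: returns list(session, choices, turns, violations).
# Checks the presentation-safety, staged-disclosure and bookmark invariants
# at every step.
random_walk <- function(session, max_turns = 500) {
  choices <- integer(0)
  seen_levels <- list()
  n <- 0
  while (!is_terminal(session) && n < max_turns) {
    k <- length(current_turn(session)$choices)
    i <- sample.int(k, 1)
    session <- advance(session, i)
    choices <- c(choices, i)
    n <- n + 1
    st <- session$state
    if (st %in% c("present1", "present2", "present3")) {
      id <- session$current_trial
      rec <- session$corpus[[match(id, session$corpus_ids)]]
      if (!matches(rec, session$active_query))
        stop("presented trial violates confirmed criteria")
      level <- as.integer(substr(st, 8, 8))
      prior <- seen_levels[[id]] %||% integer(0)
      if (level > 1 && !all(seq_len(level - 1) %in% prior))
        stop("level ", level, " shown before earlier levels")
      seen_levels[[id]] <- union(prior, level)
    }
    if (!all(session$bookmarks %in% session$trials_viewed))
      stop("bookmark of an unviewed trial")
  }
  list(session = session, choices = choices, turns = n,
       terminated = is_terminal(session))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
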