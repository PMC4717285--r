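test_that("script loading validates structure and names offenders", {
  s <- load_script(tiny_script_yaml())
  expect_s3_class(s, "dialog_script")
  expect_identical(s$start, "greet")

  dangling <- sub("target: end", "target: nowhere", tiny_script_yaml())
  expect_error(load_script(dangling), "nowhere")

  badtmpl <- sub("template: bye", "template: missing", tiny_script_yaml())
  expect_error(load_script(badtmpl), "missing")

  noterm <- sub("    terminal: true", "", tiny_script_yaml())
  expect_error(load_script(noterm), "choices|terminal")
})

test_that("the shipped default script covers the full session flow", {
  s <- load_script(default_script_path())
  expect_true(all(c("greet", "tutorial_offer", "ask_cancer", "ask_age",
                    "confirm", "results", "present1", "present2",
                    "present3", "dictionary", "summary", "farewell")
                  %in% names(s$states)))
  expect_true(isTRUE(s$states$farewell$terminal))
  expect_identical(s$subnetworks$education, "edu_voluntary")
})

test_that("template rendering fills every slot or fails loudly", {
  expect_identical(render_template("Hello {name}.", list(name = "Rosa")),
                   "Hello Rosa.")
  expect_identical(render_template("I found {n} trials.", list(n = 0)),
                   "I found 0 trials.")
  expect_error(render_template("Hi {who}.", list(name = "x")), "who")
})

test_that("difficult terms are extracted longest-match, deduplicated, in order", {
  lex <- c(placebo = "a treatment with no medicine",
           metastatic = "cancer that has spread",
           "investigational drug" = "a drug still being tested")
  got <- extract_difficult_terms(
    "A placebo-controlled study of metastatic disease.", lex)
  expect_identical(got$term, c("placebo", "metastatic"))

  # multi-word terms match before their single-word prefixes would
  got <- extract_difficult_terms(
    "Uses an Investigational Drug; the investigational drug is new.", lex)
  expect_identical(got$term, "investigational drug")

  expect_identical(nrow(extract_difficult_terms("anything",
                                                character(0))), 0L)
  expect_identical(nrow(extract_difficult_terms("", lex)), 0L)
})

test_that("lexicon files reject duplicate terms", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("term,definition", "Biopsy,a", "biopsy,b"), path)
  expect_error(read_lexicon(path), "duplicate")
})

test_that("interview choices fill facet slots and search respects them", {
  s <- default_fixture_session()
  expect_identical(s$state, "greet")
  s <- advance(s, 1)  # get started
  s <- advance(s, 2)  # skip tutorial
  expect_identical(s$state, "ask_cancer")
  labels <- vapply(current_turn(s)$choices, `[[`, character(1), "label")
  pick <- match("Breast Cancer", labels)
  s <- advance(s, pick)
  expect_identical(s$model$query$cancer_type, "Breast Cancer")
  expect_identical(s$state, "ask_age")
  s <- advance(s, 5)  # about 70
  expect_identical(s$model$query$age, 70L)
  s <- advance(s, 3)  # any sex
  expect_null(s$model$query$sex)
  s <- advance(s, 1)  # anywhere
  s <- advance(s, 1)  # treatment
  s <- advance(s, 5)  # any phase
  s <- advance(s, 3)  # drug: not sure
  s <- advance(s, 1)  # low pain preference
  expect_identical(s$model$prefs$pain, 0L)
  s <- advance(s, 4); s <- advance(s, 4)  # no inv/time preference
  expect_identical(s$state, "confirm")

  # accept -> search; every presented trial must satisfy the criteria
  s <- advance(s, 1)
  expect_identical(s$state, "results")
  expect_gt(length(s$results), 0)
  s <- advance(s, 1)  # present first trial
  rec <- s$corpus[[match(s$current_trial, s$corpus_ids)]]
  expect_true(matches(rec, s$model$query))
  expect_identical(s$trials_viewed, s$current_trial)

  # staged disclosure through the levels, then bookmark at level 3
  s <- advance(s, 1)
  expect_identical(s$state, "present2")
  s <- advance(s, 1)
  expect_identical(s$state, "present3")
  labels <- vapply(current_turn(s)$choices, `[[`, character(1), "label")
  s <- advance(s, grep("^Save this trial", labels))
  expect_identical(s$bookmarks, s$trials_viewed[1])
  expect_identical(s$state, "confirm")
})

test_that("out-of-range and post-terminal advances are errors", {
  s <- default_fixture_session()
  expect_error(advance(s, 99), "out of range")
  expect_error(advance(s, 0), "out of range")
})

test_that("criteria confirmation lists set facets with revision choices", {
  s <- default_fixture_session()
  cc <- confirm_criteria(s)
  expect_identical(nrow(cc$display), 0L)
  expect_length(cc$choices, 1L)  # accept only when nothing is set

  s$model$query <- facet_query(age = 70, cancer_type = "Breast Cancer")
  cc <- confirm_criteria(s)
  expect_identical(nrow(cc$display), 2L)
  expect_length(cc$choices, 3L)  # accept + one revision per set facet

  # revising through the dialog returns to the confirmation state
  s <- default_fixture_session()
  s <- replay_choices(s, c(1, 2))        # to ask_cancer
  s <- replay_choices(s, c(1, 5, 3, 1, 1, 5, 3, 4, 4, 4))  # to confirm
  expect_identical(s$state, "confirm")
  labels <- vapply(current_turn(s)$choices, `[[`, character(1), "label")
  i <- grep("Change the cancer type", labels)
  s <- advance(s, i)
  expect_identical(s$state, "ask_cancer")
  s <- advance(s, 2)  # pick a different cancer
  expect_identical(s$state, "confirm")
})

test_that("session summaries list viewed trials with bookmark flags", {
  s <- default_fixture_session()
  expect_identical(nrow(session_summary(s)), 0L)

  s$trials_viewed <- c("SYN-00001", "SYN-00002", "SYN-00003")
  s$bookmarks <- "SYN-00002"
  summ <- session_summary(s)
  expect_identical(summ$trial_id, s$trials_viewed)
  expect_identical(summ$bookmarked, c(FALSE, TRUE, FALSE))

  s <- toggle_bookmark(s, "SYN-00002")
  expect_identical(session_summary(s)$bookmarked, rep(FALSE, 3))
  expect_error(toggle_bookmark(s, "SYN-09999"), "viewed")
})

test_that("random walks terminate with all safety invariants holding", {
  script <- load_script(default_script_path())
  gen <- generate_corpus(corpus_config(n_trials = 30, seed = 3))
  lex <- read_lexicon(default_lexicon_path())
  for (seed in 1:30) {
    set.seed(seed)
    s <- new_session(script, gen$records, lexicon = lex)
    walk <- random_walk(s)
    expect_true(walk$terminated)
    expect_lte(walk$turns, 500)
  }
})

test_that("replaying a recorded choice sequence reproduces the transcript", {
  script <- load_script(default_script_path())
  gen <- generate_corpus(corpus_config(n_trials = 30, seed = 3))
  lex <- read_lexicon(default_lexicon_path())
  set.seed(99)
  s1 <- new_session(script, gen$records, lexicon = lex)
  walk <- random_walk(s1)
  s2 <- replay_choices(new_session(script, gen$records, lexicon = lex),
                       walk$choices)
  expect_identical(transcript_jsonl(walk$session), transcript_jsonl(s2))
  expect_identical(walk$session$bookmarks, s2$bookmarks)
})

test_that("education subnetworks return to the interrupted flow", {
  s <- default_fixture_session()
  s <- advance(s, 1)  # get started
  s <- advance(s, 1)  # yes, explain trials -> subnetwork
  expect_identical(s$state, "edu_voluntary")
  s <- advance(s, 1)  # what about risks
  expect_identical(s$state, "edu_risk")
  s <- advance(s, 1)  # pop back into the interview
  expect_identical(s$state, "ask_cancer")
})
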