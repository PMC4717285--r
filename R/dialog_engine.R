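## Augmented-transition-network dialog manager.
##
## A DialogScript is a set of named states. Each state renders one agent
## turn (a template-generated utterance, an optional display, and a
## multiple-choice menu) and each choice carries actions (facet slot-fills,
## search, bookmarking, subnetwork calls) plus a target state. Menus are
## either static (listed in the YAML) or produced by a named provider for
## menus that depend on the corpus or session (facet values, search-result
## options, criteria confirmation, query relaxations). Education modules are
## subnetworks entered through a call stack and left via the "@pop" target.

MENU_PROVIDERS <- c("facet", "pref", "confirm", "results", "present")

#' Load and validate a dialog script
#'
#' Scripts are YAML with `start`, `templates` (id -> text with `{slot}`
#' markers), `facet_states` (facet -> interview state, used to build
#' revision menus), `states` and optional `subnetworks` (named sub-scripts
#' whose states are merged; their exit arcs use the special target
#' `"@pop"`). Validation rejects dangling targets, undefined templates,
#' unknown menu providers, and scripts from whose start no terminal state is
#' reachable, naming the offender.
#'
#' @param config Path to a YAML file, or YAML text, or an already-parsed
#'   list.
#' @return A validated `dialog_script`.
#' @export
load_script <- function(config) {
  raw <- if (is.list(config)) config
         else if (length(config) == 1 && !grepl("\n", config) &&
                  file.exists(config)) yaml::read_yaml(config)
         else yaml::yaml.load(paste(config, collapse = "\n"))
  states <- raw$states
  if (is.null(states) || is.null(raw$start))
    stop("script needs 'start' and 'states'", call. = FALSE)
  # merge subnetwork states; remember which states belong to subnetworks
  sub_states <- character(0)
  for (sub in names(raw$subnetworks)) {
    ss <- raw$subnetworks[[sub]]$states
    clash <- intersect(names(ss), names(states))
    if (length(clash))
      stop("subnetwork '", sub, "' redefines state(s): ",
           paste(clash, collapse = ", "), call. = FALSE)
    states <- c(states, ss)
    sub_states <- c(sub_states, names(ss))
  }
  script <- structure(
    list(start = raw$start, states = states,
         templates = raw$templates %||% list(),
         facet_states = raw$facet_states %||% list(),
         subnetworks = lapply(raw$subnetworks, `[[`, "start"),
         sub_states = sub_states),
    class = "dialog_script")
  validate_script(script)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

state_targets <- function(cfg, script) {
  targets <- character(0)
  for (ch in cfg$choices) targets <- c(targets, ch$target)
  m <- cfg$menu
  if (!is.null(m))
    targets <- c(targets,
                 unlist(m[intersect(names(m),
                                    c("next", "accept", "present", "revise",
                                      "summary", "more", "dictionary"))],
                        use.names = FALSE))
  if (!is.null(cfg$menu) && identical(cfg$menu$provider, "confirm"))
    targets <- c(targets, unlist(script$facet_states, use.names = FALSE))
  unique(targets)
}

validate_script <- function(script) {
  states <- script$states
  nm <- names(states)
  if (!script$start %in% nm)
    stop("start state '", script$start, "' is not defined", call. = FALSE)
  terminals <- nm[vapply(states, function(s) isTRUE(s$terminal), logical(1))]
  if (length(terminals) == 0)
    stop("script has no terminal state", call. = FALSE)
  for (s in nm) {
    cfg <- states[[s]]
    if (!isTRUE(cfg$terminal) && is.null(cfg$choices) && is.null(cfg$menu))
      stop("non-terminal state '", s, "' offers no choices", call. = FALSE)
    if (!is.null(cfg$menu) && !cfg$menu$provider %in% MENU_PROVIDERS)
      stop("state '", s, "': unknown menu provider '", cfg$menu$provider,
           "'", call. = FALSE)
    tid <- c(cfg$template, cfg$template_empty)
    for (t in tid)
      if (!t %in% names(script$templates))
        stop("state '", s, "': undefined template '", t, "'", call. = FALSE)
    for (target in state_targets(cfg, script)) {
      if (target %in% c("@pop", "@return")) {
        if (target == "@pop" && !s %in% script$sub_states)
          stop("state '", s, "': '@pop' is only valid inside a subnetwork",
               call. = FALSE)
        next
      }
      if (!target %in% nm)
        stop("state '", s, "': arc targets undefined state '", target, "'",
             call. = FALSE)
    }
  }
  # reachability from start over declared targets (subnetwork calls enter
  # the subnetwork's start; '@pop' may resume at any pushed target)
  reach <- script$start
  frontier <- script$start
  while (length(frontier)) {
    nxt <- character(0)
    for (s in frontier) {
      cfg <- states[[s]]
      tg <- setdiff(state_targets(cfg, script), c("@pop", "@return"))
      for (ch in cfg$choices)
        if (!is.null(ch$call))
          tg <- c(tg, script$subnetworks[[ch$call]])
      nxt <- c(nxt, setdiff(tg, reach))
    }
    frontier <- unique(nxt)
    reach <- c(reach, frontier)
  }
  # '@return'/'@pop' resumption can only reach states already declared as
  # targets somewhere, so the frontier above covers the reachable set.
  unreachable <- setdiff(terminals, reach)
  if (length(unreachable))
    stop("terminal state(s) unreachable from start: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  script
}

#' Fill a text template
#'
#' Replaces every `{slot}` marker with the corresponding value; a marker
#' without a value is an error naming the slot.
#'
#' @param template Template text.
#' @param values Named list of slot values.
#' @return The rendered text with no markers remaining.
#' @examples
#' render_template("Hello {name}.", list(name = "Rosa"))
#' @export
render_template <- function(template, values = list()) {
  out <- template
  for (nm in names(values))
    out <- gsub(paste0("{", nm, "}"), format(values[[nm]]), out,
                fixed = TRUE)
  left <- regmatches(out, gregexpr("\\{[a-zA-Z_]+\\}", out))[[1]]
  if (length(left))
    stop("no value for template slot ", left[1], call. = FALSE)
  out
}

#' Read a term lexicon from CSV
#'
#' Columns `term,definition`; terms are stored lowercase and must be unique.
#'
#' @param path CSV path.
#' @return Named character vector, term -> plain-language definition.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "definition") %in% names(df)))
    stop("lexicon CSV needs columns term,definition", call. = FALSE)
  terms <- tolower(trimws(df$term))
  if (anyDuplicated(terms))
    stop("duplicate lexicon term: ", terms[duplicated(terms)][1],
         call. = FALSE)
  stats::setNames(as.character(df$definition), terms)
}

#' Extract difficult terms from text
#'
#' Case-insensitive longest-match scan of the tokenized text against the
#' lexicon (terms may span several words). Each matched term is reported
#' once, in order of first occurrence.
#'
#' @param text Free text.
#' @param lexicon Named character vector from [read_lexicon()] (term ->
#'   definition), terms lowercase.
#' @return Data frame with columns `term`, `definition` (possibly empty).
#' @export
extract_difficult_terms <- function(text, lexicon) {
  empty <- data.frame(term = character(0), definition = character(0),
                      stringsAsFactors = FALSE)
  if (length(lexicon) == 0) return(empty)
  toks <- tokenize(text)
  if (length(toks) == 0) return(empty)
  term_toks <- lapply(names(lexicon), function(t) tokenize(t))
  ord <- order(-lengths(term_toks))  # longest match first
  found <- character(0)
  i <- 1L
  while (i <= length(toks)) {
    matched <- 0L
    for (k in ord) {
      tt <- term_toks[[k]]
      len <- length(tt)
      if (i + len - 1L <= length(toks) &&
          identical(toks[i:(i + len - 1L)], tt)) {
        term <- names(lexicon)[k]
        if (!term %in% found) found <- c(found, term)
        matched <- len
        break
      }
    }
    i <- i + max(1L, matched)
  }
  data.frame(term = found, definition = unname(lexicon[found]),
             stringsAsFactors = FALSE)
}

#' Start a dialog session
#'
#' @param script A `dialog_script` from [load_script()].
#' @param corpus List of `trial_record`s the session searches over.
#' @param models Optional named list of the three criterion
#'   `decision_tree`s; used to infer ranking criteria for the corpus.
#' @param inferred Optional precomputed `trial_id -> inferred_criteria` map
#'   (overrides `models`). If neither is given all trials rank equally.
#' @param lexicon Named term -> definition vector (see [read_lexicon()]).
#' @param user_name The user's display name — the only free-text input the
#'   interface accepts; everything else is menu selection.
#' @return A `dialog_session` positioned at the script's start state, with
#'   its first `Turn` available via [current_turn()].
#' @export
new_session <- function(script, corpus, models = NULL, inferred = NULL,
                        lexicon = character(0), user_name = "friend") {
  if (is.null(inferred)) {
    inferred <- if (!is.null(models)) infer_corpus_criteria(corpus, models)
    else {
      ids <- vapply(corpus, `[[`, character(1), "trial_id")
      stats::setNames(rep(list(structure(
        c(pain = 0L, invasiveness = 0L, time_burden = 0L),
        class = "inferred_criteria")), length(ids)), ids)
    }
  }
  session <- structure(
    list(script = script, corpus = corpus,
         corpus_ids = vapply(corpus, `[[`, character(1), "trial_id"),
         inferred = inferred, lexicon = lexicon,
         model = list(query = facet_query(), prefs = preferences(),
                      name = user_name),
         state = script$start, stack = character(0), return_to = NULL,
         active_query = facet_query(), results = character(0), cursor = 1L,
         current_trial = NULL, dict_level = 1L,
         trials_viewed = character(0), bookmarks = character(0),
         transcript = list(), turn = NULL),
    class = "dialog_session")
  session <- enter_state(session, script$start)
  session
}

get_record <- function(session, id) {
  session$corpus[[match(id, session$corpus_ids)]]
}

## ---- actions -------------------------------------------------------------

run_action <- function(session, action) {
  switch(action$type,
    set_facet = {
      session$model$query[[action$facet]] <- action$value
      session
    },
    clear_facet = {
      session$model$query[action$facet] <- list(NULL)
      session
    },
    set_pref = {
      session$model$prefs[[action$criterion]] <- action$level
      session
    },
    run_search = {
      q <- session$model$query
      hits <- filter_trials(session$corpus, q)
      ranked <- rank_trials(hits, session$model$prefs, session$inferred)
      ids <- vapply(ranked, `[[`, character(1), "trial_id")
      session$active_query <- q
      session$results <- setdiff(ids, session$trials_viewed)
      session$cursor <- 1L
      session$current_trial <- NULL
      session
    },
    view_current = {
      id <- session$results[session$cursor]
      if (!identical(session$current_trial, id)) {
        session$current_trial <- id
        session$trials_viewed <- c(session$trials_viewed, id)
      }
      session
    },
    next_trial = {
      session$cursor <- session$cursor + 1L
      session$current_trial <- NULL
      session
    },
    bookmark = {
      session$bookmarks <- union(session$bookmarks, session$current_trial)
      session
    },
    set_return = {
      session$return_to <- action$state
      if (!is.null(action$level)) session$dict_level <- action$level
      session
    },
    stop("unknown action type: ", action$type, call. = FALSE))
}

remaining_results <- function(session) {
  max(0L, length(session$results) - session$cursor + 1L)
}

## ---- menu providers ------------------------------------------------------

FACET_VALUE_LABELS <- list(
  age = function(v) sprintf("About %d years old", v),
  sex = function(v) c(FEMALE = "Female", MALE = "Male")[[v]],
  cancer_type = function(v) v,
  location = function(v) if (v == "ANYWHERE") "Can be anywhere" else
    sprintf("Near me, in region %s", v),
  trial_type = function(v) sprintf("A %s trial", tolower(v)),
  phase = function(v) sprintf("Phase %s", v),
  investigational_drug_ok = function(v)
    if (v) "An experimental drug would be okay"
    else "No experimental drugs, please")

facet_values <- function(session, facet) {
  switch(facet,
    age = c(30L, 40L, 50L, 60L, 70L, 80L),
    sex = c("FEMALE", "MALE"),
    cancer_type = sort(unique(vapply(session$corpus, `[[`, character(1),
                                     "cancer_type"))),
    location = c("ANYWHERE",
                 sort(unique(unlist(lapply(session$corpus,
                                           `[[`, "locations"))))),
    trial_type = TRIAL_TYPES,
    phase = setdiff(TRIAL_PHASES, "UNSPECIFIED"),
    investigational_drug_ok = c(TRUE, FALSE),
    stop("unknown facet: ", facet, call. = FALSE))
}

choice_item <- function(label, target, actions = list(), call = NULL) {
  list(label = label, target = target, actions = actions, call = call)
}

interview_next <- function(session, mcfg) {
  if (!is.null(session$return_to)) "@return" else mcfg[["next"]]
}

menu_facet <- function(session, mcfg) {
  facet <- mcfg$facet
  nxt <- interview_next(session, mcfg)
  lab <- FACET_VALUE_LABELS[[facet]]
  out <- lapply(facet_values(session, facet), function(v)
    choice_item(lab(v), nxt,
                list(list(type = "set_facet", facet = facet, value = v))))
  c(out, list(choice_item(mcfg$skip %||% "It doesn't matter to me.", nxt,
                          list(list(type = "clear_facet", facet = facet)))))
}

PREF_LABELS <- list(
  pain = c("As little pain as possible", "A little pain would be okay",
           "Pain does not worry me"),
  invasiveness = c("Nothing invasive, like surveys only",
                   "Some tests or scans would be okay",
                   "Invasive procedures are fine"),
  time_burden = c("As little of my time as possible",
                  "A moderate time commitment is okay",
                  "I can commit a lot of time"))

menu_pref <- function(session, mcfg) {
  crit <- mcfg$criterion
  nxt <- interview_next(session, mcfg)
  out <- lapply(0:2, function(lev)
    choice_item(PREF_LABELS[[crit]][lev + 1L], nxt,
                list(list(type = "set_pref", criterion = crit,
                          level = lev))))
  c(out, list(choice_item(mcfg$skip %||% "I have no preference.", nxt)))
}

PRETTY_FACETS <- c(age = "age", sex = "sex", cancer_type = "cancer type",
                   location = "location", trial_type = "trial type",
                   phase = "phase",
                   investigational_drug_ok = "experimental-drug choice")

menu_confirm <- function(session, mcfg) {
  q <- session$model$query
  out <- list(choice_item(
    mcfg$accept_label %||% "That all looks right. Search for trials!",
    mcfg$accept, list(list(type = "run_search"))))
  for (facet in set_facets(q)) {
    st <- session$script$facet_states[[facet]]
    if (is.null(st)) next
    out[[length(out) + 1L]] <- choice_item(
      sprintf("Change the %s (now: %s)", PRETTY_FACETS[[facet]],
              format(q[[facet]])),
      st, list(list(type = "set_return", state = "@confirm")))
  }
  out
}

menu_results <- function(session, mcfg) {
  if (remaining_results(session) > 0) {
    list(choice_item("Tell me about the next trial.", mcfg$present),
         choice_item("Let me change my search criteria.", mcfg$revise),
         choice_item("Show me a summary of what I have seen.",
                     mcfg$summary))
  } else {
    out <- list()
    for (rel in suggest_relaxations(session$model$query, session$corpus)) {
      unseen <- setdiff(
        vapply(filter_trials(session$corpus, rel$relaxed_query), `[[`,
               character(1), "trial_id"),
        session$trials_viewed)
      if (length(unseen) == 0) next
      out[[length(out) + 1L]] <- choice_item(
        sprintf("Stop asking for a specific %s (%d more trial%s)",
                PRETTY_FACETS[[rel$dropped_facet]], length(unseen),
                if (length(unseen) == 1) "" else "s"),
        mcfg$present %||% "results",
        list(list(type = "clear_facet", facet = rel$dropped_facet),
             list(type = "run_search")))
    }
    # dropping a relaxed facet re-enters this state, so target results again
    out <- lapply(out, function(ch) { ch$target <- mcfg$self %||% "results"; ch })
    c(out, list(choice_item("Show me a summary of what I have seen.",
                            mcfg$summary)))
  }
}

menu_present <- function(session, mcfg) {
  level <- mcfg$level
  out <- list()
  if (!is.null(mcfg$more))
    out[[length(out) + 1L]] <- choice_item(
      if (level == 1) "Tell me more about this trial."
      else "Tell me even more — what would I have to do?", mcfg$more)
  rec <- get_record(session, session$current_trial)
  terms <- extract_difficult_terms(
    paste(unlist(detail_view(rec, level)$sections), collapse = " "),
    session$lexicon)
  if (!is.null(mcfg$dictionary) && nrow(terms) > 0)
    out[[length(out) + 1L]] <- choice_item(
      "What do those medical words mean?", mcfg$dictionary,
      list(list(type = "set_return", state = "@here", level = level)))
  if (level == 3)
    out[[length(out) + 1L]] <- choice_item(
      "Save this trial for me to look at later.", mcfg[["next"]],
      list(list(type = "bookmark"), list(type = "next_trial")))
  if (!is.null(mcfg$again))
    out[[length(out) + 1L]] <- choice_item(
      "Could you go over that again?", mcfg$again)
  out[[length(out) + 1L]] <- choice_item(
    if (level == 3) "I have seen enough of this one. What else is there?"
    else "This one is not for me. What else is there?",
    mcfg[["next"]], list(list(type = "next_trial")))
  out
}

build_choices <- function(session) {
  cfg <- session$script$states[[session$state]]
  if (!is.null(cfg$menu)) {
    provider <- switch(cfg$menu$provider, facet = menu_facet,
                       pref = menu_pref, confirm = menu_confirm,
                       results = menu_results, present = menu_present)
    provider(session, cfg$menu)
  } else {
    lapply(cfg$choices, function(ch)
      choice_item(ch$label, ch$target,
                  actions = ch$actions %||% list(), call = ch$call))
  }
}

## ---- displays and turns --------------------------------------------------

build_display <- function(session, cfg) {
  d <- cfg$display
  if (is.null(d)) return(NULL)
  switch(d,
    criteria = confirm_criteria(session)$display,
    summary = session_summary(session),
    dictionary = {
      rec <- get_record(session, session$current_trial)
      extract_difficult_terms(
        paste(unlist(detail_view(rec, session$dict_level)$sections),
              collapse = " "),
        session$lexicon)
    },
    detail1 = ,
    detail2 = ,
    detail3 = detail_view(get_record(session, session$current_trial),
                          as.integer(substr(d, 7, 7))),
    stop("unknown display: ", d, call. = FALSE))
}

turn_context <- function(session) {
  ctx <- list(name = session$model$name,
              n = remaining_results(session),
              total = length(session$results))
  if (!is.null(session$current_trial)) {
    rec <- get_record(session, session$current_trial)
    ctx$title <- simplify_title(rec)
    ctx$trial_id <- rec$trial_id
  }
  ctx
}

build_turn <- function(session) {
  cfg <- session$script$states[[session$state]]
  tid <- cfg$template
  if (!is.null(cfg$template_empty) && remaining_results(session) == 0)
    tid <- cfg$template_empty
  utterance <- render_template(session$script$templates[[tid]],
                               turn_context(session))
  choices <- if (isTRUE(cfg$terminal)) list() else build_choices(session)
  if (!isTRUE(cfg$terminal) && length(choices) == 0)
    stop("state '", session$state, "' produced an empty menu", call. = FALSE)
  structure(list(state = session$state, agent_utterance = utterance,
                 display = build_display(session, cfg),
                 choices = choices),
            class = "dialog_turn")
}

#' @export
print.dialog_turn <- function(x, ...) {
  cat(sprintf("[%s] Agent: %s\n", x$state, x$agent_utterance))
  if (!is.null(x$display)) { print(x$display); cat("\n") }
  for (i in seq_along(x$choices))
    cat(sprintf("  %d. %s\n", i, x$choices[[i]]$label))
  invisible(x)
}

enter_state <- function(session, state) {
  session$state <- state
  cfg <- session$script$states[[state]]
  for (a in cfg$on_enter %||% character(0))
    session <- run_action(session, list(type = a))
  session$turn <- build_turn(session)
  session
}

#' The current agent turn of a session
#' @param session A `dialog_session`.
#' @return The pending `dialog_turn`.
#' @export
current_turn <- function(session) session$turn

#' Is the session at a terminal state?
#' @param session A `dialog_session`.
#' @return Logical scalar.
#' @export
is_terminal <- function(session) {
  isTRUE(session$script$states[[session$state]]$terminal)
}

#' Advance a dialog session by one user choice
#'
#' Executes the chosen arc's actions (slot-fills, search, bookmarking,
#' subnetwork entry), transitions to the target state, runs that state's
#' entry actions and returns the session with the next turn pending.
#' Deterministic given script, corpus, models and the prior choices.
#'
#' @param session A `dialog_session`.
#' @param choice_index 1-based index into the current turn's choices.
#' @return The updated `dialog_session`; inspect [current_turn()].
#' @export
advance <- function(session, choice_index) {
  if (is_terminal(session))
    stop("session has ended; cannot advance a terminal state",
         call. = FALSE)
  turn <- session$turn
  if (length(choice_index) != 1 || is.na(choice_index) ||
      choice_index < 1 || choice_index > length(turn$choices))
    stop(sprintf("choice_index %s out of range 1..%d",
                 format(choice_index), length(turn$choices)), call. = FALSE)
  choice <- turn$choices[[as.integer(choice_index)]]
  session$transcript[[length(session$transcript) + 1L]] <-
    list(state = turn$state, agent_utterance = turn$agent_utterance,
         choices = vapply(turn$choices, `[[`, character(1), "label"),
         chosen = as.integer(choice_index), chosen_label = choice$label)
  here <- session$state
  for (a in choice$actions) {
    if (identical(a$type, "set_return")) {
      if (identical(a$state, "@here")) a$state <- here
      if (identical(a$state, "@confirm")) a$state <- choice_return_confirm(session)
    }
    session <- run_action(session, a)
  }
  target <- choice$target
  if (!is.null(choice$call)) {
    session$stack <- c(session$stack, target)
    target <- session$script$subnetworks[[choice$call]]
  } else if (identical(target, "@pop")) {
    target <- session$stack[length(session$stack)]
    session$stack <- session$stack[-length(session$stack)]
  } else if (identical(target, "@return")) {
    target <- session$return_to
    session$return_to <- NULL
  }
  enter_state(session, target)
}

## The confirm state that revision menus return to: the state carrying the
## confirm provider (there is one in the shipped script).
choice_return_confirm <- function(session) {
  states <- session$script$states
  nm <- names(states)[vapply(states, function(s)
    identical(s$menu$provider, "confirm"), logical(1))]
  nm[1]
}

#' Run a session through a fixed choice sequence
#'
#' @param session A fresh `dialog_session`.
#' @param choices Integer vector of 1-based choice indices.
#' @return The session after applying every choice.
#' @export
replay_choices <- function(session, choices) {
  for (i in choices) session <- advance(session, i)
  session
}

#' Summary of trials viewed this session
#'
#' @param session A `dialog_session`.
#' @return Data frame `trial_id`, `title`, `bookmarked`, in view order.
#' @export
session_summary <- function(session) {
  ids <- session$trials_viewed
  data.frame(
    trial_id = ids,
    title = vapply(ids, function(id)
      simplify_title(get_record(session, id)), character(1),
      USE.NAMES = FALSE),
    bookmarked = ids %in% session$bookmarks,
    stringsAsFactors = FALSE)
}

#' Toggle a bookmark on a viewed trial
#'
#' @param session A `dialog_session`.
#' @param trial_id A trial that has been viewed this session.
#' @return The updated session.
#' @export
toggle_bookmark <- function(session, trial_id) {
  if (!trial_id %in% session$trials_viewed)
    stop("only viewed trials can be bookmarked", call. = FALSE)
  session$bookmarks <- if (trial_id %in% session$bookmarks)
    setdiff(session$bookmarks, trial_id)
  else c(session$bookmarks, trial_id)
  session
}

#' Current search criteria with revision choices
#'
#' The display lists every set facet and preference; the choices offer one
#' revision per set facet plus acceptance.
#'
#' @param session A `dialog_session`.
#' @return List with `display` (data frame `item`, `value`) and `choices`
#'   (labels: one "Change ..." per set facet plus the accept option).
#' @export
confirm_criteria <- function(session) {
  q <- session$model$query
  p <- session$model$prefs
  items <- character(0); values <- character(0)
  for (facet in set_facets(q)) {
    items <- c(items, PRETTY_FACETS[[facet]])
    values <- c(values, format(q[[facet]]))
  }
  for (crit in CRITERIA_NAMES)
    if (!is.null(p[[crit]])) {
      items <- c(items, paste("preferred", gsub("_", " ", crit)))
      values <- c(values, names(CRITERIA_LEVELS)[p[[crit]] + 1L])
    }
  display <- data.frame(item = items, value = values,
                        stringsAsFactors = FALSE)
  choices <- c("That all looks right. Search for trials!",
               vapply(set_facets(q), function(f)
                 sprintf("Change the %s", PRETTY_FACETS[[f]]), character(1),
                 USE.NAMES = FALSE))
  list(display = display, choices = choices)
}

#' Serialize a session transcript as JSON Lines
#'
#' @param session A `dialog_session`.
#' @param path Optional output path.
#' @return The JSONL lines (invisibly when written to `path`).
#' @export
transcript_jsonl <- function(session, path = NULL) {
  lines <- vapply(session$transcript, function(entry)
    as.character(jsonlite::toJSON(entry, auto_unbox = TRUE)), character(1))
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Path of the shipped default dialog script / lexicon
#' @return File path within the installed package.
#' @export
default_script_path <- function() {
  system.file("extdata", "default_script.yaml", package = "trialtalk",
              mustWork = TRUE)
}

#' @rdname default_script_path
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "default_lexicon.csv", package = "trialtalk",
              mustWork = TRUE)
}
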