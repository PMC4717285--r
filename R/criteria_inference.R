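## Ordinal label scale shared by the three subjective criteria.
CRITERIA_LEVELS <- c(low = 0L, medium = 1L, high = 2L)
CRITERIA_NAMES <- c("pain", "invasiveness", "time_burden")

## Short stopword list applied when the vocabulary is derived from the
## training set itself (function words carry no occurrence signal and only
## slow induction down).
ID3_STOPWORDS <- c(
  "a", "an", "and", "are", "as", "at", "be", "by", "for", "from", "in",
  "is", "it", "of", "on", "or", "that", "the", "this", "to", "was",
  "were", "will", "with")

#' Tokenize free text into lowercase word tokens
#'
#' Tokens are maximal alphabetic runs; digits, hyphens and all punctuation
#' act as separators, so `"pre-biopsy"` yields tokens `"pre"` and `"biopsy"`.
#'
#' @param text Character scalar (or vector; tokens are concatenated).
#' @return Character vector of lowercase tokens, possibly empty.
#' @export
tokenize <- function(text) {
  if (length(text) == 0) return(character(0))
  text <- tolower(paste(text, collapse = " "))
  unlist(regmatches(text, gregexpr("[a-z]+", text)))
}

#' Boolean word-occurrence features
#'
#' Maps every vocabulary word to whether it occurs as a whole token in the
#' text. These are the only features the decision trees see.
#'
#' @param text Free text.
#' @param vocabulary Non-empty character vector of lowercase words.
#' @return Named logical vector over exactly the vocabulary.
#' @export
featurize <- function(text, vocabulary) {
  if (length(vocabulary) == 0) stop("vocabulary must be non-empty",
                                    call. = FALSE)
  toks <- tokenize(text)
  stats::setNames(vocabulary %in% toks, vocabulary)
}

#' Shannon entropy of a label distribution, in bits
#'
#' @param label_counts Non-negative integer counts per label; total >= 1.
#' @return Entropy in bits: `-sum(p * log2(p))` over labels with nonzero
#'   count. Zero iff the node is pure.
#' @export
entropy <- function(label_counts) {
  n <- sum(label_counts)
  if (n < 1) stop("total count must be >= 1", call. = FALSE)
  p <- label_counts[label_counts > 0] / n
  -sum(p * log2(p))
}

label_counts <- function(labels) {
  tabulate(labels + 1L, nbins = length(CRITERIA_LEVELS))
}

#' Information gain of splitting on one word
#'
#' The entropy of the parent node minus the size-weighted entropies of the
#' present/absent partition induced by the word. An empty branch contributes
#' nothing.
#'
#' @param features Logical matrix, one row per example, columns named by
#'   vocabulary word (as built by [featurize()] rows).
#' @param labels Integer vector of ordinal labels (0, 1, 2), one per row.
#' @param word Column name to split on.
#' @return Gain in bits (>= 0).
#' @export
information_gain <- function(features, labels, word) {
  if (length(labels) == 0) stop("examples must be non-empty", call. = FALSE)
  present <- features[, word]
  h_all <- entropy(label_counts(labels))
  h_split <- 0
  for (branch in list(labels[present], labels[!present])) {
    if (length(branch) > 0)
      h_split <- h_split + length(branch) / length(labels) *
        entropy(label_counts(branch))
  }
  h_all - h_split
}

majority_label <- function(labels) {
  counts <- label_counts(labels)
  # ties broken toward the lowest ordinal level, for determinism
  as.integer(which.max(counts) - 1L)
}

id3_node <- function(features, labels, words) {
  counts <- label_counts(labels)
  if (sum(counts > 0) == 1L || length(words) == 0)
    return(list(leaf = majority_label(labels)))
  gains <- vapply(words, function(w) information_gain(features, labels, w),
                  numeric(1))
  best <- max(gains)
  if (best <= 0) return(list(leaf = majority_label(labels)))
  # ties on gain broken by the lexicographically smallest word
  word <- min(words[gains >= best - 1e-12])
  present <- features[, word]
  rest <- setdiff(words, word)
  pres_branch <- if (any(present))
    id3_node(features[present, , drop = FALSE], labels[present], rest)
  else list(leaf = majority_label(labels))
  abs_branch <- if (any(!present))
    id3_node(features[!present, , drop = FALSE], labels[!present], rest)
  else list(leaf = majority_label(labels))
  list(word = word, present = pres_branch, absent = abs_branch)
}

#' Build a model vocabulary from training texts
#'
#' All distinct tokens of the training texts minus a short stopword list.
#'
#' @param texts Character vector of training texts.
#' @param stopwords Words to exclude.
#' @return Sorted character vector.
#' @export
build_vocabulary <- function(texts, stopwords = ID3_STOPWORDS) {
  sort(setdiff(unique(unlist(lapply(texts, tokenize))), stopwords))
}

#' Train an ID3 decision tree on word-occurrence features
#'
#' Greedy top-down induction: at each node the unused vocabulary word with
#' maximal information gain is chosen and the examples are partitioned into
#' word-present and word-absent branches. Recursion stops at pure nodes, when
#' the vocabulary is exhausted, or when no word has positive gain; leaves
#' carry the majority label of their examples. No pruning is applied.
#' Tie-breaks (lexicographically smallest word on equal gain, lowest ordinal
#' label on majority ties) make training deterministic.
#'
#' @param examples Data frame with columns `text` and `label`; labels are
#'   integers 0/1/2 or the strings `"low"`, `"medium"`, `"high"`.
#' @param vocabulary Optional word set; defaults to the training-set tokens
#'   minus the shipped stopword list. An empty vocabulary yields a single
#'   majority leaf.
#' @return A `decision_tree`: nested lists of `list(word, present, absent)`
#'   nodes ending in `list(leaf = label)` leaves.
#' @examples
#' ex <- data.frame(
#'   text = c("biopsy required", "a biopsy weekly", "survey only", "a survey"),
#'   label = c("high", "high", "low", "low"))
#' tr <- train_id3(ex)
#' classify(tr, "one biopsy then imaging")
#' @export
train_id3 <- function(examples, vocabulary = NULL) {
  if (nrow(examples) == 0) stop("examples must be non-empty", call. = FALSE)
  labels <- coerce_labels(examples$label)
  if (is.null(vocabulary)) vocabulary <- build_vocabulary(examples$text)
  if (length(vocabulary) == 0) {
    tree <- list(leaf = majority_label(labels))
  } else {
    features <- t(vapply(examples$text, featurize, logical(length(vocabulary)),
                         vocabulary = vocabulary, USE.NAMES = FALSE))
    colnames(features) <- vocabulary
    tree <- id3_node(features, labels, vocabulary)
  }
  structure(tree, class = "decision_tree")
}

coerce_labels <- function(label) {
  if (is.character(label) || is.factor(label)) {
    label <- as.character(label)
    bad <- setdiff(unique(label), names(CRITERIA_LEVELS))
    if (length(bad))
      stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    unname(CRITERIA_LEVELS[label])
  } else {
    label <- as.integer(label)
    if (any(!label %in% 0:2))
      stop("labels must be in 0..2", call. = FALSE)
    label
  }
}

#' Classify free text with a trained tree
#'
#' Walks the tree from the root, following the present branch when the
#' node's word occurs as a token in the text and the absent branch otherwise.
#'
#' @param tree A `decision_tree`.
#' @param text Free text.
#' @return Ordinal level 0 (low), 1 (medium) or 2 (high).
#' @export
classify <- function(tree, text) {
  toks <- tokenize(text)
  node <- tree
  while (is.null(node$leaf)) {
    node <- if (node$word %in% toks) node$present else node$absent
  }
  as.integer(node$leaf)
}

#' Tree depth and size (internal helpers for inspection)
#' @param tree A `decision_tree`.
#' @return Number of decision nodes.
#' @export
tree_size <- function(tree) {
  if (!is.null(tree$leaf)) return(0L)
  1L + tree_size(tree$present) + tree_size(tree$absent)
}

#' @export
print.decision_tree <- function(x, ...) {
  rec <- function(node, indent) {
    if (!is.null(node$leaf)) {
      cat(indent, "-> ", names(CRITERIA_LEVELS)[node$leaf + 1L], "\n",
          sep = "")
    } else {
      cat(indent, "[", node$word, "?]\n", sep = "")
      rec(node$present, paste0(indent, "  yes "))
      rec(node$absent, paste0(indent, "  no  "))
    }
  }
  rec(x, "")
  invisible(x)
}

#' Infer the three subjective criteria for a trial
#'
#' Applies the pain, invasiveness and time-burden trees to the concatenated
#' free text of the record (purpose, procedures, eligibility).
#'
#' @param record A `trial_record`.
#' @param models Named list with `decision_tree`s `pain`, `invasiveness`,
#'   `time_burden`.
#' @return An `inferred_criteria`: named integer vector of the three levels.
#' @export
infer_criteria <- function(record, models) {
  stopifnot(all(CRITERIA_NAMES %in% names(models)))
  text <- trial_text(record)
  structure(vapply(models[CRITERIA_NAMES], classify, integer(1),
                   text = text),
            class = "inferred_criteria")
}

#' Infer criteria for an entire corpus
#'
#' @param corpus List of `trial_record`s.
#' @param models As in [infer_criteria()].
#' @return Named list, `trial_id` -> `inferred_criteria`.
#' @export
infer_corpus_criteria <- function(corpus, models) {
  out <- lapply(corpus, infer_criteria, models = models)
  names(out) <- vapply(corpus, `[[`, character(1), "trial_id")
  out
}

#' Serialize / load a decision tree as JSON
#'
#' Nodes are written as `{"word": w, "present": ..., "absent": ...}` and
#' leaves as `{"leaf": label}`.
#'
#' @param tree A `decision_tree`.
#' @param path Output (input) file path.
#' @return `path` invisibly; `read_tree_json` returns the tree.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(unclass(tree), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyVector = FALSE),
            class = "decision_tree")
}

#' Read a labeled training set from CSV
#'
#' Expected columns: `text`, `label` with labels `low`/`medium`/`high`.
#'
#' @param path CSV path.
#' @return Data frame with `text` (character) and `label` (integer 0..2).
#' @export
read_training_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("text", "label") %in% names(df)))
    stop("training CSV needs columns text,label", call. = FALSE)
  data.frame(text = as.character(df$text),
             label = coerce_labels(df$label),
             stringsAsFactors = FALSE)
}
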