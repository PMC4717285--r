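# trialtalk

A conversational search engine for clinical-trial registries, built for
users with low health literacy — people for whom keyword search boxes and
dense registry prose are an outright barrier to finding a trial. Instead of
typing queries, the user answers a scripted interview one multiple-choice
turn at a time; the agent searches a faceted trial index, discloses each
candidate trial in stages, explains difficult medical terms, and suggests
ways to loosen the search when nothing matches. The package is aimed at
researchers in consumer health informatics who want to study or extend this
interaction style, and it ships everything needed to run fully synthetic,
reproducible experiments: seeded corpus generators, a scripted dialog
engine, and the nonparametric statistics used to compare a conversational
arm against a conventional one.

## What is inside

**Faceted retrieval.** Trials are indexed on seven eligibility facets —
age range, sex, cancer type, locations, trial type, phase, and
investigational-drug use. A query sets any subset of facets; a trial
matches iff every set facet is satisfied (`min_age ≤ age ≤ max_age`, sex
`ANY` or equal, exact matches on categorical facets, empty location set =
offered anywhere). When a search returns nothing, single-facet relaxations
are suggested in a fixed priority order, each with its hit count.

**Inferred subjective criteria.** Three attributes no registry indexes —
pain, invasiveness, and time burden, each on an ordinal scale
low/medium/high — are predicted from the trial free text by ID3 decision
trees over boolean word-occurrence features. At each node ID3 picks the
unused word *w* maximizing the information gain

    gain(S, w) = H(S) − Σ_b (|S_b|/|S|) · H(S_b),   H(S) = −Σ_i p_i log2 p_i,

splitting into word-present/word-absent branches, stopping at pure nodes,
exhausted vocabulary, or zero gain. Matching trials are ranked by the
preference mismatch score `Σ |inferred level − desired level|` over the
user's set preferences, ties broken by trial id.

**Dialog engine.** An augmented-transition-network manager: named states,
template-generated utterances with `{slot}` markers, multiple-choice arcs
carrying guards and actions (slot filling, search, staged detail views,
bookmarking, dictionary look-ups, education subnetworks). The shipped
default script walks interview → criteria confirmation → search → level
1/2/3 disclosure → refinement → summary → farewell, and is plain YAML you
can replace.

**Evaluation statistics.** Uncorrected Pearson chi-square on 2×2
arm-by-outcome tables, `χ² = n(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))`, and the
Mann-Whitney U test with midranks, tie-corrected normal approximation and
exact enumeration for small samples, plus per-arm outcome summaries.

## Worked example

Find a treatment trial for a 70-year-old breast-cancer patient, anywhere,
preferring low-pain studies, over a 200-trial synthetic corpus:

```r
library(trialtalk)

gen    <- generate_corpus(corpus_config(n_trials = 200, seed = 70))
models <- lapply(c(pain = "pain", invasiveness = "invasiveness",
                   time_burden = "time_burden"), function(crit)
  train_id3(generate_training_set(corpus_config(n_trials = 100, seed = 8),
                                  crit)))
inferred <- infer_corpus_criteria(gen$records, models)

rosa <- facet_query(age = 70, cancer_type = "Breast Cancer",
                    trial_type = "TREATMENT", location = "ANYWHERE")
hits   <- filter_trials(gen$records, rosa)          # 8 trials
ranked <- rank_trials(hits, preferences(pain = 0), inferred)
```

The first three ranked trials print as

```
SYN-00022  Phase III Treatment Trial for Breast Cancer   pain=0
SYN-00075  Phase IV Treatment Trial for Breast Cancer    pain=0
SYN-00040  Phase II Treatment Trial for Breast Cancer    pain=1
```

— every hit satisfies all four facets, and trials whose procedures text
signals low pain sort first. The evaluation statistics work on plain
counts and vectors:

```r
chi_square_2x2(contingency_2x2(5, 9, 0, 8))
#> CHI_SQUARE_2x2: statistic = 3.697, p = 0.05449
mann_whitney_u(c(1, 2), c(3, 4))
#> MANN_WHITNEY_U: statistic = 0, p = 0.3333
```

The same pipeline is available from a shell via the installed script
(`system.file("cli", "trialtalk", package = "trialtalk")`): `synth`,
`train`, `infer`, `search`, `chat --choices`, `evaluate`.

A scripted conversation, for tests or demos:

```r
script  <- load_script(default_script_path())
lexicon <- read_lexicon(default_lexicon_path())
s <- new_session(script, gen$records, models = models, lexicon = lexicon,
                 user_name = "Rosa")
print(current_turn(s))   # greeting + choice menu
s <- advance(s, 1)       # each advance() applies one menu choice
```

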