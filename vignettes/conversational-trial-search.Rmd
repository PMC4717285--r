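---
title: "Conversational faceted search over clinical-trial corpora: models and methods"
author: "trialtalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conversational faceted search over clinical-trial corpora: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialtalk)
```

## The problem

Roughly a third of US adults have low health literacy, and for many of
them a conventional search engine — a keyword box, a results list, pages
of registry prose — is unusable. Clinical-trial search is a stark case:
the information is public, the stakes are high, and the interface is the
barrier. `trialtalk` implements the alternative interaction this package
is organized around: a system-initiative dialog agent that interviews the
user with multiple-choice questions, searches a faceted trial index on
their behalf, and reveals each candidate trial in small, staged steps with
plain-language support. Because no public hand-rated corpus exists for the
subjective trial attributes involved, the package treats synthetic data
generation as a first-class module, so every component is testable
end-to-end with no downloads.

## Retrieval model

A trial record carries seven indexed facets (age range, sex eligibility,
cancer type, location set, trial type, phase, investigational-drug flag)
and three free-text sections (purpose, procedures, eligibility). A
`facet_query` sets any subset of facets; `matches()` is a conjunction over
the set facets with these conventions, chosen once and documented as the
package's matching semantics:

* age bounds are inclusive on both ends;
* a trial with sex eligibility `ANY` matches either queried sex;
* an empty location set means the trial is offered anywhere, and the
  query value `ANYWHERE` matches every trial;
* `investigational_drug_ok = FALSE` excludes drug trials, while `TRUE`
  (or unset) excludes nothing.

`filter_trials()` is deliberately nothing more than this predicate mapped
over the corpus in order — the tests hold it equal to an independently
written brute-force predicate on randomized corpora, and the monotonicity
property (unsetting a facet never shrinks the result set) follows from
conjunctive semantics.

When a query returns no (or no more) trials, `suggest_relaxations()`
unsets one facet at a time in the fixed order *phase, trial type,
location, investigational drug, cancer type, sex, age*, and keeps the
relaxations with at least one hit. The order is configuration, not
science: it starts with the facets that least constrain clinical
appropriateness (phase rarely matters to a patient; age and cancer type
almost define the search). Relaxations are only ever *suggested* — the
dialog never silently rewrites the user's criteria; the user picks one
from a menu.

## Inferred criteria: ID3 over word occurrence

Three attributes users care about are in no registry index: how painful
participation is likely to be, how invasive the protocol is, and how much
time it demands. Each is modeled as an ordinal label low/medium/high
(0/1/2). The three-level scale is a design choice motivated by the natural
invasiveness gradient survey → diagnostic → treatment; the label set is
deliberately coarse because the labels exist to *sort* search results, not
to diagnose.

The classifier is deliberately minimal: ID3 over boolean word-occurrence
features. Text is tokenized into lowercase maximal alphabetic runs (so
`pre-biopsy` yields `pre` and `biopsy`); the feature vector maps each
vocabulary word to whether it occurs as a token. Induction is the
standard greedy recursion on information gain in bits; there is no
pruning and no minimum leaf size, and growth stops at pure nodes, when
the vocabulary is exhausted, or when no remaining word has positive gain.
Two tie-breaks make training fully deterministic: equal-gain words resolve
to the lexicographically smallest, and majority-leaf ties resolve to the
lowest ordinal label. Determinism matters more than the marginal accuracy
a cleverer tie-break might buy: identical training data must give
identical models for transcripts and experiments to be replayable.

One tree is trained per criterion (the three attributes are independent
models), and `infer_criteria()` classifies the concatenation of a trial's
purpose, procedures and eligibility text. Training examples, by contrast,
pair each criterion's *own* section with its label — procedures text for
pain, purpose for invasiveness, eligibility for time burden. This is the
package's resolution of a genuinely open design point (the original
hand-rated data are unpublished, so which fields were rated is unknown),
and it is the scientifically safer choice for two reasons. First, it
mirrors how a rater would work: you judge painfulness from the procedures,
not from the eligibility rules. Second, it matters for noise robustness:
ID3 with no pruning will happily memorize mislabeled examples if the
feature space is rich enough to isolate them, and training on full
concatenations hands it exactly that richness (every other criterion's
marker words become potential split points). Trained on sections, a
mislabeled example is featurally identical to many correctly labeled ones,
the majority rule outvotes it, and held-out accuracy under 10% label noise
stays near its ceiling of 90% instead of degrading toward 80%. A tree
trained on sections applies unchanged to whole trials, because every word
it tests occurs in the concatenation.

Ranking uses the absolute-distance mismatch score
`Σ |inferred − desired|` over the user's set preferences, ascending, with
trial-id tie-breaks. Absolute distance (rather than, say, penalizing only
exceedances) keeps the score interpretable and symmetric; a user who wants
a medium time commitment genuinely may not want a trivially short study.

## The dialog engine

The manager is an augmented transition network: named states whose arcs
carry an action list and a target, with utterances produced by template
substitution (`{slot}` markers; a missing slot value is an error, never
silently left in place). The script is YAML. Menus that depend on the
corpus or the session — cancer types present in the corpus, the
confirmation menu's one-revision-per-set-facet choices, relaxation
suggestions with hit counts, the staged presentation options — are
produced by named providers in the engine, referenced from the script;
everything static lives in the YAML. Education modules are subnetworks
entered through a call stack and left with a `@pop` arc, so tutorial
content is configuration text, not code.

The shipped default script follows the canonical session shape: greeting →
optional education module → seven-facet interview plus three preference
questions → criteria confirmation → search → staged presentation →
refinement → summary → farewell. Several deliberate properties:

* **Only menus.** The user's display name is the single piece of free
  text in the system; every other input is a menu selection. Age is
  therefore offered as a decade menu (30–80) — a coarseness cost accepted
  to preserve the no-typing rule.
* **Staged disclosure is structural.** The only arc into the level-2 view
  is from level 1, and into level 3 from level 2, so the invariant
  "deeper views only after shallower ones" holds by construction, and the
  tests verify it on random walks.
* **Safety by re-search.** Facets only change in interview states, every
  path from the interview to presentation passes through confirmation,
  and accepting the confirmation re-runs the search. Consequently every
  trial presented at any detail level satisfies the currently confirmed
  criteria at presentation time.
* **Progress.** A search excludes trials already viewed this session, so
  the confirm→search→present cycle consumes the corpus instead of
  looping, and refinement activates exactly when the user runs out of
  matching trials.
* **Read-aloud as re-display.** The original interaction concept pairs
  text with speech; here "go over that again" re-renders the display, and
  the turn contract (utterance + display + choices) is kept so a speech
  layer could attach without engine changes.

Dictionary support is a lexicon of lowercase terms (possibly multi-word)
with plain-language definitions; `extract_difficult_terms()` scans the
tokenized text longest-match-first and reports each term once, in order of
first occurrence. Lexicon membership — not corpus frequency — defines
"difficult", because the lexicon is curated and auditable.

Replay determinism is absolute: the engine itself draws no random numbers,
so a script, corpus, model set and choice sequence reproduce a transcript
byte for byte. Random walks are used only in tests, where 100 seeded walks
over the shipped script all reach the farewell state well inside 500
turns; the exit probability at the summary and confirmation hubs makes
non-termination vanishingly unlikely.

## Synthetic data

`generate_corpus()` emulates a registry extract: facets drawn from
configurable categorical weights (defaults: six cancer types, phase and
type distributions skewed toward treatment trials, 30% of trials offered
anywhere, 40% using an investigational drug), and free text assembled from
sentence templates with punctuation, hyphens and mixed case so the
tokenizer is exercised honestly. For each trial and criterion a true level
is drawn uniformly; with probability `association_strength` a marker word
from that level's pool is embedded in the criterion's section (a neutral
filler otherwise), and with probability `label_noise` the *emitted* label
is flipped to a random other level while the text keeps its true-level
marker. The defaults — `association_strength = 1`, `label_noise = 0`,
`n_trials = 200` — are the clean planted-rule condition; the noisy
condition exercised in the tests (noise 0.1, n = 200) is the stated
robustness condition, not a new default. Marker pools ship with two words
per level per criterion, disjoint within and across criteria: with
uniform levels and two words per pool, each marker appears ~8 times in a
50-example training set, so even small clean training sets cover the whole
vocabulary and recovery is exact.

What the generator does *not* emulate, and what passing tests therefore do
not show: real registry prose (vocabulary breadth, negation, section
cross-references), correlated facets (real phase and type are not
independent), multi-marker and contradictory texts, and rater
disagreement structure beyond symmetric label flips. Results on synthetic
corpora demonstrate that the machinery is correct, not that three ordinal
labels are recoverable from real trial descriptions at any particular
accuracy.

`generate_rct_outcomes()` simulates a two-arm experiment, one row per
participant with independent Bernoulli outcomes (completion,
declared-found, found-correct) and a 7-point rating from a per-arm
discrete distribution. The defaults encode a realistic two-arm comparison
of a conversational versus conventional interface: 42 vs 45 analyzable
participants, completion rates 0.86/0.80, declared-found 0.48/0.40,
found-correct 0.43/0.31, satisfaction centered near 4.8 vs 3.2. Outcomes
are drawn independently per participant and per measure; real outcome
correlations (a participant who completes is likelier to declare success)
are intentionally not modeled, because the generator's purpose is to
exercise the summary and test machinery at known parameter values.

All generators are pure functions of their configuration including the
seed, consume a single pseudo-random stream in documented field order, and
restore the caller's RNG state.

## Statistical conventions

* **Chi-square**: the uncorrected Pearson statistic
  $\chi^2 = n(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ with p from the
  $\chi^2_1$ distribution. No Yates continuity correction — that is the
  convention under which published arm-comparison statistics computed from
  printed 2×2 counts reproduce exactly, and a regression test pins all
  four such tables to the uncorrected form. A zero marginal total is an
  error, not a zero.
* **Mann-Whitney U**: midranks throughout, the conventional
  `min(U, n1·n2 − U)` reported. For `n1 + n2 ≤ 10` the two-sided p comes
  from exact enumeration of all group assignments of the pooled values
  (valid under ties, since midranks are enumerated too): at these sizes no
  normal approximation is adequate — its worst-case error against the
  exact distribution exceeds 0.1 even with a continuity correction, which
  is why the switch is a size rule rather than a tie rule. Above that,
  the normal approximation with tie correction and 0.5 continuity
  correction is used, matching the reference implementation's
  large-sample default to which it is tested equal.
* **Summaries**: sample standard deviations use the n−1 denominator;
  percentages are always reported with their counts.
* Two-sided p values everywhere; no multiple-testing adjustment is
  applied by the package (reporting conventions in this literature apply
  none at the per-table level; adjust downstream if you need to).

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run
comfortably on one core: corpora of 30–200 trials, training sets of
50–200 examples, 100 random filter/query oracle pairs, 1,000 random
chi-square tables against the reference implementation, exhaustive
Mann-Whitney enumeration over all rank arrangements up to `n1 + n2 = 10`,
and 100 random dialog walks. These sizes were chosen as the smallest at
which the properties are sharp (exact equalities, accuracy ceilings,
3-standard-error bands); growing them changes runtimes, not conclusions.
Gain comparisons use a `1e-12` tolerance before the lexicographic
tie-break so that floating-point noise cannot make tree induction
platform-dependent.

## Known limitations

* The ID3 vocabulary is the training corpus minus a short function-word
  stopword list; there is no feature selection beyond information gain,
  and no alternative learners — word occurrence plus ID3 is the modeled
  design point, not a recommendation.
* The dialog scripting language is small by intent: guards and actions
  cover the shipped flow (slot filling, search, staged views, bookmarks,
  subnetworks) and menu providers are engine code, so a structurally
  different dialog needs a provider, not just YAML.
* Inferred-criteria ranking trusts the models; no confidence or
  abstention is modeled.
* The simulated experiment generator draws outcomes independently and
  cannot reproduce participant-level correlation structure.
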