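---
title: "Mining vaccine risk perceptions from short messages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining vaccine risk perceptions from short messages: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

riskmine studies how false health claims on social media attribute effects
to a vaccine. It combines two components: a *veracity classifier* that
labels short messages as true or false information, and an *unsupervised
causality miner* that extracts the "candidate effect" phrases people
causally attribute to a vaccine (risk perceptions), scores them with
normalized pointwise mutual information (NPMI), collapses near-duplicates,
and validates the mined effects against a curated risk-perception lexicon.
This vignette documents the models, their assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## Pipeline overview

`run_pipeline()` chains the stages through files, so each stage can be
inspected and re-run independently:

1. simulate or load a message corpus (JSON Lines);
2. lexical normalization (`normalize_messages()`);
3. classifier training and prediction (`train_classifier()`, `predict()`);
4. high-confidence filter (`filter_by_confidence()`);
5. causal-cue screening (`has_causal_cue()`);
6. candidate cause/effect phrase extraction (`extract_candidate_pairs()`);
7. co-occurrence model and NPMI (`build_cooccurrence_model()`, `npmi()`);
8. collapsing near-duplicate effects (`cluster_effect_phrases()`,
   `collapse_to_representatives()`);
9. per-query effect ranking (`rank_effects()`,
   `cumulative_category_score()`);
10. gold-lexicon matching (`match_statistics()`).

The per-stage record counts the pipeline reports (messages before
filtering, after the confidence threshold, and containing a causal cue, per
predicted class) are the pipeline's accounting artifact; the invariant that
they are non-increasing along the chain is enforced by construction and
re-checked in the tests against recounts of the persisted intermediates.

## Lexical normalization

Short health messages are noisy: URLs, user mentions, retweet markers,
numerals, hashtags, contractions. `normalize_text()` applies a fixed,
ordered rule list — lower-casing; URL removal; tagging of leading retweet
markers, `@user` mentions and numerals as the reserved tokens `RT`,
`MENTION`, `NUMBER`; contraction expansion from an editable CSV table
(`riskmine_contractions()`); hyphen/slash splitting; splitting of joined
letter-digit runs (`"2x"` → `"NUMBER x"`, so joined alphanumeric pairings
become reachable by the numeral rule); removal of hashtag marks and
remaining
punctuation, keeping tag text as a content term; whitespace collapsing; and
reduction of runs of three or more `MENTION` tokens to exactly two.

Two properties are guaranteed for *every* input and enforced by
property-based tests: the function is total (any string yields a possibly
empty normalized string) and idempotent (re-normalizing is a no-op; the
reserved upper-case tokens are shielded from the lower-casing rule to make
this true, and the retweet rule is re-applied once after punctuation
removal because a leading `rt` can first surface there). A 30-pair golden
file freezes the behaviour byte-for-byte across releases. There is no
spelling correction, lemmatization or language identification.

The rules are applied in the order listed above; where the order is
load-bearing (mention collapse versus punctuation removal) it was chosen
so that the stated invariants hold for all inputs, not just well-formed
ones.

## Veracity classification

The classifier family mirrors common practice for short-text veracity
tasks: a convolutional network (CNN) as the primary model, a bidirectional
LSTM, and SVM / Bernoulli Naive Bayes baselines over a binary
document-term matrix (via e1071).

`architecture_spec()` defaults encode the package's full-size configuration: 300-d
embeddings, 256 convolution filters at kernel widths 3/4/5 with ReLU,
max-over-time pooling, a 128-unit dense layer with 0.1 dropout, softmax
output, cross-entropy loss, Adam at learning rate 1e-4 with 0.01 decay and
batch size 32. Open points were resolved as follows:

* **"decay 0.01"** is interpreted as *weight decay*, implemented decoupled
  (AdamW-style) on weight matrices only; `decay_mode = "l2"` switches to a
  classic L2 penalty added to the gradient.
* **Sequence length** is capped at `max_length = 64` tokens
  (pad/truncate); short messages rarely exceed this after normalization.
* **Stopping rule**: early stopping on validation macro-F with patience 5
  and an epoch cap of 50; the best-epoch weights are restored.
* **Seeds** control initialisation, shuffling and dropout through a single
  RNG stream, so identical data/spec/seed reproduce the fit exactly.

No deep-learning framework is used: both neural models are implemented
directly in base-R matrix algebra with hand-derived gradients
(`R/nn-cnn.R`, `R/nn-bilstm.R`). The gradients are verified in the test
suite against central finite differences for every parameter group,
including the embedding table (the `<pad>` row is frozen at zero). The
BiLSTM uses masked mean-pooling over both directions' hidden states and
the same dense head; its hyperparameters beyond the shared optimizer
settings are configurable but carry no claim of parity with any reference.

`split_and_dedupe()` splits 60/20/20 *first* and removes exact-text
duplicates *within* each split afterwards. The order matters for
retweet-heavy corpora: splitting first means a text recurring in several
splits survives once in each, and split sizes are no longer exactly
proportional after deduplication.

`filter_by_confidence()` keeps predictions whose predicted-class softmax
probability reaches a threshold (default 0.998). The filter applies to
both classes by default, because the accounting table it reproduces shows
thresholded counts for both; the narrative use case (mining only
high-confidence false messages) is available via the `classes` argument.

**What the synthetic benchmark does and does not show.** The
synthetic-data generator produces classes with partially disjoint
vocabularies, which makes the task solvable from bag-of-words statistics
alone. On such a corpus Bernoulli Naive Bayes is essentially the
Bayes-optimal classifier, so the real-data ordering CNN > Naive Bayes —
driven by n-gram structure in real text — is *not* reproduced here, and
real-data scores on annotated vaccine tweets cannot be reproduced
without such an annotated corpus. The benchmark
instead certifies mechanics: the CNN reaches macro-F ≥ 95 on a held-out
split of a separable 2000-message corpus, deterministically per seed. The
test suite trains compact configurations (embedding 16–32, 16–32 filters,
16–32 dense units, ≤ 30 epochs at learning rate 1e-3) so the whole suite
runs at desk scale; these sizes are the package's own test-time choice,
and the full-size default remains available.

## Causal extraction

A message asserts causality when it contains a *causal cue*
("causes", "leads to", "due to", ...). The original cue dictionary for
Twitter causality detection is not reprinted anywhere accessible, so
`default_cue_lexicon()` ships a small, explicitly user-replaceable
stand-in; any plain-text file with one cue per line can substitute
(`read_cue_lexicon()`). Cue matching is longest-first and non-overlapping
("lead to" beats "to").

For each cue occurrence, the term sets left and right of the cue become
the candidate *cause* and *effect* phrases — the cue wording
("precipitates") implies cause-before-effect, and a flag-level swap for
passive constructions is deliberately not attempted. All noun phrases on
each side are kept, regardless of any dependency with the cue. Noun
phrases come from a *parse provider* with the contract
`function(tokens) -> chunk terms`. The provider used is `rule_chunker()`:
maximal runs of content tokens (not stopwords, not special tokens) form
chunks, merged into single underscore-joined terms so multi-word effects
("premature ovarian failure") keep their identity inside term sets. No
statistical dependency parser is available in this package's dependency
footprint; the chunker is deterministic, which also makes extraction
reproducible. A dependency-parser-backed provider can be plugged in
without touching the rest of the pipeline. A pair with an empty side is
flagged degenerate rather than dropped, so accounting stays conservative.

`build_phrase_vocabularies()` forms the cause-side and effect-side
vocabularies V_c and V_e by removing stopwords and terms of corpus
frequency 1 (hapax legomena). Special tokens (`MENTION`, `NUMBER`, `RT`)
are excluded as carrying no phrase content.

## Co-occurrence, PMI and NPMI

The counting unit is the candidate pair: for pair *i*, every
(w_c ∈ c_i ∩ V_c, w_e ∈ e_i ∩ V_e) combination increments the joint count
once (set semantics, no within-phrase multiplicity), so a tweet with two
cues contributes once per pair. Laplace smoothing adds α (default 1) to
every joint cell; the joint table is then normalized and the marginals are
its row/column sums, which keeps the model a coherent probability
distribution for any α ≥ 0. With

$$\mathrm{pmi}(w_c, w_e) = \log \frac{p(w_c, w_e)}{p(w_c)\,p(w_e)},
\qquad
\mathrm{npmi}(w_c, w_e) = \frac{\mathrm{pmi}(w_c, w_e)}{-\log p(w_c, w_e)},$$

NPMI ranges over [-1, 1]: -1 means the terms never co-occur (the α = 0,
zero-joint-count convention), 0 means statistical independence, and 1
complete co-occurrence (including the guarded limit p = 1, where the ratio
is 0/0). These are the standard normalized forms; smoothing constant and log base are
configuration (`alpha`, `log_base`), PMI defaults to the natural log, and NPMI is provably base-invariant (asserted to 1e-12 in the
tests). Because marginals derive from the joint, NPMI is automatically
bounded; the implementation additionally clamps floating-point jitter at
the boundaries. Model-based values are tested to 1e-12 against brute-force
nested-loop recomputation from the raw pairs.

## Collapsing and ranking effects

Retweets and near-copies make candidate effects highly redundant. Each
effect phrase is embedded as the arithmetic mean of its per-token vectors
from an *embedding provider* (`token_vectors()` contract). In this
package the default provider is `hash_embedding_provider()`: every token
maps to a deterministic pseudo-random unit vector derived from its bytes,
so identical phrases coincide and unrelated phrases are nearly orthogonal
in moderate dimension. That is exactly the property collapsing needs
(phrase *identity*, not meaning), it requires no model download, and it
makes runs reproducible. A trained provider is available in-package:
`pretrain_embeddings()` fits subword-augmented skip-gram embeddings (word
vectors plus hashed character n-gram buckets, negative sampling), which
also serve the classifier's embedding initialisation and resolve
out-of-vocabulary terms by subword composition. A contextual transformer
provider can be supplied through the same contract.

Clustering is DBSCAN with reachability ε = 0.1 and minimum points 1.
Cosine distance was chosen as the metric because ε = 0.1 is implausibly tight for unnormalized Euclidean
distances between averaged embeddings, and it is switchable
(`metric = "euclidean"`). With min_points = 1 every point is core, so no
phrase is labelled noise — and "cluster cores as representatives" becomes
ill-defined (every member is a core). The package therefore defines the
representative as the cluster *medoid*: minimum summed cosine distance to
the other members, ties broken by higher phrase frequency and then
lexicographically — a deterministic choice that always respects cluster
membership. DBSCAN itself is implemented in the package (~40 lines); no
clustering dependency of the right shape is part of the dependency
footprint, and OPTICS/HDBSCAN are deliberately out of scope.

Ranking treats retrieval of effects for a query q (for example "HPV
Vaccine", normalized through the same pipeline as messages and looked up
on the cause side) as scoring each collapsed effect e by the mean NPMI
over all (query term, effect term) pairs. Pairs with an out-of-vocabulary
member are *skipped* by default; `oov = "zero"` instead counts them as
zero contributions, which penalises partly out-of-vocabulary effects. An effect
with no in-vocabulary pair is flagged undefined and excluded from the
ranking rather than silently scored. Collapsing never changes a surviving
phrase's score, because scores depend only on the co-occurrence model.
`cumulative_category_score()` sums the scores of the effects assigned to
each perception category, retaining per-effect contributions so the totals
decompose into a stacked-bar view (`autoplot()`).

## Gold-lexicon matching

Real consumer risk-perception lexicons of the kind this stage targets
(a few hundred phrases organised into a few dozen categories) are
typically not publicly deposited, so the package ships a *synthetic*
structural stand-in generator (`generate_gold_lexicon()`) and reads any
real lexicon from `phrase,category` CSV. Comparison is on normalized, stopword-free term
sets (a light suffix stemmer is available but off by default):

* **exact** — sets equal ("match" is interpreted as exact set equality
  after normalization);
* **proper** — the candidate is strictly more specific (gold ⊂ candidate:
  mined "early onset menopause" against gold "menopause");
* **reverse** — the candidate is strictly more general (candidate ⊂ gold:
  mined "fatigue" against gold "extreme fatigue");
* **partial** — the sets merely intersect (mined "prevent throat cancer"
  against gold "prevent cervical cancer").

A single (gold, candidate) comparison is exclusive under the precedence
exact > proper > reverse > partial. Across candidates, a gold phrase
counts toward every type some candidate achieves, so the per-type tallies
may overlap and sum to more than the partial-or-proper union — which is
why `match_statistics()` reports that union explicitly, with percentages
over the gold-lexicon size. Coverage percentages on a real lexicon and
corpus depend on those inputs; the worked single-pair examples and the
counting mechanics are what the tests pin down.

## The synthetic corpus generator

`generator_config()` defines the study conditions and
`generate_corpus()` draws from them through a single seeded RNG stream,
so identical configuration and seed give byte-identical corpora.

* **Classes.** Non-cue messages are bags of 4–10 tokens, each drawn from
  the class-specific vocabulary with probability `class_sep = 0.5` and
  from the shared vocabulary otherwise (true-class terms like "prevent",
  "protect", "effective"; false-class terms like "danger", "adverse",
  "deadly"), with injected noise — mentions (including runs of three, to
  exercise the collapse rule), numerals, hashtags, contractions, URLs —
  so the normalizer has real work to do.
* **Causal assertions.** A fraction `cue_rate = 0.3` of original messages
  carry exactly one assertion, rendered as
  `"the <cause> <cue> the <effect terms>"` with optional retweet/URL
  noise; the leading stopword isolates the cause as its own chunk. The
  (cause, effect) pair is drawn from the mixture
  (1 − Σ j_a)·p0(c)·p0(e) + Σ_a j_a·δ(c_a, e_a), where p0 is uniform over
  the cause/effect pools and j_a is association a's `joint_boost`. Because
  every cue message contributes exactly one counted pair, the population
  NPMI of any pair has the closed form implemented by `expected_npmi()` —
  an analytic oracle the empirical pipeline is tested against (within
  ±0.05 on a 10^5-message corpus). Each planted association carries a
  veracity class (adverse-effect assertions circulate as false
  information), which is what lets assertions survive a high-confidence
  classifier filter, as in the real pipeline. Defaults plant five
  associations with boosts 0.06–0.10 against five background causes and
  fifteen background effects.
* **Duplicates.** A `duplicate_rate` fraction of messages are exact
  copies of earlier originals with fresh ids, appended after the
  originals — which is precisely what makes the split-then-dedupe
  accounting testable.
* **Gold lexicon.** For each planted effect, `generate_gold_lexicon()`
  emits phrases engineered to elicit each match type: the effect itself
  (exact), a strict sub-phrase (proper — the *mined* effect is then the
  more specific form, matching the worked example where mined "early
  onset menopause" properly matches gold "menopause"), strict
  super-phrases (reverse), and an overlapping-but-incomparable variant
  (partial, when the effect has at least two terms).

What the generator does **not** emulate: real lexical n-gram structure
(hence the Naive Bayes caveat above), network structure, timestamps, user
metadata, engagement, or the character-length profile of real messages.
Passing tests certify the pipeline's mechanics and statistical
consistency, not real-world classifier accuracy or real coverage rates.

## Numerical choices and degenerate inputs

* NPMI conventions: joint probability 0 → −1; joint probability 1 → 1
  (division-by-zero guarded); values clamped to [−1, 1] against
  floating-point jitter; oracle equivalence asserted at 1e-12.
* Ranking ties break lexicographically; medoid ties by frequency, then
  lexicographically; `max.col` pooling ties take the first index.
* Empty-token messages predict the training-majority label at confidence
  0.5 with a warning; empty candidate sets yield a zero-coverage match
  report with a warning; a query with no in-vocabulary term, or an
  extraction that yields no pairs, aborts with a stage-named diagnostic.
* Degenerate candidate pairs (empty side) are flagged, persisted, and
  contribute nothing to the co-occurrence counts.
* The acceptance-style checks run at the study conditions: 20 seeds ×
  5000 messages for association recovery, a 2000-message separable corpus
  for the classifier benchmark, 200 phrases (20 planted × 10 perturbed
  copies) for collapsing fidelity, 10^5 messages for oracle convergence.

## Known limitations

* The rule chunker approximates noun phrases; genuine parses would split
  some long content runs it merges. The provider contract exists exactly
  so a parser can replace it.
* The default cue lexicon is a stand-in, not the original dictionary;
  screening rates depend on it.
* Real-data headline numbers (classifier scores on annotated vaccine
  tweets, corpus filter counts, gold-lexicon coverage of the real
  lexicon) require data that is not deposited anywhere and are out of
  scope by design; the package reproduces the *procedures* and their
  analytic properties.
* The light stemmer is intentionally minimal; for morphologically rich
  matching, pre-stem the phrases upstream.
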