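---
title: "Distant supervision, noise reduction and transfer learning in dsre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distant supervision, noise reduction and transfer learning in dsre}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dsre` implements a complete pipeline for augmenting a small manually
annotated (MA) relation-extraction corpus with a large, automatically
labeled (DS) one. This vignette documents the modelling assumptions, the
parameters that matter, the design decisions taken where the procedure was
genuinely open, and what the synthetic benchmark does and does not show.

## The distant-supervision assumption and its failure modes

Distant supervision labels an instance — one sentence with one mention pair
— positive whenever the pair of normalized entity identifiers appears in a
relation knowledge base, and negative otherwise. The labeling never reads
the sentence, so it errs in two systematic directions:

* **Co-occurrence false positives.** A truly related pair can be mentioned
  for many reasons (contrast, enumeration, shared assay) without the
  sentence expressing the relation.
* **Incompleteness false negatives.** Knowledge bases are incomplete; a
  sentence expressing a relation for an unrecorded pair is labeled
  negative.

A third, more mechanical artifact arises when one entity is mentioned
several times in a sentence: every pairing is labeled positive although
usually only the closest one participates in the stated relation.

Candidates are enumerated strictly within sentences. Mention pairs that
normalize to the same entity identifier are excluded (`REMOVED`) rather
than labeled: self-interactions are out of scope, and leaving them negative
would plant systematic noise. For undirected relations, slot 1 is the
mention whose span starts first, which makes featurization and piecewise
segmentation deterministic.

## Noise-reduction heuristics

All heuristics share two invariants: no instance ever flips between POS and
NEG (the only transition is to `REMOVED`), and each step appends its tag to
the instance's provenance trail, so every label can be audited.

**Closest pair (CP)** groups positive instances by (sentence, entity-ID
pair) and keeps the one minimizing the token count between the inner span
boundaries. Distance ties keep the instance whose left mention starts
first (then the left-most right mention) — an arbitrary but fixed rule that
makes the filter deterministic.

**Trigger word (TW)** rests on the observation that expressed relations
almost always carry a lexical trigger, usually a verb, sometimes its
nominal or adjectival form. Trigger mining is reconstructed as follows:
candidate lemmas are tokens with verbal/nominal/adjectival POS tags (tags
starting V/N/J) inside the inter-entity span extended by `trigger_window`
(default 2) tokens on each side; each lemma is scored by the smoothed
log-ratio `log((c_pos + 1)/(c_neg + 1))` of instance-level occurrence
counts; the `trigger_top_k` (default 20) best-scoring lemmas form the
lexicon, ties broken lexicographically. One amendment proved necessary:
**only positively scored lemmas are admitted**. In a lexically narrow
corpus fewer than `top_k` lemmas may score above zero, and padding the
lexicon with lemmas that are *more* frequent in negatives would make the
filter vacuous — a lemma carrying no positive evidence is no trigger.
Lemmatization is a rule-based suffix stripper (`ions/ion/ing/ed/s`, with a
small irregular table for *be/have/bind*); it conflates the inflected
trigger variants that actually occur and a full lemmatizer would add a
dependency without changing the decisions.

**High-confidence pattern (HP)** mines inter-entity templates from the
positive set: lowercased surface tokens from the left mention through the
right mention plus `pattern_tail` (default 1) following tokens, with the
two target spans replaced by `ENTITY1`/`ENTITY2` and other same-type
mentions by `ENTITY`. Templates separated by more than `pattern_max_len`
(default 10) tokens are not extracted — long gaps make template identity
meaningless. Templates with support at least `pattern_min_support`
(default 10) among positives mark negatives for removal; matched negatives
are removed, **not** relabeled positive, since pattern match is evidence of
mislabeling, not proof of the relation.

**Top-k entity filter.** For the localization task the trigger concept is
unreliable (the relation is often expressed without a verb), so pipelines
for that task use CP only, optionally restricted to the `k` most frequent
entities in one slot; entities tied with the rank-k frequency are all kept.

## Featurization

Each token is the concatenation of six channels (defaults in parentheses):
word embedding (200), POS-tag embedding (10), incoming-dependency embedding
(10), embeddings of the signed distances to entity 1 and entity 2 (5 each),
and a 4-d one-hot role vector — 234 dimensions. Distances are measured in
tokens from the nearest span boundary (0 inside the span, −1/+1 for
adjacent tokens) and clipped to ±50 to bound the distance vocabulary.
Sentences are padded with all-zero rows, or pruned from the right, to
`max_len` = 100 tokens; instances whose mentions fall beyond the pruning
point are rejected with a dedicated error class and counted, never silently
dropped.

The categorical-channel embeddings are *learned* parameters, initialized
uniform(−0.1, 0.1) from a seed, updated by backpropagation, and counted
among the "feature" weights for transfer (a configuration flag excludes
them). Word embeddings are pre-trained input and stay fixed.
Out-of-vocabulary words receive a deterministic pseudo-random vector with
components uniform(−0.05, 0.05) keyed by (word, seed), so repeated runs and
repeated lookups agree exactly.

Multi-token mentions use their span *ends* for segmentation and their
nearest boundary for distances; the earlier-ending entity closes segment 1
and the later-ending one closes segment 2, so each of the first two
segments ends with its entity and empty segments are legal (e.g. when the
second entity is sentence-final).

## Models and training

**PCNN.** A window-3 same-padded convolution (tanh, 400 filters) over the
token matrix, max-pooled separately over the three entity-delimited
segments (an empty segment contributes zeros), concatenated to a 1200-d
vector, then a dense softmax over {positive, negative}. Convolution and
pooling are restricted to the unpadded rows, so padding content can never
influence the output.

**BiLSTM.** Forward and backward LSTMs (400 units each) over the unpadded
rows; the readout concatenates the two final hidden states (800-d) before
the dense softmax. Max-over-time is available as a configuration
alternative (`bilstm_readout = "max"`); final-state concatenation is the
default because it is the convention of the bidirectional PPI models this
architecture follows.

Both models train with mini-batch Adam (batch 128, lr 0.001, binary
cross-entropy); the PCNN applies staircase exponential decay (×0.95 every
1000 steps), the BiLSTM a constant rate. Dropout acts only in training
mode: 0.5 on the convolutional feature map / recurrent readout, 0.2 on the
dense input. Prediction ties at probability 0.5 resolve to negative — the
conservative choice for a precision-oriented extraction task. Forward and
backward passes are hand-written matrix code; the analytic gradients of
every learnable weight, including the categorical embedding tables, are
verified against central finite differences in the test suite (relative
tolerance 10⁻³ at ε = 10⁻⁵).

Epoch budgets follow the two-phase design: 30 epochs on DS and mixed data,
200 (PCNN) or 100 (BiLSTM) on MA data and during fine-tuning — MA sets are
tiny, so many passes are affordable, while DS corpora are large and noisy
and long training mostly fits the noise.

**Transfer.** `transfer_params(source, mode)` copies either every weight
(`ALL`) or the feature weights only (`FEATURES_ONLY`, classifier
re-initialized from a seed). Nothing is frozen: fine-tuning adjusts all
weights. The parameter partition {feature, classifier} covers each
learnable array exactly once, which is what makes the two transfer modes
well-defined.

## Evaluation

Precision, recall and F1 are reported as percentages over POS/NEG instances
only, with 0 substituted when a denominator vanishes. Cross-validation
partitions *documents*, not instances, into folds by a seeded shuffle —
instance-level folding would let near-duplicate sentences from one abstract
straddle train and test. Fold confusion counts are pooled (micro-averaged)
rather than averaging per-fold F1, which is ill-defined for folds without
positives. The learning-curve runner subsamples MA training documents
nested across fractions (the 25 % documents are a subset of the 50 %
documents) to reduce variance between fraction points; held-out test
documents are never subsampled.

## The synthetic benchmark

The generator plants exactly the phenomena the pipeline targets, on a
closed template grammar with a 12-tag POS / 10-label dependency inventory:

* a world of 120 entities with 150 truly related pairs, of which 20 % are
  withheld from the *observed* KB (incompleteness false negatives);
* sentences about a related pair express the relation with probability
  0.7 (i.e. `cooccurrence_fp_rate = 0.3`), using one of ten trigger verbs
  either between the entities or after an `ENTITY1 and ENTITY2` frame;
* 20 % of relation sentences repeat the second entity farther away, making
  the closest pairing the gold-correct one;
* non-relational sentences draw connectors, auxiliaries, verbs and nouns
  from independent distractor slots, so no spurious inter-entity template
  recurs often enough among co-occurrence false positives to reach the
  HP support threshold — mirroring the lexical diversity of real text at a
  scale a desk-size corpus can afford;
* gold labels are recorded per mention pair at generation time,
  independently of any KB.

The standard benchmark is 2000 DS sentences and a 10× smaller gold-labeled
MA corpus (40 documents of 5 sentences), with seeded 25-d embeddings over
the closed vocabulary. These sizes were chosen so that a full
raw-vs-cleaned comparison plus the regime suite runs in minutes on one CPU
while keeping every count (template supports, trigger statistics) far from
small-sample degeneracy. The models used on it are correspondingly reduced
— 50 filters, 25-d word channel, 5 DS epochs, 20 MA/fine-tune epochs —
keeping the architecture, loss and optimizer identical to the full
configuration.

What passing on this benchmark shows: the labeling, filtering,
featurization, training and transfer machinery interact correctly, the
heuristics remove precisely the planted noise, and the qualitative regime
ordering (transfer learning ≥ MA-only ≥ naive union, larger transfer gains
with scarcer MA data) emerges for the planted noise structure. What it does
not show: performance on real biomedical text, whose lexical and syntactic
diversity, annotation guidelines, tagger/parser errors and class imbalance
the closed grammar deliberately does not model. Numbers obtained on the
benchmark are not comparable to numbers on AIMed-like corpora.

## Degenerate inputs and numerical notes

* Overlapping or nested mentions are rejected at read time; the pipeline
  never guesses a resolution.
* Empty pooling segments contribute zeros; an all-zero input yields a
  bias-determined prediction.
* A directed KB checks the (slot 1, slot 2) order as stored; an undirected
  KB canonicalizes pairs lexicographically on insert, making membership
  symmetric by construction. Self-pairs are dropped with a warning count.
* Training on a single-class instance set is an error, not a silent
  degenerate fit; transfer into a model of a different kind
  (PCNN ↔ BiLSTM) is an error.
* Transfer-learning pretraining on an empty DS set degrades to MA-only
  training with a warning.
* All randomness (initialization, shuffling, dropout, fold assignment,
  subsampling, the generator) flows from explicit integer seeds through
  stream labels, and package functions restore the caller's RNG state.

## Known limitations

* The trigger-mining and pattern-confidence procedures are principled
  reconstructions (scoring formula, window, thresholds are configurable)
  rather than ports of a reference implementation.
* The rule-based lemmatizer under-conflates irregular English morphology
  outside its exception table; on real corpora a proper lemmatizer should
  be substituted upstream.
* Class imbalance is left unweighted; cost-sensitive losses are future
  work.
* The PubTator adapter requires mention offsets aligned to whitespace
  token boundaries and carries no POS/dependency information; it is a
  convenience for entity-annotated raw text, not a parser substitute.
* Multi-instance (at-least-one) learning formulations of distant
  supervision are deliberately out of scope.
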