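---
title: "Methods: weakly supervised NER for EMS narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly supervised NER for EMS narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsner)
```

## The task and the weak-supervision model

Paramedic case reports are short telegraphic narratives. The goal is to
locate and type every mention of 17 clinical entities in three categories
(clinical procedures such as ECG and stroke assessment, clinical findings
such as bleeding, and medications such as aspirin or GTN), so that
protocol-adherence audits can be automated. No labelled data exists;
instead, a curated synonym lexicon generates *pseudo-labels* over the whole
corpus, and a sequence tagger is trained on those. The tagger then
generalizes beyond the lexicon (context can rescue misspelled or truncated
surface forms that dictionary matching alone would miss).

Negation is deliberately not modelled: for audit purposes a documented
entity counts as documented, whether asserted or negated.

## Preprocessing

`normalize_text()` lower-cases, applies Unicode NFKC folding, replaces
every character outside `a–z 0–9 % &` (plus space) by a single space,
collapses whitespace and trims; `tokenize()` splits on single spaces.
Three choices deserve comment:

* **Symbols are replaced by a space, never elided.** "c/o" must become
  "c o", and "0.4" must become "0 4"; eliding would fuse tokens and change
  the vocabulary.
* **`%` is kept** (oxygen saturation, fluid concentrations such as
  "ns 0 9%"); **`&` is kept by default** because shorthand like "a&e" is a
  single lexical unit in this register. Both are flags
  (`keep_ampersand`), since the right choice depends on the local
  documentation style.
* **Slashes are removed**, including in date-like shorthand ("2/7" becomes
  "2 7"). Slash-bearing forms are too heterogeneous ("c/o", "o/a",
  "115/57") for a retain rule to be consistent.

Normalization is idempotent, and tokenize-then-join reproduces the
normalized string exactly; both properties are tested.

## The lexicon and fuzzy matching

A lexicon row is (entity, phrase, `exact_only`); phrases are stored in
normalized form. Matching against a tokenized report proceeds per phrase:

* **Exact matching** finds every token window equal to the phrase,
  including overlapping self-occurrences.
* **Fuzzy matching** applies only to phrases whose single-space-joined form
  has at least 5 characters and that are not flagged `exact_only`. A window
  matches if its joined form equals the phrase or equals it with **exactly
  one character deleted** — no insertions and no substitutions. The
  deletion may fall anywhere in the character stream, including a boundary
  space, which merges two tokens; hence for a k-token phrase both k- and
  (k−1)-token windows are candidates, pre-filtered by joined length.

The strict one-deletion semantics (rather than Levenshtein ≤ 1) is the
deliberate default: substitution-type misspellings ("salbutumol",
"facial drop" → "facial droop" is a deletion, but "aspirim" is not) are a
*known residual error family* of this labeling scheme, and widening the
matcher would trade precision for them. A `mode = "lev1"` option exists
for experimentation. The 5-character gate applies to the joined phrase,
not to individual tokens: short phrases fuzz-matched would flood the
labels with false positives.

Overlapping candidates are resolved greedily under a total order: longer
span first, then exact before fuzzy, then smaller start, then
lexicographically smaller entity name. The order is invented plumbing (any
deterministic rule would do), but it encodes two sensible preferences:
maximal surface forms ("12 lead ecg" over its inner "ecg") and
higher-confidence match sources first.

`mentions_to_iob2()` and `iob2_to_mentions()` interconvert mention sets
and the fixed 35-tag IOB2 vocabulary (`O` plus B-/I- per entity; the tag
set never shrinks to the entities present in a split, so model output
layers are always comparable). The inverse direction repairs stray `I-`
tags — model output is not guaranteed IOB2-valid — by opening a new
mention, and the round trip is exact on valid input.

## Corpus management

* **Splits.** `split_corpus()` permutes under a seed and cuts at
  cumulative half-up-rounded boundaries, remainder to train. For 44,211
  reports at 95/2.5/2.5 this yields 42,000 / 1105 / 1106 — matching the
  reference corpus bookkeeping. (The source description carries an
  internal inconsistency about the training count, 42,000 vs 41,984;
  the cumulative rule reproduces the split counts that are arithmetically
  consistent.)
* **Statistics.** `corpus_stats()` reports per-entity mention counts,
  entity-token counts, average tokens per entity (ATE = tokens/mentions,
  printed half-up at 2 decimals) and mention shares (half-up at 1 decimal
  percent). Half-up rounding is used everywhere a printed table cell is
  reproduced, because banker's rounding cannot.
* **Vocabulary and padding.** The vocabulary is built from the training
  split only; index 1 is padding, index 2 unknown. `pad_batch()` masks
  padding positions, and the loss provably never reads them (a test
  randomizes tags under the mask and asserts bit-identical loss).
  The tagger pads per batch to the longest member rather than to a global
  constant: with masked loss the two are equivalent, and a test asserts
  the equivalence directly.
* **Subtoken aggregation.** For subword tokenizers, a word's tag is the
  majority vote over its subtokens' non-`O` tags (all-`O` gives `O`), ties
  broken by first occurrence. Whether the vote should pool B-/I- variants
  of one entity is ambiguous; full-tag voting is the default and
  `level = "type"` the alternative.

## The BiLSTM-CRF

Architecture: trainable word embeddings (default dim 100) feed a
bidirectional LSTM (default 64 hidden units **per direction**; the
concatenated output is 128-dimensional), a linear projection produces
per-token emission scores over the 35 tags, and a linear-chain CRF with
transition, start and end scores defines the sequence distribution. The
negative log-likelihood is `log Z − score(gold path)`, with `log Z` from
the forward algorithm in log space (max-shifted; emission magnitudes up to
1e3 are safe). Prediction is Viterbi decoding, ties broken toward the
lower tag index.

All gradients — CRF expected counts via forward–backward,
backpropagation-through-time through both LSTM directions, and the
embedding scatter-add — are derived and implemented by hand on BLAS-backed
matrix operations, and verified against central-difference numerical
gradients in the test suite (relative error below 1e-4 at every sampled
coordinate). The CRF forward and Viterbi pass are verified against
exhaustive path enumeration for small problems.

Training uses Adam (default learning rate 0.001, batch size 512), epoch
shuffling seeded from the configuration, early stopping when the dev loss
fails to set a new running minimum for `patience` (default 5) consecutive
epochs, a 300-epoch cap, and restoration of the best-dev-loss parameters.
"Did not decrease" is read against the running minimum (the standard
reading); `stop_rule = "previous"` implements the alternative.

Further deliberate choices: embeddings are **zero-initialized by default**
(rows differentiate through word-specific gradients); this demonstrably
slows early learning, so `embedding_init = "uniform"` exists and is used
in the scaled experiments. No dropout. No hard transition constraints —
invalid I-after-O output is repaired downstream by `iob2_to_mentions()`.

## Evaluation

Each prediction is categorized independently against the gold mentions of
its report (MUC-5): exact span-and-type match → COR; overlapping span
(≥ 1 shared token index) with the correct type → COR under
*entity-type matching*, INC under *strict*; overlapping span with the
wrong type → INC; no overlap → SPU. A gold mention that no prediction
overlaps → MIS. PAR never occurs in these two modes. Because
categorization is prediction-driven, one gold mention overlapped by
several predictions is counted against each, so POS = COR + INC + MIS can
exceed the number of gold mentions — this is the only reading consistent
with the published count tables, and it is why POS/ACT rather than raw
mention counts are the metric denominators: P = COR/ACT, R = COR/POS,
F1 = 2PR/(P+R). A prediction overlapping several golds is scored against
the first in span order (documented tie-break); zero denominators give
zero metrics with a warning.

Token-level metrics compute per-class precision/recall/F1 from the token
confusion and average them weighted by gold support over every class
except `O`, which contributes neither metric nor weight.

An independently written naive scorer cross-checks the MUC counts on
random mention sets in the tests, together with the invariants: identity,
count conservation, gold/prediction symmetry (MIS↔SPU, P↔R), and mode
dominance (type-matching F1 ≥ strict F1 always).

## The synthetic generator

Because the source reports are restricted, validation uses generated
corpora. A report is assembled from entity-free filler phrases and entity
surface forms drawn from the lexicon:

* **Entity frequencies** default to the reference training-split mention
  shares (ECG ~50.6%, bleeding ~14.1%, stroke assessment ~12.5%, ...).
* **Mentions per report** are 0–4 with probabilities (.30, .35, .22, .09,
  .04), mean ≈ 1.2, which lands near the reference ~2.7% entity-token
  share at the default report lengths.
* **Report lengths** are uniform on 30–120 tokens, echoing the published
  example narratives.
* **Misspellings**: with probability 0.05 per mention, one character of
  the joined surface is deleted, position uniform over *safe* positions —
  a space (merging two tokens) or a character of a token with at least two
  characters. Deleting the only character of a single-letter token would
  collapse two separators at once and amount to a double deletion, outside
  the error model the fuzzy matcher targets, so such positions are
  excluded. Surfaces under the 5-character gate are never misspelled.
  A substitution mode exists to generate the error family the
  deletion-only matcher is *expected* to miss; `exact_only` phrases are
  never misspelled, since they opted out of fuzzy recovery by definition.
* **Fillers are token-disjoint from all lexicon phrases** (validated at
  generation time). This makes gold annotation exhaustive by construction
  — no accidental unlabeled entity can occur — which is the precondition
  for treating generator output as ground truth, and it yields the exact
  generator–labeler consistency law tested in the suite: at
  `misspell_prob = 0` the weak labeler reproduces gold with precision and
  recall 1; with deletion misspellings and fuzzy matching on, recall
  remains 1.

What the generator does **not** emulate: the real corpus's vocabulary
breadth (~39k types vs. a few hundred here), substitution/transposition
misspellings (unless asked), negated mentions, non-entity phrases that
resemble entities, and discourse structure. Passing end-to-end tests on
synthetic data therefore demonstrates the *machinery* — labeling
soundness, learnability of the pseudo-label distribution, correct scoring
— not field performance on real reports.

## The scaled end-to-end experiment

The full-scale reference experiment (44k reports, batch 512, up to 300
epochs) is not a desk-scale computation, and its corpus is restricted. The
package's end-to-end acceptance experiment instead trains on 2,000
weak-labeled synthetic reports (1,800 train / 200 dev) and scores on a
clean 200-report synthetic test split, three seeds, median reported. The
architecture keeps the reference dimensions (embedding 100, hidden 64 per
direction). The training profile is scaled to the corpus: batch size 32
(batch 512 would give only four gradient steps per epoch at n = 2000,
where the reference setting took ~80 per epoch at n = 42k), learning rate
0.003, uniform embedding initialization, at most 15 epochs with patience
5. These values were fixed as the experiment's design before its
acceptance thresholds were evaluated. Expected behaviour: entity-type
matching F1 ≥ 0.90 and strict F1 ≥ 0.85, the desk-scale analogue of the
reference model's ~0.98.

## Numerical conventions and degenerate inputs

* Half-up rounding (`round_half_up()`) for all printed-precision
  reproduction; full precision retained alongside.
* Log-sum-exp everywhere in the CRF; all-`-Inf` columns are handled.
* Viterbi ties → lower tag index; subtoken-vote ties → first occurrence;
  overlap-resolution ties → the documented total order.
* Empty report → empty prediction; empty lexicon → all-`O` tags; zero
  mention counts → `NA` ATE; ACT = 0 or POS = 0 → zero metric with
  warning; empty training corpus → error.

## Known limitations

* The lexicon shipped as `default_lexicon()` is a compact starter seeded
  from surface forms typical of the register; real deployments must curate
  their own per EMS system, and labeling quality is bounded by lexicon
  coverage.
* Substitution misspellings defeat the deletion-only matcher by design;
  spelling correction is out of scope.
* Nested, overlapping and discontinuous mentions are not representable.
* The tagger is a from-scratch implementation in R; it is deliberately
  CPU-sized (minutes for thousands of short reports) and does not target
  GPU-scale corpora.
* Pretrained-transformer fine-tuning is out of scope; of that model
  family, only the subtoken tag-aggregation rule is implemented.
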