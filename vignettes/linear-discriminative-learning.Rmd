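---
title: "Modeling inflection with linear discriminative learning"
author: "discrimlex"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Modeling inflection with linear discriminative learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discrimlex)
```

# The model

discrimlex implements linear discriminative learning (LDL): comprehension
and production of inflected words as linear mappings between a binary form
space and a real-valued semantic space. There are no stems, exponents or
rules anywhere in the machinery; whatever morphological structure the model
exhibits emerges from the regression between whole-word form vectors and
compositional meaning vectors.

**Form.** A word is the set of its sublexical n-gram cues, extracted from
the boundary-padded string (`#al@#` for *al@*). The cue matrix `C` has one
binary row per paradigm cell realization; homophones have identical rows by
construction, which is the formal heart of everything the model says about
German-style case syncretism. Cue order in the inventory is
first-occurrence order over the training data: the choice is arbitrary but
deterministic, so rebuilding an inventory from the same lexicon is
byte-identical. A form shorter than the n-gram size collapses to the single
padded cue (`#a#`), keeping extraction total.

**Meaning.** A cell's semantic vector is the sum of its lexeme vector and
one vector per inflectional feature (number, case **or** semantic role,
optionally definiteness), plus Gaussian noise drawn once per entry. Number
is treated as an equipollent opposition by default (both SINGULAR and
PLURAL have vectors); a privative mode (singular unmarked) is available.
Simulated vectors are i.i.d. Normal: sd 4 for lexemes and features, noise
sd 1. With these defaults an inflected word's vector is numerically
dominated by its inflectional features; `featureScale` shrinks the feature
vectors (1/110 in the wug regime) to let the lexeme dominate instead.
Feature vectors are fixed across entries; only the entry noise is redrawn —
whether reused features should also be perturbed is underdetermined, and
fixed features keep the compositional account clean. Gender never receives
a semantic vector: it is a lexical classification, not a meaning
difference. Empirical embeddings can replace simulated vectors; they are
looked up by surface form, so homophones share vectors exactly, and
`deriveAnalyticalVectors()` reconstructs lexeme/feature vectors from them
by plain averaging.

**Mappings.** `estimateEndstate()` returns the minimum-norm least-squares
solution `W = X⁺Y` via the SVD pseudoinverse. Minimum-norm matters: with
homophones `C` is always rank-deficient and plain normal equations are
singular. No intercept is fitted — the network formulation `S = C F` has
none, and adding one would break the equivalence between the regression
solution and the converged network. `trainIncremental()` starts from zero
weights (the discriminative-learning convention) and applies one
Widrow-Hoff update per token. The update is stable for learning rates
below `2/λ_max(CᵀC)`; `stableLearningRate()` computes that bound, training
monitors divergence explicitly, and the package default η = 0.001 is a
conservative generic choice (the originating analyses never report η, so
it is declared, not inferred).

**Comprehension evaluation.** Predictions are compared against *all* gold
vectors (training and validation) by Pearson correlation; ties break to
the lowest row index, and zero-variance vectors get r defined as 0 rather
than NA so degenerate rows are scored, not dropped. Strict scoring demands
the entry's own row win; lenient scoring accepts any row sharing the
surface form. The blind validation accuracy (`val_all`) is the lenient
criterion over every validation entry including novel-lemma entries: that
is the only reading under which the overall accuracy decomposes exactly
into the count-weighted homophone and new-form accuracies, and the suite
asserts that identity.

**Production.** Cue supports `ĉ = s G` feed a path search over the
directed graph whose edges connect cues overlapping in n−1 symbols. A word
is a boundary-to-boundary path; cycles are legal (reduplicating strings)
and bounded by `maxPathLength`, defaulting to the longest training path
plus two. Candidates are ranked by synthesis by analysis: project the
candidate's cue vector through `F`, correlate with the target meaning,
rank descending; ties break shorter-path-first, then lexicographically, so
output is deterministic. Graph mode admits cues with support ≥ θ plus at
most `tolerance` sub-threshold cues per path — tolerance exists because a
validation form can contain one cue that training never supported, and a
small allowance recovers exactly those forms. Positional mode is this
package's concrete definition of the top-k positional algorithm: for each
word position an end-state mapping from `S` to "cue x occurs at position
p" indicators is fitted with the same machinery, and each search step is
restricted to the top-k cues for its position. A brute-force enumerator
(`enumeratePathsBruteforce`) provides the oracle that graph-mode search is
tested against on small inventories.

**Threshold calibration.** θ trades accuracy against search cost and needs
per-dataset tuning. `calibrateThreshold()` picks the median over training
entries of the minimum support among the entry's own cues: half the
training forms then retain every cue they need. This is deliberately
conservative — it caps training production near 50% while keeping the
candidate space small; analyses that want maximal accuracy should lower θ
toward the low quantiles of those minima.

# Role frequencies

For words in context, case labels are replaced by semantic roles drawn
per case (nominative: agent 50%, theme 40%, patient 10%; genitive:
possessive 90%, partitive 10%; dative: beneficiary/location 50% each;
accusative: patient 40%, motion 30%, experiencer 30%). Token frequencies
at the role level are simulated: a form's frequency is split equally over
the paradigm cells realizing that exact surface string (the homophone
group, article included if attached — four cells for a feminine singular);
within a cell each of the K roles is dropped independently with
probability 1/K (so on average one role per cell disappears, which the
suite verifies over 10,000 cells); surviving roles split the cell share in
proportion to their renormalized probabilities, rounded **up** to the
nearest integer. Ceiling-plus-renormalization is a reconstruction: the
published worked example (frequency 137 over four singular cells) is
reproduced cell-for-cell only under this rule (35 = ⌈34.25⌉,
20 = ⌈34.25·5/9⌉, 16 = ⌈34.25·4/9⌉, 18 = ⌈17.125⌉), whereas truncation or
unrenormalized allocation contradict it. Likewise the per-form (rather
than per-lemma) denominator for the cell share is the reading consistent
with that arithmetic.

# The synthetic generator

`generateToyLexicon()` produces German-like paradigm lexicons so every
experiment is reproducible without distributable corpus data. It emulates,
by construction: five plural classes at the corpus type-frequency mix
(-en 56.5%, -e 23.9%, -er 2.3%, zero 13.3%, -s 2.6%, renormalized), each
non-en/s class fronting the final stem vowel with probability 0.5; the
declension homophony template (nominative/dative/accusative singular
identical; masculine/neuter genitive singular in -s, feminine singulars
all identical; nominative/genitive/accusative plural identical; dative
plural in -n unless the plural already ends in n or s); one Zipf-drawn
token frequency (`P(k) ∝ k^-a`, a = 1, support 1..1000) shared by all
cells realizing the same form; a 35/45/20 m/f/n gender mix; and
CV-maximal-onset syllabification over its own alphabet so syllable-cue
mode is testable. Stems are alternating CVC strings — phonotactically
plausible but *not* faithful German; frequencies are i.i.d. rather than
rank-correlated with lemma identity; and lexeme meanings are orthogonal
rather than clustered. Tests passing on these lexicons therefore establish
the mechanics (homophony handling, frequency effects, generalization
patterns), not corpus-level accuracy values, which depend on a real
lexicon.

Wug nonces are built by swapping the onset consonant of an attested form,
keeping its entire rhyme — nonce items with existing rhymes keep most of
their cues trainable, which is the precondition for meaningful nonce
comprehension. The wug pipeline estimates a nonce's nominative-singular
meaning through the comprehension mapping, retrains production on real
words plus the nonces (end-state estimation; the retraining regime is
underdetermined and end-state matches the rest of the pipeline), shifts
each meaning by PLURAL − SINGULAR, and synthesizes ranked plural
candidates. The packaged demonstration nonces (`wugNonceForms()`) are
letter strings for letter-bigram runs; the stem-fidelity property (top
candidate contains the nonce) is asserted on a dense regular fixture — 60
CVC lemmas over a six-consonant/three-vowel alphabet, a single -e class —
because on sparse fixtures the model reproduces the attraction of nonces
to existing words, which is linguistically interesting but not a test of
mechanics.

# Numerical choices and degenerate inputs

- Pseudoinverse tolerance is MASS::ginv's default (relative to the largest
  singular value); end-state fits are checked post hoc by the
  normal-equation residual `Cᵀ(S − CF) ≈ 0` in the suite.
- Pearson r on constant vectors is defined as 0 (logged, never NA).
- A validation entry none of whose cues are known vectorizes to a zero row
  and is flagged; in the wug pipeline such nonces are rejected by name.
- Splits are seeded; under the no-novel-cues mode, validation candidates
  are visited rarest-cue-first and moved into training when uncovered,
  which minimizes forced moves; a cue occurring in exactly one form forces
  that form into training with a message.
- Checkpoints beyond the stream length are dropped with a warning.
- Empty candidate lists score as production errors and carry a diagnostic
  attribute naming the failure (no admissible initial cue vs. no complete
  path).

# Problem sizes

The test and acceptance runs use small, seeded problems chosen to finish
quickly while exercising every code path: 20–320-entry lexicons (10–40
lemmas), cue inventories of 30–250 triphones, semantic dimensions equal to
the cue count (the package's default convention), 500-epoch convergence
runs on 20–35 forms, a 200-entry Zipfian lexicon (≈27,000 tokens) for the
single-pass frequency contrast, and 100 random ≤12-cue inventories for the
path-enumeration oracle. All of these are the package's own choices of
demonstration scale; the machinery itself is size-agnostic.

# Known limitations

Linear mappings cannot represent non-linear form–meaning relations; where
accuracy drops, that linearity bound is the diagnosis, not a bug. The
model operates on isolated words: strict accuracy on homophones is bounded
by 1/(group size) in principle, and only context (articles, roles — both
implemented — or syntax, not implemented) can raise it. Incremental
production (positional supports under Widrow-Hoff) is not implemented;
incremental training covers comprehension, matching the end-state-only
production pipeline. The generator does not attempt phonotactically or
semantically faithful German, and embeddings must be supplied externally —
the package never trains them.
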