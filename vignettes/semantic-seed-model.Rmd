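---
title: "Bootstrapping noun and verb categories from a semantic seed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrapping noun and verb categories from a semantic seed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(semseed)
```

## The learning problem and the model

Toddlers work out which words of their language are nouns and which are
verbs long before anyone teaches them grammar. One candidate mechanism is
distributional: the contexts that words occur in are strongly predictive of
their category (in French and English, determiners precede nouns, personal
pronouns precede verbs). `semseed` implements a deliberately minimal model
of this mechanism:

1. **The semantic seed.** The learner is assumed to already know a handful
   of frequent content words with concrete referents, grouped into
   object-referring words (proto-nouns) and action-referring words
   (proto-verbs). This is the only supervision the model gets. In the
   package the seed is a `seed_lexicon`; the shipped presets `V0`–`V4`
   (8/1 up to 128/12 noun/verb lexemes, French) are nested.
2. **Projection.** The seed is projected as an *incomplete category tier*
   over a POS-tagged corpus: seed tokens are marked `N` or `V`, every other
   token is left unlabeled (`project_seed()`). Matching is by lemma when a
   lemma is available, so inflections of a seed verb project too.
3. **Context counting.** From a training corpus the model memorizes, for
   every token position, the two-word context and the item that filled it
   — the *completer*: the projection symbol for seed tokens, the raw
   surface form otherwise (`train_tables()`). Context words are always
   surface forms, even for seed words. Each utterance is padded with two
   `{` symbols before and two `}` after; no n-gram crosses a boundary.
   Three context schemes are compared: `left` (w−2, w−1), `right`
   (w+1, w+2) and `framing` (w−1, w+1).
4. **Categorization in context.** At test, for each eligible target token
   the model answers the most frequent completer of its two-word context;
   if that trigram key was never seen it backs off to the one-word context
   (the left word for framing contexts); if that bigram is unknown too it
   abstains (`categorize_corpus()`). The answer can be a category symbol
   (useful) or a specific wordform (scored as a non-category answer). The
   model never builds a word-to-category dictionary, so noun/verb
   homographs cost it nothing: each token is classified by its context
   alone.

Targets are restricted to plausible *unknown* words: tokens whose training
frequency is below a threshold (default 0.05% of training tokens,
exclusive — words at or above it are excluded; never-seen words qualify),
and whose nearest context word was seen in training (the model does not
guess with zero information). The threshold is also available as an
absolute occurrence cutoff (`rule = "count"`), since either formulation
may be wanted; the ratio rule is the default.

## Evaluation

Responses are coded noun/verb/other. Per category: a **hit** is a correct
category answer; a **miss** is any other reply on a gold noun (resp. verb)
target — a wordform reply causes only a miss, while answering the *other*
category books one miss and one false alarm; a **false alarm** is a
category answer on a target of a different category. Precision is
hit/(hit + FA), recall hit/(hit + miss); both are undefined (`NA`, never 0)
on an empty denominator. Abstentions are excluded from scoring by default
(misses are wrong *replies*); `abstain_as_miss = TRUE` gives the
sensitivity variant. Two report generators support error analysis:
`miss_breakdown()` (what was answered instead, with wordform replies
classed by their majority gold tag as `item-N`, `item-V`, `ADJ`, ...) and
`frequent_context_report()` (per-context usage, gold-category tallies and
the modal answer; both the all-uses and modal-answer-uses tallies are
emitted because "number of uses" is ambiguous between them).

The **chance baseline** ignores context entirely and draws N/V/other with
probabilities equal to the projected-token proportions of the training
corpus (`chance_rates()`, `chance_predict()`), once per fold with a
derived seed. Its target set drops the known-context condition, since the
baseline uses no context; a matched-targets comparison is available by
passing the same sites.

## Cross-validation design

`split_folds()` cuts the corpus into `k` contiguous, in-order mini-corpora
and splits each 2/3 train / 1/3 test, deterministically. Whether the
original study's mini-corpora were contiguous or randomized is not
documented; contiguous in-order blocks were chosen as the reproducible
default, and a seeded shuffle flag covers the other reading.
`run_experiment()` crosses folds × seeds × schemes (+ chance) and
`summarize_experiment()` reports mean ± SEM over folds.

## The synthetic corpus generator

Real child-directed corpora require downloads and manual tag audits, so
the package ships a generator (`synth_grammar()`, `generate_corpus()`)
that emulates the *statistical skeleton* the model actually exploits:

* short utterances drawn from weighted category templates
  (`DET N`, `PRON V`, `PRON V DET N`, ...), head-initial like French;
* a small closed inventory of high-frequency function words;
* Zipf-distributed content lexicons (default 200 nouns, 120 verbs,
  exponent 1.2 — a size at which a 0.05% threshold separates frequent
  function words from a long rare-content tail, as in real corpora);
* noun/verb homographs: one surface form with two lexeme entries (default
  rate 0.05, roughly the "touche"-type ambiguity rate a learner meets);
* a noise process (default rate 0.05): with that probability a content
  slot is filled by a word of the *other* category, and the gold tag
  records that word's true category. This makes contexts genuinely
  misleading — the analogue of French "tu as faim", where a noun follows
  a frame that usually precedes verbs.

`theoretical_fidelity()` computes, from the template weights and the noise
rate alone, the probability that the word after each function-word (or
boundary) context belongs to that context's majority category — the
ceiling any context-based categorizer can reach. The calibration tests
verify that the model reaches precision 1.0 on noise-free corpora and
tracks the fidelity ceiling at noise 0.1. For that comparison the model
categorizes *every* token in a known context (threshold 1): the rarity
filter changes the scored population (rare tokens over-represent the
noise-injected minority when the two content lexicons differ in size), so
filtered precision measures something slightly different from context
fidelity. The main experiments keep the 0.05% filter.

What the generator does **not** emulate: morphology and agreement,
prosody, semantic coherence, speaker variation, or the heavy-tailed
utterance-length distribution of real speech. Passing tests on synthetic
data therefore show that the algorithm exploits context→category
regularities correctly at realistic sparsity — not that any particular
precision level will transfer to a specific natural corpus.

## Numerical choices

* **Tie-breaking** for "most frequent completer" is unspecified in the
  underlying design; the package uses: highest count, then category
  symbols before wordforms (N before V), then lexicographic order. This
  is deterministic and biased toward categorizing; every application is
  flagged in the prediction records (`tie`) and logged.
* **Boundary symbols** `{` and `}` are reserved: they may appear in
  context keys but never as tokens or completers.
* **Projection of homographs** requires the token's gold tag to match the
  seed category (a seed represents word *meanings*, so "touche" the
  button is projected, "touche!" the verb is not); `require_gold_tag =
  FALSE` gives the surface-only alternative since the original design is
  silent on this.
* **Degenerate inputs**: empty corpora are valid everywhere except
  training and chance-rate estimation (errors); a fold whose test side is
  empty warns and is skipped by the harness; undefined precision/recall
  is `NA`, and SEM is `NA` with a single fold.
* **Determinism**: everything except the chance baseline is
  deterministic; the baseline and the generator take explicit integer
  seeds, and the experiment harness derives per-fold baseline seeds from
  its `rng_seed`, so whole runs are exactly reproducible.

## Problem sizes used in the test-suite

The oracle-equivalence tests compare the vectorized counting/prediction
path against a naive per-utterance enumeration on 50 corpora of at most
200 tokens. Calibration uses generated corpora of ~12,000 tokens (4,000
utterances); the directional experiments (context models beat chance,
right context worst, recall grows with seed size while precision stays
high) use 5,000 utterances, 10 folds, and frequency-built seeds of
8 nouns/1 verb vs. 64 nouns/8 verbs. These sizes give stable averages
while keeping the default check fast.

## A worked micro-example

```{r}
corp <- tagged_corpus(tibble::tibble(
  utterance_id = c(1, 1, 2, 2, 2, 2, 2, 2),
  form = c("mais", "regarde", "le", "bébé", "éléphant", "il", "va",
           "manger"),
  pos = c("CONJ", "VERB", "DET", "NOUN", "NOUN", "PRON", "VERB", "VERB"),
  lemma = c("mais", "regarder", "le", "bébé", "éléphant", "il", "aller",
            "manger")))
proj <- project_seed(corp, load_seed("V0"))
extract_contexts(proj, "framing")[, c("context", "target_label")]
```

With the `V0` seed, "bébé" projects as `N` and "va" as `V` (lemma
"aller"); every other token stays a surface form, and the padded context
strings show the boundary handling.

## Known limitations

* The model has perfect memory and cannot grow its seed from its own
  confident predictions; both extensions are deliberately out of scope.
* CHAT ingestion is best-effort: clean `%mor` tiers convert well, heavy
  retracing markup may fall back to lemmas as surface forms (logged).
* The mixed-effects significance analysis that usually accompanies such
  experiment grids is out of scope; the harness reports means and SEMs.
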