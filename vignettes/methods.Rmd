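---
title: "Methods: knowledge-guided augmentation and prompt contrastive learning for few-shot BioNER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-guided augmentation and prompt contrastive learning for few-shot BioNER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model, its assumptions, the tunable parameters,
and the design decisions behind `fewner` — in the spirit of the long-form
methods vignettes of packages like DESeq2 or vegan.

## 1. Setting

Few-shot biomedical NER: a BIO-annotated training corpus is downsampled at
sentence level to a K-shot support set (K sentences, every configured entity
type present at least once), a model is trained on that support set only, and
evaluation runs on the full, untouched test set. The draw is repeated over
several seeds (five by default) and results are reported as mean ± standard
deviation of entity-level micro-averaged exact-match F1. We use the sample
(n−1) standard deviation, treating the seeds as a sample of possible draws;
a single run reports 0 by convention.

K counts sentences, not entity mentions. For multi-type corpora one could
instead require K mentions per type; we implement the sentence reading, which
matches how the benchmark support sizes (5/20/50 sentences) are usually
tabulated.

## 2. Knowledge-guided instance generation

### Candidate matching

A concept tagger such as MetaMap is a licensed external service, and the
algorithm only needs candidate spans; the package therefore ships a
case-insensitive, longest-match-first, left-to-right dictionary matcher over
the whitespace-tokenized surface forms of the knowledge-graph nodes
(`match_candidates()`, `max_len` 6 tokens by default — enough for every
multi-word concept we care about while bounding the scan). The matcher is a
plain function of the sentence and the graph, so a real concept tagger can be
swapped in by producing the same span table.

A candidate that coincides exactly with a gold entity span is an *entity
candidate* and remembers its type; a candidate that only partially overlaps a
gold span is dropped outright — replacing half an entity would corrupt the
labels, and nothing in the method requires it. Everything else is a
*non-entity candidate*.

### Sub-graphs and the relation whitelist

`build_subgraph()` collects the edges incident to a candidate whose relation
code is one of SY, RL, RB, RQ, PAR, CHD — the six Metathesaurus relations
that keep a neighbour close enough in meaning to stand in for the original
concept in its sentence context. Neighbours are ordered deterministically
(relation code, then target) so augmentation is reproducible.

Semantic types act as a guard for non-entity candidates: a neighbour must
share at least one semantic type with the center before it may replace a
non-entity mention (`require_semtype_overlap = TRUE` for non-entities,
`FALSE` for entities). The role of semantic types in the source method is
ambiguous — they could also be read as extra *type nodes* in the sub-graph
rather than as a replacement filter — so the gate is an explicit flag rather
than a hard-wired rule; the default errs on the conservative side for
non-entities, where a bad substitution damages context rather than an entity.

### Building instances

An augmented instance chooses, for every candidate with a non-empty
sub-graph, either *keep* or one specific neighbour, excluding the all-keep
assignment — so several spans can change in a single instance (both an entity
and a nearby non-entity, for example), and every instance differs from its
source. Labels are adjusted mechanically: entity replacements get
`B-T I-T ...` of the unchanged gold type, non-entity replacements get `O`.
When the number of combinations exceeds the per-sentence cap (`n_max`, default
9) a seeded sample without replacement is drawn; whether one should sample or
enumerate in that regime is not pinned down anywhere, and seeded sampling is
the reproducible choice. Per-sentence seeds are derived from the master seed
and the sentence index, so corpus-level augmentation is order-stable.
Augmentation applies to the support set only, never to dev or test.

Invariants maintained (and tested): token/label alignment and BIO legality of
every instance; bit-identical context outside replaced spans; unchanged
multiset of entity types; cap ≤ `n_max`; relation whitelist; determinism in
the seed.

## 3. Question-prompt NER

For each entity type `T` the question prompt
`can you detect {T} entity like {E1}, {E2} ?` is rendered with two example
entities drawn (seeded, without replacement) from the support set's gold
surfaces — never from augmented instances or from dev/test, to avoid leakage.
A degenerate pool of one surface fills both slots. The minimal alternative
`The {T}.` (label-conditional prompt) is also provided; both templates are
configurable.

The model input is `[CLS] X [SEP] Q [SEP]` at sub-token level. The tokenizer
is a contract (`tokenize_word`, plus `cls`/`sep` tokens): the default keeps
whole words; a chunking tokenizer that splits long words into fixed-size
pieces exercises the alignment machinery the way WordPiece would. A word's
gold label attaches to its first sub-token; continuations carry an ignore
marker and contribute nothing to the cross-entropy. Over-long sentences are
truncated (whole words) with a warning; the prompt is never truncated.

Supervision is *projected* per prompt: a question about Disease must not be
penalized on unlabeled Gene tokens, so tags of other types map to `O` for
that view, and the classification head always works over the 3-tag set
{O, B, I} relative to the queried type. One view per configured type is
produced for every sentence. The per-view cross-entropies of a batch are
averaged (summing would only rescale the loss weight; averaging keeps
`lambda` comparable across type-set sizes).

## 4. Prompt contrastive learning

Sequence features `Hx` are split by the position mask of the queried type's
gold spans into positive rows (entity sub-tokens, continuations following
their word) and negative rows (everything else). The Jensen-Shannon lower
bound on the mutual information between prompt and answer is

```
I = mean_pos( -sp(-T(p, u)) ) - mean_neg( sp(T(p, v)) ),   sp(x) = log(1 + exp(x))
```

with `p` the mean-pooled prompt vector, one positive unit `u` per gold span
(mean-pooled over its sub-tokens) and one negative unit `v` per context row.
The expectations need defined sample units, which the source notation leaves
open; span-level positives match the query–entity pairing the method argues
for, and token-level negatives maximize the number of negatives in tiny
few-shot batches. The discriminator `T` is a one-hidden-layer MLP on
`[a; b; a*b]` — the minimal standard choice for a neural MI scorer. Both
softplus terms are non-negative, so `I <= 0` always, with 0 approached under
perfect discrimination; a zero discriminator gives exactly `-2 log 2`, a handy
closed-form reference point. A sentence with no entities contributes only the
negative term; a sentence with no negative rows is excluded from the
contrastive term.

The batch loss is `L_pcl = -mean(I)` (so `L_pcl >= 0`), and the joint
objective is `L = lambda * L_ce + (1 - lambda) * L_pcl`. The printed form of
the batch loss in the source ("−argmax …") is not a well-formed expression;
we implement the maximization-of-the-lower-bound reading that its surrounding
text describes, without claiming to resolve the notation. The batch-size `N`
in that loss is unrelated to the augmentation cap `N`; the two are distinct
quantities here (`batch_size` vs `n_max`). Softplus is computed with the
`log1p(exp(·))` branch trick so large scores cannot overflow.

## 5. The desk-scale encoder and training

The encoder is a contract: anything mapping an assembled input to final-layer
representations `Hx` (sequence) and `Hp` (prompt) works, and a pretrained
biomedical transformer is the intended full-scale backbone. The shipped
default is a deliberately small trainable encoder — token and position
embeddings plus two single-head self-attention blocks with feed-forward
residuals, width `d = 64`, no layer normalization (two blocks at this width
train fine without it) — so the whole pipeline runs in seconds on one CPU
with no downloads.

Gradients come from a package-internal reverse-mode autodiff tape over dense
matrices (`R/autodiff.R`), gradient-checked against central finite differences
in the test suite; no deep-learning framework is required. Training uses AdamW
(decoupled weight decay on weight matrices only) under a linear warmup-decay
schedule (10% warmup). Defaults: 20 epochs, `lambda = 0.5`, peak learning rate
0.01, batch size 2 views per step — the batch size and learning rate were
chosen so that the 20-epoch budget reliably drives a 20-sentence support set
to near-perfect training F1 across seeds, the standard overfit sanity check
for a trainable stack. All randomness (init, prompt examples, shuffling)
derives from a single config seed; determinism is bit-exact on one machine and
best-effort across BLAS builds. Non-finite losses abort with a diagnostic
rather than being clipped. Model selection keeps the best dev-F1 state
(training F1 when no dev set is given).

Decoding takes the argmax tag at each word's first sub-token, per prompt
view; `B I ...` runs become spans; an orphan `I-T` is repaired as `B-T`
(the conlleval-compatible dialect — one dialect had to be picked; it is
configurable at the decoder). Per-type span lists are merged by union, with
overlaps resolved by higher mean token probability, then longer span, then
earlier start.

## 6. Synthetic data: what it emulates and what it does not

`make_toy_corpus()` generates sentences of 5–15 filler tokens with 1–3-token
entity surfaces inserted at a configurable per-sentence rate (0.8 by default,
so most but not all sentences carry an entity, as in disease-annotation
corpora), every configured type realized at least once. `make_toy_kg()` gives
every distinct entity surface a star of whitelisted-relation neighbours
(3 by default), plus a fraction of disallowed-relation edges (0.25) to
exercise the filter and a few filler-token concepts so non-entity replacement
paths run. Semantic types are consistent within a concept family. Entity and
filler vocabularies are disjoint, which makes the learning problem largely
lexical: passing the overfit and protocol checks shows the pipeline trains,
selects and scores correctly — it says nothing about contextual
generalization on real biomedical text, which needs a pretrained backbone and
real corpora. The packaged `demo_fixture()` additionally carries the classic
worked examples (aniridia, alkaptonuria, myalgias, hypertension/intracellular)
with their documented neighbourhoods; fixture edges whose relation is not
documented anywhere use SY, since any whitelisted code behaves identically
under augmentation.

Problem sizes used by the test suite and the acceptance script — 1000
sentences for the augmentation invariant sweep, 20 sentences for the overfit
run, 40/10/20 train/dev/test with K = 5 over five seeds for the end-to-end
protocol — were chosen as the smallest sizes at which each property is
meaningfully exercised.

## 7. Known limitations

* The dictionary matcher finds only exact (case-insensitive) surface matches;
  no normalization, abbreviation expansion or CUI resolution.
* Headline benchmark scores from the literature (e.g. 60s F1 at 20-shot on
  NCBI-disease) are out of reach at desk scale by design: they need the
  licensed UMLS Metathesaurus, the benchmark corpora and a pretrained
  biomedical transformer. The package reproduces the *method* and its
  verifiable properties, not those numbers.
* Checkpoints serialize parameters as JSON — portable and text-only, but not
  compact; fine at desk scale.
* Alternative MI estimators (InfoNCE, NWJ) and learned/continuous prompts are
  out of scope.
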