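---
title: "Methods: layered nested entity recognition for phenotype text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered nested entity recognition for phenotype text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Phenotype descriptions in the chronic obstructive pulmonary disease (COPD)
literature are compositional: a phrase such as *elevation of pulmonary
arterial pressures* is itself a phenotype mention (a test-or-measure
result), but it contains a measurement mention (*pulmonary arterial
pressures*) which in turn contains an anatomical mention. Useful corpora
therefore annotate **nested** entity mentions — in the corpus this package
is designed around, roughly 29% of all annotated mentions sit strictly
inside another mention. A conventional ("flat") sequence tagger can emit at
most one label per token and cannot represent this structure.

`phenonest` implements, end to end, the machinery needed to work with such
data without any external resources:

* brat-style standoff I/O under a 16-category hierarchical annotation
  scheme (`corpus_io`, `copd_scheme()`),
* conversion between nested mention sets and per-level BIO label sequences
  (`assign_levels()`, `encode_bio()`, `decode_bio()`),
* a **layered BiLSTM-CRF** tagger whose stacked layers recognize
  successively more enclosing mentions (`train_layered()`,
  `predict_layered()`), plus a flat single-layer baseline (`train_flat()`),
* strict-match evaluation at three nesting regimes and inter-annotator
  agreement as micro-averaged F (`strict_prf()`, `iaa_fscore()`,
  `error_taxonomy()`),
* rule-based normalization of mentions to a pluggable terminology
  (`normalize_mention()`, `coverage_report()`), and
* a seeded synthetic corpus generator that makes all of the above testable
  (`generate_corpus()`, `generate_annotator_pair()`).

# Nesting as levels

`assign_levels()` maps every mention to a nesting level: level 0 holds the
innermost mentions and the level of a mention is the length of the longest
chain of strictly contained mentions beneath it. Levels are the model's
training target: level $\ell$ becomes one BIO sequence over the sentence
tokens. Three conventions are worth making explicit:

* **Disjoint-or-nested invariant.** Two mention spans must be disjoint,
  identical (with different categories), or properly nested. Crossing
  overlaps cannot be expressed in any per-level BIO encoding; on input they
  are dropped (later-starting mention, with a warning) or rejected in
  strict mode.
* **Same-span stacking.** Two mentions with an identical span and different
  categories are placed on consecutive levels in byte-lexicographic
  category order. This is a convention of ours — annotation practice allows
  such double annotations, one level can hold only one of them, and any
  fixed deterministic order works.
* **Innermost / outermost / all.** Innermost mentions contain no other
  mention; outermost mentions are contained in none; nesting-free mentions
  belong to both sets. These regimes drive evaluation (below).

BIO is the default label scheme because several scheme categories are
rare, and the richer BIOES scheme multiplies the label inventory; BIOES
remains available via `scheme_variant = "bioes"` for ablation.

# The tagger

## Flat building block

Each token is represented by the concatenation of (i) a word embedding,
looked up after lowercasing, with a learned unknown-word vector, and (ii) a
character-level summary: a bidirectional LSTM over the token's characters
(case preserved), final states of the two directions concatenated. The
combined vector passes through dropout, then a sentence-level bidirectional
LSTM; a linear projection yields per-tag emission scores, and a
linear-chain CRF with learned transition scores — including virtual start
and stop tags — scores whole label paths. Decoding is Viterbi; training
minimizes the CRF negative log-likelihood computed with the forward
algorithm in log space. Structurally invalid BIO transitions (`O → I-x`,
`B-x → I-y`) are masked to a large negative constant ($-10^4$) by default,
so decoded sequences are always well formed; masked entries receive no
gradient.

All forward and backward passes are implemented in this package (the LSTM
kernels in C++, the CRF in R) and are verified in the test suite against
finite-difference gradients and, for the CRF, against exhaustive
enumeration of all tag paths on small instances.

## Layered stacking

The layered model applies the flat block repeatedly. Layer 1 reads the
token representations and is trained to recognize level-0 (innermost)
mentions. Every mention a layer detects is then **merged into a single
unit**: the element-wise average of the BiLSTM states of its constituent
units replaces them in the sequence handed to the next layer. Averaging
preserves dimension, is the identity for single-unit regions, and is
order-robust; the lineage of layered taggers this follows describes the
merge only as "combining" the word states, so the average is our concrete
choice. Layer 2 is trained on level-1 mentions over the collapsed
sequence, and so on.

At prediction time the stack is dynamic: layers are applied until a layer
decodes no entity (or the layer cap is reached), and the output is the
union over layers of all decoded mentions, mapped back to original
character spans through the composed unit-to-token maps and deduplicated
on (span, category) keeping the earliest layer. Model layers do **not**
correspond one-to-one to nesting levels at prediction time; per-regime
evaluation therefore always uses the union of all layers' outputs,
filtered by regime, never "layer $k$ versus level $k$".

Design choices that were genuinely open, and how we resolved them:

* **Teacher forcing.** During training, the next layer's input is built
  from *gold* lower-level regions by default. This keeps the objective
  deterministic and stable. Stacking on the model's own decoded regions is
  available (`teacher_forcing = FALSE`): gold mentions not expressible over
  the predicted unit sequence are skipped in that layer's loss.
* **Learned termination.** The empirical stopping rule ("no entities
  decoded") only works if the layer above the deepest real level predicts
  all-`O` reliably. We therefore train `max depth + 1` layers, the last on
  all-`O` targets. `max_layers` can cap the stack; per-layer parameters
  are independent by default, with optional sharing across layers ≥ 2
  (`share_layers = TRUE`), which also permits stacking beyond the trained
  depth.
* **Flat baselines per regime.** A flat tagger cannot represent nesting, so
  `train_flat()` trains on one regime's mentions only (outermost by
  default), mirroring how flat baselines are normally compared against
  layered models.

## Hyperparameters

| parameter | default | meaning / rationale |
|---|---|---|
| `word_dim` | 100 | word-embedding dimension (standard for this model family) |
| `char_emb_dim` | 25 | character-embedding dimension |
| `char_hidden` | 25 | character LSTM units per direction (summary = 50) |
| `hidden` | 200 | sentence BiLSTM units per direction |
| `dropout` | 0.5 | on the combined token representation, training only |
| `lr` | 0.01 | Adam step size; updates are per sentence |
| `clip` | 5 | global gradient-norm clip |
| `epochs`, `patience` | 30, 5 | early stopping on development micro-F |
| `mask_transitions` | TRUE | hard BIO constraints in the CRF |
| `seed` | 42 | controls initialization, shuffling, dropout |

No hyperparameter search is performed; these are fixed, conventional
defaults, all overridable through `nen_config()` or the CLI's YAML config.
Pretrained word embeddings in the common whitespace text format can
initialize the embedding table (`read_word_embeddings()`); training remains
possible from random initialization, which is what all tests use.

Two numerical details matter for reproducibility. First, every string
ordering that influences parameters (vocabulary, character set, tag set,
canonical mention order, same-span tie-breaks) uses byte-order (radix)
sorting, so trained weights are identical regardless of the session
locale. Second, early stopping keeps the checkpoint with the best
development F, breaking ties toward lower training loss — with small or
easy development sets the F criterion saturates immediately and would
otherwise freeze training at the first epoch.

# Evaluation

`strict_prf()` counts a prediction as correct only when span and category
both match a gold mention exactly, and reports percentages to two
decimals. The regime filters **both** sides: the gold side by the regime
computed on the gold nesting structure, and the predicted side by the
regime computed on the predictions' own structure. For flat per-regime
models the prediction-side filter is the identity; for the layered model it
prevents, say, a correctly found nested mention from counting as an
outermost false positive. Precision over an empty prediction set is
reported as 0 and flagged.

Inter-annotator agreement is the same strict micro-F with one annotator as
gold — micro-F is symmetric in the two roles since swapping them exchanges
precision and recall. Each annotated mention counts once, regardless of
nesting depth.

`error_taxonomy()` assigns every residual error to exactly one bucket by
greedy one-to-one matching: exact matches first; then same-span /
different-category pairs (*wrong type*); then same-category / overlapping
span pairs, largest overlap first with earliest-start tie-break (*wrong
span*); leftovers are *spurious* (predictions) or *missed* (gold). The
matcher itself is our construction — only the bucket definitions come from
standard error-analysis practice — and the test suite checks bucket
conservation: the buckets partition both the prediction set and the gold
set exactly.

# Normalization

`normalize_mention()` maps a mention string to a concept identifier by
generating semantically consistent string variants and matching them —
case-insensitively, after whitespace folding — against a terminology's
preferred labels and synonyms, restricted to concepts whose semantic tags
include the mention's category. Six techniques run in a fixed order:

1. acronym/abbreviation expansion (*Type 2 DM → Type 2 diabetes mellitus*),
2. plural-to-singular conversion (*alveolar septa → alveolar septum*),
3. neoclassical-to-English morpheme substitution (*leukocyte → white blood
   cell*),
4. English-to-neoclassical substitution (*pleural inflammation →
   pleuritis*),
5. syntactic variation (*supplemental oxygen → oxygen supplementation*),
6. synonym substitution (*worsening → deterioration of*).

Variants compose at most two techniques deep and the list is capped
(default 200) to bound the combinatorics; the original mention is always
tried first and the first variant with a terminology hit wins, so results
are deterministic and every reported identifier provably exists in the
terminology. Mentions describing several concepts at once are deliberately
not split; they simply fail to normalize. The packaged rule tables are
small, declarative, user-extensible text files; the packaged terminology
(`mock_terminology()`) is a *synthetic*, hand-written table in the CUI
style used by tests and examples — real deployments supply their own
terminology file.

`coverage_table()` performs the per-category coverage arithmetic
(percentage = 100 × normalized / total, two decimals, grand-total row);
`coverage_report()` applies it to corpus normalization results.

# The synthetic corpus generator

`generate_corpus()` builds documents from phrase-slot grammars: each
sentence draws 2–5 slots; a slot is either a run of distractor tokens
(probability `distractor_rate` = 0.4) or an entity construct. A construct
is a nesting chain whose depth is truncated-geometric in `p_nest`:
depth 1 is a flat mention (sign/symptom, condition, measurement, drug,
treatment or quality vocabulary); depth 2 embeds a constituent in a frame
(a drug inside *inhaled … therapy*, an anatomical term inside *chronic …
obstruction*, a protein inside *… deficiency*); depth 3 chains a
measurement inside a result phrase (*elevation of … pressures*). A chain
of depth $d$ contributes $d$ mentions of which $d-1$ are embedded, so the
expected embedded share is $\mathbb{E}[d-1]/\mathbb{E}[d]$
(`expected_embedded_fraction()`). The default `p_nest = 0.29/0.71` makes
that expectation exactly 0.29, the embedded share reported for the real
corpus; the default 30 documents mirror its document count. Vocabulary
defaults quote printed scheme examples (*emphysema*, *chronic cough*,
*inhaled corticosteroids*, *spirometry*, *alpha1 antitrypsin*, …) purely so
fixtures read like the domain.

The generator is deterministic under its seed (byte-identical corpora),
every output satisfies the disjoint-or-nested invariant by construction,
and gold spans are exact. `generate_annotator_pair()` derives a second
annotator from a generated corpus by seeded perturbations — dropping,
relabelling, or extending mentions by one token (skipped when a shift
would create a crossing or duplicate) — which gives evaluation and
agreement code fixtures with known error structure.

**What the generator does not emulate.** Sentences are template-generated,
not natural language: outer mentions carry fully discriminative lexical
frames, vocabulary is closed, mention lengths are short and regular, and
category frequencies are nothing like a real corpus. Passing tests on this
data demonstrate that the machinery is correct (round trips, oracle
equivalence, learnability, termination, back-mapping), **not** that the
model reaches any particular accuracy on real text.

# Study sizes used by the tests

The automated checks train on corpora of 45 generated documents
(≈ 200 training sentences under the 8:1:1 document split) with reduced
dimensions (word 16, char 8, char-hidden 8, hidden 24, dropout 0.2,
≤ 15 epochs, patience 4). These sizes are the package's chosen study
conditions for its own verification: small enough to iterate on, large
enough that the layered model reliably reaches ≥ 95% all-entities F on
held-out documents from random initialization.

# Known limitations

* **Ceiling effect in the layered-versus-flat comparison.** On this
  generator's corpora both the layered model and the outermost-trained
  flat baseline operate at or near 100% outermost F, because template
  frames make outer boundaries recognizable from surface words alone. The
  mechanism that favors layered models on real data — outer boundaries
  that are ambiguous without knowing the inner structure — therefore has
  no room to operate, and at ceiling the comparison can tip either way on
  single boundary errors. The generator's templates are fixed study
  conditions and are not adjusted to manufacture the ordering.
* Sentence segmentation is deliberately naive (newlines and
  full-stop-plus-space); abbreviation-heavy running text will over-split.
* Mentions crossing a sentence boundary are dropped from training
  sentences; discontinuous mentions and relation/event annotations are out
  of scope.
* The normalization rule tables are small and English-specific; they cover
  the documented example transformations, not a production morphology.
* Training is CPU-only and per-sentence (no batching); it is sized for
  corpora of tens to hundreds of documents, not millions of sentences.
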