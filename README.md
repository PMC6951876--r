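# phenonest

Nested named-entity recognition and normalization for phenotype text
mining, built around chronic obstructive pulmonary disease (COPD)
literature.

Phenotype descriptions are compositional: *elevation of pulmonary arterial
pressures* is a phenotype mention (a test-or-measure result) that contains
a measurement mention, which contains an anatomical mention. Corpora for
this task therefore annotate **nested** mentions — shorter constituent
concepts embedded inside longer phenotype descriptions — under a
16-category hierarchical scheme (`Problem`, `Treatment`, `TestOrMeasure`,
`ConstituentConcept` and their subtypes; see `copd_scheme()`). A flat
sequence tagger emits one label per token and cannot represent this.

`phenonest` provides the full toolchain in R, with no external data or
services required:

* **Corpus I/O** — brat-style standoff (`.txt`/`.ann`) reading, validation
  (disjoint-or-nested invariant, crossing-overlap policy) and writing,
  plus corpus statistics including the embedded-mention fraction.
* **Level encoding** — nested mention sets ↔ one BIO label sequence per
  nesting level (`assign_levels()`, `encode_bio()`, `decode_bio()`), and
  innermost / outermost / all entity-set extraction.
* **Layered BiLSTM-CRF tagger** — the core model. Each token is
  represented by a word embedding plus a character-level BiLSTM summary
  and encoded by a sentence BiLSTM; a linear-chain CRF scores label paths

      score(y) = Σᵢ emission(i, yᵢ) + Σᵢ transition(yᵢ₋₁, yᵢ)

  (virtual start/stop tags included), trained by minimizing
  `−log p(y_gold) = logZ − score(y_gold)` with the forward algorithm and
  decoded with Viterbi. Detected entity regions are merged into single
  averaged units and fed to the next stacked layer, which recognizes the
  enclosing mentions; stacking continues until a layer finds nothing. A
  flat single-layer baseline (`train_flat()`) trains on one nesting regime.
* **Evaluation** — strict span-and-category matching with
  precision/recall/F per category and regime, inter-annotator agreement as
  micro-averaged F, and an error taxonomy (wrong type / wrong span /
  spurious / missed) with bucket conservation.
* **Normalization** — six rule-based variant-generation techniques
  (abbreviation expansion, plural→singular, neoclassical↔English,
  syntactic variation, synonym substitution) matched against a pluggable
  terminology, with per-category coverage tables.
* **Synthetic corpus generator** — seeded, deterministic nested corpora
  (default embedded-mention share 0.29) so every component above is
  testable end to end.

The LSTM kernels are compiled (Rcpp/RcppArmadillo); all gradients are
hand-derived and verified against finite differences in the test suite,
and the CRF is verified against exhaustive path enumeration.

## Worked example

```r
library(phenonest)

corpus <- generate_corpus(synth_config(seed = 7, n_documents = 45))
parts  <- split_corpus(corpus$docs, seed = 7)          # 36 / 4 / 5 documents
cfg    <- nen_config(word_dim = 16, char_emb_dim = 8, char_hidden = 8,
                     hidden = 24, dropout = 0.2, epochs = 15, patience = 4,
                     seed = 7)
model  <- train_layered(parts$train, parts$dev, cfg)
model
#> <nen_model> layered BiLSTM-CRF: 3 layer(s), 9 categories, vocab 57, best dev F 100.00

pred <- predict_layered(model, parts$test[[1]])
head(pred$mentions)
#>   start end   category concept_id
#> 1    23  47  Treatment       <NA>
#> 2    48  77 RiskFactor       <NA>
#> 3    48  66    Protein       <NA>
#> 4    78 109  Treatment       <NA>
#> 5    86 101       Drug       <NA>
#> 6   153 182 RiskFactor       <NA>
```

Rows 2–3 show the nesting at work: the model finds the protein mention
(*C-reactive protein*, offsets 48–66) **inside** the risk-factor phrase
*C-reactive protein deficiency* (48–77) — the inner mention is decoded by
layer 1, merged into one unit, and the enclosing mention is decoded by
layer 2 over the shortened sequence. Evaluating all entities on the
held-out documents:

```r
gold <- phenonest:::pool_corpus_mentions(parts$test)
pred <- phenonest:::pool_corpus_mentions(lapply(parts$test, function(d)
  nen_document(d$doc_id, d$text, predict_layered(model, d)$mentions)))
strict_prf(gold, pred, "all")
#> Strict-match evaluation (all entities)
#>           category tp fp fn precision recall   f
#>  AnatomicalConcept  6  0  0       100    100 100
#>          Condition  9  0  0       100    100 100
#>  ...
#>              micro 74  0  0       100    100 100
```

(100% F on this synthetic test split; template corpora are far easier than
real text — see the methods vignette.) Normalizing a mention against the
packaged synthetic terminology:

```r
normalize_mention("increased PVR", "Problem")
#> 'increased PVR' [Problem] -> C1867423 via abbreviation
```

## Command line

A thin Rscript over the same functions ships at `inst/cli/phenonest.R`:

```sh
Rscript inst/cli/phenonest.R generate --out corpus --seed 1
Rscript inst/cli/phenonest.R train --in corpus --out model.rds --model layered --seed 1
Rscript inst/cli/phenonest.R predict --model model.rds --in corpus --out pred
Rscript inst/cli/phenonest.R evaluate --gold corpus --pred pred --regime all
Rscript inst/cli/phenonest.R stats --in corpus
Rscript inst/cli/phenonest.R normalize --in corpus --out norm
```

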