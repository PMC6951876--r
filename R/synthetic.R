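# Seeded generator of annotated corpora with controlled nesting structure.
# Sentences come from small phrase-slot grammars whose vocabulary follows the
# printed examples of the COPD scheme (emphysema, chronic cough, inhaled
# corticosteroids, spirometry, alpha1 antitrypsin, ...), purely for
# readability; the generator makes no attempt to model real phenotype
# frequency distributions. Determinism and exact gold spans take priority
# over linguistic realism.

default_vocabulary <- function() {
  list(
    SignOrSymptom = list("dyspnea", c("chronic", "cough"),
                         c("shortness", "of", "breath"), "wheezing"),
    Condition = list("emphysema", "asthma", c("chronic", "bronchitis"),
                     c("pulmonary", "vascular", "disease")),
    TestOrMeasure = list("spirometry", "FEV1", c("respiratory", "frequency"),
                         c("blood", "gas", "analysis")),
    Drug = list("corticosteroids", "bronchodilators", "theophylline",
                "salbutamol"),
    Treatment = list(c("oxygen", "therapy"), c("pulmonary", "rehabilitation")),
    AnatomicalConcept = list("airway", "lung", "bronchial", "arterial"),
    Protein = list(c("alpha1", "antitrypsin"), c("C-reactive", "protein")),
    Quality = list("chronic", "reduced", "elevated", "decreased")
  )
}

default_distractors <- function() {
  c("the", "patients", "with", "showed", "during", "study", "of", "severe",
    "was", "observed", "in", "group", "reported", "after", "treatment-period")
}

#' Synthetic corpus generator configuration
#'
#' Controls the phrase-slot grammar: document and sentence counts, the
#' per-category vocabulary tables, the nesting probability, maximum nesting
#' depth, and the rate of non-entity distractor slots. With the defaults the
#' expected fraction of embedded mentions is 0.29, mirroring the share of
#' embedded annotations reported for the real phenotype corpus; see
#' [expected_embedded_fraction()].
#'
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   corpus byte for byte.
#' @param n_documents Number of documents.
#' @param sentences_per_doc Integer range (length 2) of sentences a document
#'   may have.
#' @param slots_per_sentence Integer range of phrase slots per sentence.
#' @param vocabulary Named list of per-category phrase tables (each a list
#'   of token vectors).
#' @param p_nest Probability that an entity slot produces a nested construct
#'   (and, given depth `>= 2` and `max_depth >= 3`, that it deepens again).
#' @param max_depth Maximum nesting depth (`>= 1`).
#' @param distractor_rate Probability that a slot emits distractor tokens
#'   instead of an entity.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_documents = 30L,
                         sentences_per_doc = c(3L, 8L),
                         slots_per_sentence = c(2L, 5L),
                         vocabulary = default_vocabulary(),
                         p_nest = 0.29 / (1 - 0.29), max_depth = 2L,
                         distractor_rate = 0.4) {
  stopifnot(p_nest >= 0, p_nest <= 1, distractor_rate >= 0,
            distractor_rate <= 1, max_depth >= 1L)
  if (!length(vocabulary) || any(!lengths(vocabulary))) {
    stop("vocabulary tables must be non-empty")
  }
  structure(list(seed = as.integer(seed),
                 n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 slots_per_sentence = as.integer(slots_per_sentence),
                 vocabulary = vocabulary, p_nest = p_nest,
                 max_depth = as.integer(max_depth),
                 distractor_rate = distractor_rate),
            class = "synth_config")
}

#' Expected embedded-mention fraction of a generator configuration
#'
#' A nesting chain of depth `d` contributes `d` mentions of which `d - 1`
#' are embedded; the chain depth is truncated-geometric in `p_nest` up to
#' `max_depth`. The expected embedded fraction is `E[d - 1] / E[d]` over
#' that distribution (0.29 under the defaults).
#'
#' @param config A [synth_config()].
#' @return A number in `[0, 1)`.
#' @export
expected_embedded_fraction <- function(config) {
  p <- config$p_nest; md <- config$max_depth
  probs <- numeric(md)
  for (d in seq_len(md)) {
    probs[d] <- if (d < md) p^(d - 1) * (1 - p) else p^(md - 1)
  }
  d <- seq_len(md)
  sum(probs * (d - 1)) / sum(probs * d)
}

# nested-construct templates; each draws fillers from the vocabulary and
# returns tokens plus mention descriptors (token ranges + categories)
draw_phrase <- function(vocab, cat) {
  opts <- vocab[[cat]]
  if (is.null(opts)) stop("vocabulary has no phrases for category ", cat)
  opts[[sample.int(length(opts), 1L)]]
}

# depth-1: a single flat mention
gen_flat_construct <- function(vocab) {
  cats <- intersect(c("SignOrSymptom", "Condition", "TestOrMeasure", "Drug",
                      "Treatment", "Quality"), names(vocab))
  cat_ <- cats[sample.int(length(cats), 1L)]
  toks <- draw_phrase(vocab, cat_)
  list(tokens = toks,
       mentions = data.frame(first = 1L, last = length(toks),
                             category = cat_, stringsAsFactors = FALSE))
}

# depth-2: outer mention with one embedded constituent
gen_nest2_construct <- function(vocab) {
  kind <- sample.int(3L, 1L)
  if (kind == 1L) {
    inner <- draw_phrase(vocab, "Drug")
    toks <- c("inhaled", inner, "therapy")
    inner_rng <- c(2L, 1L + length(inner))
    outer_cat <- "Treatment"; inner_cat <- "Drug"
  } else if (kind == 2L) {
    inner <- draw_phrase(vocab, "AnatomicalConcept")
    toks <- c("chronic", inner, "obstruction")
    inner_rng <- c(2L, 1L + length(inner))
    outer_cat <- "Condition"; inner_cat <- "AnatomicalConcept"
  } else {
    inner <- draw_phrase(vocab, "Protein")
    toks <- c(inner, "deficiency")
    inner_rng <- c(1L, length(inner))
    outer_cat <- "RiskFactor"; inner_cat <- "Protein"
  }
  list(tokens = toks,
       mentions = data.frame(
         first = c(1L, inner_rng[1]), last = c(length(toks), inner_rng[2]),
         category = c(outer_cat, inner_cat), stringsAsFactors = FALSE))
}

# depth-3 chain: result > measure > anatomy
gen_nest3_construct <- function(vocab) {
  anat <- draw_phrase(vocab, "AnatomicalConcept")
  toks <- c("elevation", "of", anat, "pressures")
  a0 <- 3L; a1 <- 2L + length(anat)
  list(tokens = toks,
       mentions = data.frame(
         first = c(1L, a0, a0), last = c(length(toks), length(toks), a1),
         category = c("TestOrMeasureResult", "TestOrMeasure",
                      "AnatomicalConcept"),
         stringsAsFactors = FALSE))
}

gen_construct <- function(config) {
  depth <- 1L
  while (depth < config$max_depth && stats::runif(1) < config$p_nest) {
    depth <- depth + 1L
  }
  if (depth == 1L) gen_flat_construct(config$vocabulary)
  else if (depth == 2L) gen_nest2_construct(config$vocabulary)
  else gen_nest3_construct(config$vocabulary)
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic under the configured seed. Every generated document
#' satisfies the disjoint-or-nested mention invariant by construction, and
#' the gold level assignment returned alongside each document agrees with
#' [assign_levels()].
#'
#' @param config A [synth_config()].
#' @return A list with `docs` (list of `nen_document`), `gold_levels` (list
#'   of integer level vectors parallel to each document's mentions), and
#'   `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  distractors <- default_distractors()
  with_local_seed(config$seed, {
    docs <- list(); gold <- list()
    for (di in seq_len(config$n_documents)) {
      n_sent <- sample(seq(config$sentences_per_doc[1],
                           config$sentences_per_doc[2]), 1L)
      lines <- character(0)
      starts <- integer(0); ends <- integer(0); cats <- character(0)
      off <- 0L
      for (si in seq_len(n_sent)) {
        n_slots <- sample(seq(config$slots_per_sentence[1],
                              config$slots_per_sentence[2]), 1L)
        toks <- character(0)
        sm <- list()
        for (sl in seq_len(n_slots)) {
          if (stats::runif(1) < config$distractor_rate) {
            toks <- c(toks, sample(distractors,
                                   sample.int(3L, 1L), replace = TRUE))
          } else {
            cons <- gen_construct(config)
            base <- length(toks)
            toks <- c(toks, cons$tokens)
            cons$mentions$first <- cons$mentions$first + base
            cons$mentions$last <- cons$mentions$last + base
            sm[[length(sm) + 1L]] <- cons$mentions
          }
        }
        toks <- c(toks, ".")
        # token character offsets within the sentence
        tok_start <- cumsum(c(0L, nchar(toks[-length(toks)]) + 1L))
        tok_end <- tok_start + nchar(toks)
        line <- paste(toks, collapse = " ")
        if (length(sm)) {
          mdf <- do.call(rbind, sm)
          starts <- c(starts, off + tok_start[mdf$first])
          ends <- c(ends, off + tok_end[mdf$last])
          cats <- c(cats, mdf$category)
        }
        lines <- c(lines, line)
        off <- off + nchar(line) + 1L  # newline separator
      }
      text <- paste(lines, collapse = "\n")
      doc <- nen_document(sprintf("synth%03d", di), text,
                          mentions(starts, ends, cats))
      docs[[doc$doc_id]] <- doc
      gold[[doc$doc_id]] <- assign_levels(doc$mentions)
    }
    list(docs = docs, gold_levels = gold, config = config)
  })
}

#' Write a generated corpus with its provenance manifest
#'
#' Emits brat `.txt`/`.ann` pairs via [write_corpus_dir()] plus a
#' `manifest.json` echoing the seed and configuration.
#'
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory.
#' @export
write_generated_corpus <- function(corpus, dir) {
  write_corpus_dir(corpus$docs, dir)
  cfg <- corpus$config
  cfg$vocabulary <- lapply(cfg$vocabulary, function(v) {
    vapply(v, paste, character(1), collapse = " ")
  })
  jsonlite::write_json(list(generator = "phenonest synthetic corpus",
                            seed = cfg$seed, config = unclass(cfg)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Generate a simulated annotator pair
#'
#' Produces two annotation sets over identical texts: the first is a
#' generated corpus, the second derives from it by seeded perturbations —
#' dropping mentions, relabelling them to a different category, or shifting
#' a span by one token (skipped when the shift would create a crossing
#' overlap or a duplicate). With all rates 0 the two sets are identical.
#'
#' @param config A [synth_config()].
#' @param span_shift_rate,relabel_rate,drop_rate Perturbation probabilities
#'   in `[0, 1]`.
#' @return A list with `annotator_a` and `annotator_b` (lists of documents
#'   over the same texts).
#' @export
generate_annotator_pair <- function(config = synth_config(),
                                    span_shift_rate = 0, relabel_rate = 0,
                                    drop_rate = 0) {
  stopifnot(span_shift_rate >= 0, span_shift_rate <= 1,
            relabel_rate >= 0, relabel_rate <= 1,
            drop_rate >= 0, drop_rate <= 1)
  corpus <- generate_corpus(config)
  scheme <- copd_scheme()
  b_docs <- with_local_seed(config$seed + 7919L, {
    lapply(corpus$docs, function(doc) {
      df <- doc$mentions
      toks <- tokenize_text(doc$text)
      keep <- stats::runif(nrow(df)) >= drop_rate
      df <- df[keep, , drop = FALSE]
      if (nrow(df)) {
        for (i in seq_len(nrow(df))) {
          if (stats::runif(1) < relabel_rate) {
            others <- setdiff(scheme$labels, df$category[i])
            cand <- sample(others, 1L)
            dup <- any(df$start == df$start[i] & df$end == df$end[i] &
                         df$category == cand)
            if (!dup) df$category[i] <- cand
          }
          if (stats::runif(1) < span_shift_rate) {
            # extend the span to the end of the following token if possible
            nxt <- which(toks$start >= df$end[i])
            if (length(nxt) && toks$surface[nxt[1]] != ".") {
              cand_end <- toks$end[nxt[1]]
              trial <- df
              trial$end[i] <- cand_end
              dup <- sum(trial$start == trial$start[i] &
                           trial$end == cand_end &
                           trial$category == trial$category[i]) > 1L
              if (!dup && !nrow(crossing_pairs(trial))) df <- trial
            }
          }
        }
      }
      nen_document(doc$doc_id, doc$text, df)
    })
  })
  list(annotator_a = corpus$docs, annotator_b = b_docs)
}
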