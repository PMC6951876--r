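#' Merge the states of an entity region into a single unit
#'
#' When a layer detects an entity, the contextual states of its constituent
#' units are combined into one representation that stands for the whole
#' entity in the next layer's input. The combination is the element-wise
#' average, which preserves dimension and reduces to the identity for
#' single-unit regions.
#'
#' @param states Numeric matrix, one row per unit of the region (at least
#'   one row).
#' @return A numeric vector (the average of the rows).
#' @export
merge_region <- function(states) {
  states <- as.matrix(states)
  if (!nrow(states)) stop("cannot merge an empty region")
  colMeans(states)
}

#' Build the next layer's input from detected entity regions
#'
#' Each decoded mention collapses its unit range into a single merged unit
#' ([merge_region()]); units outside any mention pass through unchanged, in
#' order. The returned map records, for every output unit, the input unit
#' indices it came from, so that spans can be composed back to original
#' character offsets across layers.
#'
#' @param states Numeric matrix of the current layer's contextual states
#'   (units x dim).
#' @param regions Data frame with columns `first`, `last`: 1-based inclusive
#'   unit ranges of the decoded mentions; must be pairwise disjoint.
#' @return A list with `states` (next layer's input matrix) and `map` (list
#'   of integer vectors of source unit indices).
#' @export
build_next_layer_input <- function(states, regions) {
  states <- as.matrix(states)
  u <- nrow(states)
  if (nrow(regions)) {
    regions <- regions[order(regions$first), , drop = FALSE]
    covered <- unlist(mapply(seq, regions$first, regions$last,
                             SIMPLIFY = FALSE))
    if (anyDuplicated(covered)) {
      stop("decoded regions must be pairwise disjoint")
    }
  }
  map <- list(); uu <- 1L
  while (uu <= u) {
    hit <- if (nrow(regions)) match(uu, regions$first) else NA_integer_
    if (!is.na(hit)) {
      map[[length(map) + 1L]] <- regions$first[hit]:regions$last[hit]
      uu <- regions$last[hit] + 1L
    } else {
      map[[length(map) + 1L]] <- uu
      uu <- uu + 1L
    }
  }
  nxt <- do.call(rbind, lapply(map, function(g) {
    merge_region(states[g, , drop = FALSE])
  }))
  list(states = nxt, map = map)
}

#' Train the layered BiLSTM-CRF nested entity tagger
#'
#' Trains a stack of BiLSTM-CRF layers on per-level BIO label sequences:
#' layer 1 learns the innermost (level-0) mentions from word + character
#' embeddings; each subsequent layer learns the next nesting level over a
#' unit sequence in which the previous level's entity regions are merged into
#' single averaged units. By default the merged regions follow the *gold*
#' lower-level mentions during training (teacher forcing); set
#' `teacher_forcing = FALSE` in the config to stack on the model's own
#' decoded regions instead. One extra layer beyond the maximum gold depth is
#' trained on all-`O` labels so the model learns to stop stacking. The loss
#' is the sum of per-layer CRF negative log-likelihoods; early stopping
#' monitors micro-averaged F over all entities on the development set.
#'
#' @param train_docs,dev_docs Lists of `nen_document`s (dev may be empty).
#' @param config An [nen_config()].
#' @param categories Category label set; default is every category observed
#'   in the training data.
#' @return An object of class `nen_model` with elements `params`, `log`
#'   (per-epoch loss and dev F), `best_dev_f`, and the vocabulary tables.
#' @seealso [predict_layered()], [train_flat()]
#' @export
train_layered <- function(train_docs, dev_docs = list(),
                          config = nen_config(), categories = NULL) {
  train_tagger(train_docs, dev_docs, config, categories, flat = FALSE)
}

#' Train a flat (single-layer) BiLSTM-CRF baseline
#'
#' The non-layered building block, trained to recognize one regime of
#' entities only (a flat tagger cannot represent nesting): `regime`
#' selects which gold mentions form the single BIO level.
#'
#' @inheritParams train_layered
#' @param regime `"innermost"`, `"outermost"`, or `"all"` (for `"all"`,
#'   same-span duplicates are reduced to one mention per span).
#' @return An `nen_model` with `n_layers == 1`.
#' @export
train_flat <- function(train_docs, dev_docs = list(), config = nen_config(),
                       categories = NULL,
                       regime = c("outermost", "innermost", "all")) {
  regime <- match.arg(regime)
  train_tagger(train_docs, dev_docs, config, categories, flat = TRUE,
               regime = regime)
}

#' Predict nested mentions with a trained model
#'
#' Applies the layered tagger sentence by sentence: each layer encodes the
#' current unit sequence, decodes a BIO path with the CRF, maps decoded unit
#' ranges back to original character spans, merges the detected regions, and
#' feeds the shortened sequence to the next layer. Stacking stops as soon as
#' a layer decodes no entity, or when the layer cap is reached. The output is
#' the union of all layers' mentions, deduplicated on (span, category) with
#' the earliest layer kept.
#'
#' @param model An `nen_model` from [train_layered()] or [train_flat()].
#' @param doc An `nen_document`, or a plain string of text.
#' @return A list with `mentions` (mention data frame with a `layer`
#'   attribute column removed after deduplication) and `trace` (per sentence,
#'   the per-layer decoded labels and unit maps).
#' @export
predict_layered <- function(model, doc) {
  stopifnot(inherits(model, "nen_model"))
  if (is.character(doc)) doc <- nen_document("doc", doc)
  sents <- split_sentences(doc$text)
  out <- list(); traces <- list()
  for (si in seq_len(nrow(sents))) {
    s0 <- sents$start[si]; e0 <- sents$end[si]
    toks <- tokenize_text(span_text(doc$text, s0, e0))
    if (!nrow(toks)) next
    toks$start <- toks$start + s0
    toks$end <- toks$end + s0
    ps <- predict_sentence(model, toks)
    out[[length(out) + 1L]] <- ps$mentions
    traces[[length(traces) + 1L]] <- ps$trace
  }
  m <- if (length(out)) do.call(rbind, out) else empty_mentions()
  list(mentions = canonical_mention_order(m), trace = traces)
}

#' Contextual token states of the first tagger layer
#'
#' Exposes the shared token representation (word embedding + character-level
#' encoder) run through the first BiLSTM layer: one state vector per token,
#' each depending on the whole sentence through the bidirectional pass.
#'
#' @param model A trained `nen_model`.
#' @param surfaces Character vector of token surfaces (one sentence).
#' @return A numeric matrix, `length(surfaces)` rows.
#' @export
encode_tokens <- function(model, surfaces) {
  stopifnot(inherits(model, "nen_model"))
  if (!length(surfaces)) return(matrix(0, 0L, 2L * model$config$hidden))
  tr_fwd <- token_rep_forward(model$params, surfaces, model$vocab,
                              model$charset, model$config, train = FALSE)
  bilstm_forward(tr_fwd$X, model$params$layers[[1]]$rnn)$h
}

#' Split a corpus into train/development/test parts
#'
#' Document-level random split, deterministic under `seed`. The default
#' ratios are four-fifths training, one-tenth development, one-tenth test.
#'
#' @param docs List of documents.
#' @param ratios Numeric vector of 3 ratios summing to 1.
#' @param seed Integer seed.
#' @return A list with elements `train`, `dev`, `test` (disjoint sublists
#'   whose union is `docs`).
#' @export
split_corpus <- function(docs, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L)
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  n <- length(docs)
  n_parts <- sum(ratios > 0)
  if (n < n_parts) stop("fewer documents than requested parts")
  ord <- with_local_seed(seed, sample.int(n))
  n_train <- round(n * ratios[1])
  n_dev <- round(n * ratios[2])
  if (ratios[1] > 0) n_train <- max(1L, n_train)
  if (ratios[2] > 0) n_dev <- max(1L, n_dev)
  n_train <- min(n_train, n - (ratios[2] > 0) - (ratios[3] > 0))
  n_test <- n - n_train - n_dev
  if (ratios[3] > 0 && n_test < 1L) {
    n_dev <- n_dev - (1L - n_test)
    n_test <- 1L
  }
  list(train = docs[ord[seq_len(n_train)]],
       dev = docs[ord[n_train + seq_len(n_dev)]],
       test = docs[ord[n_train + n_dev + seq_len(n_test)]])
}

#' Save or load a trained model
#'
#' The checkpoint is a single-file serialized archive holding the learned
#' parameters together with a manifest (configuration, category set,
#' vocabulary, package version).
#'
#' @param model An `nen_model`.
#' @param path File path.
#' @return `load_model` returns the `nen_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nen_model"))
  model$manifest <- list(package = "phenonest",
                         version = as.character(utils::packageVersion("phenonest")),
                         saved = format(Sys.time(), tz = "UTC"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "nen_model")) stop("not a phenonest model checkpoint")
  m
}
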