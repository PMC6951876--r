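# Internal training/prediction engine shared by the flat and layered taggers.
#
# A "sentence record" holds everything static about a training sentence:
# tokens, gold mentions with token-aligned ranges, the per-layer gold tag
# sequences over collapsed unit sequences, and the unit-collapse groups used
# for teacher-forced stacking.

#' Tagger configuration
#'
#' Hyperparameters of the (layered) BiLSTM-CRF. Dimensions follow the common
#' recipe for this architecture family: 100-dimensional word embeddings,
#' a character-level bidirectional LSTM with 25 units per direction over
#' 25-dimensional character embeddings, a 200-unit sentence-level BiLSTM per
#' direction, dropout 0.5 on the combined token representation. All are
#' overridable; the test fixtures use much smaller dimensions.
#'
#' @param word_dim Word embedding dimension.
#' @param char_emb_dim Character embedding dimension.
#' @param char_hidden Character LSTM units per direction (summary is twice
#'   this).
#' @param hidden Sentence BiLSTM units per direction.
#' @param dropout Dropout probability on the combined token representation.
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without dev-F improvement).
#' @param clip Global gradient-norm clip.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param scheme_variant `"bio"` (default) or `"bioes"` label scheme.
#' @param mask_transitions Forbid structurally invalid BIO transitions in the
#'   CRF (default `TRUE`).
#' @param teacher_forcing Build next-layer inputs from gold lower-level
#'   regions during training (default `TRUE`); `FALSE` uses the model's own
#'   decoded regions.
#' @param share_layers Share BiLSTM-CRF parameters across layers 2..L.
#' @param max_layers Cap on stacked layers; default (`NULL`) is the maximum
#'   gold nesting depth in the training data plus one.
#' @param embeddings Optional pretrained word-embedding matrix with token
#'   rownames (see [read_word_embeddings()]); matched rows initialize the
#'   word-embedding table.
#' @return A list of class `nen_config`.
#' @export
nen_config <- function(word_dim = 100L, char_emb_dim = 25L, char_hidden = 25L,
                       hidden = 200L, dropout = 0.5, lr = 0.01,
                       epochs = 30L, patience = 5L, clip = 5,
                       seed = 42L, scheme_variant = c("bio", "bioes"),
                       mask_transitions = TRUE, teacher_forcing = TRUE,
                       share_layers = FALSE, max_layers = NULL,
                       embeddings = NULL) {
  scheme_variant <- match.arg(scheme_variant)
  structure(list(word_dim = as.integer(word_dim),
                 char_emb_dim = as.integer(char_emb_dim),
                 char_hidden = as.integer(char_hidden),
                 hidden = as.integer(hidden), dropout = dropout, lr = lr,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 clip = clip, seed = as.integer(seed),
                 scheme_variant = scheme_variant,
                 mask_transitions = mask_transitions,
                 teacher_forcing = teacher_forcing,
                 share_layers = share_layers,
                 max_layers = if (is.null(max_layers)) NULL
                              else as.integer(max_layers),
                 embeddings = embeddings),
            class = "nen_config")
}

# map a mention char span to a whole-token index range (snap outward)
mention_token_range <- function(tokens, start, end) {
  first <- which(tokens$end > start)[1]
  last <- rev(which(tokens$start < end))[1]
  if (is.na(first) || is.na(last) || first > last) return(NULL)
  c(first, last)
}

# split docs into per-sentence records with gold level structure
prepare_sentences <- function(docs, regime = "all", flat = FALSE) {
  recs <- list()
  for (doc in docs) {
    sents <- split_sentences(doc$text)
    for (si in seq_len(nrow(sents))) {
      s0 <- sents$start[si]; e0 <- sents$end[si]
      toks <- tokenize_text(span_text(doc$text, s0, e0))
      if (!nrow(toks)) next
      toks$start <- toks$start + s0
      toks$end <- toks$end + s0
      df <- doc$mentions
      inside <- df$start >= s0 & df$end <= e0
      df <- df[inside, , drop = FALSE]
      if (flat) {
        df <- regime_set(df, regime)
        # one mention per span on the single level: keep lexicographic first
        key <- paste(df$start, df$end)
        df <- df[!duplicated(key), , drop = FALSE]
      }
      rownames(df) <- NULL
      rng <- lapply(seq_len(nrow(df)), function(i) {
        mention_token_range(toks, df$start[i], df$end[i])
      })
      ok <- !vapply(rng, is.null, logical(1))
      df <- df[ok, , drop = FALSE]; rng <- rng[ok]
      lev <- if (flat) rep(0L, nrow(df)) else assign_levels(df)
      recs[[length(recs) + 1L]] <- list(
        doc_id = doc$doc_id, tokens = toks, mentions = df,
        m_first = vapply(rng, `[`, integer(1), 1L),
        m_last = vapply(rng, `[`, integer(1), 2L),
        levels = as.integer(lev),
        depth = if (nrow(df)) max(lev) + 1L else 0L)
    }
  }
  recs
}

# per-layer gold structure for one sentence under teacher forcing:
# layers[[k]] = list(gold = tag indices over layer-k units,
#                    groups = list of current-unit index vectors that collapse
#                             into the next layer's units)
sentence_layer_plan <- function(rec, n_layers, tagmap) {
  n_tok <- nrow(rec$tokens)
  unit_first <- seq_len(n_tok); unit_last <- seq_len(n_tok)
  plan <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    sel <- which(rec$levels == k - 1L)
    u <- length(unit_first)
    gold <- rep(1L, u)  # "O"
    # mentions of this level mapped to unit ranges
    ua <- integer(0); ub <- integer(0); mcat <- character(0)
    for (i in sel) {
      a <- match(rec$m_first[i], unit_first)
      b <- match(rec$m_last[i], unit_last)
      if (is.na(a) || is.na(b) || a > b) next  # not expressible; skip
      ua <- c(ua, a); ub <- c(ub, b); mcat <- c(mcat, rec$mentions$category[i])
    }
    if (length(ua)) {
      ord <- order(ua)
      ua <- ua[ord]; ub <- ub[ord]; mcat <- mcat[ord]
      for (i in seq_along(ua)) {
        gold[ua[i]:ub[i]] <- tagmap[paste0("I-", mcat[i])]
        gold[ua[i]] <- tagmap[paste0("B-", mcat[i])]
      }
    }
    # collapse groups for next layer input
    groups <- list()
    uu <- 1L
    while (uu <= u) {
      hit <- match(uu, ua)
      if (!is.na(hit)) {
        groups[[length(groups) + 1L]] <- ua[hit]:ub[hit]
        uu <- ub[hit] + 1L
      } else {
        groups[[length(groups) + 1L]] <- uu
        uu <- uu + 1L
      }
    }
    plan[[k]] <- list(gold = gold, groups = groups)
    nf <- vapply(groups, function(g) unit_first[g[1]], integer(1))
    nl <- vapply(groups, function(g) unit_last[g[length(g)]], integer(1))
    unit_first <- nf; unit_last <- nl
  }
  plan
}

new_tagger_params <- function(config, vocab, charset, n_layers, k_tags) {
  D <- config$word_dim + 2L * config$char_hidden
  H <- config$hidden
  E_word <- init_mat(length(vocab), config$word_dim)
  if (!is.null(config$embeddings)) {
    emb <- config$embeddings
    hit <- match(vocab, rownames(emb))
    use <- which(!is.na(hit))
    if (length(use)) {
      E_word[use, seq_len(min(ncol(emb), config$word_dim))] <-
        emb[hit[use], seq_len(min(ncol(emb), config$word_dim)), drop = FALSE]
    }
  }
  mk_layer <- function(in_dim) {
    list(rnn = new_bilstm_params(in_dim, H),
         W_emit = init_mat(2L * H, k_tags),
         b_emit = rep(0, k_tags),
         trans = matrix(0, k_tags + 2L, k_tags + 2L))
  }
  n_distinct <- if (config$share_layers) min(n_layers, 2L) else n_layers
  layers <- lapply(seq_len(n_distinct), function(k) {
    mk_layer(if (k == 1L) D else 2L * H)
  })
  list(E_word = E_word,
       E_char = init_mat(length(charset), config$char_emb_dim),
       char = new_bilstm_params(config$char_emb_dim, config$char_hidden),
       layers = layers)
}

# which stored parameter set serves model layer k
layer_slot <- function(model, k) {
  if (model$config$share_layers) min(k, 2L) else min(k, length(model$params$layers))
}

# --- token representation ----------------------------------------------------

token_rep_forward <- function(params, surfaces, vocab, charset, config,
                              train = FALSE) {
  wid <- match(tolower(surfaces), vocab)
  wid[is.na(wid)] <- 1L
  us <- unique(surfaces)
  cc <- lapply(us, char_encode_one, charset = charset,
               E_char = params$E_char, p = params$char)
  cs <- do.call(rbind, lapply(cc, `[[`, "summary"))
  map <- match(surfaces, us)
  X <- cbind(params$E_word[wid, , drop = FALSE], cs[map, , drop = FALSE])
  mask <- NULL
  if (train && config$dropout > 0) {
    mask <- matrix(stats::rbinom(length(X), 1L, 1 - config$dropout),
                   nrow(X), ncol(X)) / (1 - config$dropout)
    X <- X * mask
  }
  list(X = X, cache = list(wid = wid, us = us, map = map, cc = cc,
                           mask = mask))
}

token_rep_backward <- function(params, cache, dX, config, grads) {
  if (!is.null(cache$mask)) dX <- dX * cache$mask
  Dw <- config$word_dim
  dW <- dX[, seq_len(Dw), drop = FALSE]
  dC <- dX[, Dw + seq_len(2L * config$char_hidden), drop = FALSE]
  for (r in seq_along(cache$wid)) {
    grads$E_word[cache$wid[r], ] <- grads$E_word[cache$wid[r], ] + dW[r, ]
  }
  # accumulate char-summary gradients per unique surface
  nsum <- matrix(0, length(cache$us), ncol(dC))
  for (r in seq_along(cache$map)) {
    nsum[cache$map[r], ] <- nsum[cache$map[r], ] + dC[r, ]
  }
  for (ui in seq_along(cache$us)) {
    bk <- char_backward_one(params$char, cache$cc[[ui]]$cache,
                            cache$cc[[ui]]$ids, nsum[ui, ], grads$E_char)
    grads$E_char <- bk$d_E_char
    grads$char <- tree_add(grads$char, bk$grads)
  }
  grads
}

# --- per-sentence loss and gradient ------------------------------------------

effective_transitions <- function(layer, model) {
  if (model$config$mask_transitions) {
    apply_transition_mask(layer$trans, model$mask)
  } else {
    layer$trans
  }
}

sentence_loss_grad <- function(model, rec, plan) {
  params <- model$params
  config <- model$config
  n_layers <- length(plan)
  tr_fwd <- token_rep_forward(params, rec$tokens$surface, model$vocab,
                              model$charset, config, train = TRUE)
  X <- tr_fwd$X
  caches <- vector("list", n_layers)
  loss <- 0
  for (k in seq_len(n_layers)) {
    layer <- params$layers[[layer_slot(model, k)]]
    bi <- bilstm_forward(X, layer$rnn)
    emis <- bi$h %*% layer$W_emit +
      matrix(layer$b_emit, nrow(bi$h), length(layer$b_emit), byrow = TRUE)
    tre <- effective_transitions(layer, model)
    g <- crf_nll_grad(emis, tre, plan[[k]]$gold,
                      trainable = if (config$mask_transitions) model$mask
                                  else NULL)
    loss <- loss + (g$log_partition -
                      crf_sequence_score(emis, tre, plan[[k]]$gold))
    caches[[k]] <- list(bi = bi, emis = emis, g = g, X = X)
    if (k < n_layers) {
      groups <- plan[[k]]$groups
      X <- do.call(rbind, lapply(groups, function(gr) {
        colMeans(bi$h[gr, , drop = FALSE])
      }))
    }
  }
  grads <- tree_zero(params)
  dX_next <- NULL
  for (k in rev(seq_len(n_layers))) {
    slot <- layer_slot(model, k)
    layer <- params$layers[[slot]]
    ck <- caches[[k]]
    dS <- ck$g$d_emissions %*% t(layer$W_emit)
    grads$layers[[slot]]$W_emit <- grads$layers[[slot]]$W_emit +
      t(ck$bi$h) %*% ck$g$d_emissions
    grads$layers[[slot]]$b_emit <- grads$layers[[slot]]$b_emit +
      colSums(ck$g$d_emissions)
    grads$layers[[slot]]$trans <- grads$layers[[slot]]$trans +
      ck$g$d_transitions
    if (!is.null(dX_next)) {
      groups <- plan[[k]]$groups
      for (j in seq_along(groups)) {
        gr <- groups[[j]]
        dS[gr, ] <- dS[gr, ] +
          matrix(dX_next[j, ] / length(gr), length(gr), ncol(dS),
                 byrow = TRUE)
      }
    }
    bk <- bilstm_backward(layer$rnn, ck$bi$cache, dS)
    grads$layers[[slot]]$rnn <- tree_add(grads$layers[[slot]]$rnn, bk$grads)
    dX_next <- bk$dX
  }
  grads <- token_rep_backward(params, tr_fwd$cache, dX_next, config, grads)
  list(loss = loss, grads = grads)
}

# non-teacher-forced plan: unit-collapse groups come from the model's own
# decoded regions (a prediction-style pass with current parameters); gold
# labels are whatever gold mentions of level k-1 are expressible over the
# resulting unit sequence.
sentence_dynamic_plan <- function(model, rec, n_layers) {
  tr_fwd <- token_rep_forward(model$params, rec$tokens$surface, model$vocab,
                              model$charset, model$config, train = FALSE)
  X <- tr_fwd$X
  unit_first <- seq_len(nrow(rec$tokens))
  unit_last <- seq_len(nrow(rec$tokens))
  plan <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    u <- length(unit_first)
    gold <- rep(1L, u)
    sel <- which(rec$levels == k - 1L)
    for (i in sel) {
      a <- match(rec$m_first[i], unit_first)
      b <- match(rec$m_last[i], unit_last)
      if (is.na(a) || is.na(b) || a > b) next
      gold[a:b] <- model$tagmap[paste0("I-", rec$mentions$category[i])]
      gold[a] <- model$tagmap[paste0("B-", rec$mentions$category[i])]
    }
    layer <- model$params$layers[[layer_slot(model, k)]]
    bi <- bilstm_forward(X, layer$rnn)
    emis <- bi$h %*% layer$W_emit +
      matrix(layer$b_emit, nrow(bi$h), length(layer$b_emit), byrow = TRUE)
    vit <- crf_viterbi(emis, effective_transitions(layer, model))
    units_df <- data.frame(start = seq_len(u) - 1L, end = seq_len(u))
    dec <- decode_bio(model$tags[vit$tags], units_df)
    ua <- dec$start + 1L; ub <- dec$end
    groups <- list(); uu <- 1L
    while (uu <= u) {
      hit <- match(uu, ua)
      if (!is.na(hit)) {
        groups[[length(groups) + 1L]] <- ua[hit]:ub[hit]
        uu <- ub[hit] + 1L
      } else {
        groups[[length(groups) + 1L]] <- uu
        uu <- uu + 1L
      }
    }
    plan[[k]] <- list(gold = gold, groups = groups)
    if (k < n_layers) {
      X <- do.call(rbind, lapply(groups, function(gr) {
        colMeans(bi$h[gr, , drop = FALSE])
      }))
      unit_first <- vapply(groups, function(g) unit_first[g[1]], integer(1))
      unit_last <- vapply(groups, function(g) unit_last[g[length(g)]],
                          integer(1))
    }
  }
  plan
}

# --- prediction ---------------------------------------------------------------

# decode one sentence with the layered stack; returns mentions + trace
predict_sentence <- function(model, tokens) {
  if (!nrow(tokens)) {
    return(list(mentions = empty_mentions(), trace = list()))
  }
  params <- model$params
  tr_fwd <- token_rep_forward(params, tokens$surface, model$vocab,
                              model$charset, model$config, train = FALSE)
  X <- tr_fwd$X
  unit_first <- seq_len(nrow(tokens)); unit_last <- seq_len(nrow(tokens))
  out <- list(); trace <- list()
  max_layers <- model$n_layers
  if (model$config$share_layers) max_layers <- max(max_layers, 16L)
  for (k in seq_len(max_layers)) {
    if (k > model$n_layers && !model$config$share_layers) break
    layer <- params$layers[[layer_slot(model, k)]]
    bi <- bilstm_forward(X, layer$rnn)
    emis <- bi$h %*% layer$W_emit +
      matrix(layer$b_emit, nrow(bi$h), length(layer$b_emit), byrow = TRUE)
    vit <- crf_viterbi(emis, effective_transitions(layer, model))
    labels <- model$tags[vit$tags]
    units_df <- data.frame(start = seq_along(unit_first) - 1L,
                           end = seq_along(unit_first))
    dec <- decode_bio(labels, units_df)  # unit-index spans
    trace[[k]] <- list(labels = labels,
                       unit_first = unit_first, unit_last = unit_last)
    if (!nrow(dec)) break
    # map decoded unit ranges back to original character spans
    ua <- dec$start + 1L; ub <- dec$end
    ms <- tokens$start[unit_first[ua]]
    me <- tokens$end[unit_last[ub]]
    out[[length(out) + 1L]] <- data.frame(start = ms, end = me,
                                          category = dec$category,
                                          layer = k,
                                          stringsAsFactors = FALSE)
    if (k == max_layers) break
    # collapse decoded regions into single averaged units
    nxt <- build_next_layer_input(bi$h, data.frame(first = ua, last = ub))
    X <- nxt$states
    unit_first <- vapply(nxt$map, function(g) unit_first[g[1]], integer(1))
    unit_last <- vapply(nxt$map, function(g) unit_last[g[length(g)]],
                        integer(1))
  }
  if (!length(out)) {
    return(list(mentions = empty_mentions(), trace = trace))
  }
  df <- do.call(rbind, out)
  # deduplicate identical (span, category), keeping the earliest layer
  df <- df[order(df$layer), , drop = FALSE]
  df <- df[!duplicated(paste(df$start, df$end, df$category)), , drop = FALSE]
  m <- mentions(df$start, df$end, df$category)
  list(mentions = m, trace = trace)
}

# dev-set micro F (percent) for early stopping
dev_fscore <- function(model, dev_recs, regime) {
  tp <- 0L; np <- 0L; ng <- 0L
  for (rec in dev_recs) {
    pred <- predict_sentence(model, rec$tokens)$mentions
    gold <- regime_set(rec$mentions, regime)
    pred_f <- regime_set(pred, regime)
    np <- np + nrow(pred_f); ng <- ng + nrow(gold)
    if (nrow(pred_f) && nrow(gold)) {
      tp <- tp + sum(paste(pred_f$start, pred_f$end, pred_f$category) %in%
                       paste(gold$start, gold$end, gold$category))
    }
  }
  p <- if (np) tp / np else 0
  r <- if (ng) tp / ng else 0
  if (p + r > 0) 200 * p * r / (p + r) else 0
}

# --- training loop ------------------------------------------------------------

train_tagger <- function(train_docs, dev_docs, config, categories,
                         flat = FALSE, regime = "all") {
  recs <- prepare_sentences(train_docs, regime = regime, flat = flat)
  if (!length(recs)) stop("empty training set")
  dev_recs <- if (length(dev_docs)) {
    prepare_sentences(dev_docs, regime = regime, flat = flat)
  } else list()
  if (is.null(categories)) {
    categories <- sort_c(unique(unlist(lapply(recs, function(r) {
      r$mentions$category
    }))))
  }
  tags <- bio_tagset(categories, config$scheme_variant)
  tagmap <- stats::setNames(seq_along(tags), tags)
  max_depth <- max(c(1L, vapply(recs, `[[`, integer(1), "depth")))
  n_layers <- if (flat) 1L else max_depth + 1L
  if (!is.null(config$max_layers)) {
    n_layers <- min(n_layers, max(1L, config$max_layers))
  }
  vocab <- c("<unk>",
             sort_c(unique(tolower(unlist(lapply(recs, function(r) {
               r$tokens$surface
             }))))))
  charset <- c("<unk>",
               sort_c(unique(unlist(strsplit(unlist(lapply(recs, function(r) {
                 r$tokens$surface
               })), "", fixed = TRUE)))))
  model <- with_local_seed(config$seed, {
    params <- new_tagger_params(config, vocab, charset, n_layers,
                                length(tags))
    m <- list(params = params, config = config, vocab = vocab,
              charset = charset, categories = categories, tags = tags,
              tagmap = tagmap, n_layers = n_layers, flat = flat,
              regime = regime, mask = bio_transition_mask(tags))
    class(m) <- "nen_model"
    plans <- lapply(recs, sentence_layer_plan, n_layers = n_layers,
                    tagmap = tagmap)
    st <- adam_state(params)
    log <- data.frame(epoch = integer(0), loss = numeric(0),
                      dev_f = numeric(0))
    best_f <- -Inf; best_loss <- Inf; best_params <- params; since_best <- 0L
    eval_regime <- if (flat) regime else "all"
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(recs))
      total <- 0
      for (si in ord) {
        plan_i <- if (config$teacher_forcing) plans[[si]] else
          sentence_dynamic_plan(m, recs[[si]], n_layers)
        sg <- sentence_loss_grad(m, recs[[si]], plan_i)
        total <- total + sg$loss
        upd <- adam_step(m$params, sg$grads, st, lr = config$lr,
                         clip = config$clip)
        m$params <- upd$params
        st <- upd$state
      }
      f <- if (length(dev_recs)) dev_fscore(m, dev_recs, eval_regime) else NA_real_
      log <- rbind(log, data.frame(epoch = epoch, loss = total, dev_f = f))
      if (length(dev_recs)) {
        # keep the best dev F; when dev F ties (small dev sets saturate),
        # prefer the checkpoint with the lower training loss
        if (f > best_f + 1e-9 ||
            (f > best_f - 1e-9 && total < best_loss - 1e-9)) {
          improved_f <- f > best_f + 1e-9
          best_f <- max(best_f, f); best_loss <- total
          best_params <- m$params
          since_best <- if (improved_f) 0L else since_best + 1L
        } else {
          since_best <- since_best + 1L
        }
        if (since_best >= config$patience) break
      } else {
        best_params <- m$params
      }
    }
    m$params <- best_params
    m$log <- log
    m$best_dev_f <- if (is.finite(best_f)) best_f else NA_real_
    m
  })
  model
}

#' @export
print.nen_model <- function(x, ...) {
  cat("<nen_model> ", if (x$flat) "flat" else "layered",
      " BiLSTM-CRF: ", x$n_layers, " layer(s), ",
      length(x$categories), " categories, vocab ", length(x$vocab),
      if (!is.na(x$best_dev_f)) sprintf(", best dev F %.2f", x$best_dev_f),
      "\n", sep = "")
  invisible(x)
}
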