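test_that("merge_region averages states and is identity on single units", {
  v <- c(1, 2, 3)
  expect_equal(merge_region(matrix(v, 1)), v)
  w <- c(5, 0, -1)
  expect_equal(merge_region(rbind(v, w)), (v + w) / 2)
  expect_equal(merge_region(matrix(rep(v, 4), 4, byrow = TRUE)), v)
  expect_error(merge_region(matrix(0, 0, 3)), "empty")
})

test_that("build_next_layer_input collapses regions and preserves order", {
  S <- matrix(seq_len(12), 4, 3)
  # no regions: identity
  id <- build_next_layer_input(S, data.frame(first = integer(0),
                                             last = integer(0)))
  expect_equal(id$states, S)
  expect_length(id$map, 4L)
  # a 2-unit region collapses: sequence shortens by 1
  nx <- build_next_layer_input(S, data.frame(first = 2L, last = 3L))
  expect_equal(nrow(nx$states), 3L)
  expect_equal(nx$states[2, ], (S[2, ] + S[3, ]) / 2)
  expect_equal(nx$map, list(1L, 2:3, 4L))
  # one region covering everything leaves a single unit
  all_ <- build_next_layer_input(S, data.frame(first = 1L, last = 4L))
  expect_equal(nrow(all_$states), 1L)
  expect_error(build_next_layer_input(S, data.frame(first = c(1L, 2L),
                                                    last = c(2L, 3L))),
               "disjoint")
})

test_that("unit counts never grow across stacked layers", {
  set.seed(31)
  for (rep in 1:10) {
    u <- sample(3:8, 1L)
    S <- matrix(stats::rnorm(u * 4L), u, 4L)
    n_reg <- sample(0:2, 1L)
    regions <- data.frame(first = integer(0), last = integer(0))
    if (n_reg > 0L && u >= 2L) {
      f <- sample.int(u - 1L, 1L)
      regions <- data.frame(first = f, last = min(u, f + 1L))
    }
    nx <- build_next_layer_input(S, regions)
    expect_lte(nrow(nx$states), u)
    expect_equal(sort(unlist(nx$map)), seq_len(u))
  }
})

test_that("split_corpus partitions deterministically at 8:1:1", {
  docs <- generate_corpus(synth_config(seed = 13L, n_documents = 30L))$docs
  p1 <- split_corpus(docs, seed = 99L)
  expect_length(p1$train, 24L)
  expect_length(p1$dev, 3L)
  expect_length(p1$test, 3L)
  p2 <- split_corpus(docs, seed = 99L)
  expect_identical(lapply(p1$train, `[[`, "doc_id"),
                   lapply(p2$train, `[[`, "doc_id"))
  ids <- c(vapply(p1$train, `[[`, character(1), "doc_id"),
           vapply(p1$dev, `[[`, character(1), "doc_id"),
           vapply(p1$test, `[[`, character(1), "doc_id"))
  expect_setequal(ids, unname(vapply(docs, `[[`, character(1), "doc_id")))
  expect_equal(anyDuplicated(ids), 0L)
  expect_error(split_corpus(docs[1:2]), "fewer")
  expect_error(split_corpus(docs, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("training memorizes a single repeated sentence (loss decreases to ~0)", {
  txt <- "patients with emphysema received inhaled corticosteroids therapy ."
  m <- mentions(c(14L, 33L, 41L), c(23L, 64L, 56L),
                c("Condition", "Treatment", "Drug"))
  doc <- nen_document("d1", txt, m)
  cfg <- nen_config(word_dim = 8L, char_emb_dim = 4L, char_hidden = 4L,
                    hidden = 8L, dropout = 0, epochs = 30L, patience = 30L,
                    seed = 3L)
  model <- train_layered(list(doc, doc, doc, doc), list(), cfg)
  expect_lt(model$log$loss[nrow(model$log)], model$log$loss[1] / 10)
  expect_lt(model$log$loss[nrow(model$log)], 1)
  pred <- predict_layered(model, doc)
  expect_equal(pred$mentions[, c("start", "end", "category")],
               doc$mentions[, c("start", "end", "category")])
})

test_that("prediction terminates, back-maps spans and deduplicates across layers", {
  g <- generate_corpus(synth_config(seed = 14L, n_documents = 12L))
  parts <- split_corpus(g$docs, seed = 14L)
  cfg <- tiny_config(seed = 14L)
  cfg$epochs <- 8L
  model <- train_layered(parts$train, parts$dev, cfg)
  expect_lte(model$n_layers, 4L)
  for (doc in parts$test) {
    pr <- predict_layered(model, doc)
    # every trace stops within the layer cap
    for (tr in pr$trace) expect_lte(length(tr), model$n_layers)
    df <- pr$mentions
    expect_equal(anyDuplicated(paste(df$start, df$end, df$category)), 0L)
    # back-mapped spans are whole-token ranges of the original text
    toks <- tokenize_text(doc$text)
    expect_true(all(df$start %in% toks$start))
    expect_true(all(df$end %in% toks$end))
  }
  # the empty document yields an empty prediction
  empty <- predict_layered(model, nen_document("e", ""))
  expect_equal(nrow(empty$mentions), 0L)
})

test_that("a model trained without nesting stops after its entity layer", {
  g <- generate_corpus(synth_config(seed = 15L, n_documents = 14L,
                                    p_nest = 0))
  parts <- split_corpus(g$docs, seed = 15L)
  cfg <- tiny_config(seed = 15L)
  cfg$epochs <- 8L
  model <- train_layered(parts$train, parts$dev, cfg)
  expect_equal(model$n_layers, 2L)  # entity layer + termination layer
  hits <- 0L
  for (doc in parts$test) {
    pr <- predict_layered(model, doc)
    for (tr in pr$trace) {
      if (length(tr) >= 1L && any(tr[[1]]$labels != "O")) {
        hits <- hits + 1L
        # a layer that found entities is followed by at most one more layer
        expect_lte(length(tr), 2L)
      }
    }
  }
  expect_gt(hits, 0L)
})

test_that("capping max_layers withholds outer mentions (ablation)", {
  g <- generate_corpus(synth_config(seed = 16L, n_documents = 14L,
                                    p_nest = 1, distractor_rate = 0.2))
  parts <- split_corpus(g$docs, seed = 16L)
  cfg <- tiny_config(seed = 16L)
  cfg$epochs <- 8L
  capped <- nen_config(word_dim = 16L, char_emb_dim = 8L, char_hidden = 8L,
                       hidden = 24L, dropout = 0.2, epochs = 8L,
                       patience = 4L, seed = 16L, max_layers = 1L)
  m_cap <- train_layered(parts$train, parts$dev, capped)
  expect_equal(m_cap$n_layers, 1L)
  f_cap <- corpus_micro_f(m_cap, parts$test, "outermost")
  m_full <- train_layered(parts$train, parts$dev, cfg)
  f_full <- corpus_micro_f(m_full, parts$test, "outermost")
  # with every mention nested, a single layer cannot reach the outer level
  expect_lt(f_cap, f_full)
})

test_that("training is reproducible under a fixed seed", {
  g <- generate_corpus(synth_config(seed = 17L, n_documents = 6L))
  cfg <- nen_config(word_dim = 8L, char_emb_dim = 4L, char_hidden = 4L,
                    hidden = 8L, dropout = 0.3, epochs = 2L, seed = 55L)
  m1 <- train_layered(g$docs, list(), cfg)
  m2 <- train_layered(g$docs, list(), cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log, m2$log)
})

test_that("predicted-region stacking and shared layers train without error", {
  g <- generate_corpus(synth_config(seed = 18L, n_documents = 5L))
  cfg <- nen_config(word_dim = 8L, char_emb_dim = 4L, char_hidden = 4L,
                    hidden = 8L, dropout = 0, epochs = 2L, seed = 2L,
                    teacher_forcing = FALSE)
  m <- train_layered(g$docs, list(), cfg)
  expect_true(all(is.finite(m$log$loss)))
  cfg2 <- nen_config(word_dim = 8L, char_emb_dim = 4L, char_hidden = 4L,
                     hidden = 8L, dropout = 0, epochs = 2L, seed = 2L,
                     share_layers = TRUE)
  m2 <- train_layered(g$docs, list(), cfg2)
  expect_true(all(is.finite(m2$log$loss)))
  expect_lte(length(m2$params$layers), 2L)
  pr <- predict_layered(m2, g$docs[[1]])
  expect_true(is.data.frame(pr$mentions))
})

test_that("model checkpoints round-trip through disk", {
  g <- generate_corpus(synth_config(seed = 19L, n_documents = 4L))
  cfg <- nen_config(word_dim = 8L, char_emb_dim = 4L, char_hidden = 4L,
                    hidden = 8L, dropout = 0, epochs = 1L, seed = 1L)
  m <- train_layered(g$docs, list(), cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  p1 <- predict_layered(m, g$docs[[1]])$mentions
  p2 <- predict_layered(m2, g$docs[[1]])$mentions
  expect_identical(p1, p2)
})
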