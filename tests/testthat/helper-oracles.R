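# Shared fixtures and independent oracles used across test files.

# small, fast tagger configuration for training tests
tiny_config <- function(seed = 11L, ...) {
  nen_config(word_dim = 16L, char_emb_dim = 8L, char_hidden = 8L,
             hidden = 24L, dropout = 0.2, lr = 0.01, epochs = 15L,
             patience = 4L, seed = seed, ...)
}

# enumerate all k^n tag paths (rows) for brute-force CRF checks
enum_paths <- function(n, k) {
  if (n == 1L) return(matrix(seq_len(k), ncol = 1L))
  sub <- enum_paths(n - 1L, k)
  do.call(rbind, lapply(seq_len(k), function(j) cbind(sub, j)))
}

# brute-force O(n^2) containment oracle, written independently of the
# package's vectorized span helpers: plain double loop over mention pairs
oracle_containment <- function(df) {
  n <- nrow(df)
  contains <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$start[i] <= df$start[j] && df$end[j] <= df$end[i] &&
          (df$end[i] - df$start[i]) > (df$end[j] - df$start[j])) {
        contains[i, j] <- TRUE
      }
    }
  }
  contains
}

oracle_innermost <- function(df) {
  cm <- oracle_containment(df)
  df[!apply(cm, 1, any), , drop = FALSE]
}

oracle_outermost <- function(df) {
  cm <- oracle_containment(df)
  df[!apply(cm, 2, any), , drop = FALSE]
}

# random disjoint-or-nested mention set over a token grid (for property
# tests); builds nesting by sampling nested intervals explicitly
random_nested_mentions <- function(n_max = 10L, width = 40L) {
  cats <- c("Condition", "Drug", "Quality", "Treatment", "AnatomicalConcept")
  n <- sample.int(n_max, 1L)
  starts <- integer(0); ends <- integer(0); cat_ <- character(0)
  compatible <- function(s, e) {
    for (j in seq_along(starts)) {
      overlaps <- s < ends[j] && starts[j] < e
      same <- s == starts[j] && e == ends[j]
      nested <- (s <= starts[j] && ends[j] <= e) ||
        (starts[j] <= s && e <= ends[j])
      if (overlaps && !same && !nested) return(FALSE)
    }
    TRUE
  }
  for (i in seq_len(n)) {
    if (length(starts) && stats::runif(1) < 0.5) {
      # try to nest inside an existing mention (if it is wide enough)
      j <- sample.int(length(starts), 1L)
      w <- ends[j] - starts[j]
      if (w >= 2L) {
        s <- starts[j] + sample.int(w - 1L, 1L) - 1L
        e <- s + sample.int(ends[j] - s - 1L, 1L)
        if (compatible(s, e)) {
          starts <- c(starts, s); ends <- c(ends, e)
          cat_ <- c(cat_, sample(cats, 1L))
        }
        next
      }
    }
    s <- sample.int(width - 2L, 1L) - 1L
    e <- s + sample.int(min(6L, width - s - 1L), 1L)
    if (compatible(s, e)) {
      starts <- c(starts, s); ends <- c(ends, e)
      cat_ <- c(cat_, sample(cats, 1L))
    }
  }
  df <- data.frame(start = starts, end = ends, category = cat_,
                   concept_id = NA_character_, stringsAsFactors = FALSE)
  df[!duplicated(paste(df$start, df$end, df$category)), , drop = FALSE]
}

# micro F (%) of predictions against gold over a document list
corpus_micro_f <- function(model, docs, regime) {
  gm <- phenonest:::pool_corpus_mentions(docs)
  pm <- phenonest:::pool_corpus_mentions(lapply(docs, function(d) {
    nen_document(d$doc_id, d$text, predict_layered(model, d)$mentions)
  }))
  strict_prf(gm, pm, regime)$micro$f
}
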