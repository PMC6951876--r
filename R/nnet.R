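# Neural building blocks: parameter initialization, bidirectional LSTM
# wrappers around the compiled kernels, the character-level encoder, and an
# Adam optimizer operating over nested parameter lists. All gradients are
# hand-derived and checked against finite differences in the test suite.

# run expr with a local RNG state seeded by `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

init_mat <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

new_lstm_params <- function(in_dim, hidden) {
  list(Wx = init_mat(in_dim, 4L * hidden),
       Wh = init_mat(hidden, 4L * hidden),
       b = rep(0, 4L * hidden))
}

new_bilstm_params <- function(in_dim, hidden) {
  list(f = new_lstm_params(in_dim, hidden),
       b = new_lstm_params(in_dim, hidden))
}

lstm_forward_r <- function(X, p) {
  out <- lstm_forward_cpp(X, p$Wx, p$Wh, matrix(p$b, 1))
  out
}

# X: T x D. Returns list(h = T x 2H aligned states, cache)
bilstm_forward <- function(X, p) {
  Tn <- nrow(X)
  rev_idx <- rev(seq_len(Tn))
  fw <- lstm_forward_r(X, p$f)
  bw <- lstm_forward_r(X[rev_idx, , drop = FALSE], p$b)
  h <- cbind(fw$h, bw$h[rev_idx, , drop = FALSE])
  list(h = h, cache = list(X = X, fw = fw, bw = bw, rev_idx = rev_idx))
}

# dH: T x 2H. Returns list(dX, grads = bilstm param gradients)
bilstm_backward <- function(p, cache, dH) {
  H <- ncol(cache$fw$h)
  rev_idx <- cache$rev_idx
  dHf <- dH[, seq_len(H), drop = FALSE]
  dHb <- dH[, H + seq_len(H), drop = FALSE][rev_idx, , drop = FALSE]
  Xr <- cache$X[rev_idx, , drop = FALSE]
  gf <- lstm_backward_cpp(cache$X, p$f$Wx, p$f$Wh, cache$fw$h, cache$fw$c,
                          cache$fw$gates, dHf)
  gb <- lstm_backward_cpp(Xr, p$b$Wx, p$b$Wh, cache$bw$h, cache$bw$c,
                          cache$bw$gates, dHb)
  dX <- gf$dX + gb$dX[rev_idx, , drop = FALSE]
  list(dX = dX,
       grads = list(f = list(Wx = gf$dWx, Wh = gf$dWh, b = as.vector(gf$db)),
                    b = list(Wx = gb$dWx, Wh = gb$dWh, b = as.vector(gb$db))))
}

# --- character-level encoder -------------------------------------------------

char_ids <- function(surface, charset) {
  ch <- strsplit(surface, "", fixed = TRUE)[[1]]
  i <- match(ch, charset)
  i[is.na(i)] <- 1L  # <unk> char at index 1
  i
}

# summary vector for one surface: final fwd state + final bwd state
char_encode_one <- function(surface, charset, E_char, p) {
  ids <- char_ids(surface, charset)
  X <- E_char[ids, , drop = FALSE]
  out <- bilstm_forward(X, p)
  H <- ncol(out$cache$fw$h)
  Tn <- nrow(X)
  summary <- c(out$h[Tn, seq_len(H)], out$h[1L, H + seq_len(H)])
  list(summary = summary, cache = out$cache, ids = ids)
}

char_backward_one <- function(p, cache, ids, dsummary, d_E_char) {
  H <- ncol(cache$fw$h)
  Tn <- nrow(cache$X)
  dH <- matrix(0, Tn, 2L * H)
  dH[Tn, seq_len(H)] <- dsummary[seq_len(H)]
  dH[1L, H + seq_len(H)] <- dsummary[H + seq_len(H)]
  bk <- bilstm_backward(p, cache, dH)
  for (r in seq_along(ids)) {
    d_E_char[ids[r], ] <- d_E_char[ids[r], ] + bk$dX[r, ]
  }
  list(d_E_char = d_E_char, grads = bk$grads)
}

# --- nested-list parameter utilities ----------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_gnorm2 <- function(g) {
  if (is.list(g)) sum(vapply(g, tree_gnorm2, numeric(1))) else sum(g^2)
}

# Adam with global-norm gradient clipping over a nested parameter list
adam_state <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.01, clip = 5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(tree_gnorm2(grads))
  if (is.finite(gn) && gn > clip) {
    scale <- clip / gn
    grads <- tree_map2(function(g, z) g * scale, grads, grads)
  }
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

#' Read word embeddings in text format
#'
#' Whitespace-separated format: one token per line followed by its vector
#' components. Files with a `.gz` extension are read transparently.
#'
#' @param path Path to the embedding file.
#' @return A numeric matrix with tokens as rownames.
#' @export
read_word_embeddings <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  # a possible "<count> <dim>" header line has no token
  if (length(parts) && length(parts[[1]]) == 2L &&
      !is.na(suppressWarnings(as.numeric(parts[[1]][1])))) {
    parts <- parts[-1]
  }
  toks <- vapply(parts, `[`, character(1), 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1]))
  dims <- lengths(vals)
  if (length(unique(dims)) != 1L) stop("inconsistent embedding dimensions")
  m <- do.call(rbind, vals)
  rownames(m) <- toks
  m
}
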