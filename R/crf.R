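# Linear-chain CRF over BIO tag sequences.
#
# Conventions: `emissions` is a T x K matrix of per-token tag scores;
# `transitions` is a (K+2) x (K+2) matrix whose entry [i, j] scores tag i
# followed by tag j, with two virtual boundary tags appended: row K+1 is the
# start tag (scores start -> j) and column K+2 is the stop tag (scores
# i -> stop). A path's score is the sum of its emission scores plus all
# transition scores including the start and stop transitions.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

col_logsumexp <- function(M) {
  m <- apply(M, 2, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok)) {
    out[ok] <- m[ok] + log(colSums(exp(sweep(M[, ok, drop = FALSE], 2, m[ok]))))
  }
  out
}

#' Empty CRF transition matrix
#'
#' @param k Number of real tags.
#' @param tag_names Optional tag names for dimnames (boundary tags are named
#'   `<start>` and `<stop>`).
#' @return A zero `(k+2) x (k+2)` matrix; index `k+1` is the virtual start
#'   tag, index `k+2` the virtual stop tag.
#' @export
crf_empty_transitions <- function(k, tag_names = NULL) {
  m <- matrix(0, k + 2L, k + 2L)
  if (!is.null(tag_names)) {
    nm <- c(tag_names, "<start>", "<stop>")
    dimnames(m) <- list(nm, nm)
  }
  m
}

check_crf_shapes <- function(emissions, transitions, tags = NULL) {
  k <- ncol(emissions)
  if (nrow(transitions) != k + 2L || ncol(transitions) != k + 2L) {
    stop("transitions must be (K+2) x (K+2) with K = ncol(emissions)")
  }
  if (!is.null(tags)) {
    if (length(tags) != nrow(emissions)) {
      stop("tag sequence length must equal nrow(emissions)")
    }
    if (any(tags < 1L | tags > k)) stop("tag index out of range")
  }
  invisible(k)
}

#' Score of one tag path under a linear-chain CRF
#'
#' @param emissions `T x K` matrix of per-token tag scores.
#' @param transitions `(K+2) x (K+2)` matrix (see [crf_empty_transitions()]).
#' @param tags Integer vector of tag indices (1-based), length `T`.
#' @return The path score: emissions along the path plus transitions,
#'   including virtual start and stop transitions.
#' @export
crf_sequence_score <- function(emissions, transitions, tags) {
  k <- check_crf_shapes(emissions, transitions, tags)
  n <- length(tags)
  s <- sum(emissions[cbind(seq_len(n), tags)]) +
    transitions[k + 1L, tags[1]] + transitions[tags[n], k + 2L]
  if (n > 1L) s <- s + sum(transitions[cbind(tags[-n], tags[-1])])
  s
}

#' Log-partition function of a linear-chain CRF
#'
#' Computed with the forward algorithm in log space; equals
#' `log(sum over all K^T tag paths of exp(path score))`.
#'
#' @inheritParams crf_sequence_score
#' @return A single number.
#' @export
crf_log_partition <- function(emissions, transitions) {
  k <- check_crf_shapes(emissions, transitions)
  n <- nrow(emissions)
  if (n == 0L) return(0)
  alpha <- transitions[k + 1L, seq_len(k)] + emissions[1, ]
  if (n > 1L) {
    tr <- transitions[seq_len(k), seq_len(k), drop = FALSE]
    for (t in 2:n) {
      alpha <- col_logsumexp(alpha + tr) + emissions[t, ]
    }
  }
  logsumexp(alpha + transitions[seq_len(k), k + 2L])
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Max-product decoding; ties are broken deterministically toward the lowest
#' tag index at the latest divergent step (`which.max` semantics applied
#' backwards through the lattice).
#'
#' @inheritParams crf_sequence_score
#' @return A list with `tags` (integer vector) and `score` (the attained
#'   maximum path score).
#' @export
crf_viterbi <- function(emissions, transitions) {
  k <- check_crf_shapes(emissions, transitions)
  n <- nrow(emissions)
  if (n == 0L) return(list(tags = integer(0), score = 0))
  delta <- transitions[k + 1L, seq_len(k)] + emissions[1, ]
  back <- matrix(NA_integer_, n, k)
  if (n > 1L) {
    tr <- transitions[seq_len(k), seq_len(k), drop = FALSE]
    for (t in 2:n) {
      m <- delta + tr                      # K x K: [prev, next]
      back[t, ] <- apply(m, 2, which.max)
      delta <- m[cbind(back[t, ], seq_len(k))] + emissions[t, ]
    }
  }
  fin <- delta + transitions[seq_len(k), k + 2L]
  tags <- integer(n)
  tags[n] <- which.max(fin)
  if (n > 1L) {
    for (t in n:2) tags[t - 1L] <- back[t, tags[t]]
  }
  list(tags = tags, score = fin[tags[n]])
}

#' Negative log-likelihood of a gold tag path
#'
#' `crf_nll = crf_log_partition - crf_sequence_score(gold)`; always
#' non-negative, and `exp(-crf_nll)` is the model probability of the gold
#' path.
#'
#' @inheritParams crf_sequence_score
#' @return A single non-negative number.
#' @export
crf_nll <- function(emissions, transitions, tags) {
  crf_log_partition(emissions, transitions) -
    crf_sequence_score(emissions, transitions, tags)
}

# Forward-backward gradients of crf_nll with respect to emissions and
# transitions. d_emissions = marginal tag probabilities - gold one-hot;
# d_transitions = expected transition counts - gold transition counts.
# `trainable` marks transition entries whose gradient is kept (used to
# freeze masked, forbidden BIO transitions).
crf_nll_grad <- function(emissions, transitions, tags, trainable = NULL) {
  k <- check_crf_shapes(emissions, transitions, tags)
  n <- nrow(emissions)
  tr <- transitions[seq_len(k), seq_len(k), drop = FALSE]
  alpha <- matrix(0, n, k); beta <- matrix(0, n, k)
  alpha[1, ] <- transitions[k + 1L, seq_len(k)] + emissions[1, ]
  if (n > 1L) {
    for (t in 2:n) {
      alpha[t, ] <- col_logsumexp(alpha[t - 1L, ] + tr) + emissions[t, ]
    }
  }
  beta[n, ] <- transitions[seq_len(k), k + 2L]
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      # beta[t, i] = logsumexp_j tr[i, j] + emis[t+1, j] + beta[t+1, j]
      beta[t, ] <- col_logsumexp(t(tr) + (emissions[t + 1L, ] + beta[t + 1L, ]))
    }
  }
  logz <- logsumexp(alpha[n, ] + beta[n, ])
  marg <- exp(alpha + beta - logz)
  d_emis <- marg
  d_emis[cbind(seq_len(n), tags)] <- d_emis[cbind(seq_len(n), tags)] - 1
  d_trans <- matrix(0, k + 2L, k + 2L)
  # start and stop expectations
  p_start <- exp(transitions[k + 1L, seq_len(k)] + emissions[1, ] +
                   beta[1, ] - logz)
  d_trans[k + 1L, seq_len(k)] <- p_start
  p_stop <- exp(alpha[n, ] + transitions[seq_len(k), k + 2L] - logz)
  d_trans[seq_len(k), k + 2L] <- p_stop
  if (n > 1L) {
    for (t in seq_len(n - 1L)) {
      pm <- exp(outer(alpha[t, ], emissions[t + 1L, ] + beta[t + 1L, ], "+") +
                  tr - logz)
      d_trans[seq_len(k), seq_len(k)] <-
        d_trans[seq_len(k), seq_len(k)] + pm
    }
    idx <- cbind(tags[-n], tags[-1])
    for (r in seq_len(nrow(idx))) {
      d_trans[idx[r, 1], idx[r, 2]] <- d_trans[idx[r, 1], idx[r, 2]] - 1
    }
  }
  d_trans[k + 1L, tags[1]] <- d_trans[k + 1L, tags[1]] - 1
  d_trans[tags[n], k + 2L] <- d_trans[tags[n], k + 2L] - 1
  if (!is.null(trainable)) d_trans[!trainable] <- 0
  list(d_emissions = d_emis, d_transitions = d_trans, log_partition = logz)
}

#' BIO tag vocabulary and transition constraints
#'
#' `bio_tagset` builds the tag list for a category set (`O` first, then
#' `B-`/`I-` per category, or `B/I/E/S` for BIOES). `bio_transition_mask`
#' returns a logical `(K+2) x (K+2)` matrix marking the structurally valid
#' transitions: `I-x` may only follow `B-x` or `I-x` (`E-x` analogously for
#' BIOES), and the start tag may not be followed by any `I`/`E` tag. Masked
#' (forbidden) transitions are held at a large negative score during scoring
#' and decoding so that emitted label sequences are always well-formed.
#'
#' @param categories Character vector of category labels.
#' @param scheme_variant `"bio"` or `"bioes"`.
#' @return `bio_tagset`: character vector of tags. `bio_transition_mask`:
#'   logical matrix, `TRUE` = allowed.
#' @export
bio_tagset <- function(categories, scheme_variant = c("bio", "bioes")) {
  scheme_variant <- match.arg(scheme_variant)
  categories <- sort_c(unique(categories))
  if (scheme_variant == "bio") {
    c("O", as.vector(rbind(paste0("B-", categories), paste0("I-", categories))))
  } else {
    c("O", as.vector(rbind(paste0("B-", categories), paste0("I-", categories),
                           paste0("E-", categories), paste0("S-", categories))))
  }
}

#' @rdname bio_tagset
#' @param tags A tag vector from `bio_tagset`.
#' @export
bio_transition_mask <- function(tags) {
  k <- length(tags)
  prefix <- ifelse(tags == "O", "O", substr(tags, 1, 1))
  cat_ <- ifelse(tags == "O", "", substr(tags, 3, nchar(tags)))
  allowed <- matrix(TRUE, k + 2L, k + 2L)
  for (j in seq_len(k)) {
    if (prefix[j] %in% c("I", "E")) {
      # only B-x or I-x may precede I-x / E-x
      ok_prev <- (prefix %in% c("B", "I")) & (cat_ == cat_[j])
      allowed[seq_len(k), j] <- ok_prev
      allowed[k + 1L, j] <- FALSE  # cannot start inside an entity
    }
  }
  # in BIOES, B-x and I-x may not end the sequence or precede non-continuation
  if (any(prefix %in% c("E", "S"))) {
    for (i in seq_len(k)) {
      if (prefix[i] %in% c("B", "I")) {
        ok_next <- (prefix %in% c("I", "E")) & (cat_ == cat_[i])
        allowed[i, seq_len(k)] <- ok_next
        allowed[i, k + 2L] <- FALSE
      }
    }
  }
  allowed[k + 2L, ] <- FALSE   # nothing follows stop
  allowed[, k + 1L] <- FALSE   # nothing precedes start
  allowed[k + 1L, k + 2L] <- TRUE  # empty sequence edge case
  allowed
}

# large negative, finite score for forbidden transitions
apply_transition_mask <- function(transitions, mask, penalty = -1e4) {
  transitions[!mask] <- penalty
  transitions
}
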