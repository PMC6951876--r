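#' Assign nesting levels to mentions
#'
#' Level 0 holds the innermost mentions; the level of a mention is the length
#' of the longest chain of strictly contained mentions beneath it, so a
#' 3-deep nest occupies levels 0, 1, 2. Mentions sharing an identical span
#' with different categories are placed on consecutive levels in lexicographic
#' category order (a convention; the encoding cannot hold two mentions of one
#' token range on one level).
#'
#' @param mention_df Mention data frame satisfying the disjoint-or-nested
#'   invariant (see [nen_document()]).
#' @return Integer vector of levels aligned with the rows of `mention_df`,
#'   with attribute `n_levels`.
#' @export
assign_levels <- function(mention_df) {
  df <- as.data.frame(mention_df)
  n <- nrow(df)
  if (!n) return(structure(integer(0), n_levels = 0L))
  if (nrow(crossing_pairs(df))) {
    stop("crossing mention spans violate the disjoint-or-nested invariant")
  }
  lev <- rep(NA_integer_, n)
  # byte-order category ranks make the tie-break locale-independent
  cat_rank <- match(df$category, sort_c(unique(df$category)))
  # process by increasing width so contained mentions are levelled first
  ord <- order_c(df$end - df$start, df$start, df$category)
  for (i in ord) {
    inside <- which(span_strictly_contains(df$start[i], df$end[i],
                                           df$start, df$end))
    base <- if (length(inside)) max(lev[inside]) + 1L else 0L
    # same-span predecessors (lexicographically smaller category) stack up
    same <- which(df$start == df$start[i] & df$end == df$end[i] &
                    cat_rank < cat_rank[i])
    if (length(same)) base <- max(base, max(lev[same], na.rm = FALSE) + 1L)
    lev[i] <- base
  }
  structure(lev, n_levels = max(lev) + 1L)
}

#' Encode mentions as per-level BIO label sequences
#'
#' Each nesting level becomes one BIO sequence over the sentence tokens:
#' a mention assigned to that level is labelled `B-<category>` on its first
#' token and `I-<category>` on the rest; all other tokens are `O`. BIO is
#' used (rather than BIOES) to limit label sparsity for small categories; set
#' `scheme_variant = "bioes"` for the richer scheme.
#'
#' @param tokens Token data frame from [tokenize_text()] (document offsets).
#' @param mention_df Mentions falling within the token range.
#' @param levels Level assignment from [assign_levels()] (computed when `NULL`).
#' @param boundary Policy for mention boundaries falling inside a token:
#'   `"snap"` (default) widens the mention to whole tokens with a message,
#'   `"drop"` discards the mention.
#' @param scheme_variant `"bio"` or `"bioes"`.
#' @return An object of class `levelled_sentence`: list with `tokens` and
#'   `labels` (list of character vectors, one per level, innermost first).
#' @export
encode_bio <- function(tokens, mention_df, levels = NULL,
                       boundary = c("snap", "drop"),
                       scheme_variant = c("bio", "bioes")) {
  boundary <- match.arg(boundary)
  scheme_variant <- match.arg(scheme_variant)
  df <- as.data.frame(mention_df)
  if (is.null(levels)) levels <- assign_levels(df)
  nt <- nrow(tokens)
  n_lev <- max(1L, if (length(levels)) max(levels) + 1L else 0L)
  labs <- replicate(n_lev, rep("O", nt), simplify = FALSE)
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      first <- which(tokens$end > df$start[i])[1]
      last <- rev(which(tokens$start < df$end[i]))[1]
      if (is.na(first) || is.na(last) || first > last) next
      snapped <- tokens$start[first] != df$start[i] ||
        tokens$end[last] != df$end[i]
      if (snapped) {
        if (boundary == "drop") next
        message("snapping mention (", df$start[i], ",", df$end[i],
                ") outward to token boundaries")
      }
      l <- levels[i] + 1L
      rng <- first:last
      if (scheme_variant == "bioes" && length(rng) == 1L) {
        labs[[l]][rng] <- paste0("S-", df$category[i])
      } else {
        labs[[l]][rng] <- paste0("I-", df$category[i])
        labs[[l]][first] <- paste0("B-", df$category[i])
        if (scheme_variant == "bioes") {
          labs[[l]][last] <- paste0("E-", df$category[i])
        }
      }
    }
  }
  structure(list(tokens = tokens, labels = labs), class = "levelled_sentence")
}

#' Decode one BIO label sequence back to mentions
#'
#' Maximal `B-x I-x ...` runs become mentions with character spans taken from
#' the underlying tokens. Malformed sequences are repaired conventionally: an
#' `I-x` following `O`, a different category, or the sequence start is treated
#' as `B-x`, so decoding is total. BIOES labels (`E-`/`S-`) are accepted.
#'
#' @param labels Character vector of BIO labels, one per token.
#' @param tokens Token data frame aligned with `labels`.
#' @return A mention data frame (no `concept_id` values).
#' @export
decode_bio <- function(labels, tokens) {
  stopifnot(length(labels) == nrow(tokens))
  starts <- integer(0); ends <- integer(0); cats <- character(0)
  cur_cat <- NULL; cur_first <- NA_integer_
  flush <- function(last) {
    if (!is.null(cur_cat)) {
      starts <<- c(starts, tokens$start[cur_first])
      ends <<- c(ends, tokens$end[last])
      cats <<- c(cats, cur_cat)
    }
  }
  for (t in seq_along(labels)) {
    lab <- labels[t]
    if (lab == "O") {
      flush(t - 1L); cur_cat <- NULL
    } else {
      prefix <- substr(lab, 1, 1)
      cat_ <- substr(lab, 3, nchar(lab))
      if (prefix %in% c("B", "S") || is.null(cur_cat) || cat_ != cur_cat) {
        flush(t - 1L)
        cur_cat <- cat_; cur_first <- t
      }
      if (prefix %in% c("E", "S")) {
        flush(t); cur_cat <- NULL
      }
    }
  }
  flush(length(labels))
  mentions(starts, ends, cats)
}

#' Innermost, outermost and all entity sets
#'
#' Innermost mentions contain no other mention; outermost mentions are
#' contained in no other mention. A mention with no nesting partner is both
#' innermost and outermost. Containment is strict, so two mentions sharing an
#' identical span are each both innermost and outermost with respect to one
#' another.
#'
#' @param mention_df A mention data frame.
#' @return The subset of rows belonging to the requested set.
#' @export
innermost_set <- function(mention_df) {
  df <- as.data.frame(mention_df)
  if (!nrow(df)) return(df)
  keep <- vapply(seq_len(nrow(df)), function(i) {
    !any(span_strictly_contains(df$start[i], df$end[i], df$start, df$end)[-i])
  }, logical(1))
  out <- df[keep, , drop = FALSE]; rownames(out) <- NULL; out
}

#' @rdname innermost_set
#' @export
outermost_set <- function(mention_df) {
  df <- as.data.frame(mention_df)
  if (!nrow(df)) return(df)
  keep <- vapply(seq_len(nrow(df)), function(i) {
    !any(span_strictly_contains(df$start, df$end, df$start[i], df$end[i])[-i])
  }, logical(1))
  out <- df[keep, , drop = FALSE]; rownames(out) <- NULL; out
}

#' @rdname innermost_set
#' @export
all_set <- function(mention_df) {
  df <- as.data.frame(mention_df)
  rownames(df) <- NULL
  df
}

#' Filter a mention set by nesting regime
#'
#' @param mention_df A mention data frame.
#' @param regime One of `"all"`, `"innermost"`, `"outermost"`.
#' @return The regime's subset of `mention_df`.
#' @export
regime_set <- function(mention_df, regime = c("all", "innermost", "outermost")) {
  regime <- match.arg(regime)
  switch(regime,
         all = all_set(mention_df),
         innermost = innermost_set(mention_df),
         outermost = outermost_set(mention_df))
}

#' Export levelled sentences in column format
#'
#' One token per line, tab-separated: surface followed by one BIO column per
#' nesting level; sentences separated by a blank line. This is the common
#' interchange format of sequence-labeling tooling.
#'
#' @param sentences List of `levelled_sentence` objects.
#' @param n_levels Pad every sentence to this many label columns (`O`);
#'   defaults to the corpus-wide maximum.
#' @return A single string.
#' @export
format_column_export <- function(sentences, n_levels = NULL) {
  if (is.null(n_levels)) {
    n_levels <- max(1L, vapply(sentences, function(s) length(s$labels),
                               integer(1)))
  }
  blocks <- vapply(sentences, function(s) {
    labs <- s$labels
    while (length(labs) < n_levels) {
      labs <- c(labs, list(rep("O", nrow(s$tokens))))
    }
    cols <- do.call(cbind, c(list(s$tokens$surface), labs))
    paste(apply(cols, 1, paste, collapse = "\t"), collapse = "\n")
  }, character(1))
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}
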