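#' Annotated documents
#'
#' An annotated document couples raw text with a set of typed, possibly nested
#' entity mentions. After validation, any two mention spans are either
#' disjoint, identical (with different categories), or properly nested —
#' crossing overlaps are not representable in the per-level BIO encoding used
#' by the layered tagger and are handled according to `policy`.
#'
#' @param doc_id Document identifier string.
#' @param text Document text (UTF-8).
#' @param mentions A mention data frame (see [mentions()]).
#' @param scheme An `nen_scheme`; categories are checked against it when given.
#' @param policy `"drop"` removes the later-starting mention of every crossing
#'   pair with a warning; `"strict"` raises an error instead.
#' @return An object of class `nen_document`.
#' @export
nen_document <- function(doc_id, text, mentions = empty_mentions(),
                         scheme = NULL, policy = c("drop", "strict")) {
  policy <- match.arg(policy)
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  df <- canonical_mention_order(as.data.frame(mentions))
  if (!all(c("start", "end", "category") %in% names(df))) {
    stop("mentions must have columns start, end, category")
  }
  if (is.null(df$concept_id)) df$concept_id <- NA_character_
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$end <= df$start)) {
      stop("invalid span in document ", doc_id, ": need 0 <= start < end")
    }
    if (any(df$end > nchar(text))) {
      stop("mention span beyond end of text in document ", doc_id)
    }
    if (!is.null(scheme)) assert_category(df$category, scheme)
    df <- dedup_mentions(df)
    df <- resolve_crossings(df, doc_id, policy)
  }
  structure(list(doc_id = doc_id, text = text, mentions = df),
            class = "nen_document")
}

# drop (or reject) the later-starting member of every crossing pair
resolve_crossings <- function(df, doc_id, policy) {
  repeat {
    cp <- crossing_pairs(df)
    if (!nrow(cp)) return(df)
    if (policy == "strict") {
      stop("crossing mention spans in document ", doc_id, ": (",
           df$start[cp[1, 1]], ",", df$end[cp[1, 1]], ") vs (",
           df$start[cp[1, 2]], ",", df$end[cp[1, 2]], ")", call. = FALSE)
    }
    # canonical order sorts by start, so the second member starts no earlier
    drop_i <- cp[1, 2]
    warning("dropping crossing mention (", df$start[drop_i], ",",
            df$end[drop_i], ",", df$category[drop_i], ") in document ",
            doc_id, call. = FALSE)
    df <- df[-drop_i, , drop = FALSE]
    rownames(df) <- NULL
  }
}

#' @export
print.nen_document <- function(x, ...) {
  cat("<nen_document> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      nrow(x$mentions), " mentions\n", sep = "")
  invisible(x)
}

#' Read brat-style standoff annotations
#'
#' Parses the `.txt`/`.ann` content pair of the brat standoff dialect:
#' `T`-lines (`Tn<TAB>Category start end<TAB>surface`) carry entity mentions
#' and `N`-lines (`Nn<TAB>Reference Tn concept_id<TAB>label`) attach concept
#' identifiers. The surface string of every `T`-line is checked against the
#' text at the stated offsets.
#'
#' @param txt_content Document text.
#' @param ann_content Annotation content (possibly empty string).
#' @param doc_id Identifier for the resulting document.
#' @inheritParams nen_document
#' @return A validated `nen_document`.
#' @export
read_standoff <- function(txt_content, ann_content, scheme = copd_scheme(),
                          policy = c("drop", "strict"), doc_id = "doc") {
  policy <- match.arg(policy)
  lines <- strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  starts <- integer(0); ends <- integer(0); cats <- character(0)
  tids <- character(0)
  concept <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tag <- substr(fields[1], 1, 1)
    if (tag == "T") {
      if (length(fields) < 2L) {
        stop("malformed standoff line: ", ln, call. = FALSE)
      }
      head <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      if (length(head) != 3L || is.na(suppressWarnings(as.integer(head[2])))) {
        stop("malformed T-line: ", ln, call. = FALSE)
      }
      cat_ <- head[1]
      s <- as.integer(head[2]); e <- as.integer(head[3])
      assert_category(cat_, scheme)
      if (is.na(s) || is.na(e) || s < 0L || e <= s || e > nchar(txt_content)) {
        stop("offset out of range in line: ", ln, call. = FALSE)
      }
      surf <- if (length(fields) >= 3L) fields[3] else span_text(txt_content, s, e)
      if (surf != span_text(txt_content, s, e)) {
        stop("surface/offset mismatch in line: ", ln, " (text has '",
             span_text(txt_content, s, e), "')", call. = FALSE)
      }
      tids <- c(tids, fields[1])
      starts <- c(starts, s); ends <- c(ends, e); cats <- c(cats, cat_)
    } else if (tag == "N") {
      if (length(fields) < 2L) stop("malformed standoff line: ", ln, call. = FALSE)
      head <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      if (length(head) != 3L) stop("malformed N-line: ", ln, call. = FALSE)
      concept[[head[2]]] <- head[3]
    }
    # other brat line types (A, R, E, comments) are ignored
  }
  cid <- rep(NA_character_, length(tids))
  if (length(concept)) {
    hit <- match(tids, names(concept))
    cid[!is.na(hit)] <- unlist(concept)[hit[!is.na(hit)]]
  }
  df <- data.frame(start = starts, end = ends, category = cats,
                   concept_id = cid, stringsAsFactors = FALSE)
  nen_document(doc_id, txt_content, df, scheme = scheme, policy = policy)
}

#' Write brat-style standoff annotations
#'
#' Inverse of [read_standoff()]: emits deterministic `T`-lines (sorted by
#' start offset, then longer mentions first, then category) and `N`-lines for
#' mentions carrying a concept identifier. `read_standoff()` applied to the
#' output reproduces the document exactly.
#'
#' @param doc An `nen_document`.
#' @return A list with elements `txt` and `ann` (single strings; `ann` is
#'   `""` for a document without mentions).
#' @export
write_standoff <- function(doc) {
  stopifnot(inherits(doc, "nen_document"))
  df <- canonical_mention_order(doc$mentions)
  if (!nrow(df)) return(list(txt = doc$text, ann = ""))
  tl <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(df)), df$category,
                df$start, df$end, span_text(doc$text, df$start, df$end))
  out <- tl
  has_c <- which(!is.na(df$concept_id))
  if (length(has_c)) {
    nl <- sprintf("N%d\tReference T%d %s\t%s", seq_along(has_c), has_c,
                  df$concept_id[has_c],
                  span_text(doc$text, df$start[has_c], df$end[has_c]))
    out <- c(tl, nl)
  }
  list(txt = doc$text, ann = paste0(paste(out, collapse = "\n"), "\n"))
}

#' Corpus-level mention statistics
#'
#' Per-category mention counts and the fraction of mentions embedded
#' (strictly contained) inside another mention of the same document.
#'
#' @param docs A list of `nen_document` objects.
#' @param scheme Scheme whose categories define the count table rows;
#'   categories outside the scheme found in `docs` are appended.
#' @return A list with `counts` (data frame `category`, `n`), `n_mentions`,
#'   `n_embedded`, `embedded_fraction`, and `embedded_fraction_defined`
#'   (`FALSE`, with fraction reported as 0, for an empty corpus).
#' @export
corpus_statistics <- function(docs, scheme = copd_scheme()) {
  stopifnot(is.list(docs))
  cats <- scheme$labels
  tot <- stats::setNames(rep(0L, length(cats)), cats)
  n_all <- 0L; n_emb <- 0L
  for (doc in docs) {
    df <- doc$mentions
    n <- nrow(df)
    n_all <- n_all + n
    if (!n) next
    tc <- table(df$category)
    extra <- setdiff(names(tc), names(tot))
    if (length(extra)) tot <- c(tot, stats::setNames(rep(0L, length(extra)), extra))
    tot[names(tc)] <- tot[names(tc)] + as.integer(tc)
    if (n > 1L) {
      emb <- vapply(seq_len(n), function(i) {
        any(span_strictly_contains(df$start, df$end,
                                   df$start[i], df$end[i])[-i])
      }, logical(1))
      n_emb <- n_emb + sum(emb)
    }
  }
  list(counts = data.frame(category = names(tot), n = as.integer(tot),
                           stringsAsFactors = FALSE, row.names = NULL),
       n_mentions = n_all, n_embedded = n_emb,
       embedded_fraction = if (n_all > 0L) n_emb / n_all else 0,
       embedded_fraction_defined = n_all > 0L)
}

#' Read or write a directory of .txt/.ann document pairs
#'
#' @param dir Directory containing (`read_corpus_dir`) or to receive
#'   (`write_corpus_dir`) paired `<id>.txt` and `<id>.ann` files.
#' @param docs List of `nen_document`s.
#' @inheritParams read_standoff
#' @return `read_corpus_dir`: a named list of documents. `write_corpus_dir`:
#'   the directory, invisibly.
#' @export
read_corpus_dir <- function(dir, scheme = copd_scheme(),
                            policy = c("drop", "strict")) {
  policy <- match.arg(policy)
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- list()
  for (tp in txts) {
    id <- sub("\\.txt$", "", basename(tp))
    ap <- file.path(dir, paste0(id, ".ann"))
    txt <- readChar(tp, file.info(tp)$size, useBytes = FALSE)
    ann <- if (file.exists(ap)) readChar(ap, file.info(ap)$size) else ""
    docs[[id]] <- read_standoff(txt, ann, scheme = scheme, policy = policy,
                                doc_id = id)
  }
  docs
}

#' @rdname read_corpus_dir
#' @export
write_corpus_dir <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in docs) {
    so <- write_standoff(doc)
    writeLines(so$txt, file.path(dir, paste0(doc$doc_id, ".txt")), sep = "")
    writeLines(so$ann, file.path(dir, paste0(doc$doc_id, ".ann")), sep = "")
  }
  invisible(dir)
}
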