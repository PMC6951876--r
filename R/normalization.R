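# Rule-based mention normalization: generate semantically consistent string
# variants of a mention with six techniques (abbreviation expansion, plural
# to singular, neoclassical->English, English->neoclassical, syntactic
# variation, synonym substitution), and match the variants against a
# terminology's labels and synonyms, filtered by semantic category.

#' Read a terminology file
#'
#' Tab-separated columns: `id`, `preferred_label`, `synonyms`
#' (pipe-separated, may be empty), `semantic_tags` (pipe-separated category
#' labels used to filter candidates per mention category). Lookup is
#' case-insensitive after whitespace folding. The packaged
#' `mock_terminology()` is a small hand-written synthetic table used by the
#' tests and examples; real deployments plug in their own file.
#'
#' @param path Path to the terminology file.
#' @return An object of class `nen_terminology`.
#' @export
read_terminology <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", header = FALSE,
                          col.names = c("id", "preferred_label", "synonyms",
                                        "semantic_tags"))
  if (anyDuplicated(df$id)) stop("duplicate identifiers in terminology")
  entries <- lapply(seq_len(nrow(df)), function(i) {
    syn <- strsplit(df$synonyms[i], "|", fixed = TRUE)[[1]]
    syn <- syn[nzchar(syn)]
    tags <- strsplit(df$semantic_tags[i], "|", fixed = TRUE)[[1]]
    list(id = df$id[i], preferred = df$preferred_label[i],
         synonyms = syn, tags = tags[nzchar(tags)])
  })
  # flat lookup table: folded string -> entry index (first wins)
  keys <- character(0); idx <- integer(0)
  for (i in seq_along(entries)) {
    strs <- c(entries[[i]]$preferred, entries[[i]]$synonyms)
    keys <- c(keys, fold_term(strs))
    idx <- c(idx, rep(i, length(strs)))
  }
  keep <- !duplicated(keys)
  structure(list(entries = entries, keys = keys[keep], idx = idx[keep]),
            class = "nen_terminology")
}

#' @rdname read_terminology
#' @export
mock_terminology <- function() {
  read_terminology(system.file("extdata", "mock_terminology.tsv",
                               package = "phenonest", mustWork = TRUE))
}

#' @export
print.nen_terminology <- function(x, ...) {
  cat("<nen_terminology> ", length(x$entries), " concepts, ",
      length(x$keys), " lookup strings\n", sep = "")
  invisible(x)
}

fold_term <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

# first terminology hit for a folded string under a category filter
terminology_lookup <- function(terminology, s, category = NULL) {
  hits <- which(terminology$keys == fold_term(s))
  for (h in hits) {
    e <- terminology$entries[[terminology$idx[h]]]
    if (is.null(category) || !length(e$tags) || category %in% e$tags) {
      return(e$id)
    }
  }
  NA_character_
}

#' Variant-generation rule set
#'
#' Loads the declarative rule tables driving the six variant-generation
#' techniques. The packaged defaults cover common respiratory-medicine
#' abbreviations, Latin/Greek plurals, a finite neoclassical/English
#' morpheme table, adjective/nominalization and inversion patterns, and a
#' small synonym table; each file is one rule per line and user-extensible.
#'
#' @param dir Directory containing `abbreviations.tsv`, `plurals.tsv`,
#'   `neoclassical.tsv`, `syntactic.tsv`, `synonyms.tsv`; defaults to the
#'   packaged tables.
#' @return An object of class `variant_rules`.
#' @export
read_variant_rules <- function(dir = system.file("extdata", "rules",
                                                 package = "phenonest",
                                                 mustWork = TRUE)) {
  rd <- function(f, n) {
    utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE,
                      quote = "", comment.char = "#", header = FALSE,
                      col.names = n)
  }
  structure(list(
    abbreviations = rd("abbreviations.tsv", c("abbrev", "expansion")),
    plurals = rd("plurals.tsv", c("kind", "pattern", "replacement")),
    neoclassical = rd("neoclassical.tsv", c("neoclassical", "english")),
    syntactic = rd("syntactic.tsv", c("pattern", "replacement")),
    synonyms = rd("synonyms.tsv", c("phrase", "substitute"))
  ), class = "variant_rules")
}

# --- individual techniques: each maps a string to 0+ rewrites ---------------

sub_phrase <- function(s, phrase, substitute, ignore_case = TRUE) {
  pat <- paste0("\\b", gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", phrase,
                            perl = TRUE),
                "\\b")
  if (!grepl(pat, s, ignore.case = ignore_case, perl = TRUE)) return(character(0))
  sub(pat, substitute, s, ignore.case = ignore_case, perl = TRUE)
}

tech_abbreviation <- function(s, rules) {
  out <- character(0)
  for (i in seq_len(nrow(rules$abbreviations))) {
    out <- c(out, sub_phrase(s, rules$abbreviations$abbrev[i],
                             rules$abbreviations$expansion[i]))
  }
  out
}

tech_plural <- function(s, rules) {
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  out <- character(0)
  for (ti in seq_along(toks)) {
    tk <- toks[ti]
    for (i in seq_len(nrow(rules$plurals))) {
      kind <- rules$plurals$kind[i]
      new <- NULL
      if (kind == "token" && tolower(tk) == rules$plurals$pattern[i]) {
        new <- rules$plurals$replacement[i]
      } else if (kind == "suffix" &&
                 grepl(rules$plurals$pattern[i], tk, perl = TRUE)) {
        new <- sub(rules$plurals$pattern[i], rules$plurals$replacement[i],
                   tk, perl = TRUE)
      }
      if (!is.null(new) && new != tk) {
        v <- toks; v[ti] <- new
        out <- c(out, paste(v, collapse = " "))
        break  # first matching plural rule per token
      }
    }
  }
  out
}

tech_neo_to_english <- function(s, rules) {
  out <- character(0)
  for (i in seq_len(nrow(rules$neoclassical))) {
    out <- c(out, sub_phrase(s, rules$neoclassical$neoclassical[i],
                             rules$neoclassical$english[i]))
  }
  out
}

tech_english_to_neo <- function(s, rules) {
  out <- character(0)
  for (i in seq_len(nrow(rules$neoclassical))) {
    out <- c(out, sub_phrase(s, rules$neoclassical$english[i],
                             rules$neoclassical$neoclassical[i]))
  }
  # productive -itis pattern: "<stem>al inflammation" -> "<stem>itis"
  if (grepl("^(.*\\w)al inflammation$", s, perl = TRUE)) {
    out <- c(out, sub("^(.*\\w)al inflammation$", "\\1itis", s, perl = TRUE))
  }
  out
}

tech_syntactic <- function(s, rules) {
  out <- character(0)
  for (i in seq_len(nrow(rules$syntactic))) {
    if (grepl(rules$syntactic$pattern[i], s, perl = TRUE)) {
      v <- sub(rules$syntactic$pattern[i], rules$syntactic$replacement[i],
               s, perl = TRUE)
      if (v != s) out <- c(out, v)
    }
  }
  out
}

tech_synonym <- function(s, rules) {
  out <- character(0)
  for (i in seq_len(nrow(rules$synonyms))) {
    out <- c(out, sub_phrase(s, rules$synonyms$phrase[i],
                             rules$synonyms$substitute[i]))
  }
  out
}

technique_order <- c("abbreviation", "plural", "neo_to_english",
                     "english_to_neo", "syntactic", "synonym")

apply_technique <- function(tech, s, rules) {
  switch(tech,
         abbreviation = tech_abbreviation(s, rules),
         plural = tech_plural(s, rules),
         neo_to_english = tech_neo_to_english(s, rules),
         english_to_neo = tech_english_to_neo(s, rules),
         syntactic = tech_syntactic(s, rules),
         synonym = tech_synonym(s, rules))
}

#' Generate semantically consistent variants of a mention
#'
#' Applies the six variant-generation techniques in a fixed order
#' (abbreviation expansion, plural-to-singular, neoclassical-to-English,
#' English-to-neoclassical, syntactic variation, synonym substitution),
#' composing at most two techniques deep. The original mention is always the
#' first variant; duplicates are removed keeping the first occurrence; the
#' list is capped at `max_variants`.
#'
#' @param mention Non-empty mention string.
#' @param rules A [read_variant_rules()] rule set.
#' @param max_variants Cap on the number of returned variants.
#' @return A character vector of variants with attribute `trails`: a list of
#'   the technique sequence that produced each variant (empty for the
#'   original).
#' @export
generate_variants <- function(mention, rules = read_variant_rules(),
                              max_variants = 200L) {
  stopifnot(is.character(mention), length(mention) == 1L, nzchar(mention))
  variants <- mention
  trails <- list(character(0))
  frontier <- 1L
  for (depth in 1:2) {
    new_from <- frontier
    frontier <- integer(0)
    for (vi in new_from) {
      for (tech in technique_order) {
        for (v in apply_technique(tech, variants[vi], rules)) {
          if (length(variants) >= max_variants) break
          if (!(v %in% variants)) {
            variants <- c(variants, v)
            trails[[length(trails) + 1L]] <- c(trails[[vi]], tech)
            frontier <- c(frontier, length(variants))
          }
        }
      }
    }
    if (!length(frontier) || length(variants) >= max_variants) break
  }
  structure(variants, trails = trails)
}

#' Normalize a mention to a terminology concept
#'
#' Generates variants of the mention and returns the concept identifier of
#' the first variant (in generation order) found in the terminology after
#' filtering concepts by the mention's semantic category. A mention whose
#' variants all miss stays unnormalized; multi-concept mentions are not
#' split and simply fail to match.
#'
#' @param mention Mention string.
#' @param category Scheme category of the mention.
#' @param terminology An `nen_terminology`.
#' @param rules A `variant_rules` rule set.
#' @param scheme Scheme used to validate `category`.
#' @param max_variants Passed to [generate_variants()].
#' @return A list of class `normalization_result`: `mention`, `category`,
#'   `concept_id` (`NA` if unnormalized), `matched_variant`, and `trail`
#'   (character vector of applied techniques; empty for a direct match).
#' @export
normalize_mention <- function(mention, category, terminology = mock_terminology(),
                              rules = read_variant_rules(),
                              scheme = copd_scheme(), max_variants = 200L) {
  assert_category(category, scheme)
  vs <- generate_variants(mention, rules, max_variants)
  trails <- attr(vs, "trails")
  for (i in seq_along(vs)) {
    id <- terminology_lookup(terminology, vs[i], category)
    if (!is.na(id)) {
      return(structure(list(mention = mention, category = category,
                            concept_id = id, matched_variant = vs[i],
                            trail = trails[[i]]),
                       class = "normalization_result"))
    }
  }
  structure(list(mention = mention, category = category,
                 concept_id = NA_character_, matched_variant = NA_character_,
                 trail = character(0)),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("'", x$mention, "' [", x$category, "] -> ",
      if (is.na(x$concept_id)) "unnormalized" else x$concept_id, sep = "")
  if (length(x$trail)) cat(" via ", paste(x$trail, collapse = " + "), sep = "")
  cat("\n")
  invisible(x)
}

#' Normalize every mention of a corpus
#'
#' @param docs List of `nen_document`s.
#' @inheritParams normalize_mention
#' @return A data frame with one row per mention: `doc_id`, `start`, `end`,
#'   `mention`, `category`, `concept_id`, `n_techniques`.
#' @export
normalize_corpus <- function(docs, terminology = mock_terminology(),
                             rules = read_variant_rules(),
                             scheme = copd_scheme()) {
  rows <- list()
  for (doc in docs) {
    df <- doc$mentions
    for (i in seq_len(nrow(df))) {
      surf <- span_text(doc$text, df$start[i], df$end[i])
      r <- normalize_mention(surf, df$category[i], terminology, rules, scheme)
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = doc$doc_id, start = df$start[i], end = df$end[i],
        mention = surf, category = df$category[i],
        concept_id = r$concept_id, n_techniques = length(r$trail),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(doc_id = character(0), start = integer(0),
                      end = integer(0), mention = character(0),
                      category = character(0), concept_id = character(0),
                      n_techniques = integer(0)))
  }
  do.call(rbind, rows)
}

#' Per-category normalization coverage
#'
#' `coverage_report` summarizes normalization results; `coverage_table`
#' performs the underlying arithmetic from plain counts (percentage =
#' 100 x normalized / total, two decimals, with a grand-total row). A
#' category with zero mentions reports 0 and is flagged.
#'
#' @param results Data frame from [normalize_corpus()].
#' @return A data frame with columns `category`, `total`, `normalized`,
#'   `pct`, `flag_empty`, ending with a `Total` row.
#' @export
coverage_report <- function(results) {
  cats <- sort_c(unique(results$category))
  total <- vapply(cats, function(cc) sum(results$category == cc), integer(1))
  normd <- vapply(cats, function(cc) {
    sum(results$category == cc & !is.na(results$concept_id))
  }, integer(1))
  coverage_table(cats, total, normd)
}

#' @rdname coverage_report
#' @param categories,total,normalized Parallel vectors of category names and
#'   counts.
#' @export
coverage_table <- function(categories, total, normalized) {
  stopifnot(length(categories) == length(total),
            length(total) == length(normalized))
  if (any(normalized > total)) stop("normalized count exceeds total")
  pct <- ifelse(total > 0, round(100 * normalized / total, 2), 0)
  df <- data.frame(category = as.character(categories),
                   total = as.integer(total),
                   normalized = as.integer(normalized),
                   pct = pct, flag_empty = total == 0,
                   stringsAsFactors = FALSE)
  tot <- sum(total); nn <- sum(normalized)
  rbind(df, data.frame(category = "Total", total = tot, normalized = nn,
                       pct = if (tot > 0) round(100 * nn / tot, 2) else 0,
                       flag_empty = tot == 0))
}

#' Attach normalization results to documents
#'
#' Fills the `concept_id` column of each document's mentions from a
#' [normalize_corpus()] result table, so that [write_standoff()] emits the
#' corresponding `N`-lines.
#'
#' @param docs List of documents.
#' @param results Result table from [normalize_corpus()].
#' @return The list of documents with concept identifiers attached.
#' @export
apply_normalization <- function(docs, results) {
  for (di in seq_along(docs)) {
    df <- docs[[di]]$mentions
    if (!nrow(df)) next
    key <- paste(docs[[di]]$doc_id, df$start, df$end, df$category)
    rkey <- paste(results$doc_id, results$start, results$end,
                  results$category)
    hit <- match(key, rkey)
    df$concept_id <- ifelse(is.na(hit), df$concept_id,
                            results$concept_id[hit])
    docs[[di]]$mentions <- df
  }
  docs
}
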