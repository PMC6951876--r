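# Character-offset helpers. All offsets in this package are 0-based,
# half-open [start, end) over Unicode code points, the brat convention.

# a strictly contains b: a covers b and is strictly larger on at least one side
span_strictly_contains <- function(a_start, a_end, b_start, b_end) {
  (a_start <= b_start) & (b_end <= a_end) &
    ((a_start < b_start) | (b_end < a_end))
}

# a and b overlap but neither contains the other and spans are not identical
span_crossing <- function(a_start, a_end, b_start, b_end) {
  overlaps <- (a_start < b_end) & (b_start < a_end)
  same <- (a_start == b_start) & (a_end == b_end)
  a_in_b <- (b_start <= a_start) & (a_end <= b_end)
  b_in_a <- (a_start <= b_start) & (b_end <= a_end)
  overlaps & !same & !a_in_b & !b_in_a
}

# substring by 0-based half-open character offsets
span_text <- function(text, start, end) {
  substr(rep_len(text, length(start)), start + 1L, end)
}

#' Construct a mention table
#'
#' Mentions are kept in an ordinary data frame with columns `start`, `end`
#' (0-based half-open character offsets), `category`, and `concept_id`
#' (`NA` when the mention is not linked to a terminology concept).
#'
#' @param start,end Integer offsets, `0 <= start < end`.
#' @param category Character vector of scheme category labels.
#' @param concept_id Optional character vector of concept identifiers.
#' @return A data frame of class `data.frame` in canonical order
#'   (by `start`, then longer mentions first, then `category`).
#' @export
mentions <- function(start = integer(0), end = integer(0),
                     category = character(0), concept_id = NA_character_) {
  n <- length(start)
  if (length(end) != n || length(category) != n) {
    stop("start, end and category must have equal length")
  }
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   category = as.character(category),
                   concept_id = rep_len(as.character(concept_id), n),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0L) || any(df$end <= df$start)) {
    stop("invalid span: need 0 <= start < end")
  }
  canonical_mention_order(df)
}

empty_mentions <- function() mentions()

# locale-independent character sort/order (byte order), so that canonical
# orders, vocabularies and tag sets are identical across platforms
sort_c <- function(x) sort(x, method = "radix")
order_c <- function(...) order(..., method = "radix")

# deterministic order: by start asc, end desc (longer first), category asc
canonical_mention_order <- function(df) {
  if (!nrow(df)) return(df)
  df <- df[order_c(df$start, -df$end, df$category), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# drop exact (start, end, category) duplicates, keeping the first
dedup_mentions <- function(df) {
  if (!nrow(df)) return(df)
  key <- paste(df$start, df$end, df$category)
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# indices i, j of crossing pairs (i < j), brute force
crossing_pairs <- function(df) {
  n <- nrow(df)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    i < j & span_crossing(df$start[i], df$end[i], df$start[j], df$end[j])
  }), arr.ind = TRUE)
  idx
}
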