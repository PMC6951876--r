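#' Offset-preserving tokenization
#'
#' Splits text into word and punctuation tokens while recording the 0-based
#' half-open character span of every token, so that entity mention offsets can
#' be mapped exactly between text and token space. Alphanumeric runs are kept
#' whole, including biomedical tokens such as `FEV1` and internally hyphenated
#' or apostrophized compounds (`alpha1-antitrypsin`); every other non-space
#' character becomes a single-character token.
#'
#' @param text A single character string.
#' @return A data frame with columns `surface`, `start`, `end`.
#' @examples
#' tokenize_text("reduced FEV1 .")
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) {
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  pat <- "[[:alnum:]]+(?:[-'][[:alnum:]]+)*|[^[:space:]]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(surface = span_text(text, start, end),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Sentence segmentation with offsets
#'
#' Sentences are split at newlines and at a full stop followed by whitespace.
#' This simple segmenter fits both the synthetic corpora produced by
#' [generate_corpus()] (one sentence per line) and plain article text; it does
#' not attempt abbreviation handling.
#'
#' @param text A single character string.
#' @return A data frame with 0-based half-open columns `start`, `end`, one row
#'   per non-empty sentence.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  out <- data.frame(start = integer(0), end = integer(0))
  if (n == 0L) return(out)
  # boundary positions (0-based offset *after* which a break occurs)
  brk <- integer(0)
  m <- gregexpr("\\n|\\.[[:space:]]", text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    # break right after the '.' or the newline (first matched character)
    brk <- as.integer(m)
  }
  bounds <- sort(unique(c(brk, n)))
  s <- 0L
  starts <- integer(0); ends <- integer(0)
  for (b in bounds) {
    seg <- span_text(text, s, b)
    # trim surrounding whitespace, keeping offsets exact
    lead <- nchar(sub("^([[:space:]]*).*$", "\\1", seg))
    trail <- nchar(sub("^.*?([[:space:]]*)$", "\\1", seg))
    s2 <- s + lead
    e2 <- b - trail
    if (e2 > s2) {
      starts <- c(starts, s2); ends <- c(ends, e2)
    }
    s <- b
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}
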