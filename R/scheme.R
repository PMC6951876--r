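#' Entity annotation schemes
#'
#' A scheme is a small forest of semantic category labels. The packaged COPD
#' phenotype scheme has 16 categories arranged under four top-level groups
#' (`Problem`, `Treatment`, `TestOrMeasure`, `ConstituentConcept`); phenotype
#' descriptions receive the most specific label available, and constituent
#' concepts (anatomy, drugs, proteins, qualities) may be annotated nested
#' inside them.
#'
#' @param path Path to a tab-separated scheme file with columns `label` and
#'   `parent` (`-` marks a root).
#' @return An object of class `nen_scheme`: a list with `labels` (character)
#'   and `parent` (named character, `NA` for roots).
#' @examples
#' sch <- copd_scheme()
#' length(sch$labels)  # 16
#' @export
read_scheme <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (!all(c("label", "parent") %in% names(df))) {
    stop("scheme file must have columns 'label' and 'parent'")
  }
  labels <- df$label
  if (anyDuplicated(labels)) stop("duplicate labels in scheme file")
  parent <- ifelse(df$parent %in% c("-", ""), NA_character_, df$parent)
  names(parent) <- labels
  bad <- parent[!is.na(parent) & !(parent %in% labels)]
  if (length(bad)) stop("unknown parent label(s): ", paste(bad, collapse = ", "))
  # acyclicity: walk up from every label, must reach a root
  for (l in labels) {
    seen <- character(0)
    p <- l
    while (!is.na(parent[[p]])) {
      if (p %in% seen) stop("cycle in scheme hierarchy at label ", l)
      seen <- c(seen, p)
      p <- parent[[p]]
    }
  }
  structure(list(labels = labels, parent = parent), class = "nen_scheme")
}

#' @rdname read_scheme
#' @export
copd_scheme <- function() {
  read_scheme(system.file("extdata", "copd_scheme.tsv", package = "phenonest",
                          mustWork = TRUE))
}

#' @export
print.nen_scheme <- function(x, ...) {
  roots <- x$labels[is.na(x$parent[x$labels])]
  cat("<nen_scheme> ", length(x$labels), " categories, roots: ",
      paste(roots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

is_scheme <- function(x) inherits(x, "nen_scheme")

assert_category <- function(category, scheme) {
  bad <- setdiff(unique(category), scheme$labels)
  if (length(bad)) {
    stop("category not in scheme: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
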