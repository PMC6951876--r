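#' Strict-match precision, recall and F-score
#'
#' A prediction counts as a true positive only when both its character span
#' and its category exactly equal a gold mention. The nesting `regime`
#' restricts which mentions are evaluated: the gold side is filtered by the
#' regime computed on the gold nesting structure, and the predicted side by
#' the regime computed on the predictions' own nesting structure (so a
#' nested prediction is not penalized in the outermost regime; for flat
#' per-regime models the prediction filter is the identity). Percentages are
#' reported to two decimals; precision over an empty prediction set is
#' reported as 0 and flagged.
#'
#' @param gold,pred Mention data frames (deduplicated internally).
#' @param regime `"all"`, `"innermost"`, or `"outermost"`.
#' @param categories Category rows to include in the per-category table;
#'   defaults to those observed.
#' @return An object of class `eval_report`: list with `per_category` (data
#'   frame of tp/fp/fn and percentage P/R/F per category), `micro` (one-row
#'   data frame), `regime`, and `undefined_precision` flag.
#' @export
strict_prf <- function(gold, pred, regime = c("all", "innermost", "outermost"),
                       categories = NULL) {
  regime <- match.arg(regime)
  gold <- dedup_mentions(canonical_mention_order(as.data.frame(gold)))
  pred <- dedup_mentions(canonical_mention_order(as.data.frame(pred)))
  gold <- regime_set(gold, regime)
  pred <- regime_set(pred, regime)
  if (is.null(categories)) {
    categories <- sort_c(unique(c(gold$category, pred$category)))
  }
  gk <- paste(gold$start, gold$end, gold$category)
  pk <- paste(pred$start, pred$end, pred$category)
  rows <- lapply(categories, function(cc) {
    g <- gk[gold$category == cc]
    p <- pk[pred$category == cc]
    tp <- sum(p %in% g)
    data.frame(category = cc, tp = tp, fp = length(p) - tp,
               fn = length(g) - tp, stringsAsFactors = FALSE)
  })
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(0), tp = integer(0), fp = integer(0),
               fn = integer(0))
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(round(p, 2), round(r, 2), round(f, 2))
  }
  if (nrow(per)) {
    m <- t(mapply(function(tp, fp, fn) prf(tp, fp, fn),
                  per$tp, per$fp, per$fn))
    per$precision <- m[, 1]; per$recall <- m[, 2]; per$f <- m[, 3]
  } else {
    per$precision <- numeric(0); per$recall <- numeric(0); per$f <- numeric(0)
  }
  mtp <- sum(per$tp); mfp <- sum(per$fp); mfn <- sum(per$fn)
  mm <- prf(mtp, mfp, mfn)
  micro <- data.frame(tp = mtp, fp = mfp, fn = mfn, precision = mm[1],
                      recall = mm[2], f = mm[3])
  structure(list(per_category = per, micro = micro, regime = regime,
                 undefined_precision = (mtp + mfp) == 0),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Strict-match evaluation (", x$regime, " entities)\n", sep = "")
  df <- rbind(cbind(data.frame(category = x$per_category$category),
                    x$per_category[, c("tp", "fp", "fn", "precision",
                                       "recall", "f")]),
              cbind(data.frame(category = "micro"), x$micro))
  print(df, row.names = FALSE)
  if (x$undefined_precision) {
    cat("note: no predictions; precision reported as 0\n")
  }
  invisible(x)
}

# serialize a report for JSON output (micro as a scalar object)
eval_report_to_list <- function(x) {
  list(regime = x$regime, per_category = x$per_category,
       micro = as.list(x$micro))
}

#' Inter-annotator agreement as micro-averaged F-score
#'
#' Agreement between two annotators over the same texts, computed by
#' treating one annotator's mentions as gold and the other's as predictions
#' under strict matching, micro-averaged over all documents and categories.
#' Micro-F is symmetric in the two annotators (swapping exchanges precision
#' and recall).
#'
#' @param docs_a,docs_b Lists of `nen_document`s over identical texts,
#'   matched by `doc_id`.
#' @return An object of class `eval_report` whose `micro$f` is the IAA
#'   percentage.
#' @export
iaa_fscore <- function(docs_a, docs_b) {
  ids_a <- vapply(docs_a, `[[`, character(1), "doc_id")
  ids_b <- vapply(docs_b, `[[`, character(1), "doc_id")
  if (!setequal(ids_a, ids_b)) stop("annotator document sets differ")
  gold_all <- list(); pred_all <- list()
  off <- 0L
  for (id in sort_c(ids_a)) {
    a <- docs_a[[match(id, ids_a)]]
    b <- docs_b[[match(id, ids_b)]]
    if (a$text != b$text) {
      stop("annotators disagree on the text of document ", id)
    }
    # shift offsets so documents never collide in the pooled mention set
    ga <- a$mentions; gb <- b$mentions
    ga$start <- ga$start + off; ga$end <- ga$end + off
    gb$start <- gb$start + off; gb$end <- gb$end + off
    gold_all[[id]] <- ga; pred_all[[id]] <- gb
    off <- off + nchar(a$text) + 1L
  }
  strict_prf(do.call(rbind, gold_all), do.call(rbind, pred_all),
             regime = "all")
}

#' Error taxonomy for strict-match mistakes
#'
#' Classifies every false positive and false negative into exactly one
#' bucket via greedy one-to-one matching: exact (span, category) matches are
#' removed first; remaining pairs with identical span but different category
#' fill the `wrong_type` bucket; then pairs with the same category and
#' overlapping (but not identical) spans fill the `wrong_span` bucket,
#' matched in decreasing overlap size with ties broken by earliest start;
#' unmatched predictions are `spurious` and unmatched gold mentions
#' `missed`.
#'
#' @param gold,pred Mention data frames.
#' @return An object of class `error_breakdown`: list with `by_category`
#'   (data frame of bucket counts per category: gold category for matched
#'   and missed buckets, predicted category for spurious), `totals`, and
#'   `confusion` (gold x predicted category counts of wrong-type pairs).
#' @export
error_taxonomy <- function(gold, pred) {
  gold <- dedup_mentions(canonical_mention_order(as.data.frame(gold)))
  pred <- dedup_mentions(canonical_mention_order(as.data.frame(pred)))
  gk <- paste(gold$start, gold$end, gold$category)
  pk <- paste(pred$start, pred$end, pred$category)
  tp_p <- pk %in% gk
  tp_g <- gk %in% pk
  gl <- gold[!tp_g, , drop = FALSE]
  pl <- pred[!tp_p, , drop = FALSE]
  n_tp <- sum(tp_p)
  wrong_type <- data.frame(gold_category = character(0),
                           pred_category = character(0))
  wrong_span_cat <- character(0)
  # pass 1: same span, different category
  if (nrow(gl) && nrow(pl)) {
    repeat {
      hit <- NULL
      for (i in seq_len(nrow(gl))) {
        j <- which(pl$start == gl$start[i] & pl$end == gl$end[i])
        if (length(j)) { hit <- c(i, j[1]); break }
      }
      if (is.null(hit)) break
      wrong_type <- rbind(wrong_type, data.frame(
        gold_category = gl$category[hit[1]],
        pred_category = pl$category[hit[2]], stringsAsFactors = FALSE))
      gl <- gl[-hit[1], , drop = FALSE]
      pl <- pl[-hit[2], , drop = FALSE]
      if (!nrow(gl) || !nrow(pl)) break
    }
  }
  # pass 2: same category, overlapping span, greedy by overlap size
  if (nrow(gl) && nrow(pl)) {
    repeat {
      best <- NULL; best_ov <- 0L; best_start <- Inf
      for (i in seq_len(nrow(gl))) {
        for (j in seq_len(nrow(pl))) {
          if (gl$category[i] != pl$category[j]) next
          ov <- min(gl$end[i], pl$end[j]) - max(gl$start[i], pl$start[j])
          if (ov <= 0L) next
          st <- min(gl$start[i], pl$start[j])
          if (ov > best_ov || (ov == best_ov && st < best_start)) {
            best <- c(i, j); best_ov <- ov; best_start <- st
          }
        }
      }
      if (is.null(best)) break
      wrong_span_cat <- c(wrong_span_cat, gl$category[best[1]])
      gl <- gl[-best[1], , drop = FALSE]
      pl <- pl[-best[2], , drop = FALSE]
      if (!nrow(gl) || !nrow(pl)) break
    }
  }
  cats <- sort_c(unique(c(gold$category, pred$category)))
  count_by <- function(v) {
    t <- table(factor(v, levels = cats))
    as.integer(t)
  }
  by_cat <- data.frame(category = cats,
                       wrong_type = count_by(wrong_type$gold_category),
                       wrong_span = count_by(wrong_span_cat),
                       spurious = count_by(pl$category),
                       missed = count_by(gl$category),
                       stringsAsFactors = FALSE)
  confusion <- table(factor(wrong_type$gold_category, levels = cats),
                     factor(wrong_type$pred_category, levels = cats))
  totals <- data.frame(tp = n_tp,
                       wrong_type = nrow(wrong_type),
                       wrong_span = length(wrong_span_cat),
                       spurious = nrow(pl), missed = nrow(gl),
                       n_pred = nrow(pred), n_gold = nrow(gold))
  structure(list(by_category = by_cat, totals = totals,
                 confusion = confusion),
            class = "error_breakdown")
}

#' @export
print.error_breakdown <- function(x, ...) {
  cat("Error taxonomy\n")
  print(x$totals, row.names = FALSE)
  print(x$by_category, row.names = FALSE)
  invisible(x)
}
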