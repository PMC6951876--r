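test_that("strict matching scores identity, misses and category errors", {
  gold <- mentions(c(0L, 10L), c(7L, 20L), c("Condition", "Treatment"))
  perfect <- strict_prf(gold, gold, "all")
  expect_equal(perfect$micro$precision, 100)
  expect_equal(perfect$micro$recall, 100)
  expect_equal(perfect$micro$f, 100)

  none <- strict_prf(gold, mentions(), "all")
  expect_equal(none$micro$precision, 0)
  expect_equal(none$micro$recall, 0)
  expect_equal(none$micro$f, 0)
  expect_true(none$undefined_precision)

  # right span, wrong category: no credit under strict matching
  wrong <- strict_prf(mentions(0L, 7L, "SignOrSymptom"),
                      mentions(0L, 7L, "Condition"), "all")
  expect_equal(wrong$micro$tp, 0L)
  expect_equal(wrong$micro$f, 0)
})

test_that("regimes filter both sides by their own nesting structure", {
  # gold: outer Condition containing inner AnatomicalConcept, plus a flat one
  gold <- mentions(c(0L, 3L, 30L), c(10L, 7L, 37L),
                   c("Condition", "AnatomicalConcept", "SignOrSymptom"))
  # prediction found only the nested pair
  pred <- mentions(c(0L, 3L), c(10L, 7L), c("Condition", "AnatomicalConcept"))
  inn <- strict_prf(gold, pred, "innermost")
  expect_equal(inn$micro$tp, 1L)   # the anatomical mention
  expect_equal(inn$micro$fn, 1L)   # flat mention is innermost too
  expect_equal(inn$micro$fp, 0L)   # outer prediction not counted here
  out <- strict_prf(gold, pred, "outermost")
  expect_equal(out$micro$tp, 1L)
  expect_equal(out$micro$fp, 0L)
  all_ <- strict_prf(gold, pred, "all")
  expect_equal(all_$micro$tp, 2L)
  expect_equal(all_$micro$fn, 1L)
  # for nesting-free sets, the three regimes coincide
  flat_g <- mentions(c(0L, 20L), c(7L, 27L), c("Condition", "Drug"))
  flat_p <- mentions(0L, 7L, "Condition")
  for (r in c("all", "innermost", "outermost")) {
    expect_equal(strict_prf(flat_g, flat_p, r)$micro$f,
                 strict_prf(flat_g, flat_p, "all")$micro$f)
  }
})

test_that("strict_prf ignores mention ordering and duplicates", {
  gold <- mentions(c(0L, 10L), c(7L, 20L), c("Condition", "Treatment"))
  shuffled <- gold[c(2L, 1L), ]
  dup <- rbind(gold, gold[1L, ])
  expect_equal(strict_prf(gold, shuffled, "all")$micro$f, 100)
  expect_equal(strict_prf(dup, gold, "all")$micro$f, 100)
})

test_that("inter-annotator agreement is symmetric and bounded by its extremes", {
  pair0 <- generate_annotator_pair(synth_config(seed = 23L, n_documents = 6L))
  expect_equal(iaa_fscore(pair0$annotator_a, pair0$annotator_b)$micro$f, 100)

  pair <- generate_annotator_pair(synth_config(seed = 23L, n_documents = 10L),
                                  span_shift_rate = 0.1, relabel_rate = 0.15,
                                  drop_rate = 0.15)
  ab <- iaa_fscore(pair$annotator_a, pair$annotator_b)
  ba <- iaa_fscore(pair$annotator_b, pair$annotator_a)
  expect_equal(ab$micro$f, ba$micro$f)
  expect_equal(ab$micro$precision, ba$micro$recall)
  expect_lt(ab$micro$f, 100)
  expect_gt(ab$micro$f, 0)

  # disjoint annotation sets agree at 0
  a <- list(nen_document("d", "abc def", mentions(0L, 3L, "Condition")))
  b <- list(nen_document("d", "abc def", mentions(4L, 7L, "Drug")))
  expect_equal(iaa_fscore(a, b)$micro$f, 0)
  # mismatched texts are an alignment error
  b2 <- list(nen_document("d", "abc xyz", mentions(4L, 7L, "Drug")))
  expect_error(iaa_fscore(a, b2), "text")
})

test_that("error taxonomy fills the right buckets", {
  # same span, different category
  et <- error_taxonomy(mentions(0L, 10L, "Problem"),
                       mentions(0L, 10L, "Condition"))
  expect_equal(et$totals$wrong_type, 1L)
  expect_equal(et$totals$wrong_span + et$totals$spurious + et$totals$missed,
               0L)
  expect_equal(as.integer(et$confusion["Problem", "Condition"]), 1L)
  # same category, overlapping span
  et2 <- error_taxonomy(mentions(0L, 10L, "Treatment"),
                        mentions(0L, 6L, "Treatment"))
  expect_equal(et2$totals$wrong_span, 1L)
  expect_equal(et2$totals$wrong_type, 0L)
  # perfect prediction: all buckets empty
  g <- mentions(c(0L, 12L), c(7L, 20L), c("Condition", "Drug"))
  et3 <- error_taxonomy(g, g)
  expect_equal(et3$totals$tp, 2L)
  expect_equal(sum(et3$totals[c("wrong_type", "wrong_span", "spurious",
                                "missed")]), 0L)
  # disjoint sets: only spurious and missed
  et4 <- error_taxonomy(mentions(0L, 5L, "Condition"),
                        mentions(20L, 25L, "Drug"))
  expect_equal(et4$totals$spurious, 1L)
  expect_equal(et4$totals$missed, 1L)
})

test_that("taxonomy buckets conserve prediction and gold counts", {
  set.seed(77)
  for (rep in 1:25) {
    gold <- random_nested_mentions()
    pred <- random_nested_mentions()
    et <- error_taxonomy(gold, pred)
    t <- et$totals
    expect_equal(t$tp + t$wrong_type + t$wrong_span + t$spurious, t$n_pred)
    expect_equal(t$tp + t$wrong_type + t$wrong_span + t$missed, t$n_gold)
  }
})

test_that("relabel-only annotator noise produces pure wrong-type errors", {
  pair <- generate_annotator_pair(synth_config(seed = 24L, n_documents = 8L),
                                  relabel_rate = 0.4)
  for (id in names(pair$annotator_a)) {
    et <- error_taxonomy(pair$annotator_a[[id]]$mentions,
                         pair$annotator_b[[id]]$mentions)
    expect_equal(et$totals$wrong_span, 0L)
    expect_equal(et$totals$spurious, 0L)
    expect_equal(et$totals$missed, 0L)
  }
})
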