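test_that("each variant-generation technique produces its documented rewrite", {
  rules <- read_variant_rules()
  v <- function(m) as.character(generate_variants(m, rules))
  expect_true("Type 2 diabetes mellitus" %in% v("Type 2 DM"))
  expect_true("alveolar septum" %in% v("alveolar septa"))
  expect_true("pleuritis" %in% v("pleural inflammation"))
  expect_true("oxygen supplementation" %in% v("supplemental oxygen"))
  expect_true("shortness of breath" %in% v("dyspnea"))
  # depth-2 composition: synonym then neoclassical-to-English
  expect_true("deterioration of lung function" %in%
                v("worsening pulmonary function"))
  # the original mention always comes first
  expect_equal(v("emphysema")[1], "emphysema")
  # no applicable rule: singleton set with an empty trail
  out <- generate_variants("qqq zzz", rules)
  expect_equal(as.character(out)[1], "qqq zzz")
  expect_equal(attr(out, "trails")[[1]], character(0))
})

test_that("variant generation is deterministic, deduplicated and capped", {
  rules <- read_variant_rules()
  a <- generate_variants("worsening pulmonary function", rules)
  b <- generate_variants("worsening pulmonary function", rules)
  expect_identical(a, b)
  expect_equal(anyDuplicated(as.character(a)), 0L)
  capped <- generate_variants("worsening pulmonary function", rules,
                              max_variants = 5L)
  expect_lte(length(capped), 5L)
  expect_equal(as.character(capped)[1], "worsening pulmonary function")
})

test_that("mentions normalize to the documented concepts", {
  term <- mock_terminology()
  rules <- read_variant_rules()
  cases <- list(
    c("increased PVR", "Problem", "C1867423"),
    c("lung failure", "Condition", "C0948755"),
    c("left atrial", "AnatomicalConcept", "C0225860"),
    c("arm training", "Treatment", "C0556501"),
    c("spirometric test", "TestOrMeasure", "C0037981"),
    c("genetic predisposition", "RiskFactor", "C1455997"))
  for (cs in cases) {
    r <- normalize_mention(cs[1], cs[2], term, rules)
    expect_equal(r$concept_id, cs[3])
  }
  # a preferred label matches directly with an empty technique trail
  direct <- normalize_mention("Pulmonary failure", "Condition", term, rules)
  expect_equal(direct$concept_id, "C0948755")
  expect_length(direct$trail, 0L)
  # no matching concept: unnormalized
  miss <- normalize_mention("negative pleural pressure",
                            "TestOrMeasureResult", term, rules)
  expect_true(is.na(miss$concept_id))
  # multi-concept mentions are not split and fail to normalize
  multi <- normalize_mention("coughing and/or corticosteroid-induced osteoporosis",
                             "SignOrSymptom", term, rules)
  expect_true(is.na(multi$concept_id))
  expect_error(normalize_mention("dyspnea", "NotACategory", term, rules),
               "category")
})

test_that("category filtering restricts candidate concepts", {
  term <- mock_terminology()
  rules <- read_variant_rules()
  # "lung failure" is tagged Condition in the terminology
  r <- normalize_mention("lung failure", "Treatment", term, rules)
  expect_true(is.na(r$concept_id))
})

test_that("matched identifiers always exist in the terminology (soundness)", {
  term <- mock_terminology()
  rules <- read_variant_rules()
  ids <- vapply(term$entries, `[[`, character(1), "id")
  g <- generate_corpus(synth_config(seed = 25L, n_documents = 8L))
  res <- normalize_corpus(g$docs, term, rules)
  hit <- res$concept_id[!is.na(res$concept_id)]
  expect_gt(length(hit), 0L)
  expect_true(all(hit %in% ids))
})

test_that("enlarging the terminology never loses normalizations (monotonicity)", {
  rules <- read_variant_rules()
  small_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("C1\tDyspnea\tshortness of breath\tSignOrSymptom", small_tsv)
  small <- read_terminology(small_tsv)
  big_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("C1\tDyspnea\tshortness of breath\tSignOrSymptom",
               "C2\tChronic cough\t\tSignOrSymptom"), big_tsv)
  big <- read_terminology(big_tsv)
  ms <- c("dyspnea", "chronic cough", "wheezing")
  n_small <- sum(!vapply(ms, function(m) {
    is.na(normalize_mention(m, "SignOrSymptom", small, rules)$concept_id)
  }, logical(1)))
  n_big <- sum(!vapply(ms, function(m) {
    is.na(normalize_mention(m, "SignOrSymptom", big, rules)$concept_id)
  }, logical(1)))
  expect_gte(n_big, n_small)
})

test_that("coverage arithmetic recomputes percentages from counts", {
  tab <- coverage_table(c("Condition", "Quality"), c(5119L, 1153L),
                        c(4969L, 1015L))
  expect_equal(tab$pct[tab$category == "Condition"], 97.07)
  expect_equal(tab$pct[tab$category == "Quality"], 88.03)
  tot <- tab[tab$category == "Total", ]
  expect_equal(tot$total, 6272L)
  expect_equal(tot$pct, round(100 * (4969 + 1015) / 6272, 2))
  # zero-total categories are flagged and report 0
  z <- coverage_table("Drug", 0L, 0L)
  expect_equal(z$pct[1], 0)
  expect_true(z$flag_empty[1])
  expect_error(coverage_table("Drug", 1L, 2L), "exceeds")
  # report percentages recompute exactly from their own counts
  g <- generate_corpus(synth_config(seed = 26L, n_documents = 6L))
  res <- normalize_corpus(g$docs)
  cov <- coverage_report(res)
  expect_equal(cov$pct,
               ifelse(cov$total > 0, round(100 * cov$normalized / cov$total, 2), 0))
  expect_equal(cov$total[cov$category == "Total"], nrow(res))
})

test_that("normalization results attach as N-lines on written standoff", {
  g <- generate_corpus(synth_config(seed = 27L, n_documents = 3L))
  res <- normalize_corpus(g$docs)
  docs2 <- apply_normalization(g$docs, res)
  anns <- vapply(docs2, function(d) write_standoff(d)$ann, character(1))
  expect_true(any(grepl("\nN1\tReference T", anns)))
  # round trip keeps the attached identifiers
  d <- docs2[[which(grepl("N1", anns))[1]]]
  so <- write_standoff(d)
  back <- read_standoff(so$txt, so$ann, doc_id = d$doc_id)
  expect_identical(back$mentions, d$mentions)
})
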