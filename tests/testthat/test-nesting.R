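test_that("level assignment is innermost-first and respects containment order", {
  # measurement-result phrase containing a nested anatomical mention
  txt <- "elevation of pulmonary arterial pressures"
  m <- mentions(c(0L, 13L), c(41L, 31L),
                c("TestOrMeasureResult", "AnatomicalConcept"))
  lev <- assign_levels(m)
  inner <- which(m$category == "AnatomicalConcept")
  outer <- which(m$category == "TestOrMeasureResult")
  expect_equal(lev[inner], 0L)
  expect_gte(lev[outer], 1L)

  single <- mentions(0L, 7L, "Condition")
  expect_equal(as.integer(assign_levels(single)), 0L)

  crossing <- data.frame(start = c(0L, 3L), end = c(5L, 8L),
                         category = c("Drug", "Condition"))
  expect_error(assign_levels(crossing), "crossing")
})

test_that("levels agree with the brute-force containment oracle on random nests", {
  set.seed(41)
  for (rep in 1:40) {
    df <- random_nested_mentions()
    if (!nrow(df)) next
    lev <- assign_levels(df)
    cm <- oracle_containment(df)
    for (i in seq_len(nrow(df))) {
      for (j in seq_len(nrow(df))) {
        if (cm[i, j]) expect_gt(lev[i], lev[j])
      }
    }
    # mentions on one level are pairwise disjoint
    for (l in unique(lev)) {
      sel <- df[lev == l, , drop = FALSE]
      if (nrow(sel) < 2L) next
      for (i in seq_len(nrow(sel) - 1L)) {
        for (j in (i + 1L):nrow(sel)) {
          expect_true(sel$end[i] <= sel$start[j] ||
                        sel$end[j] <= sel$start[i])
        }
      }
    }
  }
})

test_that("same-span multi-category mentions stack on consecutive levels", {
  m <- mentions(c(0L, 0L), c(9L, 9L), c("Problem", "Condition"))
  lev <- assign_levels(m)
  expect_equal(sort(as.integer(lev)), c(0L, 1L))
  # lexicographically first category gets the lower level
  expect_equal(lev[m$category == "Condition"], 0L)
})

test_that("BIO encoding produces per-level B/I runs and all-O for no mentions", {
  toks <- tokenize_text("inhaled corticosteroids therapy .")
  m <- mentions(c(0L, 8L), c(31L, 23L), c("Treatment", "Drug"))
  ls <- encode_bio(toks, m)
  expect_length(ls$labels, 2L)
  expect_equal(ls$labels[[1]], c("O", "B-Drug", "O", "O"))
  expect_equal(ls$labels[[2]],
               c("B-Treatment", "I-Treatment", "I-Treatment", "O"))

  none <- encode_bio(toks, mentions())
  expect_length(none$labels, 1L)
  expect_equal(none$labels[[1]], rep("O", 4L))

  one <- encode_bio(tokenize_text("dyspnea"), mentions(0L, 7L, "SignOrSymptom"))
  expect_equal(one$labels[[1]], "B-SignOrSymptom")
})

test_that("mention boundaries inside a token snap outward (or drop)", {
  toks <- tokenize_text("bronchodilation works")
  m <- mentions(0L, 8L, "ConstituentConcept")  # cuts "bronchodilation"
  expect_message(ls <- encode_bio(toks, m), "snapping")
  expect_equal(ls$labels[[1]][1], "B-ConstituentConcept")
  dropped <- encode_bio(toks, m, boundary = "drop")
  expect_equal(dropped$labels[[1]], c("O", "O"))
})

test_that("BIO decoding repairs dangling I tags and round-trips encodings", {
  toks <- tokenize_text("inhaled corticosteroids .")
  dec <- decode_bio(c("B-Drug", "I-Drug", "O"), toks)
  expect_equal(nrow(dec), 1L)
  expect_equal(dec$start, 0L)
  expect_equal(dec$end, 23L)
  expect_equal(dec$category, "Drug")

  expect_equal(nrow(decode_bio(c("O", "O", "O"), toks)), 0L)

  rep_ <- decode_bio(c("O", "I-Drug", "O"), toks)
  expect_equal(rep_$start, 8L)
  expect_equal(rep_$end, 23L)

  # category switch without B starts a new mention
  two <- decode_bio(c("B-Drug", "I-Treatment", "O"), toks)
  expect_equal(nrow(two), 2L)
})

test_that("encode/decode round-trips each level of generated documents", {
  corpus <- generate_corpus(synth_config(seed = 12L, n_documents = 20L))
  for (doc in corpus$docs) {
    toks <- tokenize_text(doc$text)
    lev <- assign_levels(doc$mentions)
    ls <- encode_bio(toks, doc$mentions, lev)
    for (l in seq_along(ls$labels)) {
      dec <- decode_bio(ls$labels[[l]], toks)
      want <- doc$mentions[lev == l - 1L, c("start", "end", "category")]
      want <- want[order(want$start, want$end, want$category), ]
      rownames(want) <- NULL
      got <- dec[order(dec$start, dec$end, dec$category),
                 c("start", "end", "category")]
      rownames(got) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("BIOES encoding marks single and end tokens and decodes back", {
  toks <- tokenize_text("dyspnea and chronic cough")
  m <- mentions(c(0L, 12L), c(7L, 25L), c("SignOrSymptom", "SignOrSymptom"))
  ls <- encode_bio(toks, m, scheme_variant = "bioes")
  expect_equal(ls$labels[[1]],
               c("S-SignOrSymptom", "O", "B-SignOrSymptom", "E-SignOrSymptom"))
  dec <- decode_bio(ls$labels[[1]], toks)
  expect_equal(nrow(dec), 2L)
})

test_that("innermost/outermost/all sets match the brute-force oracle", {
  # nested pair: inner in innermost, outer in outermost
  m <- mentions(c(0L, 3L), c(10L, 7L), c("Condition", "AnatomicalConcept"))
  expect_equal(innermost_set(m)$category, "AnatomicalConcept")
  expect_equal(outermost_set(m)$category, "Condition")
  # singleton is in both
  s <- mentions(0L, 7L, "SignOrSymptom")
  expect_equal(nrow(innermost_set(s)), 1L)
  expect_equal(nrow(outermost_set(s)), 1L)

  set.seed(42)
  for (rep in 1:40) {
    df <- random_nested_mentions()
    if (!nrow(df)) next
    key <- function(d) sort(paste(d$start, d$end, d$category))
    expect_equal(key(innermost_set(df)), key(oracle_innermost(df)))
    expect_equal(key(outermost_set(df)), key(oracle_outermost(df)))
    expect_equal(key(all_set(df)), key(df))
    # union of regimes within all; equality for nesting-free sets
    expect_true(all(key(innermost_set(df)) %in% key(df)))
    if (nrow(oracle_innermost(df)) == nrow(df)) {
      expect_equal(key(outermost_set(df)), key(df))
    }
  }
})

test_that("column export writes one BIO column per level", {
  toks <- tokenize_text("reduced FEV1")
  m <- mentions(c(0L, 8L), c(12L, 12L), c("TestOrMeasureResult", "TestOrMeasure"))
  ls <- encode_bio(toks, m)
  out <- format_column_export(list(ls))
  lines <- strsplit(out, "\n")[[1]]
  expect_equal(lines[1], "reduced\tO\tB-TestOrMeasureResult")
  expect_equal(lines[2], "FEV1\tB-TestOrMeasure\tI-TestOrMeasureResult")
})
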