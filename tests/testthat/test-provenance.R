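test_that("tokenizer splits scripts and drops punctuation", {
  tok <- default_tokenizer()
  expect_identical(tok("renal abscess"), c("renal", "abscess"))
  expect_identical(tok("4月10日に入院"), c("4", "月", "10", "日", "に", "入院"))
  expect_identical(tok(""), character(0))
  expect_identical(tok("--- !"), character(0))
})

test_that("bigram sets match hand enumeration and union over records", {
  case <- case_from_tokens(list(list(c("a", "b", "c"))), list(c("a", "b")))
  bg <- build_bigram_set(case)
  expect_setequal(bg$bigrams, c("a\rb", "b\rc"))

  case2 <- case_from_tokens(list(list(c("a", "b")), list(c("b", "a"))),
                            list(c("a", "b")))
  bg2 <- build_bigram_set(case2)
  expect_setequal(bg2$bigrams, c("a\rb", "b\ra"))  # direction-sensitive union
  expect_identical(bg2$source_doc_count, 2L)

  # pairs never span sentence boundaries
  case3 <- case_from_tokens(list(list(c("a", "b"), c("c", "d"))),
                            list(c("b", "c")))
  expect_false("b\rc" %in% build_bigram_set(case3)$bigrams)
})

test_that("coverage matches the brute-force oracle on random instances", {
  set.seed(202)
  tok <- default_tokenizer()
  vocab <- paste0("t", letters[1:12])
  for (rep in 1:60) {
    sents <- replicate(sample(1:4, 1),
                       sample(vocab, sample(2:8, 1), replace = TRUE),
                       simplify = FALSE)
    seg <- sample(vocab, sample(1:8, 1), replace = TRUE)
    case <- case_from_tokens(list(sents), list(seg))
    bg <- build_bigram_set(case)
    got <- coverage_ratio(paste(seg, collapse = " "), bg, tok)
    expect_equal(got, oracle_coverage(seg, sents))
  }
})

test_that("self-coverage is 1 and partial coverage counts occurrences", {
  case <- case_from_tokens(list(list(c("a", "b", "c"))),
                           list(c("a", "b", "c"), c("a", "b", "x")))
  bg <- build_bigram_set(case)
  expect_identical(coverage_ratio("a b c", bg), 1)
  expect_identical(coverage_ratio("a b x", bg), 0.5)
  # duplicated bi-gram occurrences each count
  expect_identical(coverage_ratio("a b a b x", bg), 0.5)  # ab,ba,ab,bx -> 2/4
  expect_identical(coverage_ratio("a b a b x", bg, count_mode = "types"), 1 / 3)
  expect_identical(coverage_ratio("solo", bg), NA_real_)
})

test_that("adding bigrams never decreases coverage (monotonicity)", {
  set.seed(303)
  vocab <- paste0("m", letters[1:10])
  for (rep in 1:20) {
    seg <- sample(vocab, 6, replace = TRUE)
    s1 <- replicate(2, sample(vocab, 5, replace = TRUE), simplify = FALSE)
    s2 <- c(s1, replicate(2, sample(vocab, 5, replace = TRUE), simplify = FALSE))
    c1 <- coverage_ratio(paste(seg, collapse = " "),
                         build_bigram_set(case_from_tokens(list(s1), list(seg))))
    c2 <- coverage_ratio(paste(seg, collapse = " "),
                         build_bigram_set(case_from_tokens(list(s2), list(seg))))
    expect_gte(c2, c1)
  }
})

test_that("origin classification follows threshold, exclusions, and bins", {
  cfg <- provenance_config()
  seg <- new_segment("s", "c", "discharge_summary", 1L, c(0L, 5L), "a b c",
                     gold_labels = label_set("description"))
  expect_identical(classify_origin(0.5, seg, cfg)$origin, "sourced")
  expect_identical(classify_origin(0.49, seg, cfg)$origin, "unsourced")
  expect_identical(classify_origin(0.09, seg, cfg)$bin_index, 0L)
  expect_identical(classify_origin(0.49, seg, cfg)$bin_index, 4L)
  expect_identical(classify_origin(0.1, seg, cfg)$bin_index, 1L)

  sym <- seg; sym$is_symbolic <- TRUE
  expect_identical(classify_origin(0.9, sym, cfg)$origin, "excluded")

  mid <- new_segment("s", "c", "discharge_summary", 1L, c(0L, 5L), "a b c",
                     gold_labels = label_set("result"))
  expect_identical(classify_origin(0.9, mid, cfg)$origin, "excluded")
  # probable promotes a middle-role segment out of the exclusion
  midp <- new_segment("s", "c", "discharge_summary", 1L, c(0L, 5L), "a b c",
                      gold_labels = label_set("result", probable = TRUE))
  expect_identical(classify_origin(0.9, midp, cfg)$origin, "sourced")

  # predicted subjectivity overrides gold
  expect_identical(classify_origin(0.9, seg, cfg, subjectivity = "middle")$origin,
                   "excluded")

  # short segments: policy
  expect_identical(classify_origin(NA_real_, seg, cfg)$origin, "excluded")
  cfg2 <- provenance_config(short_segment_policy = "unsourced")
  r <- classify_origin(NA_real_, seg, cfg2)
  expect_identical(r$origin, "unsourced")
  expect_identical(r$bin_index, 0L)
})

test_that("classification is a partition of summary segments", {
  corpus <- generate_corpus(synth_config(n_cases = 20, seed = 9))
  res <- classify_corpus(corpus)
  n_summary <- sum(vapply(corpus, function(c) {
    sum(vapply(c$segments, function(s) s$doc_kind == "discharge_summary",
               logical(1)))
  }, integer(1)))
  expect_identical(nrow(res), n_summary)
  expect_true(all(res$origin %in% c("sourced", "unsourced", "excluded")))
  expect_true(all(is.na(res$bin_index) | res$origin == "unsourced"))
  expect_true(all(res$coverage >= 0 & res$coverage <= 1, na.rm = TRUE))
})

test_that("bin proportions demand gold labels and handle empty bins", {
  res <- data.frame(segment_id = c("a", "b"), case_id = "c",
                    coverage = c(0.05, 0.45), origin = "unsourced",
                    bin_index = c(0L, 4L), stringsAsFactors = FALSE)
  expect_error(bin_unsourced_proportions(res, c(a = "unsourced")), "missing gold")
  bp <- bin_unsourced_proportions(res, c(a = "unsourced", b = "sourced"))
  expect_identical(bp$n, c(1L, 0L, 0L, 0L, 1L))
  expect_identical(bp$proportion_unsourced[1], 1)
  expect_identical(bp$proportion_unsourced[5], 0)
  expect_true(all(is.na(bp$proportion_unsourced[2:4])))
  empty <- bin_unsourced_proportions(res[0, ], character(0))
  expect_identical(nrow(empty), 5L)
  expect_identical(empty$n, rep(0L, 5))
})

test_that("document rate counts summaries with any unsourced segment", {
  corpus <- generate_corpus(synth_config(n_cases = 4, unsourced_prob = 0,
                                         tier_unsourced_probs = NULL,
                                         section_rates = NULL,
                                         hospital_profiles = NULL, seed = 1))
  res <- resolve_origins(classify_corpus(corpus), corpus)
  expect_identical(document_unsourced_rate(corpus, res), 0)
  # flip one segment of one case to unsourced
  res$origin_final[match(res$case_id[1], res$case_id)] <- "unsourced"
  expect_identical(document_unsourced_rate(corpus, res), 0.25)
})

test_that("gold origins rescue paraphrased below-threshold segments", {
  g <- generate_gradient_corpus(synth_config(n_cases = 10,
                                             tokens_per_sentence = 12,
                                             seed = 4))
  res <- classify_corpus(g)
  expect_true(all(res$origin == "unsourced"))  # all planted below threshold
  fin <- resolve_origins(res, g)
  gold <- dsaudit:::gold_origin_map(g)
  expect_identical(fin$origin_final, unname(gold[fin$segment_id]))
  expect_true(any(fin$origin_final == "sourced"))
})
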