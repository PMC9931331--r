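test_that("perfect predictions give F1 = 1 and P = R implies F1 = P", {
  df <- labeled_frame(100, seed = 1)
  ev <- evaluate(df, df)
  expect_equal(ev$sub$macro_f1, 1)
  expect_equal(ev$role$macro_f1, 1)
  expect_equal(ev$prob$macro_f1, 1)
  # harmonic-mean identity
  pc <- ev$role$per_class
  eq <- abs(pc$precision - pc$recall) < 1e-12 & pc$precision > 0
  expect_true(all(abs(pc$f1[eq] - pc$precision[eq]) < 1e-12))
})

test_that("evaluate matches a confusion-matrix oracle on random labels", {
  set.seed(33)
  n <- 200
  gold <- data.frame(subjectivity = sample(subjectivity_tiers(), n, TRUE),
                     role = sample(clinical_roles(), n, TRUE),
                     probable = sample(c(TRUE, FALSE), n, TRUE))
  pred <- data.frame(subjectivity = sample(subjectivity_tiers(), n, TRUE),
                     role = sample(clinical_roles(), n, TRUE),
                     probable = sample(c(TRUE, FALSE), n, TRUE))
  ev <- evaluate(pred, gold)
  for (cls in clinical_roles()) {
    tp <- sum(pred$role == cls & gold$role == cls)
    fp <- sum(pred$role == cls & gold$role != cls)
    fn <- sum(pred$role != cls & gold$role == cls)
    row <- ev$role$per_class[ev$role$per_class$class == cls, ]
    expect_identical(row$tp, tp)
    p <- if (tp + fp) tp / (tp + fp) else 0
    r <- if (tp + fn) tp / (tp + fn) else 0
    expect_equal(row$precision, p)
    expect_equal(row$recall, r)
    expect_equal(row$f1, if (p + r) 2 * p * r / (p + r) else 0)
  }
  expect_error(evaluate(pred[1:10, ], gold), "same length")
})

test_that("stratified rates equal hand-computed values on the fixture", {
  fr <- fixture_frame()
  t5 <- unsourced_by_label(fr)
  get <- function(kind, stratum) t5$rate[t5$kind == kind & t5$stratum == stratum]
  expect_equal(get("role", "description"), 1 / 4)
  expect_equal(get("role", "action"), 2 / 4)
  expect_equal(get("role", "diag"), 2 / 4)
  expect_equal(get("role", "plan"), 3 / 4)
  expect_equal(get("probable", "probable"), 1)        # g1 only
  expect_equal(get("tier", "low"), 3 / 8)
  expect_equal(get("tier", "high"), 5 / 8)
  expect_equal(get("all", "all"), 8 / 16)
  # "all" is the weighted average of the low and high tiers
  expect_equal(get("all", "all"),
               (8 * get("tier", "low") + 8 * get("tier", "high")) / 16)

  t6 <- unsourced_by_section(fr)
  expect_equal(t6$rate[t6$stratum == "pre_hospital"], 3 / 8)
  expect_equal(t6$rate[t6$stratum == "in_hospital"], 5 / 8)
  # high-subjectivity rate keeps middle in the denominator, drops symbols
  expect_equal(t6$high_subj_rate[t6$stratum == "in_hospital"], 8 / 10)

  t8 <- unsourced_by_hospital(fr)
  expect_equal(t8$rate[t8$stratum == "H1"], 3 / 8)
  expect_equal(t8$rate[t8$stratum == "H2"], 5 / 8)
})

test_that("middle and symbolic segments never change the rates", {
  fr <- fixture_frame()
  base5 <- unsourced_by_label(fr)
  base6 <- unsourced_by_section(fr)
  mid_or_sym <- fr$tier == "middle" | fr$is_symbolic
  for (forced in c("sourced", "unsourced")) {
    flipped <- fr
    flipped$origin[mid_or_sym] <- forced
    flipped$sources[mid_or_sym] <- list("no_document")
    expect_identical(unsourced_by_label(flipped), base5)
    expect_identical(unsourced_by_section(flipped)$rate, base6$rate)
  }
})

test_that("attribution percentages count assigned labels, not segments", {
  fr <- fixture_frame()
  t7 <- attribution_breakdown(fr)
  # 8 unsourced segments; d1,d2 carry two labels each -> 10 assigned labels
  expect_equal(sum(t7$pct_all), 100)
  expect_equal(t7$pct_all[t7$label == "patient_referral"], 2 / 10 * 100)
  expect_equal(t7$pct_all[t7$label == "prescriptions"], 2 / 10 * 100)
  expect_equal(t7$pct_all[t7$label == "past_clinical_records"], 1 / 10 * 100)
  expect_equal(t7$pct_all[t7$label == "no_document"], 2 / 10 * 100)
  expect_equal(t7$pct_all[t7$label == "outpatient_records"], 3 / 10 * 100)
  expect_equal(sum(t7$pct_low, na.rm = TRUE), 100)
  expect_equal(sum(t7$pct_high, na.rm = TRUE), 100)

  # an unsourced segment without sources is an error
  bad <- fr
  bad$sources[bad$segment_id == "a1"] <- list(NULL)
  expect_error(attribution_breakdown(bad), "without source")
})

test_that("overall breakdown conserves mass", {
  fr <- fixture_frame()
  t7 <- attribution_breakdown(fr)
  fig6 <- overall_breakdown(0.613, t7)
  expect_equal(sum(fig6$share), 1, tolerance = 1e-9)
  expect_identical(fig6$source[1], "inpatient_records")
  expect_equal(fig6$share[1], 0.613)
  single <- overall_breakdown(1, t7)
  expect_identical(nrow(single), 1L)
  set.seed(9)
  for (rep in 1:10) {
    sr <- runif(1)
    expect_equal(sum(overall_breakdown(sr, t7)$share), 1, tolerance = 1e-9)
  }
})

test_that("the headline shares reproduce from their components", {
  # sourced rate 0.613 with attribution share 43.3% puts the past-records
  # share near 0.17 of all information
  t7 <- attribution_breakdown(fixture_frame())
  t7$pct_all <- ifelse(t7$label == "past_clinical_records", 43.3,
                       (100 - 43.3) / 13)
  fig6 <- overall_breakdown(0.613, t7)
  expect_equal(fig6$share[fig6$source == "past_clinical_records"],
               (1 - 0.613) * 0.433, tolerance = 1e-12)
  expect_equal(round(fig6$share[fig6$source == "past_clinical_records"], 2), 0.17)
})

test_that("empty hospitals are omitted with a warning", {
  fr <- fixture_frame()
  fr$origin[fr$hospital_id == "H2"] <- "excluded"
  expect_warning(t8 <- unsourced_by_hospital(fr), "H2")
  expect_identical(t8$stratum, "H1")
})

test_that("audit_frame prefers predictions when supplied", {
  corpus <- generate_corpus(synth_config(n_cases = 3, seed = 13))
  res <- resolve_origins(classify_corpus(corpus), corpus)
  fr_gold <- audit_frame(corpus, res)
  lab <- fr_gold[, c("segment_id", "subjectivity", "role", "probable")]
  lab$role <- "nonfact"
  fr_pred <- audit_frame(corpus, res, labels = lab)
  expect_true(all(fr_pred$role == "nonfact"))
  expect_false(all(fr_gold$role == "nonfact"))
})
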