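rand_batch <- function(n) {
  list(scores = list(sub = matrix(rnorm(n * 3), n, 3),
                     role = matrix(rnorm(n * 9), n, 9),
                     prob = matrix(rnorm(n * 2), n, 2)),
       gold = list(sub = sample(3, n, TRUE), role = sample(9, n, TRUE),
                   prob = sample(2, n, TRUE)))
}

test_that("weighted-sum loss equals the manual weighted sum", {
  set.seed(11)
  for (rep in 1:100) {
    b <- rand_batch(sample(2:20, 1))
    w0 <- runif(3)
    w <- task_weights(w0[1] / sum(w0), w0[2] / sum(w0),
                      1 - w0[1] / sum(w0) - w0[2] / sum(w0))
    lb <- compute_loss(b$scores, b$gold, w)
    manual <- w[["sub"]] * lb$L_sub + w[["role"]] * lb$L_role +
      w[["prob"]] * lb$L_prob
    expect_lt(abs(lb$L_all - manual), 1e-9)
  }
})

test_that("degenerate weights reduce to the single-task loss", {
  set.seed(12)
  b <- rand_batch(16)
  expect_equal(compute_loss(b$scores, b$gold, task_weights(1, 0, 0))$L_all,
               compute_loss(b$scores, b$gold, task_weights(1, 0, 0))$L_sub)
  # uniform scores give the analytic ln K cross-entropy
  b$scores$sub <- matrix(0, 16, 3)
  expect_equal(compute_loss(b$scores, b$gold, task_weights(1, 0, 0))$L_sub,
               log(3), tolerance = 1e-12)
})

test_that("shape violations are rejected", {
  b <- rand_batch(8)
  bad <- b$scores
  bad$role <- bad$role[, 1:8]
  expect_error(compute_loss(bad, b$gold, task_weights(1/3, 1/3, 1/3)), "9 columns")
  short <- b$gold
  short$sub <- short$sub[1:4]
  expect_error(compute_loss(b$scores, short, task_weights(1/3, 1/3, 1/3)),
               "gold labels")
})

test_that("task weights validate the simplex constraint", {
  expect_error(task_weights(0.5, 0.5, 0.5), "sum to 1")
  expect_error(task_weights(-0.5, 1, 0.5), "nonnegative")
  w <- task_weights(2, 1, 1, normalize = TRUE)
  expect_equal(unname(sum(w)), 1)
})

test_that("the quarter-step grid enumerates exactly the 16 settings", {
  g <- quarter_step_grid()
  expect_identical(nrow(g), 16L)
  expect_true(all(abs(rowSums(as.matrix(g)) - 1) < 1e-9))
  # stars-and-bars oracle for quarter steps: a + b + c = 4 over 0..4
  oracle <- expand.grid(a = 0:4, b = 0:4)
  oracle <- oracle[oracle$a + oracle$b <= 4, ]
  expect_identical(nrow(g) - 1L, nrow(oracle))  # + uniform
  has <- function(a, b, c) {
    any(abs(g$lambda_sub - a) < 1e-9 & abs(g$lambda_role - b) < 1e-9 &
          abs(g$lambda_prob - c) < 1e-9)
  }
  expect_true(has(0.5, 0.25, 0.25))
  expect_true(has(1 / 3, 1 / 3, 1 / 3))
  expect_true(has(1, 0, 0) && has(0, 1, 0) && has(0, 0, 1))
  expect_false(any(duplicated(round(as.matrix(g), 9))))
})

small_cfg <- function(...) {
  args <- utils::modifyList(list(epochs = 2L, n_heldout = 30L, n_seeds = 1L,
                                 seed = 5L), list(...))
  do.call(train_config, args)
}
small_enc <- function() default_encoder(dim = 48L)

test_that("zero epochs return the initialization; training descends", {
  df <- labeled_frame(200, seed = 3)
  m0 <- train(df, small_enc(), cfg = small_cfg(epochs = 0L))
  expect_identical(nrow(m0$trace), 0L)
  expect_equal(m0$params$tail$Wt, diag(48))
  expect_true(all(m0$params$sub$W3 == 0))

  m <- train(df, small_enc(), cfg = small_cfg(epochs = 6L))
  expect_lt(m$trace$L_all[6], m$trace$L_all[1])
  # Eq. 1 algebra holds for every logged epoch
  w <- m$w
  expect_true(all(abs(m$trace$L_all -
                        (w[["sub"]] * m$trace$L_sub +
                           w[["role"]] * m$trace$L_role +
                           w[["prob"]] * m$trace$L_prob)) < 1e-9))
})

test_that("training is deterministic and predictions are pure", {
  df <- labeled_frame(150, seed = 4)
  m1 <- train(df, small_enc(), cfg = small_cfg())
  m2 <- train(df, small_enc(), cfg = small_cfg())
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$params, m2$params)
  p1 <- predict(m1, df$text[1:10])
  p2 <- predict(m1, df$text[1:10])
  expect_identical(p1, p2)
  expect_identical(predict(m1, rep(df$text[1], 2))$role[1],
                   predict(m1, rep(df$text[1], 2))$role[2])
})

test_that("lambda = (1,0,0) leaves the other heads untrained", {
  df <- labeled_frame(150, seed = 6)
  m <- train(df, small_enc(), task_weights(1, 0, 0), small_cfg())
  m0 <- train(df, small_enc(), task_weights(1, 0, 0), small_cfg(epochs = 0L))
  expect_identical(m$params$role, m0$params$role)
  expect_identical(m$params$prob, m0$params$prob)
  expect_false(identical(m$params$sub, m0$params$sub))
  expect_equal(m$trace$L_all, m$trace$L_sub, tolerance = 1e-12)
})

test_that("missing labels and oversized holdouts are rejected", {
  df <- labeled_frame(100, seed = 7)
  df$role[3] <- NA
  expect_error(train(df, small_enc(), cfg = small_cfg()), "gold label")
  df2 <- labeled_frame(50, seed = 7)
  expect_error(train(df2, small_enc(), cfg = small_cfg()), "n_heldout")
})

test_that("grid_search reports per-task dev F1 for each setting", {
  df <- labeled_frame(150, seed = 8)
  grid <- quarter_step_grid()[c(1, 7, 16), ]
  gs <- grid_search(df, small_enc(), small_cfg(epochs = 1L), grid = grid)
  expect_identical(nrow(gs), 3L)
  expect_true(all(!is.na(gs$F1_sub)))
  expect_true(all(gs$F1_sub >= 0 & gs$F1_sub <= 1))
})

test_that("predict applies to corpora and preserves segment ids", {
  corpus <- generate_corpus(synth_config(n_cases = 4, seed = 21))
  df <- segments_frame(corpus)
  m <- train(df, small_enc(), cfg = small_cfg(epochs = 1L, n_heldout = 5L))
  p <- predict(m, corpus)
  expect_identical(p$segment_id, df$segment_id)
  expect_true(all(p$role %in% clinical_roles()))
  expect_true(all(p$subjectivity %in% subjectivity_tiers()))
  expect_type(p$probable, "logical")
})
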