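two_class_data <- function(n_per = 60, p = 5, sep = 1.5, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, sep / sqrt(p)), n_per))
  y <- factor(rep(c("responder", "non-responder"), each = n_per),
              levels = c("responder", "non-responder"))
  list(x = x, y = y)
}

test_that("well-separated classes are perfectly ranked in training", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40 * 3, 0, 0.5), 40), matrix(rnorm(40 * 3, 5, 0.5), 40))
  y <- factor(rep(c("responder", "non-responder"), each = 40),
              levels = c("responder", "non-responder"))
  m <- train_lda(x, y, positive = "non-responder")
  expect_equal(m$train_auc, 1)
  expect_error(train_lda(x[1:40, ], y[1:40]), "single-class")
})

test_that("permuted labels give chance-level AUC at large n", {
  d <- two_class_data(n_per = 250, sep = 2, seed = 3)
  set.seed(4)
  yp <- sample(d$y)
  m <- train_lda(d$x, yp, positive = "non-responder")
  expect_lt(abs(m$train_auc - 0.5), 0.08)
})

test_that("duplicated feature columns are handled by shrinkage, not a crash", {
  d <- two_class_data(seed = 5)
  x2 <- cbind(d$x, d$x[, 1])
  m <- train_lda(x2, d$y)
  expect_gt(m$shrinkage, 0)
  expect_true(all(is.finite(m$w)))
  ## scores still discriminate
  expect_gt(m$train_auc, 0.7)
})

test_that("LDA direction matches MASS::lda on well-conditioned data", {
  d <- two_class_data(seed = 6)
  m <- train_lda(d$x, d$y, positive = "non-responder")
  ref <- MASS::lda(d$x, grouping = d$y)
  sc_ref <- as.numeric(predict(ref, d$x)$x)
  expect_equal(abs(cor(sc_ref, predict(m, d$x))), 1, tolerance = 1e-10)
})

test_that("AUC is invariant to strictly monotone transforms of the scores", {
  d <- two_class_data(seed = 7)
  m <- train_lda(d$x, d$y, positive = "non-responder")
  s <- predict(m, d$x)
  a1 <- auc_mw(s, d$y, positive = "non-responder")
  a2 <- auc_mw(exp(s / 3), d$y, positive = "non-responder")
  a3 <- auc_mw(rank(s), d$y, positive = "non-responder")
  expect_equal(a1, a2)
  expect_equal(a1, a3)
  ## cross-check against pROC
  ref <- as.numeric(pROC::auc(pROC::roc(response = d$y == "non-responder",
                                        predictor = s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a1, ref, tolerance = 1e-12)
})

test_that("repeated stratified CV emits one record per iteration and balances folds", {
  d <- two_class_data(n_per = 30, seed = 8)
  cv <- cv_auc(d$x, d$y, folds = 3, iterations = 20, seed = 9,
               positive = "non-responder")
  expect_length(cv$trace, 20L)
  expect_true(all(is.finite(cv$trace)))
  expect_true(cv$ci[1] <= cv$mean_auc && cv$mean_auc <= cv$ci[2])
  ## stratification: per-fold class ratios within one subject of the cohort's
  set.seed(9)
  fold <- integer(length(d$y))
  for (cl in levels(d$y)) {
    i <- which(d$y == cl)
    fold[i] <- sample(rep(1:3, length.out = length(i)))
  }
  counts <- table(fold, d$y)
  expect_true(all(abs(counts[, 1] - counts[, 2]) <= 1 + max(counts[, 1]) / 3))
  expect_error(cv_auc(d$x[c(1, 2, 31, 60), ], d$y[c(1, 2, 31, 60)], folds = 3),
               "too small")
  ## determinism under seed
  cv2 <- cv_auc(d$x, d$y, folds = 3, iterations = 20, seed = 9,
                positive = "non-responder")
  expect_identical(cv$trace, cv2$trace)
})

test_that("holdout evaluation freezes the training threshold", {
  d <- two_class_data(seed = 10)
  m <- train_lda(d$x, d$y, positive = "non-responder")
  thr <- m$threshold
  dh <- two_class_data(seed = 11)
  rep_ <- evaluate_holdout(m, dh$x, dh$y)
  expect_equal(rep_$threshold, thr)       # never recomputed on holdout
  expect_true(rep_$auc > 0.5 && rep_$auc <= 1)
  expect_true(all(c(rep_$accuracy, rep_$sensitivity, rep_$specificity) >= 0 &
                    c(rep_$accuracy, rep_$sensitivity, rep_$specificity) <= 1))
  expect_true(rep_$auc_ci[1] <= rep_$auc && rep_$auc <= rep_$auc_ci[2])

  ## perfect scores
  mperf <- m; mperf$w <- m$w
  xs <- rbind(matrix(-10, 5, ncol(d$x)) * 0 - 100, matrix(100, 5, ncol(d$x)))
  yy <- factor(rep(c("responder", "non-responder"), each = 5),
               levels = c("responder", "non-responder"))
  ## construct scores directly via a one-feature model
  m1 <- train_lda(matrix(c(rnorm(5, -3, 0.1), rnorm(5, 3, 0.1)), 10, 1),
                  yy, positive = "non-responder")
  rp <- evaluate_holdout(m1, matrix(c(-5, -4, -3, -6, -2, 5, 4, 3, 6, 2), 10, 1), yy)
  expect_equal(rp$auc, 1)
  expect_equal(rp$sensitivity, 1)
  expect_equal(rp$specificity, 1)

  ## constant scores: AUC 0.5 by the tie convention, degenerate threshold flagged
  mC <- train_lda(matrix(rnorm(20), 20, 1), rep(yy, 2))
  mC$w[] <- 0
  mC$threshold <- NA_real_
  rc <- evaluate_holdout(mC, matrix(rnorm(10), 10, 1), yy)
  expect_equal(rc$auc, 0.5)
  expect_true(rc$degenerate)

  ## single-class holdout: AUC reported missing
  rs <- evaluate_holdout(m1, matrix(rnorm(4), 4, 1),
                         factor(rep("responder", 4),
                                levels = c("responder", "non-responder")))
  expect_true(is.na(rs$auc))
})
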