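test_that("stratified folds balance every class to within one subject", {
  labels <- c(rep("ASD", 10), rep("HC", 20))
  f <- stratified_kfold(labels, 5, seed = 1)
  expect_equal(unname(table(f[labels == "ASD"])), rep(2L, 5),
               ignore_attr = TRUE)
  expect_equal(unname(table(f[labels == "HC"])), rep(4L, 5),
               ignore_attr = TRUE)

  lab7 <- c(rep("ASD", 7), rep("HC", 13))
  f7 <- stratified_kfold(lab7, 5, seed = 2)
  pos_counts <- table(factor(f7[lab7 == "ASD"], levels = 1:5))
  expect_true(all(pos_counts %in% 1:2))
  expect_equal(sum(pos_counts), 7)

  expect_identical(stratified_kfold(labels, 5, seed = 3),
                   stratified_kfold(labels, 5, seed = 3))
  expect_false(identical(stratified_kfold(labels, 5, seed = 3),
                         stratified_kfold(labels, 5, seed = 4)))
  expect_error(stratified_kfold(c("ASD", rep("HC", 10)), 5), "smaller than k")
})

test_that("metrics match direct counting and brute-force AUC", {
  # TP=3 FN=1 TN=4 FP=2
  truth <- c(rep("ASD", 4), rep("HC", 6))
  pred <- c("ASD", "ASD", "ASD", "HC", "HC", "HC", "HC", "HC", "ASD", "ASD")
  scores <- c(.9, .8, .7, .3, .2, .1, .15, .25, .6, .55)
  m <- classification_metrics(truth, pred, scores, positive = "ASD")
  expect_equal(m$sensitivity, 75)
  expect_equal(m$specificity, 100 * 4 / 6)
  expect_equal(m$accuracy, 70)
  expect_equal(m$auc, brute_auc(scores, truth == "ASD"))

  # perfect prediction
  mp <- classification_metrics(truth, truth, c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                               positive = "ASD")
  expect_equal(c(mp$accuracy, mp$sensitivity, mp$specificity, mp$auc),
               c(100, 100, 100, 1))

  # AUC example: positives {0.9, 0.4}, negatives {0.5, 0.1} -> 0.75
  m2 <- classification_metrics(c("ASD", "ASD", "HC", "HC"),
                               rep("ASD", 4), c(0.9, 0.4, 0.5, 0.1),
                               positive = "ASD")
  expect_equal(m2$auc, 0.75)

  expect_warning(classification_metrics(rep("ASD", 3), rep("ASD", 3),
                                        1:3, positive = "ASD"), "one class")
})

test_that("midrank AUC equals exhaustive pair counting, ties included", {
  for (s in 1:8) {
    set.seed(s)
    n <- sample(10:100, 1)
    is_pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(is_pos) || all(is_pos)) next
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    expect_equal(dtlconn:::auc_midrank(scores, is_pos),
                 brute_auc(scores, is_pos))
  }
})

test_that("cross-validation tests each subject once, metrics on concatenation", {
  ds <- make_covariate_dataset(m = 20)
  const_trainer <- function(tr) structure(list(), class = "const_model")
  # constant positive predictor via a local predict method
  assign("predict.const_model",
         function(object, X, ...)
           data.frame(label = rep("ASD", nrow(X)), prob = 0.5),
         envir = globalenv())
  on.exit(rm("predict.const_model", envir = globalenv()))
  cv <- suppressWarnings(cross_validate(const_trainer, ds, k = 5, seed = 1,
                                        positive = "ASD"))
  expect_setequal(cv$subject_id, ds$subject_ids)
  expect_equal(sort(cv$truth), sort(ds$labels))     # permutation of labels
  expect_equal(cv$metrics$accuracy, 50)             # prevalence of ASD

  # leave-one-out on 8 subjects
  ds8 <- make_covariate_dataset(m = 8)
  cv8 <- suppressWarnings(cross_validate(const_trainer, ds8, k = 4, seed = 2,
                                         positive = "ASD"))
  expect_length(cv8$truth, 8)

  cv2 <- suppressWarnings(cross_validate(const_trainer, ds, k = 5, seed = 1,
                                         positive = "ASD"))
  expect_equal(cv$truth, cv2$truth)
  expect_equal(cv$scores, cv2$scores)
})

test_that("paired t-test matches the closed form and is antisymmetric", {
  a <- c(2, 4, 6, 8); b <- c(1, 2, 3, 4)      # differences 1,2,3,4
  r <- paired_t_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(r$t, t_hand)
  expect_equal(r$p, 2 * pt(-abs(t_hand), df = 3))
  expect_equal(r$df, 3)

  r2 <- paired_t_test(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)), "zero variance")
})

test_that("saliency is the absolute chained weight product", {
  hp <- hyperparams(c(1))
  s1 <- dtlconn:::new_ssae(list(list(W = matrix(c(2, -1), 1, 2), b = 0)),
                           c(2L, 1L), hp, "offline", 1L)
  expect_equal(saliency_scores(s1), c(2, 1))

  s2 <- dtlconn:::new_ssae(
    list(list(W = matrix(c(1, 0, 0, 2), 2, 2), b = c(0, 0)),
         list(W = matrix(c(1, 1), 1, 2), b = 0)),
    c(2L, 2L, 1L), hyperparams(c(2, 1)), "offline", 1L)
  expect_equal(saliency_scores(s2), c(1, 2))
})

test_that("saliency of a linear network matches the finite-difference Jacobian", {
  set.seed(3)
  W1 <- matrix(rnorm(12), 3, 4); W2 <- matrix(rnorm(6), 2, 3)
  lin_net <- function(x) W2 %*% (W1 %*% x)       # purely linear reference
  J <- sapply(1:4, function(j) {
    e <- numeric(4); e[j] <- 1e-6
    (lin_net(e) - lin_net(-e)) / 2e-6
  })
  scores_fd <- colSums(abs(J))
  s <- dtlconn:::new_ssae(list(list(W = W1, b = numeric(3)),
                               list(W = W2, b = numeric(2))),
                          c(4L, 3L, 2L), hyperparams(c(3, 2)), "offline", 1L)
  expect_equal(saliency_scores(s), scores_fd, tolerance = 1e-8)
})

test_that("rankings accumulate raw scores across folds with stable ties", {
  f1 <- c(3, 1, 2, 0.5, 0.1, 0.2)    # 4-ROI problem, 6 edges
  one <- accumulate_rankings(list(f1), top_k = 3)
  expect_equal(one$edge_scores, f1)
  expect_equal(order(one$ranks)[1:3], c(1, 3, 2))

  two <- accumulate_rankings(list(f1, f1), top_k = 3)
  expect_equal(two$edge_scores, 2 * f1)
  expect_identical(two$ranks, one$ranks)

  tied <- accumulate_rankings(list(c(1, 1, 1, 0, 0, 0)))
  expect_equal(order(tied$ranks)[1:3], c(1, 2, 3))  # ties by ascending index
  expect_true(all(sort(tied$ranks) == 1:6))
  expect_error(accumulate_rankings(list(1:6, 1:5)), "length")
})

test_that("cross-validation export writes the documented TSV columns", {
  ds <- make_covariate_dataset(m = 20)
  trainer <- function(tr) {
    proto <- train_ssae(tr$features, tiny_hp(layer_sizes = c(4),
                                             max_epochs = 10), "offline")
    train_dtl_nn(proto, tr$features, tr$labels,
                 tiny_hp(layer_sizes = c(4), max_epochs = 10),
                 positive = "ASD")
  }
  cv <- cross_validate(trainer, ds, k = 4, seed = 5, positive = "ASD")
  dir <- withr::local_tempdir()
  write_cv_result(cv, file.path(dir, "cv.tsv"), file.path(dir, "m.tsv"))
  tab <- read.delim(file.path(dir, "cv.tsv"))
  expect_named(tab, c("subject_id", "fold", "truth", "pred", "score"))
  expect_equal(nrow(tab), 20)
  ms <- read.delim(file.path(dir, "m.tsv"))
  expect_named(ms, c("accuracy", "sensitivity", "specificity", "auc"))

  rk <- accumulate_rankings(lapply(cv$per_fold_models, saliency_scores))
  write_saliency(rk, file.path(dir, "sal.tsv"))
  sal <- read.delim(file.path(dir, "sal.tsv"))
  expect_equal(nrow(sal), ncol(ds$features))
  expect_equal(sal$rank, seq_len(nrow(sal)))
})
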