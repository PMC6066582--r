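#' Stratified k-fold assignments
#'
#' Assigns each subject to one of `k` folds so that within every class the
#' per-fold counts differ by at most one. The permutation is seeded and
#' reproducible.
#'
#' @param labels per-subject class labels.
#' @param k number of folds (>= 2); every class must have >= k members.
#' @param seed integer seed.
#' @return Integer vector of fold indices in 1..k, one per subject.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  stopifnot(k >= 2)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("class(es) smaller than k = ", k, ": ",
         paste(names(counts)[counts < k], collapse = ", "))
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))            # shuffle within class
    folds[idx] <- rep_len(sample.int(k), length(idx))
  }
  folds
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity (true-positive rate among disease subjects),
#' specificity (true-negative rate among healthy subjects) as percentages,
#' and AUC as the probability that a randomly chosen positive's score
#' exceeds a randomly chosen negative's (ties count 1/2; computed via
#' midranks).
#'
#' @param truth true labels. @param pred predicted labels.
#' @param scores positive-class scores (for AUC).
#' @param positive label of the positive class (default: lexicographically
#'   larger label of `truth`).
#' @return A list of class `"class_metrics"` with elements `accuracy`,
#'   `sensitivity`, `specificity` (percent), `auc` (in \[0, 1\]) and the
#'   confusion counts. With one-class truth, the undefined rate(s) are
#'   `NaN` with a warning.
#' @export
classification_metrics <- function(truth, pred, scores, positive = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) == length(scores))
  if (is.null(positive)) positive <- sort(unique(truth))[length(unique(truth))]
  is_pos <- truth == positive
  if (!any(is_pos) || all(is_pos))
    warning("only one class present in truth; sensitivity/specificity ",
            "and AUC are undefined (NaN)")
  tp <- sum(is_pos & pred == positive)
  fn <- sum(is_pos & pred != positive)
  tn <- sum(!is_pos & pred != positive)
  fp <- sum(!is_pos & pred == positive)
  auc <- if (any(is_pos) && any(!is_pos)) auc_midrank(scores, is_pos) else NaN
  structure(list(accuracy = 100 * (tp + tn) / length(truth),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 auc = auc, tp = tp, fn = fn, tn = tn, fp = fp),
            class = "class_metrics")
}

auc_midrank <- function(scores, is_pos) {
  r <- rank(scores)                       # midranks handle ties as 1/2
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%  AUC %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Stratified cross-validated evaluation
#'
#' Splits the cohort into `k` stratified folds; for each fold, calls
#' `trainer` on the remaining k-1 folds and predicts the held-out fold.
#' Metrics are computed on the *concatenation* of all held-out
#' predictions, not averaged per fold. Per-fold models are retained so
#' saliency can be accumulated across folds.
#'
#' @param trainer `function(train_ds)` returning a model that
#'   [predict()] accepts (e.g. a closure around [train_dtl_nn()] or
#'   [train_dnn_baseline()], or an external comparator).
#' @param ds a [connectome_dataset()].
#' @param k number of folds (default 5). @param seed fold-permutation seed.
#' @param positive positive-class label (default: lexicographically larger).
#' @return An object of class `"cv_result"`: `fold_assignments`,
#'   concatenated `truth`/`pred`/`scores` (+ `subject_id`, `fold`),
#'   `metrics`, and `per_fold_models`.
#' @export
cross_validate <- function(trainer, ds, k = 5L, seed = 1L, positive = NULL) {
  folds <- stratified_kfold(ds$labels, k, seed)
  truth <- pred <- character(0)
  scores <- numeric(0)
  sid <- character(0)
  foldcol <- integer(0)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- tryCatch(trainer(subset_dataset(ds, !test)),
                      error = function(e)
                        stop("training failed in fold ", f, ": ",
                             conditionMessage(e)))
    pr <- predict(model, ds$features[test, , drop = FALSE])
    truth <- c(truth, ds$labels[test])
    pred <- c(pred, as.character(pr$label))
    scores <- c(scores, pr$prob)
    sid <- c(sid, ds$subject_ids[test])
    foldcol <- c(foldcol, rep.int(f, sum(test)))
    models[[f]] <- model
  }
  structure(list(fold_assignments = folds, truth = truth, pred = pred,
                 scores = scores, subject_id = sid, fold = foldcol,
                 metrics = classification_metrics(truth, pred, scores,
                                                  positive),
                 per_fold_models = models, k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(x$k, "fold cross-validation,", length(x$truth), "subjects\n")
  print(x$metrics)
  invisible(x)
}

#' Export cross-validation results as TSV
#'
#' Writes per-subject predictions (`subject_id`, `fold`, `truth`, `pred`,
#' `score`) and, optionally, a one-row metrics summary file.
#'
#' @param cv a `"cv_result"`. @param path output TSV path.
#' @param metrics_path optional path for the metrics summary.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path, metrics_path = NULL) {
  utils::write.table(
    data.frame(subject_id = cv$subject_id, fold = cv$fold, truth = cv$truth,
               pred = cv$pred, score = cv$scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metrics_path)) {
    m <- cv$metrics
    utils::write.table(
      data.frame(accuracy = m$accuracy, sensitivity = m$sensitivity,
                 specificity = m$specificity, auc = m$auc),
      metrics_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Paired-sample t-test
#'
#' Classical two-sided paired t-test on per-unit differences (df = n - 1),
#' as used to compare per-site performance metrics of two models.
#'
#' @param a,b equal-length numeric vectors (n >= 2).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `t`, `p`, `df` and `mean_diff`.
#' @export
paired_t_test <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) < .Machine$double.eps)
    stop("paired_t_test: differences have zero variance (degenerate input)")
  ht <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d))
}

#' Weight-product saliency scores
#'
#' Approximates the partial derivative of the network output with respect
#' to each input FC feature by the chained product of the SSAE layer
#' weight matrices `W^(L) x ... x W^(1)`. The score of input feature j is
#' the sum over top-layer units of the absolute product entries; larger
#' scores mark connections more important for the classification.
#' Activation derivatives and (by default) the softmax coefficients are
#' deliberately excluded.
#'
#' @param model a trained `"dtlnn"` (or a bare `"ssae"`).
#' @param include_head if `TRUE`, additionally multiply by the softmax
#'   coefficient matrix (sensitivity-analysis variant; default `FALSE`).
#' @return Non-negative numeric vector, one score per input feature.
#' @export
saliency_scores <- function(model, include_head = FALSE) {
  ssae <- if (inherits(model, "dtlnn")) model$ssae else model
  stopifnot(inherits(ssae, "ssae"))
  P <- ssae$encoders[[1]]$W
  for (enc in ssae$encoders[-1]) {
    if (ncol(enc$W) != nrow(P))
      stop("saliency_scores: inconsistent layer widths (corrupt model?)")
    P <- enc$W %*% P
  }
  if (include_head) {
    if (!inherits(model, "dtlnn"))
      stop("include_head = TRUE requires a classifier model")
    P <- model$head$theta %*% P
  }
  colSums(abs(P))
}

#' Accumulate saliency rankings across folds
#'
#' Sums per-fold saliency score vectors, ranks edges in descending order of
#' the accumulated score (ties broken by ascending edge index), and reports
#' the top connections as ROI-name pairs.
#'
#' @param per_fold_scores list of equal-length score vectors, one per fold.
#' @param roi_names optional ROI names (defaults to `ROI1..ROIn`).
#' @param top_k how many top edges to list (default 10).
#' @return An object of class `"saliency_ranking"` with `edge_scores`,
#'   `ranks` (a permutation; 1 = most salient), `pairs` (edge index map)
#'   and `top` (data.frame `roi_a`, `roi_b`, `score`, `rank`).
#' @export
accumulate_rankings <- function(per_fold_scores, roi_names = NULL,
                                top_k = 10L) {
  stopifnot(length(per_fold_scores) >= 1)
  len <- unique(vapply(per_fold_scores, length, 1L))
  if (length(len) != 1)
    stop("per-fold score vectors have differing lengths")
  total <- Reduce(`+`, per_fold_scores)
  n <- (1 + sqrt(1 + 8 * len)) / 2
  if (n != round(n))
    stop("score length ", len, " is not a valid n*(n-1)/2 edge count")
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(n))
  ord <- order(-total, seq_along(total))   # stable: ties by edge index
  ranks <- integer(len); ranks[ord] <- seq_len(len)
  pairs <- edge_pairs(n)
  topi <- ord[seq_len(min(top_k, len))]
  top <- data.frame(roi_a = roi_names[pairs[topi, 1]],
                    roi_b = roi_names[pairs[topi, 2]],
                    score = total[topi], rank = seq_along(topi),
                    stringsAsFactors = FALSE)
  structure(list(edge_scores = total, ranks = ranks, pairs = pairs,
                 top = top, roi_names = roi_names),
            class = "saliency_ranking")
}

#' @export
print.saliency_ranking <- function(x, ...) {
  cat("Saliency ranking over", length(x$edge_scores), "edges; top:\n")
  print(x$top)
  invisible(x)
}

#' Export a saliency ranking as TSV
#'
#' Columns: `roi_a`, `roi_b`, `score`, `rank`, ordered by rank.
#'
#' @param ranking a `"saliency_ranking"`. @param path output path.
#' @return `path`, invisibly.
#' @export
write_saliency <- function(ranking, path) {
  ord <- order(ranking$ranks)
  utils::write.table(
    data.frame(roi_a = ranking$roi_names[ranking$pairs[ord, 1]],
               roi_b = ranking$roi_names[ranking$pairs[ord, 2]],
               score = ranking$edge_scores[ord],
               rank = ranking$ranks[ord]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
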