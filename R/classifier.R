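#' Softmax regression head
#'
#' @param theta coefficient matrix, one row per class, one column per
#'   top-layer feature.
#' @param intercept optional per-class intercept vector (or `NULL`).
#' @return An object of class `"softmax_model"`.
#' @export
softmax_model <- function(theta, intercept = NULL) {
  theta <- as.matrix(theta)
  stopifnot(nrow(theta) >= 2, all(is.finite(theta)))
  if (!is.null(intercept))
    stopifnot(length(intercept) == nrow(theta), all(is.finite(intercept)))
  structure(list(theta = theta, intercept = intercept),
            class = "softmax_model")
}

#' Class probabilities under a softmax head
#'
#' `p(y = j | z)` is proportional to `exp(theta_j' z (+ c_j))`; overflow is
#' guarded by subtracting the row maximum before exponentiation, which
#' leaves the probabilities unchanged (softmax shift invariance).
#'
#' @param head a [softmax_model()]. @param Z feature matrix (rows = samples).
#' @return Matrix of class probabilities; each row is non-negative and sums
#'   to 1.
#' @export
softmax_predict <- function(head, Z) {
  Z <- as_row_matrix(Z, ncol(head$theta), "softmax_predict")
  if (any(is.na(Z))) stop("softmax_predict: NaN/NA in input features")
  A <- Z %*% t(head$theta)
  if (!is.null(head$intercept)) A <- sweep(A, 2L, head$intercept, "+")
  A <- A - apply(A, 1L, max)
  E <- exp(A)
  E / rowSums(E)
}

#' Binary cross-entropy cost of a softmax head
#'
#' The both-terms form
#' `-(1/m) * sum_ij [ y_ij ln h_ij + (1 - y_ij) ln(1 - h_ij) ]`
#' with the predicted probabilities `h` inside the logarithms (logarithms of
#' hard 0/1 labels are undefined, so labels multiply and predictions are
#' logged). Probabilities are clamped to \[1e-12, 1-1e-12\] before logs.
#'
#' @param head a [softmax_model()]. @param Z feature matrix.
#' @param Y one-hot label matrix (rows sum to 1).
#' @return Non-negative scalar; approaches 0 as predictions approach labels.
#' @export
cross_entropy <- function(head, Z, Y) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == nrow(head$theta), all(Y %in% c(0, 1)),
            all(rowSums(Y) == 1))
  P <- clamp01(softmax_predict(head, Z))
  -sum(Y * log(P) + (1 - Y) * log(1 - P)) / nrow(Y)
}

# Gradient of the both-terms binary cross-entropy through the softmax.
# Returns the gradient wrt pre-softmax scores A (m x K) and, for
# backpropagation, dE/dZ.
ce_backward <- function(P, Y) {
  m <- nrow(Y)
  Pc <- clamp01(P)
  G <- -(Y / Pc - (1 - Y) / (1 - Pc)) / m      # dE/dP
  P * (G - rowSums(G * P))                     # dE/dA via softmax Jacobian
}

one_hot <- function(labels, classes) {
  labels <- as.character(labels)
  if (!all(labels %in% classes))
    stop("labels contain values outside the class set: ",
         paste(setdiff(labels, classes), collapse = ", "))
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  colnames(Y) <- classes
  Y
}

# Class vector -> c(negative, positive) ordering. The positive class is the
# disease group; probabilities reported downstream are for this class.
resolve_classes <- function(labels, positive = NULL) {
  u <- sort(unique(as.character(labels)))
  if (length(u) != 2)
    stop("exactly two classes are required, got: ", paste(u, collapse = ", "))
  if (is.null(positive)) positive <- u[2]
  if (!positive %in% u) stop("positive class '", positive, "' not in labels")
  c(setdiff(u, positive), positive)
}

#' Train a softmax regression head
#'
#' Minimizes [cross_entropy()] over the coefficients (zero-initialized)
#' with [scg_minimize()].
#'
#' @param Z feature matrix. @param Y one-hot label matrix (one column per
#'   class; every class must have at least one sample).
#' @param hp a [hyperparams()] object (`cost_goal`, `max_epochs`,
#'   `softmax_intercept` are used).
#' @return A trained [softmax_model()].
#' @export
train_softmax <- function(Z, Y, hp) {
  Z <- as.matrix(Z); Y <- as.matrix(Y)
  K <- ncol(Y); kf <- ncol(Z)
  if (any(colSums(Y) == 0))
    stop("train_softmax: every class needs at least one sample")
  use_int <- hp$softmax_intercept
  npar <- K * kf + if (use_int) K else 0L
  fn <- function(w) cross_entropy(unpack_head(w, K, kf, use_int), Z, Y)
  gr <- function(w) {
    head <- unpack_head(w, K, kf, use_int)
    dA <- ce_backward(softmax_predict(head, Z), Y)
    g <- crossprod(dA, Z)                       # K x kf
    if (use_int) c(g, colSums(dA)) else c(g)
  }
  res <- scg_minimize(fn, gr, numeric(npar), goal = hp$cost_goal,
                      max_iter = max(hp$max_epochs, 1L))
  unpack_head(res$w_star, K, kf, use_int)
}

unpack_head <- function(w, K, kf, use_int) {
  theta <- matrix(w[seq_len(K * kf)], K, kf)
  intercept <- if (use_int) w[K * kf + seq_len(K)] else NULL
  softmax_model(theta, intercept)
}

pack_head <- function(head) c(head$theta, head$intercept)

# ---- deep transfer-learning network ----

new_dtlnn <- function(ssae, head, classes, mode, fine_tuned = FALSE,
                      training_log = NULL) {
  stopifnot(mode %in% c("DTL-NN", "DNN"),
            ncol(head$theta) == ssae$layer_sizes[length(ssae$layer_sizes)])
  structure(list(ssae = ssae, head = head, classes = classes, mode = mode,
                 fine_tuned = fine_tuned, training_log = training_log),
            class = "dtlnn")
}

# Flatten all SSAE encoder parameters plus the head into one vector.
flatten_dtlnn <- function(model) {
  c(unlist(lapply(model$ssae$encoders, function(e) c(e$W, e$b))),
    pack_head(model$head))
}

unflatten_dtlnn <- function(w, model) {
  sizes <- model$ssae$layer_sizes
  L <- length(model$ssae$encoders)
  i <- 0L
  encoders <- vector("list", L)
  for (l in seq_len(L)) {
    k <- sizes[l + 1]; n <- sizes[l]
    encoders[[l]] <- list(W = matrix(w[i + seq_len(k * n)], k, n),
                          b = w[i + k * n + seq_len(k)])
    i <- i + k * n + k
  }
  K <- nrow(model$head$theta); kf <- ncol(model$head$theta)
  head <- unpack_head(w[i + seq_len(length(w) - i)], K, kf,
                      !is.null(model$head$intercept))
  model$ssae$encoders <- encoders
  model$head <- head
  model
}

# End-to-end cost and gradient of cross-entropy wrt every parameter.
dtlnn_cost_grad <- function(model, X, Y) {
  L <- length(model$ssae$encoders)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    enc <- model$ssae$encoders[[l]]
    acts[[l + 1]] <- sigmoid(sweep(acts[[l]] %*% t(enc$W), 2L, enc$b, "+"))
  }
  ZL <- acts[[L + 1]]
  P <- softmax_predict(model$head, ZL)
  Pc <- clamp01(P)
  cost <- -sum(Y * log(Pc) + (1 - Y) * log(1 - Pc)) / nrow(Y)

  dA <- ce_backward(P, Y)
  g_theta <- crossprod(dA, ZL)
  g_int <- if (!is.null(model$head$intercept)) colSums(dA) else NULL
  dZ <- dA %*% model$head$theta
  g_enc <- vector("list", L)
  for (l in rev(seq_len(L))) {
    delta <- dZ * acts[[l + 1]] * (1 - acts[[l + 1]])
    g_enc[[l]] <- list(W = crossprod(delta, acts[[l]]), b = colSums(delta))
    if (l > 1L) dZ <- delta %*% model$ssae$encoders[[l]]$W
  }
  grad <- c(unlist(lapply(g_enc, function(g) c(g$W, g$b))), g_theta, g_int)
  list(cost = cost, grad = grad)
}

#' Jointly fine-tune an assembled network
#'
#' Optimizes the cross-entropy objective over the fully flattened parameter
#' vector (every SSAE layer plus the softmax coefficients, updated
#' simultaneously at each iteration) with [scg_minimize()]. No L2 or
#' sparsity penalties apply during fine-tuning; those act only during
#' unsupervised pretraining. With `hp$max_epochs == 0` the model is
#' returned unchanged and `fine_tuned` stays `FALSE`.
#'
#' @param model a `"dtlnn"`. @param X input feature matrix.
#' @param Y one-hot label matrix. @param hp a [hyperparams()] object.
#' @param optimizer `"scg"` (default) or `"gd"` (fixed-step 0.01 gradient
#'   descent, the alternative reading of a fine-tuning learning rate).
#' @return The fine-tuned `"dtlnn"` with `fine_tuned = TRUE` and
#'   `training_log` holding the objective trace.
#' @export
fine_tune <- function(model, X, Y, hp, optimizer = c("scg", "gd")) {
  optimizer <- match.arg(optimizer)
  if (hp$max_epochs == 0L) return(model)
  X <- as.matrix(X); Y <- as.matrix(Y)
  fn <- function(w) dtlnn_cost_grad(unflatten_dtlnn(w, model), X, Y)$cost
  gr <- function(w) dtlnn_cost_grad(unflatten_dtlnn(w, model), X, Y)$grad
  w0 <- flatten_dtlnn(model)
  res <- if (optimizer == "scg")
    scg_minimize(fn, gr, w0, goal = hp$cost_goal, max_iter = hp$max_epochs)
  else
    gd_minimize(fn, gr, w0, goal = hp$cost_goal, max_iter = hp$max_epochs)
  out <- unflatten_dtlnn(res$w_star, model)
  out$fine_tuned <- TRUE
  out$training_log <- res$trace
  out
}

#' Train a deep transfer-learning network (DTL-NN)
#'
#' The transfer pipeline: copy the offline prototype
#' ([transfer_init()]), extract top-layer features ([ssae_extract()]),
#' train the softmax head ([train_softmax()]), assemble, then jointly
#' [fine_tune()] all layers. The offline corpus must be disjoint from the
#' target subjects (enforced upstream by subject id).
#'
#' @param prototype an offline-trained `"ssae"`.
#' @param X target training feature matrix. @param labels per-sample class
#'   labels (two classes).
#' @param hp a [hyperparams()] object.
#' @param positive label of the positive (disease) class; defaults to the
#'   lexicographically larger label.
#' @param do_fine_tune set `FALSE` to keep the prototype frozen.
#' @return An object of class `"dtlnn"` with `mode = "DTL-NN"`.
#' @export
train_dtl_nn <- function(prototype, X, labels, hp, positive = NULL,
                         do_fine_tune = TRUE) {
  ssae <- transfer_init(prototype)
  assemble_and_tune(ssae, X, labels, hp, positive, do_fine_tune,
                    mode = "DTL-NN")
}

#' Train the conventional DNN baseline
#'
#' Identical architecture, hyperparameters and training pipeline as
#' [train_dtl_nn()], except the SSAE is greedily pretrained on the target
#' training features themselves (`provenance = "target-pretrained"`), so
#' any performance difference is attributable to transfer learning.
#'
#' @inheritParams train_dtl_nn
#' @return An object of class `"dtlnn"` with `mode = "DNN"`.
#' @export
train_dnn_baseline <- function(X, labels, hp, positive = NULL,
                               do_fine_tune = TRUE) {
  ssae <- train_ssae(X, hp, provenance = "target-pretrained")
  assemble_and_tune(ssae, X, labels, hp, positive, do_fine_tune,
                    mode = "DNN")
}

assemble_and_tune <- function(ssae, X, labels, hp, positive, do_fine_tune,
                              mode) {
  X <- as.matrix(X)
  X <- scale_features(X, hp)
  classes <- resolve_classes(labels, positive)
  Y <- one_hot(labels, classes)
  Z <- ssae_extract(ssae, X)
  head <- train_softmax(Z, Y, hp)
  model <- new_dtlnn(ssae, head, classes, mode)
  if (do_fine_tune && hp$max_epochs > 0L) model <- fine_tune(model, X, Y, hp)
  model
}

scale_features <- function(X, hp) {
  if (identical(hp$feature_scaling, "unit_interval")) (X + 1) / 2 else X
}

#' Predict classes and positive-class probabilities
#'
#' @param object a trained `"dtlnn"`. @param X feature matrix (raw scale;
#'   the model's `feature_scaling` setting is applied internally).
#' @param ... unused.
#' @return A data.frame with columns `label` (argmax class; an exact 0.5
#'   tie goes to the positive class) and `prob` (positive-class
#'   probability).
#' @export
predict.dtlnn <- function(object, X, ...) {
  X <- as_row_matrix(X, object$ssae$layer_sizes[1], "predict.dtlnn")
  X <- scale_features(X, object$ssae$hyperparams)
  P <- softmax_predict(object$head, ssae_extract(object$ssae, X))
  prob <- P[, 2L]
  data.frame(label = ifelse(prob >= 0.5, object$classes[2], object$classes[1]),
             prob = prob, stringsAsFactors = FALSE)
}

#' @export
print.dtlnn <- function(x, ...) {
  cat(x$mode, " (", paste(x$ssae$layer_sizes, collapse = "-"), "-",
      nrow(x$head$theta), "), classes: ",
      paste(x$classes, collapse = " vs "),
      if (x$fine_tuned) ", fine-tuned" else "", "\n", sep = "")
  invisible(x)
}
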