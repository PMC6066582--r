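#' Hyperparameters for sparse autoencoder and network training
#'
#' Collects every tunable of the training pipeline in one validated object.
#'
#' @param layer_sizes integer vector of hidden-layer widths, one per stacked
#'   autoencoder (e.g. `c(100, 100, 100)`).
#' @param lambda_l2 L2 penalty coefficient on encoding weights (default 0.001).
#' @param beta coefficient of the KL sparsity penalty (typical values 1-4).
#' @param rho sparsity target: desired mean activation of each hidden unit,
#'   in (0, 1) (typical values 0.001-0.1).
#' @param cost_goal training stops once the cost reaches this value
#'   (default `1e-5`).
#' @param max_epochs maximum optimizer iterations per training stage.
#' @param seed integer seed controlling weight initialization.
#' @param decoder_activation `"linear"` (default) or `"sigmoid"` output layer
#'   for the autoencoder decoder. Correlation-valued inputs live in
#'   \[-1, 1\], which a sigmoid output cannot reproduce, hence the linear
#'   default; the sigmoid variant is kept switchable.
#' @param feature_scaling `"none"` (default) or `"unit_interval"`
#'   (affine map of correlations from \[-1, 1\] to \[0, 1\] before training).
#' @param softmax_intercept logical; include per-class intercepts in the
#'   softmax head (default `TRUE`).
#'
#' @return A list of class `"hyperparams"`.
#' @export
hyperparams <- function(layer_sizes, lambda_l2 = 0.001, beta = 1, rho = 0.05,
                        cost_goal = 1e-5, max_epochs = 400, seed = 1L,
                        decoder_activation = c("linear", "sigmoid"),
                        feature_scaling = c("none", "unit_interval"),
                        softmax_intercept = TRUE) {
  decoder_activation <- match.arg(decoder_activation)
  feature_scaling <- match.arg(feature_scaling)
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 1, all(layer_sizes >= 1),
            lambda_l2 >= 0, beta >= 0, rho > 0, rho < 1,
            max_epochs >= 0, is.finite(cost_goal))
  structure(list(layer_sizes = layer_sizes, lambda_l2 = lambda_l2,
                 beta = beta, rho = rho, cost_goal = cost_goal,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 decoder_activation = decoder_activation,
                 feature_scaling = feature_scaling,
                 softmax_intercept = isTRUE(softmax_intercept)),
            class = "hyperparams")
}

sigmoid <- function(x) stats::plogis(x)

clamp01 <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

#' Construct a sparse autoencoder with given parameters
#'
#' @param W1 encoding weights (k x n). @param b1 encoding bias (length k).
#' @param W2 decoding weights (n x k). @param b2 decoding bias (length n).
#' @param decoder_activation `"linear"` or `"sigmoid"`.
#' @return An object of class `"sparse_ae"`.
#' @export
sparse_ae <- function(W1, b1, W2, b2,
                      decoder_activation = c("linear", "sigmoid")) {
  decoder_activation <- match.arg(decoder_activation)
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  k <- nrow(W1); n <- ncol(W1)
  stopifnot(length(b1) == k, nrow(W2) == n, ncol(W2) == k, length(b2) == n,
            all(is.finite(W1)), all(is.finite(b1)),
            all(is.finite(W2)), all(is.finite(b2)))
  structure(list(W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2),
                 n_in = n, k = k, decoder_activation = decoder_activation),
            class = "sparse_ae")
}

#' Randomly initialize a sparse autoencoder
#'
#' All weights and biases are drawn i.i.d. from a symmetric uniform
#' distribution inside \[-1, 1\], in the order W1, b1, W2, b2, from the
#' current RNG state. The range is `min(1, sqrt(6 / (n + k + 1)))`: a
#' fan-in/fan-out scaled (Glorot-style) width that keeps hidden sigmoids
#' in their responsive region. With thousands of input features a literal
#' unit range saturates every hidden unit at initialization, after which
#' the sparsity penalty collapses all activations to the constant target
#' rho and the representation degenerates; the scaled range avoids this
#' while every fresh entry still lies within \[-1, 1\].
#'
#' @param n input width. @param k hidden width.
#' @param decoder_activation decoder output, `"linear"` or `"sigmoid"`.
#' @return A `"sparse_ae"` object.
#' @export
init_sparse_ae <- function(n, k, decoder_activation = "linear") {
  r <- min(1, sqrt(6 / (n + k + 1)))
  W1 <- matrix(stats::runif(k * n, -r, r), k, n)
  b1 <- stats::runif(k, -r, r)
  W2 <- matrix(stats::runif(n * k, -r, r), n, k)
  b2 <- stats::runif(n, -r, r)
  sparse_ae(W1, b1, W2, b2, decoder_activation)
}

#' Encode samples through an autoencoder's hidden layer
#'
#' Computes `z = sigmoid(W1 x + b1)` row-wise for a sample-by-feature matrix.
#'
#' @param ae a `"sparse_ae"`. @param X matrix with `ae$n_in` columns
#'   (or a single vector of that length).
#' @return Matrix of hidden activations with `ae$k` columns, entries in (0,1).
#' @export
ae_encode <- function(ae, X) {
  X <- as_row_matrix(X, ae$n_in, "ae_encode")
  sigmoid(sweep(X %*% t(ae$W1), 2L, ae$b1, "+"))
}

#' Decode hidden activations back to input space
#'
#' Computes `xhat = g(W2 z + b2)` where `g` is the identity (linear decoder,
#' default) or the logistic sigmoid.
#'
#' @param ae a `"sparse_ae"`. @param Z matrix with `ae$k` columns.
#' @return Reconstruction matrix with `ae$n_in` columns.
#' @export
ae_decode <- function(ae, Z) {
  Z <- as_row_matrix(Z, ae$k, "ae_decode")
  A <- sweep(Z %*% t(ae$W2), 2L, ae$b2, "+")
  if (ae$decoder_activation == "sigmoid") sigmoid(A) else A
}

as_row_matrix <- function(X, width, where) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != width)
    stop(where, ": input has ", ncol(X), " columns, expected ", width)
  X
}

#' KL-divergence sparsity penalty
#'
#' `sum_i rho*log(rho/rho_hat_i) + (1-rho)*log((1-rho)/(1-rho_hat_i))`, the
#' Kullback-Leibler divergence between the Bernoulli sparsity target and the
#' observed mean activation of each hidden unit (natural logarithm).
#'
#' @param rho sparsity target in (0, 1).
#' @param rho_hat vector of observed mean activations, each in (0, 1);
#'   values at exactly 0 or 1 are clamped to \[1e-12, 1-1e-12\] with a warning.
#' @return Non-negative scalar; zero iff `rho_hat` is identically `rho`.
#' @export
kl_sparsity <- function(rho, rho_hat) {
  stopifnot(length(rho) == 1, rho > 0, rho < 1)
  if (any(rho_hat <= 0 | rho_hat >= 1)) {
    warning("mean activations at 0 or 1 clamped to (0, 1) for KL penalty")
    rho_hat <- clamp01(rho_hat)
  }
  sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
}

# Flatten / unflatten autoencoder parameters (order: W1, b1, W2, b2).
ae_flatten <- function(ae) c(ae$W1, ae$b1, ae$W2, ae$b2)

ae_unflatten <- function(w, n, k, decoder_activation) {
  i <- 0L
  W1 <- matrix(w[seq_len(k * n)], k, n); i <- k * n
  b1 <- w[i + seq_len(k)]; i <- i + k
  W2 <- matrix(w[i + seq_len(n * k)], n, k); i <- i + n * k
  b2 <- w[i + seq_len(n)]
  sparse_ae(W1, b1, W2, b2, decoder_activation)
}

#' Sparse-autoencoder cost and analytic gradients
#'
#' The cost is the per-sample mean of the summed squared reconstruction
#' error, plus an L2 penalty on the encoding weights only, plus the
#' beta-weighted KL sparsity penalty on the mean hidden activations:
#' `E = (1/p) * sum((xhat - x)^2) + lambda * 0.5 * sum(W1^2) + beta * KL`.
#' Gradients are exact analytic partial derivatives with respect to every
#' parameter (biases are never penalized).
#'
#' @param ae a `"sparse_ae"`. @param X non-empty sample-by-feature matrix.
#' @param hp a [hyperparams()] object (`lambda_l2`, `beta`, `rho` are used).
#' @return List with `cost` (scalar) and `grads`, a list with components
#'   `W1`, `b1`, `W2`, `b2` of the same shapes as the parameters.
#' @export
ae_cost_grad <- function(ae, X, hp) {
  X <- as_row_matrix(X, ae$n_in, "ae_cost_grad")
  p <- nrow(X)
  if (p < 1L) stop("ae_cost_grad: X is empty")
  Z <- ae_encode(ae, X)
  A <- sweep(Z %*% t(ae$W2), 2L, ae$b2, "+")
  Xhat <- if (ae$decoder_activation == "sigmoid") sigmoid(A) else A

  rho_hat <- clamp01(colMeans(Z))
  R <- Xhat - X
  cost <- sum(R * R) / p +
    hp$lambda_l2 * 0.5 * sum(ae$W1^2) +
    hp$beta * sum(hp$rho * log(hp$rho / rho_hat) +
                  (1 - hp$rho) * log((1 - hp$rho) / (1 - rho_hat)))
  if (!is.finite(cost)) stop("ae_cost_grad: non-finite cost")

  delta_out <- (2 / p) * R
  if (ae$decoder_activation == "sigmoid") delta_out <- delta_out * Xhat * (1 - Xhat)
  gW2 <- crossprod(delta_out, Z)
  gb2 <- colSums(delta_out)

  dkl <- hp$beta * (-hp$rho / rho_hat + (1 - hp$rho) / (1 - rho_hat)) / p
  delta_hid <- (delta_out %*% ae$W2 +
                  matrix(dkl, p, ae$k, byrow = TRUE)) * Z * (1 - Z)
  gW1 <- crossprod(delta_hid, X) + hp$lambda_l2 * ae$W1
  gb1 <- colSums(delta_hid)

  list(cost = cost, grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

#' Train one sparse autoencoder
#'
#' Initializes weights and biases uniformly on \[-1, 1\] (drawing W1, b1,
#' W2, b2 in that order from a generator seeded by `hp$seed`) and minimizes
#' [ae_cost_grad()]'s cost with [scg_minimize()] until the cost goal or
#' `hp$max_epochs` iterations.
#'
#' @param X sample-by-feature matrix with at least 2 rows.
#' @param k hidden width (>= 1).
#' @param hp a [hyperparams()] object.
#' @return The trained `"sparse_ae"`, with attributes `"trace"` (objective
#'   trace) and `"converged"`.
#' @export
train_sparse_ae <- function(X, k, hp) {
  X <- as.matrix(X)
  stopifnot(k >= 1, nrow(X) >= 2)
  n <- ncol(X)
  set.seed(hp$seed)
  ae0 <- init_sparse_ae(n, k, hp$decoder_activation)
  fn <- function(w) {
    ae <- ae_unflatten(w, n, k, hp$decoder_activation)
    ae_cost_grad(ae, X, hp)$cost
  }
  gr <- function(w) {
    ae <- ae_unflatten(w, n, k, hp$decoder_activation)
    g <- ae_cost_grad(ae, X, hp)$grads
    c(g$W1, g$b1, g$W2, g$b2)
  }
  res <- scg_minimize(fn, gr, ae_flatten(ae0), goal = hp$cost_goal,
                      max_iter = max(hp$max_epochs, 1L))
  ae <- ae_unflatten(res$w_star, n, k, hp$decoder_activation)
  attr(ae, "trace") <- res$trace
  attr(ae, "converged") <- res$converged
  ae
}
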