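#' Scaled conjugate gradient minimization
#'
#' Batch minimization of a smooth objective by Moller's scaled conjugate
#' gradient (SCG) method. SCG combines conjugate directions with a
#' Levenberg-Marquardt style scale parameter that replaces the line search,
#' so each iteration costs a small, fixed number of objective/gradient
#' evaluations. It is the workhorse optimizer for all autoencoder training,
#' softmax training and joint fine-tuning in this package.
#'
#' One "epoch" of network training corresponds to one SCG iteration (an
#' accepted or rejected step); the optimizer is deterministic given `w0`.
#'
#' @param objective function mapping a numeric parameter vector to a scalar.
#' @param gradient function mapping a numeric parameter vector to the
#'   gradient vector of `objective`.
#' @param w0 numeric vector, the starting point.
#' @param goal stop as soon as the objective falls to or below this value
#'   (default `1e-5`, the conventional cost-function goal for these models).
#' @param max_iter maximum number of SCG iterations (>= 1).
#' @param grad_tol stop when the infinity norm of the gradient falls below
#'   this value (default `1e-8`); guards against spinning at flat optima.
#' @param sigma0 initial finite-difference scale for the curvature estimate
#'   (Moller's sigma, default `1e-4`).
#' @param lambda0 initial scale (damping) parameter (Moller's lambda,
#'   default `1e-6`).
#'
#' @return An object of class `"scg_result"`: a list with elements
#'   `w_star` (the final parameter vector), `f_star` (objective at
#'   `w_star`), `n_iter` (iterations used), `converged` (`TRUE` iff the
#'   objective goal or the gradient tolerance was met before `max_iter`),
#'   and `trace` (objective value at the start plus after every iteration;
#'   non-increasing over accepted steps).
#'
#' @examples
#' f <- function(w) 0.5 * ((w[1] - 1)^2 + 2 * (w[2] - 1)^2)
#' g <- function(w) c(w[1] - 1, 2 * (w[2] - 1))
#' res <- scg_minimize(f, g, c(0, 0))
#' res$w_star
#' @export
scg_minimize <- function(objective, gradient, w0, goal = 1e-5, max_iter = 500,
                         grad_tol = 1e-8, sigma0 = 1e-4, lambda0 = 1e-6) {
  stopifnot(is.function(objective), is.function(gradient))
  w0 <- as.numeric(w0)
  if (length(w0) < 1L) stop("w0 must be a non-empty numeric vector")
  if (!is.numeric(max_iter) || max_iter < 1) stop("max_iter must be >= 1")

  fw <- objective(w0)
  if (!is.finite(fw)) stop("objective is non-finite at the starting point")
  grad <- gradient(w0)
  if (length(grad) != length(w0) || any(!is.finite(grad)))
    stop("gradient is non-finite (or wrong length) at the starting point")

  w <- w0
  trace <- fw
  converged <- FALSE
  n_iter <- 0L

  if (fw <= goal || max(abs(grad)) < grad_tol) {
    return(structure(list(w_star = w, f_star = fw, n_iter = n_iter,
                          converged = TRUE, trace = trace),
                     class = "scg_result"))
  }

  d <- -grad              # search direction
  gradnew <- grad
  success <- TRUE
  nsuccess <- 0L
  lambda <- lambda0       # Moller's scale parameter
  ndim <- length(w)
  mu <- 0; kappa <- 0; theta <- 0

  for (j in seq_len(max_iter)) {
    n_iter <- j
    if (success) {
      mu <- sum(d * gradnew)
      if (mu >= 0) {            # not a descent direction: restart
        d <- -gradnew
        mu <- sum(d * gradnew)
      }
      kappa <- sum(d * d)
      if (kappa < .Machine$double.eps) { converged <- TRUE; break }
      sigma <- sigma0 / sqrt(kappa)
      gplus <- gradient(w + sigma * d)
      if (any(!is.finite(gplus)))
        stop("non-finite gradient during SCG at iteration ", j)
      theta <- sum(d * (gplus - gradnew)) / sigma   # d' H d estimate
    }
    # scale the curvature to enforce positive definiteness
    delta <- theta + lambda * kappa
    if (delta <= 0) {
      delta <- lambda * kappa
      lambda <- lambda - theta / kappa
    }
    alpha <- -mu / delta
    wnew <- w + alpha * d
    fnew <- objective(wnew)
    if (!is.finite(fnew))
      stop("non-finite objective during SCG at iteration ", j)

    Delta <- 2 * (fnew - fw) / (alpha * mu)   # comparison parameter
    if (Delta >= 0) {
      success <- TRUE
      nsuccess <- nsuccess + 1L
      w <- wnew
      fw <- fnew
    } else {
      success <- FALSE
    }
    trace <- c(trace, fw)

    if (success) {
      if (fw <= goal) { converged <- TRUE; break }
      gradold <- gradnew
      gradnew <- gradient(w)
      if (any(!is.finite(gradnew)))
        stop("non-finite gradient during SCG at iteration ", j)
      if (max(abs(gradnew)) < grad_tol) { converged <- TRUE; break }
    }

    # comparison-parameter update of the scale (Moller 1993)
    if (Delta < 0.25) lambda <- min(lambda + delta * (1 - Delta) / kappa, 1e100)
    if (Delta > 0.75) lambda <- max(lambda / 2, 1e-20)

    if (success) {
      if (nsuccess == ndim) {   # periodic restart along steepest descent
        d <- -gradnew
        nsuccess <- 0L
      } else {
        gamma <- sum((gradold - gradnew) * gradnew) / mu
        d <- gamma * d - gradnew
      }
    }
  }

  structure(list(w_star = w, f_star = fw, n_iter = n_iter,
                 converged = converged, trace = trace),
            class = "scg_result")
}

#' Fixed-step gradient descent (fallback optimizer)
#'
#' A plain batch gradient-descent loop with a constant step size, provided
#' as an alternative reading of "back-propagation with learning rate 0.01"
#' for fine-tuning. SCG is the default everywhere; this exists so both
#' readings are runnable.
#'
#' @inheritParams scg_minimize
#' @param step constant step size (default 0.01).
#' @return An `"scg_result"` object (same shape as [scg_minimize()]).
#' @export
gd_minimize <- function(objective, gradient, w0, goal = 1e-5, max_iter = 500,
                        grad_tol = 1e-8, step = 0.01) {
  w <- as.numeric(w0)
  fw <- objective(w)
  if (!is.finite(fw)) stop("objective is non-finite at the starting point")
  trace <- fw
  converged <- FALSE
  n_iter <- 0L
  for (j in seq_len(max_iter)) {
    n_iter <- j
    g <- gradient(w)
    if (any(!is.finite(g))) stop("non-finite gradient at iteration ", j)
    if (max(abs(g)) < grad_tol) { converged <- TRUE; break }
    w <- w - step * g
    fw <- objective(w)
    if (!is.finite(fw)) stop("non-finite objective at iteration ", j)
    trace <- c(trace, fw)
    if (fw <= goal) { converged <- TRUE; break }
  }
  structure(list(w_star = w, f_star = fw, n_iter = n_iter,
                 converged = converged, trace = trace),
            class = "scg_result")
}

#' @export
print.scg_result <- function(x, ...) {
  cat("SCG result: f* =", format(x$f_star), "after", x$n_iter,
      "iterations;", if (x$converged) "converged" else "not converged", "\n")
  invisible(x)
}
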