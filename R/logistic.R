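#' @name regularized-logistic
#' @title L2-regularized logistic regression for per-structure annotation
#'
#' @description
#' Each brain structure gets one binary classifier: labels are +1 (expression
#' detected) / -1 (undetected), and the model minimizes
#' \deqn{\sum_i \log(1 + e^{-y_i (w^T x_i + b)}) + \lambda \|w\|_2^2}
#' with the bias unpenalized. The optimizer is a damped (Armijo-backtracked)
#' Newton method; when the feature dimension exceeds the sample count the
#' problem is solved in the span of the data rows (`w = X'a`), where the
#' optimum provably lies, so the Newton system is at most `(n+1)`-dimensional.
#' The objective trace is recorded and is non-increasing by construction.
NULL

#' Logistic objective and gradient
#'
#' Exposed for verification: the analytic gradient can be checked against
#' central finite differences.
#'
#' @param w Weight vector (length p).
#' @param b Bias scalar.
#' @param X n x p feature matrix.
#' @param y Labels in -1/+1.
#' @param lambda Ridge penalty on `w` (bias unpenalized).
#' @return `logistic_objective`: scalar; `logistic_gradient`: list(w =
#'   length-p gradient, b = scalar).
#' @export
logistic_objective <- function(w, b, X, y, lambda) {
  m <- y * (as.vector(X %*% w) + b)
  # log(1 + exp(-m)) computed stably for large |m|
  sum(ifelse(m > 0, log1p(exp(-m)), -m + log1p(exp(m)))) + lambda * sum(w^2)
}

#' @rdname logistic_objective
#' @export
logistic_gradient <- function(w, b, X, y, lambda) {
  m <- y * (as.vector(X %*% w) + b)
  s <- 1 / (1 + exp(m))            # sigma(-m)
  g0 <- -y * s
  list(w = as.vector(crossprod(X, g0)) + 2 * lambda * w, b = sum(g0))
}

check_labels <- function(y) {
  abort_if(!all(y %in% c(-1, 1)), "labels must be -1/+1")
  abort_if(length(unique(y)) < 2,
           "training requires both classes to be present")
}

# damped Newton on parameters theta with objective/gradient/Hessian closures
newton_minimize <- function(theta, fn, gr, hess, tol = 1e-6, max_iter = 1000L) {
  f <- fn(theta)
  trace <- f
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- gr(theta)
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    H <- hess(theta)
    d <- tryCatch(-solve(H + diag(1e-10, nrow(H)), g),
                  error = function(e) -g)
    if (sum(d * g) >= 0) d <- -g      # ensure a descent direction
    step <- 1
    repeat {
      f_new <- fn(theta + step * d)
      if (is.finite(f_new) && f_new <= f + 1e-4 * step * sum(d * g)) break
      step <- step / 2
      if (step < 1e-14) { f_new <- f; break }
    }
    if (f_new >= f - .Machine$double.eps * (abs(f) + 1)) {
      trace <- c(trace, f_new)
      converged <- sqrt(sum(gr(theta)^2)) < tol * 100
      break
    }
    theta <- theta + step * d
    f <- f_new
    trace <- c(trace, f)
  }
  list(theta = theta, objective = f, trace = trace, converged = converged,
       iterations = length(trace) - 1L)
}

#' Train one structure's binary classifier
#'
#' @param X n x p feature matrix (rows = genes).
#' @param y Labels in -1/+1, both classes present.
#' @param lambda Regularization parameter (default 1), >= 0.
#' @param tol Gradient-norm convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @return Object of class `ish_logistic`: `w`, `b`, `lambda`, `trace`
#'   (objective per accepted iteration, non-increasing), `converged`.
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' y <- ifelse(X[, 1] > 0, 1, -1)
#' fit <- train_logistic(X, y, lambda = 0.01)
#' mean(sign(predict(fit, X)) == y)
#' @export
train_logistic <- function(X, y, lambda = 1, tol = 1e-6, max_iter = 1000L) {
  X <- as.matrix(X)
  abort_if(any(!is.finite(X)), "non-finite values in the feature matrix")
  abort_if(nrow(X) != length(y), "X rows and labels differ in length")
  check_labels(y)
  abort_if(lambda < 0, "lambda must be >= 0")
  n <- nrow(X); p <- ncol(X)

  if (p <= n) {
    fn <- function(th) logistic_objective(th[-(p + 1)], th[p + 1], X, y, lambda)
    gr <- function(th) {
      g <- logistic_gradient(th[-(p + 1)], th[p + 1], X, y, lambda)
      c(g$w, g$b)
    }
    hess <- function(th) {
      m <- y * (as.vector(X %*% th[-(p + 1)]) + th[p + 1])
      s <- 1 / (1 + exp(m))
      d <- s * (1 - s)
      Xb <- cbind(X, 1)
      H <- crossprod(Xb, Xb * d)
      H[seq_len(p), seq_len(p)] <- H[seq_len(p), seq_len(p)] +
        diag(2 * lambda, p)
      H
    }
    res <- newton_minimize(numeric(p + 1), fn, gr, hess,
                           tol = tol, max_iter = max_iter)
    w <- res$theta[seq_len(p)]; b <- res$theta[p + 1]
  } else {
    # span parametrization: w = X'a; loss depends on Xw = K a, K = X X'
    K <- tcrossprod(X)
    fn <- function(th) {
      a <- th[seq_len(n)]; b <- th[n + 1]
      m <- y * (as.vector(K %*% a) + b)
      sum(ifelse(m > 0, log1p(exp(-m)), -m + log1p(exp(m)))) +
        lambda * sum(a * (K %*% a))
    }
    gr <- function(th) {
      a <- th[seq_len(n)]; b <- th[n + 1]
      m <- y * (as.vector(K %*% a) + b)
      s <- 1 / (1 + exp(m))
      g0 <- -y * s + 2 * lambda * a
      c(as.vector(K %*% g0), sum(-y * s))
    }
    hess <- function(th) {
      a <- th[seq_len(n)]; b <- th[n + 1]
      m <- y * (as.vector(K %*% a) + b)
      s <- 1 / (1 + exp(m))
      d <- s * (1 - s)
      KD <- K * rep(d, each = n)        # K %*% diag(d), K symmetric
      H <- matrix(0, n + 1, n + 1)
      H[seq_len(n), seq_len(n)] <- KD %*% K + 2 * lambda * K
      H[seq_len(n), n + 1] <- as.vector(K %*% d)
      H[n + 1, seq_len(n)] <- H[seq_len(n), n + 1]
      H[n + 1, n + 1] <- sum(d)
      H
    }
    res <- newton_minimize(numeric(n + 1), fn, gr, hess,
                           tol = tol, max_iter = max_iter)
    a <- res$theta[seq_len(n)]
    w <- as.vector(crossprod(X, a)); b <- res$theta[n + 1]
  }
  structure(list(w = w, b = b, lambda = lambda, trace = res$trace,
                 converged = res$converged, iterations = res$iterations,
                 n = n, p = p),
            class = "ish_logistic")
}

#' @export
print.ish_logistic <- function(x, ...) {
  cat(sprintf("L2-regularized logistic classifier: p = %d, lambda = %g, %s after %d iterations\n",
              x$p, x$lambda,
              if (x$converged) "converged" else "stopped", x$iterations))
  invisible(x)
}

#' @export
coef.ish_logistic <- function(object, ...) {
  c(bias = object$b, object$w)
}

#' Linear decision scores
#'
#' @param model An `ish_logistic` fit.
#' @param X Feature matrix with the training dimensionality.
#' @return Numeric vector `X w + b`.
#' @export
score_genes <- function(model, X) {
  X <- as.matrix(X)
  abort_if(ncol(X) != length(model$w),
           sprintf("feature dimension %d does not match model dimension %d",
                   ncol(X), length(model$w)))
  as.vector(X %*% model$w) + model$b
}

#' @export
predict.ish_logistic <- function(object, newdata,
                                 type = c("score", "prob"), ...) {
  type <- match.arg(type)
  s <- score_genes(object, newdata)
  if (type == "prob") 1 / (1 + exp(-s)) else s
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive scores above a random negative, ties counted half. Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores Numeric scores.
#' @param labels Labels in -1/+1 (or logical / 0-1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, 1, -1)
  if (all(labels %in% c(0, 1))) labels <- ifelse(labels == 1, 1, -1)
  abort_if(length(scores) != length(labels),
           "scores and labels differ in length")
  check_labels(labels)
  pos <- labels == 1
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
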