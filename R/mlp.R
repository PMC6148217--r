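#' Multi-layer perceptron posterior classifier
#'
#' The per-iteration classifier: a single hidden layer of logistic units and
#' a softmax output, trained by minimising the L2-regularised multinomial
#' cross-entropy with L-BFGS using analytic gradients. Inputs are
#' standardised internally (the scaling is stored and re-applied at
#' prediction). Training is deterministic given `seed`, which controls the
#' random initial weights.
#'
#' @param x numeric matrix, one row per training location.
#' @param y integer class labels in `1..K`.
#' @param K number of classes (default `max(y)`).
#' @param hidden number of logistic hidden units (default 20).
#' @param decay L2 penalty on all weights (default 1e-3).
#' @param maxit L-BFGS iteration cap (default 500).
#' @param tol convergence tolerance on the change in loss (default 1e-5).
#' @param seed integer seed for weight initialisation.
#' @return an object of class `"pluckseg_mlp"`.
#' @export
mlp_fit <- function(x, y, K = max(y), hidden = 20, decay = 1e-3,
                    maxit = 500, tol = 1e-5, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y), all(y >= 1 & y <= K))
  n <- nrow(x); p <- ncol(x); H <- hidden
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  npar <- (p + 1) * H + (H + 1) * K
  i_w1 <- seq_len(p * H)
  i_b1 <- p * H + seq_len(H)
  i_w2 <- p * H + H + seq_len(H * K)
  i_b2 <- p * H + H + H * K + seq_len(K)
  forward <- function(w) {
    A <- 1 / (1 + exp(-(xs %*% matrix(w[i_w1], p, H) +
                          rep(w[i_b1], each = n))))
    Z <- A %*% matrix(w[i_w2], H, K) + rep(w[i_b2], each = n)
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    list(A = A, P = E / rowSums(E), Z = Z)
  }
  fn <- function(w) {
    fw <- forward(w)
    -sum(log(pmax(fw$P[cbind(seq_len(n), y)], 1e-300))) / n +
      0.5 * decay * sum(w^2)
  }
  gr <- function(w) {
    fw <- forward(w)
    D2 <- (fw$P - Y) / n
    D1 <- (D2 %*% t(matrix(w[i_w2], H, K))) * fw$A * (1 - fw$A)
    c(as.vector(crossprod(xs, D1)), colSums(D1),
      as.vector(crossprod(fw$A, D2)), colSums(D2)) + decay * w
  }
  w0 <- with_seed(seed, c(stats::rnorm(p * H, 0, 1 / sqrt(p)), numeric(H),
                          stats::rnorm(H * K, 0, 1 / sqrt(H)), numeric(K)))
  res <- stats::optim(w0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit,
                                     factr = tol / .Machine$double.eps))
  structure(list(weights = res$par, p = p, hidden = H, K = K,
                 center = center, scale = scale, decay = decay,
                 loss = res$value, convergence = res$convergence,
                 counts = res$counts, seed = seed),
            class = "pluckseg_mlp")
}

#' @rdname mlp_fit
#' @param object a fitted `"pluckseg_mlp"`.
#' @param newdata numeric matrix with `p` columns.
#' @param ... unused.
#' @return `predict()` returns an `n x K` matrix of class probabilities
#'   (rows sum to one).
#' @export
predict.pluckseg_mlp <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == object$p)
  n <- nrow(newdata)
  p <- object$p; H <- object$hidden; K <- object$K
  w <- object$weights
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  A <- 1 / (1 + exp(-(xs %*% matrix(w[seq_len(p * H)], p, H) +
                        rep(w[p * H + seq_len(H)], each = n))))
  Z <- A %*% matrix(w[p * H + H + seq_len(H * K)], H, K) +
    rep(w[p * H + H + H * K + seq_len(K)], each = n)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' @export
print.pluckseg_mlp <- function(x, ...) {
  cat("MLP classifier:", x$p, "inputs ->", x$hidden,
      "logistic hidden units ->", x$K, "softmax outputs\n")
  cat("final penalised loss:", format(x$loss),
      "(", x$counts[1], "function evaluations )\n")
  invisible(x)
}
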