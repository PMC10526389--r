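# Internal linear support-vector machine.
#
# No SVM library ships with this environment, so a compact L2-regularized
# squared-hinge SVM is solved with BFGS: the objective is differentiable,
# the problem here is tiny (a handful of log-variance features), and the
# solver is deterministic. For separable data the decision boundary matches
# the usual hinge-loss linear SVM closely.

svm_linear_fit <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(-1, 1)), nrow(X) == length(y))
  d <- ncol(X)
  obj <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1L]
    mrg <- 1 - y * (X %*% w + b)
    viol <- pmax(mrg, 0)
    0.5 * sum(w * w) + cost * sum(viol^2)
  }
  grad <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1L]
    mrg <- as.numeric(1 - y * (X %*% w + b))
    act <- mrg > 0
    gy <- -2 * cost * (y * mrg)[act]
    gw <- w + colSums(X[act, , drop = FALSE] * gy)
    gb <- sum(gy)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, d + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  list(w = fit$par[seq_len(d)], b = fit$par[d + 1L])
}

svm_linear_predict <- function(fit, X) {
  s <- as.numeric(as.matrix(X) %*% fit$w + fit$b)
  ifelse(s >= 0, 1, -1)
}
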