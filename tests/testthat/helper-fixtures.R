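# Shared fixtures, built in code at test time.

rand_recording <- function(n_ch = 4, n_s = 100, fs = 250, seed = 1) {
  set.seed(seed)
  new_recording(matrix(rnorm(n_ch * n_s), n_ch, n_s),
                paste0("ch", seq_len(n_ch)), fs)
}

# a tiny epoch set with per-epoch variance structure along given directions
toy_epochs <- function(n_ep, C, S, v1, v2, Q, noise_sd = 0.1, fs = 250,
                       condition = "mi_left") {
  eps <- array(0, dim = c(C, S, n_ep))
  for (i in seq_len(n_ep)) {
    eps[, , i] <- Q[, 1] %o% (sqrt(v1) * rnorm(S)) +
      Q[, 2] %o% (sqrt(v2) * rnorm(S)) +
      matrix(rnorm(C * S, sd = noise_sd), C, S)
  }
  new_epoch_set(eps, fs, condition)
}

# brute-force GMD straight from its definition
gmd_loop <- function(u, v) {
  N <- length(u)
  ub <- mean(u); vb <- mean(v)
  gu <- sqrt(sum((u - ub)^2) / N)
  gv <- sqrt(sum((v - vb)^2) / N)
  s <- 0
  for (i in seq_len(N))
    s <- s + ((u[i] - ub) / gu - (v[i] - vb) / gv)^2
  sqrt(s / N)
}

# matching of fitted templates to planted maps by absolute spatial
# correlation (greedy over all permutations for K <= 4)
match_maps <- function(fitted, truth) {
  K <- nrow(truth)
  cc <- abs(fitted %*% t(truth)) / ncol(truth)
  perms <- if (K <= 4) {
    m <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
    m[apply(m, 1, function(r) length(unique(r)) == K), , drop = FALSE]
  } else stop("K > 4 unsupported in fixture")
  best <- NULL; best_s <- -Inf
  for (i in seq_len(nrow(perms))) {
    s <- sum(cc[cbind(seq_len(K), perms[i, ])])
    if (s > best_s) {best_s <- s; best <- perms[i, ]}
  }
  list(perm = best, corr = cc[cbind(seq_len(K), best)])
}
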