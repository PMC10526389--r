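# Ground-truth MI-BCI performance: CSP spatial filtering, log-variance
# features, stratified 10-fold cross-validated classification accuracy with
# a linear SVM, and the high/low performer grouping.

trace_normalized_cov <- function(epoch) {
  S <- tcrossprod(epoch - rowMeans(epoch))
  S / sum(diag(S))
}

epoch_covs <- function(epochs) {
  lapply(seq_len(dim(epochs$epochs)[3]),
         function(i) trace_normalized_cov(epochs$epochs[, , i]))
}

# channels x channels x epochs array of centered scatter / (S - 1)
centered_scatters <- function(arr) {
  d <- dim(arr)
  out <- array(0, c(d[1], d[1], d[3]))
  for (i in seq_len(d[3])) {
    x <- arr[, , i] - rowMeans(arr[, , i])
    out[, , i] <- tcrossprod(x) / (d[2] - 1)
  }
  out
}

# log-variance features from cached scatters: identical to csp_features
# on the raw epochs (w' S w is the filtered component's variance)
features_from_scatters <- function(W, scats) {
  E <- dim(scats)[3]
  out <- matrix(0, E, nrow(W))
  for (i in seq_len(E)) {
    v <- rowSums((W %*% scats[, , i]) * W)
    out[i, ] <- log(v / sum(v))
  }
  out
}

# CSP from per-class lists of per-epoch covariances.
csp_from_covs <- function(covs1, covs2, m) {
  C1 <- Reduce(`+`, covs1) / length(covs1)
  C2 <- Reduce(`+`, covs2) / length(covs2)
  Cc <- C1 + C2
  e <- eigen(Cc, symmetric = TRUE)
  tolr <- max(e$values) * 1e-10
  if (any(e$values < tolr)) {
    warning("rank-deficient composite covariance: ridge regularization applied",
            call. = FALSE)
    ridge <- 1e-8 * sum(diag(Cc))
    C1 <- C1 + ridge * diag(nrow(C1)) / 2
    C2 <- C2 + ridge * diag(nrow(C2)) / 2
    Cc <- C1 + C2
    e <- eigen(Cc, symmetric = TRUE)
  }
  P <- e$vectors %*% diag(1 / sqrt(e$values)) # whitening of C1 + C2
  S1 <- crossprod(P, C1 %*% P)
  S1 <- (S1 + t(S1)) / 2
  eb <- eigen(S1, symmetric = TRUE)           # eigenvalues in (0, 1), desc
  W <- P %*% eb$vectors
  keep <- c(seq_len(m), (ncol(W) - m + 1L):ncol(W))
  W <- W[, keep, drop = FALSE]
  for (j in seq_len(ncol(W))) {
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  structure(list(filters = t(W), m = m, eigenvalues = eb$values[keep]),
            class = "csp_model")
}

#' Fit common spatial patterns
#'
#' Solves the generalized eigenproblem of the two normalized class
#' covariances (per-epoch covariance divided by its trace, averaged within
#' class) and retains the `m` filters at each end of the eigenvalue
#' spectrum: the directions of maximal variance contrast between left- and
#' right-hand motor imagery. Filter signs are fixed by making each filter's
#' largest-magnitude coefficient positive.
#'
#' @param epochs_left,epochs_right [new_epoch_set()]s of the two classes.
#' @param m Filter pairs to retain (default 3, so `2m` filters).
#' @return Object of class `csp_model` with fields `filters` (2m x
#'   channels), `m` and `eigenvalues` (left-class variance ratios of the
#'   retained components).
#' @export
fit_csp <- function(epochs_left, epochs_right, m = 3L) {
  if (n_epochs(epochs_left) < 2L || n_epochs(epochs_right) < 2L)
    stop("need at least 2 epochs per class", call. = FALSE)
  C <- dim(epochs_left$epochs)[1]
  if (2L * m > C)
    stop("2m filters exceed the channel count", call. = FALSE)
  csp_from_covs(epoch_covs(epochs_left), epoch_covs(epochs_right), m)
}

#' Log-variance CSP features
#'
#' Feature j of an epoch is `log(var_j / sum_k var_k)` over the retained
#' CSP components: scale-invariant by construction.
#'
#' @param model A `csp_model`.
#' @param epochs An `epoch_set` (matching channel count).
#' @return Numeric matrix, epochs x 2m features.
#' @export
csp_features <- function(model, epochs) {
  csp_features_arr(model$filters, epochs$epochs)
}

# vectorized log-variance features from a channels x samples x epochs array
csp_features_arr <- function(W, arr) {
  d <- dim(arr)
  S <- d[2]; E <- d[3]
  Z <- W %*% matrix(arr, d[1], S * E)          # filters x (S*E)
  Z3 <- array(Z, c(nrow(W), S, E))
  s1 <- colSums(aperm(Z3, c(2L, 1L, 3L)))      # filters x E sums over S
  s2 <- colSums(aperm(Z3 * Z3, c(2L, 1L, 3L)))
  v <- (s2 - s1 * s1 / S) / (S - 1)            # per-filter, per-epoch var
  if (any(colSums(v) == 0))
    stop("degenerate epoch: zero variance", call. = FALSE)
  t(log(sweep(v, 2L, colSums(v), "/")))
}

#' High/low performer grouping rule
#'
#' Sessions with classification accuracy strictly greater than 75% form the
#' "high group"; accuracy of exactly 75% is "low".
#'
#' @param accuracy Accuracy in percent.
#' @return `"high"` or `"low"`.
#' @export
performance_group <- function(accuracy) {
  ifelse(accuracy > 75, "high", "low")
}

stratified_folds <- function(n, folds) {
  idx <- sample.int(n)
  split(idx, rep_len(seq_len(folds), n))
}

#' Cross-validated MI classification accuracy of one session
#'
#' Stratified k-fold cross-validation (default 10 folds). Within each fold
#' the CSP filters are fit on the training epochs only, log-variance
#' features are standardized on the training folds, and a linear
#' support-vector machine (C = 1) separates left from right imagery.
#' Accuracy is the mean fold accuracy in percent; sessions above 75% are the
#' "high group" (strictly greater), the rest the "low group".
#'
#' @param epochs_left,epochs_right Epoch sets of the two classes.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed fixing the fold assignment.
#' @param m CSP filter pairs (default 3).
#' @param subject_id,session_id Carried into the result.
#' @param fold_assignment Optional list of two integer vectors (fold id per
#'   left / right epoch) overriding the seeded stratified assignment.
#' @return Object of class `session_performance`: list with `accuracy`
#'   (percent), `accuracy_sd` (percent, across folds), `group`
#'   (`"high"`/`"low"`), `fold_accuracy`, ids.
#' @export
session_accuracy <- function(epochs_left, epochs_right, folds = 10L,
                             seed = NULL, m = 3L,
                             subject_id = NA, session_id = NA,
                             fold_assignment = NULL) {
  n1 <- n_epochs(epochs_left); n2 <- n_epochs(epochs_right)
  if (min(n1, n2) < folds)
    stop("need at least `folds` epochs per class", call. = FALSE)
  # centered per-epoch scatter: trace-normalizing it gives the CSP class
  # covariances, and w' S w is the filtered component's variance, so the
  # features in every fold come from the same cached matrices
  scat1 <- centered_scatters(epochs_left$epochs)
  scat2 <- centered_scatters(epochs_right$epochs)
  tn <- function(scats, i) {S <- scats[, , i]; S / sum(diag(S))}
  covs1 <- lapply(seq_len(n1), function(i) tn(scat1, i))
  covs2 <- lapply(seq_len(n2), function(i) tn(scat2, i))
  if (is.null(fold_assignment)) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      }
      set.seed(seed)
    }
    f1 <- integer(n1); f2 <- integer(n2)
    sf1 <- stratified_folds(n1, folds)
    sf2 <- stratified_folds(n2, folds)
    for (fl in seq_len(folds)) {
      f1[sf1[[fl]]] <- fl
      f2[sf2[[fl]]] <- fl
    }
  } else {
    f1 <- fold_assignment[[1]]; f2 <- fold_assignment[[2]]
    stopifnot(length(f1) == n1, length(f2) == n2)
  }
  acc <- numeric(folds)
  for (fl in seq_len(folds)) {
    tr1 <- which(f1 != fl); te1 <- which(f1 == fl)
    tr2 <- which(f2 != fl); te2 <- which(f2 == fl)
    csp <- csp_from_covs(covs1[tr1], covs2[tr2], m)
    W <- csp$filters
    Xtr <- rbind(features_from_scatters(W, scat1[, , tr1, drop = FALSE]),
                 features_from_scatters(W, scat2[, , tr2, drop = FALSE]))
    ytr <- rep(c(1, -1), c(length(tr1), length(tr2)))
    mu <- colMeans(Xtr); sdv <- apply(Xtr, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- scale(Xtr, mu, sdv)
    fit <- svm_linear_fit(Xtr, ytr, cost = 1)
    Xte <- rbind(features_from_scatters(W, scat1[, , te1, drop = FALSE]),
                 features_from_scatters(W, scat2[, , te2, drop = FALSE]))
    Xte <- scale(Xte, mu, sdv)
    yte <- rep(c(1, -1), c(length(te1), length(te2)))
    pred <- svm_linear_predict(fit, Xte)
    acc[fl] <- mean(pred == yte)
  }
  a <- mean(acc) * 100
  structure(list(subject_id = subject_id, session_id = session_id,
                 accuracy = a, accuracy_sd = stats::sd(acc) * 100,
                 group = performance_group(a),
                 fold_accuracy = acc * 100),
            class = "session_performance")
}

#' @export
print.session_performance <- function(x, ...) {
  cat(sprintf("<session_performance> accuracy %.2f%% (sd %.2f), group: %s\n",
              x$accuracy, x$accuracy_sd, x$group))
  invisible(x)
}
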