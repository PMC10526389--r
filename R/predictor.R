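# Correlation screening of microstate parameters against MI accuracy, the
# two-feature LDA high/low-performer predictor with per-session
# leave-one-out cross-validation, ROC/AUC, and the spectral-entropy
# baseline predictor.

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length series with n >= 3", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  xd <- x - mean(x); yd <- y - mean(y)
  sx <- sum(xd^2); sy <- sum(yd^2)
  if (sx == 0 || sy == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  r <- sum(xd * yd) / sqrt(sx * sy)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Correlation table of microstate parameters vs MI accuracy
#'
#' One row per parameter (duration, occurrence, coverage, TP1..TPK) and
#' microstate class, holding the Pearson r and unadjusted two-sided p
#' against classification accuracy across all records. Self-transitions are
#' reported as `NA`. Significance flags follow the two-level convention
#' `"**"` for p < 0.001 and `"*"` for 0.01 < p < 0.05; `holm = TRUE`
#' additionally reports Holm-adjusted p-values.
#'
#' @param records data.frame of subject-session records: column `accuracy`
#'   plus `ms<k>_duration`, `ms<k>_occurrence`, `ms<k>_coverage`,
#'   `tp_<j>_<k>` columns as produced by [parameters_row()].
#' @param K Number of microstate classes (default 4).
#' @param holm Add a Holm-adjusted p column? Default `FALSE`.
#' @return data.frame with columns `parameter`, `class`, `r`, `p`, `signif`.
#' @export
correlation_table <- function(records, K = 4L, holm = FALSE) {
  if (nrow(records) < 3L) stop("need at least 3 records", call. = FALSE)
  acc <- records$accuracy
  rows <- list()
  add <- function(parameter, class, col) {
    val <- if (col %in% names(records)) records[[col]] else NULL
    if (is.null(val)) return()
    ct <- pearson_r(val, acc)
    rows[[length(rows) + 1L]] <<- data.frame(parameter = parameter,
                                             class = paste0("MS", class),
                                             r = ct$r, p = ct$p)
  }
  for (k in seq_len(K)) add("Duration", k, paste0("ms", k, "_duration"))
  for (k in seq_len(K)) add("Occurrence", k, paste0("ms", k, "_occurrence"))
  for (k in seq_len(K)) add("Coverage", k, paste0("ms", k, "_coverage"))
  for (j in seq_len(K)) for (k in seq_len(K)) {
    if (j == k) {
      rows[[length(rows) + 1L]] <- data.frame(parameter = paste0("TP", j),
                                              class = paste0("MS", k),
                                              r = NA_real_, p = NA_real_)
    } else {
      add(paste0("TP", j), k, paste0("tp_", k, "_", j))
    }
  }
  out <- do.call(rbind, rows)
  out$signif <- ifelse(is.na(out$p), "",
                       ifelse(out$p < 0.001, "**",
                              ifelse(out$p > 0.01 & out$p < 0.05, "*", "")))
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Normalize a feature without test-set leakage
#'
#' Normalization statistics are estimated on the `fit_on` subset only and
#' applied to the whole series.
#'
#' @param values Numeric vector.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @param fit_on Indices of the training subset (default: all).
#' @return Normalized numeric vector.
#' @export
normalize_feature <- function(values, method = c("zscore", "minmax"),
                              fit_on = seq_along(values)) {
  method <- match.arg(method)
  v <- values[fit_on]
  if (method == "zscore") {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("constant training subset: normalization undefined", call. = FALSE)
    (values - mean(v)) / s
  } else {
    rng <- range(v)
    if (diff(rng) == 0)
      stop("constant training subset: normalization undefined", call. = FALSE)
    (values - rng[1]) / diff(rng)
  }
}

#' Fisher linear discriminant for high/low grouping
#'
#' Weights proportional to the inverse pooled within-class covariance times
#' the class-mean difference (high minus low); scores are `w' x` and the
#' decision threshold sits at the midpoint of the projected class means
#' (equal priors). A ridge of `1e-8 * mean(diag)` rescues a singular pooled
#' covariance.
#'
#' @param features Numeric matrix, records x features.
#' @param groups Vector with values `"high"`/`"low"` (or a factor).
#' @return List with `weights`, `threshold`, `means`.
#' @export
lda_fit <- function(features, groups) {
  X <- as.matrix(features)
  g <- as.character(groups)
  hi <- X[g == "high", , drop = FALSE]
  lo <- X[g == "low", , drop = FALSE]
  if (!nrow(hi) || !nrow(lo))
    stop("both groups must be non-empty", call. = FALSE)
  mu_h <- colMeans(hi); mu_l <- colMeans(lo)
  n_h <- nrow(hi); n_l <- nrow(lo)
  Sw <- matrix(0, ncol(X), ncol(X))
  if (n_h > 1) Sw <- Sw + (n_h - 1) * stats::cov(hi)
  if (n_l > 1) Sw <- Sw + (n_l - 1) * stats::cov(lo)
  Sw <- Sw / max(n_h + n_l - 2, 1)
  w <- tryCatch(solve(Sw, mu_h - mu_l), error = function(e) {
    solve(Sw + diag(1e-8 * mean(diag(Sw)) + 1e-12, ncol(X)), mu_h - mu_l)
  })
  thr <- sum(w * (mu_h + mu_l)) / 2
  list(weights = w, threshold = thr,
       means = rbind(high = mu_h, low = mu_l))
}

lda_score <- function(fit, X) as.numeric(as.matrix(X) %*% fit$weights)

#' Leave-one-out cross-validated predictor scores within one session
#'
#' For each record, the chosen feature columns are normalized and the LDA
#' is fit on the session's remaining records, then the held-out record is
#' scored with the training normalization; folds are fully independent.
#' Records whose training fold lacks one of the groups get `NA` scores.
#'
#' @param records data.frame with the feature columns and a `group` column.
#' @param features Character vector of feature column names (default the
#'   two-feature microstate predictor: MS1 occurrence and MS3 duration).
#' @param method Normalization passed to [normalize_feature()].
#' @return data.frame with columns `score` (raw discriminant value),
#'   `score_std` (the raw score standardized against the training fold's
#'   score distribution — the fold-consistent quantity to pool across
#'   folds and sessions), `predicted` and `ok`.
#' @export
loocv_scores <- function(records,
                         features = c("ms1_occurrence", "ms3_duration"),
                         method = "zscore") {
  n <- nrow(records)
  X <- as.matrix(records[, features, drop = FALSE])
  g <- as.character(records$group)
  score <- score_std <- rep(NA_real_, n)
  pred <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(g[tr])) < 2L) next
    Xn <- X
    bad <- FALSE
    for (j in seq_len(ncol(X))) {
      Xn[, j] <- tryCatch(normalize_feature(X[, j], method, fit_on = tr),
                          error = function(e) {bad <<- TRUE; X[, j]})
    }
    if (bad) next
    fit <- lda_fit(Xn[tr, , drop = FALSE], g[tr])
    s <- lda_score(fit, Xn[i, , drop = FALSE])
    tr_scores <- lda_score(fit, Xn[tr, , drop = FALSE])
    score[i] <- s
    score_std[i] <- (s - mean(tr_scores)) /
      max(stats::sd(tr_scores), .Machine$double.eps)
    pred[i] <- if (s > fit$threshold) "high" else "low"
  }
  data.frame(score = score, score_std = score_std, predicted = pred,
             ok = !is.na(score))
}

#' ROC curve and AUC
#'
#' "High" records are positives. The AUC uses the Mann-Whitney identity
#' (ties count one half); the curve comes from a threshold sweep over the
#' observed scores.
#'
#' @param scores Numeric predictor scores (larger = more "high").
#' @param groups Vector of `"high"`/`"low"` labels.
#' @return Object of class `roc_result`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`.
#' @export
roc_auc <- function(scores, groups) {
  g <- as.character(groups)
  ok <- !is.na(scores) & g %in% c("high", "low")
  s <- scores[ok]; g <- g[ok]
  n1 <- sum(g == "high"); n0 <- sum(g == "low")
  if (n1 == 0 || n0 == 0)
    stop("ROC undefined: one group absent", call. = FALSE)
  rk <- rank(s)                     # midranks handle ties
  auc <- (sum(rk[g == "high"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(s >= t & g == "high") / n1, 0)
  fpr <- vapply(thr, function(t) sum(s >= t & g == "low") / n0, 0)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d thresholds)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Normalized spectral entropy of a single channel
#'
#' Welch-averaged periodogram (1 s Hann segments, 50% overlap), restricted
#' to the analysis band, normalized to a probability mass; the Shannon
#' entropy of that mass divided by the log of the bin count. 1 means a flat
#' in-band spectrum, small values a concentrated one.
#'
#' @param signal Numeric single-channel series.
#' @param fs Sampling rate in Hz.
#' @param band Two-element band in Hz (default `c(7, 30)`).
#' @param segment_s Welch segment length in seconds (default 1).
#' @return Entropy in \[0, 1\].
#' @export
spectral_entropy <- function(signal, fs, band = c(7, 30), segment_s = 1) {
  x <- as.numeric(signal)
  L <- round(segment_s * fs)
  if (length(x) < 2 * fs / band[1])
    stop("signal too short for the requested band", call. = FALSE)
  if (length(x) < L) stop("signal shorter than one Welch segment",
                          call. = FALSE)
  step <- max(1L, floor(L / 2))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))  # Hann
  acc <- numeric(floor(L / 2) + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1L)] * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(length(acc))]
  }
  freqs <- (seq_along(acc) - 1) * fs / L
  inband <- freqs >= band[1] & freqs <= band[2]
  p <- acc[inband]
  if (sum(p) <= 0) stop("zero power in the analysis band", call. = FALSE)
  p <- p / sum(p)
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(sum(inband))
}

#' Compare the microstate predictor with the spectral-entropy baseline
#'
#' Runs per-session leave-one-out scoring for the two-feature microstate
#' predictor and a one-feature LDA on spectral entropy, reports per-session
#' AUCs and pooled ROC curves. Raw LDA scores are only comparable within
#' the fold they were fit in, so pooling uses each held-out score
#' standardized against its training fold's score distribution
#' (`score_std` from [loocv_scores()]): this makes scores comparable
#' across folds and sessions and removes the leave-one-out pessimism that
#' otherwise biases a null predictor's pooled AUC below 0.5. Sessions with
#' a single group are excluded and reported.
#'
#' @param records data.frame with columns `session`, `group`, the
#'   microstate feature columns and `spectral_entropy`.
#' @param features Microstate feature columns (default MS1 occurrence +
#'   MS3 duration).
#' @return List with `per_session` (data.frame of per-session AUCs),
#'   `pooled_microstate` and `pooled_entropy` ([roc_auc()] results), and
#'   `excluded_sessions`.
#' @export
evaluate_predictors <- function(records,
                                features = c("ms1_occurrence",
                                             "ms3_duration")) {
  sess <- sort(unique(records$session))
  if (length(sess) < 2L) stop("need records from >= 2 sessions", call. = FALSE)
  per <- list(); excl <- c()
  pool_ms <- pool_se <- pool_g <- c()
  for (s in sess) {
    rs <- records[records$session == s, , drop = FALSE]
    if (length(unique(rs$group)) < 2L) {
      excl <- c(excl, s)
      next
    }
    ms <- loocv_scores(rs, features)
    se <- loocv_scores(rs, "spectral_entropy")
    ok <- ms$ok & se$ok
    auc_ms <- roc_auc(ms$score_std[ok], rs$group[ok])$auc
    auc_se <- roc_auc(se$score_std[ok], rs$group[ok])$auc
    per[[length(per) + 1L]] <- data.frame(session = s,
                                          auc_microstate = auc_ms,
                                          auc_entropy = auc_se,
                                          n_high = sum(rs$group == "high"),
                                          n_low = sum(rs$group == "low"))
    pool_ms <- c(pool_ms, ms$score_std[ok])
    pool_se <- c(pool_se, se$score_std[ok])
    pool_g <- c(pool_g, as.character(rs$group[ok]))
  }
  list(per_session = do.call(rbind, per),
       pooled_microstate = roc_auc(pool_ms, pool_g),
       pooled_entropy = roc_auc(pool_se, pool_g),
       excluded_sessions = excl)
}
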