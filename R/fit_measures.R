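# Goodness-of-fit measures for cluster-number selection: spatial
# correlation, global explained variance (GEV), the cross-validation
# criterion, within-cluster dispersion, and a K-scan.

#' Spatial correlation between two topographies
#'
#' Cosine similarity of the average-referenced maps, i.e. the spatial
#' Pearson correlation between the two voltage distributions. Related to
#' the polarity-sensitive dissimilarity by `GMD^2 = 2 (1 - r)`.
#'
#' @param u,v Numeric voltage vectors over the same electrodes.
#' @return Correlation in \[-1, 1\].
#' @export
spatial_correlation <- function(u, v) {
  if (length(u) != length(v))
    stop("topographies must share the channel count", call. = FALSE)
  un <- u - mean(u); vn <- v - mean(v)
  nu <- sum(un^2); nv <- sum(vn^2)
  if (nu == 0 || nv == 0)
    stop("degenerate map: zero norm after average reference", call. = FALSE)
  sum(un * vn) / sqrt(nu * nv)
}

#' Global explained variance of a microstate labeling
#'
#' The fraction of GFP-weighted topographic variance explained by the
#' assigned templates: `sum_n C^2(x_n, a_ln) GFP_n^2 / sum_n GFP_n^2`, where
#' `C` is the spatial correlation between sample `x_n` and its template.
#' Perfect fit gives 1. `literal_mean = TRUE` additionally divides by the
#' sample count (a printed variant that no longer reaches 1 at perfect fit;
#' see the methods vignette).
#'
#' @param model A [microstate_model()].
#' @param labels A [label_sequence()] aligned with `segment`.
#' @param segment Channels x samples matrix or `eeg_recording`.
#' @param literal_mean Divide the sum by the number of samples? Default
#'   `FALSE`.
#' @return GEV in \[0, 1\].
#' @export
gev <- function(model, labels, segment, literal_mean = FALSE) {
  X <- avg_ref_cols(as_segment(segment))
  l <- labels$labels
  if (length(l) != ncol(X))
    stop("labels do not align with segment samples", call. = FALSE)
  sq <- colSums(X * X)
  if (all(sq == 0)) stop("degenerate segment: all-zero data", call. = FALSE)
  A <- t(model$maps)
  A <- sweep(A, 2L, sqrt(colSums(A * A)), "/")
  proj <- crossprod(A, X)
  num <- proj[cbind(l, seq_along(l))]^2    # C^2 * GFP^2 * N cancels
  g <- sum(num[sq > 0]) / sum(sq)
  if (literal_mean) g <- g / length(l)
  g
}

#' Cross-validation criterion for cluster-number selection
#'
#' Residual-noise-based criterion `V = sigma2 * ((C - 1) / (C - K - 1))^2`,
#' where `sigma2 = sum_n (x_n' x_n - (a_ln' x_n)^2) / (N (C - 1))` is the
#' residual variance left after projecting each sample onto its assigned
#' unit-norm template, `C` the channel count, `K` the number of templates
#' and `N` the sample count. Lower is better; the penalty factor grows with
#' K, so the criterion trades fit quality against model size.
#'
#' @inheritParams gev
#' @return Non-negative criterion value (squared microvolts).
#' @export
cv_criterion <- function(model, labels, segment) {
  X <- avg_ref_cols(as_segment(segment))
  C <- nrow(X); K <- model$K
  if (K >= C - 1L)
    stop("cv criterion undefined for K >= C - 1 (K = ", K, ", C = ", C, ")",
         call. = FALSE)
  l <- labels$labels
  if (length(l) != ncol(X))
    stop("labels do not align with segment samples", call. = FALSE)
  A <- t(model$maps)
  A <- sweep(A, 2L, sqrt(colSums(A * A)), "/")
  proj <- crossprod(A, X)
  resid <- colSums(X * X) - proj[cbind(l, seq_along(l))]^2
  sigma2 <- sum(resid) / (length(l) * (C - 1))
  sigma2 * ((C - 1) / (C - K - 1))^2
}

#' Within-cluster dispersion of peak maps
#'
#' For each cluster, the sum of squared Euclidean distances over all ordered
#' same-cluster pairs divided by twice the cluster size; summed over
#' clusters. Algebraically the classical within-cluster sum of squares about
#' the cluster centroids. Lower is tighter.
#'
#' @param labels Integer cluster assignment of the peak maps (values `1..K`).
#' @param peaks Channels x peaks matrix of the clustered maps.
#' @return Non-negative dispersion (squared microvolts).
#' @export
dispersion <- function(labels, peaks) {
  X <- as_segment(peaks)
  labels <- as.integer(labels)
  if (length(labels) != ncol(X))
    stop("one label per peak map required", call. = FALSE)
  K <- max(labels)
  tot <- 0
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    if (!length(idx))
      stop("empty cluster ", k, ": dispersion undefined", call. = FALSE)
    Xk <- X[, idx, drop = FALSE]
    ctr <- rowMeans(Xk)
    # sum over ordered pairs of |x - x'|^2 equals 2 N_k * SS about centroid
    tot <- tot + sum(sweep(Xk, 1L, ctr)^2)
  }
  tot
}

#' Scan candidate cluster numbers
#'
#' For each K in `K_range`: cluster the peak maps with
#' [modified_kmeans()], backfit the full segment, and report GEV, the
#' cross-validation criterion (both on all samples of the segment) and the
#' within-cluster dispersion of the peak maps.
#'
#' @param peaks Channels x peaks matrix of GFP-peak topographies.
#' @param segment Channels x samples matrix the criteria are evaluated on.
#' @param fs Sampling rate in Hz.
#' @param K_range Integer candidates, default `2:10`.
#' @param n_restarts Restarts per K (default 20).
#' @param seed Integer seed; each K uses a sub-seed derived from it.
#' @return data.frame with columns `K`, `gev`, `cv`, `dispersion`;
#'   attribute `best_k_cv` holds the argmin-CV K.
#' @export
scan_cluster_numbers <- function(peaks, segment, fs, K_range = 2:10,
                                 n_restarts = 20L, seed = NULL) {
  X <- as_segment(segment)
  C <- nrow(X)
  if (max(K_range) >= C - 1L)
    stop("largest K must satisfy K < C - 1 for the cv criterion",
         call. = FALSE)
  rows <- lapply(seq_along(K_range), function(i) {
    K <- K_range[i]
    sk <- if (is.null(seed)) NULL else seed + 1000L * i
    model <- modified_kmeans(peaks, K, n_restarts = n_restarts, seed = sk)
    lab <- backfit(model, X, fs = fs)
    # align each peak map's polarity with its template before measuring
    # within-cluster spread: sign-invariant clustering otherwise makes the
    # cluster centroids collapse towards zero and the measure constant in K
    pl <- attr(model, "peak_labels")
    P <- as_segment(peaks)
    sgn <- sign(colSums(P * t(model$maps)[, pl, drop = FALSE]))
    sgn[sgn == 0] <- 1
    data.frame(K = K,
               gev = gev(model, lab, X),
               cv = cv_criterion(model, lab, X),
               # overfit K can leave a template unused on degenerate data;
               # dispersion is undefined there and reported as NA
               dispersion = tryCatch(dispersion(pl, sweep(P, 2L, sgn, "*")),
                                     error = function(e) NA_real_))
  })
  out <- do.call(rbind, rows)
  attr(out, "best_k_cv") <- out$K[which.min(out$cv)]
  out
}
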