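# Microstate segmentation: GFP, GMD, GFP-peak extraction, modified k-means
# clustering of peak topographies, and backfitting.

# ---- helpers ---------------------------------------------------------------

as_segment <- function(segment) {
  if (inherits(segment, "eeg_recording")) segment <- segment$data
  segment <- as.matrix(segment)
  storage.mode(segment) <- "double"
  segment
}

# average-reference the columns of a channels x samples matrix
avg_ref_cols <- function(x) sweep(x, 2L, colMeans(x))

#' Global field power
#'
#' The spatial standard deviation of the scalp potential at each instant:
#' `GFP(t) = sqrt( mean_i (v_i(t) - vbar(t))^2 )` over the N electrodes,
#' where `vbar(t)` is the instantaneous cross-channel mean. GFP peaks mark
#' the moments of highest topographic signal-to-noise ratio.
#'
#' @param segment Channels x samples numeric matrix (or `eeg_recording`).
#' @return Numeric vector of per-sample GFP values (same length as samples).
#' @export
gfp <- function(segment) {
  x <- as_segment(segment)
  if (nrow(x) < 2L)
    stop("GFP requires at least 2 channels", call. = FALSE)
  v <- avg_ref_cols(x)
  sqrt(colMeans(v * v))
}

#' GFP series with sampling-rate metadata
#'
#' @param segment Channels x samples matrix or `eeg_recording`.
#' @param fs Sampling rate in Hz (taken from the recording if omitted).
#' @return Object of class `gfp_series`: numeric vector with attribute `fs`.
#' @export
gfp_series <- function(segment, fs = NULL) {
  if (inherits(segment, "eeg_recording") && is.null(fs)) fs <- segment$fs
  if (is.null(fs)) stop("`fs` required", call. = FALSE)
  structure(gfp(segment), fs = as.numeric(fs), class = "gfp_series")
}

#' Global map dissimilarity between two topographies
#'
#' The root-mean-square difference between the two maps after each has been
#' average-referenced and scaled to unit GFP. Ranges over \[0, 2\]: 0 for
#' identical map shapes, 2 for identical shapes of opposite polarity. With
#' `polarity_invariant = TRUE` the smaller of GMD(u, v) and GMD(u, -v) is
#' returned (range \[0, sqrt(2)\]).
#'
#' @param u,v Numeric voltage vectors over the same electrodes.
#' @param polarity_invariant Ignore map polarity? Default `FALSE`.
#' @return Scalar dissimilarity.
#' @export
gmd <- function(u, v, polarity_invariant = FALSE) {
  if (length(u) != length(v))
    stop("topographies must share the channel count", call. = FALSE)
  un <- u - mean(u); vn <- v - mean(v)
  gu <- sqrt(mean(un^2)); gv <- sqrt(mean(vn^2))
  if (gu == 0 || gv == 0)
    stop("degenerate map: zero GFP", call. = FALSE)
  un <- un / gu; vn <- vn / gv
  d <- sqrt(mean((un - vn)^2))
  if (polarity_invariant) d <- min(d, sqrt(mean((un + vn)^2)))
  d
}

#' Locate GFP peaks with a minimum temporal separation
#'
#' Finds strictly interior local maxima of the GFP curve and enforces a
#' minimum spacing (default 10 ms) greedily by peak height: when two
#' candidate maxima are closer than the spacing, the larger one is kept.
#'
#' @param g A `gfp_series`, or a numeric vector (then `fs` is required).
#' @param min_distance_ms Minimum separation between returned peaks, in ms.
#' @param fs Sampling rate in Hz if `g` is a bare vector.
#' @return Integer vector of peak sample indices (1-based), sorted.
#' @export
find_gfp_peaks <- function(g, min_distance_ms = 10, fs = attr(g, "fs")) {
  v <- as.numeric(g)
  if (is.null(fs)) stop("`fs` required", call. = FALSE)
  if (length(v) < 3L) {
    warning("series shorter than 3 samples: no peaks", call. = FALSE)
    return(integer(0))
  }
  if (min_distance_ms < 1000 / fs)
    stop("min_distance_ms must be at least one sample period", call. = FALSE)
  n <- length(v)
  inner <- 2:(n - 1)
  cand <- inner[v[inner] > v[inner - 1] & v[inner] > v[inner + 1]]
  if (!length(cand)) return(integer(0))
  min_samp <- min_distance_ms * fs / 1000
  cand <- cand[order(v[cand], decreasing = TRUE)]
  block <- ceiling(min_samp) - 1L          # neighbours strictly closer
  blocked <- logical(n)
  kept <- integer(length(cand))
  nk <- 0L
  for (i in cand) {
    if (blocked[i]) next
    nk <- nk + 1L
    kept[nk] <- i
    lo <- max(1L, i - block); hi <- min(n, i + block)
    blocked[lo:hi] <- TRUE
  }
  sort(kept[seq_len(nk)])
}

#' Microstate template model
#'
#' @param maps K x channels matrix of template topographies; each row is
#'   average-referenced and rescaled to unit GFP.
#' @param polarity_invariant Whether fitting/backfitting ignores polarity.
#' @param channel_names Optional electrode labels.
#' @return Object of class `microstate_model` with fields `maps` (K x N,
#'   unit GFP rows), `K`, `polarity_invariant`, `channel_names`.
#' @export
microstate_model <- function(maps, polarity_invariant = TRUE,
                             channel_names = NULL) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 1L || ncol(maps) < 2L)
    stop("need K >= 1 maps over >= 2 channels", call. = FALSE)
  maps <- sweep(maps, 1L, rowMeans(maps))
  g <- sqrt(rowMeans(maps^2))
  if (any(g == 0)) stop("degenerate template map (zero GFP)", call. = FALSE)
  maps <- maps / g
  structure(list(maps = maps, K = nrow(maps),
                 polarity_invariant = isTRUE(polarity_invariant),
                 channel_names = channel_names),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> K=%d templates over %d channels (%s)\n",
              x$K, ncol(x$maps),
              if (x$polarity_invariant) "polarity-invariant"
              else "polarity-sensitive"))
  invisible(x)
}

#' Label sequence of microstate classes
#'
#' @param labels Integer vector of per-sample class indices in `1..K`.
#' @param fs Sampling rate in Hz.
#' @param K Number of classes (default `max(labels)`).
#' @return Object of class `label_sequence`.
#' @export
label_sequence <- function(labels, fs, K = max(labels)) {
  labels <- as.integer(labels)
  if (!length(labels) || anyNA(labels) || any(labels < 1L) || any(labels > K))
    stop("labels must be integers in 1..K", call. = FALSE)
  structure(list(labels = labels, fs = as.numeric(fs), K = as.integer(K)),
            class = "label_sequence")
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d samples @ %g Hz, K=%d\n",
              length(x$labels), x$fs, x$K))
  invisible(x)
}

# squared-correlation assignment of average-referenced columns X (C x P)
# to unit-L2 templates A (C x K); returns list(labels, proj) where proj is
# the K x P matrix of inner products a_k . x_p
assign_maps <- function(A, X) {
  proj <- crossprod(A, X)                  # K x P
  labels <- max.col(t(proj * proj), ties.method = "first")
  list(labels = labels, proj = proj)
}

# GEV of an assignment on average-referenced columns X given unit-L2
# templates A: sum_p (a_{l_p} . x_p)^2 / sum_p ||x_p||^2
gev_of_assignment <- function(A, X, labels, proj = NULL) {
  if (is.null(proj)) proj <- crossprod(A, X)
  num <- proj[cbind(labels, seq_along(labels))]^2
  sum(num) / sum(colSums(X * X))
}

#' Modified k-means clustering of peak topographies
#'
#' Clusters GFP-peak maps into K microstate templates, ignoring map
#' polarity: a map and its negation are the same microstate. Assignment
#' maximizes the squared spatial correlation with the templates; each
#' template is re-estimated as the dominant eigenvector of the outer-product
#' sum of its assigned maps. Multiple random restarts are run and the one
#' with the highest global explained variance (GEV) on the peak set wins.
#'
#' @param peaks Channels x peaks numeric matrix of peak topographies (or a
#'   list of voltage vectors).
#' @param K Number of microstate classes.
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Iteration cap per restart (default 100).
#' @param tol Relative GEV change declaring convergence (default 1e-7).
#' @param seed Integer RNG seed; the fit is reproducible given the seed.
#' @param channel_names Optional electrode labels stored in the model.
#' @return A [microstate_model()]; attributes `gev` (GEV on the peak set),
#'   `gev_trace` (per-iteration GEV of the winning restart) and `restarts`.
#' @export
modified_kmeans <- function(peaks, K, n_restarts = 20L, max_iter = 100L,
                            tol = 1e-7, seed = NULL, channel_names = NULL) {
  if (is.list(peaks)) peaks <- do.call(cbind, peaks)
  X <- avg_ref_cols(as_segment(peaks))
  P <- ncol(X); C <- nrow(X)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (P < K) stop("need at least K = ", K, " peak maps, got ", P,
                  call. = FALSE)
  nrm <- sqrt(colSums(X * X))
  if (any(nrm == 0)) stop("degenerate peak map (zero GFP)", call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- sample.int(P, K)
    A <- X[, init, drop = FALSE]
    A <- sweep(A, 2L, sqrt(colSums(A * A)), "/")
    gev_prev <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      as_ <- assign_maps(A, X)
      labels <- as_$labels
      # re-seed empty clusters from the worst-fit map
      for (k in seq_len(K)) {
        if (!any(labels == k)) {
          resid <- colSums(X * X) - as_$proj[cbind(labels, seq_len(P))]^2
          worst <- which.max(resid)
          A[, k] <- X[, worst] / nrm[worst]
          labels[worst] <- k
        }
      }
      for (k in seq_len(K)) {
        idx <- which(labels == k)
        S <- tcrossprod(X[, idx, drop = FALSE])
        A[, k] <- eigen(S, symmetric = TRUE)$vectors[, 1L]
      }
      as_ <- assign_maps(A, X)
      gev_now <- gev_of_assignment(A, X, as_$labels, as_$proj)
      trace <- c(trace, gev_now)
      if (is.finite(gev_prev) &&
          abs(gev_now - gev_prev) <= tol * max(gev_prev, .Machine$double.eps))
        break
      gev_prev <- gev_now
    }
    if (is.null(best) || gev_now > best$gev)
      best <- list(A = A, gev = gev_now, trace = trace,
                   labels = as_$labels)
  }
  model <- microstate_model(t(best$A), polarity_invariant = TRUE,
                            channel_names = channel_names)
  attr(model, "gev") <- best$gev
  attr(model, "gev_trace") <- best$trace
  attr(model, "peak_labels") <- best$labels
  attr(model, "restarts") <- n_restarts
  model
}

#' Backfit a segment to microstate classes
#'
#' Assigns every sample to the template with minimal global map
#' dissimilarity. Under the polarity-invariant default this is the template
#' with the largest squared spatial correlation; with
#' `polarity_invariant = FALSE` the dissimilarity of the literal maps
#' (polarity-sensitive) is minimized. Ties go to the lowest class index;
#' zero-GFP samples inherit the previous sample's label (the first such
#' sample gets class 1).
#'
#' @param model A [microstate_model()].
#' @param segment Channels x samples matrix or `eeg_recording`.
#' @param fs Sampling rate (taken from the recording if omitted).
#' @param polarity_invariant Override the model's polarity flag.
#' @return A [label_sequence()].
#' @export
backfit <- function(model, segment, fs = NULL,
                    polarity_invariant = model$polarity_invariant) {
  if (inherits(segment, "eeg_recording") && is.null(fs)) fs <- segment$fs
  if (is.null(fs)) stop("`fs` required", call. = FALSE)
  X <- avg_ref_cols(as_segment(segment))
  if (nrow(X) != ncol(model$maps))
    stop("segment channel count does not match the model", call. = FALSE)
  A <- t(model$maps)                        # C x K, unit-GFP columns
  A <- sweep(A, 2L, sqrt(colSums(A * A)), "/")
  nrm <- sqrt(colSums(X * X))
  proj <- crossprod(A, X)                   # K x S inner products
  # GMD^2 = 2 (1 - r): argmin GMD == argmax r (or |r| if polarity-blind)
  score <- if (polarity_invariant) proj * proj else proj
  labels <- max.col(t(score), ties.method = "first")
  zero <- which(nrm == 0)
  if (length(zero)) {
    for (i in zero) labels[i] <- if (i == 1L) 1L else labels[i - 1L]
  }
  label_sequence(labels, fs, K = model$K)
}

#' Serialize a microstate model to a delimited text file
#'
#' Header lines `# K=`, `# polarity_invariant=`, `# channels=` precede a
#' K x N tab-separated matrix of template maps.
#'
#' @param model A `microstate_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_microstate_model <- function(model, path) {
  ch <- model$channel_names
  hdr <- c(paste0("# K=", model$K),
           paste0("# polarity_invariant=", model$polarity_invariant),
           paste0("# channels=", paste(if (is.null(ch)) "" else ch,
                                       collapse = ",")))
  writeLines(hdr, path)
  utils::write.table(model$maps, path, append = TRUE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a microstate model written by [write_microstate_model()]
#' @param path Path to the model file.
#' @return A `microstate_model`.
#' @export
read_microstate_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("^# ", key, "="), "",
                           hdr[startsWith(hdr, paste0("# ", key, "="))])
  pol <- identical(get("polarity_invariant"), "TRUE")
  ch <- strsplit(get("channels"), ",")[[1]]
  if (!length(ch) || identical(ch, "")) ch <- NULL
  maps <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")]))
  microstate_model(maps, polarity_invariant = pol, channel_names = ch)
}

#' Write/read a label sequence as a single-column integer file
#' @param labels A `label_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  writeLines(c(paste0("# fs=", labels$fs), paste0("# K=", labels$K),
               as.character(labels$labels)), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  fs <- as.numeric(sub("^# fs=", "", lines[1]))
  K <- as.integer(sub("^# K=", "", lines[2]))
  label_sequence(as.integer(lines[-(1:2)]), fs, K)
}
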