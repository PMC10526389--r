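# The four microstate feature parameters computed from a label sequence:
# mean duration, occurrence per second, time coverage ratio, and the
# transition probability matrix.

#' Run-length encode a label sequence
#'
#' @param labels A [label_sequence()] or integer vector.
#' @return data.frame with columns `class` and `length` (samples); adjacent
#'   rows always differ in class and the lengths sum to the sequence length.
#' @export
run_length_encode <- function(labels) {
  l <- if (inherits(labels, "label_sequence")) labels$labels else
    as.integer(labels)
  if (!length(l)) stop("empty label sequence", call. = FALSE)
  r <- rle(l)
  data.frame(class = r$values, length = r$lengths)
}

# Internal sufficient statistics for the four parameters; additive across
# epochs, which is what makes exact aggregation possible.
param_counts <- function(labels, K, fs, boundary_policy) {
  segs <- run_length_encode(labels)
  n <- length(labels$labels)
  S <- nrow(segs)
  counted <- rep(TRUE, S)
  if (boundary_policy == "exclude_truncated") {
    counted[1L] <- FALSE
    counted[S] <- FALSE
  }
  seg_count <- tabulate(segs$class[counted], nbins = K)
  seg_len <- vapply(seq_len(K), function(k)
    sum(segs$length[counted & segs$class == k]), 0)
  samples <- tabulate(labels$labels, nbins = K)
  trans <- matrix(0L, K, K)
  if (S > 1L) {
    from <- segs$class[-S]; to <- segs$class[-1L]
    for (i in seq_along(from)) trans[from[i], to[i]] <- trans[from[i], to[i]] + 1L
  }
  list(K = K, fs = fs, n_samples = n, seg_count = seg_count,
       seg_len = seg_len, samples = samples, trans = trans)
}

finish_params <- function(cnt) {
  K <- cnt$K; fs <- cnt$fs
  mean_duration <- ifelse(cnt$seg_count > 0,
                          cnt$seg_len / cnt$seg_count * 1000 / fs, NA_real_)
  occurrence <- cnt$seg_count / (cnt$n_samples / fs)
  coverage <- cnt$samples / cnt$n_samples
  out_deg <- rowSums(cnt$trans)
  tp <- cnt$trans / ifelse(out_deg > 0, out_deg, NA_real_)
  diag(tp) <- 0
  dimnames(tp) <- list(paste0("MS", seq_len(K)), paste0("MS", seq_len(K)))
  nm <- paste0("MS", seq_len(K))
  structure(list(mean_duration = stats::setNames(mean_duration, nm),
                 occurrence = stats::setNames(occurrence, nm),
                 coverage = stats::setNames(coverage, nm),
                 tp = tp, K = K, fs = fs, n_samples = cnt$n_samples),
            counts = cnt, class = "microstate_parameters")
}

#' Microstate feature parameters of a label sequence
#'
#' Per class k: mean duration (mean stable-segment length, ms), occurrence
#' (segments per second), time coverage (fraction of samples), and the
#' transition probability matrix `tp[j, k]` = fraction of segment boundaries
#' leaving j that enter k (zero diagonal). A class that never appears gets
#' `NA` duration (absence is not a zero-millisecond measurement); a class
#' with no outgoing transitions gets an `NA` row in `tp`.
#'
#' With the default `boundary_policy = "count_all"`, the possibly truncated
#' first and last segments count toward duration and occurrence, which keeps
#' the identity `coverage = occurrence * mean_duration / 1000` exact;
#' `"exclude_truncated"` drops them from those two statistics.
#'
#' @param labels A [label_sequence()].
#' @param boundary_policy `"count_all"` (default) or `"exclude_truncated"`.
#' @param K Number of classes; defaults to the sequence's `K`.
#' @return Object of class `microstate_parameters`.
#' @export
compute_parameters <- function(labels,
                               boundary_policy = c("count_all",
                                                   "exclude_truncated"),
                               K = labels$K) {
  boundary_policy <- match.arg(boundary_policy)
  stopifnot(inherits(labels, "label_sequence"))
  finish_params(param_counts(labels, K, labels$fs, boundary_policy))
}

#' @export
print.microstate_parameters <- function(x, ...) {
  cat(sprintf("<microstate_parameters> K=%d, %d samples @ %g Hz\n",
              x$K, x$n_samples, x$fs))
  df <- data.frame(mean_duration_ms = round(x$mean_duration, 2),
                   occurrence_per_s = round(x$occurrence, 3),
                   coverage = round(x$coverage, 4))
  print(df)
  invisible(x)
}

#' Pool microstate parameters over epochs
#'
#' Exact pooling by summed sufficient statistics: coverage and transition
#' probabilities from pooled counts, mean duration from the pooled segment
#' list, occurrence from the pooled segment count over pooled time. Segments
#' never merge across epoch boundaries (pre-trial epochs are not
#' contiguous).
#'
#' @param params_list List of `microstate_parameters`, one per epoch.
#' @return A single pooled `microstate_parameters`.
#' @export
aggregate_parameters <- function(params_list) {
  stopifnot(length(params_list) >= 1L)
  cnts <- lapply(params_list, attr, "counts")
  K <- cnts[[1]]$K; fs <- cnts[[1]]$fs
  if (any(vapply(cnts, function(cc) cc$K, 0L) != K))
    stop("all epochs must share K", call. = FALSE)
  if (any(vapply(cnts, function(cc) cc$fs, 0) != fs))
    stop("all epochs must share the sampling rate", call. = FALSE)
  pool <- list(K = K, fs = fs,
               n_samples = sum(vapply(cnts, `[[`, 0, "n_samples")),
               seg_count = Reduce(`+`, lapply(cnts, `[[`, "seg_count")),
               seg_len = Reduce(`+`, lapply(cnts, `[[`, "seg_len")),
               samples = Reduce(`+`, lapply(cnts, `[[`, "samples")),
               trans = Reduce(`+`, lapply(cnts, `[[`, "trans")))
  finish_params(pool)
}

#' Flatten microstate parameters to a one-row data.frame
#'
#' Columns `ms<k>_duration`, `ms<k>_occurrence`, `ms<k>_coverage` and
#' `tp_<j>_<k>` for the off-diagonal transition entries: the row format used
#' by the cohort-level correlation and prediction analyses.
#'
#' @param params A `microstate_parameters`.
#' @return One-row data.frame.
#' @export
parameters_row <- function(params) {
  K <- params$K
  out <- list()
  for (k in seq_len(K)) {
    out[[paste0("ms", k, "_duration")]] <- unname(params$mean_duration[k])
    out[[paste0("ms", k, "_occurrence")]] <- unname(params$occurrence[k])
    out[[paste0("ms", k, "_coverage")]] <- unname(params$coverage[k])
  }
  for (j in seq_len(K)) for (k in seq_len(K)) if (j != k)
    out[[paste0("tp_", j, "_", k)]] <- unname(params$tp[j, k])
  as.data.frame(out)
}
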