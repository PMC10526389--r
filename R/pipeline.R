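# End-to-end drivers: single-recording segmentation and the cohort-level
# analysis that the correlation screening and the predictor run on.

#' Full microstate segmentation of one recording
#'
#' Band-pass filter (7-30 Hz by default), average reference, GFP-peak
#' extraction (10 ms minimum spacing), modified k-means clustering of the
#' peak maps, and backfit of every sample.
#'
#' @param rec An `eeg_recording`.
#' @param K Number of microstate classes (default 4).
#' @param band Band-pass edges in Hz, or `NULL` to skip filtering.
#' @param min_distance_ms Minimum GFP-peak spacing (default 10 ms).
#' @param n_restarts,seed Passed to [modified_kmeans()].
#' @return List with `model`, `labels`, `peaks` (channels x peaks matrix),
#'   `peak_idx`, `gfp` and the preprocessed `recording`.
#' @export
segment_recording <- function(rec, K = 4L, band = c(7, 30),
                              min_distance_ms = 10, n_restarts = 20L,
                              seed = NULL) {
  if (!is.null(band)) rec <- bandpass(rec, band[1], band[2])
  rec <- average_reference(rec)
  g <- gfp_series(rec)
  pk <- find_gfp_peaks(g, min_distance_ms = min_distance_ms)
  peaks <- rec$data[, pk, drop = FALSE]
  model <- modified_kmeans(peaks, K, n_restarts = n_restarts, seed = seed,
                           channel_names = rec$channel_names)
  labels <- backfit(model, rec)
  list(model = model, labels = labels, peaks = peaks, peak_idx = pk,
       gfp = g, recording = rec)
}

# labels of one session chopped into epochs of epoch_s seconds, parameters
# pooled over epochs (segments never merge across epoch boundaries)
epoched_parameters <- function(labels, epoch_s,
                               boundary_policy = "count_all") {
  n <- length(labels$labels)
  len <- round(epoch_s * labels$fs)
  n_ep <- n %/% len
  pool <- NULL
  for (i in seq_len(n_ep)) {
    l <- label_sequence(labels$labels[((i - 1L) * len + 1L):(i * len)],
                        labels$fs, labels$K)
    cnt <- param_counts(l, labels$K, labels$fs, boundary_policy)
    pool <- if (is.null(pool)) cnt else
      list(K = cnt$K, fs = cnt$fs,
           n_samples = pool$n_samples + cnt$n_samples,
           seg_count = pool$seg_count + cnt$seg_count,
           seg_len = pool$seg_len + cnt$seg_len,
           samples = pool$samples + cnt$samples,
           trans = pool$trans + cnt$trans)
  }
  finish_params(pool)
}

#' Run the full analysis over a synthetic cohort
#'
#' Two passes over the cohort's sessions. Pass one: filter each session's
#' resting stream, extract GFP peaks, and pool the `peaks_per_session`
#' highest-GFP peak maps per session into one group-level modified k-means
#' clustering (the group-template convention). Pass two: backfit each
#' session, pool the four microstate parameters over its 1 s pre-trial
#' epochs, compute the spectral-entropy baseline from channel C3 of the raw
#' resting stream, and score the session's cross-validated CSP/SVM MI
#' accuracy. Sessions are regenerated from their seeds between passes
#' rather than held in memory.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param K Number of microstate classes (default 4).
#' @param band Band-pass edges for preprocessing (default `c(7, 30)`).
#' @param peaks_per_session Peak maps per session pooled into the group
#'   clustering (default 100).
#' @param n_restarts Restarts of the group clustering (default 10).
#' @param folds CV folds for MI accuracy (default 10).
#' @param seed Analysis seed (clustering restarts, fold assignment).
#' @param entropy_channel Channel for the spectral-entropy baseline
#'   (default `"C3"`).
#' @param progress Print per-session progress? Default `FALSE`.
#' @return List with `records` (one row per subject-session: microstate
#'   parameter columns, `spectral_entropy`, `accuracy`, `accuracy_sd`,
#'   `group`) and `model` (the group `microstate_model`).
#' @export
analyze_cohort <- function(cohort, K = 4L, band = c(7, 30),
                           peaks_per_session = 100L, n_restarts = 10L,
                           folds = 10L, seed = 1L,
                           entropy_channel = "C3", progress = FALSE) {
  cfg <- cohort$config
  n_rec <- nrow(cohort$truth)
  # pass 1: generate each session once; cache its filtered, average-
  # referenced resting stream for the backfit pass, collect the highest-GFP
  # peak maps for the group clustering, and score everything that does not
  # depend on the group templates (spectral entropy, MI accuracy)
  rest_cache <- vector("list", n_rec)
  peak_pool <- vector("list", n_rec)
  pre <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    dat <- cohort_session_data(cohort, i)
    rec <- dat$rest
    if (!is.null(band)) rec <- bandpass(rec, band[1], band[2],
                                        method = "fft")
    rec <- average_reference(rec)
    rest_cache[[i]] <- rec$data
    g <- gfp_series(rec)
    pk <- find_gfp_peaks(g, min_distance_ms = 10)
    top <- pk[order(g[pk], decreasing = TRUE)][
      seq_len(min(peaks_per_session, length(pk)))]
    peak_pool[[i]] <- rec$data[, sort(top), drop = FALSE]
    se <- spectral_entropy(dat$rest$data[entropy_channel, ], cfg$fs,
                           band = c(7, 30))
    perf <- session_accuracy(dat$left, dat$right, folds = folds,
                             seed = seed + i,
                             subject_id = dat$truth$subject,
                             session_id = dat$truth$session)
    pre[[i]] <- data.frame(subject = dat$truth$subject,
                           session = dat$truth$session,
                           spectral_entropy = se,
                           accuracy = perf$accuracy,
                           accuracy_sd = perf$accuracy_sd,
                           group = perf$group)
    if (progress) message("session ", i, "/", n_rec)
  }
  model <- modified_kmeans(do.call(cbind, peak_pool), K,
                           n_restarts = n_restarts, seed = seed,
                           channel_names = cfg$channel_names)
  # pass 2: backfit the cached streams against the group templates
  rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    labels <- backfit(model, rest_cache[[i]], fs = cfg$fs)
    params <- epoched_parameters(labels, cfg$rest_epoch_s)
    rows[[i]] <- cbind(pre[[i]][, c("subject", "session")],
                       parameters_row(params),
                       pre[[i]][, c("spectral_entropy", "accuracy",
                                    "accuracy_sd", "group")])
  }
  list(records = do.call(rbind, rows), model = model)
}
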