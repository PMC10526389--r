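test_that("gfp matches its closed-form examples and the loop oracle", {
  expect_equal(gfp(cbind(c(0, 0, 0, 0))), 0)
  expect_equal(gfp(cbind(c(1, -1))), 1)
  expect_equal(gfp(cbind(c(2, 0, 0, -2))), sqrt(2))
  set.seed(1)
  x <- matrix(rnorm(6 * 40), 6, 40)
  oracle <- sapply(seq_len(40), function(t) {
    v <- x[, t]; sqrt(sum((v - mean(v))^2) / 6)
  })
  expect_equal(gfp(x), oracle, tolerance = 1e-12)
  expect_error(gfp(matrix(1, 1, 5)), "2 channels")
})

test_that("gfp is offset-invariant and amplitude-linear", {
  set.seed(2)
  x <- matrix(rnorm(5 * 30), 5, 30)
  expect_equal(gfp(x + 17), gfp(x), tolerance = 1e-12)
  expect_equal(gfp(3.5 * x), 3.5 * gfp(x), tolerance = 1e-12)
})

test_that("gmd matches its examples, the loop oracle, and its invariances", {
  u <- c(1, -1, 1, -1); v <- c(1, 1, -1, -1)
  expect_equal(gmd(u, u), 0)
  expect_equal(gmd(u, -u), 2)
  expect_equal(gmd(u, -u, polarity_invariant = TRUE), 0)
  expect_equal(gmd(u, v), sqrt(2))
  expect_equal(gmd(u, v, polarity_invariant = TRUE), sqrt(2))
  expect_error(gmd(u, rep(2, 4)), "zero GFP")
  set.seed(3)
  for (i in 1:25) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(gmd(a, b), gmd_loop(a, b), tolerance = 1e-12)
    expect_equal(gmd(a, b), gmd(b, a), tolerance = 1e-12)     # symmetry
    expect_equal(gmd(2.3 * a, b), gmd(a, 0.7 * b), tolerance = 1e-12)
    expect_equal(gmd(a, -b, TRUE), gmd(a, b, TRUE), tolerance = 1e-12)
  }
})

test_that("GMD^2 = 2(1 - r) links dissimilarity to spatial correlation", {
  set.seed(4)
  for (i in 1:50) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(gmd(a, b)^2, 2 * (1 - spatial_correlation(a, b)),
                 tolerance = 1e-8)
  }
})

test_that("GFP peak finding honours interiority and greedy spacing", {
  expect_equal(find_gfp_peaks(c(1, 2, 3, 4, 5), fs = 250), integer(0))
  expect_equal(find_gfp_peaks(c(0, 1, 0), fs = 250), 2L)
  # two maxima 8 ms apart at 250 Hz: only the taller one survives 10 ms
  g <- c(0, 1, 0, 2, 0)
  expect_equal(find_gfp_peaks(g, 10, fs = 250), 4L)
  expect_warning(out <- find_gfp_peaks(c(1, 2), fs = 250), "shorter")
  expect_equal(out, integer(0))
  expect_error(find_gfp_peaks(c(0, 1, 0), 1, fs = 250), "sample period")
})

test_that("greedy-by-height peak pruning matches a brute-force oracle", {
  brute <- function(v, min_samp) {
    cand <- which(diff(sign(diff(v))) < 0) + 1L
    cand <- cand[v[cand] > v[cand - 1] & v[cand] > v[cand + 1]]
    cand <- cand[order(v[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in cand)
      if (!length(kept) || all(abs(kept - i) >= min_samp))
        kept <- c(kept, i)
    sort(kept)
  }
  set.seed(5)
  for (i in 1:20) {
    v <- abs(rnorm(400))
    expect_equal(find_gfp_peaks(v, 10, fs = 250), brute(v, 2.5))
    expect_equal(find_gfp_peaks(v, 20, fs = 250), brute(v, 5))
  }
})

test_that("modified k-means recovers noiseless planted structure exactly", {
  maps <- make_planted_maps(8, 2, seed = 11)
  peaks <- cbind(sweep(t(maps)[, rep(1, 50)], 2, rep(c(1, -1), 25), "*"),
                 t(maps)[, rep(2, 50)])
  m <- modified_kmeans(peaks, 2, n_restarts = 5, seed = 1)
  mm <- match_maps(m$maps, maps)
  expect_true(all(mm$corr > 1 - 1e-8))
  expect_equal(attr(m, "gev"), 1, tolerance = 1e-10)
  # K = 1 with alternating polarity recovers the map up to sign
  m1 <- modified_kmeans(sweep(t(maps)[, rep(1, 20)], 2,
                              rep(c(1, -1), 10), "*"), 1,
                        n_restarts = 3, seed = 2)
  expect_gt(abs(spatial_correlation(m1$maps[1, ], maps[1, ])), 1 - 1e-8)
})

test_that("modified k-means templates satisfy the model invariants", {
  set.seed(6)
  peaks <- matrix(rnorm(10 * 200), 10, 200)
  m <- modified_kmeans(peaks, 3, n_restarts = 5, seed = 3)
  expect_lt(max(abs(rowMeans(m$maps))), 1e-8)
  expect_equal(sqrt(rowMeans(m$maps^2)), rep(1, 3), tolerance = 1e-8)
  expect_error(modified_kmeans(peaks[, 1:2], 3, seed = 1), "at least K")
})

test_that("modified k-means is reproducible and GEV-monotone per restart", {
  set.seed(7)
  peaks <- matrix(rnorm(12 * 300), 12, 300)
  a <- modified_kmeans(peaks, 4, n_restarts = 4, seed = 99)
  b <- modified_kmeans(peaks, 4, n_restarts = 4, seed = 99)
  expect_identical(a$maps, b$maps)
  tr <- attr(a, "gev_trace")
  expect_true(all(diff(tr) >= -1e-9))
})

test_that("noisy planted maps are recovered at high spatial correlation", {
  maps <- make_planted_maps(30, 4, seed = 21)
  set.seed(22)
  idx <- sample(1:4, 2000, replace = TRUE)
  peaks <- t(maps)[, idx] * rep(sample(c(-1, 1), 2000, TRUE), each = 30) +
    matrix(rnorm(30 * 2000, sd = 1 / 5), 30, 2000)   # SNR 5
  m <- modified_kmeans(peaks, 4, n_restarts = 20, seed = 23)
  mm <- match_maps(m$maps, maps)
  expect_true(all(mm$corr >= 0.95))
})

test_that("backfit labels agree with an exhaustive per-sample GMD scan", {
  maps <- make_planted_maps(30, 4, seed = 31)
  model <- microstate_model(maps)
  set.seed(32)
  seg <- matrix(rnorm(30 * 100), 30, 100)
  lab <- backfit(model, seg, fs = 250)
  lab_sens <- backfit(model, seg, fs = 250, polarity_invariant = FALSE)
  for (t in seq_len(100)) {
    d_inv <- sapply(1:4, function(k) gmd(seg[, t], maps[k, ], TRUE))
    d_sen <- sapply(1:4, function(k) gmd(seg[, t], maps[k, ], FALSE))
    expect_equal(lab$labels[t], which.min(d_inv))
    expect_equal(lab_sens$labels[t], which.min(d_sen))
  }
})

test_that("backfit handles exact templates, sign flips and zero samples", {
  maps <- make_planted_maps(10, 3, seed = 41)
  model <- microstate_model(maps)
  seg <- t(maps)[, rep(3, 10)]
  expect_equal(backfit(model, seg, fs = 100)$labels, rep(3L, 10))
  expect_equal(backfit(model, cbind(-maps[2, ]), fs = 100)$labels, 2L)
  # zero-GFP column inherits previous label; leading zero gets class 1
  seg2 <- cbind(0, t(maps)[, 2], 0)
  expect_equal(backfit(model, seg2, fs = 100)$labels, c(1L, 2L, 2L))
  # exact templates backfit to GEV 1
  lab <- backfit(model, t(maps), fs = 100)
  expect_equal(gev(model, lab, t(maps)), 1, tolerance = 1e-10)
})

test_that("model and label serialization round-trips", {
  maps <- make_planted_maps(6, 2, seed = 51)
  model <- microstate_model(maps, channel_names = paste0("e", 1:6))
  p1 <- withr::local_tempfile()
  write_microstate_model(model, p1)
  back <- read_microstate_model(p1)
  expect_equal(back$maps, model$maps, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$channel_names, model$channel_names)
  expect_true(back$polarity_invariant)
  lab <- label_sequence(c(1L, 2L, 2L, 1L), 250, 2L)
  p2 <- withr::local_tempfile()
  write_labels(lab, p2)
  lab2 <- read_labels(p2)
  expect_equal(lab2$labels, lab$labels)
  expect_equal(lab2$fs, 250)
})
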