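test_that("run-length encoding matches its examples and round-trips", {
  expect_equal(run_length_encode(c(1, 1, 2, 2, 2, 1)),
               data.frame(class = c(1, 2, 1), length = c(2, 3, 1)))
  expect_equal(run_length_encode(3L), data.frame(class = 3L, length = 1L))
  set.seed(1)
  for (i in 1:20) {
    x <- sample(1:4, 200, replace = TRUE)
    enc <- run_length_encode(x)
    expect_true(all(diff(enc$class) != 0))
    expect_equal(rep(enc$class, enc$length), x)
  }
})

test_that("the four parameters match the worked example", {
  lab <- label_sequence(c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2), fs = 1000, K = 2)
  p <- compute_parameters(lab)
  expect_equal(unname(p$mean_duration), c(4, 6))
  expect_equal(unname(p$coverage), c(0.4, 0.6))
  expect_equal(unname(p$occurrence), c(100, 100))
  expect_equal(p$tp[1, 2], 1)
  expect_true(is.na(p$tp[2, 1]))     # class 2 has no outgoing transition
})

test_that("single-class and alternating sequences hit the contract edges", {
  lab <- label_sequence(rep(2L, 50), fs = 250, K = 3)
  p <- compute_parameters(lab)
  expect_equal(unname(p$coverage), c(0, 1, 0))
  expect_true(all(is.na(p$tp[2, c(1, 3)])))   # no outgoing boundary
  expect_true(is.na(p$mean_duration[1]))      # absent class is missing
  expect_equal(unname(p$occurrence[1]), 0)
  alt <- label_sequence(rep(c(1L, 2L), 25), fs = 250, K = 2)
  pa <- compute_parameters(alt)
  expect_equal(pa$tp[1, 2], 1)
  expect_equal(pa$tp[2, 1], 1)
})

test_that("parameters match a segment-walking oracle on long sequences", {
  set.seed(2)
  x <- integer(0)
  while (length(x) < 10000)
    x <- c(x, rep(sample(1:4, 1), sample(1:30, 1)))
  x <- x[1:10000]
  lab <- label_sequence(x, fs = 250, K = 4)
  p <- compute_parameters(lab)
  # independent walk over the sequence
  segs <- list(); cur <- x[1]; len <- 0
  for (v in x) {
    if (v == cur) len <- len + 1
    else {segs[[length(segs) + 1]] <- c(cur, len); cur <- v; len <- 1}
  }
  segs[[length(segs) + 1]] <- c(cur, len)
  sm <- do.call(rbind, segs)
  for (k in 1:4) {
    lens <- sm[sm[, 1] == k, 2]
    expect_equal(unname(p$mean_duration[k]), mean(lens) * 1000 / 250)
    expect_equal(unname(p$occurrence[k]), length(lens) / (10000 / 250))
    expect_equal(unname(p$coverage[k]), sum(lens) / 10000)
  }
  for (j in 1:4) {
    from <- sm[-nrow(sm), 1]; to <- sm[-1, 1]
    out_j <- sum(from == j)
    for (k in 1:4) if (j != k)
      expect_equal(p$tp[j, k], sum(from == j & to == k) / out_j)
  }
})

test_that("coverage = occurrence x duration / 1000 under count-all policy", {
  set.seed(3)
  for (i in 1:30) {
    x <- sample(1:3, sample(20:400, 1), replace = TRUE)
    lab <- label_sequence(x, fs = sample(c(100, 250, 500), 1), K = 3)
    p <- compute_parameters(lab, boundary_policy = "count_all")
    pres <- !is.na(p$mean_duration)
    expect_equal(unname(p$coverage[pres]),
                 unname(p$occurrence[pres] * p$mean_duration[pres] / 1000),
                 tolerance = 1e-10)
    expect_equal(sum(p$coverage), 1, tolerance = 1e-10)
    for (j in seq_len(3)) {
      if (!all(is.na(p$tp[j, -j])))
        expect_equal(sum(p$tp[j, -j]), 1, tolerance = 1e-10)
    }
  }
})

test_that("excluding truncated boundary segments changes only dur/occ", {
  lab <- label_sequence(c(1, 1, 2, 2, 2, 1, 1, 1, 1), fs = 1000, K = 2)
  pa <- compute_parameters(lab, "count_all")
  pe <- compute_parameters(lab, "exclude_truncated")
  expect_equal(pe$coverage, pa$coverage)
  expect_equal(unname(pe$mean_duration), c(NA_real_, 3))
  expect_equal(unname(pe$occurrence), c(0, 1 / 0.009))
})

test_that("parameters are invariant under consistent relabeling", {
  set.seed(4)
  x <- sample(1:3, 500, replace = TRUE)
  perm <- c(3L, 1L, 2L)
  p1 <- compute_parameters(label_sequence(x, 250, 3))
  p2 <- compute_parameters(label_sequence(perm[x], 250, 3))
  inv <- order(perm)
  expect_equal(unname(p2$mean_duration[perm]), unname(p1$mean_duration))
  expect_equal(unname(p2$coverage[perm]), unname(p1$coverage))
  expect_equal(unname(p2$tp[perm, perm]), unname(p1$tp))
})

test_that("aggregation equals parameters of the concatenated sequence", {
  set.seed(5)
  eps <- lapply(1:10, function(i)
    label_sequence(sample(1:4, 250, replace = TRUE), 250, 4))
  agg <- aggregate_parameters(lapply(eps, compute_parameters))
  expect_equal(sum(agg$coverage), 1, tolerance = 1e-10)
  # hand-checkable two-epoch case where a merge would change the answer
  eps2 <- list(label_sequence(c(1, 1, 2), 100, 2),
               label_sequence(c(2, 1, 1), 100, 2))
  agg2 <- aggregate_parameters(lapply(eps2, compute_parameters))
  # durations: class 1 segments (2, 2), class 2 segments (1, 1)
  expect_equal(unname(agg2$mean_duration), c(20, 10))
  expect_equal(unname(agg2$coverage), c(4 / 6, 2 / 6))
  expect_equal(unname(agg2$occurrence), c(2 / 0.06, 2 / 0.06))
  # two identical epochs aggregate to the single-epoch parameters
  same <- compute_parameters(eps[[1]])
  aggs <- aggregate_parameters(list(same, same))
  expect_equal(aggs$mean_duration, same$mean_duration)
  expect_equal(aggs$coverage, same$coverage)
  expect_equal(aggs$occurrence, same$occurrence)
  expect_equal(aggs$tp, same$tp)
  # disjoint single-class epochs of equal length -> coverage 0.5 / 0.5
  half <- aggregate_parameters(list(
    compute_parameters(label_sequence(rep(1L, 100), 100, 2)),
    compute_parameters(label_sequence(rep(2L, 100), 100, 2))))
  expect_equal(unname(half$coverage), c(0.5, 0.5))
  expect_error(aggregate_parameters(list(
    compute_parameters(label_sequence(1:2, 100, 2)),
    compute_parameters(label_sequence(1:3, 100, 3)))), "share K")
})

test_that("aggregation matches pooled-count oracle on random epochs", {
  set.seed(6)
  eps <- lapply(1:6, function(i)
    label_sequence(sample(1:3, 40, replace = TRUE), 200, 3))
  agg <- aggregate_parameters(lapply(eps, compute_parameters))
  # oracle: walk each epoch independently, pool segment lists
  all_segs <- do.call(rbind, lapply(eps, function(e) {
    r <- rle(e$labels); cbind(r$values, r$lengths)
  }))
  for (k in 1:3) {
    lens <- all_segs[all_segs[, 1] == k, 2]
    expect_equal(unname(agg$mean_duration[k]), mean(lens) * 1000 / 200)
    expect_equal(unname(agg$occurrence[k]), length(lens) / (240 / 200))
    expect_equal(unname(agg$coverage[k]), sum(lens) / 240)
  }
})
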