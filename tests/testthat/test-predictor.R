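test_that("pearson_r matches the sum-formula oracle and cor.test", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  n <- 4
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  out <- pearson_r(x, y)
  expect_equal(out$r, r_oracle, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(out$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(out$p, ct$p.value, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("pearson_r is affine-invariant and antisymmetric", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    r0 <- pearson_r(x, y)$r
    expect_equal(pearson_r(3 * x + 2, 0.5 * y - 7)$r, r0, tolerance = 1e-12)
    expect_equal(pearson_r(-x, y)$r, -r0, tolerance = 1e-12)
  }
})

test_that("normalize_feature fits on the training subset only", {
  z <- normalize_feature(c(1, 2, 3), "zscore")
  expect_equal(mean(z), 0); expect_equal(sd(z), 1)
  expect_equal(normalize_feature(c(2, 4, 6), "minmax"), c(0, 0.5, 1))
  # statistics come from fit_on, the held-out point may fall outside [0,1]
  v <- normalize_feature(c(2, 4, 10), "minmax", fit_on = 1:2)
  expect_equal(v, c(0, 1, 4))
  z2 <- normalize_feature(c(1, 2, 100), "zscore", fit_on = 1:2)
  expect_equal(z2[1:2], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_error(normalize_feature(c(1, 1, 2), "zscore", fit_on = 1:2),
               "constant")
})

test_that("lda separates separated clouds and aligns with mean difference", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40, 5), 20, 2), matrix(rnorm(40, -5), 20, 2))
  g <- rep(c("high", "low"), each = 20)
  fit <- lda_fit(X, g)
  sc <- as.numeric(X %*% fit$weights)
  expect_equal(mean((sc > fit$threshold) == (g == "high")), 1)
  # spherical within-class covariance: weights parallel to mean difference
  set.seed(3)
  X2 <- rbind(matrix(rnorm(4000), 2000, 2) + rep(c(1, 2), each = 2000),
              matrix(rnorm(4000), 2000, 2))
  g2 <- rep(c("high", "low"), each = 2000)
  fit2 <- lda_fit(X2, g2)
  mdiff <- colMeans(X2[g2 == "high", ]) - colMeans(X2[g2 == "low", ])
  cosine <- sum(fit2$weights * mdiff) /
    sqrt(sum(fit2$weights^2) * sum(mdiff^2))
  expect_gt(cosine, 0.999)
  expect_error(lda_fit(X, rep("high", 40)), "non-empty")
})

test_that("identical class means give near-chance AUC", {
  set.seed(4)
  aucs <- sapply(1:10, function(i) {
    # fit on one half, score the other: no training optimism
    X <- matrix(rnorm(800), 400, 2)
    g <- rep(c("high", "low"), 200)
    fit <- lda_fit(X[1:200, ], g[1:200])
    roc_auc(as.numeric(X[201:400, ] %*% fit$weights), g[201:400])$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("loocv scores equal a naive refit-per-record oracle", {
  set.seed(5)
  rec <- data.frame(ms1_occurrence = rnorm(12), ms3_duration = rnorm(12),
                    group = rep(c("high", "low"), 6))
  out <- loocv_scores(rec)
  for (i in 1:12) {
    tr <- setdiff(1:12, i)
    f1 <- normalize_feature(rec$ms1_occurrence, "zscore", fit_on = tr)
    f2 <- normalize_feature(rec$ms3_duration, "zscore", fit_on = tr)
    fit <- lda_fit(cbind(f1, f2)[tr, ], rec$group[tr])
    raw <- sum(fit$weights * c(f1[i], f2[i]))
    expect_equal(out$score[i], raw, tolerance = 1e-10)
    trs <- as.numeric(cbind(f1, f2)[tr, ] %*% fit$weights)
    expect_equal(out$score_std[i], (raw - mean(trs)) / sd(trs),
                 tolerance = 1e-10)
  }
  # separable 4-record session: all predicted correctly
  rec2 <- data.frame(ms1_occurrence = c(1, 1.1, -1, -1.1),
                     ms3_duration = c(1, 0.9, -1, -0.9),
                     group = c("high", "high", "low", "low"))
  out2 <- loocv_scores(rec2)
  expect_equal(out2$predicted, rec2$group)
  # training fold missing a group -> flagged missing
  rec3 <- data.frame(ms1_occurrence = rnorm(3), ms3_duration = rnorm(3),
                     group = c("high", "low", "low"))
  out3 <- loocv_scores(rec3)
  expect_true(is.na(out3$score[1]))
  expect_true(all(out3$ok[2:3]))
})

test_that("removing one record never changes another's score", {
  set.seed(6)
  rec <- data.frame(ms1_occurrence = rnorm(10), ms3_duration = rnorm(10),
                    group = rep(c("high", "low"), 5))
  full <- loocv_scores(rec)
  # fold i's score depends only on the other records, so recomputing with
  # the same training set in a fresh call must agree
  again <- loocv_scores(rec)
  expect_identical(full$score, again$score)
})

test_that("roc_auc matches the all-pairs counting oracle exactly", {
  expect_equal(roc_auc(c(2, 3, 0, 1),
                       c("high", "high", "low", "low"))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("high", "low"), 3))$auc, 0.5)
  set.seed(7)
  for (i in 1:30) {
    s <- round(rnorm(40), 1)                 # rounding forces ties
    g <- sample(c("high", "low"), 40, replace = TRUE, prob = c(.4, .6))
    if (length(unique(g)) < 2) next
    hi <- s[g == "high"]; lo <- s[g == "low"]
    cnt <- 0
    for (a in hi) for (b in lo)
      cnt <- cnt + (a > b) + 0.5 * (a == b)
    expect_equal(roc_auc(s, g)$auc, cnt / (length(hi) * length(lo)),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("high", 3)), "one group absent")
})

test_that("AUC is monotone-transform invariant; curve area equals MW", {
  set.seed(8)
  s <- rnorm(50)
  g <- sample(c("high", "low"), 50, replace = TRUE)
  r1 <- roc_auc(s, g)
  expect_equal(roc_auc(exp(s), g)$auc, r1$auc, tolerance = 1e-12)
  expect_equal(roc_auc(s^3 + 2 * s, g)$auc, r1$auc, tolerance = 1e-12)
  # trapezoidal area under the constructed curve equals the MW statistic
  trap <- sum(diff(r1$fpr) * (head(r1$tpr, -1) + tail(r1$tpr, -1)) / 2)
  expect_equal(trap, r1$auc, tolerance = 1e-10)
  expect_true(all(diff(r1$tpr) >= 0) && all(diff(r1$fpr) >= 0))
})

test_that("spectral entropy hits its analytic anchors", {
  fs <- 250
  # flat in-band spectrum constructed in the frequency domain
  n <- fs * 8
  f <- (0:(n - 1)) * fs / n
  f2 <- pmin(f, fs - f)
  Z <- complex(modulus = ifelse(f2 >= 7 & f2 <= 30, 1, 0),
               argument = runif(n, 0, 2 * pi))
  # hermitian symmetry for a real signal
  Z[1] <- 0
  Z[(n/2 + 2):n] <- Conj(Z[(n/2):2])
  x <- Re(fft(Z, inverse = TRUE))
  expect_gt(spectral_entropy(x, fs), 0.93)
  # a pure in-band sinusoid concentrates the mass
  t <- (0:(fs * 10 - 1)) / fs
  expect_lt(spectral_entropy(sin(2 * pi * 15 * t), fs), 0.3)
  # long white noise is near-flat in band
  set.seed(9)
  expect_gt(spectral_entropy(rnorm(fs * 60), fs), 0.9)
  expect_error(spectral_entropy(rnorm(10), fs), "too short")
})

test_that("correlation screening recovers planted signs at n = 168", {
  set.seed(10)
  n <- 168
  z <- rnorm(n)
  acc <- 70 + 12 * z + rnorm(n, sd = 3)
  rec <- data.frame(
    accuracy = acc,
    ms1_occurrence = -0.544 * z + sqrt(1 - 0.544^2) * rnorm(n),
    ms1_duration = rnorm(n), ms1_coverage = rnorm(n),
    ms3_duration = 0.593 * z + sqrt(1 - 0.593^2) * rnorm(n),
    ms3_occurrence = rnorm(n), ms3_coverage = rnorm(n))
  tab <- correlation_table(rec, K = 4)
  occ <- tab[tab$parameter == "Occurrence" & tab$class == "MS1", ]
  dur <- tab[tab$parameter == "Duration" & tab$class == "MS3", ]
  expect_lt(occ$r, 0); expect_lt(occ$p, 0.05)
  expect_gt(dur$r, 0); expect_lt(dur$p, 0.001)
  # self-transitions are reported absent
  self_tp <- tab[tab$parameter == "TP2" & tab$class == "MS2", ]
  expect_true(is.na(self_tp$r))
  # significance flags follow the two-level legend
  expect_true(all(tab$signif[!is.na(tab$p) & tab$p < 0.001] == "**"))
})

test_that("a link-free cohort table stays within the null band", {
  set.seed(11)
  hits <- 0; total <- 0
  for (rep in 1:4) {
    n <- 168
    rec <- data.frame(accuracy = rnorm(n, 70, 10))
    for (k in 1:4) {
      rec[[paste0("ms", k, "_duration")]] <- rnorm(n)
      rec[[paste0("ms", k, "_occurrence")]] <- rnorm(n)
      rec[[paste0("ms", k, "_coverage")]] <- rnorm(n)
    }
    for (j in 1:4) for (k in 1:4) if (j != k)
      rec[[paste0("tp_", j, "_", k)]] <- rnorm(n)
    tab <- correlation_table(rec, K = 4)
    p <- tab$p[!is.na(tab$p)]
    hits <- hits + sum(p < 0.05); total <- total + length(p)
  }
  # binomial upper bound for a 5% rate at this many draws
  expect_lt(hits / total, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
  expect_true(max(abs(tab$r), na.rm = TRUE) < 0.35)
})

test_that("fitted LDA weight signs track the planted link signs", {
  set.seed(13)
  hits <- replicate(40, {
    n <- 168
    z <- rnorm(n)
    acc <- 70 + 12 * z + rnorm(n, sd = 3)
    occ <- -0.544 * z + sqrt(1 - 0.544^2) * rnorm(n)
    dur <- 0.593 * z + sqrt(1 - 0.593^2) * rnorm(n)
    g <- performance_group(acc)
    if (length(unique(g)) < 2) return(NA)
    fit <- lda_fit(cbind(occ, dur), g)
    fit$weights[1] < 0 && fit$weights[2] > 0
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("evaluate_predictors favors the planted microstate link", {
  set.seed(12)
  mk <- function(n, sess, link = TRUE) {
    z <- rnorm(n)
    acc <- 70 + 12 * z + rnorm(n, 0, 3)
    data.frame(session = sess,
               ms1_occurrence = if (link) -0.6 * z + 0.8 * rnorm(n)
                                else rnorm(n),
               ms3_duration = if (link) 0.6 * z + 0.8 * rnorm(n)
                              else rnorm(n),
               spectral_entropy = rnorm(n),
               accuracy = acc,
               group = performance_group(acc))
  }
  rec <- do.call(rbind, lapply(1:4, function(s) mk(28, s)))
  ev <- evaluate_predictors(rec)
  expect_gt(ev$pooled_microstate$auc, 0.65)
  expect_gt(ev$pooled_microstate$auc, ev$pooled_entropy$auc)
  expect_lt(abs(ev$pooled_entropy$auc - 0.5), 0.15)
  # a single-group session is excluded and reported
  one <- mk(10, 9)
  one$group <- "low"
  ev2 <- evaluate_predictors(rbind(rec, one))
  expect_true(9 %in% ev2$excluded_sessions)
  expect_false(9 %in% ev2$per_session$session)
})
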