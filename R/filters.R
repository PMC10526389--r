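# IIR band-pass design and zero-phase filtering.
#
# No DSP package is assumed: the Butterworth band-pass is designed from the
# analog prototype (poles on the unit semicircle), transformed
# lowpass -> bandpass, and discretized by the bilinear transform with
# frequency pre-warping. Filtering runs forward and backward over
# odd-reflection padding (scipy-style filtfilt), so the net phase is zero.

# Polynomial coefficients (descending powers) from roots, real part taken
# after the complex product; roots come in conjugate pairs.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  Re(p)
}

# Butterworth band-pass (b, a) for prototype order n and edges in Hz.
butter_bandpass <- function(n, low, high, fs) {
  stopifnot(n >= 1, low > 0, high > low, high < fs / 2)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)   # pre-warped analog edges (rad/s)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left-half-plane poles
  # lowpass -> bandpass: each prototype pole spawns two analog poles
  bp <- bw * proto / 2
  disc <- sqrt(bp^2 - w0^2 + 0i)
  poles_a <- c(bp + disc, bp - disc)
  zeros_a <- rep(0 + 0i, n)                          # n zeros at s = 0
  gain_a <- bw^n
  # bilinear transform
  poles_z <- (fs2 + poles_a) / (fs2 - poles_a)
  zeros_z <- (fs2 + zeros_a) / (fs2 - zeros_a)
  zeros_z <- c(zeros_z, rep(-1 + 0i, length(poles_a) - length(zeros_a)))
  gain_z <- Re(gain_a * prod(fs2 - zeros_a) / prod(fs2 - poles_a))
  b <- gain_z * poly_from_roots(zeros_z)
  a <- poly_from_roots(poles_z)
  list(b = b, a = a)
}

# Single-pass IIR filter y[t] = sum b_j x[t-j] - sum a_j y[t-j] using the
# C-level recursions in stats::filter; x may be a samples x channels matrix
# (both filter methods operate column-wise).
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  x <- as.matrix(x)
  xp <- rbind(matrix(0, nb - 1L, ncol(x)), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- v[nb:nrow(xp), , drop = FALSE]
  if (length(a) > 1) {
    y <- stats::filter(v, -a[-1], method = "recursive")
    matrix(as.numeric(y), nrow(x), ncol(x))
  } else matrix(as.numeric(v), nrow(x), ncol(x))
}

# Zero-phase filtering with odd-reflection edge padding; x is samples x
# channels.
filtfilt_mat <- function(x, b, a) {
  x <- as.matrix(x)
  n <- nrow(x)
  pad <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= pad)
    stop("signal too short (", n, " samples) for zero-phase filtering",
         call. = FALSE)
  pre <- matrix(rep(2 * x[1L, ], each = pad), pad) - x[(pad + 1L):2L, ,
                                                       drop = FALSE]
  post <- matrix(rep(2 * x[n, ], each = pad), pad) -
    x[(n - 1L):(n - pad), , drop = FALSE]
  xx <- rbind(pre, x, post)
  y <- iir_filter(b, a, xx)
  y <- iir_filter(b, a, y[nrow(y):1L, , drop = FALSE])
  y[(nrow(y) - pad):(pad + 1L), , drop = FALSE][seq_len(n), , drop = FALSE]
}

filtfilt_ba <- function(x, b, a) as.numeric(filtfilt_mat(cbind(x), b, a))
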