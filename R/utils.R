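# Internal helpers shared across modules.

# Indices (1-based) of samples whose times fall in the half-open window
# [a, b), for a trace sampled at `fs` with sample i at time (i-1)/fs.
win_idx <- function(fs, a, b, n) {
  eps <- 1e-9
  i0 <- ceiling(a * fs - eps)
  i1 <- ceiling(b * fs - eps) - 1L
  i0 <- max(i0, 0L)
  i1 <- min(i1, n - 1L)
  if (i1 < i0) return(integer(0))
  seq.int(i0, i1) + 1L
}

window_mean <- function(x, fs, a, b) {
  idx <- win_idx(fs, a, b, length(x))
  if (length(idx) == 0L) return(NA_real_)
  mean(x[idx])
}

# State label of each sample time, from an interval table (state, start, end).
state_at <- function(times, seq_tab) {
  i <- findInterval(times, seq_tab$start, rightmost.closed = FALSE)
  i[i < 1L] <- 1L
  i[i > nrow(seq_tab)] <- nrow(seq_tab)
  seq_tab$state[i]
}

# Discrete unit-mass Gaussian kernel (sums to 1), radius 4 sd.
gauss_kernel <- function(fs, sd) {
  half <- max(1L, ceiling(4 * sd * fs))
  tt <- seq.int(-half, half) / fs
  k <- exp(-tt^2 / (2 * sd^2))
  k / sum(k)
}

# FFT-based 'same' convolution with zero padding outside the trace.
conv_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  half <- (m - 1L) %/% 2L
  nf <- stats::nextn(n + m - 1L, factors = c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nf - n)))
  K <- stats::fft(c(k, numeric(nf - m)))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / nf
  y[(half + 1L):(half + n)]
}

gauss_smooth <- function(x, fs, sd) {
  conv_same(x, gauss_kernel(fs, sd))
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
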