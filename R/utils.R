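## Internal numerical helpers.

## Zero-phase Butterworth filtering with odd-reflection padding at both
## ends, so short windows and epochs come out transient-free (the plain
## forward-backward pass leaves large edge artifacts on segments of a few
## hundred samples).
.zerophase <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1L, 36L)
  ext <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- signal::filtfilt(filt = b, a = a, x = ext)
  y[(p + 1L):(p + n)]
}

.butterBand <- function(low, high, rate, order) {
  signal::butter(order, c(low, high) / (rate / 2), type = "pass")
}

## Apply a filter row-wise to a channels x samples matrix.
.filterMatrix <- function(flt, x, causal = FALSE) {
  out <- x
  for (i in seq_len(nrow(x))) {
    out[i, ] <- if (causal)
      as.numeric(signal::filter(flt$b, flt$a, x[i, ]))
    else .zerophase(flt$b, flt$a, x[i, ])
  }
  out
}

## Trace-normalized covariance of a channels x samples matrix (zero-mean
## assumption from band-pass preprocessing).
.traceCov <- function(x) {
  C <- tcrossprod(x) / ncol(x)
  C / sum(diag(C))
}

## Symmetric inverse square root with eigenvalue floor.
.invSqrtm <- function(C, floor = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  d <- pmax(e$values, floor * max(e$values))
  e$vectors %*% diag(1 / sqrt(d), length(d)) %*% t(e$vectors)
}

## Fix eigenvector sign: largest-magnitude component positive.
.fixSigns <- function(V) {
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  V
}

.degToRad <- function(x) x * pi / 180
.radToDeg <- function(x) x * 180 / pi

## Band power of one channel via the periodogram, in [lo, hi] Hz.
.bandPower <- function(x, rate, lo, hi) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))^2 / n
  freqs <- (seq_len(n) - 1) * rate / n
  keep <- freqs <= rate / 2
  sum(spec[keep & freqs >= lo & freqs <= hi])
}

## Ordered channel index lookup with a clear error.
.channelIndex <- function(have, want) {
  idx <- match(want, have)
  if (anyNA(idx))
    stop("channels not present in recording: ",
         paste(want[is.na(idx)], collapse = ", "))
  idx
}
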