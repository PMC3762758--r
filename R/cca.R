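#' @include AllClasses.R
NULL

#' Reference signal block for a CCAReference
#'
#' @param ref a [CCAReference-class].
#' @param startTime reference start offset in seconds (the sin/cos basis
#'   spans all phases, so correlations are invariant to it).
#' @return samples x (2 * nHarmonics) matrix of zero-mean sin/cos columns.
#' @export
referenceMatrix <- function(ref, startTime = 0) {
  n <- round(ref@duration * ref@rate)
  tt <- startTime + (seq_len(n) - 1) / ref@rate
  cols <- lapply(seq_len(ref@nHarmonics), function(h)
    cbind(sin(2 * pi * h * ref@freq * tt), cos(2 * pi * h * ref@freq * tt)))
  Y <- do.call(cbind, cols)
  sweep(Y, 2, colMeans(Y))
}

## First canonical correlation between centered blocks X (n x p) and
## Y (n x q): largest singular value of Sxx^{-1/2} Sxy Syy^{-1/2}, with a
## small trace-scaled ridge on the autocovariances for numerical safety.
.firstCanCor <- function(X, Y, ridge = 1e-9) {
  n <- nrow(X)
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  Sxx <- crossprod(X) / n
  Syy <- crossprod(Y) / n
  Sxy <- crossprod(X, Y) / n
  Sxx <- Sxx + ridge * mean(diag(Sxx)) * diag(ncol(X))
  Syy <- Syy + ridge * mean(diag(Syy)) * diag(ncol(Y))
  K <- .invSqrtm(Sxx) %*% Sxy %*% .invSqrtm(Syy)
  min(max(svd(K)$d[1], 0), 1)
}

#' Canonical correlation of a window with a sinusoidal reference
#'
#' Returns the first canonical correlation between the occipital EEG block
#' (channels O1 and O2 when present, otherwise all channels) and the
#' sin/cos reference block at the stimulus frequency. The value is
#' invariant to invertible linear mixing of the EEG channels and to the
#' reference phase.
#'
#' @param w a [Window-class] (band-passed 4-50 Hz in the decoding pipeline).
#' @param ref a [CCAReference-class] with the window's rate and duration.
#' @return First canonical correlation in \[0, 1\].
#' @export
ccaCorrelation <- function(w, ref) {
  x <- w@data
  occ <- intersect(c("O1", "O2"), w@channelNames)
  if (length(occ) > 0)
    x <- x[.channelIndex(w@channelNames, occ), , drop = FALSE]
  if (any(apply(x, 1, stats::sd) < 1e-12))
    stop("constant channel: zero variance in CCA input")
  .firstCanCor(t(x), referenceMatrix(ref))
}

#' Correlation pair with the two stimulus references
#'
#' Computes the canonical correlations of one window against both stimulus
#' frequencies with identical preprocessing; the pair is the feature the
#' protocol arbiter operates on.
#'
#' @param w a [Window-class].
#' @param freqs the two stimulus frequencies in Hz.
#' @param nHarmonics harmonics per reference (1 in the reference
#'   configuration).
#' @return Named numeric vector `c(rho12 = ..., rho15 = ...)` (names follow
#'   the frequencies).
#' @export
ssvepCorrelationPair <- function(w, freqs = c(12, 15), nHarmonics = 1) {
  dur <- ncol(w@data) / w@rate
  vals <- vapply(freqs, function(f)
    ccaCorrelation(w, CCAReference(f, nHarmonics, w@rate, dur)), numeric(1))
  names(vals) <- paste0("rho", freqs)
  vals
}
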