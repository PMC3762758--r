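#' @include AllClasses.R
NULL

#' Band-pass filter a recording or window
#'
#' Butterworth band-pass filter applied per channel. The default is
#' zero-phase (forward-backward) filtering, which doubles the effective
#' order and leaves no phase distortion; set `causal = TRUE` for a single
#' forward pass as an online system would run. The three bands used by the
#' decoders are 8-30 Hz (motor imagery, mu/beta), 4-50 Hz (SSVEP artifact
#' reduction) and 1-20 Hz (P300 epochs).
#'
#' @param x an [EEGRecording-class] or [Window-class].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < rate/2`.
#' @param order Butterworth order (5, matching the stated SSVEP filter; the
#'   same family is used for every band).
#' @param causal if `TRUE`, single forward pass instead of zero-phase.
#' @return An object of the same class, filtered, same shape.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(14 * 512), 14), rate = 128)
#' filt <- bandpassFilter(rec, 8, 30)
#' dim(eegData(filt))
#' @export
bandpassFilter <- function(x, low, high, order = 5, causal = FALSE) {
  rate <- samplingRate(x)
  if (!(low > 0 && high > low && high < rate / 2))
    stop("band edges must satisfy 0 < low < high < rate/2 (Nyquist ",
         rate / 2, " Hz)")
  flt <- .butterBand(low, high, rate, order)
  filtered <- .filterMatrix(flt, eegData(x), causal = causal)
  if (is(x, "EEGRecording")) {
    initialize(x, data = filtered)
  } else {
    initialize(x, data = filtered)
  }
}

#' Cut sliding analysis windows from a recording
#'
#' Windows of `width` seconds starting at 0, `step`, `2 * step`, ...; only
#' windows that lie fully inside the recording are returned, so the count
#' is `floor((T - width) / step) + 1`. The online system uses 2 s windows
#' with 250 ms increments.
#'
#' @param rec an [EEGRecording-class].
#' @param width window width in seconds.
#' @param step increment between window starts in seconds.
#' @return List of [Window-class] objects (empty, with a warning, when the
#'   recording is shorter than `width`).
#' @examples
#' rec <- EEGRecording(matrix(rnorm(14 * 1280), 14), rate = 128)
#' length(slidingWindows(rec, 2, 0.25))  # 33
#' @export
slidingWindows <- function(rec, width = 2, step = 0.25) {
  stopifnot(step > 0, width > 0)
  rate <- samplingRate(rec)
  total <- nSamples(rec) / rate
  if (width > total) {
    warning("window width exceeds recording duration; no windows produced")
    return(list())
  }
  n <- floor((total - width) / step + 1e-9) + 1
  wlen <- round(width * rate)
  lapply(seq_len(n) - 1, function(k) {
    s0 <- round(k * step * rate)
    Window(eegData(rec)[, (s0 + 1):(s0 + wlen), drop = FALSE],
           rate = rate, channelNames = channelNames(rec),
           startTime = k * step)
  })
}

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per selected event, aligned to the event onset and
#' `floor(span * rate)` samples long (76 samples for the 600 ms P300 epoch
#' at 128 Hz). Events too close to the end of the recording for a full
#' epoch are skipped with a message.
#'
#' @param rec an [EEGRecording-class] with event markers.
#' @param eventCodes character vector of codes to epoch; `NULL` selects all
#'   events.
#' @param span epoch length in seconds from the event onset.
#' @param protocol protocol tag for the returned [TrialSet-class].
#' @param labels optional per-epoch labels; defaults to the event codes.
#' @return A [TrialSet-class] of epochs, one per usable event.
#' @export
extractEpochs <- function(rec, eventCodes = NULL, span = 0.6,
                          protocol = "P300", labels = NULL) {
  ev <- eventTable(rec)
  if (!is.null(eventCodes)) ev <- ev[ev$code %in% eventCodes, , drop = FALSE]
  rate <- samplingRate(rec)
  len <- floor(span * rate)
  keep <- ev$sample + len <= nSamples(rec)
  if (any(!keep))
    message(sum(!keep), " event(s) too close to the recording end; skipped")
  ev <- ev[keep, , drop = FALSE]
  wins <- lapply(seq_len(nrow(ev)), function(i) {
    s0 <- ev$sample[i]
    Window(eegData(rec)[, (s0 + 1):(s0 + len), drop = FALSE], rate = rate,
           channelNames = channelNames(rec), startTime = s0 / rate,
           label = ev$code[i])
  })
  if (is.null(labels)) labels <- ev$code
  TrialSet(wins, protocol = protocol, labels = labels)
}

#' Downsample a trial set
#'
#' Anti-alias filters (zero-phase low-pass at 80% of the target Nyquist)
#' and decimates every window by the integer factor `from/to`. The 76-sample
#' P300 epoch at 128 Hz becomes 19 samples at 32 Hz.
#'
#' @param ts a [TrialSet-class].
#' @param toRate target rate in Hz; the source rate must be an integer
#'   multiple.
#' @return A [TrialSet-class] at the new rate.
#' @export
downsampleTrials <- function(ts, toRate = 32) {
  if (length(ts@windows) == 0) return(ts)
  fromRate <- ts@windows[[1]]@rate
  q <- fromRate / toRate
  if (abs(q - round(q)) > 1e-9)
    stop("source rate ", fromRate, " is not an integer multiple of ", toRate)
  q <- as.integer(round(q))
  if (q == 1L) return(ts)
  lp <- signal::butter(5, 0.8 / q, type = "low")
  wins <- lapply(ts@windows, function(w) {
    x <- w@data
    out <- matrix(0, nrow(x), length(seq(1, ncol(x), by = q)))
    for (i in seq_len(nrow(x)))
      out[i, ] <- .zerophase(lp$b, lp$a, x[i, ])[seq(1, ncol(x), by = q)]
    initialize(w, data = out, rate = toRate)
  })
  initialize(ts, windows = wins)
}
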