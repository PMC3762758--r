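#' @include AllClasses.R
NULL

## Evaluate expr with a locally seeded RNG, restoring global state after.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## One channel of 1/f^alpha noise, zero mean, unit variance. Shaped in the
## frequency domain from a white draw; the DC bin is zeroed.
.colorNoise <- function(n, alpha, rate) {
  white <- stats::rnorm(n)
  if (alpha == 0) {
    x <- white
  } else {
    spec <- stats::fft(white)
    freqs <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * rate / n
    gain <- c(0, freqs[-1]^(-alpha / 2))
    x <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  }
  x <- x - mean(x)
  x / stats::sd(x)
}

.backgroundMatrix <- function(cfg, nSamp) {
  t(vapply(seq_len(cfg@nChannels),
           function(i) .colorNoise(nSamp, cfg@noiseExponent, cfg@rate),
           numeric(nSamp)))
}

#' Generate background EEG noise
#'
#' `1/f^alpha` ("pink" for the default `alpha = 1`) noise, independently per
#' channel, zero mean and unit variance per channel. All generators in this
#' module are bit-reproducible under the configuration seed.
#'
#' @param cfg a [SynthConfig-class].
#' @param duration recording length in seconds.
#' @return An [EEGRecording-class] with no events.
#' @examples
#' bg <- genBackground(SynthConfig(seed = 1), duration = 2)
#' round(apply(eegData(bg), 1, sd), 3)
#' @export
genBackground <- function(cfg, duration) {
  stopifnot(duration > 0)
  .withSeed(cfg@seed, {
    n <- round(duration * cfg@rate)
    EEGRecording(.backgroundMatrix(cfg, n), rate = cfg@rate,
                 channelNames = cfg@channelNames)
  })
}

#' Generate motor-imagery (ERD) trials
#'
#' Emulates the desynchronization contrast: idle trials carry an additive
#' mu-band oscillation (default 10 Hz, random phase per trial) on the
#' sensorimotor-adjacent channels, with amplitude `cfg@snr` relative to the
#' unit-variance background; active (imagery) trials attenuate that
#' oscillation's amplitude by the `attenuation` fraction. The oscillation is
#' additive and not phase-locked, matching the band-power (not evoked)
#' nature of event-related desynchronization.
#'
#' @param cfg a [SynthConfig-class].
#' @param nActive,nIdle trial counts per class (20 each mirrors a training
#'   session of 20 repetitions).
#' @param attenuation fraction in \[0, 1\] by which imagery suppresses the
#'   rhythm's amplitude.
#' @param duration trial length in seconds (2 s analysis windows).
#' @param muFreq rhythm frequency in Hz (mu band, 8-13).
#' @param channels channels carrying the rhythm.
#' @return A [TrialSet-class] with labels `"active"` and `"idle"`.
#' @export
genErdTrials <- function(cfg, nActive = 20, nIdle = 20, attenuation = 0.7,
                         duration = 2, muFreq = 10,
                         channels = c("FC5", "FC6", "F3", "F4")) {
  stopifnot(attenuation >= 0, attenuation <= 1)
  chIdx <- .channelIndex(cfg@channelNames, channels)
  .withSeed(cfg@seed, {
    n <- round(duration * cfg@rate)
    tt <- (seq_len(n) - 1) / cfg@rate
    amp <- cfg@snr * sqrt(2)          # oscillation sd = snr x background sd
    makeTrial <- function(label) {
      x <- .backgroundMatrix(cfg, n)
      scale <- if (label == "active") 1 - attenuation else 1
      phase <- stats::runif(1, 0, 2 * pi)
      osc <- amp * scale * sin(2 * pi * muFreq * tt + phase)
      x[chIdx, ] <- sweep(x[chIdx, , drop = FALSE], 2, osc, "+")
      Window(x, rate = cfg@rate, channelNames = cfg@channelNames,
             label = label)
    }
    labels <- c(rep("active", nActive), rep("idle", nIdle))
    TrialSet(lapply(labels, makeTrial), protocol = "ERD", labels = labels)
  })
}

#' Generate SSVEP trials
#'
#' Adds a sinusoid at the stimulus frequency (random phase per trial, plus
#' an optional weak second harmonic) to the occipital channels O1 and O2, at
#' amplitude `cfg@snr` relative to the unit-variance background.
#'
#' @param cfg a [SynthConfig-class].
#' @param freq stimulus frequency in Hz (12 or 15 for this system); must be
#'   below the Nyquist rate.
#' @param n number of trials.
#' @param duration trial length in seconds.
#' @param harmonic2 relative amplitude of the second harmonic (0 disables).
#' @param channels channels carrying the response.
#' @return A [TrialSet-class] labeled with the frequency (e.g. `"12"`).
#' @export
genSsvepTrials <- function(cfg, freq, n = 20, duration = 2, harmonic2 = 0,
                           channels = c("O1", "O2")) {
  stopifnot(freq < cfg@rate / 2)
  chIdx <- .channelIndex(cfg@channelNames, channels)
  .withSeed(cfg@seed, {
    ns <- round(duration * cfg@rate)
    tt <- (seq_len(ns) - 1) / cfg@rate
    amp <- cfg@snr * sqrt(2)
    wins <- lapply(seq_len(n), function(i) {
      x <- .backgroundMatrix(cfg, ns)
      phase <- stats::runif(1, 0, 2 * pi)
      osc <- amp * sin(2 * pi * freq * tt + phase)
      if (harmonic2 > 0)
        osc <- osc + amp * harmonic2 * sin(2 * pi * 2 * freq * tt + phase)
      x[chIdx, ] <- sweep(x[chIdx, , drop = FALSE], 2, osc, "+")
      Window(x, rate = cfg@rate, channelNames = cfg@channelNames,
             label = as.character(freq))
    })
    TrialSet(wins, protocol = "SSVEP",
             labels = rep(as.character(freq), n))
  })
}

#' Generate a P300 flash stream
#'
#' A continuous recording over a randomized flash schedule: `nObjects`
#' object regions each flash `nFlashesPerObject` times at 250 ms
#' inter-stimulus spacing, in a seed-randomized order with equal counts per
#' object. Epochs following flashes of the favorite object(s) carry the
#' evoked-response template (peak scaled by `cfg@snr`) with optional
#' Gaussian latency jitter. Event markers carry the flashed object id.
#'
#' @param cfg a [SynthConfig-class].
#' @param nObjects number of object regions (>= 2).
#' @param nFlashesPerObject flashes per object (5 in the online protocol).
#' @param favoriteIndex index (or indices) of the favorite object;
#'   `integer(0)` plants no response. Exactly one favorite is the default
#'   semantics.
#' @param template an [ERPTemplate-class]; the planted peak amplitude is
#'   `template@amplitude * cfg@snr`.
#' @param latencyJitterSd standard deviation of peak-latency jitter in s.
#' @param isi inter-stimulus interval in s.
#' @param leadIn quiet time before the first flash in s.
#' @return List with `recording` (an [EEGRecording-class] whose events mark
#'   each flash with its object id) and `schedule` (data.frame of `onset`
#'   seconds and `object` id).
#' @export
genP300Stream <- function(cfg, nObjects = 2, nFlashesPerObject = 5,
                          favoriteIndex = 1, template = ERPTemplate(),
                          latencyJitterSd = 0, isi = 0.25, leadIn = 0.5) {
  stopifnot(nObjects >= 2)
  .withSeed(cfg@seed, {
    nFlash <- nObjects * nFlashesPerObject
    order <- sample(rep(seq_len(nObjects), nFlashesPerObject))
    onsets <- leadIn + (seq_len(nFlash) - 1) * isi
    duration <- leadIn + (nFlash - 1) * isi + 0.6 + 0.2
    n <- round(duration * cfg@rate)
    x <- .backgroundMatrix(cfg, n)
    peakAmp <- template@amplitude * cfg@snr
    for (k in seq_len(nFlash)) {
      if (!(order[k] %in% favoriteIndex) || peakAmp == 0) next
      peak <- template@peakLatency +
        if (latencyJitterSd > 0) stats::rnorm(1, 0, latencyJitterSd) else 0
      tt <- (seq_len(n) - 1) / cfg@rate - onsets[k] - peak
      inside <- abs(tt) <= template@width / 2
      bump <- numeric(n)
      bump[inside] <- peakAmp * cos(pi * tt[inside] / template@width)
      x <- x + template@spatialPattern %o% bump
    }
    events <- data.frame(sample = as.integer(round(onsets * cfg@rate)),
                         code = as.character(order))
    rec <- EEGRecording(x, rate = cfg@rate,
                        channelNames = cfg@channelNames, events = events)
    list(recording = rec,
         schedule = data.frame(onset = onsets, object = order))
  })
}
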