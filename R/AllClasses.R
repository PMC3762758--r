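#' @import methods
NULL

## Standard 14-channel layout of the low-cost headset (10-20 subset).
.EMOTIV_CHANNELS <- c("AF3", "AF4", "F3", "F4", "F7", "F8", "FC5", "FC6",
                      "P7", "P8", "T7", "T8", "O1", "O2")

.PROTOCOLS <- c("ERD", "SSVEP", "P300")
.COMMANDS  <- c("HEAD_LEFT", "HEAD_RIGHT", "ERD_SWITCH", "NONE")
.MODES     <- c("NAV_IDLE", "WALKING", "ALIGNING", "RECOGNITION")

#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG time series: a channels x
#' samples matrix in microvolts, the sampling rate in Hz, ordered channel
#' labels, and a table of event markers. Sample indices are 0-based
#' throughout the package.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot rate sampling rate in samples/s (128 for the target headset).
#' @slot channelNames unique channel labels, one per row of `data`.
#' @slot events data.frame with integer column `sample` (0-based, within
#'   the recording) and character column `code`.
#'
#' @seealso [EEGRecording()], [bandpassFilter()], [slidingWindows()],
#'   [extractEpochs()]
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(data = "matrix", rate = "numeric",
                 channelNames = "character", events = "data.frame"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "number of channel names must equal number of data rows")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  ev <- object@events
  if (!all(c("sample", "code") %in% names(ev)))
    msg <- c(msg, "events must have columns 'sample' and 'code'")
  else if (nrow(ev) > 0 &&
           (any(ev$sample < 0) || any(ev$sample >= ncol(object@data))))
    msg <- c(msg, "event sample indices must lie in [0, n_samples)")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param rate sampling rate in Hz.
#' @param channelNames character vector of unique channel labels; defaults
#'   to the 14-channel 10-20 subset of the low-cost headset when the matrix
#'   has 14 rows, otherwise `"ch1"`, `"ch2"`, ...
#' @param events data.frame with 0-based integer `sample` and character
#'   `code` columns; defaults to no events.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(14 * 256), 14), rate = 128)
#' nChannels(rec)
#' @export
EEGRecording <- function(data, rate = 128,
                         channelNames = NULL, events = NULL) {
  data <- as.matrix(data)
  dimnames(data) <- NULL
  if (is.null(channelNames)) {
    channelNames <- if (nrow(data) == 14L) .EMOTIV_CHANNELS
                    else paste0("ch", seq_len(nrow(data)))
  }
  if (is.null(events))
    events <- data.frame(sample = integer(), code = character())
  events$sample <- as.integer(events$sample)
  events$code <- as.character(events$code)
  new("EEGRecording", data = data, rate = as.numeric(rate),
      channelNames = as.character(channelNames), events = events)
}

#' Fixed-length EEG window
#'
#' A single analysis window cut from a recording: the 2 s / 250 ms-increment
#' sliding windows used online, or a stimulus-locked epoch. The half-open
#' convention `[start, start + duration)` applies.
#'
#' @slot data channels x samples numeric matrix.
#' @slot rate sampling rate in Hz of the source recording.
#' @slot channelNames channel labels (same order as the source).
#' @slot startTime window start in seconds from the start of the source.
#' @slot label optional class tag (`NA_character_` when unlabeled).
#' @exportClass Window
setClass("Window",
  representation(data = "matrix", rate = "numeric",
                 channelNames = "character", startTime = "numeric",
                 label = "character"))

setValidity("Window", function(object) {
  msg <- character()
  if (object@rate <= 0) msg <- c(msg, "rate must be positive")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "channel names must match data rows")
  if (length(object@label) != 1L) msg <- c(msg, "label must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a Window
#'
#' @param data channels x samples matrix.
#' @param rate sampling rate (Hz).
#' @param channelNames channel labels.
#' @param startTime start time in seconds.
#' @param label optional class tag.
#' @return A [Window-class] object.
#' @export
Window <- function(data, rate, channelNames = NULL, startTime = 0,
                   label = NA_character_) {
  data <- as.matrix(data)
  dimnames(data) <- NULL
  if (is.null(channelNames)) {
    channelNames <- if (nrow(data) == 14L) .EMOTIV_CHANNELS
                    else paste0("ch", seq_len(nrow(data)))
  }
  new("Window", data = data, rate = as.numeric(rate),
      channelNames = as.character(channelNames),
      startTime = as.numeric(startTime), label = as.character(label))
}

#' Labeled trial collection for one protocol
#'
#' A set of equally shaped [Window-class] objects with per-trial class
#' labels, tagged with the decoding protocol they feed (ERD, SSVEP or P300).
#'
#' @slot windows list of [Window-class] objects, all with identical shape.
#' @slot protocol one of `"ERD"`, `"SSVEP"`, `"P300"`.
#' @slot labels per-window class tags.
#' @exportClass TrialSet
setClass("TrialSet",
  representation(windows = "list", protocol = "character",
                 labels = "character"))

setValidity("TrialSet", function(object) {
  msg <- character()
  if (!(object@protocol %in% .PROTOCOLS))
    msg <- c(msg, sprintf("protocol must be one of %s",
                          paste(.PROTOCOLS, collapse = ", ")))
  if (length(object@windows) != length(object@labels))
    msg <- c(msg, "one label per window required")
  if (length(object@windows) > 0) {
    dims <- vapply(object@windows, function(w) dim(w@data), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      msg <- c(msg, "all windows must have the same shape")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TrialSet
#'
#' @param windows list of [Window-class] objects of identical shape.
#' @param protocol `"ERD"`, `"SSVEP"` or `"P300"`.
#' @param labels per-window class labels; defaults to each window's own
#'   label slot.
#' @return A [TrialSet-class] object.
#' @export
TrialSet <- function(windows, protocol, labels = NULL) {
  if (is.null(labels))
    labels <- vapply(windows, function(w) w@label, character(1))
  new("TrialSet", windows = windows, protocol = protocol,
      labels = as.character(labels))
}

#' Fitted Common Spatial Patterns model
#'
#' Spatial filters maximizing the band-power ratio between two motor-imagery
#' classes, obtained from the generalized eigenproblem of the two mean class
#' covariances. The first `m` filters maximize active-class variance, the
#' last `m` maximize idle-class variance.
#'
#' @slot filters channels x 2m matrix of spatial filter vectors (columns).
#' @slot patterns channels x 2m matrix of corresponding forward activation
#'   patterns.
#' @slot m filter pairs per extreme (2 in the reference configuration).
#' @slot eigenvalues whitened-problem eigenvalues of the retained filters
#'   (active-class variance share, descending then ascending).
#' @slot covActive,covIdle mean class covariance matrices.
#' @slot band analysis band in Hz (8-30 for the mu/beta range).
#' @slot channelNames channel order the filters apply to.
#' @exportClass CSPModel
setClass("CSPModel",
  representation(filters = "matrix", patterns = "matrix", m = "integer",
                 eigenvalues = "numeric", covActive = "matrix",
                 covIdle = "matrix", band = "numeric",
                 channelNames = "character"))

#' Linear max-margin classifier over CSP features
#'
#' Weight/bias form of a linear-kernel support-vector classifier; the
#' decision value `w . f + b` is positive for the first class.
#'
#' @slot weights feature weights.
#' @slot bias intercept.
#' @slot classes the two class labels, positive-decision class first.
#' @exportClass ERDClassifier
setClass("ERDClassifier",
  representation(weights = "numeric", bias = "numeric",
                 classes = "character"))

#' Sinusoidal reference set for SSVEP canonical correlation
#'
#' Defines the reference block: sine and cosine at the stimulus frequency
#' and optionally its harmonics, sampled over one analysis window.
#'
#' @slot freq stimulus frequency in Hz (12 or 15 for this system).
#' @slot nHarmonics number of harmonics (1 in the reference configuration).
#' @slot rate sampling rate in Hz.
#' @slot duration window duration in seconds.
#' @exportClass CCAReference
setClass("CCAReference",
  representation(freq = "numeric", nHarmonics = "integer",
                 rate = "numeric", duration = "numeric"))

setValidity("CCAReference", function(object) {
  if (object@freq <= 0 || object@freq >= object@rate / 2)
    "freq must lie in (0, rate/2)" else TRUE
})

#' Construct a CCAReference
#'
#' @param freq stimulus frequency in Hz.
#' @param nHarmonics number of harmonics in the reference block.
#' @param rate sampling rate in Hz.
#' @param duration reference/window duration in seconds.
#' @return A [CCAReference-class] object.
#' @export
CCAReference <- function(freq, nHarmonics = 1, rate = 128, duration = 2) {
  new("CCAReference", freq = as.numeric(freq),
      nHarmonics = as.integer(nHarmonics), rate = as.numeric(rate),
      duration = as.numeric(duration))
}

#' Fitted xDAWN spatial filter model
#'
#' Three spatial filters maximizing the ratio of evoked-response power to
#' total signal power, used to project P300 epochs onto a 3-dimensional
#' subspace before classification.
#'
#' @slot filters channels x nComponents matrix of spatial filters.
#' @slot patterns channels x nComponents forward activation patterns.
#' @slot eigenvalues generalized eigenvalues (signal-to-signal-plus-noise
#'   ratios), decreasing.
#' @slot epochSamples epoch length in samples the filters were fit on.
#' @slot rate sampling rate of the fitted epochs (32 Hz after decimation).
#' @slot band preprocessing band in Hz (1-20).
#' @slot channelNames channel order the filters apply to.
#' @exportClass XdawnModel
setClass("XdawnModel",
  representation(filters = "matrix", patterns = "matrix",
                 eigenvalues = "numeric", epochSamples = "integer",
                 rate = "numeric", band = "numeric",
                 channelNames = "character"))

#' Bayesian linear discriminant model
#'
#' Posterior-mean weight vector of Bayesian linear regression onto class
#' targets, with prior precision `alpha` and noise precision `beta` set by
#' evidence maximization. Equivalent to ridge regression with penalty
#' `alpha/beta` when the hyperparameters are held fixed.
#'
#' @slot weights weight vector; the last element multiplies the constant 1
#'   (bias).
#' @slot alpha prior precision.
#' @slot beta noise precision.
#' @slot evidence log marginal likelihood trace over update iterations.
#' @slot converged logical, whether the update loop converged.
#' @exportClass BLDAModel
setClass("BLDAModel",
  representation(weights = "numeric", alpha = "numeric", beta = "numeric",
                 evidence = "numeric", converged = "logical"))

#' Protocol arbiter in canonical-correlation space
#'
#' Decision functions over the pair of canonical correlations with the 12 Hz
#' and 15 Hz references: a quadratic boundary separating the motor-imagery
#' region E from the visual-stimulus region S, and a linear boundary inside
#' S separating left from right. Stored as plain kernel expansions so the
#' model serializes to JSON and predicts without the fitting library.
#'
#' @slot quadSV support vectors of the quadratic E-vs-S boundary.
#' @slot quadCoefs kernel expansion coefficients.
#' @slot quadRho decision offset.
#' @slot quadGamma,quadCoef0 polynomial kernel parameters (degree 2).
#' @slot quadPositive region label carried by positive decision values.
#' @slot linWeights,linBias linear boundary inside S.
#' @slot linPositive region (`"S_l"` or `"S_r"`) for positive values.
#' @exportClass SelectorModel
setClass("SelectorModel",
  representation(quadSV = "matrix", quadCoefs = "numeric",
                 quadRho = "numeric", quadGamma = "numeric",
                 quadCoef0 = "numeric", quadPositive = "character",
                 linWeights = "numeric", linBias = "numeric",
                 linPositive = "character"))

#' Fading-feedback confirmation state
#'
#' State of the counter-based command confirmation rule: the current
#' command candidate and its selection level (0-4). A command is confirmed
#' only when the level reaches 4, i.e. after at least five consistent
#' classifications at 250 ms spacing (1 s).
#'
#' @slot candidate current candidate command, `NA_character_` when empty.
#' @slot level selection level, integer in 0-4.
#' @exportClass FadingState
setClass("FadingState",
  representation(candidate = "character", level = "integer"))

setValidity("FadingState", function(object) {
  msg <- character()
  if (object@level < 0L || object@level > 4L)
    msg <- c(msg, "level must lie in 0..4")
  if (is.na(object@candidate) && object@level != 0L)
    msg <- c(msg, "empty candidate requires level 0")
  if (!is.na(object@candidate) && !(object@candidate %in% .COMMANDS))
    msg <- c(msg, "candidate must be a known command")
  if (length(msg)) msg else TRUE
})

#' Construct an (empty) FadingState
#'
#' @param candidate candidate command or `NA` for the empty state.
#' @param level selection level in 0-4.
#' @return A [FadingState-class] object.
#' @export
FadingState <- function(candidate = NA_character_, level = 0L) {
  new("FadingState", candidate = as.character(candidate),
      level = as.integer(level))
}

#' Simulated humanoid surrogate state
#'
#' Pose and mode of the simulated robot: arena-frame position in cm, body
#' heading and head offset in degrees (positive = leftward /
#' counter-clockwise from above), and one of four modes. Walking advances
#' at 3.3 cm/s; body turns run at 0.13 rad/s.
#'
#' @slot position (x, y) in cm.
#' @slot bodyHeading body heading in degrees.
#' @slot headOffset head angle relative to the body in degrees.
#' @slot mode one of `"NAV_IDLE"`, `"WALKING"`, `"ALIGNING"`,
#'   `"RECOGNITION"`.
#' @slot walkSpeed cm/s.
#' @slot turnSpeed rad/s.
#' @slot headLimit maximum |head offset| in degrees.
#' @exportClass RobotState
setClass("RobotState",
  representation(position = "numeric", bodyHeading = "numeric",
                 headOffset = "numeric", mode = "character",
                 walkSpeed = "numeric", turnSpeed = "numeric",
                 headLimit = "numeric"))

setValidity("RobotState", function(object) {
  msg <- character()
  if (!(object@mode %in% .MODES)) msg <- c(msg, "unknown mode")
  if (abs(object@headOffset) > object@headLimit + 1e-9)
    msg <- c(msg, "head offset exceeds configured limit")
  if (length(object@position) != 2L) msg <- c(msg, "position must be (x, y)")
  if (length(msg)) msg else TRUE
})

#' Construct a RobotState
#'
#' @param position (x, y) position in cm.
#' @param bodyHeading heading in degrees (0 = +x axis, counter-clockwise).
#' @param headOffset head angle relative to body in degrees.
#' @param mode robot mode.
#' @param walkSpeed walking speed in cm/s.
#' @param turnSpeed turning speed in rad/s.
#' @param headLimit maximum |head offset| in degrees.
#' @return A [RobotState-class] object.
#' @export
RobotState <- function(position = c(0, 0), bodyHeading = 90,
                       headOffset = 0, mode = "NAV_IDLE",
                       walkSpeed = 3.3, turnSpeed = 0.13, headLimit = 90) {
  new("RobotState", position = as.numeric(position),
      bodyHeading = as.numeric(bodyHeading),
      headOffset = as.numeric(headOffset), mode = mode,
      walkSpeed = as.numeric(walkSpeed), turnSpeed = as.numeric(turnSpeed),
      headLimit = as.numeric(headLimit))
}

#' Rectangular maze arena
#'
#' A 150 x 300 cm rectangular arena with wall segments (the border plus any
#' internal walls) and colored object placements on the walls.
#'
#' @slot width,height arena extent in cm.
#' @slot walls n x 4 matrix of wall segments (x1, y1, x2, y2) in cm.
#' @slot objects data.frame with columns `x`, `y`, `colorId`.
#' @exportClass Arena
setClass("Arena",
  representation(width = "numeric", height = "numeric", walls = "matrix",
                 objects = "data.frame"))

#' Construct an Arena
#'
#' @param width,height arena extent in cm (defaults 150 x 300).
#' @param innerWalls optional n x 4 matrix of internal wall segments.
#' @param objects data.frame with columns `x`, `y`, `colorId`; default none.
#' @return An [Arena-class] object with the border walls included.
#' @export
Arena <- function(width = 150, height = 300, innerWalls = NULL,
                  objects = NULL) {
  border <- rbind(c(0, 0, width, 0), c(width, 0, width, height),
                  c(width, height, 0, height), c(0, height, 0, 0))
  walls <- if (is.null(innerWalls)) border else rbind(border, innerWalls)
  if (is.null(objects))
    objects <- data.frame(x = numeric(), y = numeric(), colorId = integer())
  new("Arena", width = as.numeric(width), height = as.numeric(height),
      walls = walls, objects = objects)
}

#' Cross-validation result
#'
#' @slot folds per-fold accuracies.
#' @slot mean mean accuracy.
#' @slot sd sample standard deviation over folds.
#' @exportClass CVResult
setClass("CVResult",
  representation(folds = "numeric", mean = "numeric", sd = "numeric"))

#' Navigation performance metrics
#'
#' The metric set used to score a maze run: total time, travelled distance,
#' forward and turning step counts, accumulated head-exploration angle,
#' navigation/exploration transitions, and wall collisions.
#'
#' @slot totalTime seconds.
#' @slot distance cm travelled while walking.
#' @slot forwardSteps forward strides (3.3 cm each).
#' @slot turningSteps body-turn steps (0.13 rad each).
#' @slot exploredAngle summed |head rotation| in radians.
#' @slot transitions navigation/exploration mode changes.
#' @slot collisions wall contacts.
#' @exportClass NavMetrics
setClass("NavMetrics",
  representation(totalTime = "numeric", distance = "numeric",
                 forwardSteps = "numeric", turningSteps = "numeric",
                 exploredAngle = "numeric", transitions = "numeric",
                 collisions = "numeric"))

setValidity("NavMetrics", function(object) {
  vals <- c(object@totalTime, object@distance, object@forwardSteps,
            object@turningSteps, object@exploredAngle, object@transitions,
            object@collisions)
  if (any(vals < 0)) "all metrics must be non-negative" else TRUE
})

#' Construct a NavMetrics record
#'
#' @param totalTime,distance,forwardSteps,turningSteps,exploredAngle,transitions,collisions
#'   metric values, see [NavMetrics-class].
#' @return A [NavMetrics-class] object.
#' @export
NavMetrics <- function(totalTime = 0, distance = 0, forwardSteps = 0,
                       turningSteps = 0, exploredAngle = 0,
                       transitions = 0, collisions = 0) {
  new("NavMetrics", totalTime = totalTime, distance = distance,
      forwardSteps = forwardSteps, turningSteps = turningSteps,
      exploredAngle = exploredAngle, transitions = transitions,
      collisions = collisions)
}

#' Synthetic EEG generator configuration
#'
#' @slot rate sampling rate in Hz.
#' @slot nChannels channel count (14 for the headset layout).
#' @slot channelNames channel labels.
#' @slot noiseExponent spectral slope alpha of the 1/f^alpha background
#'   (1 = pink).
#' @slot snr linear amplitude ratio of planted signal to unit-variance
#'   background.
#' @slot seed integer seed; identical seeds give bit-identical output.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(rate = "numeric", nChannels = "integer",
                 channelNames = "character", noiseExponent = "numeric",
                 snr = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@rate <= 0) msg <- c(msg, "rate must be positive")
  if (object@snr < 0) msg <- c(msg, "snr must be non-negative")
  if (length(object@channelNames) != object@nChannels)
    msg <- c(msg, "channelNames must match nChannels")
  if (length(msg)) msg else TRUE
})

#' Construct a SynthConfig
#'
#' @param rate sampling rate (Hz).
#' @param nChannels number of channels.
#' @param channelNames channel labels; defaults to the headset layout for
#'   14 channels.
#' @param noiseExponent background spectral slope (1 = pink noise).
#' @param snr linear signal-to-noise amplitude ratio.
#' @param seed integer random seed.
#' @return A [SynthConfig-class] object.
#' @export
SynthConfig <- function(rate = 128, nChannels = 14, channelNames = NULL,
                        noiseExponent = 1, snr = 1, seed = 1L) {
  if (is.null(channelNames)) {
    channelNames <- if (nChannels == 14L) .EMOTIV_CHANNELS
                    else paste0("ch", seq_len(nChannels))
  }
  new("SynthConfig", rate = as.numeric(rate),
      nChannels = as.integer(nChannels),
      channelNames = as.character(channelNames),
      noiseExponent = as.numeric(noiseExponent), snr = as.numeric(snr),
      seed = as.integer(seed))
}

#' Parametric evoked-response template
#'
#' Positive half-cosine bump used to plant P300-like deflections: peak at
#' `peakLatency` seconds after stimulus onset, total width `width`, scaled
#' by `amplitude` and distributed over channels by a unit-norm spatial
#' pattern (largest over the parietal sites P7/P8).
#'
#' @slot peakLatency peak time after stimulus onset in s (default 0.30).
#' @slot width bump width in s.
#' @slot amplitude peak amplitude in microvolts (relative to unit-variance
#'   background).
#' @slot spatialPattern unit-norm per-channel gain vector.
#' @exportClass ERPTemplate
setClass("ERPTemplate",
  representation(peakLatency = "numeric", width = "numeric",
                 amplitude = "numeric", spatialPattern = "numeric"))

setValidity("ERPTemplate", function(object) {
  msg <- character()
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (abs(sqrt(sum(object@spatialPattern^2)) - 1) > 1e-6)
    msg <- c(msg, "spatial pattern must have unit norm")
  if (length(msg)) msg else TRUE
})

#' Construct an ERPTemplate
#'
#' @param peakLatency peak latency in seconds.
#' @param width bump width in seconds.
#' @param amplitude peak amplitude (microvolts).
#' @param spatialPattern per-channel gain vector (normalized internally);
#'   defaults to a parietal-dominant pattern over the 14-channel layout.
#' @param channelNames channel labels used to build the default pattern.
#' @return An [ERPTemplate-class] object.
#' @export
ERPTemplate <- function(peakLatency = 0.30, width = 0.2, amplitude = 1,
                        spatialPattern = NULL,
                        channelNames = .EMOTIV_CHANNELS) {
  if (is.null(spatialPattern)) {
    spatialPattern <- rep(0.15, length(channelNames))
    spatialPattern[channelNames %in% c("P7", "P8")] <- 1
  }
  spatialPattern <- spatialPattern / sqrt(sum(spatialPattern^2))
  new("ERPTemplate", peakLatency = as.numeric(peakLatency),
      width = as.numeric(width), amplitude = as.numeric(amplitude),
      spatialPattern = as.numeric(spatialPattern))
}

#' The closed command enumeration
#'
#' @return Character vector of the four commands the hybrid decoder can
#'   emit: `"HEAD_LEFT"`, `"HEAD_RIGHT"`, `"ERD_SWITCH"`, `"NONE"`.
#' @export
bciCommands <- function() .COMMANDS

#' The standard 14-channel layout
#'
#' @return Channel labels of the low-cost headset's 10-20 subset, in
#'   recording order.
#' @export
emotivChannels <- function() .EMOTIV_CHANNELS
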