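#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname accessors
setMethod("eegData", "Window", function(x) x@data)
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@rate)
#' @rdname accessors
setMethod("samplingRate", "Window", function(x) x@rate)
#' @rdname accessors
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)
#' @rdname accessors
setMethod("channelNames", "Window", function(x) x@channelNames)
#' @rdname accessors
setMethod("eventTable", "EEGRecording", function(x) x@events)
#' @rdname accessors
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nChannels", "Window", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))
#' @rdname accessors
setMethod("nSamples", "Window", function(x) ncol(x@data))
#' @rdname accessors
setMethod("recordingDuration", "EEGRecording",
          function(x) ncol(x@data) / x@rate)
#' @rdname accessors
setMethod("trialWindows", "TrialSet", function(x) x@windows)
#' @rdname accessors
setMethod("trialLabels", "TrialSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("length", "TrialSet", function(x) length(x@windows))

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples at %g Hz (%.2f s), %d events\n",
              nrow(object@data), ncol(object@data), object@rate,
              ncol(object@data) / object@rate, nrow(object@events)))
  cat("  channels:", paste(object@channelNames, collapse = " "), "\n")
})

setMethod("show", "Window", function(object) {
  cat(sprintf("Window: %d channels x %d samples at %g Hz, start %.3f s, label %s\n",
              nrow(object@data), ncol(object@data), object@rate,
              object@startTime, object@label))
})

setMethod("show", "TrialSet", function(object) {
  tab <- table(object@labels)
  cat(sprintf("TrialSet (%s): %d windows", object@protocol,
              length(object@windows)))
  if (length(tab))
    cat(" [", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "]", sep = "")
  cat("\n")
})

setMethod("show", "CSPModel", function(object) {
  cat(sprintf("CSPModel: %d spatial filters (m = %d) over %d channels, band %g-%g Hz\n",
              ncol(object@filters), object@m, nrow(object@filters),
              object@band[1], object@band[2]))
  cat("  whitened eigenvalues:",
      paste(sprintf("%.3f", object@eigenvalues), collapse = " "), "\n")
})

setMethod("show", "XdawnModel", function(object) {
  cat(sprintf("XdawnModel: %d filters over %d channels, epochs of %d samples at %g Hz\n",
              ncol(object@filters), nrow(object@filters),
              object@epochSamples, object@rate))
})

setMethod("show", "BLDAModel", function(object) {
  cat(sprintf("BLDAModel: %d weights (incl. bias), alpha = %.4g, beta = %.4g, %s after %d evidence updates\n",
              length(object@weights), object@alpha, object@beta,
              if (object@converged) "converged" else "not converged",
              length(object@evidence)))
})

setMethod("show", "SelectorModel", function(object) {
  cat(sprintf("SelectorModel: quadratic E/S boundary (%d support vectors), linear %s/%s split\n",
              nrow(object@quadSV),
              object@linPositive,
              setdiff(c("S_l", "S_r"), object@linPositive)))
})

setMethod("show", "FadingState", function(object) {
  cat(sprintf("FadingState: candidate %s, level %d\n",
              object@candidate, object@level))
})

setMethod("show", "RobotState", function(object) {
  cat(sprintf("RobotState: (%.1f, %.1f) cm, body %.1f deg, head %+.1f deg, mode %s\n",
              object@position[1], object@position[2], object@bodyHeading,
              object@headOffset, object@mode))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: mean accuracy %.3f (sd %.3f) over %d folds\n",
              object@mean, object@sd, length(object@folds)))
})

setMethod("show", "NavMetrics", function(object) {
  cat(sprintf(paste0("NavMetrics: %.1f s, %.1f cm, %g forward / %g turning steps, ",
                     "%.3f rad explored, %g transitions, %g collisions\n"),
              object@totalTime, object@distance, object@forwardSteps,
              object@turningSteps, object@exploredAngle,
              object@transitions, object@collisions))
})
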