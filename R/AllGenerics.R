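#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics over the package's S4 classes: `eegData` returns
#' the channels x samples matrix, `samplingRate` the rate in Hz,
#' `channelNames` the ordered channel labels, `eventTable` the event marker
#' data.frame, `nChannels`/`nSamples` the matrix dimensions,
#' `recordingDuration` the length in seconds, `trialWindows` the list of
#' windows in a [TrialSet-class] and `trialLabels` their class tags.
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("recordingDuration",
           function(x) standardGeneric("recordingDuration"))

#' @rdname accessors
#' @export
setGeneric("trialWindows", function(x) standardGeneric("trialWindows"))

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
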