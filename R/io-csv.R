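#' @include AllClasses.R
NULL

.eventSidecar <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_events.csv")
}

#' Read and write recordings
#'
#' Two on-disk formats are supported. `"csv"`: a delimited-text file whose
#' header row holds a `time_s` column plus one column per channel, with
#' event markers in a two-column sidecar file (`sample`, `code`) named
#' `<stem>_events.csv`. `"edf"`: a 16-bit European Data Format file (one
#' data record per second; events again in the sidecar, since the base EDF
#' layout carries no annotations). A write-then-read round trip preserves
#' channel names, rate and events exactly, and sample values to the format
#' precision (exact for CSV, quantized to the 16-bit range for EDF).
#'
#' @param rec an [EEGRecording-class] (for writing).
#' @param path file path; the format is inferred from the `.csv`/`.edf`
#'   extension when `format` is `NULL`.
#' @param format `"csv"`, `"edf"`, or `NULL` to infer.
#' @return `readRecording` returns an [EEGRecording-class];
#'   `writeRecording` invisibly returns `path`.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(14 * 256), 14), rate = 128)
#' f <- tempfile(fileext = ".csv")
#' writeRecording(rec, f)
#' rec2 <- readRecording(f)
#' all.equal(eegData(rec), eegData(rec2))
#' @export
writeRecording <- function(rec, path, format = NULL) {
  format <- .ioFormat(path, format)
  if (format == "csv") {
    df <- data.frame(time_s = (seq_len(nSamples(rec)) - 1) / samplingRate(rec))
    mat <- t(eegData(rec))
    colnames(mat) <- channelNames(rec)
    utils::write.csv(cbind(df, mat), path, row.names = FALSE)
  } else {
    .writeEDF(rec, path)
  }
  utils::write.csv(eventTable(rec), .eventSidecar(path), row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path, format = NULL) {
  format <- .ioFormat(path, format)
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- if (format == "csv") .readCSVRecording(path) else .readEDF(path)
  sidecar <- .eventSidecar(path)
  if (file.exists(sidecar)) {
    ev <- utils::read.csv(sidecar, colClasses = c("integer", "character"))
    names(ev) <- c("sample", "code")
    rec <- initialize(rec, events = ev)
  }
  rec
}

.ioFormat <- function(path, format) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("csv", "edf"))
  format
}

.readCSVRecording <- function(path) {
  fields <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(fields)) > 1) {
    bad <- which(fields != fields[1])[1]
    stop("malformed CSV ", path, ": row ", bad, " has ", fields[bad],
         " fields, expected ", fields[1])
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("time_s" %in% names(df)))
    stop("malformed CSV ", path, ": missing 'time_s' column")
  t <- df$time_s
  rate <- if (length(t) > 1) 1 / stats::median(diff(t)) else 128
  chans <- setdiff(names(df), "time_s")
  EEGRecording(t(as.matrix(df[chans])), rate = round(rate, 6),
               channelNames = chans)
}
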