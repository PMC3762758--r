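## Minimal 16-bit EDF reader/writer: fixed-width ASCII header (256 bytes
## plus 256 per signal) followed by little-endian int16 data records of one
## second each. Self-contained because no EDF package ships with the
## supported R stack; the layout follows the published EDF field table.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

.writeEDF <- function(rec, path) {
  x <- eegData(rec)
  nc <- nrow(x)
  rate <- samplingRate(rec)
  spr <- as.integer(round(rate))            # samples per 1 s record
  nrec <- ceiling(ncol(x) / spr)
  if (nrec * spr > ncol(x)) {               # pad final record with zeros
    x <- cbind(x, matrix(0, nc, nrec * spr - ncol(x)))
  }
  physMin <- apply(x, 1, min)
  physMax <- apply(x, 1, max)
  flat <- physMax - physMin < 1e-12
  physMax[flat] <- physMin[flat] + 1        # avoid a degenerate scale
  digMin <- -32768L; digMax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(.edfPad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)                                 # version
  wr("synthetic subject", 80)                # patient id
  wr("hybridBCI recording", 80)              # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)       # start date/time
  wr(256L * (nc + 1L), 8)                    # header byte count
  wr("", 44)                                 # reserved
  wr(nrec, 8)
  wr("1", 8)                                 # record duration (s)
  wr(nc, 4)
  for (lab in channelNames(rec)) wr(lab, 16)
  for (i in seq_len(nc)) wr("", 80)          # transducer
  for (i in seq_len(nc)) wr("uV", 8)
  for (i in seq_len(nc)) wr(signif(physMin[i], 6), 8)
  for (i in seq_len(nc)) wr(signif(physMax[i], 6), 8)
  for (i in seq_len(nc)) wr(digMin, 8)
  for (i in seq_len(nc)) wr(digMax, 8)
  for (i in seq_len(nc)) wr("", 80)          # prefiltering
  for (i in seq_len(nc)) wr(spr, 8)
  for (i in seq_len(nc)) wr("", 32)          # reserved

  ## physMin/Max were written at 6 significant digits; quantize against the
  ## values as stored so the round trip is exact to the 16-bit precision.
  pmin <- signif(physMin, 6); pmax <- signif(physMax, 6)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(nc)) {
      dig <- round((x[i, cols] - pmin[i]) / (pmax[i] - pmin[i]) *
                     (digMax - digMin) + digMin)
      writeBin(as.integer(pmin(pmax(dig, digMin), digMax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

.readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rdn <- function(width) as.numeric(rd(width))
  version <- rd(8)
  if (version != "0") stop("malformed EDF ", path,
                           ": version field is '", version, "', expected '0'")
  rd(80); rd(80); rd(8); rd(8)
  headerBytes <- rdn(8)
  rd(44)
  nrec <- rdn(8)
  recDur <- rdn(8)
  nc <- as.integer(rdn(4))
  if (is.na(nc) || nc < 1) stop("malformed EDF ", path,
                                ": bad signal count field")
  if (headerBytes != 256 * (nc + 1))
    stop("malformed EDF ", path, ": header byte count field (",
         headerBytes, ") inconsistent with ", nc, " signals")
  labels <- vapply(seq_len(nc), function(i) rd(16), character(1))
  for (i in seq_len(nc)) rd(80)
  for (i in seq_len(nc)) rd(8)
  physMin <- vapply(seq_len(nc), function(i) rdn(8), numeric(1))
  physMax <- vapply(seq_len(nc), function(i) rdn(8), numeric(1))
  digMin <- vapply(seq_len(nc), function(i) rdn(8), numeric(1))
  digMax <- vapply(seq_len(nc), function(i) rdn(8), numeric(1))
  for (i in seq_len(nc)) rd(80)
  spr <- vapply(seq_len(nc), function(i) as.integer(rdn(8)), integer(1))
  for (i in seq_len(nc)) rd(32)

  data <- matrix(0, nc, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (i in seq_len(nc)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      phys <- (dig - digMin[i]) / (digMax[i] - digMin[i]) *
        (physMax[i] - physMin[i]) + physMin[i]
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  EEGRecording(data, rate = spr[1] / recDur, channelNames = labels)
}
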