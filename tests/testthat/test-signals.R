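test_that("band-pass filter preserves passband tones and rejects stopband", {
  rate <- 128
  tt <- (0:(4 * rate - 1)) / rate
  rec10 <- EEGRecording(matrix(sin(2 * pi * 10 * tt), 1), rate = rate)
  filt <- bandpassFilter(rec10, 8, 30)
  core <- eegData(filt)[1, (0.5 * rate):(3.5 * rate)]
  expect_lt(abs(max(abs(core)) - 1), 0.05)

  rec60 <- EEGRecording(matrix(sin(2 * pi * 60 * tt), 1), rate = rate)
  out60 <- eegData(bandpassFilter(rec60, 4, 50, order = 5))[1, ]
  expect_lt(sqrt(mean(out60^2)), 0.1 * sqrt(0.5))

  set.seed(42)
  recW <- EEGRecording(matrix(rnorm(8 * rate), 1), rate = rate)
  outW <- eegData(bandpassFilter(recW, 8, 30))[1, ]
  inBand <- bandPowerOracle(outW, rate, 6, 32)
  total <- bandPowerOracle(outW, rate, 0, rate / 2)
  expect_lt((total - inBand) / total, 0.05)
})

test_that("band edges outside the Nyquist range are rejected", {
  rec <- EEGRecording(matrix(rnorm(256), 1), rate = 128)
  expect_error(bandpassFilter(rec, 8, 70), "Nyquist")
  expect_error(bandpassFilter(rec, 30, 8), "Nyquist")
})

test_that("filtering is linear in the input", {
  set.seed(7)
  x <- matrix(rnorm(2 * 512), 2)
  rec <- EEGRecording(x, rate = 128)
  for (a in c(0.5, 3, -2)) {
    y1 <- eegData(bandpassFilter(EEGRecording(a * x, rate = 128), 8, 30))
    y2 <- a * eegData(bandpassFilter(rec, 8, 30))
    expect_lt(max(abs(y1 - y2)), 1e-9)
  }
})

test_that("sliding window count follows the closed-form formula", {
  mk <- function(T) EEGRecording(matrix(rnorm(T * 128), 1), rate = 128)
  expect_length(slidingWindows(mk(10), 2, 0.25), 33)
  expect_length(slidingWindows(mk(2), 2, 0.25), 1)
  w5 <- slidingWindows(mk(5), 2, 0.25)
  expect_length(w5, 13)
  expect_equal(w5[[13]]@startTime, 3.0)
  # property: matches floor((T - width)/step) + 1 whether or not step
  # divides T - width
  for (T in c(3, 4.7, 6)) {
    for (step in c(0.25, 0.3, 1)) {
      rec <- mk(T)
      Teff <- nSamples(rec) / samplingRate(rec)
      got <- length(slidingWindows(rec, 2, step))
      expect_equal(got, floor((Teff - 2) / step + 1e-9) + 1)
    }
  }
  expect_warning(out <- slidingWindows(mk(1), 2, 0.25), "width")
  expect_length(out, 0)
})

test_that("epoch extraction aligns to events and skips truncated epochs", {
  rate <- 128
  dat <- matrix(rnorm(14 * 5 * rate), 14)
  ev <- data.frame(sample = seq(0, by = 32, length.out = 10), code = "f")
  rec <- EEGRecording(dat, rate = rate, events = ev)
  ts <- extractEpochs(rec, span = 0.6)
  expect_length(trialWindows(ts), 10)
  expect_equal(ncol(eegData(trialWindows(ts)[[1]])), 76)  # floor(0.6*128)

  empty <- extractEpochs(EEGRecording(dat, rate = rate), span = 0.6)
  expect_length(trialWindows(empty), 0)

  ev2 <- ev
  ev2$sample[10] <- ncol(dat) - 1L   # final sample: no room for an epoch
  rec2 <- EEGRecording(dat, rate = rate, events = ev2)
  expect_message(ts2 <- extractEpochs(rec2, span = 0.6), "skipped")
  expect_length(trialWindows(ts2), 9)
})

test_that("epoch extraction is translation-equivariant", {
  rate <- 128
  set.seed(3)
  dat <- matrix(rnorm(4 * 3 * rate), 4)
  ev <- data.frame(sample = c(10L, 100L, 200L), code = "f")
  shift <- 17L
  recA <- EEGRecording(dat, rate = rate, events = ev)
  recB <- EEGRecording(dat, rate = rate,
                       events = transform(ev, sample = sample + shift))
  epsA <- trialWindows(extractEpochs(recA, span = 0.5))
  epsB <- trialWindows(extractEpochs(recB, span = 0.5))
  for (i in seq_along(epsA)) {
    expect_equal(eegData(epsB[[i]]),
                 dat[, (ev$sample[i] + shift + 1):(ev$sample[i] + shift + 64)])
  }
})

test_that("decimation preserves shape, DC and in-band tones", {
  rate <- 128
  mkts <- function(x) TrialSet(list(Window(x, rate = rate)), "P300",
                               labels = "target")
  const <- downsampleTrials(mkts(matrix(1, 2, 76)), 32)
  w <- trialWindows(const)[[1]]
  expect_equal(ncol(eegData(w)), 19)   # 76 / 4
  expect_equal(samplingRate(w), 32)
  expect_lt(max(abs(eegData(w) - 1)), 5e-3)

  tt <- (0:511) / rate
  tone <- downsampleTrials(mkts(matrix(sin(2 * pi * 5 * tt), 1)), 32)
  y <- eegData(trialWindows(tone)[[1]])[1, ]
  expect_lt(abs(max(abs(y[10:118])) - 1), 0.05)

  expect_error(downsampleTrials(mkts(matrix(1, 2, 76)), 33), "multiple")
})

test_that("CSV round trip preserves data, names, rate and events", {
  set.seed(9)
  ev <- data.frame(sample = c(5L, 300L), code = c("1", "2"))
  rec <- EEGRecording(matrix(rnorm(14 * 1280), 14), rate = 128, events = ev)
  f <- file.path(tempdir(), "rt.csv")
  writeRecording(rec, f)
  back <- readRecording(f)
  expect_equal(channelNames(back), channelNames(rec))
  expect_equal(samplingRate(back), 128)
  expect_equal(eegData(back), eegData(rec), tolerance = 1e-12)
  expect_equal(eventTable(back), eventTable(rec))
})

test_that("ragged CSV rows produce a parse error naming the row", {
  f <- file.path(tempdir(), "bad.csv")
  writeLines(c("time_s,a,b", "0,1,2", "0.1,3", "0.2,4,5"), f)
  expect_error(readRecording(f), "row 3")
})

test_that("EDF writer emits the documented header layout and round-trips", {
  set.seed(11)
  rec <- EEGRecording(matrix(rnorm(14 * 1280), 14), rate = 128)
  f <- file.path(tempdir(), "rt.edf")
  writeRecording(rec, f)

  # independent structural check against the EDF field table
  raw <- readBin(f, "raw", n = 256 * 15)
  hdr <- rawToChar(raw)
  expect_equal(trimws(substr(hdr, 1, 8)), "0")              # version
  expect_equal(trimws(substr(hdr, 185, 192)), "3840")       # 256*(14+1)
  expect_equal(trimws(substr(hdr, 253, 256)), "14")         # signal count
  expect_equal(trimws(substr(hdr, 257, 272)), "AF3")        # first label
  expect_equal(file.size(f), 256 * 15 + 10 * 128 * 14 * 2)  # 10 records

  back <- readRecording(f)
  expect_equal(channelNames(back), emotivChannels())
  expect_equal(samplingRate(back), 128)
  # 16-bit quantization over the per-channel range
  scale <- apply(eegData(rec), 1, function(x) diff(range(x))) / 65535
  expect_true(all(abs(eegData(back) - eegData(rec)) <= 1.01 * scale))
})

test_that("fitted models survive a JSON round trip", {
  cfg <- SynthConfig(snr = 2, seed = 21)
  cls <- prepErdClasses(genErdTrials(cfg, nActive = 6, nIdle = 6))
  csp <- fitCSP(cls$active, cls$idle, m = 1)
  f <- file.path(tempdir(), "csp.json")
  writeModel(csp, f)
  back <- readModel(f)
  expect_s4_class(back, "CSPModel")
  expect_equal(back@filters, csp@filters, tolerance = 1e-12)
  expect_equal(back@eigenvalues, csp@eigenvalues, tolerance = 1e-12)
  w <- cls$all[[1]]
  expect_equal(cspFeatures(back, w), cspFeatures(csp, w), tolerance = 1e-9)
})
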