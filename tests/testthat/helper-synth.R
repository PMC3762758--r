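# Shared fixtures and independent oracles used across test files.

# Periodogram band power, computed directly from the FFT (independent of
# any package-internal spectral code).
bandPowerOracle <- function(x, rate, lo, hi) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))^2 / n
  freqs <- (seq_len(n) - 1) * rate / n
  sum(spec[freqs <= rate / 2 & freqs >= lo & freqs <= hi])
}

# Mean trace-normalized class covariance of a list of Window objects,
# re-derived here so CSP tests do not lean on package internals.
meanClassCov <- function(wins) {
  Cs <- lapply(wins, function(w) {
    C <- tcrossprod(eegData(w)) / ncol(eegData(w))
    C / sum(diag(C))
  })
  Reduce(`+`, Cs) / length(Cs)
}

# Band-pass (8-30 Hz) every window of an ERD trial set and split by class.
prepErdClasses <- function(ts) {
  filt <- lapply(trialWindows(ts), bandpassFilter, low = 8, high = 30)
  labs <- trialLabels(ts)
  list(active = TrialSet(filt[labs == "active"], "ERD",
                         labels = labs[labs == "active"]),
       idle = TrialSet(filt[labs == "idle"], "ERD",
                       labels = labs[labs == "idle"]),
       all = filt, labels = labs)
}

# Fit-and-score closure for ERD cross-validation: CSP + linear classifier
# trained on the fold's training trials, accuracy on its test trials.
erdFitScore <- function(m = 2) {
  function(train, test) {
    cls <- prepErdClasses(train)
    csp <- fitCSP(cls$active, cls$idle, m = m)
    feats <- t(vapply(cls$all, function(w) cspFeatures(csp, w),
                      numeric(2 * m)))
    clf <- trainERD(feats, cls$labels)
    testF <- lapply(trialWindows(test), bandpassFilter, low = 8, high = 30)
    pred <- vapply(testF, function(w) detectERD(csp, clf, w)$label,
                   character(1))
    mean(pred == trialLabels(test))
  }
}

# Parameterless SSVEP rule: pick the frequency with the larger canonical
# correlation on the 4-50 Hz filtered window.
ssvepFitScore <- function(train, test) {
  pred <- vapply(trialWindows(test), function(w) {
    rho <- ssvepCorrelationPair(bandpassFilter(w, 4, 50))
    c("12", "15")[which.max(rho)]
  }, character(1))
  mean(pred == trialLabels(test))
}

# Full P300 preprocessing: epoch, band-pass 1-20 Hz, decimate to 32 Hz,
# with target/nontarget labels relative to the favorite object "1".
prepP300Epochs <- function(rec, favorite = "1") {
  ep <- extractEpochs(rec, span = 0.6)
  filt <- lapply(trialWindows(ep), bandpassFilter, low = 1, high = 20)
  labs <- ifelse(trialLabels(ep) %in% favorite, "target", "nontarget")
  downsampleTrials(TrialSet(filt, "P300", labels = labs), 32)
}

# Gaussian (rho12, rho15) cloud for selector tests.
rhoCloud <- function(n, center, sd = 0.05, seed = 1) {
  set.seed(seed)
  cbind(pmin(pmax(rnorm(n, center[1], sd), 0), 1),
        pmin(pmax(rnorm(n, center[2], sd), 0), 1))
}
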