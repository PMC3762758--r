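# Windows with exact (population) covariances diag(4,1)/trace and
# diag(1,4)/trace: orthogonal square waves with amplitudes 2 and 1.
.exactCovWindow <- function(a1, a2) {
  ch1 <- a1 * rep(c(1, -1), 8)
  ch2 <- a2 * rep(c(1, 1, -1, -1), 4)
  Window(rbind(ch1, ch2), rate = 128, channelNames = c("c1", "c2"))
}

test_that("CSP solves the 2x2 problem in closed form", {
  act <- TrialSet(list(.exactCovWindow(2, 1), .exactCovWindow(2, 1)),
                  "ERD", labels = c("active", "active"))
  idl <- TrialSet(list(.exactCovWindow(1, 2), .exactCovWindow(1, 2)),
                  "ERD", labels = c("idle", "idle"))
  m <- fitCSP(act, idl, m = 1)
  expect_equal(m@eigenvalues, c(0.8, 0.2), tolerance = 1e-9)
  # filters proportional to the coordinate axes
  f <- apply(m@filters, 2, function(v) abs(v) / sqrt(sum(v^2)))
  expect_equal(f[, 1], c(1, 0), tolerance = 1e-9)
  expect_equal(f[, 2], c(0, 1), tolerance = 1e-9)
})

test_that("identical class covariances are flagged as non-discriminative", {
  act <- TrialSet(list(.exactCovWindow(2, 1), .exactCovWindow(2, 1)),
                  "ERD", labels = c("active", "active"))
  expect_warning(m <- fitCSP(act, initialize(act, labels = c("idle", "idle")),
                             m = 1),
                 "no discriminative")
  expect_equal(m@eigenvalues, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("CSP matches a brute-force generalized-eigenproblem oracle", {
  set.seed(31)
  for (nc in c(3, 4, 6)) {
    mk <- function(mix) lapply(1:5, function(i)
      Window(mix %*% matrix(rnorm(nc * 128), nc), rate = 128,
             channelNames = paste0("c", 1:nc)))
    A <- diag(runif(nc, 0.5, 2)) + matrix(rnorm(nc * nc, 0, 0.1), nc)
    B <- diag(runif(nc, 0.5, 2)) + matrix(rnorm(nc * nc, 0, 0.1), nc)
    actW <- mk(A); idlW <- mk(B)
    act <- TrialSet(actW, "ERD", labels = rep("active", 5))
    idl <- TrialSet(idlW, "ERD", labels = rep("idle", 5))
    mdl <- fitCSP(act, idl, m = 1)

    # oracle: plain eigen() on solve(Ca + Ci) %*% Ca
    Ca <- meanClassCov(actW); Ci <- meanClassCov(idlW)
    eo <- eigen(solve(Ca + Ci) %*% Ca)
    vals <- Re(eo$values); vecs <- Re(eo$vectors)
    ord <- order(vals, decreasing = TRUE)
    expect_equal(mdl@eigenvalues, vals[ord][c(1, nc)], tolerance = 1e-6)
    for (j in 1:2) {
      got <- mdl@filters[, j] / sqrt(sum(mdl@filters[, j]^2))
      want <- vecs[, ord[c(1, nc)][j]]
      want <- want / sqrt(sum(want^2))
      expect_lt(min(sum((got - want)^2), sum((got + want)^2)), 1e-12)
    }
  }
})

test_that("CSP filters are invariant to a common channel rescaling", {
  cfg <- SynthConfig(seed = 32, snr = 1.5)
  cls <- prepErdClasses(genErdTrials(cfg, nActive = 8, nIdle = 8))
  m1 <- fitCSP(cls$active, cls$idle, m = 2)
  scale7 <- function(ts) initialize(ts, windows = lapply(
    trialWindows(ts), function(w) initialize(w, data = 7 * eegData(w))))
  m2 <- fitCSP(scale7(cls$active), scale7(cls$idle), m = 2)
  expect_equal(m1@filters, m2@filters, tolerance = 1e-9)
})

test_that("log-variance features are normalized and scale-invariant", {
  cfg <- SynthConfig(seed = 33, snr = 1.5)
  cls <- prepErdClasses(genErdTrials(cfg, nActive = 5, nIdle = 5))
  csp <- fitCSP(cls$active, cls$idle, m = 2)
  w <- cls$all[[1]]
  f <- cspFeatures(csp, w)
  expect_length(f, 4)
  expect_true(all(is.finite(f)))
  expect_lt(abs(sum(exp(f)) - 1), 1e-9)
  f10 <- cspFeatures(csp, initialize(w, data = 10 * eegData(w)))
  expect_equal(f, f10, tolerance = 1e-9)
  expect_error(cspFeatures(csp, initialize(w, data = 0 * eegData(w))),
               "zero variance")
})

test_that("planted sensorimotor pattern is recovered by the extreme filter", {
  cfg <- SynthConfig(seed = 34, snr = 3)
  cls <- prepErdClasses(genErdTrials(cfg, attenuation = 0.7))
  csp <- fitCSP(cls$active, cls$idle, m = 2)
  planted <- as.numeric(emotivChannels() %in% c("FC5", "FC6", "F3", "F4"))
  # the planted rhythm lives in the idle class, so the filter maximizing
  # idle variance (smallest eigenvalue, last column) is the discriminative
  # one
  j <- ncol(csp@patterns)
  expect_gt(abs(cor(csp@patterns[, j], planted)), 0.9)
})

test_that("the linear classifier separates and returns margins", {
  feats <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  labels <- rep(c("active", "idle"), each = 20)
  clf <- trainERD(feats, labels)
  expect_equal(clf@classes[1], "active")
  dec <- feats %*% clf@weights + clf@bias
  expect_equal(mean((dec > 0) == (labels == "active")), 1)
  expect_error(trainERD(feats, rep("active", 40)), "two classes")
})

test_that("imagery decoding accuracy: discriminable at attenuation 0.7, chance at 0", {
  cfg <- SynthConfig(seed = 35, snr = 1)
  good <- genErdTrials(cfg, nActive = 20, nIdle = 20, attenuation = 0.7)
  cvGood <- crossValidate(good, erdFitScore(), k = 10, seed = 1)
  expect_gte(cvGood@mean, 0.85)

  none <- genErdTrials(SynthConfig(seed = 36, snr = 1), nActive = 20,
                       nIdle = 20, attenuation = 0)
  cvNone <- crossValidate(none, erdFitScore(), k = 10, seed = 1)
  expect_lt(abs(cvNone@mean - 0.5), 0.15)
})

test_that("decoding accuracy is monotone in the attenuation depth", {
  accs <- vapply(c(0.1, 0.5, 0.9), function(att) {
    ts <- genErdTrials(SynthConfig(seed = 37, snr = 1.5), nActive = 16,
                       nIdle = 16, attenuation = att)
    crossValidate(ts, erdFitScore(), k = 8, seed = 2)@mean
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})
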