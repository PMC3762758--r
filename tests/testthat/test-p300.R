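test_that("single-channel xDAWN reduces to a scalar projection", {
  set.seed(51)
  wins <- lapply(1:10, function(i)
    Window(matrix(rnorm(19), 1), rate = 32, channelNames = "c1"))
  ts <- TrialSet(wins, "P300",
                 labels = rep(c("target", "nontarget"), each = 5))
  xd <- fitXdawn(ts, nComponents = 3)
  expect_equal(dim(xd@filters), c(1L, 1L))
  w <- wins[[1]]
  proj <- as.numeric(t(xd@filters) %*% eegData(w))
  expect_equal(proj / proj[1], eegData(w)[1, ] / eegData(w)[1, 1],
               tolerance = 1e-9)
})

test_that("xDAWN recovers a planted spatial pattern", {
  cfg <- SynthConfig(seed = 52, snr = 5)
  out <- genP300Stream(cfg, nObjects = 2, nFlashesPerObject = 20)
  ep <- prepP300Epochs(out$recording)
  xd <- fitXdawn(ep)
  planted <- rep(0.15, 14)
  planted[emotivChannels() %in% c("P7", "P8")] <- 1
  planted <- planted / sqrt(sum(planted^2))
  expect_gt(abs(cor(xd@patterns[, 1], planted)), 0.95)
})

test_that("xDAWN matches a brute-force generalized-eigenproblem oracle", {
  set.seed(53)
  for (rep in 1:3) {
    wins <- lapply(1:30, function(i)
      Window(matrix(rnorm(4 * 19), 4), rate = 32,
             channelNames = paste0("c", 1:4)))
    ts <- TrialSet(wins, "P300",
                   labels = rep(c("target", "nontarget"), 15))
    xd <- fitXdawn(ts, nComponents = 3)

    tgt <- wins[ts@labels == "target"]
    evoked <- Reduce(`+`, lapply(tgt, eegData)) / length(tgt)
    Ss <- tcrossprod(evoked) / 19
    St <- Reduce(`+`, lapply(wins, function(w)
      tcrossprod(eegData(w)) / 19)) / 30
    eo <- eigen(solve(St) %*% Ss)
    vals <- Re(eo$values); vecs <- Re(eo$vectors)
    ord <- order(vals, decreasing = TRUE)
    expect_equal(xd@eigenvalues, vals[ord[1:3]], tolerance = 1e-6)
    for (j in 1:3) {
      got <- xd@filters[, j] / sqrt(sum(xd@filters[, j]^2))
      want <- vecs[, ord[j]] / sqrt(sum(vecs[, ord[j]]^2))
      expect_lt(min(sum((got - want)^2), sum((got + want)^2)), 1e-10)
    }
  }
})

test_that("with no evoked response the leading eigenvalue sits in the permutation null", {
  cfg <- SynthConfig(seed = 54, snr = 0)
  out <- genP300Stream(cfg, nObjects = 2, nFlashesPerObject = 15)
  ep <- prepP300Epochs(out$recording)
  observed <- fitXdawn(ep)@eigenvalues[1]
  set.seed(55)
  null <- vapply(1:50, function(i) {
    fitXdawn(initialize(ep, labels = sample(trialLabels(ep))))@eigenvalues[1]
  }, numeric(1))
  rank <- mean(null >= observed)
  expect_gt(rank, 0.02)   # observed value is not extreme under the null
})

test_that("BLDA with fixed hyperparameters equals ridge regression", {
  set.seed(56)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c(1, -1), 20)
  alpha <- 3; beta <- 0.7
  mdl <- fitBLDA(X, y, fixedAlpha = alpha, fixedBeta = beta)
  Phi <- cbind(X, 1)
  ridge <- solve(crossprod(Phi) + alpha / beta * diag(7), crossprod(Phi, y))
  expect_lt(max(abs(mdl@weights - as.numeric(ridge))), 1e-8)
})

test_that("BLDA separates well-separated clusters and tracks evidence", {
  set.seed(57)
  X <- rbind(matrix(rnorm(60, 3), 20, 3), matrix(rnorm(60, -3), 20, 3))
  y <- rep(c("target", "nontarget"), each = 20)
  mdl <- fitBLDA(X, y)
  scores <- cbind(X, 1) %*% mdl@weights
  expect_equal(mean((scores > 0) == (y == "target")), 1)
  expect_gt(mdl@alpha, 0)
  expect_gt(mdl@beta, 0)
  expect_true(all(diff(mdl@evidence) > -1e-6))
})

test_that("evidence maximization shrinks a pure-noise dimension", {
  set.seed(58)
  n <- 400
  informative <- matrix(rep(c(2, -2), each = n / 2), n, 3) +
    matrix(rnorm(3 * n, 0, 0.5), n, 3)
  noise <- rnorm(n, 0, 1)
  mdl <- fitBLDA(cbind(informative, noise),
                 rep(c(1, -1), each = n / 2))
  w <- mdl@weights
  expect_lt(abs(w[4]), 0.1 * mean(abs(w[1:3])))
})

test_that("epoch scoring is linear with the bias as its zero point", {
  cfg <- SynthConfig(seed = 59, snr = 3)
  out <- genP300Stream(cfg, nObjects = 2, nFlashesPerObject = 20)
  ep <- prepP300Epochs(out$recording)
  xd <- fitXdawn(ep)
  bl <- fitBLDA(xdawnFeatures(xd, ep), trialLabels(ep))
  z <- matrix(0, 14, 19)
  expect_equal(scoreEpoch(xd, bl, z), bl@weights[length(bl@weights)],
               tolerance = 1e-12)
  set.seed(60)
  a <- matrix(rnorm(14 * 19), 14); b <- matrix(rnorm(14 * 19), 14)
  resid <- scoreEpoch(xd, bl, a + b) - scoreEpoch(xd, bl, a) -
    scoreEpoch(xd, bl, b) + scoreEpoch(xd, bl, z)
  expect_lt(abs(resid), 1e-9)
  # the mean training target epoch scores positive
  tgt <- trialWindows(ep)[trialLabels(ep) == "target"]
  meanTgt <- Reduce(`+`, lapply(tgt, eegData)) / length(tgt)
  expect_gt(scoreEpoch(xd, bl, meanTgt), 0)
  expect_error(scoreEpoch(xd, bl, matrix(0, 14, 20)), "shape")
})

test_that("object decisions aggregate scores and respect thresholds", {
  expect_error(decideObjects(numeric(0), character(0)), "non-empty")
  same <- decideObjects(rep(1, 10), rep(c("1", "2"), 5), threshold = 2)
  expect_false(any(same$flags))
  dec <- decideObjects(c(3, 3, -1, -1), c("1", "1", "2", "2"))
  expect_equal(dec$favorite, "1")
  expect_equal(unname(dec$flags), c(TRUE, FALSE))
  expect_error(decideObjects(1:3, c("1", "1", "2")), "unequal")
})

test_that("recognition improves with more flashes per object", {
  trainStream <- genP300Stream(SynthConfig(seed = 61, snr = 2.5),
                               nObjects = 2, nFlashesPerObject = 20)
  train <- prepP300Epochs(trainStream$recording)
  xd <- fitXdawn(train)
  bl <- fitBLDA(xdawnFeatures(xd, train), trialLabels(train))
  accAt <- function(nFlash) {
    hits <- vapply(1:25, function(i) {
      s <- genP300Stream(SynthConfig(seed = 600 + i, snr = 2.5),
                         nObjects = 2, nFlashesPerObject = nFlash)
      ep <- prepP300Epochs(s$recording)
      sc <- vapply(trialWindows(ep), function(w) scoreEpoch(xd, bl, w),
                   numeric(1))
      obj <- ifelse(trialLabels(ep) == "target", "1", "2")
      decideObjects(sc, obj)$favorite == "1"
    }, logical(1))
    mean(hits)
  }
  expect_gte(accAt(10), accAt(1))
})
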