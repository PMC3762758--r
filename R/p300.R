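#' @include AllClasses.R
NULL

#' Fit xDAWN spatial filters
#'
#' Estimates the evoked response as the least-squares fit of a
#' stimulus-aligned design to the epochs — which, for extracted
#' onset-aligned epochs, is the target-epoch mean — and solves the
#' generalized eigenproblem maximizing evoked-signal power over total
#' signal power by symmetric whitening. The top `nComponents` filters
#' (decreasing signal-to-signal-plus-noise ratio) define the projection
#' subspace for epoch scoring.
#'
#' @param epochs a [TrialSet-class] of preprocessed epochs (1-20 Hz,
#'   decimated to 32 Hz in the reference pipeline) labeled target /
#'   non-target.
#' @param nComponents subspace dimension (3; reduced to the channel count
#'   when fewer channels are available).
#' @param targetLabel label marking target epochs.
#' @return An [XdawnModel-class].
#' @export
fitXdawn <- function(epochs, nComponents = 3, targetLabel = "target") {
  isTarget <- epochs@labels == targetLabel
  nComponents <- min(nComponents, nrow(epochs@windows[[1]]@data))
  if (sum(isTarget) < nComponents)
    stop("need at least ", nComponents, " target epochs")
  tgt <- epochs@windows[isTarget]
  evoked <- Reduce(`+`, lapply(tgt, function(w) w@data)) / length(tgt)
  nt <- ncol(evoked)
  sigCov <- tcrossprod(evoked) / nt
  totCov <- Reduce(`+`, lapply(epochs@windows,
                               function(w) tcrossprod(w@data) / nt)) /
    length(epochs@windows)
  totCov <- totCov + 1e-9 * sum(diag(totCov)) / nrow(totCov) *
    diag(nrow(totCov))
  Wi <- .invSqrtm(totCov)
  S <- Wi %*% sigCov %*% Wi
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  filters <- .fixSigns((Wi %*% e$vectors)[, seq_len(nComponents),
                                          drop = FALSE])
  patterns <- totCov %*% filters %*% solve(t(filters) %*% totCov %*% filters)
  new("XdawnModel", filters = filters, patterns = patterns,
      eigenvalues = e$values[seq_len(nComponents)],
      epochSamples = as.integer(nt),
      rate = epochs@windows[[1]]@rate, band = c(1, 20),
      channelNames = epochs@windows[[1]]@channelNames)
}

#' xDAWN feature vectors for a trial set
#'
#' Projects each epoch through the spatial filters and flattens the
#' component x time array (component-major) into one row per epoch.
#'
#' @param xd an [XdawnModel-class].
#' @param epochs a [TrialSet-class] with epochs matching the fit metadata.
#' @return n x (nComponents * epochSamples) feature matrix.
#' @export
xdawnFeatures <- function(xd, epochs) {
  t(vapply(epochs@windows,
           function(w) as.numeric(t(xd@filters) %*% w@data),
           numeric(ncol(xd@filters) * xd@epochSamples)))
}

#' Fit the Bayesian linear discriminant
#'
#' Bayesian linear regression of class targets (+1 target, -1 non-target)
#' on the feature vectors with a constant bias column appended. The prior
#' precision `alpha` and noise precision `beta` are set by iterating their
#' closed-form evidence-maximization updates until the relative change
#' falls below `tol` (or `maxIter` is reached, returning the best iterate
#' with a warning). With both hyperparameters held fixed the posterior
#' mean equals the ridge-regression solution with penalty `alpha/beta`.
#'
#' @param features n x d feature matrix (finite values).
#' @param labels per-row labels: +1/-1, or characters where `targetLabel`
#'   marks the positive class.
#' @param targetLabel positive-class label for character input.
#' @param maxIter,tol update-loop controls.
#' @param fixedAlpha,fixedBeta hold the hyperparameters fixed (no updates).
#' @return A [BLDAModel-class]; `weights` has length d + 1 with the bias
#'   last.
#' @export
fitBLDA <- function(features, labels, targetLabel = "target",
                    maxIter = 200, tol = 1e-6,
                    fixedAlpha = NULL, fixedBeta = NULL) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) stop("features must be finite")
  if (is.numeric(labels)) {
    t <- ifelse(labels > 0, 1, -1)
  } else {
    t <- ifelse(as.character(labels) == targetLabel, 1, -1)
  }
  if (length(unique(t)) != 2) stop("both classes must be present")
  Phi <- cbind(X, 1)
  n <- nrow(Phi); D <- ncol(Phi)
  G <- crossprod(Phi)
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  Pt <- crossprod(Phi, t)
  postMean <- function(alpha, beta) {
    ## m = beta (beta G + alpha I)^{-1} Phi' t, via the eigenbasis of G
    coef <- beta / (beta * lam + alpha)
    eg$vectors %*% (coef * crossprod(eg$vectors, Pt))
  }
  logEvidence <- function(alpha, beta, m) {
    sse <- sum((t - Phi %*% m)^2)
    D / 2 * log(alpha) + n / 2 * log(beta) -
      (beta / 2 * sse + alpha / 2 * sum(m^2)) -
      0.5 * sum(log(alpha + beta * lam)) - n / 2 * log(2 * pi)
  }
  if (!is.null(fixedAlpha) && !is.null(fixedBeta)) {
    m <- postMean(fixedAlpha, fixedBeta)
    return(new("BLDAModel", weights = as.numeric(m), alpha = fixedAlpha,
               beta = fixedBeta,
               evidence = logEvidence(fixedAlpha, fixedBeta, m),
               converged = TRUE))
  }
  alpha <- 1; beta <- 1
  evid <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    m <- postMean(alpha, beta)
    gamma <- sum(beta * lam / (beta * lam + alpha))
    newAlpha <- gamma / max(sum(m^2), 1e-300)
    sse <- sum((t - Phi %*% m)^2)
    newBeta <- max(n - gamma, 1e-12) / max(sse, 1e-300)
    evid <- c(evid, logEvidence(alpha, beta, m))
    if (abs(newAlpha - alpha) / alpha < tol &&
        abs(newBeta - beta) / beta < tol) {
      alpha <- newAlpha; beta <- newBeta
      converged <- TRUE
      break
    }
    alpha <- newAlpha; beta <- newBeta
  }
  if (!converged)
    warning("evidence maximization did not converge; returning best iterate")
  m <- postMean(alpha, beta)
  new("BLDAModel", weights = as.numeric(m), alpha = alpha, beta = beta,
      evidence = evid, converged = converged)
}

#' Score one epoch for P300 presence
#'
#' Projects the epoch through the xDAWN filters, flattens, appends the
#' bias, and returns the linear discriminant score: higher is more
#' P300-like, and the score is linear in the epoch data.
#'
#' @param xd an [XdawnModel-class].
#' @param bl a [BLDAModel-class] fit on the matching feature layout.
#' @param epoch a [Window-class] or channels x samples matrix with the
#'   model's fit shape.
#' @return Numeric score.
#' @export
scoreEpoch <- function(xd, bl, epoch) {
  x <- if (is(epoch, "Window")) epoch@data else as.matrix(epoch)
  if (nrow(x) != nrow(xd@filters) || ncol(x) != xd@epochSamples)
    stop("epoch shape (", nrow(x), " x ", ncol(x),
         ") does not match fit metadata (", nrow(xd@filters), " x ",
         xd@epochSamples, ")")
  f <- as.numeric(t(xd@filters) %*% x)
  sum(bl@weights * c(f, 1))
}

#' Per-object favorite decisions from flash scores
#'
#' Aggregates epoch scores over the flashes of each object by their mean
#' and compares against the threshold: objects whose mean score exceeds it
#' are flagged as the user's favorite. The object with the largest mean is
#' also reported.
#'
#' @param scores numeric epoch scores.
#' @param objects parallel vector of flashed object ids (equal flash
#'   counts per object).
#' @param threshold decision threshold (0, or a calibrated midpoint from
#'   [calibrateThreshold()]).
#' @return List with `flags` (named logical), `means` (named numeric) and
#'   `favorite` (id with the largest mean score).
#' @export
decideObjects <- function(scores, objects, threshold = 0) {
  objects <- as.character(objects)
  if (length(scores) == 0 || length(scores) != length(objects))
    stop("scores and objects must be non-empty and parallel")
  counts <- table(objects)
  if (length(unique(as.integer(counts))) != 1)
    stop("unequal flash counts per object")
  means <- tapply(scores, objects, mean)
  means <- stats::setNames(as.numeric(means), names(means))
  means <- means[order(names(means))]
  list(flags = means > threshold, means = means,
       favorite = names(means)[which.max(means)])
}

#' Midpoint threshold from training scores
#'
#' @param targetScores,nontargetScores training epoch scores per class.
#' @return Midpoint of the two class score means, a calibrated decision
#'   threshold for [decideObjects()].
#' @export
calibrateThreshold <- function(targetScores, nontargetScores) {
  (mean(targetScores) + mean(nontargetScores)) / 2
}
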