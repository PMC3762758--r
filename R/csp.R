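#' @include AllClasses.R
NULL

#' Fit Common Spatial Patterns
#'
#' Estimates the trace-normalized spatial covariance of each class (mean
#' over trials, zero-mean assumption satisfied by band-pass preprocessing)
#' and solves the generalized eigenproblem of the class covariance against
#' the composite covariance by symmetric whitening. The returned filters
#' are the `m` eigenvectors with the largest and the `m` with the smallest
#' whitened eigenvalues, i.e. the projections whose variance ratio between
#' the two classes is most extreme. Eigenvector signs are fixed by making
#' the largest-magnitude component positive.
#'
#' @param active,idle [TrialSet-class]s of band-passed (8-30 Hz) trials for
#'   the imagery and idle classes, at least two trials each.
#' @param m filter pairs per extreme (2 in the reference configuration).
#' @param shrinkage trace-scaled ridge applied when a covariance is
#'   rank-deficient.
#' @return A [CSPModel-class].
#' @export
fitCSP <- function(active, idle, m = 2, shrinkage = 1e-6) {
  if (length(active@windows) < 2 || length(idle@windows) < 2)
    stop("need at least 2 trials per class")
  nc <- nrow(active@windows[[1]]@data)
  if (2 * m > nc) stop("2m exceeds the channel count")
  meanCov <- function(ts) {
    Cs <- lapply(ts@windows, function(w) .traceCov(w@data))
    Reduce(`+`, Cs) / length(Cs)
  }
  Ca <- meanCov(active)
  Ci <- meanCov(idle)
  fix <- function(C) {
    e <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(e) < 1e-10 * max(e)) {
      warning("rank-deficient class covariance; shrinkage applied")
      C + shrinkage * sum(diag(C)) / nrow(C) * diag(nrow(C))
    } else C
  }
  Ca <- fix(Ca); Ci <- fix(Ci)
  Cc <- Ca + Ci
  Wi <- .invSqrtm(Cc)
  S <- Wi %*% Ca %*% Wi
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (max(abs(e$values - 0.5)) < 0.05)
    warning("class covariances nearly identical; no discriminative filter")
  keep <- c(seq_len(m), nc - m + seq_len(m))
  filters <- .fixSigns((Wi %*% e$vectors)[, keep, drop = FALSE])
  patterns <- Cc %*% filters %*%
    solve(t(filters) %*% Cc %*% filters)
  colnames(filters) <- colnames(patterns) <- NULL
  new("CSPModel", filters = filters, patterns = patterns,
      m = as.integer(m), eigenvalues = e$values[keep],
      covActive = Ca, covIdle = Ci, band = c(8, 30),
      channelNames = active@windows[[1]]@channelNames)
}

#' Normalized log-variance CSP features
#'
#' Projects a band-passed window through the model's 2m spatial filters and
#' returns `f_i = log(var_i / sum_j var_j)`; by construction
#' `sum(exp(f)) == 1` and the features are invariant to a common scaling of
#' the window.
#'
#' @param model a [CSPModel-class].
#' @param w a [Window-class], band-passed to the training band and with the
#'   training channel order.
#' @return Numeric feature vector of length 2m.
#' @export
cspFeatures <- function(model, w) {
  x <- if (is(w, "Window")) w@data else as.matrix(w)
  if (nrow(x) != nrow(model@filters))
    stop("window channel count does not match the fitted model")
  y <- t(model@filters) %*% x
  v <- apply(y, 1, stats::var)
  if (any(v <= 0) || sum(v) == 0)
    stop("degenerate window: zero variance after spatial filtering")
  log(v / sum(v))
}

#' Train and apply the motor-imagery classifier
#'
#' `trainERD` fits a linear-kernel max-margin (support-vector) classifier
#' on CSP feature vectors and stores it in plain weight/bias form, so the
#' decision value `w . f + b` (positive for the first class) is available
#' to the arbitration logic as a confidence. `detectERD` filters nothing:
#' it expects a window preprocessed like the training trials.
#'
#' @param features n x 2m matrix of CSP feature vectors.
#' @param labels per-row class labels (both classes must be present);
#'   `"active"` is made the positive class when present.
#' @param cost soft-margin cost parameter.
#' @return `trainERD`: an [ERDClassifier-class]. `detectERD`: list with
#'   `label` and the raw `decision` value.
#' @export
trainERD <- function(features, labels, cost = 1) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly two classes required for training")
  if ("active" %in% lev) lev <- c("active", setdiff(lev, "active"))
  y <- factor(labels, levels = lev)
  fit <- e1071::svm(as.matrix(features), y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  ## e1071 orients the decision value toward its first recorded label
  if (fit$labels[1] != 1L) { w <- -w; b <- -b }
  new("ERDClassifier", weights = w, bias = b, classes = lev)
}

#' @rdname trainERD
#' @param model a [CSPModel-class].
#' @param classifier an [ERDClassifier-class].
#' @param w a [Window-class] band-passed to the training band.
#' @export
detectERD <- function(model, classifier, w) {
  f <- cspFeatures(model, w)
  d <- sum(classifier@weights * f) + classifier@bias
  list(label = if (d > 0) classifier@classes[1] else classifier@classes[2],
       decision = d)
}
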