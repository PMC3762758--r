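#' @include AllClasses.R
NULL

#' Wolpaw information transfer rate
#'
#' The standard bit rate of an N-class decoder at accuracy P:
#' `log2(N) + P log2(P) + (1 - P) log2((1 - P)/(N - 1))` bits per decision
#' (with `0 log2 0 = 0`), multiplied by the decision rate and clipped at
#' zero below chance. One decision per 2 s analysis window gives the 30
#' decisions/min used for the navigation protocols.
#'
#' @param P accuracy in \[0, 1\].
#' @param N number of classes (>= 2).
#' @param rate decisions per minute.
#' @return Bits per minute.
#' @examples
#' wolpawITR(0.768, 2, 30)  # 6.55 bits/min
#' wolpawITR(1.0, 2, 30)    # 30
#' @export
wolpawITR <- function(P, N = 2, rate = 30) {
  if (any(P < 0 | P > 1)) stop("P must lie in [0, 1]")
  if (N < 2) stop("N must be at least 2")
  xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)
  bits <- log2(N) + xlog2(P) +
    ifelse(P < 1, (1 - P) * log2((1 - P) / (N - 1)), 0)
  bits <- ifelse(P < 1 / N, 0, pmax(bits, 0))
  bits * rate
}

#' Stratified k-fold cross-validation over trials
#'
#' Splits at the trial level (no window of a test trial ever enters its
#' fold's training set), stratified by class so fold sizes differ by at
#' most one per class, deterministic under the seed. If a training fold
#' loses a class entirely the folds are redrawn with a warning.
#'
#' @param trials a [TrialSet-class].
#' @param fitScore function(trainSet, testSet) returning the accuracy on
#'   the test set.
#' @param k number of folds (10 in the evaluation protocol).
#' @param seed integer seed for the fold assignment.
#' @return A [CVResult-class].
#' @export
crossValidate <- function(trials, fitScore, k = 10, seed = 1L) {
  n <- length(trials@windows)
  if (n < k) stop("need at least k trials")
  labels <- trials@labels
  drawFolds <- function(s) {
    fold <- integer(n)
    load <- integer(k)
    .withSeed(s, for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      ## cycle folds from least- to most-loaded so extras spread evenly
      ord <- order(load, sample.int(k))
      fold[idx] <- rep_len(ord, length(idx))
      load <- tabulate(fold[fold > 0], k)
    })
    fold
  }
  fold <- drawFolds(seed)
  for (attempt in 1:10) {
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(labels[fold != f])) == length(unique(labels)),
      logical(1)))
    if (ok) break
    warning("a training fold lost a class; redrawing folds")
    fold <- drawFolds(seed + attempt)
  }
  subsetTS <- function(idx)
    initialize(trials, windows = trials@windows[idx],
               labels = labels[idx])
  accs <- vapply(seq_len(k), function(f) {
    fitScore(subsetTS(which(fold != f)), subsetTS(which(fold == f)))
  }, numeric(1))
  new("CVResult", folds = accs, mean = mean(accs),
      sd = stats::sd(accs))
}

#' Accumulate navigation metrics from a trajectory log
#'
#' Consumes the per-tick trajectory log written by [runClosedLoop()] (or
#' any log with columns `time`, `x`, `y`, `mode`, `confirmed`,
#' `collision`): distance is the summed positional displacement, forward
#' and turning steps convert distance and body rotation into the robot's
#' stride quanta, the explored angle sums the 3-degree head rotations of
#' confirmed head-turn commands, and transitions count switches between
#' exploration (head-turn) and navigation (switch) activity in the
#' confirmed-command sequence.
#'
#' @param log data.frame trajectory log.
#' @param walkSpeed,turnSpeed stride conversion constants (cm/s and rad/s;
#'   one second of motion per step).
#' @return A [NavMetrics-class].
#' @export
accumulateMetrics <- function(log, walkSpeed = 3.3, turnSpeed = 0.13) {
  need <- c("time", "x", "y", "mode", "confirmed", "collision")
  if (!all(need %in% names(log)))
    stop("malformed trajectory log: missing column(s) ",
         paste(setdiff(need, names(log)), collapse = ", "))
  if (nrow(log) == 0) return(NavMetrics())
  dist <- sum(sqrt(diff(log$x)^2 + diff(log$y)^2))
  rotation <- if ("rotation" %in% names(log)) sum(log$rotation)
              else sum(abs(diff(log$bodyHeading))) * pi / 180
  conf <- log$confirmed[!is.na(log$confirmed) & log$confirmed != ""]
  headTurns <- sum(conf %in% c("HEAD_LEFT", "HEAD_RIGHT"))
  cat3 <- ifelse(conf %in% c("HEAD_LEFT", "HEAD_RIGHT"), "explore", "nav")
  transitions <- if (length(cat3) > 1) sum(cat3[-1] != cat3[-length(cat3)])
                 else 0
  NavMetrics(totalTime = max(log$time) - min(log$time),
             distance = dist,
             forwardSteps = dist / walkSpeed,
             turningSteps = rotation / turnSpeed,
             exploredAngle = headTurns * .degToRad(3),
             transitions = transitions,
             collisions = sum(log$collision))
}

.metricsVector <- function(m) {
  c(totalTime = m@totalTime, distance = m@distance,
    forwardSteps = m@forwardSteps, turningSteps = m@turningSteps,
    exploredAngle = m@exploredAngle, transitions = m@transitions,
    collisions = m@collisions)
}

#' Per-metric BCI / manual performance ratios
#'
#' Elementwise ratio of each metric under BCI control to the same metric
#' under manual control; a zero manual value yields `NaN` (undefined
#' marker). Given lists (one element per subject), per-subject ratios are
#' averaged elementwise.
#'
#' @param bci,manual [NavMetrics-class] objects, equal-length lists of
#'   them, or plain named numeric vectors.
#' @return Named numeric vector of ratios; for list input the mean ratio
#'   across subjects, with the per-subject matrix in attribute
#'   `"perSubject"`.
#' @export
ratioReport <- function(bci, manual) {
  toVec <- function(x) if (is(x, "NavMetrics")) .metricsVector(x) else x
  if (is.list(bci)) {
    per <- mapply(function(b, m) toVec(b) / toVec(m),
                  bci, manual)
    out <- rowMeans(per)
    attr(out, "perSubject") <- per
    return(out)
  }
  toVec(bci) / toVec(manual)
}
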