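#' @include AllClasses.R
NULL

#' Fit the protocol arbiter in correlation space
#'
#' Fits two max-margin boundaries over (rho12, rho15) pairs: a
#' degree-2 polynomial-kernel (quadratic) boundary separating the
#' motor-imagery region E from the visual-stimulus region S, and a linear
#' boundary inside S separating the left-stimulus cloud from the right.
#' Both are stored as plain kernel expansions so region prediction needs
#' no fitting library and the model serializes to JSON. Every point of the
#' unit square maps to exactly one of E, S_l, S_r.
#'
#' @param erdPairs n x 2 matrix of pairs from motor-imagery operation
#'   (imagery and idle windows both belong to region E).
#' @param leftPairs,rightPairs n x 2 matrices of pairs recorded under the
#'   left- and right-stimulus conditions.
#' @param cost soft-margin cost for both boundaries.
#' @return A [SelectorModel-class].
#' @export
fitSelector <- function(erdPairs, leftPairs, rightPairs, cost = 1) {
  erdPairs <- as.matrix(erdPairs)
  leftPairs <- as.matrix(leftPairs)
  rightPairs <- as.matrix(rightPairs)
  if (nrow(erdPairs) < 10 || nrow(leftPairs) < 10 || nrow(rightPairs) < 10)
    stop("need at least 10 training pairs per group")
  cents <- rbind(colMeans(erdPairs), colMeans(leftPairs),
                 colMeans(rightPairs))
  if (min(stats::dist(cents)) < 1e-8)
    stop("degenerate training clouds: identical group centers")

  sPairs <- rbind(leftPairs, rightPairs)
  yES <- factor(c(rep("E", nrow(erdPairs)), rep("S", nrow(sPairs))),
                levels = c("E", "S"))
  fitQ <- e1071::svm(rbind(erdPairs, sPairs), yES, kernel = "polynomial",
                     degree = 2, gamma = 1, coef0 = 1, cost = cost,
                     scale = FALSE)
  quadPositive <- if (fitQ$labels[1] == 1L) "E" else "S"

  yLR <- factor(c(rep("S_l", nrow(leftPairs)), rep("S_r", nrow(rightPairs))),
                levels = c("S_l", "S_r"))
  fitL <- e1071::svm(sPairs, yLR, kernel = "linear", cost = cost,
                     scale = FALSE)
  wL <- as.numeric(t(fitL$coefs) %*% fitL$SV)
  bL <- -fitL$rho
  linPositive <- if (fitL$labels[1] == 1L) "S_l" else "S_r"

  new("SelectorModel", quadSV = as.matrix(fitQ$SV),
      quadCoefs = as.numeric(fitQ$coefs), quadRho = fitQ$rho,
      quadGamma = 1, quadCoef0 = 1, quadPositive = quadPositive,
      linWeights = wL, linBias = bL, linPositive = linPositive)
}

#' Predict the arbiter region for correlation pairs
#'
#' @param selector a [SelectorModel-class].
#' @param pairs numeric pair (rho12, rho15) or an n x 2 matrix of pairs.
#' @return Character vector of regions: `"E"`, `"S_l"` or `"S_r"`.
#' @export
predictRegion <- function(selector, pairs) {
  x <- if (is.null(dim(pairs))) matrix(pairs, 1) else as.matrix(pairs)
  k <- (x %*% t(selector@quadSV) * selector@quadGamma +
          selector@quadCoef0)^2
  dq <- as.numeric(k %*% selector@quadCoefs - selector@quadRho)
  isE <- if (selector@quadPositive == "E") dq > 0 else dq <= 0
  dl <- as.numeric(x %*% selector@linWeights + selector@linBias)
  lr <- if (selector@linPositive == "S_l")
    ifelse(dl > 0, "S_l", "S_r") else ifelse(dl > 0, "S_r", "S_l")
  ifelse(isE, "E", lr)
}

#' Classify one analysis window into a command
#'
#' The per-window (250 ms cadence) hybrid decision: the 4-50 Hz-filtered
#' occipital block gives the (rho12, rho15) pair; the arbiter picks the
#' region; in S_l/S_r the head-turn command follows the frequency-direction
#' mapping, in E the motor-imagery detector runs on the 8-30 Hz-filtered
#' window and an `active` decision emits the state-transition switch,
#' otherwise no command.
#'
#' @param selector a [SelectorModel-class].
#' @param cspModel a [CSPModel-class].
#' @param erdClassifier an [ERDClassifier-class].
#' @param w the latest raw 2 s [Window-class] (all channels).
#' @param commandMap named mapping of regions to commands; the default maps
#'   the 12 Hz region to `HEAD_LEFT` and the 15 Hz region to `HEAD_RIGHT`.
#' @return List with `command`, `region`, the correlation `rho` pair and
#'   the ERD `decision` value (`NA` outside region E).
#' @export
classifyWindow <- function(selector, cspModel, erdClassifier, w,
                           commandMap = c(S_l = "HEAD_LEFT",
                                          S_r = "HEAD_RIGHT")) {
  rho <- ssvepCorrelationPair(bandpassFilter(w, 4, 50))
  region <- predictRegion(selector, rho)
  if (region %in% names(commandMap)) {
    return(list(command = unname(commandMap[region]), region = region,
                rho = rho, decision = NA_real_))
  }
  det <- detectERD(cspModel, erdClassifier, bandpassFilter(w, 8, 30))
  cmd <- if (det$label == "active") "ERD_SWITCH" else "NONE"
  list(command = cmd, region = region, rho = rho, decision = det$decision)
}

#' One step of the dynamic fading feedback rule
#'
#' The counter-based confirmation rule that turns the 250 ms classification
#' stream into confirmed commands: the first classification becomes the
#' candidate at level 0; an identical classification raises the level by
#' one, a differing one lowers it by one; once the level has reached zero a
#' further differing classification drops the candidate, and the next
#' classification is adopted fresh; when the level reaches four the
#' candidate is confirmed and the state resets. `NONE` (idle) decrements
#' like any differing input but is never adopted as a candidate and never
#' confirmed, so idle activity alone can never actuate the robot. The
#' shortest path to a confirmation is five consistent inputs, i.e. 1 s at
#' the 250 ms cadence.
#'
#' @param state a [FadingState-class].
#' @param candidate the new per-window classification (a command,
#'   `"NONE"` allowed).
#' @return List with the new `state` and `confirmed` (a command, or
#'   `NA_character_` when nothing was confirmed).
#' @examples
#' st <- FadingState()
#' for (i in 1:5) { r <- fadingStep(st, "HEAD_LEFT"); st <- r$state }
#' r$confirmed  # confirmed on the fifth consistent input
#' @export
fadingStep <- function(state, candidate) {
  if (!(candidate %in% .COMMANDS)) stop("unknown command: ", candidate)
  cur <- state@candidate
  lvl <- state@level
  if (is.na(cur)) {
    if (candidate == "NONE")
      return(list(state = state, confirmed = NA_character_))
    return(list(state = FadingState(candidate, 0L),
                confirmed = NA_character_))
  }
  if (candidate == cur) {
    lvl <- lvl + 1L
    if (lvl >= 4L)
      return(list(state = FadingState(), confirmed = cur))
    return(list(state = FadingState(cur, lvl), confirmed = NA_character_))
  }
  ## differing candidate: decay, or drop the candidate once at level zero
  if (lvl > 0L)
    return(list(state = FadingState(cur, lvl - 1L),
                confirmed = NA_character_))
  list(state = FadingState(), confirmed = NA_character_)
}
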