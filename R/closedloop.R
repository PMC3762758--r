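#' @include AllClasses.R
NULL

#' Train the navigation decoders from synthetic sessions
#'
#' Convenience wrapper reproducing the training-session structure on
#' synthetic data: 20 imagery + 20 idle trials fit the spatial filters and
#' the motor-imagery classifier; 20 trials per stimulus frequency plus the
#' motor-imagery windows provide the (rho12, rho15) clouds the arbiter is
#' fit on (the E cloud contains both imagery and idle windows).
#'
#' @param cfg a [SynthConfig-class]; trials are generated at its SNR.
#' @param nTrials trials per condition.
#' @param attenuation imagery attenuation fraction passed to the generator.
#' @return List with `csp` ([CSPModel-class]), `classifier`
#'   ([ERDClassifier-class]) and `selector` ([SelectorModel-class]).
#' @export
trainHybridDecoders <- function(cfg, nTrials = 20, attenuation = 0.7) {
  erd <- genErdTrials(cfg, nActive = nTrials, nIdle = nTrials,
                      attenuation = attenuation)
  filt <- lapply(erd@windows, bandpassFilter, low = 8, high = 30)
  active <- TrialSet(filt[erd@labels == "active"], "ERD",
                     labels = rep("active", nTrials))
  idle <- TrialSet(filt[erd@labels == "idle"], "ERD",
                   labels = rep("idle", nTrials))
  csp <- fitCSP(active, idle, m = 2)
  feats <- t(vapply(filt, function(w) cspFeatures(csp, w),
                    numeric(2 * csp@m)))
  classifier <- trainERD(feats, erd@labels)

  left <- genSsvepTrials(initialize(cfg, seed = cfg@seed + 1L), freq = 12,
                         n = nTrials)
  right <- genSsvepTrials(initialize(cfg, seed = cfg@seed + 2L), freq = 15,
                          n = nTrials)
  pairsOf <- function(ts) t(vapply(ts@windows, function(w)
    ssvepCorrelationPair(bandpassFilter(w, 4, 50)), numeric(2)))
  selector <- fitSelector(pairsOf(erd), pairsOf(left), pairsOf(right))
  list(csp = csp, classifier = classifier, selector = selector)
}

## Synthesize the 2 s window the scripted brain "produces" for an intent.
.intentWindow <- function(intent, cfg, seed) {
  cfg <- initialize(cfg, seed = as.integer(seed %% .Machine$integer.max))
  ts <- switch(intent,
    HEAD_LEFT = genSsvepTrials(cfg, freq = 12, n = 1),
    HEAD_RIGHT = genSsvepTrials(cfg, freq = 15, n = 1),
    ERD_SWITCH = genErdTrials(cfg, nActive = 1, nIdle = 0),
    NONE = genErdTrials(cfg, nActive = 0, nIdle = 1))
  ts@windows[[1]]
}

## Waypoint-following intent policy for the scripted brain.
.navIntent <- function(s, target, arena, lookahead = 25) {
  bearing <- .radToDeg(atan2(target[2] - s@position[2],
                             target[1] - s@position[1]))
  err <- ((bearing - s@bodyHeading + 180) %% 360) - 180
  if (s@mode == "WALKING") {
    dir <- c(cos(.degToRad(s@bodyHeading)), sin(.degToRad(s@bodyHeading)))
    wall <- .wallHit(s@position, dir * lookahead, arena@walls)
    toGo <- sqrt(sum((target - s@position)^2))
    if (wall <= 1 || abs(err) > 20 || toGo < 8) return("ERD_SWITCH")
    return("NONE")
  }
  ## idle: orient the head toward the target bearing, then switch
  if (abs(err) > 9) {
    gap <- err - s@headOffset
    if (gap > 1.5) return("HEAD_LEFT")
    if (gap < -1.5) return("HEAD_RIGHT")
    return("ERD_SWITCH")        # head on target and off-body: align
  }
  if (abs(s@headOffset) > 9) return("ERD_SWITCH")  # fold head back in
  "ERD_SWITCH"                  # aligned: start walking
}

#' Run the closed-loop surrogate simulation
#'
#' Wires a scripted "oracle brain" to the full decoding stack: every 250 ms
#' the waypoint-following policy picks an intent, the synthetic generator
#' produces the 2 s EEG window that intent would evoke at the configured
#' SNR, [classifyWindow()] decodes it, the fading rule accumulates the
#' decision, and any confirmed command actuates the simulated robot, which
#' is then integrated over the 250 ms step. The run ends when the robot is
#' within `goalTolerance` of the final waypoint (and has stopped) or when
#' `maxTime` elapses.
#'
#' @param decoders list from [trainHybridDecoders()].
#' @param cfg a [SynthConfig-class] for the simulated brain's signals.
#' @param arena an [Arena-class].
#' @param start a [RobotState-class] starting pose.
#' @param waypoints list/matrix of (x, y) waypoints, last one the goal.
#' @param maxTime simulated time budget in seconds.
#' @param goalTolerance waypoint capture radius in cm.
#' @param seed integer seed decorrelating the per-window noise draws.
#' @return List with the trajectory `log` (data.frame: time, x, y,
#'   bodyHeading, headOffset, mode, rotation, candidate, confirmed,
#'   collision), the final `state`, `reachedGoal`, and `metrics`
#'   ([NavMetrics-class]) accumulated live during the run.
#' @export
runClosedLoop <- function(decoders, cfg, arena, start, waypoints,
                          maxTime = 600, goalTolerance = 12, seed = 1L) {
  if (is.matrix(waypoints))
    waypoints <- lapply(seq_len(nrow(waypoints)), function(i) waypoints[i, ])
  s <- start
  fading <- FadingState()
  dt <- 0.25
  nSteps <- ceiling(maxTime / dt)
  wpIdx <- 1
  rows <- vector("list", nSteps)
  live <- list(dist = 0, rot = 0, collisions = 0, conf = character(0))
  reached <- FALSE
  for (k in seq_len(nSteps)) {
    now <- k * dt
    target <- waypoints[[wpIdx]]
    if (sqrt(sum((target - s@position)^2)) < goalTolerance) {
      if (wpIdx < length(waypoints)) {
        wpIdx <- wpIdx + 1
        target <- waypoints[[wpIdx]]
      } else if (s@mode != "WALKING") {
        reached <- TRUE
        rows[[k]] <- data.frame(time = now, x = s@position[1],
                                y = s@position[2],
                                bodyHeading = s@bodyHeading,
                                headOffset = s@headOffset, mode = s@mode,
                                rotation = 0, candidate = NA_character_,
                                confirmed = NA_character_,
                                collision = FALSE)
        break
      }
    }
    intent <- if (s@mode == "ALIGNING") "NONE"
              else .navIntent(s, target, arena)
    w <- .intentWindow(intent, cfg, seed * 100003L + k)
    cls <- classifyWindow(decoders$selector, decoders$csp,
                          decoders$classifier, w)
    step <- fadingStep(fading, cls$command)
    fading <- step$state
    if (!is.na(step$confirmed)) {
      s <- applyCommand(s, step$confirmed)
      live$conf <- c(live$conf, step$confirmed)
    }
    tk <- tickRobot(s, dt, arena)
    s <- tk$state
    live$dist <- live$dist + tk$distance
    live$rot <- live$rot + tk$rotation
    live$collisions <- live$collisions + tk$collision
    rows[[k]] <- data.frame(time = now, x = s@position[1],
                            y = s@position[2], bodyHeading = s@bodyHeading,
                            headOffset = s@headOffset, mode = s@mode,
                            rotation = tk$rotation,
                            candidate = cls$command,
                            confirmed = step$confirmed,
                            collision = tk$collision)
  }
  log <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  headTurns <- sum(live$conf %in% c("HEAD_LEFT", "HEAD_RIGHT"))
  cat3 <- ifelse(live$conf %in% c("HEAD_LEFT", "HEAD_RIGHT"),
                 "explore", "nav")
  metrics <- NavMetrics(
    totalTime = max(log$time) - min(log$time),
    distance = live$dist,
    forwardSteps = live$dist / s@walkSpeed,
    turningSteps = live$rot / s@turnSpeed,
    exploredAngle = headTurns * .degToRad(3),
    transitions = if (length(cat3) > 1)
      sum(cat3[-1] != cat3[-length(cat3)]) else 0,
    collisions = live$collisions)
  list(log = log, state = s, reachedGoal = reached, metrics = metrics)
}
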