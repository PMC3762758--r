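#' @include AllClasses.R
NULL

#' Apply a confirmed command to the surrogate
#'
#' Implements the postural-dependent command semantics: head-turn commands
#' rotate the head by 3 degrees per decision (positive offset = leftward);
#' the motor-imagery switch either triggers body alignment — when head and
#' body differ by more than 9 degrees, the body turns toward the head at
#' 0.13 rad/s, ignoring all commands until aligned — or, when roughly
#' aligned, toggles walking. Commands are ignored entirely in the ALIGNING
#' and RECOGNITION modes.
#'
#' @param s a [RobotState-class].
#' @param cmd a command from [bciCommands()].
#' @return The updated [RobotState-class].
#' @export
applyCommand <- function(s, cmd) {
  if (!(cmd %in% .COMMANDS)) stop("unknown command: ", cmd)
  if (s@mode %in% c("ALIGNING", "RECOGNITION")) return(s)
  if (cmd == "NONE") return(s)
  if (cmd == "HEAD_LEFT")
    return(initialize(s, headOffset = min(s@headOffset + 3, s@headLimit)))
  if (cmd == "HEAD_RIGHT")
    return(initialize(s, headOffset = max(s@headOffset - 3, -s@headLimit)))
  ## ERD_SWITCH
  if (abs(s@headOffset) > 9) {
    initialize(s, mode = "ALIGNING")
  } else {
    initialize(s, mode = if (s@mode == "WALKING") "NAV_IDLE" else "WALKING")
  }
}

## Earliest intersection parameter of the segment p -> p + d with any wall,
## or Inf. Standard 2D segment-segment intersection.
.wallHit <- function(p, d, walls) {
  best <- Inf
  for (i in seq_len(nrow(walls))) {
    a <- walls[i, 1:2]; b <- walls[i, 3:4]
    e <- b - a
    denom <- d[1] * e[2] - d[2] * e[1]
    if (abs(denom) < 1e-12) next
    t <- ((a[1] - p[1]) * e[2] - (a[2] - p[2]) * e[1]) / denom
    u <- ((a[1] - p[1]) * d[2] - (a[2] - p[2]) * d[1]) / denom
    if (t >= 0 && t <= 1 && u >= -1e-9 && u <= 1 + 1e-9) best <- min(best, t)
  }
  best
}

#' Advance the surrogate simulation
#'
#' Integrates the robot pose over `dt` seconds: WALKING advances
#' `walkSpeed * dt` cm along the body heading, stopping at the first wall
#' contact (collision flag set, mode back to NAV_IDLE); ALIGNING rotates
#' the body toward the head at `turnSpeed` rad/s, clamped exactly at
#' alignment (body heading gains the prior head offset, head offset
#' returns to zero, mode NAV_IDLE).
#'
#' @param s a [RobotState-class].
#' @param dt time step in seconds (0.1 s in the closed-loop simulator).
#' @param arena an [Arena-class].
#' @return List with the new `state`, a `collision` flag, the `distance`
#'   walked (cm) and the body `rotation` performed (rad) in this step.
#' @export
tickRobot <- function(s, dt, arena) {
  stopifnot(dt > 0)
  collision <- FALSE
  dist <- 0
  rot <- 0
  if (s@mode == "WALKING") {
    dir <- c(cos(.degToRad(s@bodyHeading)), sin(.degToRad(s@bodyHeading)))
    step <- s@walkSpeed * dt
    hit <- .wallHit(s@position, dir * step, arena@walls)
    if (hit <= 1) {
      dist <- step * max(hit - 1e-9, 0)
      s <- initialize(s, position = s@position + dir * dist,
                      mode = "NAV_IDLE")
      collision <- TRUE
    } else {
      dist <- step
      s <- initialize(s, position = s@position + dir * step)
    }
  } else if (s@mode == "ALIGNING") {
    maxRot <- .radToDeg(s@turnSpeed * dt)
    rotDeg <- min(abs(s@headOffset), maxRot)
    sgn <- sign(s@headOffset)
    s <- initialize(s, bodyHeading = s@bodyHeading + sgn * rotDeg,
                    headOffset = s@headOffset - sgn * rotDeg)
    rot <- .degToRad(rotDeg)
    if (abs(s@headOffset) < 1e-9)
      s <- initialize(s, headOffset = 0, mode = "NAV_IDLE")
  }
  list(state = s, collision = collision, distance = dist, rotation = rot)
}

#' Recognition-mode event plan
#'
#' The timed sequence run while the robot stands still in recognition
#' mode: a 4 s rest, then the randomized flash schedule (each object
#' flashing `flashesPerObject` times at 250 ms spacing), the 600 ms tail of
#' the final epoch, and a 2 s result display before returning to
#' navigation. The flash phase therefore lasts
#' `(nObjects * flashesPerObject - 1) * 0.25 + 0.6` seconds: 2.85 s for two
#' objects and 5.35 s for four, at five flashes each.
#'
#' @param nObjects number of detected objects (>= 2).
#' @param flashesPerObject flashes per object.
#' @param isi inter-stimulus interval in seconds.
#' @param epochSpan epoch length in seconds.
#' @param restDuration pre-flash rest in seconds.
#' @param displayDuration result display in seconds.
#' @return List with the flash `schedule` (data.frame of `time` within the
#'   flash phase and `object`), `restDuration`, `flashPhaseDuration`,
#'   `displayDuration` and `totalDuration`.
#' @export
recognitionSequence <- function(nObjects, flashesPerObject = 5,
                                isi = 0.25, epochSpan = 0.6,
                                restDuration = 4, displayDuration = 2) {
  if (nObjects < 2) stop("recognition needs at least 2 objects")
  nFlash <- nObjects * flashesPerObject
  order <- sample(rep(seq_len(nObjects), flashesPerObject))
  flashPhase <- (nFlash - 1) * isi + epochSpan
  list(schedule = data.frame(time = (seq_len(nFlash) - 1) * isi,
                             object = order),
       restDuration = restDuration,
       flashPhaseDuration = flashPhase,
       displayDuration = displayDuration,
       totalDuration = restDuration + flashPhase + displayDuration)
}

#' Read an arena from a YAML config
#'
#' The config holds `width`, `height`, optional `walls` (list of 4-number
#' segments) and optional `objects` (list of `{x, y, colorId}`).
#'
#' @param path YAML file path.
#' @return An [Arena-class].
#' @export
readArena <- function(path) {
  cfg <- yaml::read_yaml(path)
  inner <- if (length(cfg$walls))
    do.call(rbind, lapply(cfg$walls, as.numeric)) else NULL
  objects <- if (length(cfg$objects))
    do.call(rbind, lapply(cfg$objects, function(o) {
      ## YAML 1.1 parses a bare `y` key as boolean TRUE; map it back
      names(o)[names(o) == "TRUE"] <- "y"
      data.frame(x = o$x, y = o$y, colorId = o$colorId)
    })) else NULL
  Arena(width = cfg$width %||% 150, height = cfg$height %||% 300,
        innerWalls = inner, objects = objects)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
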