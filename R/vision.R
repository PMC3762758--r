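#' @include AllClasses.R
NULL

#' Render the surrogate's camera view
#'
#' Toy pinhole camera producing a single hue-like channel: a `height` x
#' `width` pixel matrix (origin top-left, 0-based coordinates) with value 0
#' for the white background and the object's `colorId` inside each
#' projected blob. Objects within the horizontal field of view of the
#' head's gaze direction are drawn as disks whose radius scales inversely
#' with distance.
#'
#' @param s a [RobotState-class]; the gaze direction is body heading plus
#'   head offset.
#' @param arena an [Arena-class] with object placements.
#' @param width,height frame size in pixels.
#' @param fov horizontal field of view in degrees.
#' @param objectRadius physical object radius in cm.
#' @param maxRange draw distance in cm.
#' @return The pixel matrix.
#' @export
renderView <- function(s, arena, width = 160, height = 120, fov = 60,
                       objectRadius = 8, maxRange = 250) {
  frame <- matrix(0, height, width)
  if (nrow(arena@objects) == 0) return(frame)
  gaze <- s@bodyHeading + s@headOffset
  focal <- (width / 2) / tan(.degToRad(fov / 2))
  for (i in seq_len(nrow(arena@objects))) {
    dx <- arena@objects$x[i] - s@position[1]
    dy <- arena@objects$y[i] - s@position[2]
    d <- sqrt(dx^2 + dy^2)
    if (d < 1 || d > maxRange) next
    bearing <- .radToDeg(atan2(dy, dx)) - gaze
    bearing <- ((bearing + 180) %% 360) - 180
    if (abs(bearing) > fov / 2) next
    ## positive bearing = object to the left = smaller image x
    cx <- width / 2 - focal * tan(.degToRad(bearing))
    cy <- height / 2
    r <- max(focal * objectRadius / d, 1.5)
    cols <- max(1, floor(cx - r)):min(width, ceiling(cx + r))
    rows <- max(1, floor(cy - r)):min(height, ceiling(cy + r))
    for (px in cols) for (py in rows) {
      if ((px - 0.5 - cx)^2 + (py - 0.5 - cy)^2 <= r^2)
        frame[py, px] <- arena@objects$colorId[i]
    }
  }
  frame
}

#' Detect colored objects in a frame
#'
#' The simple color-filtering stage: for each color id, pixels whose value
#' falls inside the color's range are grouped into connected components and
#' each component at least `minArea` pixels large yields a tight bounding
#' box in normalized coordinates (center x, y in \[0, 1\], origin
#' top-left).
#'
#' @param frame pixel matrix from [renderView()].
#' @param colorTable named list mapping color ids to `c(lo, hi)` value
#'   ranges; by default each distinct nonzero value is its own color with
#'   a +/- 0.5 range.
#' @param minArea minimum component area in pixels.
#' @return data.frame with columns `x`, `y`, `width`, `height` (normalized)
#'   and `colorId`; zero rows when nothing is detected.
#' @export
detectObjects <- function(frame, colorTable = NULL, minArea = 9) {
  h <- nrow(frame); w <- ncol(frame)
  if (is.null(colorTable)) {
    vals <- sort(unique(frame[frame != 0]))
    colorTable <- stats::setNames(lapply(vals, function(v) c(v - 0.5, v + 0.5)),
                                  as.character(vals))
  }
  out <- list()
  for (id in names(colorTable)) {
    rng <- colorTable[[id]]
    mask <- frame >= rng[1] & frame <= rng[2] & frame != 0
    if (!any(mask)) next
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), h, w))
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < minArea) next
      rows <- range(idx[, 1]); cols <- range(idx[, 2])
      out[[length(out) + 1]] <- data.frame(
        x = (mean(cols) - 0.5) / w,
        y = (mean(rows) - 0.5) / h,
        width = (cols[2] - cols[1] + 1) / w,
        height = (rows[2] - rows[1] + 1) / h,
        colorId = as.numeric(id))
    }
  }
  if (length(out) == 0)
    return(data.frame(x = numeric(), y = numeric(), width = numeric(),
                      height = numeric(), colorId = numeric()))
  do.call(rbind, out)
}

#' Virtual center of detected objects
#'
#' @param boxes bounding-box data.frame from [detectObjects()] (>= 1 row).
#' @return Numeric (x, y): the unweighted mean of the box centers.
#' @export
virtualCenter <- function(boxes) {
  if (nrow(boxes) == 0) stop("no bounding boxes: cannot form a center")
  c(x = mean(boxes$x), y = mean(boxes$y))
}

#' Central-zone test
#'
#' The frame is divided into five zones per axis; the middle zone — the
#' half-open square \[0.4, 0.6) x \[0.4, 0.6) in normalized coordinates —
#' is the central region that triggers recognition mode.
#'
#' @param center numeric (x, y) from [virtualCenter()].
#' @return Logical.
#' @export
inCentralZone <- function(center) {
  center[1] >= 0.4 && center[1] < 0.6 && center[2] >= 0.4 && center[2] < 0.6
}
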