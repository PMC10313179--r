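#' Arena configuration
#'
#' Describes the recording setup that every unit conversion in the package
#' depends on: frame rate, spatial scale, chamber geometry, group size, the
#' optional food region, and the nominal fly body length.
#'
#' All geometry is in image coordinates: origin at the top-left of the frame,
#' x rightward, y downward, pixel units, 0-based frame indices.
#'
#' @param n_flies Number of flies in the group (N). Must be >= 1.
#' @param mm_per_px Millimetres per pixel. Must be > 0.
#' @param fps Frame rate in frames per second. Default 30.
#' @param chamber Numeric vector `c(cx, cy, r)` giving the circular chamber
#'   centre and radius in pixels. Default is a 4 cm chamber at the default
#'   scale: centre (400, 400), radius 400 px (20 mm / 0.05 mm/px).
#' @param food_roi Optional food region: either
#'   `list(type = "circle", cx =, cy =, r =)` or
#'   `list(type = "polygon", x =, y =)` (vertex coordinates in px).
#'   Must lie inside the chamber.
#' @param body_length_mm Nominal fly body length in mm. Default 2.5.
#'
#' @return An object of class `arena_config` (a named list).
#' @examples
#' cfg <- arena_config(n_flies = 13, mm_per_px = 0.05)
#' cfg$fps
#' @export
arena_config <- function(n_flies,
                         mm_per_px,
                         fps = 30,
                         chamber = c(cx = 400, cy = 400, r = 400),
                         food_roi = NULL,
                         body_length_mm = 2.5) {
  n_flies <- as.integer(n_flies)
  if (is.na(n_flies) || n_flies < 1L) {
    stop("`n_flies` must be an integer >= 1 (got ", n_flies, ").", call. = FALSE)
  }
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L || mm_per_px <= 0) {
    stop("`mm_per_px` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a single positive number.", call. = FALSE)
  }
  chamber <- as.numeric(chamber)
  if (length(chamber) != 3L || chamber[3] <= 0) {
    stop("`chamber` must be c(cx, cy, r) with r > 0.", call. = FALSE)
  }
  names(chamber) <- c("cx", "cy", "r")
  if (!is.null(food_roi)) {
    food_roi <- validate_food_roi(food_roi, chamber)
  }
  if (!is.numeric(body_length_mm) || body_length_mm <= 0) {
    stop("`body_length_mm` must be positive.", call. = FALSE)
  }
  structure(
    list(
      n_flies = n_flies,
      mm_per_px = mm_per_px,
      fps = fps,
      chamber = chamber,
      food_roi = food_roi,
      body_length_mm = body_length_mm
    ),
    class = "arena_config"
  )
}

validate_food_roi <- function(food_roi, chamber) {
  if (!is.list(food_roi) || is.null(food_roi$type)) {
    stop("`food_roi` must be a list with a `type` field.", call. = FALSE)
  }
  if (food_roi$type == "circle") {
    needed <- c("cx", "cy", "r")
    if (!all(needed %in% names(food_roi))) {
      stop("circular food_roi needs fields cx, cy, r.", call. = FALSE)
    }
    if (food_roi$r <= 0) stop("food_roi radius must be > 0.", call. = FALSE)
    d <- sqrt((food_roi$cx - chamber["cx"])^2 + (food_roi$cy - chamber["cy"])^2)
    if (unname(d) + food_roi$r > chamber["r"] + 1e-9) {
      stop("food_roi must lie within the chamber.", call. = FALSE)
    }
  } else if (food_roi$type == "polygon") {
    if (is.null(food_roi$x) || is.null(food_roi$y) ||
        length(food_roi$x) != length(food_roi$y) || length(food_roi$x) < 3L) {
      stop("polygon food_roi needs x and y vertex vectors of equal length >= 3.",
           call. = FALSE)
    }
    d <- sqrt((food_roi$x - chamber["cx"])^2 + (food_roi$y - chamber["cy"])^2)
    if (any(d > chamber["r"] + 1e-9)) {
      stop("food_roi must lie within the chamber.", call. = FALSE)
    }
  } else {
    stop("food_roi type must be 'circle' or 'polygon'.", call. = FALSE)
  }
  food_roi
}

#' @export
print.arena_config <- function(x, ...) {
  cat("<arena_config>\n")
  cat("  n_flies:       ", x$n_flies, "\n")
  cat("  fps:           ", x$fps, "frames/s\n")
  cat("  mm_per_px:     ", x$mm_per_px, "\n")
  cat(sprintf("  chamber:        centre (%g, %g) px, radius %g px (%.1f mm)\n",
              x$chamber["cx"], x$chamber["cy"], x$chamber["r"],
              x$chamber["r"] * x$mm_per_px))
  if (is.null(x$food_roi)) {
    cat("  food_roi:       none\n")
  } else {
    cat("  food_roi:      ", x$food_roi$type, "\n")
  }
  cat("  body_length_mm:", x$body_length_mm, "\n")
  invisible(x)
}

#' Test whether points lie inside the food region
#'
#' @param x,y Pixel coordinates (vectors of equal length).
#' @param config An [arena_config()] with a non-NULL `food_roi`.
#' @return Logical vector.
#' @export
in_food_roi <- function(x, y, config) {
  roi <- config$food_roi
  if (is.null(roi)) stop("config has no food_roi.", call. = FALSE)
  if (roi$type == "circle") {
    (x - roi$cx)^2 + (y - roi$cy)^2 <= roi$r^2
  } else {
    point_in_polygon(x, y, roi$x, roi$y)
  }
}

# Even-odd ray casting; boundary points count as inside (<= on the crossing
# test keeps a point sitting exactly on an edge in the ROI).
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px <= (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
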