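#' Display geometry for a two-choice mouse-tracking task
#'
#' Describes the three screen regions the analysis needs: the start (home)
#' area at the bottom centre of the display and the two response targets in
#' the upper left and right. All regions are axis-aligned rectangles and
#' region membership is boundary-inclusive.
#'
#' Coordinates may be given in either of two frames:
#' \describe{
#'   \item{`"canonical"`}{y increases upward (mathematical convention).}
#'   \item{`"screen"`}{y increases downward (origin at the top of the
#'     display, as logged by most experiment software).}
#' }
#' Analysis functions convert everything to a canonical frame with the
#' start-area centre at the origin and y up; see [as_canonical()].
#'
#' @param start,target_left,target_right Named numeric vectors (or lists)
#'   with elements `x_center`, `y_center`, `width`, `height`, in pixels.
#' @param frame `"canonical"` (y-up) or `"screen"` (y-down).
#' @param tol Absolute tolerance (px) for the left/right mirror-symmetry
#'   check. Default `0` (exact).
#'
#' @return An object of class `display_geometry`.
#'
#' @details The constructor enforces the layout invariants the classifier
#'   relies on: the left target lies left of the start centre and the right
#'   target right of it, both targets lie strictly above the start area
#'   (in the y-up sense), and the two targets are mirror images about the
#'   vertical line through the start-area centre.
#'
#' @examples
#' geom <- display_geometry(
#'   start        = c(x_center = 0, y_center = 0, width = 100, height = 100),
#'   target_left  = c(x_center = -600, y_center = 500, width = 140, height = 140),
#'   target_right = c(x_center = 600, y_center = 500, width = 140, height = 140)
#' )
#' geom
#' @export
display_geometry <- function(start, target_left, target_right,
                             frame = c("canonical", "screen"), tol = 0) {
  frame <- match.arg(frame)
  geom <- structure(
    list(
      start        = as_region(start, "start"),
      target_left  = as_region(target_left, "target_left"),
      target_right = as_region(target_right, "target_right"),
      frame        = frame
    ),
    class = "display_geometry"
  )
  validate_geometry(geom, tol = tol)
  geom
}

as_region <- function(r, name) {
  need <- c("x_center", "y_center", "width", "height")
  r <- unlist(r)
  if (!all(need %in% names(r))) {
    stop("region '", name, "' must supply x_center, y_center, width, height",
         call. = FALSE)
  }
  r <- r[need]
  if (anyNA(r) || !is.numeric(r)) {
    stop("region '", name, "' has non-numeric or missing fields", call. = FALSE)
  }
  if (r[["width"]] < 0 || r[["height"]] < 0) {
    stop("region '", name, "' has negative extent", call. = FALSE)
  }
  as.list(r)
}

validate_geometry <- function(geom, tol = 0) {
  g <- as_canonical(geom, .validate = FALSE)
  st <- g$start; tl <- g$target_left; tr <- g$target_right
  if (!(tl$x_center < st$x_center && st$x_center < tr$x_center)) {
    stop("invalid geometry: targets not on opposite sides of the start area",
         call. = FALSE)
  }
  # strictly above: target bottom edge above start top edge (y-up frame)
  st_top <- st$y_center + st$height / 2
  for (t in list(tl, tr)) {
    if (!(t$y_center - t$height / 2 > st_top)) {
      stop("invalid geometry: targets must lie strictly above the start area",
           call. = FALSE)
    }
  }
  dx_l <- st$x_center - tl$x_center
  dx_r <- tr$x_center - st$x_center
  asym <- max(
    abs(dx_l - dx_r),
    abs(tl$y_center - tr$y_center),
    abs(tl$width - tr$width),
    abs(tl$height - tr$height)
  )
  if (asym > tol) {
    stop("invalid geometry: targets are not mirror-symmetric about the ",
         "start-area centre (max deviation ", format(asym), " px, tolerance ",
         format(tol), ")", call. = FALSE)
  }
  overlap <- function(a, b) {
    abs(a$x_center - b$x_center) < (a$width + b$width) / 2 &&
      abs(a$y_center - b$y_center) < (a$height + b$height) / 2
  }
  if (overlap(st, tl) || overlap(st, tr)) {
    stop("invalid geometry: start area overlaps a target area", call. = FALSE)
  }
  invisible(geom)
}

#' Convert a geometry to the canonical analysis frame
#'
#' The canonical frame has the start-area centre at the origin and y
#' increasing upward. Screen-frame (y-down) geometries have their y axis
#' negated.
#'
#' @param geom A [display_geometry()].
#' @param .validate Internal; skip re-validation.
#' @return A `display_geometry` with `frame = "canonical"` and the start
#'   centre at (0, 0).
#' @export
as_canonical <- function(geom, .validate = TRUE) {
  stopifnot(inherits(geom, "display_geometry"))
  s <- if (geom$frame == "screen") -1 else 1
  cx <- geom$start$x_center
  cy <- geom$start$y_center
  shift <- function(r) {
    r$x_center <- r$x_center - cx
    r$y_center <- s * (r$y_center - cy)
    r
  }
  out <- structure(
    list(
      start        = shift(geom$start),
      target_left  = shift(geom$target_left),
      target_right = shift(geom$target_right),
      frame        = "canonical"
    ),
    class = "display_geometry"
  )
  out
}

#' @export
print.display_geometry <- function(x, ...) {
  cat("<display_geometry> frame:", x$frame, "\n")
  for (nm in c("start", "target_left", "target_right")) {
    r <- x[[nm]]
    cat(sprintf("  %-12s centre (%g, %g), %g x %g px\n",
                nm, r$x_center, r$y_center, r$width, r$height))
  }
  invisible(x)
}

region_bounds <- function(r) {
  c(
    xmin = r$x_center - r$width / 2, xmax = r$x_center + r$width / 2,
    ymin = r$y_center - r$height / 2, ymax = r$y_center + r$height / 2
  )
}

#' Test whether points fall inside a rectangular region
#'
#' Membership is boundary-inclusive: points exactly on an edge count as
#' inside.
#'
#' @param x,y Numeric vectors of coordinates.
#' @param region One region element of a [display_geometry()] (e.g.
#'   `geom$start`).
#' @return Logical vector.
#' @export
in_region <- function(x, y, region) {
  b <- region_bounds(region)
  x >= b[["xmin"]] & x <= b[["xmax"]] & y >= b[["ymin"]] & y <= b[["ymax"]]
}

#' Read or write a display-geometry configuration
#'
#' The configuration is a YAML or JSON document with top-level keys
#' `start`, `target_left`, `target_right` (each with `x_center`,
#' `y_center`, `width`, `height`) and `frame` (`"canonical"` or
#' `"screen"`). Format is chosen by file extension (`.json` for JSON,
#' anything else is parsed as YAML).
#'
#' @param path Path to the configuration file.
#' @param tol Symmetry tolerance passed to [display_geometry()].
#' @return [read_geometry()] returns a validated `display_geometry`;
#'   [write_geometry()] returns `path` invisibly.
#' @export
read_geometry <- function(path, tol = 0) {
  if (!file.exists(path)) stop("geometry file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (nm in c("start", "target_left", "target_right")) {
    if (is.null(cfg[[nm]])) {
      stop("geometry config is missing region '", nm, "'", call. = FALSE)
    }
  }
  display_geometry(
    start = cfg$start, target_left = cfg$target_left,
    target_right = cfg$target_right,
    frame = if (is.null(cfg$frame)) "canonical" else cfg$frame,
    tol = tol
  )
}

#' @param geom A [display_geometry()].
#' @rdname read_geometry
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "display_geometry"))
  cfg <- list(
    start = geom$start, target_left = geom$target_left,
    target_right = geom$target_right, frame = geom$frame
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
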