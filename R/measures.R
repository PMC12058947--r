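#' Signed orthogonal deviations from the ideal line
#'
#' The ideal path of a movement is the straight line through its first and
#' last points. Each point's deviation is its orthogonal distance from
#' that line, signed by the side convention of the canonical flipped
#' frame: deviations toward the opposite (wrong) target — i.e. to the left
#' of the start-to-end direction — are positive, deviations the other way
#' negative.
#'
#' @param x,y Numeric coordinate vectors of equal length (at least 2),
#'   canonical flipped frame.
#' @return Numeric vector of signed deviations (px), zero at both
#'   endpoints.
#' @export
signed_deviations <- function(x, y) {
  if (length(x) < 2 || length(x) != length(y)) {
    stop("need equal-length x and y with at least 2 points", call. = FALSE)
  }
  ex <- x[length(x)] - x[1]
  ey <- y[length(y)] - y[1]
  len <- sqrt(ex^2 + ey^2)
  if (len == 0) {
    stop("ideal line undefined: trajectory endpoints coincide", call. = FALSE)
  }
  ux <- ex / len
  uy <- ey / len
  # z-component of u x (p - p0): positive to the left of the travel direction
  ux * (y - y[1]) - uy * (x - x[1])
}

# arc-length coordinate of each point projected onto the ideal line
ideal_arc <- function(x, y) {
  ex <- x[length(x)] - x[1]
  ey <- y[length(y)] - y[1]
  len <- sqrt(ex^2 + ey^2)
  ((x - x[1]) * ex + (y - y[1]) * ey) / len
}

#' Signed maximum absolute deviation (MAD)
#'
#' The signed orthogonal deviation at the point of maximum absolute
#' deviation from the ideal line. Ties are broken toward the earliest
#' time step.
#'
#' @inheritParams signed_deviations
#' @return A list with `mad_px` (signed deviation, px) and `mad_index`
#'   (0-based time-step index of the maximum).
#' @export
signed_mad <- function(x, y) {
  d <- signed_deviations(x, y)
  i <- which.max(abs(d)) # earliest index on ties
  list(mad_px = d[i], mad_index = i - 1L)
}

#' Signed area under the curve (AUC)
#'
#' The net signed area between the executed path and the ideal line,
#' computed by projecting each point onto the line (arc coordinate s) and
#' accumulating trapezoids of the signed deviation d over s. Lobes on
#' opposite sides of the line cancel, and backtracking (s decreasing)
#' contributes with negative ds, so the result equals the shoelace area of
#' the closed polygon formed by the path and the reversed ideal line.
#' Positive area lies toward the wrong target (same convention as
#' [signed_deviations()]).
#'
#' @inheritParams signed_deviations
#' @return Signed area in px^2.
#' @export
signed_auc <- function(x, y) {
  d <- signed_deviations(x, y)
  s <- ideal_arc(x, y)
  n <- length(d)
  sum((d[-n] + d[-1]) / 2 * diff(s))
}

#' Per-trial movement measures
#'
#' Computes the four per-trial measures from time-normalized movements:
#' initiation time (IT, ms), movement time (MT, ms), signed area under
#' the curve (AUC, px^2) and signed maximum absolute deviation (MAD, px),
#' plus the time-step index of the MAD point (used by the velocity-profile
#' split).
#'
#' @param normalized A normalized-trajectory tibble from
#'   [normalize_time()].
#' @return A tibble with one row per trial: metadata, `it_ms`, `mt_ms`,
#'   `auc_px2`, `mad_px`, `mad_index`.
#' @export
trial_measures <- function(normalized) {
  groups <- split_trials(normalized)
  x <- normalized$x; y <- normalized$y
  nt <- length(groups)
  auc <- mad <- numeric(nt)
  mad_i <- integer(nt)
  for (i in seq_len(nt)) {
    idx <- groups[[i]]
    m <- signed_mad(x[idx], y[idx])
    auc[i] <- signed_auc(x[idx], y[idx])
    mad[i] <- m$mad_px
    mad_i[i] <- m$mad_index
  }
  meta <- trial_meta(normalized, groups)
  first <- vapply(groups, `[`, integer(1), 1L)
  meta$it_ms <- normalized$it_ms[first]
  meta$mt_ms <- normalized$mt_ms[first]
  meta$auc_px2 <- auc
  meta$mad_px <- mad
  meta$mad_index <- mad_i
  tibble::as_tibble(meta)
}
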