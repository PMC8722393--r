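#' Construct a nuclear Dorsal gradient profile
#'
#' Per-nuclear-column nuclear Dorsal levels \eqn{D(x)}, rescaled so that the
#' level at the ventral midline (column 0) is 1. The measured gradient is not
#' shipped with the package, so a parameterized Gaussian family
#' \eqn{D(x) = \exp(-x^2 / (2\sigma^2))} stands in for it; \code{sigma} is
#' expressed in nuclear columns.
#'
#' @param sigma Gaussian width of the gradient, in nuclear columns (> 0).
#'   Default 4, which spans a ~20-column mesoderm.
#' @param half_width Number of columns on each side of the midline
#'   (columns \code{-half_width .. half_width}).
#' @param levels Optional explicit levels for columns \code{0..half_width}
#'   (overrides the Gaussian family; mirrored to negative columns). Must be
#'   non-negative and non-increasing; rescaled so the midline is 1.
#' @return A \code{dorsal_profile}: data frame with columns \code{column}
#'   (signed integer, 0 = ventral midline) and \code{level}.
#' @examples
#' prof <- make_dorsal_profile(sigma = 4, half_width = 9)
#' prof$level[prof$column == 0]  # 1
#' @export
make_dorsal_profile <- function(sigma = 4, half_width = 9, levels = NULL) {
  if (!is.null(levels)) {
    if (length(levels) != half_width + 1L)
      stop("`levels` must have length half_width + 1 (columns 0..half_width)")
    if (any(levels < 0)) stop("Dorsal levels must be non-negative")
    if (any(diff(levels) > 1e-12))
      stop("Dorsal levels must be non-increasing away from the midline")
    lev <- levels / levels[1L]
  } else {
    if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
        sigma <= 0)
      stop("`sigma` must be a single positive number")
    if (half_width < 1L) stop("`half_width` must be >= 1")
    x <- 0:half_width
    lev <- exp(-x^2 / (2 * sigma^2))
  }
  cols <- c(rev(-(1:half_width)), 0:half_width)
  prof <- data.frame(column = cols,
                     level  = c(rev(lev[-1L]), lev))
  class(prof) <- c("dorsal_profile", "data.frame")
  validate_dorsal_profile(prof)
  prof
}

#' Validate a Dorsal profile
#'
#' Checks the profile invariants: midline level 1, non-negative levels,
#' monotone non-increasing with distance from the midline.
#'
#' @param profile A \code{dorsal_profile} or a data frame with \code{column}
#'   and \code{level} columns.
#' @return The profile, invisibly; errors if invalid.
#' @export
validate_dorsal_profile <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("column", "level") %in% names(profile)))
  if (!any(profile$column == 0L))
    stop("profile must contain the midline column 0")
  if (abs(profile$level[profile$column == 0L][1L] - 1) > 1e-9)
    stop("midline Dorsal level must equal 1 (profile is rescaled to 1)")
  if (any(profile$level < 0)) stop("Dorsal levels must be non-negative")
  ord <- order(abs(profile$column), profile$column)
  lev <- profile$level[ord]
  adist <- abs(profile$column)[ord]
  # non-increasing in |column|
  for (side in split(seq_along(lev), sign(profile$column[ord]))) {
    o <- side[order(adist[side])]
    if (any(diff(lev[o]) > 1e-9))
      stop("Dorsal levels must be non-increasing with |column|")
  }
  invisible(profile)
}

#' Linearly interpolate Dorsal level at a fractional column distance
#'
#' Piecewise-linear interpolation of the row-based Dorsal measurement at the
#' exact (real-valued, signed) column distance of a spot or nucleus.
#'
#' @param profile A \code{dorsal_profile}.
#' @param column_distance Numeric vector of signed column distances.
#' @return Interpolated Dorsal levels.
#' @export
interpolate_dorsal <- function(profile, column_distance) {
  validate_dorsal_profile(profile)
  rng <- range(profile$column)
  if (any(column_distance < rng[1L] - 1e-9 | column_distance > rng[2L] + 1e-9))
    stop("column distance outside the support of the Dorsal profile")
  approx(profile$column, profile$level, xout = column_distance,
         method = "linear", ties = "ordered")$y
}
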