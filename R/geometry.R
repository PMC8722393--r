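#' Define the ventral midline from an expression image
#'
#' The 2D expression image (e.g. maximally projected *twi* smFISH signal)
#' is summed along the anteroposterior axis, the resulting 1D dorsoventral
#' profile is smoothed with a moving average, and the midline is the
#' intensity-weighted centroid of the smoothed profile.
#'
#' @param img 2D matrix \code{(y, x)}.
#' @param axis Image axis that runs along the DV direction: \code{"y"}
#'   (rows, default) or \code{"x"}.
#' @param smooth Moving-average window in pixels (default 24, about two
#'   nuclear columns).
#' @return Midline coordinate (pixels, 1-based) along the DV axis.
#' @export
find_midline <- function(img, axis = c("y", "x"), smooth = 24) {
  axis <- match.arg(axis)
  if (!is.matrix(img)) stop("img must be a 2D matrix")
  prof <- if (axis == "y") rowSums(img) else colSums(img)
  k <- rep(1 / max(1, round(smooth)), max(1, round(smooth)))
  if (length(k) %% 2 == 0) k <- c(k, 0)
  sm <- as.numeric(conv1d_axis_cpp(prof, length(prof), k, 0L))
  sm <- sm - min(sm)
  if (sum(sm) <= 0 || max(sm) == 0)
    stop("flat expression profile: no domain to define a midline")
  sum(seq_along(sm) * sm) / sum(sm)
}

#' Estimate the nuclear-column spacing from a DAPI image
#'
#' Nuclei are detected on the (projected) DAPI image as local maxima of
#' the LoG response at a nucleus-scale sigma (above a fixed fraction of
#' the strongest response; nuclei are of comparable brightness), their
#' positions are projected onto the DV axis, projected positions are
#' clustered into columns (split at gaps larger than half the largest
#' gap), and the mean spacing between adjacent column centers is
#' returned.
#'
#' @param dapi 2D matrix (projected DAPI).
#' @param axis DV axis, \code{"y"} or \code{"x"}.
#' @param sigma LoG sigma for nucleus-scale detection (default 6 px).
#' @param peak_frac Fraction of the maximal LoG response above which a
#'   local maximum counts as a nucleus (default 0.2).
#' @return List with \code{spacing} (px per column), \code{centers}
#'   (column DV positions) and \code{nuclei} (data frame of nucleus peak
#'   positions).
#' @export
estimate_column_spacing <- function(dapi, axis = c("y", "x"), sigma = 6,
                                    peak_frac = 0.2) {
  axis <- match.arg(axis)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  filt <- log_filter(dapi, size = size, sigma = sigma)
  d <- dim(filt)
  # 3x3-neighborhood local maxima above peak_frac of the global maximum
  pad <- matrix(-Inf, d[1L] + 2L, d[2L] + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L)] <- filt
  is_peak <- matrix(TRUE, d[1L], d[2L])
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[2:(d[1L] + 1L) + dy, 2:(d[2L] + 1L) + dx]
    is_peak <- is_peak & (filt >= nb)
  }
  is_peak <- is_peak & (filt > peak_frac * max(filt))
  pk <- which(is_peak, arr.ind = TRUE)
  nuc <- data.frame(nucleus_id = seq_len(nrow(pk)),
                    y = pk[, 1L], x = pk[, 2L],
                    response = filt[pk])
  if (nrow(nuc) < 5) stop("fewer than 5 nuclei detected")
  pos <- sort(if (axis == "y") nuc$y else nuc$x)
  gaps <- diff(pos)
  cut <- max(gaps) / 2
  grp <- cumsum(c(1, gaps > cut))
  centers <- as.numeric(tapply(pos, grp, mean))
  if (length(centers) < 2) stop("could not resolve at least two columns")
  list(spacing = mean(diff(centers)), centers = centers, nuclei = nuc)
}

#' Embryo geometry container
#'
#' @param midline_px Midline coordinate along the DV axis (pixels).
#' @param spacing_px Pixels per nuclear column (> 0).
#' @param axis DV axis, \code{"y"} or \code{"x"}.
#' @param roi Optional region of interest \code{c(y0, y1, x0, x1)} in
#'   pixels; spots outside it are flagged excluded. \code{NULL} = whole
#'   image.
#' @return An \code{embryo_geometry} list.
#' @export
embryo_geometry <- function(midline_px, spacing_px, axis = "y", roi = NULL) {
  if (spacing_px <= 0) stop("column spacing must be > 0")
  structure(list(midline_px = midline_px, spacing_px = spacing_px,
                 axis = match.arg(axis, c("y", "x")), roi = roi),
            class = "embryo_geometry")
}

#' Assign signed column distances to spots
#'
#' Column distance = (DV coordinate - midline) / spacing, real-valued and
#' signed. Spots outside the geometry ROI are flagged \code{excluded}.
#'
#' @param spots A \code{spot_calls} data frame.
#' @param geom An [embryo_geometry()].
#' @return \code{spots} with added \code{col_dist}, \code{column}
#'   (nearest integer) and \code{excluded} columns.
#' @export
assign_columns <- function(spots, geom) {
  stopifnot(inherits(geom, "embryo_geometry"))
  dv <- if (geom$axis == "y") spots$y else spots$x
  spots$col_dist <- (dv - geom$midline_px) / geom$spacing_px
  spots$column <- as.integer(round(spots$col_dist))
  spots$excluded <- FALSE
  if (!is.null(geom$roi)) {
    r <- geom$roi
    spots$excluded <- !(spots$y >= r[1L] & spots$y <= r[2L] &
                        spots$x >= r[3L] & spots$x <= r[4L])
  }
  spots
}

#' Assign TS calls to nuclei and count TSs per nucleus
#'
#' A TS is assigned to the nucleus whose circular footprint contains it;
#' failing that, to the nearest nucleus centroid within \code{max_radius}
#' (distance ties broken deterministically by the lower nucleus id);
#' otherwise it stays unassigned. Counts above 2 are flagged.
#'
#' @param ts_spots \code{spot_calls} (2D positions used).
#' @param nuclei Data frame with \code{nucleus_id}, \code{y}, \code{x} and
#'   optionally \code{radius} (otherwise \code{footprint_radius} is used).
#' @param max_radius Maximum centroid distance for fallback assignment.
#' @param footprint_radius Default nucleus footprint radius (px).
#' @return List with \code{spots} (adds \code{nucleus_id}) and
#'   \code{counts} (nucleus_id, n_ts, flagged).
#' @export
assign_nuclei <- function(ts_spots, nuclei, max_radius = 8,
                          footprint_radius = 5) {
  stopifnot(all(c("nucleus_id", "y", "x") %in% names(nuclei)))
  rad <- if ("radius" %in% names(nuclei)) nuclei$radius
         else rep(footprint_radius, nrow(nuclei))
  nid <- rep(NA_integer_, nrow(ts_spots))
  ord <- order(nuclei$nucleus_id)
  for (i in seq_len(nrow(ts_spots))) {
    dd <- sqrt((ts_spots$y[i] - nuclei$y)^2 + (ts_spots$x[i] - nuclei$x)^2)
    inside <- which(dd <= rad)
    if (length(inside)) {
      nid[i] <- nuclei$nucleus_id[inside[which.min(dd[inside])]]
    } else if (min(dd) <= max_radius) {
      best <- which(dd == min(dd))
      nid[i] <- min(nuclei$nucleus_id[best])
    }
  }
  ts_spots$nucleus_id <- nid
  cnt <- table(factor(nid, levels = sort(nuclei$nucleus_id)))
  counts <- data.frame(nucleus_id = as.integer(names(cnt)),
                       n_ts = as.integer(cnt))
  counts$flagged <- counts$n_ts > 2L
  list(spots = ts_spots, counts = counts)
}
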