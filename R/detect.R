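#' Maximum-intensity projection along z
#'
#' @param stack Array with dim \code{c(y, x, z)} (at least one z plane).
#' @return Matrix \code{c(y, x)}; each pixel is the maximum over z.
#' @export
project_max <- function(stack) {
  if (is.matrix(stack)) return(stack)
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[3L] < 1L)
    stop("stack must be a (y, x, z) array with >= 1 z plane")
  apply(stack, c(1L, 2L), max)
}

#' Sampled Laplacian-of-Gaussian kernel (sign-flipped, zero-sum)
#'
#' The analytic LoG of a normalized Gaussian, sampled on an odd grid,
#' negated so that bright blobs give positive response peaks, and shifted
#' to zero sum so that constant images map to zero response.
#'
#' @param size Odd kernel size in pixels (per axis).
#' @param sigma Gaussian sigma, scalar or one per axis.
#' @param ndim 2 or 3.
#' @return Array of dim \code{rep(size, ndim)}.
#' @export
log_kernel <- function(size = 15, sigma = 2.5, ndim = 2) {
  if (size %% 2 == 0) stop("kernel size must be odd")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  sigma <- rep(sigma, length.out = ndim)
  t <- seq_len(size) - (size + 1) / 2
  g <- lapply(sigma, function(s) exp(-t^2 / (2 * s^2)) / (sqrt(2 * pi) * s))
  gpp <- lapply(seq_len(ndim), function(a)
    ((t^2 - sigma[a]^2) / sigma[a]^4) * g[[a]])
  ker <- array(0, dim = rep(size, ndim))
  for (a in seq_len(ndim)) {
    fac <- lapply(seq_len(ndim), function(b) if (b == a) gpp[[b]] else g[[b]])
    term <- Reduce(function(u, v) outer(u, v), fac)
    ker <- ker + term
  }
  ker <- -ker              # bright blobs -> positive peaks
  ker - mean(ker)          # exact zero response to constants
}

# Separable convolution with the sign-flipped zero-sum LoG. Equivalent to
# direct convolution with log_kernel() (the sampled LoG is a sum of ndim
# separable terms; the zero-sum correction is a box sum).
#' Laplacian-of-Gaussian filter for blob enhancement
#'
#' Filters a 2D image or 3D stack with the sign-flipped, zero-sum sampled
#' LoG kernel (see [log_kernel()]): diffraction-limited spots become
#' positive local maxima. Boundaries are handled by reflection. The impulse
#' response equals the sampled kernel itself.
#'
#' @param img Matrix \code{(y, x)} or array \code{(y, x, z)}.
#' @param size Odd kernel size in pixels (default 15).
#' @param sigma Gaussian sigma in pixels, scalar or per axis (default 2.5).
#' @return Filtered array, same shape as the input.
#' @export
log_filter <- function(img, size = 15, sigma = 2.5) {
  d <- dim(img)
  if (is.null(d)) stop("img must be a matrix or 3D array")
  ndim <- length(d)
  if (!ndim %in% c(2L, 3L)) stop("img must be 2D or 3D")
  if (size %% 2 == 0) stop("kernel size must be odd")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  sigma <- rep(sigma, length.out = ndim)
  t <- seq_len(size) - (size + 1) / 2
  g <- lapply(sigma, function(s) exp(-t^2 / (2 * s^2)) / (sqrt(2 * pi) * s))
  gpp <- lapply(seq_len(ndim), function(a)
    ((t^2 - sigma[a]^2) / sigma[a]^4) * g[[a]])

  dims <- as.integer(d)
  x <- as.numeric(img)
  acc <- numeric(length(x))
  for (a in seq_len(ndim)) {
    term <- x
    for (b in seq_len(ndim)) {
      k <- if (b == a) gpp[[b]] else g[[b]]
      term <- conv1d_axis_cpp(term, dims, k, b - 1L)
    }
    acc <- acc + term
  }
  acc <- -acc
  # zero-sum correction: subtract mean(kernel) * box sum of the image
  ksum <- 0
  for (a in seq_len(ndim)) {
    s <- sum(gpp[[a]])
    for (b in seq_len(ndim)) if (b != a) s <- s * sum(g[[b]])
    ksum <- ksum + s
  }
  cmean <- -ksum / size^ndim
  box <- x
  ones <- rep(1, size)
  for (b in seq_len(ndim)) box <- conv1d_axis_cpp(box, dims, ones, b - 1L)
  acc <- acc - cmean * box
  array(acc, dim = d)
}

#' Subtract the local (moving-sphere median) background
#'
#' For each voxel the median intensity inside a sphere (disc in 2D) of the
#' given radius is computed (reflective boundaries) and subtracted;
#' negative residuals are clipped at zero.
#'
#' @param stack Matrix or \code{(y, x, z)} array.
#' @param radius Sphere radius in voxels (>= 1, smaller than every image
#'   extent).
#' @param clip Clip negative residuals at zero (default TRUE). Detection
#'   uses the clipped residual; unbiased flux measurement wants
#'   \code{clip = FALSE} (clipping rectifies noise and inflates the summed
#'   intensity of dim spots).
#' @return Background-subtracted array, same shape.
#' @export
subtract_local_background <- function(stack, radius = 5, clip = TRUE) {
  d <- dim(stack)
  if (is.null(d)) stop("stack must be a matrix or 3D array")
  if (radius < 1) stop("radius must be >= 1")
  if (radius >= min(d)) stop("radius exceeds the image extent")
  bg <- sphere_median_cpp(as.numeric(stack), as.integer(d),
                          as.integer(radius))
  res <- as.numeric(stack) - bg
  if (clip) res <- pmax(res, 0)
  array(res, dim = d)
}

#' Automatic detection-threshold selection from a spot-count scan
#'
#' Candidate thresholds are scanned over the positive response range of a
#' LoG-filtered image and the number of connected components above each is
#' counted. The chosen threshold is the first one in whose environment the
#' spot count stays relatively constant: the first candidate opening a
#' window of \code{window} consecutive candidates whose counts stay within
#' a \code{band} relative band. The scan starts at a few robust noise
#' standard deviations of the response (MAD-estimated), i.e. just below
#' the noise shoulder, so the first count plateau is the spot plateau
#' rather than a noise-speck regime; on noise-free images it starts at the
#' median positive response. A completely flat scan picks the lowest
#' candidate with a warning. The per-step \eqn{|\Delta \log_{10} n|} is
#' returned in the scan for audit.
#'
#' @param filtered LoG-filtered matrix or array (must contain positive
#'   values).
#' @param n_candidates Number of candidate thresholds (>= 10; default 100),
#'   geometrically spaced between a low quantile of the positive responses
#'   and the maximum.
#' @param connectivity Component connectivity (default 8 in 2D, 18 in 3D).
#' @param quantile_lo Fallback start quantile of the positive responses,
#'   used when the image carries no measurable noise floor (default 0.5).
#' @param noise_mult Multiple of the robust response noise sigma at which
#'   the scan starts (default 3).
#' @param window Plateau window length in candidates (default 5).
#' @param band Maximal relative count spread within a plateau window
#'   (default 0.1).
#' @return A \code{threshold_scan}: list with \code{scan} (data frame:
#'   threshold, n_spots, dlog), \code{threshold}, \code{index},
#'   \code{n_spots}.
#' @export
select_threshold <- function(filtered, n_candidates = 100,
                             connectivity = NULL, quantile_lo = 0.5,
                             noise_mult = 3, window = 5, band = 0.1) {
  d <- dim(filtered)
  if (is.null(d)) stop("filtered must be a matrix or 3D array")
  if (n_candidates < 10) stop("n_candidates must be >= 10")
  if (is.null(connectivity)) connectivity <- if (length(d) == 2L) 8L else 18L
  pos <- as.numeric(filtered[filtered > 0])
  if (length(pos) == 0) stop("filtered image has no positive response")
  hi <- max(pos)
  # robust noise scale of the (zero-mean) response; 0 on noise-free images
  sigma_n <- 1.4826 * median(abs(as.numeric(filtered)))
  lo <- noise_mult * sigma_n
  if (lo <= 0 || lo >= hi) lo <- quantile(pos, quantile_lo, names = FALSE)
  if (lo <= 0) lo <- min(pos)
  cand <- exp(seq(log(lo), log(hi), length.out = n_candidates))
  counts <- vapply(cand, function(t)
    count_components_cpp(as.numeric(filtered), as.integer(d), t,
                         as.integer(connectivity)), integer(1))
  # a zero count ends the scan (log undefined beyond it)
  last <- if (any(counts == 0)) which(counts == 0)[1L] - 1L else length(cand)
  if (last < 2L) stop("threshold scan degenerate: no usable candidates")
  cand <- cand[seq_len(last)]
  counts <- counts[seq_len(last)]
  dlog <- c(NA_real_, abs(diff(log10(counts))))
  mx <- max(dlog, na.rm = TRUE)
  if (mx == 0) {
    warning("flat threshold scan; choosing the lowest candidate")
    idx <- 1L
  } else {
    n <- length(counts)
    is_flat <- vapply(seq_len(n), function(i) {
      if (i + window > n) return(FALSE)
      w <- counts[i:(i + window)]
      (max(w) - min(w)) / counts[i] <= band
    }, logical(1))
    cand_idx <- which(is_flat)
    idx <- if (length(cand_idx)) cand_idx[1L] else last
  }
  structure(list(scan = data.frame(threshold = cand, n_spots = counts,
                                   dlog = dlog),
                 threshold = cand[idx], index = idx,
                 n_spots = counts[idx]),
            class = "threshold_scan")
}

#' Call spots as connected components above a threshold
#'
#' Pixels/voxels of the detection image strictly above the threshold are
#' grouped into connected components (8-connected in 2D, 18-connected in
#' 3D by default). Per spot, the intensity-weighted centroid, pixel/voxel
#' count, cumulative intensity (sum over the component in the measurement
#' image) and maximal pixel intensity are reported.
#'
#' @param detection_img LoG-filtered (or otherwise enhanced) image used for
#'   thresholding; matrix or \code{(y, x, z)} array.
#' @param threshold Detection threshold (e.g. from [select_threshold()]).
#' @param measure_img Image on which intensities are measured (typically
#'   the background-subtracted raw image); defaults to
#'   \code{detection_img}.
#' @param connectivity 4/8 (2D) or 6/18/26 (3D); default 8 resp. 18.
#' @param channel Channel label stored with the calls.
#' @param grow Voxel radius by which each component mask is grown (nearest
#'   component wins, ties to the lower label) before measuring intensities.
#'   The super-threshold core of a dim spot covers a smaller fraction of
#'   its flux than that of a bright spot; growing the mask makes cumulative
#'   intensities comparable across brightness (default 3; 0 = literal
#'   component sum).
#' @param min_vox Minimum core (super-threshold) voxel count for a call;
#'   smaller components are dropped as noise specks (default 1 = keep
#'   all).
#' @param raw_img Optional raw image for unbiased flux measurement: when
#'   given, intensities are measured on \code{raw_img} minus its
#'   spot-excluded moving-sphere mean background (the detected spot
#'   territory is left out of the mean, so a spot cannot inflate its own
#'   background estimate), overriding \code{measure_img}.
#' @param bg_radius Sphere radius for the spot-excluded background mean
#'   (default 5).
#' @return A \code{spot_calls} data frame: spot_id, channel, z, y, x,
#'   n_vox, cum_int, max_int, class.
#' @export
call_spots <- function(detection_img, threshold, measure_img = detection_img,
                       connectivity = NULL, channel = "fish", grow = 3L,
                       min_vox = 1L, raw_img = NULL, bg_radius = 5L) {
  d <- dim(detection_img)
  if (is.null(d)) stop("detection_img must be a matrix or 3D array")
  ndim <- length(d)
  if (is.null(connectivity)) connectivity <- if (ndim == 2L) 8L else 18L
  if (ndim == 2L && !connectivity %in% c(4L, 8L))
    stop("2D connectivity must be 4 or 8")
  if (ndim == 3L && !connectivity %in% c(6L, 18L, 26L))
    stop("3D connectivity must be 6, 18 or 26")
  if (!identical(dim(measure_img), d))
    stop("measure_img must have the same shape as detection_img")

  labels <- label_components_cpp(as.numeric(detection_img) > threshold,
                                 as.integer(d), as.integer(connectivity))
  n_comp <- attr(labels, "n_components")
  empty <- data.frame(spot_id = integer(), channel = character(),
                      z = numeric(), y = numeric(), x = numeric(),
                      n_vox = integer(), cum_int = numeric(),
                      max_int = numeric(), class = character())
  class(empty) <- c("spot_calls", "data.frame")
  if (n_comp == 0) return(empty)
  core <- labels
  if (grow > 0)
    labels <- grow_labels_cpp(labels, as.integer(d), as.integer(grow))

  if (!is.null(raw_img)) {
    if (!identical(dim(raw_img), d))
      stop("raw_img must have the same shape as detection_img")
    bgm <- sphere_mean_masked_cpp(as.numeric(raw_img), labels > 0,
                                  as.integer(d), as.integer(bg_radius))
    measure_img <- array(as.numeric(raw_img) - bgm, dim = d)
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  val <- as.numeric(measure_img)[idx]
  w <- pmax(val, 0)
  coords <- arrayInd(idx, d)
  sum_w <- tapply(w, lab, sum)
  sum_w[sum_w == 0] <- 1
  cum <- as.numeric(tapply(val, lab, sum))
  mx <- as.numeric(tapply(val, lab, max))
  n_core <- as.integer(table(factor(core[core > 0], levels = seq_len(n_comp))))
  cy <- as.numeric(tapply(w * coords[, 1L], lab, sum) / sum_w)
  cx <- as.numeric(tapply(w * coords[, 2L], lab, sum) / sum_w)
  cz <- if (ndim == 3L)
    as.numeric(tapply(w * coords[, 3L], lab, sum) / sum_w) else NA_real_

  out <- data.frame(spot_id = seq_len(n_comp), channel = channel,
                    z = cz, y = cy, x = cx, n_vox = n_core,
                    cum_int = cum, max_int = mx, class = "unclassified")
  if (min_vox > 1L) out <- out[out$n_vox >= min_vox, , drop = FALSE]
  class(out) <- c("spot_calls", "data.frame")
  out
}

#' Full 2D TS detection on a maximally projected stack
#'
#' Convenience wrapper chaining [project_max()], [log_filter()] (size 15,
#' sigma 2.5 by default), [select_threshold()] and [call_spots()] with
#' 8-connectivity; intensities are measured on the projected raw image.
#'
#' @param stack \code{(y, x, z)} array or 2D matrix.
#' @param size,sigma LoG filter parameters.
#' @param channel Channel label.
#' @param ... Passed to [select_threshold()].
#' @return List with \code{spots} (a \code{spot_calls} data frame) and
#'   \code{scan} (the \code{threshold_scan}).
#' @export
detect_ts_2d <- function(stack, size = 15, sigma = 2.5, channel = "fish",
                         ...) {
  img <- project_max(stack)
  filt <- log_filter(img, size = size, sigma = sigma)
  scan <- select_threshold(filt, ...)
  spots <- call_spots(filt, scan$threshold, connectivity = 8L,
                      channel = channel, raw_img = img)
  list(spots = spots, scan = scan)
}

#' Full 3D single-molecule detection on a raw stack
#'
#' Chains [subtract_local_background()], a 3D [log_filter()],
#' [select_threshold()] and [call_spots()] with 18-connectivity;
#' intensities are measured on the background-subtracted stack.
#'
#' @param stack \code{(y, x, z)} array.
#' @param radius Moving-sphere background radius (voxels).
#' @param size,sigma 3D LoG parameters (sigma may be per axis).
#' @param min_vox Minimum core voxel count per call (default 4).
#' @param channel Channel label.
#' @param ... Passed to [select_threshold()].
#' @return List with \code{spots}, \code{scan} and \code{bg_subtracted}.
#' @export
detect_spots_3d <- function(stack, radius = 5, size = 9,
                            sigma = c(1.3, 1.3, 1.6), min_vox = 4L,
                            channel = "fish", ...) {
  bg <- subtract_local_background(stack, radius = radius)
  filt <- log_filter(bg, size = size, sigma = sigma)
  scan <- select_threshold(filt, ...)
  # flux is measured on the raw stack minus a spot-excluded local mean
  # background; the clipped median-subtracted residual is for detection
  spots <- call_spots(filt, scan$threshold, connectivity = 18L,
                      channel = channel, min_vox = min_vox,
                      raw_img = stack, bg_radius = radius)
  list(spots = spots, scan = scan, bg_subtracted = bg)
}
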