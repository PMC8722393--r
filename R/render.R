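#' Rendering configuration for synthetic embryo stacks
#'
#' Image stacks are stored in R as arrays with dim \code{c(y, x, z)}; the
#' dorsoventral (DV) axis runs along \code{y} and the ventral midline sits
#' at the image center row. On disk (TIFF) stacks are written plane-wise in
#' ZYX order.
#'
#' @param shape Named or positional integer vector \code{c(y, x, z)}.
#' @param psf_sigma PSF standard deviation in voxels per axis
#'   \code{c(y, x, z)}; all > 0.
#' @param unit_intensity Integrated intensity (photons) of one mRNA
#'   molecule; the intensity calibration unit.
#' @param ratio_ts Planted TS-to-mRNA integrated-intensity ratio
#'   (\eqn{R \ge 1}); a TS carries \code{ratio_ts * unit_intensity}.
#' @param spacing Nuclear column spacing in pixels (also the within-column
#'   nucleus spacing along x).
#' @param nucleus_radius Nucleus footprint radius in pixels.
#' @param n_nuclei_per_column Nuclei rendered per column.
#' @param mrna_per_column Cytoplasmic mRNA count per column: a single
#'   number, a vector aligned with the profile columns, or \code{NULL}.
#' @param shot_noise Apply Poisson shot noise to expected photon counts.
#' @param read_noise_sd Additive Gaussian read-noise sigma (photons);
#'   0 disables.
#' @param background Uniform background level (photons) added before noise.
#' @param packing_limit Minimum allowed center-to-center distance between
#'   planted FISH spots (px); closer pairs are flagged crowded.
#' @param seed Integer seed for spot placement and noise.
#' @return A \code{render_config} list.
#' @export
render_config <- function(shape = c(y = 256, x = 96, z = 16),
                          psf_sigma = c(y = 1.3, x = 1.3, z = 1.6),
                          unit_intensity = 400,
                          ratio_ts = 70,
                          spacing = 12,
                          nucleus_radius = 4.5,
                          n_nuclei_per_column = 6,
                          mrna_per_column = 10,
                          shot_noise = TRUE,
                          read_noise_sd = 1,
                          background = 2,
                          packing_limit = 4,
                          seed = 1L) {
  if (any(psf_sigma <= 0)) stop("all PSF sigmas must be > 0")
  if (ratio_ts < 1) stop("ratio_ts must be >= 1")
  if (unit_intensity < 0 || background < 0)
    stop("intensities must be non-negative")
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be (y, x, z)")
  structure(list(shape = shape, psf_sigma = as.numeric(psf_sigma),
                 unit_intensity = unit_intensity, ratio_ts = ratio_ts,
                 spacing = spacing, nucleus_radius = nucleus_radius,
                 n_nuclei_per_column = as.integer(n_nuclei_per_column),
                 mrna_per_column = mrna_per_column,
                 shot_noise = isTRUE(shot_noise),
                 read_noise_sd = read_noise_sd, background = background,
                 packing_limit = packing_limit, seed = as.integer(seed)),
            class = "render_config")
}

# Add one PSF-blurred spot (truncated at 4 sigma, renormalized so the
# rendered voxels sum exactly to `intensity`) into `img` in place-ish.
add_gaussian_spot <- function(img, y, x, z, intensity, sigma) {
  d <- dim(img)
  win <- ceiling(4 * sigma)
  ys <- max(1L, floor(y - win[1L])):min(d[1L], ceiling(y + win[1L]))
  xs <- max(1L, floor(x - win[2L])):min(d[2L], ceiling(x + win[2L]))
  zs <- max(1L, floor(z - win[3L])):min(d[3L], ceiling(z + win[3L]))
  gy <- exp(-(ys - y)^2 / (2 * sigma[1L]^2))
  gx <- exp(-(xs - x)^2 / (2 * sigma[2L]^2))
  gz <- exp(-(zs - z)^2 / (2 * sigma[3L]^2))
  ker <- outer(outer(gy, gx), gz)
  ker <- ker * (intensity / sum(ker))
  img[ys, xs, zs] <- img[ys, xs, zs, drop = FALSE] + ker
  img
}

# Nucleus grid on hexagonally offset columns. Returns centers and geometry.
nucleus_grid <- function(columns, cfg) {
  ny <- cfg$shape[1L]; nx <- cfg$shape[2L]
  mid_y <- (ny + 1) / 2
  y <- mid_y + columns * cfg$spacing
  if (any(y < cfg$nucleus_radius + 1 | y > ny - cfg$nucleus_radius))
    stop("image too small for the configured column grid")
  n_per <- cfg$n_nuclei_per_column
  x0 <- (nx - (n_per - 1) * cfg$spacing) / 2
  if (x0 < cfg$nucleus_radius + 1)
    stop("image too small for the configured nuclei per column")
  rows <- expand.grid(idx = seq_len(n_per), column = columns)
  rows$y <- mid_y + rows$column * cfg$spacing
  rows$x <- x0 + (rows$idx - 1) * cfg$spacing +
    ifelse(rows$column %% 2 == 0, 0, cfg$spacing / 2)
  rows$x <- pmin(pmax(rows$x, cfg$nucleus_radius + 1),
                 nx - cfg$nucleus_radius)
  rows$nucleus_id <- seq_len(nrow(rows))
  list(nuclei = rows, midline_y = mid_y)
}

#' Render a multi-channel synthetic embryo image stack
#'
#' Builds a DAPI channel (one blob per nucleus on a hexagonally offset
#' column grid) and an smFISH channel containing one bright TS spot per
#' active allele (integrated intensity \code{ratio_ts * unit_intensity},
#' placed uniformly inside the nucleus footprint) plus unit-intensity
#' cytoplasmic mRNA spots. Spots are PSF-blurred analytically; Poisson shot
#' noise and Gaussian read noise are applied after blurring. The planted
#' ground truth is returned alongside the stacks.
#'
#' @param activation An \code{allele_activation} table (see
#'   [simulate_activation()]); nucleus indices must not exceed
#'   \code{cfg$n_nuclei_per_column}.
#' @param profile The \code{dorsal_profile} used for the mRNA count
#'   gradient (and for record-keeping in the truth).
#' @param cfg A [render_config()].
#' @param ts_scale Optional per-column multiplier of TS intensity (named by
#'   column or aligned with \code{profile$column}); models Dorsal-graded
#'   Pol II loading on the generation side.
#' @return List with \code{stacks} (named list of \code{(y, x, z)} arrays:
#'   \code{dapi}, \code{fish}), \code{truth} (data frame: spot_id, class,
#'   z, y, x, intensity, column, nucleus_id, crowded), \code{nuclei},
#'   \code{geometry} (midline_y, spacing), \code{config}.
#' @export
render_embryo <- function(activation, profile, cfg, ts_scale = NULL) {
  stopifnot(inherits(cfg, "render_config"))
  validate_dorsal_profile(profile)
  columns <- sort(unique(profile$column))
  grid <- nucleus_grid(columns, cfg)
  nuc <- grid$nuclei
  ny <- cfg$shape[1L]; nx <- cfg$shape[2L]; nz <- cfg$shape[3L]
  set.seed(cfg$seed)

  # DAPI channel: one blob per nucleus
  dapi <- array(0, dim = cfg$shape)
  sig_nuc <- c(cfg$nucleus_radius / 1.5, cfg$nucleus_radius / 1.5, nz / 5)
  for (i in seq_len(nrow(nuc)))
    dapi <- add_gaussian_spot(dapi, nuc$y[i], nuc$x[i], (nz + 1) / 2,
                              cfg$unit_intensity * 50, sig_nuc)

  # TS spots: one per active allele, uniform inside the nucleus footprint
  act <- activation[activation$active &
                    activation$nucleus <= cfg$n_nuclei_per_column &
                    activation$column %in% columns, , drop = FALSE]
  ts <- NULL
  if (nrow(act) > 0) {
    key <- match(paste(act$column, act$nucleus),
                 paste(nuc$column, nuc$idx))
    theta <- runif(nrow(act), 0, 2 * pi)
    rad <- (cfg$nucleus_radius - 1) * sqrt(runif(nrow(act)))
    scl <- rep(1, nrow(act))
    if (!is.null(ts_scale)) {
      s <- ts_scale[match(act$column, profile$column)]
      scl <- ifelse(is.na(s), 1, s)
    }
    ts <- data.frame(class = "TS",
                     y = nuc$y[key] + rad * sin(theta),
                     x = nuc$x[key] + rad * cos(theta),
                     z = (nz + 1) / 2 + runif(nrow(act), -nz / 6, nz / 6),
                     intensity = cfg$ratio_ts * cfg$unit_intensity * scl,
                     column = act$column, nucleus_id = nuc$nucleus_id[key])
  }

  # cytoplasmic mRNA spots, kept outside all nucleus footprints
  mr <- NULL
  if (!is.null(cfg$mrna_per_column)) {
    counts <- cfg$mrna_per_column
    if (length(counts) == 1L) counts <- rep(counts, length(columns))
    mr_list <- vector("list", length(columns))
    for (ci in seq_along(columns)) {
      n_mr <- round(counts[ci])
      if (n_mr <= 0) next
      ycen <- grid$midline_y + columns[ci] * cfg$spacing
      pts <- matrix(NA_real_, 0, 3)
      guard <- 0
      while (nrow(pts) < n_mr && guard < 60) {
        guard <- guard + 1
        yy <- runif(2 * n_mr, max(3, ycen - cfg$spacing / 2),
                    min(ny - 2, ycen + cfg$spacing / 2))
        xx <- runif(2 * n_mr, 3, nx - 2)
        zz <- runif(2 * n_mr, 2, nz - 1)
        dn <- vapply(seq_along(yy), function(i)
          min((yy[i] - nuc$y)^2 + (xx[i] - nuc$x)^2), numeric(1))
        ok <- dn > (cfg$nucleus_radius + 1)^2
        pts <- rbind(pts, cbind(yy[ok], xx[ok], zz[ok]))
      }
      pts <- pts[seq_len(min(n_mr, nrow(pts))), , drop = FALSE]
      if (nrow(pts) > 0)
        mr_list[[ci]] <- data.frame(class = "mRNA", y = pts[, 1],
                                    x = pts[, 2], z = pts[, 3],
                                    intensity = cfg$unit_intensity,
                                    column = columns[ci],
                                    nucleus_id = NA_integer_)
    }
    mr <- do.call(rbind, mr_list)
  }

  truth <- rbind(ts, mr)
  if (is.null(truth) || nrow(truth) == 0)
    truth <- data.frame(class = character(), y = numeric(), x = numeric(),
                        z = numeric(), intensity = numeric(),
                        column = integer(), nucleus_id = integer())
  truth <- cbind(spot_id = seq_len(nrow(truth)), truth)

  # crowding check
  truth$crowded <- FALSE
  if (nrow(truth) > 1) {
    dd <- as.matrix(stats::dist(truth[, c("y", "x", "z")]))
    diag(dd) <- Inf
    crowded <- apply(dd, 1, min) < cfg$packing_limit
    if (any(crowded)) {
      warning(sum(crowded), " planted spots closer than the packing limit")
      truth$crowded <- crowded
    }
  }

  fish <- array(0, dim = cfg$shape)
  for (i in seq_len(nrow(truth)))
    fish <- add_gaussian_spot(fish, truth$y[i], truth$x[i], truth$z[i],
                              truth$intensity[i], cfg$psf_sigma)

  stacks <- list(dapi = apply_noise(dapi, cfg),
                 fish = apply_noise(fish, cfg))

  list(stacks = stacks,
       truth = truth[, c("spot_id", "class", "z", "y", "x", "intensity",
                         "column", "nucleus_id", "crowded")],
       nuclei = nuc,
       geometry = list(midline_y = grid$midline_y, spacing = cfg$spacing,
                       nucleus_radius = cfg$nucleus_radius),
       config = cfg)
}

#' Render a calibration field of well-separated TS and mRNA spots
#'
#' Plants \code{n_ts} bright TS spots (integrated intensity
#' \code{ratio_ts * unit_intensity}) and \code{n_mrna} unit-intensity mRNA
#' spots at uniform random positions with a minimum pairwise distance, so
#' that every planted spot resolves as its own component. Used for
#' intensity-ratio calibration (Pol II loading) and detector validation.
#'
#' @param n_mrna,n_ts Planted spot numbers.
#' @param cfg A [render_config()] (shape, PSF, intensities, noise).
#' @param min_dist Minimum center-to-center distance in voxels (default
#'   12).
#' @param margin Margin kept free at the stack borders (default 6).
#' @return List with \code{stack} (single smFISH channel) and \code{truth}
#'   (spot_id, class, z, y, x, intensity).
#' @export
render_spot_field <- function(n_mrna, n_ts, cfg, min_dist = 12, margin = 6) {
  stopifnot(inherits(cfg, "render_config"))
  d <- cfg$shape
  n <- n_mrna + n_ts
  set.seed(cfg$seed)
  pts <- matrix(NA_real_, 0, 3)
  guard <- 0L
  while (nrow(pts) < n && guard < 200L * n) {
    guard <- guard + 1L
    p <- c(runif(1, margin, d[1L] - margin), runif(1, margin, d[2L] - margin),
           runif(1, 3, d[3L] - 2))
    if (nrow(pts) == 0 ||
        min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 +
              (pts[, 3] - p[3])^2) >= min_dist^2)
      pts <- rbind(pts, p)
  }
  if (nrow(pts) < n)
    stop("could not place ", n, " spots at min_dist = ", min_dist,
         " in this volume")
  cls <- c(rep("TS", n_ts), rep("mRNA", n_mrna))
  truth <- data.frame(spot_id = seq_len(n), class = cls,
                      z = pts[, 3], y = pts[, 1], x = pts[, 2],
                      intensity = ifelse(cls == "TS",
                                         cfg$ratio_ts * cfg$unit_intensity,
                                         cfg$unit_intensity))
  stack <- array(0, dim = d)
  for (i in seq_len(n))
    stack <- add_gaussian_spot(stack, truth$y[i], truth$x[i], truth$z[i],
                               truth$intensity[i], cfg$psf_sigma)
  list(stack = apply_noise(stack, cfg), truth = truth)
}

apply_noise <- function(img, cfg) {
  out <- img + cfg$background
  if (cfg$shot_noise) out[] <- rpois(length(out), lambda = out)
  if (cfg$read_noise_sd > 0)
    out[] <- out + rnorm(length(out), sd = cfg$read_noise_sd)
  pmax(out, 0)
}

#' Write a rendered fixture to disk (TIFF + CSV + YAML)
#'
#' One 32-bit float TIFF per channel (planes are z slices in ZYX order;
#' TIFF stores values in \[0, 1\], so each channel is divided by a scale
#' recorded in \code{tiff_scales.yaml}), a ground-truth CSV and a YAML
#' snapshot of the render configuration, from which the identical stacks
#' can be re-rendered under the same seed.
#'
#' @param embryo Output of [render_embryo()].
#' @param out_dir Writable directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(embryo, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c()
  scales <- list()
  for (ch in names(embryo$stacks)) {
    p <- file.path(out_dir, paste0(ch, ".tif"))
    stack <- embryo$stacks[[ch]]
    sc <- max(stack, 1e-12)
    scales[[ch]] <- sc
    planes <- lapply(seq_len(dim(stack)[3L]), function(z) stack[, , z] / sc)
    tiff::writeTIFF(planes, p, bits.per.sample = 32L, reduce = FALSE)
    paths[ch] <- p
  }
  sp <- file.path(out_dir, "tiff_scales.yaml")
  yaml::write_yaml(scales, sp)
  paths["scales"] <- sp
  tp <- file.path(out_dir, "truth.csv")
  write.csv(embryo$truth, tp, row.names = FALSE)
  paths["truth"] <- tp
  cp <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(embryo$config), cp)
  paths["config"] <- cp
  invisible(paths)
}

#' Read a channel stack written by [write_fixture()]
#'
#' @param path TIFF path.
#' @param scale Intensity scale the stored \[0, 1\] values are multiplied
#'   by (see \code{tiff_scales.yaml}); default 1.
#' @return Array with dim \code{c(y, x, z)}.
#' @export
read_stack <- function(path, scale = 1) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(planes)) planes <- list(planes)
  arr <- array(0, dim = c(dim(planes[[1L]]), length(planes)))
  for (z in seq_along(planes)) arr[, , z] <- planes[[z]] * scale
  arr
}

#' Read back a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with \code{stacks} (rescaled to photons), \code{truth}
#'   and \code{config} (a [render_config()]).
#' @export
read_fixture <- function(dir) {
  scales <- yaml::read_yaml(file.path(dir, "tiff_scales.yaml"))
  stacks <- lapply(names(scales), function(ch)
    read_stack(file.path(dir, paste0(ch, ".tif")), scale = scales[[ch]]))
  names(stacks) <- names(scales)
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg_raw <- lapply(cfg_raw, function(v) if (is.list(v)) unlist(v) else v)
  list(stacks = stacks,
       truth = read.csv(file.path(dir, "truth.csv")),
       config = do.call(render_config, cfg_raw))
}
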