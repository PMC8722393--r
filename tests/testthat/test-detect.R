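test_that("max projection reduces z exactly like a per-pixel maximum", {
  one <- array(runif(6 * 5), dim = c(6, 5, 1))
  expect_equal(project_max(one), one[, , 1])
  # two planes with disjoint spots both survive projection
  st <- array(0, dim = c(10, 10, 2))
  st[3, 3, 1] <- 7; st[8, 8, 2] <- 9
  pr <- project_max(st)
  expect_equal(pr[3, 3], 7)
  expect_equal(pr[8, 8], 9)
  # random stack against the brute-force elementwise oracle
  set.seed(1)
  st <- array(runif(8 * 7 * 5), dim = c(8, 7, 5))
  oracle <- matrix(NA_real_, 8, 7)
  for (y in 1:8) for (x in 1:7) oracle[y, x] <- max(st[y, x, ])
  expect_equal(project_max(st), oracle)
  expect_error(project_max(array(0, c(4, 4, 0))), "z plane")
})

test_that("LoG filter annihilates constants and reproduces its kernel", {
  expect_lt(max(abs(log_filter(matrix(5, 30, 30)))), 1e-10)
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  resp <- log_filter(img, size = 15, sigma = 2.5)
  expect_equal(resp[14:28, 14:28], log_kernel(15, 2.5, ndim = 2),
               tolerance = 1e-12)
  st <- array(0, c(21, 21, 21)); st[11, 11, 11] <- 1
  resp3 <- log_filter(st, size = 9, sigma = 1.4)
  expect_equal(resp3[7:15, 7:15, 7:15], log_kernel(9, 1.4, ndim = 3),
               tolerance = 1e-12)
  expect_lt(abs(sum(log_kernel(15, 2.5, 2))), 1e-12)
  expect_error(log_filter(img, size = 14), "odd")
})

test_that("LoG response peaks at the center of a matched Gaussian blob", {
  img <- matrix(0, 41, 41)
  for (y in 1:41) for (x in 1:41)
    img[y, x] <- exp(-((y - 21)^2 + (x - 26)^2) / (2 * 2.5^2))
  resp <- log_filter(img, size = 15, sigma = 2.5)
  expect_equal(as.integer(which(resp == max(resp), arr.ind = TRUE)),
               c(21L, 26L))
})

test_that("moving-sphere median background matches the brute-force oracle", {
  expect_equal(subtract_local_background(matrix(4, 15, 15), radius = 3),
               matrix(0, 15, 15))
  set.seed(2)
  crop <- array(rpois(9 * 9 * 9, 5), dim = c(9, 9, 9))
  crop[5, 5, 5] <- 80
  med <- oracle_sphere_median(crop, 2)
  got <- subtract_local_background(crop, radius = 2)
  expect_equal(got, array(pmax(crop - med, 0), dim(crop)), tolerance = 1e-12)
  # isolated bright spot on a flat background keeps its amplitude
  flat <- array(3, dim = c(15, 15, 15)); flat[8, 8, 8] <- 103
  res <- subtract_local_background(flat, radius = 4)
  expect_equal(res[8, 8, 8], 100)
  expect_equal(sum(res) - res[8, 8, 8], 0)
  # linear ramp residual is bounded by slope * radius
  ramp <- matrix(rep(seq_len(30), each = 30), 30, 30) * 2
  rres <- subtract_local_background(ramp, radius = 4)
  expect_lte(max(rres), 2 * 4)
  expect_error(subtract_local_background(matrix(0, 4, 4), radius = 5),
               "extent")
})

test_that("threshold selection returns the planted count on clean images", {
  st <- array(0, c(120, 120, 1))
  set.seed(3)
  ys <- c(15, 15, 40, 40, 65, 65, 90, 90, 105, 105)
  xs <- c(25, 85, 25, 85, 25, 85, 25, 85, 40, 70)
  for (i in 1:10)
    st <- gradedTS:::add_gaussian_spot(st, ys[i], xs[i], 1, 500, c(2, 2, 0.5))
  filt <- log_filter(st[, , 1], 15, 2.5)
  expect_warning(scan <- select_threshold(filt), "flat")
  expect_equal(scan$n_spots, 10L)
  # spot counts never increase with threshold on a clean image
  expect_true(all(diff(scan$scan$n_spots) <= 0))
  # the scan's own counts agree with independent recounts at each level
  at <- unique(pmin(c(1L, 25L, 50L, nrow(scan$scan)), nrow(scan$scan)))
  recount <- vapply(scan$scan$threshold[at], function(t)
    max(oracle_label(filt > t, 8)), integer(1))
  expect_equal(recount, scan$scan$n_spots[at])
})

test_that("a single spot yields one component at any sub-peak threshold", {
  st <- array(0, c(40, 40, 1))
  st <- gradedTS:::add_gaussian_spot(st, 20, 20, 1, 300, c(2, 2, 0.5))
  filt <- log_filter(st[, , 1], 15, 2.5)
  expect_warning(scan <- select_threshold(filt), "flat")
  expect_equal(scan$n_spots, 1L)
  expect_true(all(scan$scan$n_spots == 1L))
})

test_that("threshold selection lands above the noise shoulder when spots exist", {
  set.seed(4)
  img <- matrix(rpois(150 * 150, 4) + rnorm(150 * 150), 150, 150)
  st <- array(img, c(150, 150, 1))
  ys <- rep(seq(20, 140, by = 30), times = 5)
  xs <- rep(seq(20, 140, by = 30), each = 5)
  for (i in seq_along(ys))
    st <- gradedTS:::add_gaussian_spot(st, ys[i], xs[i], 1, 900, c(2, 2, 0.5))
  filt <- log_filter(st[, , 1], 15, 2.5)
  scan <- select_threshold(filt)
  expect_equal(scan$n_spots, length(ys))
  # pure noise: the scan still terminates with a small speck count at a
  # threshold several noise sigmas up
  scan0 <- select_threshold(log_filter(img, 15, 2.5))
  expect_lt(scan0$n_spots, 50)
  expect_error(select_threshold(matrix(-1, 10, 10)), "positive")
})

test_that("connectivity semantics follow the 8/18/26 neighborhood rules", {
  # two pixels touching diagonally: one spot at 8, two at 4
  m <- matrix(0, 6, 6); m[2, 2] <- 1; m[3, 3] <- 1
  expect_equal(nrow(call_spots(m, 0.5, connectivity = 8L, grow = 0L)), 1L)
  expect_equal(nrow(call_spots(m, 0.5, connectivity = 4L, grow = 0L)), 2L)
  # corner-touching voxels: separate at 18, joined at 26
  a <- array(0, c(4, 4, 4)); a[2, 2, 2] <- 1; a[3, 3, 3] <- 1
  expect_equal(nrow(call_spots(a, 0.5, connectivity = 18L, grow = 0L)), 2L)
  expect_equal(nrow(call_spots(a, 0.5, connectivity = 26L, grow = 0L)), 1L)
  # edge-touching voxels are joined at 18
  b <- array(0, c(4, 4, 4)); b[2, 2, 2] <- 1; b[3, 3, 2] <- 1
  expect_equal(nrow(call_spots(b, 0.5, connectivity = 18L, grow = 0L)), 1L)
  expect_error(call_spots(m, 0.5, connectivity = 18L), "connectivity")
  expect_error(call_spots(a, 0.5, connectivity = 8L), "connectivity")
})

test_that("component labeling agrees with a flood-fill oracle on random grids", {
  set.seed(5)
  for (rep in 1:10) {
    mask <- array(runif(1000) < 0.35, dim = c(10, 10, 10))
    for (conn in c(6L, 18L, 26L)) {
      got <- gradedTS:::label_components_cpp(as.logical(mask),
                                             dim(mask), conn)
      want <- oracle_label(mask, conn)
      expect_equal(array(got, dim(mask)), want,
                   info = paste("rep", rep, "conn", conn))
    }
  }
  mask2 <- matrix(runif(400) < 0.4, 20, 20)
  for (conn in c(4L, 8L)) {
    got <- gradedTS:::label_components_cpp(as.logical(mask2), dim(mask2),
                                           conn)
    expect_equal(matrix(got, 20, 20), oracle_label(mask2, conn))
  }
})

test_that("spot calls report centroid, size and intensities correctly", {
  m <- matrix(0, 11, 11)
  m[5:6, 5] <- c(4, 8)  # two-pixel component
  calls <- call_spots(m, 0.5, connectivity = 8L, grow = 0L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_vox, 2L)
  expect_equal(calls$cum_int, 12)
  expect_equal(calls$max_int, 8)
  expect_equal(calls$y, (5 * 4 + 6 * 8) / 12)
  expect_equal(calls$x, 5)
  expect_true(calls$cum_int >= calls$max_int)
})

test_that("detection on a noise-free field is perfect and flux-accurate", {
  fx <- fx_field_clean()
  res <- match_truth(fx$det$spots, fx$field$truth, radius = 2)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  flux_ratio <- fx$det$spots$cum_int / fx$field$truth$intensity[res$nn]
  expect_true(all(abs(flux_ratio - 1) < 0.1))
})
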