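make_two_pop <- function(n_m = 60, n_t = 15, ratio = 50, noise = 0) {
  set.seed(20)
  data.frame(
    spot_id = seq_len(n_m + n_t), channel = "fish",
    z = NA_real_, y = runif(n_m + n_t, 1, 100),
    x = runif(n_m + n_t, 1, 100), n_vox = 10L,
    cum_int = c(rnorm(n_m, 100, noise * 100),
                rnorm(n_t, 100 * ratio, noise * 100 * ratio)),
    max_int = c(rnorm(n_m, 10, noise * 10),
                rnorm(n_t, 10 * ratio, noise * 10 * ratio)),
    class = "unclassified")
}

test_that("two clean populations are split without misclassification", {
  spots <- make_two_pop(noise = 0.05)
  cls <- classify_spots(spots)
  expect_gt(cls$cutoff, max(spots$max_int[1:60]))
  expect_lt(cls$cutoff, min(spots$max_int[61:75]))
  expect_equal(sum(cls$spots$class == "TS"), 15)
  expect_equal(cls$ratio, median(spots$cum_int[61:75]) /
                 median(spots$cum_int[1:60]))
  expect_equal(cls$polII, cls$ratio)
})

test_that("classification cutoff is invariant to global intensity scaling", {
  spots <- make_two_pop(noise = 0.05)
  cls1 <- classify_spots(spots)
  spots10 <- transform(spots, cum_int = cum_int * 10,
                       max_int = max_int * 10)
  cls10 <- classify_spots(spots10)
  expect_equal(cls10$spots$class, cls1$spots$class)
  expect_equal(cls10$cutoff / cls1$cutoff, 10, tolerance = 0.05)
  expect_equal(cls10$ratio, cls1$ratio, tolerance = 1e-9)
})

test_that("unimodal intensity histograms are rejected with a clear error", {
  set.seed(21)
  uni <- data.frame(spot_id = 1:80, channel = "f", z = NA, y = 1, x = 1,
                    n_vox = 5L, cum_int = rnorm(80, 100, 5),
                    max_int = rnorm(80, 10, 0.5), class = "u")
  expect_error(classify_spots(uni), "unimodal")
  expect_error(classify_spots(uni[1:10, ]), "20 spots")
})

test_that("planted intensity ratios are recovered from rendered fields", {
  fx70 <- fx_field70()
  cls70 <- classify_spots(fx70$det$spots)
  expect_lt(abs(cls70$ratio - 70) / 70, 0.1)
  expect_equal(sum(cls70$spots$class == "TS"), 20)
  fx30 <- fx_field30()
  cls30 <- classify_spots(fx30$det$spots)
  expect_lt(abs(cls30$ratio - 30) / 30, 0.1)
})

test_that("Pol II packing density follows 1000 L / N", {
  d <- polII_density(70, builtin_gene("T48"))
  expect_equal(d$bp_per_polII, 1000 * 29 / 70)
  expect_equal(signif(d$bp_per_polII, 1), 400)
  dm <- polII_density(30, 9.3, reference = list(N = 70, gene = 29))
  expect_equal(dm$bp_per_polII, 310)
  expect_equal(dm$density_vs_reference, (1000 * 29 / 70) / 310)
  expect_equal(polII_density(1, 12)$bp_per_polII, 12000)
  expect_error(polII_density(0, 29), "N must be")
})

test_that("column summaries count alleles, nuclei and histograms coherently", {
  nuc <- data.frame(nucleus_id = 1:6, column = rep(c(0L, 1L), each = 3),
                    y = 1:6, x = 1)
  ts <- data.frame(spot_id = 1:5, y = 1, x = 1,
                   nucleus_id = c(1L, 1L, 2L, 4L, NA), cum_int = c(2, 4, 6, 8, 1))
  s <- summarize_columns(ts, nuc)
  c0 <- s[s$column == 0L, ]
  expect_equal(c0$n_nuclei, 3L)
  expect_equal(c0$n_ts, 3L)
  expect_equal(c0$f_hat, 3 / 6)
  expect_equal(c(c0$n0, c0$n1, c0$n2), c(1L, 1L, 1L))
  expect_equal(c0$median_ts_int, 4)
  c1 <- s[s$column == 1L, ]
  expect_equal(c1$f_hat, 1 / 6)
  # empty column: medians are NA, never 0
  nuc2 <- rbind(nuc, data.frame(nucleus_id = 7L, column = 2L, y = 7, x = 1))
  s2 <- summarize_columns(ts, nuc2)
  expect_true(is.na(s2$median_ts_int[s2$column == 2L]))
  expect_equal(s2$n_ts[s2$column == 2L], 0L)
})

test_that("fully active and graded activations summarize as expected", {
  prof <- make_dorsal_profile(sigma = 4, half_width = 6)
  nuc <- expand.grid(idx = 1:40, column = prof$column)
  nuc$nucleus_id <- seq_len(nrow(nuc))
  # all alleles active: F-hat is 1 everywhere
  ts_all <- data.frame(spot_id = seq_len(2 * nrow(nuc)),
                       nucleus_id = rep(nuc$nucleus_id, each = 2),
                       cum_int = 1, y = 1, x = 1)
  s_all <- summarize_columns(ts_all, nuc)
  expect_true(all(s_all$f_hat == 1))
  # p proportional to Dorsal: F-hat decreases away from the midline
  act <- simulate_activation(prof, activation_config(0.25, 15, 40, seed = 4))
  act$nucleus_id <- nuc$nucleus_id[match(paste(act$column, act$nucleus),
                                         paste(nuc$column, nuc$idx))]
  ts_g <- data.frame(spot_id = seq_len(sum(act$active)),
                     nucleus_id = act$nucleus_id[act$active],
                     cum_int = 1, y = 1, x = 1)
  s_g <- summarize_columns(ts_g, nuc)
  mid <- s_g$f_hat[s_g$column == 0]
  edge <- (s_g$f_hat[s_g$column == 6] + s_g$f_hat[s_g$column == -6]) / 2
  expect_gt(mid, edge)
  expect_true(all(s_g$n0 + s_g$n1 + s_g$n2 + s_g$n_gt2 == s_g$n_nuclei))
})

test_that("mRNA profiles are medians per distance with TSs masked out", {
  geom <- embryo_geometry(midline_px = 30, spacing_px = 10)
  expect_true(all(mrna_profile(matrix(7, 60, 20), geom)$median_intensity
                  == 7))
  # oracle on a small structured crop
  set.seed(22)
  img <- matrix(rpois(60 * 20, 10), 60, 20)
  prof <- mrna_profile(img, geom)
  for (cc in c(-2L, 0L, 2L)) {
    rows <- which(as.integer(round((seq_len(60) - 30) / 10)) == cc)
    expect_equal(prof$median_intensity[prof$column == cc],
                 median(img[rows, ]))
  }
  # masked TS pixels do not contribute
  img2 <- matrix(1, 60, 20)
  img2[30, 10] <- 1000
  ts <- data.frame(spot_id = 1L, y = 30, x = 10)
  p2 <- mrna_profile(img2, geom, ts_spots = ts, mask_radius = 3)
  expect_true(all(p2$median_intensity == 1))
})

test_that("graded cytoplasmic signal correlates with the Dorsal profile", {
  prof <- make_dorsal_profile(sigma = 4, half_width = 5)
  geom <- embryo_geometry(midline_px = 70, spacing_px = 12)
  set.seed(23)
  img <- matrix(0, 140, 50)
  for (y in 1:140) {
    d <- interpolate_dorsal(prof, max(-5, min(5, (y - 70) / 12)))
    img[y, ] <- rpois(50, 20 * d + 1)
  }
  p <- mrna_profile(img, geom)
  p <- p[abs(p$column) <= 5, ]
  r <- correlate_with_dorsal(p$median_intensity, prof, p$column)
  expect_gte(r, 0.9)
})

test_that("dual-probe matching is mutual, bounded and column-aware", {
  a <- data.frame(spot_id = 1:3, y = c(10, 20, 30), x = c(5, 5, 5),
                  z = NA_real_, column = c(0L, 0L, 1L))
  # identical coordinates: everything matches
  m <- match_dual_probes(a, a, radius = 3)
  expect_true(all(m$states_a$state == "both"))
  expect_equal(nrow(m$pairs), 3)
  # far-apart sets: nothing matches
  b <- transform(a, y = y + 100)
  m2 <- match_dual_probes(a, b, radius = 3)
  expect_equal(nrow(m2$pairs), 0)
  expect_true(all(m2$states_a$state == "a-only"))
  expect_true(all(m2$states_b$state == "b-only"))
})

test_that("planted co-localization fractions are recovered", {
  set.seed(24)
  n <- 200
  a <- data.frame(spot_id = 1:n, y = runif(n, 0, 500), x = runif(n, 0, 500),
                  z = NA_real_, column = 0L)
  co <- seq_len(n) <= 0.6 * n  # 60% co-localized within 1 px
  b <- a
  b$y <- ifelse(co, a$y + runif(n, -0.7, 0.7), runif(n, 600, 1200))
  b$x <- ifelse(co, a$x + runif(n, -0.7, 0.7), runif(n, 600, 1200))
  m <- match_dual_probes(a, b, radius = 3)
  expect_lt(abs(mean(m$states_a$state == "both") - 0.6), 0.05)
})
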