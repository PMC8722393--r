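test_that("gene models validate their coordinates", {
  expect_error(gene_model("g", -1), "length_kb")
  expect_error(gene_model("g", 10, intron_kb = c(5, 12)), "intron")
  expect_error(gene_model("g", 10, probes = list(p = c(8, 12))), "probe")
  expect_error(gene_model("g", 10, v_kb_per_min = 0), "elongation")
  t48 <- builtin_gene("T48")
  expect_equal(t48$length_kb, 29)
  expect_equal(diff(t48$intron_kb), 25)
  expect_equal(t48$exon_kb, 4)
  expect_equal(builtin_gene("mist")$length_kb, 9.3)
  expect_equal(builtin_gene("twi")$length_kb, 2.2)
})

test_that("closed-form accumulation obeys its limits", {
  prof <- make_dorsal_profile(sigma = 4, half_width = 6)
  # immediate activation: M = r(x) * T
  fast <- simulate_accumulation(prof, p_mid = 1e8, T_min = 15,
                                loading = "graded", t_grid = 15)
  expect_equal(fast$M, prof$level[match(fast$column, prof$column)] * 15,
               tolerance = 1e-6)
  # no activation: M = 0
  none <- simulate_accumulation(prof, p_mid = 0, T_min = 15)
  expect_true(all(none$M == 0) && all(none$F == 0))
  # monotone in t at every column; zero at t = 0
  sim <- simulate_accumulation(prof, p_mid = 0.2, T_min = 15)
  expect_true(all(sim$M[sim$t == 0] == 0))
  for (cc in unique(sim$column)) {
    s <- sim[sim$column == cc, ]
    s <- s[order(s$t), ]
    expect_true(all(diff(s$M) >= -1e-12) && all(diff(s$F) >= -1e-12))
  }
  # graded loading: M non-increasing with |column| at the final time
  fin <- sim <- simulate_accumulation(prof, 0.2, 15, loading = "graded",
                                      t_grid = 15)
  ord <- order(abs(fin$column))
  expect_true(all(diff(fin$M[ord][abs(fin$column[ord]) >= 0]) <= 1e-12 |
                    diff(abs(fin$column[ord])) == 0))
})

test_that("Monte-Carlo accumulation agrees with the closed form", {
  prof <- make_dorsal_profile(sigma = 4, half_width = 9)
  prof <- prof[prof$column >= 0, ]
  class(prof) <- c("dorsal_profile", "data.frame")
  n <- 10000
  cf <- simulate_accumulation(prof, 0.2, 15, loading = "graded",
                              t_grid = c(5, 15))
  mc <- simulate_accumulation(prof, 0.2, 15, loading = "graded",
                              mode = "monte_carlo", t_grid = c(5, 15),
                              n_alleles = n, seed = 3)
  for (i in seq_len(nrow(cf))) {
    p <- 0.2 * cf$dorsal[i]; t <- cf$t[i]; r <- cf$dorsal[i]
    # per-allele production X = r (t - tau)+, tau ~ Exp(p): second moment
    # by numerical quadrature (independent of the closed form under test)
    m2 <- integrate(function(u) r^2 * (t - u)^2 * p * exp(-p * u),
                    0, t)$value
    ev <- cf$M[i]
    se <- sqrt(max(m2 - ev^2, 1e-9) / n)
    expect_lt(abs(mc$M[i] - ev), 4 * se + 1e-6)
    se_f <- sqrt(max(cf$F[i] * (1 - cf$F[i]), 1e-9) / n)
    expect_lt(abs(mc$F[i] - cf$F[i]), 4 * se_f + 1e-9)
  }
})

test_that("graded-loading accumulation correlates tightly with Dorsal", {
  prof <- make_dorsal_profile(sigma = 4, half_width = 9)
  prof <- prof[prof$column >= 0 & prof$column <= 9, ]
  class(prof) <- c("dorsal_profile", "data.frame")
  sim <- simulate_accumulation(prof, p_mid = 3 / 15, T_min = 15,
                               loading = "graded", t_grid = 15)
  r <- correlate_with_dorsal(sim$M, prof, sim$column)
  expect_gte(r, 0.92)
})

test_that("elongation timelines respect gene geometry at 2 kb/min", {
  t48 <- simulate_elongation(builtin_gene("T48"), activation_time = 0)
  expect_equal(t48$mature, 29 / 2)  # 14.5 min to the 3' end
  expect_equal(unname(t48$probe_detect["p5"]), 0)
  expect_equal(unname(t48$probe_detect["intron"]), 1)
  expect_equal(unname(t48$probe_detect["p3"]), 13.5)
  cdna <- simulate_elongation(builtin_gene("T48_cDNA"), activation_time = 0)
  expect_equal(cdna$mature, 2)  # 4 kb exonic at 2 kb/min
  # intron delay: endogenous vs intronless cDNA maturation
  delay <- t48$mature - cdna$mature
  expect_gte(delay, 10)
  expect_lte(delay, 15)
  # activation time shifts everything rigidly
  t5 <- simulate_elongation(builtin_gene("T48"), activation_time = 5)
  expect_equal(t5$mature, 19.5)
  # zero-length gene: all times equal the activation time
  z <- simulate_elongation(gene_model("null", 0), activation_time = 3)
  expect_equal(z$mature, 3)
})

test_that("timeline ordering holds for randomized gene models", {
  set.seed(31)
  for (i in 1:25) {
    L <- runif(1, 1, 40)
    i0 <- sort(runif(2, 0, L))
    g <- gene_model("rand", L, intron_kb = i0,
                    probes = list(p5 = c(0, min(1, L)), intron = i0,
                                  p3 = c(max(0, L - 1), L)),
                    v_kb_per_min = runif(1, 0.5, 5))
    tl <- simulate_elongation(g, activation_time = runif(1, 0, 10))
    expect_true(tl$activation <= tl$probe_detect["p5"])
    expect_true(tl$probe_detect["p5"] <= tl$probe_detect["intron"])
    expect_true(tl$probe_detect["intron"] <= tl$probe_detect["p3"])
    expect_true(tl$probe_detect["p3"] <= tl$mature)
  }
})

test_that("probe patterns reproduce the early 5'-only regime", {
  prof <- make_dorsal_profile(sigma = 4, half_width = 9)
  pat <- simulate_probe_pattern(prof, p_mid = 0.2, t_obs = c(7, 40),
                                n_nuclei = 300, seed = 6)
  endo7 <- pat[pat$gene == "endogenous" & pat$t == 7, ]
  # elongation over 29 kb takes 14.5 min: nothing mature at 7 min
  expect_true(all(endo7$frac_mature == 0))
  expect_gt(sum(endo7$frac_5p_only), 0)
  # once elongation has caught up everywhere, mature = activated
  endo40 <- pat[pat$gene == "endogenous" & pat$t == 40, ]
  act40 <- activated_fraction(0.2 * prof$level, 40 - 14.5)
  expect_equal(endo40$frac_mature,
               act40[match(endo40$column, prof$column)], tolerance = 0.05)
  # the intronless cDNA matures earlier at every column and time
  cd <- pat[pat$gene == "cdna", ]
  en <- pat[pat$gene == "endogenous", ]
  key <- paste(cd$column, cd$t)
  expect_true(all(cd$frac_mature >=
                    en$frac_mature[match(key, paste(en$column, en$t))]))
  # mature-fraction ratio favors the cDNA away from the midline
  mid <- pat$ratio_cdna_vs_endo[pat$t == 40 & pat$column == 0 &
                                  pat$gene == "endogenous"]
  expect_gte(mid, 1)
})

test_that("probe-pattern simulation is reproducible under a fixed seed", {
  prof <- make_dorsal_profile(sigma = 4, half_width = 4)
  a <- simulate_probe_pattern(prof, 0.2, t_obs = 20, n_nuclei = 50, seed = 9)
  b <- simulate_probe_pattern(prof, 0.2, t_obs = 20, n_nuclei = 50, seed = 9)
  expect_identical(a, b)
})
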