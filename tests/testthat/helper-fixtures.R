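# Lazily built, cached fixtures shared across test files. Everything is
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# noisy calibration field with planted TS/mRNA ratio 70, plus detection
fx_field70 <- function() fixture("field70", function() {
  cfg <- render_config(shape = c(140, 140, 20), ratio_ts = 70, seed = 5)
  field <- render_spot_field(n_mrna = 100, n_ts = 20, cfg = cfg)
  det <- detect_spots_3d(field$stack)
  list(field = field, det = det, cfg = cfg)
})

# same, planted ratio 30
fx_field30 <- function() fixture("field30", function() {
  cfg <- render_config(shape = c(140, 140, 20), ratio_ts = 30, seed = 6)
  field <- render_spot_field(n_mrna = 100, n_ts = 20, cfg = cfg)
  det <- detect_spots_3d(field$stack)
  list(field = field, det = det, cfg = cfg)
})

# noise-free field for precision/recall and flux accuracy
fx_field_clean <- function() fixture("field_clean", function() {
  cfg <- render_config(shape = c(140, 140, 20), ratio_ts = 70, seed = 8,
                       shot_noise = FALSE, read_noise_sd = 0, background = 0)
  field <- render_spot_field(n_mrna = 80, n_ts = 16, cfg = cfg)
  det <- detect_spots_3d(field$stack)
  list(field = field, det = det, cfg = cfg)
})

# rendered embryo (9 columns) with known geometry and activation truth
fx_embryo <- function() fixture("embryo", function() {
  prof <- make_dorsal_profile(sigma = 4, half_width = 4)
  acfg <- activation_config(p_mid = 0.2, T_min = 15,
                            n_nuclei_per_column = 6, seed = 11)
  act <- simulate_activation(prof, acfg)
  cfg <- render_config(shape = c(160, 96, 16), spacing = 14,
                       mrna_per_column = 8, seed = 12)
  emb <- suppressWarnings(render_embryo(act, prof, cfg))
  list(profile = prof, activation = act, embryo = emb, cfg = cfg)
})
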