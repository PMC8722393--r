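# One simulated embryo -> activation fit, under the study conditions of
# the graded-activation analysis (ventral half-profile, diploid nuclei).
simulate_fit <- function(seed, proportional = TRUE, half_width = 9,
                         p_mid = 1 / 15, T_min = 15, n = 200, sigma = 4) {
  prof <- make_dorsal_profile(sigma = sigma, half_width = half_width)
  prof <- prof[prof$column >= 0, ]
  class(prof) <- c("dorsal_profile", "data.frame")
  tab <- simulate_activation(prof,
                             activation_config(p_mid, T_min, n, seed = seed),
                             proportional = proportional)
  fr <- activation_fractions(tab)
  summ <- data.frame(column = fr$column, f_hat = fr$fraction,
                     n_nuclei = fr$n_alleles / 2)
  fit_activation(summ, prof, T_min)
}
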