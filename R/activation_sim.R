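#' Configuration for stochastic allele-activation simulation
#'
#' @param p_mid Activation probability per minute at the ventral midline
#'   (>= 0).
#' @param T_min Minutes of exposure to the stable Dorsal gradient (>= 0).
#' @param n_nuclei_per_column Nuclei simulated in each column.
#' @param alleles_per_nucleus 1 or 2 (diploid default 2); the two loci of a
#'   nucleus activate independently.
#' @param seed Integer seed for the waiting-time draws.
#' @return An \code{activation_config} list.
#' @export
activation_config <- function(p_mid, T_min, n_nuclei_per_column = 200,
                              alleles_per_nucleus = 2, seed = 1L) {
  if (!is.numeric(p_mid) || p_mid < 0) stop("p_mid must be >= 0")
  if (!is.numeric(T_min) || T_min < 0) stop("T_min must be >= 0")
  if (!alleles_per_nucleus %in% c(1L, 2L))
    stop("alleles_per_nucleus must be 1 or 2")
  if (n_nuclei_per_column < 1) stop("n_nuclei_per_column must be >= 1")
  structure(list(p_mid = p_mid, T_min = T_min,
                 n_nuclei_per_column = as.integer(n_nuclei_per_column),
                 alleles_per_nucleus = as.integer(alleles_per_nucleus),
                 seed = as.integer(seed)),
            class = "activation_config")
}

#' Simulate stochastic, independent TS activation along the gradient
#'
#' Each allele at column x becomes permanently active as the first event of
#' a memoryless (exponential) process with per-minute rate
#' \eqn{p(x) = p_{mid} D(x)} (or uniformly \eqn{p_{mid}} when
#' \code{proportional = FALSE}, the switch-like regime of *twi*). Alleles
#' whose waiting time exceeds the exposure time T are recorded inactive.
#' The expected active fraction per column is \eqn{1 - \exp(-T p(x))}.
#'
#' @param profile A \code{dorsal_profile} (any subset of columns).
#' @param cfg An [activation_config()].
#' @param proportional If \code{TRUE} (default) the activation rate is
#'   proportional to the local Dorsal level; if \code{FALSE} it is uniform.
#' @return An \code{allele_activation} data frame: \code{column},
#'   \code{nucleus}, \code{allele}, \code{active} (logical), \code{t_active}
#'   (minutes, \code{NA} for inactive alleles).
#' @examples
#' prof <- make_dorsal_profile(sigma = 4, half_width = 9)
#' tab <- simulate_activation(prof, activation_config(1 / 15, 15, 50))
#' mean(tab$active[tab$column == 0])  # near 1 - exp(-1)
#' @export
simulate_activation <- function(profile, cfg, proportional = TRUE) {
  validate_dorsal_profile(profile)
  stopifnot(inherits(cfg, "activation_config"))
  rate <- if (proportional) cfg$p_mid * profile$level
          else rep(cfg$p_mid, nrow(profile))
  n_col <- nrow(profile)
  n_per <- cfg$n_nuclei_per_column * cfg$alleles_per_nucleus
  set.seed(cfg$seed)
  tab <- data.frame(
    column  = rep(profile$column, each = n_per),
    nucleus = rep(rep(seq_len(cfg$n_nuclei_per_column),
                      each = cfg$alleles_per_nucleus), times = n_col),
    allele  = rep(seq_len(cfg$alleles_per_nucleus),
                  times = n_col * cfg$n_nuclei_per_column)
  )
  r <- rep(rate, each = n_per)
  wait <- ifelse(r > 0, rexp(nrow(tab), rate = pmax(r, .Machine$double.xmin)),
                 Inf)
  tab$active <- wait <= cfg$T_min
  tab$t_active <- ifelse(tab$active, wait, NA_real_)
  class(tab) <- c("allele_activation", "data.frame")
  tab
}

#' Per-column empirical active-allele fraction from an activation table
#'
#' @param tab An \code{allele_activation} data frame.
#' @return Data frame with \code{column}, \code{n_alleles},
#'   \code{n_active}, \code{fraction}.
#' @export
activation_fractions <- function(tab) {
  stopifnot(all(c("column", "active") %in% names(tab)))
  agg <- aggregate(active ~ column, data = tab,
                   FUN = function(a) c(n = length(a), act = sum(a)))
  data.frame(column = agg$column,
             n_alleles = agg$active[, "n"],
             n_active = agg$active[, "act"],
             fraction = agg$active[, "act"] / agg$active[, "n"])
}
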