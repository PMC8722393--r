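#' Activated promoter fraction after graded exposure
#'
#' Under stochastic, memoryless activation with per-minute probability p,
#' the fraction of promoters active after T minutes is
#' \eqn{F = 1 - \exp(-T p)}.
#'
#' @param p Activation probability per minute (>= 0); vectorized.
#' @param T_min Exposure time in minutes (>= 0).
#' @return Activated fraction in \[0, 1\].
#' @export
activated_fraction <- function(p, T_min) {
  if (any(p < 0) || any(T_min < 0)) stop("p and T_min must be >= 0")
  -expm1(-T_min * p)
}

#' Invert the activated fraction to an activation probability
#'
#' \eqn{\hat p = -\ln(1 - \hat F) / T}. A saturated observation
#' \eqn{\hat F = 1} (all alleles active) would give an infinite estimate;
#' it is capped to \eqn{1 - 1/(2 n_{alleles})} before inversion and
#' flagged.
#'
#' @param f_hat Observed activated fraction(s) in \[0, 1\].
#' @param T_min Exposure time (> 0).
#' @param n_alleles Number of alleles behind each fraction (for the
#'   saturation cap); scalar or vector.
#' @return Data frame with \code{p_hat} (per minute) and \code{capped}.
#' @export
infer_probability <- function(f_hat, T_min, n_alleles = 400) {
  if (T_min <= 0) stop("T_min must be > 0")
  if (any(f_hat < 0 | f_hat > 1)) stop("f_hat must be in [0, 1]")
  capped <- f_hat >= 1
  f_adj <- ifelse(capped, 1 - 1 / (2 * n_alleles), f_hat)
  data.frame(p_hat = -log1p(-f_adj) / T_min, capped = capped)
}

#' Pearson correlation of per-column values with the Dorsal profile
#'
#' Standard product-moment correlation between column-level values and the
#' Dorsal level of the matching columns. Zero-variance input is degenerate
#' and yields r = 0 with a warning.
#'
#' @param values Named or column-aligned numeric vector, or a data frame
#'   with \code{column} and a value column.
#' @param profile A \code{dorsal_profile}.
#' @param columns Columns matching \code{values} when \code{values} is a
#'   bare vector.
#' @return Pearson r.
#' @export
correlate_with_dorsal <- function(values, profile, columns = NULL) {
  validate_dorsal_profile(profile)
  if (is.data.frame(values)) {
    columns <- values$column
    values <- values[[setdiff(names(values), "column")[1L]]]
  }
  if (is.null(columns)) columns <- profile$column
  keep <- is.finite(values)
  values <- values[keep]; columns <- columns[keep]
  if (length(values) < 3) stop("need at least 3 columns with finite values")
  d <- profile$level[match(columns, profile$column)]
  if (anyNA(d)) stop("values refer to columns absent from the profile")
  if (stats::sd(values) == 0 || stats::sd(d) == 0) {
    warning("degenerate (zero-variance) input; r defined as 0")
    return(0)
  }
  cor(values, d)
}

#' Fit the activation model to per-column summaries
#'
#' Computes per-column activated-allele fractions, inverts them to
#' per-minute activation probabilities at the given exposure time, and
#' reports the Pearson correlation of both with the Dorsal profile.
#'
#' @param summaries A \code{column_summary} (from [summarize_columns()])
#'   or any data frame with \code{column}, \code{f_hat} and
#'   \code{n_nuclei}.
#' @param profile A \code{dorsal_profile}.
#' @param T_min Exposure time to the stable gradient (minutes, > 0); about
#'   embryo age in NC 14 minus the ~10 min the gradient needs to
#'   re-establish.
#' @param alleles_per_nucleus Default 2.
#' @return An \code{activation_fit} list: \code{table} (column, f_hat,
#'   p_hat, capped, dorsal), \code{T_min}, \code{r_fraction},
#'   \code{r_probability}.
#' @export
fit_activation <- function(summaries, profile, T_min,
                           alleles_per_nucleus = 2) {
  stopifnot(all(c("column", "f_hat") %in% names(summaries)))
  n_all <- if ("n_nuclei" %in% names(summaries))
    summaries$n_nuclei * alleles_per_nucleus else 400
  inv <- infer_probability(summaries$f_hat, T_min, n_alleles = n_all)
  tab <- data.frame(column = summaries$column, f_hat = summaries$f_hat,
                    p_hat = inv$p_hat, capped = inv$capped,
                    dorsal = profile$level[match(summaries$column,
                                                 profile$column)])
  structure(list(table = tab, T_min = T_min,
                 r_fraction = correlate_with_dorsal(tab$f_hat, profile,
                                                    tab$column),
                 r_probability = correlate_with_dorsal(tab$p_hat, profile,
                                                       tab$column)),
            class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat("Activation-model fit (T =", x$T_min, "min)\n")
  cat("  r(F_hat, Dorsal) =", format(x$r_fraction, digits = 3), "\n")
  cat("  r(p_hat, Dorsal) =", format(x$r_probability, digits = 3), "\n")
  cat("  columns:", nrow(x$table), " capped:", sum(x$table$capped), "\n")
  invisible(x)
}
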