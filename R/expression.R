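#' Gene model for elongation and probe-detectability simulation
#'
#' @param name Gene name.
#' @param length_kb Transcription-unit length in kb.
#' @param intron_kb Intron span as \code{c(start, end)} in kb along the
#'   unit (\code{NULL} for intronless genes).
#' @param probes Named list of probe regions, each \code{c(start, end)} in
#'   kb (e.g. \code{list(p5 = c(0, 2), p3 = c(27, 29))}).
#' @param v_kb_per_min Pol II elongation rate (kb/min, > 0; default 2).
#' @return A \code{gene_model} list. The exonic (mature transcript) length
#'   is \code{length_kb} minus the intron span.
#' @export
gene_model <- function(name, length_kb, intron_kb = NULL, probes = list(),
                       v_kb_per_min = 2) {
  if (length_kb < 0) stop("length_kb must be >= 0")
  if (v_kb_per_min <= 0) stop("elongation rate must be > 0")
  if (!is.null(intron_kb)) {
    if (length(intron_kb) != 2L || intron_kb[1L] > intron_kb[2L] ||
        intron_kb[1L] < 0 || intron_kb[2L] > length_kb)
      stop("intron span must lie within [0, length_kb]")
  }
  for (pr in probes)
    if (pr[1L] < 0 || pr[2L] > length_kb || pr[1L] > pr[2L])
      stop("probe regions must lie within [0, length_kb]")
  structure(list(name = name, length_kb = length_kb, intron_kb = intron_kb,
                 probes = probes, v_kb_per_min = v_kb_per_min,
                 exon_kb = length_kb -
                   if (is.null(intron_kb)) 0 else diff(intron_kb)),
            class = "gene_model")
}

#' Built-in gene models
#'
#' The mesodermal Dorsal targets analyzed by the pipeline: *T48* (29 kb,
#' ~25 kb intron, 5'/intron/3' probes), its intronless cDNA transgene
#' (exonic 4 kb), *mist* (9.3 kb) and *twi* (2.2 kb), all at the measured
#' elongation rate of ~2 kb/min.
#'
#' @param name One of \code{"T48"}, \code{"T48_cDNA"}, \code{"mist"},
#'   \code{"twi"}.
#' @param v_kb_per_min Elongation rate override (default 2 kb/min).
#' @return A [gene_model()].
#' @export
builtin_gene <- function(name = c("T48", "T48_cDNA", "mist", "twi"),
                         v_kb_per_min = 2) {
  name <- match.arg(name)
  switch(name,
    T48 = gene_model("T48", 29, intron_kb = c(2, 27),
                     probes = list(p5 = c(0, 2), intron = c(2, 27),
                                   p3 = c(27, 29)),
                     v_kb_per_min = v_kb_per_min),
    T48_cDNA = gene_model("T48_cDNA", 4, intron_kb = NULL,
                          probes = list(p3 = c(2, 4)),
                          v_kb_per_min = v_kb_per_min),
    mist = gene_model("mist", 9.3, intron_kb = NULL,
                      probes = list(p5 = c(0, 2)),
                      v_kb_per_min = v_kb_per_min),
    twi = gene_model("twi", 2.2, intron_kb = NULL,
                     probes = list(full = c(0, 2.2)),
                     v_kb_per_min = v_kb_per_min))
}

#' Simulate graded mRNA accumulation under stochastic activation
#'
#' Alleles at column x activate with per-minute rate
#' \eqn{p(x) = p_{mid} D(x)}; once active, a locus produces mRNA at rate
#' r(x): constant (= 1 everywhere) or Dorsal-graded (= D(x), fixed at 1 at
#' the midline). mRNAs are stable within the window, so the expected
#' accumulation is
#' \deqn{M(x, t) = r(x) [t - (1 - e^{-p(x) t}) / p(x)]}
#' with the limit M = 0 when p(x) = 0. Monte-Carlo mode instead averages
#' per-allele production \eqn{r(x) (t - \tau)_+} over sampled activation
#' times \eqn{\tau}.
#'
#' @param profile A \code{dorsal_profile}.
#' @param p_mid Midline activation probability per minute.
#' @param T_min End of the simulated window (minutes).
#' @param loading \code{"constant"} or \code{"graded"}.
#' @param mode \code{"closed_form"} or \code{"monte_carlo"}.
#' @param t_grid Time grid (minutes); default 30 steps to \code{T_min}.
#' @param n_alleles Alleles per column for Monte-Carlo mode.
#' @param seed Seed for Monte-Carlo mode.
#' @return An \code{expression_sim} data frame: column, t, dorsal, F
#'   (activated fraction), M (accumulated mRNA per allele, in units of the
#'   midline production rate x minutes).
#' @export
simulate_accumulation <- function(profile, p_mid, T_min,
                                  loading = c("constant", "graded"),
                                  mode = c("closed_form", "monte_carlo"),
                                  t_grid = NULL, n_alleles = 10000,
                                  seed = 1L) {
  validate_dorsal_profile(profile)
  loading <- match.arg(loading)
  mode <- match.arg(mode)
  if (p_mid < 0 || T_min < 0) stop("p_mid and T_min must be >= 0")
  if (is.null(t_grid)) t_grid <- seq(0, T_min, length.out = 31L)
  p <- p_mid * profile$level
  r <- if (loading == "graded") profile$level else rep(1, nrow(profile))

  grid <- expand.grid(i = seq_len(nrow(profile)), t = t_grid)
  px <- p[grid$i]; rx <- r[grid$i]; tt <- grid$t
  Fx <- -expm1(-px * tt)
  if (mode == "closed_form") {
    Mx <- ifelse(px > 0, rx * (tt - Fx / px), 0)
  } else {
    set.seed(seed)
    tau <- lapply(seq_len(nrow(profile)), function(i)
      if (p[i] > 0) rexp(n_alleles, p[i]) else rep(Inf, n_alleles))
    Fx <- mapply(function(i, t) mean(tau[[i]] <= t), grid$i, tt)
    Mx <- mapply(function(i, t) r[i] * mean(pmax(t - tau[[i]], 0)),
                 grid$i, tt)
  }
  out <- data.frame(column = profile$column[grid$i], t = tt,
                    dorsal = profile$level[grid$i], F = Fx, M = Mx,
                    loading = loading)
  class(out) <- c("expression_sim", "data.frame")
  out
}

#' Deterministic elongation timeline for one activated locus
#'
#' After activation, the first Pol II advances at the gene's elongation
#' rate; a probe region becomes detectable when that Pol II passes its
#' start, and the first mature mRNA appears when it reaches the gene end
#' (splicing is treated as instantaneous).
#'
#' @param gene A [gene_model()].
#' @param activation_time Activation time in minutes (default 0).
#' @return An \code{elongation_timeline} list: \code{activation},
#'   \code{probe_detect} (named vector of first-detectable times),
#'   \code{mature} (first mature-mRNA time), \code{gene}.
#' @export
simulate_elongation <- function(gene, activation_time = 0) {
  stopifnot(inherits(gene, "gene_model"))
  v <- gene$v_kb_per_min
  pd <- vapply(gene$probes, function(pr) activation_time + pr[1L] / v,
               numeric(1))
  structure(list(activation = activation_time,
                 probe_detect = pd,
                 mature = activation_time + gene$length_kb / v,
                 gene = gene$name),
            class = "elongation_timeline")
}

#' Per-column probe-state fractions over time for endogenous and cDNA loci
#'
#' Combines stochastic activation sampling with deterministic elongation:
#' at each observation time, each allele is inactive, 5'-only (initiated,
#' first Pol II not yet past the intron probe), 5'+intron, or mature
#' (3'-positive). Endogenous and cDNA loci share activation times by
#' default (both respond to the same Dorsal level in the same nucleus), so
#' the faster maturation of the intronless cDNA is exposed directly; the
#' per-column ratio of mature cDNA to mature endogenous fractions is
#' reported.
#'
#' @param profile A \code{dorsal_profile}.
#' @param p_mid Midline activation probability per minute.
#' @param genes List with \code{endogenous} and \code{cdna}
#'   [gene_model()]s (default built-in *T48* pair).
#' @param t_obs Observation times (minutes into the exposure window).
#' @param n_nuclei Nuclei per column (2 alleles each).
#' @param seed Seed for activation sampling.
#' @param share_activation Use the same activation draws for both genes
#'   (default TRUE).
#' @return A \code{probe_pattern} data frame: column, t, gene,
#'   frac_active, frac_5p_only, frac_intron, frac_mature, and (joined per
#'   column/time) ratio_cdna_vs_endo of mature fractions.
#' @export
simulate_probe_pattern <- function(profile, p_mid,
                                   genes = list(
                                     endogenous = builtin_gene("T48"),
                                     cdna = builtin_gene("T48_cDNA")),
                                   t_obs = c(7, 24, 38),
                                   n_nuclei = 200, seed = 1L,
                                   share_activation = TRUE) {
  validate_dorsal_profile(profile)
  n_all <- 2L * n_nuclei
  set.seed(seed)
  draw <- function() lapply(seq_len(nrow(profile)), function(i) {
    p <- p_mid * profile$level[i]
    if (p > 0) rexp(n_all, p) else rep(Inf, n_all)
  })
  tau <- list(endogenous = draw(),
              cdna = if (share_activation) NULL else draw())
  if (share_activation) tau$cdna <- tau$endogenous

  state_fracs <- function(gene, tact, t) {
    v <- gene$v_kb_per_min
    pos <- pmax(t - tact, -Inf) * v          # first Pol II position, kb
    active <- tact <= t
    t5 <- if (!is.null(gene$probes$p5)) gene$probes$p5[1L] else 0
    ti <- if (!is.null(gene$probes$intron)) gene$probes$intron[1L] else NA
    mature <- active & pos >= gene$length_kb
    seen5 <- active & pos >= t5
    seeni <- if (!is.na(ti)) active & pos >= ti else rep(FALSE, length(pos))
    c(frac_active = mean(active),
      frac_5p_only = mean(seen5 & !seeni & !mature),
      frac_intron = mean(seeni & !mature),
      frac_mature = mean(mature))
  }

  rows <- list()
  for (gname in names(genes)) {
    g <- genes[[gname]]
    for (t in t_obs) {
      fr <- t(vapply(seq_len(nrow(profile)), function(i)
        state_fracs(g, tau[[gname]][[i]], t), numeric(4)))
      rows[[length(rows) + 1L]] <-
        data.frame(column = profile$column, t = t, gene = gname, fr)
    }
  }
  out <- do.call(rbind, rows)
  # ratio of mature cDNA vs endogenous fractions per column/time
  endo <- out[out$gene == "endogenous", ]
  cdna <- out[out$gene == "cdna", ]
  key <- paste(out$column, out$t)
  ek <- paste(endo$column, endo$t); ck <- paste(cdna$column, cdna$t)
  ratio <- cdna$frac_mature[match(ek, ck)] / endo$frac_mature
  ratio[!is.finite(ratio)] <- NA_real_
  out$ratio_cdna_vs_endo <- ratio[match(key, ek)]
  class(out) <- c("probe_pattern", "data.frame")
  out
}
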