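#' Classify spots into single mRNAs and transcription sites
#'
#' The maximal pixel intensity separates the dim, dispersed cytoplasmic
#' mRNA molecules from the bright, concentrated nascent TS foci. A kernel
#' density is fitted to \eqn{\log_{10}} maximal intensities; the cutoff is
#' the density minimum between the two largest modes. Spots above the
#' cutoff are TSs, below are mRNAs. The TS-to-mRNA ratio of median
#' cumulative intensities, R, estimates the number of transcript
#' equivalents at a TS and hence the Pol II loading N (one unit = one
#' transcript).
#'
#' @param spots A \code{spot_calls} data frame (>= 20 spots) with
#'   \code{max_int} and \code{cum_int}.
#' @param bw Density bandwidth in log10 units: \code{"SJ"} plug-in rule
#'   (default, falling back to \code{"nrd0"} on failure) or a number.
#' @param min_sep Minimum separation (log10 units) between the two modes
#'   taken as the mRNA and TS populations; narrower density wiggles within
#'   one population are not split (default 0.5, i.e. a factor ~3 in
#'   maximal intensity).
#' @return A \code{spot_classification} list: \code{spots} (classes
#'   filled), \code{cutoff} (on max intensity, linear scale),
#'   \code{median_mrna}, \code{median_ts} (cumulative intensities),
#'   \code{ratio} (R), \code{polII} (N = R), \code{density} (the scanned
#'   density, for audit).
#' @export
classify_spots <- function(spots, bw = "SJ", min_sep = 0.5) {
  if (nrow(spots) < 20) stop("need at least 20 spots to classify")
  if (any(spots$max_int <= 0)) spots <- spots[spots$max_int > 0, ]
  lx <- log10(spots$max_int)
  dens <- tryCatch(density(lx, bw = bw), error = function(e)
    density(lx, bw = "nrd0"))
  y <- dens$y
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  is_max <- is_max[y[is_max] > 0]
  if (length(is_max) < 2)
    stop("no TS/mRNA separation: intensity histogram is unimodal")
  ord <- is_max[order(y[is_max], decreasing = TRUE)]
  m1 <- ord[1L]
  m2 <- ord[which(abs(dens$x[ord] - dens$x[m1]) >= min_sep)[1L]]
  if (is.na(m2))
    stop("no TS/mRNA separation: intensity histogram is unimodal")
  top2 <- c(m1, m2)
  lo <- min(top2); hi <- max(top2)
  between <- seq(lo, hi)
  cut_log <- dens$x[between[which.min(y[between])]]
  cls <- ifelse(lx > cut_log, "TS", "mRNA")
  spots$class <- cls
  med_m <- median(spots$cum_int[cls == "mRNA"])
  med_t <- median(spots$cum_int[cls == "TS"])
  structure(list(spots = spots, cutoff = 10^cut_log,
                 median_mrna = med_m, median_ts = med_t,
                 ratio = med_t / med_m, polII = med_t / med_m,
                 density = dens),
            class = "spot_classification")
}

#' Pol II packing density along a gene
#'
#' Converts a Pol II count per locus into base pairs per Pol II complex:
#' \code{1000 * length_kb / N}. With 70 complexes on a 29-kb gene this is
#' about one complex every 400 bp.
#'
#' @param N Pol II complexes per locus (> 0).
#' @param gene A [gene_model()] (its \code{length_kb} is used) or a length
#'   in kb.
#' @param reference Optional second gene/N pair \code{list(N=, gene=)};
#'   when given, the ratio of the reference density to this gene's density
#'   is reported (how much denser this gene is loaded).
#' @return List with \code{bp_per_polII} and optionally
#'   \code{density_vs_reference}.
#' @export
polII_density <- function(N, gene, reference = NULL) {
  if (!is.numeric(N) || N <= 0) stop("N must be > 0")
  L <- if (inherits(gene, "gene_model")) gene$length_kb else as.numeric(gene)
  out <- list(bp_per_polII = 1000 * L / N)
  if (!is.null(reference)) {
    ref <- polII_density(reference$N, reference$gene)
    out$density_vs_reference <- ref$bp_per_polII / out$bp_per_polII
  }
  out
}

#' Per-nuclear-column summaries of TS activity
#'
#' For every integer column, the nucleus count, TS count, active-allele
#' fraction \eqn{\hat F = n_{TS} / (alleles \cdot n_{nuclei})}, the
#' per-nucleus TS-count histogram (0/1/2, more flagged) and the median TS
#' cumulative intensity. Medians of empty classes are reported as
#' \code{NA}, never 0.
#'
#' @param ts_spots \code{spot_calls} with \code{column} and
#'   \code{nucleus_id} assigned (see [assign_columns()],
#'   [assign_nuclei()]); excluded spots are dropped.
#' @param nuclei Data frame with \code{nucleus_id} and \code{column}.
#' @param alleles_per_nucleus Default 2.
#' @return A \code{column_summary} data frame: column, n_nuclei, n_ts,
#'   f_hat, n0, n1, n2, n_gt2, median_ts_int.
#' @export
summarize_columns <- function(ts_spots, nuclei, alleles_per_nucleus = 2) {
  stopifnot(all(c("nucleus_id", "column") %in% names(nuclei)))
  if ("excluded" %in% names(ts_spots))
    ts_spots <- ts_spots[!ts_spots$excluded, , drop = FALSE]
  cols <- sort(unique(nuclei$column))
  per_nuc <- table(factor(ts_spots$nucleus_id, levels = nuclei$nucleus_id))
  out <- lapply(cols, function(cc) {
    nuc_c <- nuclei$nucleus_id[nuclei$column == cc]
    cnts <- as.integer(per_nuc[as.character(nuc_c)])
    in_col <- !is.na(ts_spots$nucleus_id) &
      ts_spots$nucleus_id %in% nuc_c
    n_ts <- sum(cnts)
    data.frame(column = cc, n_nuclei = length(nuc_c), n_ts = n_ts,
               f_hat = n_ts / (alleles_per_nucleus * length(nuc_c)),
               n0 = sum(cnts == 0L), n1 = sum(cnts == 1L),
               n2 = sum(cnts == 2L), n_gt2 = sum(cnts > 2L),
               median_ts_int = if (any(in_col))
                 median(ts_spots$cum_int[in_col]) else NA_real_)
  })
  out <- do.call(rbind, out)
  class(out) <- c("column_summary", "data.frame")
  out
}

#' Cytoplasmic mRNA profile: per-distance median pixel intensity
#'
#' TS pixels (discs around TS calls) are masked out; for each integer
#' column distance from the midline, the median intensity of the remaining
#' pixels inside the ROI is reported.
#'
#' @param img 2D matrix (projected smFISH channel).
#' @param geom An [embryo_geometry()].
#' @param ts_spots Optional \code{spot_calls}; pixels within
#'   \code{mask_radius} of a TS are omitted.
#' @param mask_radius TS masking radius in pixels (default 4).
#' @return Data frame with \code{column} (integer distance) and
#'   \code{median_intensity}.
#' @export
mrna_profile <- function(img, geom, ts_spots = NULL, mask_radius = 4) {
  stopifnot(inherits(geom, "embryo_geometry"), is.matrix(img))
  d <- dim(img)
  yy <- matrix(seq_len(d[1L]), d[1L], d[2L])
  xx <- matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE)
  keep <- matrix(TRUE, d[1L], d[2L])
  if (!is.null(geom$roi)) {
    r <- geom$roi
    keep <- yy >= r[1L] & yy <= r[2L] & xx >= r[3L] & xx <= r[4L]
  }
  if (!is.null(ts_spots) && nrow(ts_spots) > 0) {
    for (i in seq_len(nrow(ts_spots)))
      keep <- keep & ((yy - ts_spots$y[i])^2 + (xx - ts_spots$x[i])^2 >
                        mask_radius^2)
  }
  dv <- if (geom$axis == "y") yy else xx
  col_dist <- as.integer(round((dv - geom$midline_px) / geom$spacing_px))
  med <- tapply(img[keep], col_dist[keep], median)
  data.frame(column = as.integer(names(med)),
             median_intensity = as.numeric(med))
}

#' Match TS calls across two probe channels
#'
#' Mutual nearest-neighbor pairing within a radius; each TS is labeled
#' \code{a-only}, \code{b-only} or \code{both}. With 5'/3' (or intron/3')
#' probe pairs this separates initiated-but-immature TSs from TSs whose
#' transcripts have reached the 3' end. Distance ties are broken by the
#' lower spot id.
#'
#' @param spots_a,spots_b \code{spot_calls} from the two registered
#'   channels.
#' @param radius Match radius in pixels (default 3).
#' @return A \code{probe_match} list: \code{pairs} (id_a, id_b, dist),
#'   \code{states_a}, \code{states_b} (per-spot state), and, when both
#'   inputs carry a \code{column}, \code{by_column} (per-column counts of
#'   a-only / b-only / both and the ratio of \code{both} fractions).
#' @export
match_dual_probes <- function(spots_a, spots_b, radius = 3) {
  na <- nrow(spots_a); nb <- nrow(spots_b)
  use_z <- "z" %in% names(spots_a) && !all(is.na(spots_a$z)) &&
    "z" %in% names(spots_b) && !all(is.na(spots_b$z))
  pairs <- data.frame(id_a = integer(), id_b = integer(), dist = numeric())
  if (na > 0 && nb > 0) {
    dd <- outer(spots_a$y, spots_b$y, "-")^2 + outer(spots_a$x, spots_b$x, "-")^2
    if (use_z) dd <- dd + outer(spots_a$z, spots_b$z, "-")^2
    dd <- sqrt(dd)
    # deterministic mutual NN: ties to lower id via order of which.min
    nn_a <- apply(dd, 1L, which.min)
    nn_b <- apply(dd, 2L, which.min)
    for (i in seq_len(na)) {
      j <- nn_a[i]
      if (nn_b[j] == i && dd[i, j] <= radius)
        pairs <- rbind(pairs, data.frame(id_a = spots_a$spot_id[i],
                                         id_b = spots_b$spot_id[j],
                                         dist = dd[i, j]))
    }
  }
  st_a <- ifelse(spots_a$spot_id %in% pairs$id_a, "both", "a-only")
  st_b <- ifelse(spots_b$spot_id %in% pairs$id_b, "both", "b-only")
  out <- list(pairs = pairs,
              states_a = data.frame(spot_id = spots_a$spot_id, state = st_a),
              states_b = data.frame(spot_id = spots_b$spot_id, state = st_b))
  if ("column" %in% names(spots_a) && "column" %in% names(spots_b)) {
    cols <- sort(unique(c(spots_a$column, spots_b$column)))
    by_col <- lapply(cols, function(cc) {
      a_c <- st_a[spots_a$column == cc]
      b_c <- st_b[spots_b$column == cc]
      data.frame(column = cc,
                 n_a_only = sum(a_c == "a-only"),
                 n_b_only = sum(b_c == "b-only"),
                 n_both = sum(a_c == "both"),
                 frac_both_a = if (length(a_c)) mean(a_c == "both")
                               else NA_real_,
                 frac_both_b = if (length(b_c)) mean(b_c == "both")
                               else NA_real_)
    })
    out$by_column <- do.call(rbind, by_col)
  }
  class(out) <- "probe_match"
  out
}
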