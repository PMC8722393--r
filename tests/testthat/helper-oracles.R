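# Independent brute-force oracles used by the tests. These deliberately
# avoid the package's own code paths.

# half-sample symmetric reflection, matching the filters' boundary rule
reflect_1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# brute-force moving-sphere median
oracle_sphere_median <- function(arr, radius) {
  d <- dim(arr)
  nd <- length(d)
  out <- array(NA_real_, d)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius,
                      dz = if (nd == 3) -radius:radius else 0)
  offs <- offs[offs$dy^2 + offs$dx^2 + offs$dz^2 <= radius^2, ]
  for (z in seq_len(if (nd == 3) d[3] else 1)) {
    for (x in seq_len(d[2])) {
      for (y in seq_len(d[1])) {
        vals <- numeric(nrow(offs))
        for (k in seq_len(nrow(offs))) {
          yy <- reflect_1(y + offs$dy[k], d[1])
          xx <- reflect_1(x + offs$dx[k], d[2])
          if (nd == 3) {
            zz <- reflect_1(z + offs$dz[k], d[3])
            vals[k] <- arr[yy, xx, zz]
          } else vals[k] <- arr[yy, xx]
        }
        if (nd == 3) out[y, x, z] <- median(vals) else out[y, x] <- median(vals)
      }
    }
  }
  out
}

# flood-fill connected-component labeling on a logical mask
oracle_label <- function(mask, connectivity) {
  d <- dim(mask)
  nd <- length(d)
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = if (nd == 3) -1:1 else 0)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  manh <- abs(offs$dy) + abs(offs$dx) + abs(offs$dz)
  offs <- switch(as.character(connectivity),
                 "4" = offs[manh <= 1, ], "6" = offs[manh <= 1, ],
                 "8" = offs, "18" = offs[manh <= 2, ], "26" = offs)
  labels <- array(0L, d)
  nlab <- 0L
  nz <- if (nd == 3) d[3] else 1L
  for (z0 in seq_len(nz)) for (x0 in seq_len(d[2])) for (y0 in seq_len(d[1])) {
    val <- if (nd == 3) mask[y0, x0, z0] else mask[y0, x0]
    lab0 <- if (nd == 3) labels[y0, x0, z0] else labels[y0, x0]
    if (!val || lab0 != 0L) next
    nlab <- nlab + 1L
    queue <- list(c(y0, x0, z0))
    if (nd == 3) labels[y0, x0, z0] <- nlab else labels[y0, x0] <- nlab
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(offs))) {
        yy <- p[1] + offs$dy[k]; xx <- p[2] + offs$dx[k]
        zz <- p[3] + offs$dz[k]
        if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] ||
            zz < 1 || zz > nz) next
        v <- if (nd == 3) mask[yy, xx, zz] else mask[yy, xx]
        l <- if (nd == 3) labels[yy, xx, zz] else labels[yy, xx]
        if (v && l == 0L) {
          if (nd == 3) labels[yy, xx, zz] <- nlab else labels[yy, xx] <- nlab
          queue[[length(queue) + 1L]] <- c(yy, xx, zz)
        }
      }
    }
  }
  labels
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# match detected spots to planted truth within a radius
match_truth <- function(spots, truth, radius = 2) {
  if (nrow(spots) == 0)
    return(list(precision = NA, recall = 0, nn = integer(), ok = logical()))
  dd <- outer(spots$y, truth$y, "-")^2 + outer(spots$x, truth$x, "-")^2
  if (!all(is.na(spots$z))) dd <- dd + outer(spots$z, truth$z, "-")^2
  nn <- apply(dd, 1, which.min)
  mind <- sqrt(apply(dd, 1, min))
  ok <- mind <= radius
  list(precision = mean(ok),
       recall = length(unique(nn[ok])) / nrow(truth),
       nn = nn, ok = ok)
}
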