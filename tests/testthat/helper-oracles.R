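# Independent brute-force oracles used to cross-check the package's
# implementations on small instances.  Deliberately naive: explicit loops
# and first-principles formulas, no shared code with R/.

offsets_3d <- function(connectivity) {
  out <- NULL
  maxm <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    m <- abs(dx) + abs(dy) + abs(dz)
    if (m >= 1 && m <= maxm) out <- rbind(out, c(dy, dx, dz))
  }
  out
}

# naive sliding-window median with edge replication
oracle_median_filter <- function(arr, radius) {
  d <- dim(arr)
  out <- arr
  if (radius == 0) return(out)
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1])) {
    vals <- c()
    for (dx in -radius:radius) for (dy in -radius:radius) {
      yy <- min(max(y + dy, 1), d[1])
      xx <- min(max(x + dx, 1), d[2])
      vals <- c(vals, arr[yy, xx, z])
    }
    out[y, x, z] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

# exhaustive flood fill over all voxels (repeated sweeps until stable)
oracle_flood_fill <- function(vox, seed_xyz, tmin, tmax, connectivity) {
  d <- dim(vox)
  inr <- vox >= tmin & vox <= tmax
  reach <- array(FALSE, d)
  reach[seed_xyz[2], seed_xyz[1], seed_xyz[3]] <- TRUE
  off <- offsets_3d(connectivity)
  repeat {
    changed <- FALSE
    for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1])) {
      if (!reach[y, x, z]) next
      for (k in seq_len(nrow(off))) {
        yy <- y + off[k, 1]; xx <- x + off[k, 2]; zz <- z + off[k, 3]
        if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3])
          next
        if (inr[yy, xx, zz] && !reach[yy, xx, zz]) {
          reach[yy, xx, zz] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  reach
}

# BFS connected-component labelling, first-voxel order along R's linear
# index (y fastest, then x, then z)
oracle_label_bfs <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(0L, d)
  off <- offsets_3d(connectivity)
  nxt <- 0L
  # first-voxel scan in linear-index order (y fastest, then x, then z)
  for (i in seq_len(prod(d))) {
    if (!mask[i] || lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      j0 <- j - 1L
      y <- j0 %% d[1] + 1L
      x <- (j0 %/% d[1]) %% d[2] + 1L
      z <- j0 %/% (d[1] * d[2]) + 1L
      for (k in seq_len(nrow(off))) {
        yy <- y + off[k, 1]; xx <- x + off[k, 2]; zz <- z + off[k, 3]
        if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3])
          next
        if (mask[yy, xx, zz] && lab[yy, xx, zz] == 0L) {
          lab[yy, xx, zz] <- nxt
          queue <- c(queue, yy + (xx - 1L) * d[1] + (zz - 1L) * d[1] * d[2])
        }
      }
    }
  }
  lab
}

# --- first-principles threshold criteria (candidate split "<= t | > t") ---

oracle_crit_otsu <- function(counts, t) {
  g <- seq_along(counts) - 1
  lo <- g <= t
  n0 <- sum(counts[lo]); n1 <- sum(counts[!lo])
  if (n0 == 0 || n1 == 0) return(NA_real_)
  mu0 <- sum(g[lo] * counts[lo]) / n0
  mu1 <- sum(g[!lo] * counts[!lo]) / n1
  w0 <- n0 / (n0 + n1)
  w0 * (1 - w0) * (mu0 - mu1)^2
}

oracle_crit_li <- function(counts, t) {
  g <- seq_along(counts) - 1
  lo <- g <= t
  n0 <- sum(counts[lo]); n1 <- sum(counts[!lo])
  if (n0 == 0 || n1 == 0) return(NA_real_)
  m0 <- sum(g[lo] * counts[lo]); m1 <- sum(g[!lo] * counts[!lo])
  v <- 0
  if (m0 > 0) v <- v - m0 * log(m0 / n0)
  if (m1 > 0) v <- v - m1 * log(m1 / n1)
  -v # caller maximises; criterion is minimised
}

oracle_crit_huang <- function(counts, t) {
  g <- seq_along(counts) - 1
  nz <- which(counts > 0)
  C <- max(1, max(nz) - min(nz))
  lo <- g <= t
  n0 <- sum(counts[lo]); n1 <- sum(counts[!lo])
  if (n0 == 0 || n1 == 0) return(NA_real_)
  mu0 <- sum(g[lo] * counts[lo]) / n0
  mu1 <- sum(g[!lo] * counts[!lo]) / n1
  s <- 0
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    mu <- if (lo[i]) mu0 else mu1
    u <- 1 / (1 + abs(g[i] - mu) / C)
    if (u > 0 && u < 1)
      s <- s + counts[i] * (-u * log(u) - (1 - u) * log(1 - u))
  }
  -s # minimised
}

oracle_crit_yen <- function(counts, t) {
  p <- counts / sum(counts)
  g <- seq_along(counts) - 1
  lo <- g <= t
  P <- sum(p[lo])
  G0 <- sum(p[lo]^2); G1 <- sum(p[!lo]^2)
  if (P <= 0 || P >= 1 || G0 <= 0 || G1 <= 0) return(NA_real_)
  -log(G0 * G1) + 2 * log(P * (1 - P))
}

oracle_crit_renyi <- function(counts, t, rho) {
  p <- counts / sum(counts)
  g <- seq_along(counts) - 1
  lo <- g <= t
  P <- sum(p[lo])
  if (P <= 0 || P >= 1) return(NA_real_)
  if (abs(rho - 1) < 1e-9) {
    q0 <- p[lo][p[lo] > 0] / P
    q1 <- p[!lo][p[!lo] > 0] / (1 - P)
    return(-sum(q0 * log(q0)) - sum(q1 * log(q1)))
  }
  A0 <- sum((p[lo] / P)^rho); A1 <- sum((p[!lo] / (1 - P))^rho)
  if (A0 <= 0 || A1 <= 0) return(NA_real_)
  (log(A0) + log(A1)) / (1 - rho)
}

# smallest strict-improvement argmax over all candidate thresholds
oracle_scan <- function(counts, crit_fn, ...) {
  best <- NA_integer_; bestv <- -Inf
  for (t in 0:(length(counts) - 2)) {
    v <- crit_fn(counts, t, ...)
    if (is.na(v)) next
    if (v > bestv + 1e-12) { bestv <- v; best <- t }
  }
  best
}

# implementation vs oracle agree either on theta or (for fp plateau ties)
# on criterion value
expect_scan_agreement <- function(theta_impl, counts, crit_fn, ...) {
  theta_orc <- oracle_scan(counts, crit_fn, ...)
  if (is.na(theta_orc)) return(invisible(NULL))
  ok <- theta_impl == theta_orc ||
    isTRUE(all.equal(crit_fn(counts, theta_impl, ...),
                     crit_fn(counts, theta_orc, ...), tolerance = 1e-9))
  expect_true(ok, label = sprintf("theta %d vs oracle %d", theta_impl,
                                  theta_orc))
}

rand_hist <- function(seed, nbins = 256, modes = 2) {
  set.seed(seed)
  counts <- numeric(nbins)
  centres <- sample(5:(nbins - 6), modes)
  for (c0 in centres) {
    x <- round(rnorm(300, c0, sample(3:12, 1)))
    x <- x[x >= 0 & x < nbins]
    counts <- counts + tabulate(x + 1L, nbins)
  }
  counts + tabulate(sample.int(nbins, 50, TRUE), nbins)
}

# dense bimodal histogram with overlapping tails and no empty bins --
# the regime where clustering methods have a unique interior optimum
dense_bimodal_hist <- function(seed, nbins = 256) {
  set.seed(seed)
  c1 <- sample(60:90, 1); c2 <- sample(160:200, 1)
  s1 <- sample(18:28, 1); s2 <- sample(18:28, 1)
  n <- sample(20000:30000, 1)
  x <- c(round(rnorm(n, c1, s1)), round(rnorm(n, c2, s2)))
  x <- x[x >= 0 & x < nbins]
  tabulate(x + 1L, nbins) + 1
}

two_spike_hist <- function(a, b, na = 50, nb = 50, nbins = 256) {
  counts <- numeric(nbins)
  counts[a + 1] <- na; counts[b + 1] <- nb
  counts
}

as_hist <- function(counts, bit_depth = 8L) {
  structure(list(counts = as.numeric(counts), total = sum(counts),
                 bit_depth = bit_depth), class = "intensity_histogram")
}

rand_mask <- function(seed, d, p = 0.4) {
  set.seed(seed)
  array(as.integer(runif(prod(d)) < p), d)
}

rand_stack <- function(seed, d, maxv = 255L) {
  set.seed(seed)
  intensity_stack(array(sample(0:maxv, prod(d), TRUE), d))
}
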