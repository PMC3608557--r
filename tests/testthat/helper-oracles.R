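# Independent brute-force oracles used to validate the optimized
# implementations on small fixtures. These are deliberately naive:
# coordinate arithmetic, flood fills and exhaustive enumeration only.

cross_offsets <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0),
                       c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
cube_offsets <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))

# set-union dilation: translate every foreground voxel by every offset
oracle_dilate <- function(a, offsets) {
  d <- dim(a)
  out <- array(FALSE, d)
  w <- which(a, arr.ind = TRUE)
  for (r in seq_len(nrow(w))) {
    p <- sweep(offsets, 2, w[r, ], "+")
    keep <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    out[p[keep, , drop = FALSE]] <- TRUE
  }
  out
}

# flood fill in a logical matrix from a seed, 8- or 4-connectivity;
# returns the component mask
oracle_flood2d <- function(m, seed, conn = 8) {
  d <- dim(m)
  comp <- matrix(FALSE, d[1], d[2])
  if (!m[seed[1], seed[2]]) return(comp)
  queue <- list(seed)
  comp[seed[1], seed[2]] <- TRUE
  offs <- if (conn == 8) expand.grid(-1:1, -1:1) else data.frame(c(1, -1, 0, 0), c(0, 0, 1, -1))
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (t in seq_len(nrow(offs))) {
      q <- c(p[1] + offs[t, 1], p[2] + offs[t, 2])
      if (q[1] < 1 || q[1] > d[1] || q[2] < 1 || q[2] > d[2]) next
      if (m[q[1], q[2]] && !comp[q[1], q[2]]) {
        comp[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  comp
}

slice_of <- function(a, axis, idx) {
  switch(axis, a[idx, , ], a[, idx, ], a[, , idx])
}

# per-voxel minimal Cartesian cross-section by per-voxel flood fills
oracle_min_cross <- function(a) {
  d <- dim(a)
  out <- array(0L, d)
  w <- which(a, arr.ind = TRUE)
  for (r in seq_len(nrow(w))) {
    i <- w[r, 1]; j <- w[r, 2]; k <- w[r, 3]
    areas <- c(
      sum(oracle_flood2d(slice_of(a, 1, i), c(j, k))),
      sum(oracle_flood2d(slice_of(a, 2, j), c(i, k))),
      sum(oracle_flood2d(slice_of(a, 3, k), c(i, j)))
    )
    out[i, j, k] <- min(areas)
  }
  out
}

# per-orientation maximal 2D cross-section of the component containing each
# voxel (used by the particle-filter oracle)
oracle_max_cross <- function(a) {
  d <- dim(a)
  out <- array(0L, d)
  w <- which(a, arr.ind = TRUE)
  for (r in seq_len(nrow(w))) {
    i <- w[r, 1]; j <- w[r, 2]; k <- w[r, 3]
    areas <- c(
      sum(oracle_flood2d(slice_of(a, 1, i), c(j, k))),
      sum(oracle_flood2d(slice_of(a, 2, j), c(i, k))),
      sum(oracle_flood2d(slice_of(a, 3, k), c(i, j)))
    )
    out[i, j, k] <- max(areas)
  }
  out
}

# slice-wise hole fill in all three orientations, unioned (naive)
oracle_fill <- function(a) {
  d <- dim(a)
  out <- a
  for (axis in 1:3) {
    for (idx in seq_len(d[axis])) {
      m <- slice_of(a, axis, idx)
      bg <- !m
      outside <- matrix(FALSE, nrow(m), ncol(m))
      for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
        if ((i == 1 || i == nrow(m) || j == 1 || j == ncol(m)) && bg[i, j] && !outside[i, j])
          outside <- outside | oracle_flood2d(bg, c(i, j), conn = 4)
      }
      holes <- bg & !outside
      filled <- m | holes
      if (axis == 1) out[idx, , ] <- out[idx, , ] | filled
      if (axis == 2) out[, idx, ] <- out[, idx, ] | filled
      if (axis == 3) out[, , idx] <- out[, , idx] | filled
    }
  }
  out
}

# literal transcription of the three-order Renyi-entropy threshold
# criterion, straight loops over the histogram
oracle_renyi <- function(counts) {
  p <- counts / sum(counts)
  P1 <- cumsum(p); P2 <- 1 - P1
  eps <- .Machine$double.eps
  first <- which(P1 > eps)[1] - 1L
  last <- max(which(P2 >= eps)) - 1L
  best <- c(-Inf, -Inf, -Inf); arg <- c(first, first, first)
  for (it in first:last) {
    i1 <- it + 1L
    if (P1[i1] <= 0 || P2[i1] <= 0) next
    eb1 <- 0; eo1 <- 0; ebs <- 0; eos <- 0; eb2 <- 0; eo2 <- 0
    for (ih in 0:255) {
      pr <- p[ih + 1L]
      if (ih <= it) {
        if (pr > 0) eb1 <- eb1 - (pr / P1[i1]) * log(pr / P1[i1])
        ebs <- ebs + sqrt(pr / P1[i1])
        eb2 <- eb2 + (pr / P1[i1])^2
      } else {
        if (pr > 0) eo1 <- eo1 - (pr / P2[i1]) * log(pr / P2[i1])
        eos <- eos + sqrt(pr / P2[i1])
        eo2 <- eo2 + (pr / P2[i1])^2
      }
    }
    tots <- c(if (ebs > 0 && eos > 0) log(ebs * eos) / 0.5 else -Inf,
              eb1 + eo1,
              if (eb2 > 0 && eo2 > 0) -log(eb2 * eo2) else -Inf)
    for (m in 1:3) if (tots[m] > best[m]) { best[m] <- tots[m]; arg[m] <- it }
  }
  ts <- sort(arg)
  if (abs(ts[1] - ts[2]) <= 5) {
    b <- if (abs(ts[2] - ts[3]) <= 5) c(1, 2, 1) else c(0, 1, 3)
  } else {
    b <- if (abs(ts[2] - ts[3]) <= 5) c(3, 1, 0) else c(1, 2, 1)
  }
  omega <- P1[ts[3] + 1L] - P1[ts[1] + 1L]
  floor(ts[1] * (P1[ts[1] + 1L] + 0.25 * omega * b[1]) +
          0.25 * ts[2] * omega * b[2] +
          ts[3] * (P2[ts[3] + 1L] + 0.25 * omega * b[3]))
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(na)])
  combos <- utils::combn(n, na)
  ws <- apply(combos, 2, function(ix) sum(ranks[ix]))
  mu <- na * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# small geometry builders -------------------------------------------------

solid_cylinder_z <- function(dims, center, radius, z_range = seq_len(dims[3])) {
  a <- array(FALSE, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) a[i, j, z_range] <- TRUE
  a
}

solid_torus <- function(dims, center, major, minor) {
  a <- array(FALSE, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    rho <- sqrt((i - center[1])^2 + (j - center[2])^2)
    if ((rho - major)^2 + (k - center[3])^2 <= minor^2) a[i, j, k] <- TRUE
  }
  a
}

# 26-adjacency graph cycle rank (edges - vertices + components) of a
# skeleton; > 0 iff the skeleton contains a loop
cycle_rank <- function(vox) {
  w <- which(vox, arr.ind = TRUE)
  n <- nrow(w)
  if (n == 0) return(0L)
  e <- 0L
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    if (max(abs(w[a, ] - w[b, ])) == 1) e <- e + 1L
  comp <- max(halovasc:::cpp_label3d(vox, dim(vox), 26L))
  e - n + comp
}

n_components <- function(vox, conn = 26L) {
  max(halovasc:::cpp_label3d(vox, dim(vox), conn), 0L)
}

random_volume <- function(dims, density, seed) {
  set.seed(seed)
  array(runif(prod(dims)) < density, dims)
}
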