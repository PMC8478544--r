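# Brute-force reference implementations, deliberately independent of the
# package's distance-transform / simplex-triangulation code paths: exhaustive
# ball neighborhoods, BFS flood fill, direct full-kernel convolution, and a
# winding-number point-in-polygon test.

o_ball_offsets <- function(r) {
  ir <- ceiling(r)
  off <- as.matrix(expand.grid(d1 = -ir:ir, d2 = -ir:ir, d3 = -ir:ir))
  off[rowSums(off^2) <= r^2 + 1e-7, , drop = FALSE]
}

o_dilate <- function(m, r) {
  off <- o_ball_offsets(r)
  d <- dim(m)
  out <- array(FALSE, d)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  for (k in seq_len(nrow(off))) {
    p <- sweep(idx, 2, off[k, ], "+")
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    out[p[ok, , drop = FALSE]] <- TRUE
  }
  out
}

# voxel kept iff no in-bounds background voxel lies within the ball
o_erode <- function(m, r) !o_dilate(!m, r)

o_pad <- function(x, p, value = FALSE) {
  d <- dim(x)
  out <- array(value, d + 2L * p)
  out[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- x
  out
}

o_crop <- function(x, p, d) {
  x[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), drop = FALSE]
}

o_close <- function(m, r) {
  p <- as.integer(ceiling(r)) + 1L
  o_crop(o_erode(o_dilate(o_pad(m, p), r), r), p, dim(m))
}

o_open <- function(m, r) {
  p <- as.integer(ceiling(r)) + 1L
  o_crop(o_dilate(o_erode(o_pad(m, p), r), r), p, dim(m))
}

o_label <- function(m, conn = 6) {
  d <- dim(m)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (conn == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  for (start in which(m)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      ci <- arrayInd(cur, d)
      nb <- sweep(offs, 2, as.integer(ci), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      lin <- lin[m[lin] & lab[lin] == 0L]
      lab[lin] <- nxt
      queue <- c(queue, lin)
    }
  }
  lab
}

o_largest_component <- function(m, conn = 6) {
  lab <- o_label(m, conn)
  if (max(lab) == 0L) return(array(FALSE, dim(m)))
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

o_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# direct (non-separable) truncated-Gaussian convolution, reflecting borders
o_gauss <- function(vol, sigma, radius) {
  d <- dim(vol)
  ks <- -radius:radius
  k3 <- expand.grid(a = ks, b = ks, c = ks)
  w <- exp(-0.5 * (k3$a^2 + k3$b^2 + k3$c^2) / sigma^2)
  w <- w / sum(w)
  # truncation renormalizes the separable kernel per axis; the product of
  # per-axis normalized kernels equals the normalized product kernel
  out <- array(0, d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        acc <- 0
        for (t in seq_len(nrow(k3))) {
          ii <- o_reflect(i + k3$a[t], d[1])
          jj <- o_reflect(j + k3$b[t], d[2])
          kk <- o_reflect(k + k3$c[t], d[3])
          acc <- acc + w[t] * vol[ii, jj, kk]
        }
        out[i, j, k] <- acc
      }
  out
}

# winding-number point-in-polygon (boundary counts as inside)
o_point_in_poly <- function(y, x, poly) {
  n <- nrow(poly)
  ang <- 0
  for (e in seq_len(n)) {
    p1 <- poly[e, ] - c(y, x)
    p2 <- poly[e %% n + 1, ] - c(y, x)
    cr <- p1[1] * p2[2] - p1[2] * p2[1]
    dt <- sum(p1 * p2)
    if (abs(cr) < 1e-9 && dt <= 1e-9) return(TRUE)  # on an edge or vertex
    ang <- ang + atan2(cr, dt)
  }
  abs(ang) > pi
}

# 6-neighbourhood adjacency scan: plaque voxels with a face neighbor in wall
o_adjacent_layer <- function(plaque, wall) {
  d <- dim(plaque)
  out <- array(FALSE, d)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  idx <- which(plaque, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    hit <- rep(FALSE, nrow(idx))
    hit[ok] <- wall[nb[ok, , drop = FALSE]]
    out[idx[hit, , drop = FALSE]] <- TRUE
  }
  out
}
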