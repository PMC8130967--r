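# fixtures shared across test files; everything is generated in code

# a hand-built network with known geometry: filaments given as rows
# (x0, y0, z0, x1, y1, z1)
manual_network <- function(segs, radius = 0.005, box = 1) {
  segs <- matrix(segs, ncol = 6, byrow = TRUE)
  structure(list(p0 = segs[, 1:3, drop = FALSE],
                 p1 = segs[, 4:6, drop = FALSE],
                 radius = rep(radius, nrow(segs)),
                 length_nominal = sqrt(rowSums((segs[, 4:6, drop = FALSE] -
                                                  segs[, 1:3, drop = FALSE])^2)),
                 parent = rep(NA_integer_, nrow(segs)),
                 branch_angle = rep(NA_real_, nrow(segs)),
                 box_edge = box, seed = 0L, spec = NULL),
            class = "actin_network")
}

# obstacle mask of random overlapping disks (periodic), for tests that
# need a generic blocked geometry without the network machinery
disk_mask <- function(n_disks, r_disk, res = 2e-3, box = 1, seed = 1) {
  n <- round(box / res)
  px <- (seq_len(n) - 0.5) * res
  m <- matrix(0L, n, n)
  ctr <- with_seed(seed, matrix(runif(2 * n_disks, 0, box), n_disks, 2))
  for (k in seq_len(n_disks)) {
    for (sx in c(-box, 0, box)) for (sy in c(-box, 0, box)) {
      cx <- ctr[k, 1] + sx; cy <- ctr[k, 2] + sy
      ix <- which(abs(px - cx) <= r_disk)
      iy <- which(abs(px - cy) <= r_disk)
      if (length(ix) && length(iy)) {
        sub <- outer((px[ix] - cx)^2, (px[iy] - cy)^2, "+") <= r_disk^2
        m[ix, iy] <- pmax(m[ix, iy], sub + 0L)
      }
    }
  }
  attr(m, "res") <- res
  attr(m, "box") <- box
  m
}

# brute-force R implementation of the segment-segment minimum distance
# (independent oracle for the C++ kernel)
seg_dist_R <- function(p0, p1, q0, q1) {
  best <- Inf
  for (s in seq(0, 1, length.out = 401)) {
    a <- p0 + s * (p1 - p0)
    # distance from point a to segment [q0, q1]
    d2 <- q1 - q0
    tt <- sum((a - q0) * d2) / sum(d2^2)
    tt <- min(1, max(0, tt))
    b <- q0 + tt * d2
    best <- min(best, sqrt(sum((a - b)^2)))
  }
  best
}

# definition-based morphological opening oracle: a pixel is accessible
# iff it is covered by some disk of radius R whose center keeps distance
# >= R from every obstacle pixel; centers and coverage are evaluated by
# brute force on the pixel grid (O(n^2 * r^2)), so keep fixtures small
opening_oracle <- function(obst, R, res, periodic = TRUE) {
  n <- nrow(obst)
  rpx <- R / res
  if (rpx <= 0) return(obst)
  pad <- ceiling(rpx) + 1L
  idx <- if (periodic) c((n - pad + 1L):n, 1L:n, 1L:pad) else NULL
  big <- if (periodic) obst[idx, idx] else obst
  nb <- nrow(big)
  ob <- which(big == 1, arr.ind = TRUE)
  # admissible centers: distance to every obstacle pixel center > rpx
  adm <- matrix(TRUE, nb, nb)
  if (nrow(ob)) {
    for (i in seq_len(nb)) {
      dx2 <- (ob[, 1] - i)^2
      near <- ob[dx2 <= rpx^2, , drop = FALSE]
      if (!nrow(near)) next
      for (j in seq_len(nb)) {
        if (any((near[, 1] - i)^2 + (near[, 2] - j)^2 <= rpx^2))
          adm[i, j] <- FALSE
      }
    }
  }
  # accessible: within rpx of an admissible center
  acc <- matrix(FALSE, nb, nb)
  ctr <- which(adm, arr.ind = TRUE)
  rr <- floor(rpx)
  for (k in seq_len(nrow(ctr))) {
    i <- ctr[k, 1]; j <- ctr[k, 2]
    for (di in -rr:rr) {
      ii <- i + di
      if (ii < 1 || ii > nb) next
      span <- floor(sqrt(rpx^2 - di^2))
      jj <- max(1, j - span):min(nb, j + span)
      acc[ii, jj] <- TRUE
    }
  }
  blocked <- 1L - (acc + 0L)
  if (periodic) blocked[pad + (1:n), pad + (1:n)] else blocked
}
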