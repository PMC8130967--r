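# Vesicle-accessibility of 2D cross-sections through a 3D filament network.
#
# A slice through the cylinder union yields obstacles (circles, ellipses
# and near-rectangular polygons).  A vesicle of radius R cannot enter any
# point whose surrounding disk of radius R does not fit into free space:
# the blocked region is the complement of the morphological opening of
# free space by a disk of radius R.  The opening is computed exactly on a
# raster (default 1 nm/px) with Euclidean distance transforms and periodic
# wrap, so that gaps narrower than the vesicle diameter are absorbed into
# the blocked region, as are obstacle-boundary wedges the disk cannot
# reach.

#' Rasterize the obstacle cross-section of a network at height z
#'
#' Pixel centers on an `n x n` grid over `[0, box]^2` are tested exactly
#' against the solid (flat-ended) cylinders; with `periodic = TRUE` the
#' network is tiled at `+- box` in x and y so that the mask is usable for
#' periodic cell problems.
#'
#' @param net an `actin_network`.
#' @param z slice height in um, in `[0, box_edge]`.
#' @param res pixel size in um (default 0.001 = 1 nm).
#' @param periodic wrap the network periodically in x and y.
#' @param counts return the per-pixel cylinder multiplicity instead of
#'   the binary union mask (the summed-area accounting of overlapping
#'   sections).
#' @return integer matrix (1 = obstacle; multiplicities when
#'   `counts = TRUE`), attribute `res`.
#' @export
obstacle_mask <- function(net, z, res = 1e-3, periodic = TRUE,
                          counts = FALSE) {
  stopifnot(inherits(net, "actin_network"), z >= 0, z <= net$box_edge)
  n <- max(1L, round(net$box_edge / res))
  if (nrow(net$p0) == 0) {
    m <- matrix(0L, n, n)
  } else {
    m <- cpp_obstacle_mask(net$p0, net$p1, net$radius, z, n,
                           net$box_edge, periodic, counts)
  }
  attr(m, "res") <- net$box_edge / n
  attr(m, "box") <- net$box_edge
  m
}

# morphological opening of the free space (complement of `obst`) by a
# Euclidean disk of radius R (um), computed with two distance transforms;
# periodic wrap via padding.  Returns the blocked mask (integer).
.open_blocked <- function(obst, R, res, periodic = TRUE) {
  n <- nrow(obst)
  if (R <= 0) return(obst)
  rpx <- R / res
  pad <- min(n, ceiling(rpx) + 2L)
  wrap <- function(m) {
    nn <- nrow(m)
    idx <- c((nn - pad + 1L):nn, 1L:nn, 1L:pad)
    m[idx, idx]
  }
  grow <- function(m) {  # zero padding (non-periodic)
    big <- matrix(0L, n + 2L * pad, n + 2L * pad)
    big[pad + (1:n), pad + (1:n)] <- m
    big
  }
  big <- if (periodic) wrap(obst) else grow(obst)
  # distance of each free pixel to the nearest obstacle pixel
  d_obst <- EBImage::distmap(1 - big)
  eroded <- d_obst > rpx          # admissible disk centers
  # distance of each pixel to the nearest admissible center
  d_cent <- EBImage::distmap(1 - eroded)
  opened <- d_cent <= rpx         # accessible (opened free space)
  blocked <- 1L - matrix(as.integer(opened), nrow(big), ncol(big))
  ctr <- pad + (1:n)
  out <- blocked[ctr, ctr]
  storage.mode(out) <- "integer"
  out
}

#' Region of a slice inaccessible to a finite-radius vesicle
#'
#' @param x an `actin_network` (sliced at `z`), an obstacle mask as
#'   returned by [obstacle_mask()], or a list of obstacles from
#'   [slice_cross_sections()] (rasterized at `res`).
#' @param R vesicle radius in um (`R >= 0`).
#' @param z slice height (needed when `x` is a network).
#' @param res raster resolution in um.
#' @param periodic treat the slice as periodic in x and y.
#' @param box slice edge length (needed for obstacle lists).
#' @return an object of class `blocked_geometry`: the obstacle mask, the
#'   blocked mask (obstacles plus unreachable gaps/wedges), the
#'   inaccessible area fraction `phi` (fraction covered by the blocked
#'   region, i.e. union semantics) and, for network input,
#'   `phi_reported`: the same quantity under the summed-component
#'   accounting (overlapping obstacle sections counted with
#'   multiplicity, plus the wedge/gap area), the convention in which the
#'   reference inaccessible-area values and the power-law calibration
#'   are expressed.  The two agree for dilute slices and diverge as
#'   sections overlap.
#' @export
inaccessible_region <- function(x, R, z = NULL, res = 1e-3,
                                periodic = TRUE, box = NULL) {
  stopifnot(is.numeric(R), length(R) == 1, R >= 0)
  obst_sum <- NULL
  if (inherits(x, "actin_network")) {
    stopifnot(!is.null(z))
    obst <- obstacle_mask(x, z, res = res, periodic = periodic)
    obst_sum <- mean(obstacle_mask(x, z, res = res, periodic = periodic,
                                   counts = TRUE))
    box <- x$box_edge
  } else if (is.matrix(x)) {
    obst <- x
    res <- attr(x, "res") %||% res
    box <- attr(x, "box") %||% (nrow(x) * res)
  } else if (is.list(x)) {
    stopifnot(!is.null(box))
    obst <- rasterize_obstacles(x, box = box, res = res)
  } else stop("unsupported input")
  res_eff <- attr(obst, "res") %||% res
  blocked <- .open_blocked(obst, R, res_eff, periodic = periodic)
  phi <- mean(blocked)
  phi_obstacle <- mean(obst)
  structure(list(slice_z = z, R = R, res = res_eff, box = box,
                 obstacle = obst, blocked = blocked,
                 phi = phi,
                 phi_obstacle = phi_obstacle,
                 phi_reported = if (!is.null(obst_sum))
                   obst_sum + (phi - phi_obstacle) else phi),
            class = "blocked_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.blocked_geometry <- function(x, ...) {
  cat(sprintf("Blocked slice geometry (R = %g um, %d px, %g um/px)\n",
              x$R, nrow(x$blocked), x$res))
  cat(sprintf("  obstacle area fraction    : %.4f\n", x$phi_obstacle))
  cat(sprintf("  inaccessible area fraction: %.4f\n", x$phi))
  invisible(x)
}

#' Exact conic cross-sections of the filament cylinders at height z
#'
#' Every cylinder cut by the plane contributes its section: a circle for
#' an axis perpendicular to the slice, an ellipse with semi-axes
#' `(r, r/cos(gamma))` for an axis at angle `gamma` to the plane normal,
#' and an elongated near-rectangular polygon for axes within 5 degrees of
#' the slice plane.  Boundaries are returned as polygons (at most 66
#' vertices) computed from the exact cylinder equation, clipped to the
#' slice square, together with the conic parameters.
#'
#' @param net an `actin_network`.
#' @param z slice height in um.
#' @param n_theta boundary sampling resolution.
#' @return list of obstacles; each has `kind` (`"circle"`, `"ellipse"` or
#'   `"polygon"`), `center`, `semi_axes`, `angle` (radians, major axis),
#'   `vertices` (n x 2 matrix), `area` (of the clipped polygon) and
#'   `filament` (row index).
#' @export
slice_cross_sections <- function(net, z, n_theta = 64) {
  stopifnot(inherits(net, "actin_network"), z >= 0, z <= net$box_edge)
  out <- list()
  if (nrow(net$p0) == 0) return(out)
  box <- net$box_edge
  for (i in seq_len(nrow(net$p0))) {
    p0 <- net$p0[i, ]; p1 <- net$p1[i, ]; r <- net$radius[i]
    if (z < min(p0[3], p1[3]) - r || z > max(p0[3], p1[3]) + r) next
    d <- p1 - p0; L <- sqrt(sum(d^2))
    if (L <= 0) next
    dhat <- d / L
    cosg <- abs(dhat[3])                 # cos(angle to plane normal)
    near_parallel <- cosg < cos(85 * pi / 180)   # within 5 deg of plane
    if (!near_parallel) {
      # circle/ellipse: exact conic of the infinite cylinder, vertices
      # outside the finite cylinder's axial extent dropped (flat ends)
      s_star <- (z - p0[3]) / (L * dhat[3])
      c3 <- p0 + s_star * L * dhat
      proj <- c(dhat[1], dhat[2])
      pn <- sqrt(sum(proj^2))
      e_maj <- if (pn > 1e-12) proj / pn else c(1, 0)
      e_min <- c(-e_maj[2], e_maj[1])
      a_maj <- r / cosg
      th <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
      vx <- c3[1] + a_maj * cos(th) * e_maj[1] + r * sin(th) * e_min[1]
      vy <- c3[2] + a_maj * cos(th) * e_maj[2] + r * sin(th) * e_min[2]
      # axial coordinate of each boundary point on the cylinder surface
      t_ax <- ((vx - p0[1]) * d[1] + (vy - p0[2]) * d[2] +
                 (z - p0[3]) * d[3]) / L^2
      keep3 <- t_ax >= -1e-9 & t_ax <= 1 + 1e-9
      if (sum(keep3) < 3) next
      verts <- cbind(vx, vy)[keep3, , drop = FALSE]
      center <- c3[1:2]
      kind <- if (cosg > cos(1e-6)) "circle" else "ellipse"
    } else {
      # near-parallel axis: sweep along the axis; at each station the
      # cylinder surface cuts the plane in two boundary points
      ref <- if (abs(dhat[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * dhat) * dhat; u <- u / sqrt(sum(u^2))
      v <- c(dhat[2]*u[3] - dhat[3]*u[2], dhat[3]*u[1] - dhat[1]*u[3],
             dhat[1]*u[2] - dhat[2]*u[1])
      svals <- seq(0, 1, length.out = n_theta %/% 2 + 2)
      upper <- lower <- matrix(NA_real_, length(svals), 2)
      for (k in seq_along(svals)) {
        sp <- svals[k]
        # a*cos(t) + b*sin(t) = c on the surface circle at station sp
        a <- r * u[3]; b <- r * v[3]
        cc <- z - (p0[3] + sp * L * dhat[3])
        amp <- sqrt(a^2 + b^2)
        if (amp < 1e-15) {
          if (abs(cc) < 1e-12) { t1 <- 0; t2 <- pi } else next
        } else {
          if (abs(cc) > amp) next
          base <- atan2(b, a)
          dtt <- acos(pmin(1, pmax(-1, cc / amp)))
          t1 <- base + dtt; t2 <- base - dtt
        }
        q1 <- p0 + sp * L * dhat + r * cos(t1) * u + r * sin(t1) * v
        q2 <- p0 + sp * L * dhat + r * cos(t2) * u + r * sin(t2) * v
        upper[k, ] <- q1[1:2]; lower[k, ] <- q2[1:2]
      }
      ok <- stats::complete.cases(upper)
      if (sum(ok) < 2) next
      verts <- rbind(upper[ok, , drop = FALSE],
                     lower[rev(which(ok)), , drop = FALSE])
      center <- colMeans(verts)
      kind <- "polygon"
    }
    verts <- .clip_poly_square(verts, box)
    if (nrow(verts) < 3) next
    area <- .poly_area(verts)
    if (area <= 0) next
    out[[length(out) + 1L]] <-
      list(kind = kind, center = center,
           semi_axes = c(r, if (cosg > 1e-12) r / cosg else Inf),
           angle = atan2(dhat[2], dhat[1]),
           vertices = verts, area = area, filament = i)
  }
  out
}

# polygon area (shoelace, absolute value)
.poly_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clip of a polygon against [0, box]^2
.clip_poly_square <- function(v, box) {
  clip1 <- function(v, inside, intersect) {
    n <- nrow(v)
    if (n == 0) return(v)
    out <- matrix(NA_real_, 0, 2)
    for (i in seq_len(n)) {
      a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
      ia <- inside(a); ib <- inside(b)
      if (ia) out <- rbind(out, a)
      if (xor(ia, ib)) out <- rbind(out, intersect(a, b))
    }
    out
  }
  lerp <- function(a, b, t) a + t * (b - a)
  for (side in 1:4) {
    v <- switch(side,
      clip1(v, function(p) p[1] >= 0,
            function(a, b) lerp(a, b, (0 - a[1]) / (b[1] - a[1]))),
      clip1(v, function(p) p[1] <= box,
            function(a, b) lerp(a, b, (box - a[1]) / (b[1] - a[1]))),
      clip1(v, function(p) p[2] >= 0,
            function(a, b) lerp(a, b, (0 - a[2]) / (b[2] - a[2]))),
      clip1(v, function(p) p[2] <= box,
            function(a, b) lerp(a, b, (box - a[2]) / (b[2] - a[2]))))
    if (nrow(v) == 0) break
  }
  v
}

#' Rasterize a list of 2D obstacles onto a square grid
#'
#' Even-odd scanline fill of the obstacle polygons; pixel centers on an
#' `n x n` grid over `[0, box]^2`.
#'
#' @param obstacles list as returned by [slice_cross_sections()], or any
#'   list of elements with a `vertices` matrix.
#' @param box slice edge length in um.
#' @param res pixel size in um.
#' @return integer obstacle mask with `res`/`box` attributes.
#' @export
rasterize_obstacles <- function(obstacles, box, res = 1e-3) {
  n <- max(1L, round(box / res))
  m <- matrix(0L, n, n)
  py <- (seq_len(n) - 0.5) * (box / n)
  for (ob in obstacles) {
    v <- ob$vertices
    if (is.null(v) || nrow(v) < 3) next
    xs <- v[, 1]; ys <- v[, 2]
    jr <- which(py >= min(ys) & py <= max(ys))
    for (j in jr) {
      yy <- py[j]
      x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
      cross <- which((ys <= yy & y2 > yy) | (y2 <= yy & ys > yy))
      if (!length(cross)) next
      xc <- xs[cross] + (yy - ys[cross]) / (y2[cross] - ys[cross]) *
        (x2[cross] - xs[cross])
      xc <- sort(xc)
      for (k in seq(1, length(xc) - 1, by = 2)) {
        i0 <- ceiling(xc[k] / (box / n) + 0.5)
        i1 <- floor(xc[k + 1] / (box / n) + 0.5)
        i0 <- max(1L, i0); i1 <- min(n, i1)
        if (i0 <= i1) m[i0:i1, j] <- 1L
      }
    }
  }
  attr(m, "res") <- box / n
  attr(m, "box") <- box
  m
}

#' Inaccessible area fraction as a function of vesicle radius
#'
#' Evaluates [inaccessible_region()] for each radius; when several slice
#' heights are given the curves are averaged over the slices (the same
#' stack averaging the per-domain effective tensors use).  The curve is
#' sigmoid-like and nondecreasing in R, steeper for denser networks.
#'
#' @param net an `actin_network`.
#' @param z slice height(s) in um.
#' @param radii ascending vesicle radii in um.
#' @param res raster resolution in um.
#' @param periodic periodic wrap.
#' @return object of class `phi_curve` with `radii`, `phi` (union
#'   fraction) and `phi_reported` (summed-component convention).
#' @export
phi_of_radius <- function(net, z, radii, res = 1e-3, periodic = TRUE) {
  stopifnot(!is.unsorted(radii))
  phi <- rep(0, length(radii))
  rep_off <- 0
  for (zz in z) {
    obst <- obstacle_mask(net, zz, res = res, periodic = periodic)
    obst_sum <- mean(obstacle_mask(net, zz, res = res,
                                   periodic = periodic, counts = TRUE))
    phi <- phi + vapply(radii, function(R)
      mean(.open_blocked(obst, R, attr(obst, "res"), periodic)),
      numeric(1)) / length(z)
    rep_off <- rep_off + (obst_sum - mean(obst)) / length(z)
  }
  structure(list(radii = radii, phi = phi,
                 phi_reported = phi + rep_off,
                 slice_z = z,
                 seed = net$seed,
                 density = if (!is.null(net$spec))
                   net$spec$filaments_per_um3 else NA),
            class = "phi_curve")
}

#' @export
print.phi_curve <- function(x, ...) {
  cat(sprintf("phi(R) curve (%d slice(s), %d radii)\n",
              length(x$slice_z), length(x$radii)))
  print(data.frame(R_um = x$radii, phi = round(x$phi, 4)), row.names = FALSE)
  invisible(x)
}

#' Smallest vesicle diameter at which a slice becomes impassable
#'
#' Finds the first vesicle radius at which the inaccessible area fraction
#' reaches the critical fraction `phi_c` (linear interpolation between
#' evaluated radii) and returns the corresponding diameter `2R`.  By
#' default the curve's `phi_reported` values are used, since `phi_c`
#' normally comes from a power-law calibration expressed in that
#' convention.
#'
#' @param curve a `phi_curve`.
#' @param phi_c critical inaccessible area fraction.
#' @param convention `"reported"` (summed-component, default) or
#'   `"union"`.
#' @return diameter in um (`NA` if the curve never reaches `phi_c`).
#' @export
max_passable_diameter <- function(curve, phi_c,
                                  convention = c("reported", "union")) {
  stopifnot(inherits(curve, "phi_curve"))
  convention <- match.arg(convention)
  ph <- if (convention == "reported" && !is.null(curve$phi_reported))
    curve$phi_reported else curve$phi
  R <- curve$radii
  k <- which(ph >= phi_c)
  if (!length(k)) return(NA_real_)
  k <- k[1]
  if (k == 1) return(2 * R[1])
  t <- (phi_c - ph[k - 1]) / (ph[k] - ph[k - 1])
  2 * (R[k - 1] + t * (R[k] - R[k - 1]))
}

#' Stack-averaged inaccessible volume fraction
#'
#' Slices the network at `n_slices` evenly spaced heights, computes the
#' per-slice inaccessible area fraction and aggregates trapezoidally over
#' z (equivalent to averaging neighboring slices and multiplying by the
#' slice distance).
#'
#' @param net an `actin_network`.
#' @param R vesicle radius in um.
#' @param n_slices number of slices (default 100).
#' @param res raster resolution in um.
#' @return inaccessible volume fraction.
#' @export
stack_inaccessible_volume <- function(net, R, n_slices = 100, res = 1e-3) {
  stopifnot(n_slices >= 2)
  zs <- seq(0, net$box_edge, length.out = n_slices)
  ph <- vapply(zs, function(z)
    inaccessible_region(net, R, z = z, res = res)$phi, numeric(1))
  w <- rep(1, n_slices); w[c(1, n_slices)] <- 0.5
  sum(w * ph) / (n_slices - 1)
}

#' Write a blocked geometry to plain-text files
#'
#' Writes a CSV row `(z, R, phi)` and, optionally, the blocked mask as a
#' 0/1 CSV grid for inspection.
#'
#' @param bg a `blocked_geometry`.
#' @param path CSV path for the summary row.
#' @param mask_path optional CSV path for the full blocked mask.
#' @return `path`, invisibly.
#' @export
write_blocked_geometry <- function(bg, path, mask_path = NULL) {
  write.csv(data.frame(z = bg$slice_z %||% NA, R = bg$R, phi = bg$phi),
            path, row.names = FALSE)
  if (!is.null(mask_path))
    write.table(bg$blocked, mask_path, row.names = FALSE,
                col.names = FALSE, sep = ",")
  invisible(path)
}
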