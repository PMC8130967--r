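# Macroscopic actin-density field over a cell domain, represented as a
# 2D Gaussian mixture p(x) = sum_k b_k N(x | mu_k, Sigma_k).  The mixture
# is either fitted to a nonnegative raster (pixel-mass-weighted EM) or
# generated synthetically.  Filament number densities are obtained by
# anchoring the *unperturbed* field maximum to 1430 filaments/um^3, so
# perturbed fields can exceed the anchor.

#' Construct a Gaussian-mixture density field
#'
#' @param weights mixing coefficients `b_k` (sum to 1 for a fitted,
#'   unperturbed field; perturbations deliberately break the
#'   normalization to rescale the total amount).
#' @param means `K x 2` matrix of component means (um).
#' @param covs `2 x 2 x K` array of SPD covariance matrices (um^2).
#' @param cell_polygon closed cell boundary, `m x 2` matrix (um).
#' @param peak_density filament number density assigned to the field
#'   maximum of the unperturbed reference (count/um^3).
#' @param ref_peak maximum of p(x) over the cell of the unperturbed
#'   reference field; computed on a grid when `NULL`.
#' @return object of class `gmm_density`.
#' @export
gmm_density <- function(weights, means, covs, cell_polygon,
                        peak_density = 1430, ref_peak = NULL) {
  K <- length(weights)
  means <- matrix(means, K, 2)
  stopifnot(dim(covs)[3] == K, all(weights >= 0))
  for (k in seq_len(K)) {
    S <- covs[, , k]
    stopifnot(isTRUE(all.equal(S, t(S), tolerance = 1e-8)),
              det(S) > 0, S[1, 1] > 0)
  }
  g <- structure(list(weights = as.numeric(weights), means = means,
                      covs = covs, cell_polygon = cell_polygon,
                      peak_density = peak_density, ref_peak = ref_peak),
                 class = "gmm_density")
  if (is.null(g$ref_peak)) g$ref_peak <- .gmm_peak(g)
  g
}

# bivariate normal densities of all components at points xy (n x 2)
.gmm_comp_dens <- function(g, xy) {
  n <- nrow(xy)
  K <- length(g$weights)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    S <- g$covs[, , k]
    dt <- S[1, 1] * S[2, 2] - S[1, 2]^2
    inv <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2, 2) / dt
    dx <- xy[, 1] - g$means[k, 1]
    dy <- xy[, 2] - g$means[k, 2]
    q <- inv[1, 1] * dx^2 + 2 * inv[1, 2] * dx * dy + inv[2, 2] * dy^2
    out[, k] <- exp(-q / 2) / (2 * pi * sqrt(dt))
  }
  out
}

#' Evaluate a Gaussian-mixture density field
#'
#' @param g a `gmm_density`.
#' @param xy `n x 2` matrix (or length-2 vector) of points in um.
#' @return vector of density values `p(x)` (1/um^2 weight units).
#' @export
gmm_value <- function(g, xy) {
  xy <- matrix(xy, ncol = 2)
  as.numeric(.gmm_comp_dens(g, xy) %*% g$weights)
}

# grid maximum of p over the cell polygon
.gmm_peak <- function(g, n_grid = 201) {
  rng_x <- range(g$cell_polygon[, 1]); rng_y <- range(g$cell_polygon[, 2])
  gx <- seq(rng_x[1], rng_x[2], length.out = n_grid)
  gy <- seq(rng_y[1], rng_y[2], length.out = n_grid)
  pts <- cbind(rep(gx, n_grid), rep(gy, each = n_grid))
  inside <- point_in_polygon(pts, g$cell_polygon)
  if (!any(inside)) return(max(gmm_value(g, pts)))
  max(gmm_value(g, pts[inside, , drop = FALSE]))
}

#' Even-odd point-in-polygon test
#'
#' @param pts `n x 2` matrix of points.
#' @param poly `m x 2` polygon vertex matrix (closed implicitly).
#' @return logical vector.
#' @export
point_in_polygon <- function(pts, poly) {
  pts <- matrix(pts, ncol = 2)
  x <- pts[, 1]; y <- pts[, 2]
  xs <- poly[, 1]; ys <- poly[, 2]
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  inside <- rep(FALSE, nrow(pts))
  for (e in seq_along(xs)) {
    crosses <- (ys[e] <= y & y2[e] > y) | (y2[e] <= y & ys[e] > y)
    if (!any(crosses)) next
    xc <- xs[e] + (y[crosses] - ys[e]) / (y2[e] - ys[e]) * (x2[e] - xs[e])
    inside[crosses] <- xor(inside[crosses], x[crosses] < xc)
  }
  inside
}

#' @export
print.gmm_density <- function(x, ...) {
  cat(sprintf("Gaussian-mixture actin density: %d components\n",
              length(x$weights)))
  cat(sprintf("  total weight %.4f, reference peak %.4g, anchor %g fil/um^3\n",
              sum(x$weights), x$ref_peak, x$peak_density))
  invisible(x)
}

#' Perturb a density field by scaling weights and covariances
#'
#' `b_k -> b_scale * b_k` (weights deliberately not renormalized:
#' `b_scale` rescales the total filament amount) and
#' `Sigma_k -> sigma_scale * Sigma_k` (larger spread lowers the peaks).
#' The amplitude anchor (`ref_peak` of the unperturbed reference) is kept,
#' so perturbed fields may map to more than `peak_density` filaments.
#'
#' @param g a `gmm_density`.
#' @param b_scale positive weight factor.
#' @param sigma_scale positive covariance factor.
#' @return a new `gmm_density`.
#' @export
perturb_gmm <- function(g, b_scale = 1, sigma_scale = 1) {
  stopifnot(b_scale > 0, sigma_scale > 0)
  g$weights <- g$weights * b_scale
  g$covs <- g$covs * sigma_scale
  g
}

#' Local network specification from the macroscopic density field
#'
#' Maps the density value at a point to a filament number density by
#' `peak_density * p(x) / ref_peak`, where `ref_peak` is the field
#' maximum of the unperturbed reference.
#'
#' @param g a `gmm_density`.
#' @param x length-2 position (um), inside the cell polygon.
#' @param ... further arguments passed to [network_spec()] (e.g. `seed`).
#' @return a `network_spec`.
#' @export
density_to_spec <- function(g, x, ...) {
  x <- as.numeric(x)
  if (!point_in_polygon(matrix(x, 1), g$cell_polygon))
    stop("point lies outside the cell polygon")
  dens <- g$peak_density * gmm_value(g, x) / g$ref_peak
  network_spec(filaments_per_um3 = dens, ...)
}

#' Density raster container
#'
#' @param values nonnegative matrix (x along rows, y along columns).
#' @param spacing pixel size in um.
#' @param origin lower-left corner (um).
#' @return object of class `density_raster`.
#' @export
density_raster <- function(values, spacing, origin = c(0, 0)) {
  stopifnot(all(values >= 0), spacing > 0)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "density_raster")
}

#' Render a Gaussian-mixture field to a raster
#'
#' @param g a `gmm_density`.
#' @param spacing pixel size in um.
#' @param bbox optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   cell-polygon bounding box.
#' @return a [density_raster()].
#' @export
raster_from_gmm <- function(g, spacing = 0.5, bbox = NULL) {
  if (is.null(bbox))
    bbox <- c(range(g$cell_polygon[, 1]), range(g$cell_polygon[, 2]))
  gx <- seq(bbox[1] + spacing / 2, bbox[2], by = spacing)
  gy <- seq(bbox[3] + spacing / 2, bbox[4], by = spacing)
  vals <- matrix(gmm_value(g, cbind(rep(gx, length(gy)),
                                    rep(gy, each = length(gx)))),
                 length(gx), length(gy))
  density_raster(vals, spacing, origin = c(bbox[1], bbox[3]))
}

# k-means++ style seeding on weighted pixels
.kmeanspp <- function(xy, w, K) {
  n <- nrow(xy)
  centers <- matrix(0, K, 2)
  centers[1, ] <- xy[sample.int(n, 1, prob = w), ]
  if (K > 1) for (k in 2:K) {
    d2 <- rep(Inf, n)
    for (j in 1:(k - 1))
      d2 <- pmin(d2, (xy[, 1] - centers[j, 1])^2 +
                     (xy[, 2] - centers[j, 2])^2)
    p <- w * d2
    if (sum(p) <= 0) p <- w
    centers[k, ] <- xy[sample.int(n, 1, prob = p), ]
  }
  centers
}

#' Fit a Gaussian mixture to a density raster by weighted EM
#'
#' The raster is interpreted as a weighted sample (pixel centers weighted
#' by intensity mass).  Expectation-maximization with k-means++
#' initialization and multiple restarts maximizes the weighted
#' log-likelihood; iteration stops when the relative change falls below
#' `tol`.  The coefficient of determination between the fitted density
#' and the normalized raster on the pixel grid is reported.
#'
#' @param raster a [density_raster()] (normalized internally to unit
#'   mass).
#' @param K number of components.
#' @param tol relative log-likelihood convergence threshold.
#' @param max_iter iteration cap per restart.
#' @param restarts number of k-means++ restarts (best likelihood kept).
#' @param cell_polygon optional polygon stored with the result; defaults
#'   to the raster bounding box.
#' @param seed integer seed for the initialization draws.
#' @return a `gmm_density` with attributes `r_squared` and `loglik`
#'   (per-iteration trace of the kept restart).
#' @export
fit_gmm <- function(raster, K, tol = 1e-7, max_iter = 500, restarts = 3,
                    cell_polygon = NULL, seed = 1L) {
  stopifnot(inherits(raster, "density_raster"), K >= 1)
  v <- raster$values
  nx <- nrow(v); ny <- ncol(v)
  gx <- raster$origin[1] + (seq_len(nx) - 0.5) * raster$spacing
  gy <- raster$origin[2] + (seq_len(ny) - 0.5) * raster$spacing
  xy <- cbind(rep(gx, ny), rep(gy, each = nx))
  w <- as.vector(v)
  keep <- w > 0
  xy <- xy[keep, , drop = FALSE]
  w <- w[keep] / sum(w[keep])
  if (K > sum(keep)) stop("K exceeds the number of informative pixels")
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_seed(split_seed(seed, 7L, r), .kmeanspp(xy, w, K))
    em <- .em_weighted(xy, w, init, tol, max_iter,
                       var0 = raster$spacing^2)
    if (is.null(best) || em$loglik[length(em$loglik)] >
        best$loglik[length(best$loglik)]) best <- em
  }
  if (is.null(cell_polygon)) {
    bb <- c(range(gx) + c(-1, 1) * raster$spacing / 2,
            range(gy) + c(-1, 1) * raster$spacing / 2)
    cell_polygon <- cbind(bb[c(1, 2, 2, 1)], bb[c(3, 3, 4, 4)])
  }
  g <- gmm_density(best$weights, best$means, best$covs, cell_polygon)
  # R^2 of fitted density vs the normalized raster (density per um^2)
  dens_raster <- as.vector(v) / (sum(v) * raster$spacing^2)
  pts <- cbind(rep(gx, ny), rep(gy, each = nx))
  fit_vals <- gmm_value(g, pts)
  ss_res <- sum((dens_raster - fit_vals)^2)
  ss_tot <- sum((dens_raster - mean(dens_raster))^2)
  attr(g, "r_squared") <- 1 - ss_res / ss_tot
  attr(g, "loglik") <- best$loglik
  attr(g, "converged") <- best$converged
  g
}

# weighted EM core; w sums to 1
.em_weighted <- function(xy, w, centers, tol, max_iter, var0) {
  K <- nrow(centers)
  n <- nrow(xy)
  means <- centers
  covs <- array(0, c(2, 2, K))
  v_init <- max(var0, stats::var(xy[, 1]) / max(1, K))
  for (k in seq_len(K)) covs[, , k] <- diag(2) * v_init
  weights <- rep(1 / K, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- list(weights = weights, means = means, covs = covs)
    dens <- .gmm_comp_dens(g, xy)                     # n x K
    mix <- sweep(dens, 2, weights, `*`)
    tot <- rowSums(mix)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(w * log(tot))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <=
        tol * abs(ll_trace[it - 1])) { converged <- TRUE; break }
    resp <- mix / tot                                 # n x K
    for (k in seq_len(K)) {
      rk <- resp[, k] * w
      Nk <- sum(rk)
      if (Nk < 1e-12) {                               # dead component
        means[k, ] <- xy[which.max(w), ]
        covs[, , k] <- diag(2) * v_init
        weights[k] <- 1e-8
        next
      }
      weights[k] <- Nk
      means[k, ] <- colSums(xy * rk) / Nk
      dx <- xy[, 1] - means[k, 1]; dy <- xy[, 2] - means[k, 2]
      S <- matrix(c(sum(rk * dx^2), sum(rk * dx * dy),
                    sum(rk * dx * dy), sum(rk * dy^2)), 2, 2) / Nk
      covs[, , k] <- S + diag(2) * var0 / 12          # pixel-size floor
    }
    weights <- weights / sum(weights)
  }
  list(weights = weights, means = means, covs = covs,
       loglik = ll_trace, converged = converged)
}

#' Synthesize a whole-cell actin density map
#'
#' Stand-in for an experimentally derived density field (the original
#' confocal raster is not shipped): a smoothed-ellipse cell polygon
#' (default ~45 um across) with mixture components placed with a
#' cortical bias (means biased towards the boundary, as cortical actin
#' is) and random SPD covariances.  Fully reproducible from the seed.
#'
#' @param n_components number of Gaussian components.
#' @param diameter nominal cell diameter in um.
#' @param aspect ratio of minor to major axis.
#' @param seed integer seed.
#' @param cov_range eigenvalue range of component covariances (um^2).
#' @return a `gmm_density` (weights sum to 1).
#' @export
synth_cell_map <- function(n_components = 25, diameter = 45,
                           aspect = 0.8, seed = 1L,
                           cov_range = c(3, 25)) {
  stopifnot(n_components >= 1)
  with_seed(split_seed(seed, 11L), {
    a <- diameter / 2; b <- a * aspect
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    wob <- 1 + 0.06 * sin(3 * th + runif(1, 0, 2 * pi)) +
      0.04 * sin(5 * th + runif(1, 0, 2 * pi))
    poly <- cbind(a + a * wob * cos(th), b + b * wob * sin(th))
    # cortical bias: radial fraction Beta-like towards the boundary
    rf <- sqrt(stats::rbeta(n_components, 4, 1.6))
    ang <- runif(n_components, 0, 2 * pi)
    means <- cbind(a + 0.92 * a * rf * cos(ang),
                   b + 0.92 * b * rf * sin(ang))
    covs <- array(0, c(2, 2, n_components))
    for (k in seq_len(n_components)) {
      ev <- runif(2, cov_range[1], cov_range[2])
      rot <- runif(1, 0, pi)
      Q <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
      covs[, , k] <- Q %*% diag(ev) %*% t(Q)
    }
    wts <- runif(n_components, 0.3, 1)
    wts <- wts / sum(wts)
    gmm_density(wts, means, covs, poly)
  })
}

#' Write / read GMM parameters as JSON
#' @param g a `gmm_density`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_gmm` returns a `gmm_density`.
#' @export
write_gmm <- function(g, path) {
  obj <- list(weights = g$weights, means = g$means,
              covs = t(apply(g$covs, 3, as.vector)),  # one row per component
              cell_polygon = g$cell_polygon,
              peak_density = g$peak_density, ref_peak = g$ref_peak)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- length(obj$weights)
  covs <- array(0, c(2, 2, K))
  cv <- matrix(unlist(obj$covs), nrow = K, byrow = is.list(obj$covs))
  for (k in seq_len(K)) covs[, , k] <- matrix(cv[k, ], 2, 2)
  gmm_density(obj$weights, matrix(obj$means, K, 2), covs,
              matrix(obj$cell_polygon, ncol = 2),
              peak_density = obj$peak_density, ref_peak = obj$ref_peak)
}
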