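# Independent checks of the homogenization machinery: (i) Monte Carlo
# random walks of finite-size tracers amid the blocked geometry, giving
# an effective diffusivity from the mean squared displacement; (ii) a 1D
# steady-state diffusion problem with an oscillatory coefficient whose
# homogenized limit (harmonic mean) is known in closed form.

#' Effective diffusion tensor from Monte Carlo random walks
#'
#' Walkers start uniformly in the free space of a periodically tiled
#' blocked slice and take Gaussian steps; a step whose midpoint or
#' endpoint lands in the blocked region is rejected and resampled
#' (`rule = "reject"`, the default equilibrium-preserving rule) or
#' dropped in place (`rule = "bounce"`).  Unwrapped positions are
#' recorded at `n_rec` times; the tensor entries come from an affine
#' fit `<dx_i dx_j>(tau) = 2 D_ij tau + c` of the time-averaged mean
#' squared displacement over lag times in the asymptotic window
#' `[0.2, 0.6] x total_time` (short lags are excluded, and the
#' intercept absorbs the constant excess left by the crossover from
#' free to obstructed diffusion).  Standard errors come from a walker
#' bootstrap.
#'
#' @param blocked a `blocked_geometry` (periodic raster).
#' @param D_free free-space diffusivity in um^2/s.
#' @param n_walkers number of walkers.
#' @param total_time trajectory length in s; the default gives a free
#'   rms displacement of 1.5 box edges, so lag displacements in the
#'   fit window average over many obstacle correlation lengths.
#' @param step_dt time step in s; the default rms step of 0.7 nm is
#'   small against every obstacle feature and, together with the
#'   midpoint collision test, prevents tunnelling through thin blocked
#'   walls.
#' @param n_rec number of recorded position snapshots.
#' @param seed integer seed.
#' @param rule `"reject"` or `"bounce"`.
#' @param n_boot bootstrap replicates.
#' @return object of class `mc_diffusivity`: `D` (2 x 2 um^2/s), `se`
#'   (2 x 2), `msd` data frame (time-averaged, per lag), config.
#' @export
mc_effective_D <- function(blocked, D_free = 1, n_walkers = 300,
                           total_time = NULL, step_dt = NULL,
                           n_rec = 200, seed = 1L,
                           rule = c("reject", "bounce"), n_boot = 200) {
  rule <- match.arg(rule)
  stopifnot(inherits(blocked, "blocked_geometry"))
  if (mean(blocked$blocked) >= 1) stop("no free space to walk in")
  box <- blocked$box
  if (is.null(step_dt)) step_dt <- (0.7e-3)^2 / (4 * D_free)
  step_rms <- sqrt(4 * D_free * step_dt)
  if (step_rms > 2 * blocked$res)
    warning(sprintf(paste("rms step %.3g um is large relative to the",
                          "raster resolution %.3g um"),
                    step_rms, blocked$res))
  if (is.null(total_time))
    total_time <- (1.5 * box)^2 / (4 * D_free)
  n_steps <- max(n_rec, ceiling(total_time / step_dt))
  sigma <- sqrt(2 * D_free * step_dt)
  w <- cpp_mc_walk(blocked$blocked, box, as.integer(n_walkers),
                   as.integer(n_steps), sigma, as.integer(n_rec),
                   split_seed(seed, 41L), rule == "bounce")
  dt_rec <- w$step[1] * step_dt        # snapshots are evenly spaced
  lags <- unique(round(seq(0.2, 0.6, length.out = 24) * n_rec))
  lags <- lags[lags >= 1 & lags < n_rec]
  ta_msd <- function(dx, dy, lag) {
    i0 <- seq_len(n_rec - lag)
    ddx <- dx[, i0 + lag, drop = FALSE] - dx[, i0, drop = FALSE]
    ddy <- dy[, i0 + lag, drop = FALSE] - dy[, i0, drop = FALSE]
    c(mean(ddx^2), mean(ddy^2), mean(ddx * ddy))
  }
  # affine fit MSD(tau) = 2 D tau + c0: the crossover from free to
  # obstructed diffusion leaves a constant excess in the MSD, which an
  # origin-constrained fit would fold into the slope
  slope_affine <- function(t, y) {
    tc <- t - mean(t)
    sum(tc * (y - mean(y))) / sum(tc^2)
  }
  est_D <- function(dx, dy) {
    m <- t(vapply(lags, function(l) ta_msd(dx, dy, l), numeric(3)))
    tau <- lags * dt_rec
    c(slope_affine(tau, m[, 1]) / 2, slope_affine(tau, m[, 2]) / 2,
      slope_affine(tau, m[, 3]) / 2)
  }
  d <- est_D(w$dx, w$dy)
  D <- matrix(c(d[1], d[3], d[3], d[2]), 2, 2)
  msd_tab <- t(vapply(lags, function(l) ta_msd(w$dx, w$dy, l),
                      numeric(3)))
  msd <- data.frame(tau = lags * dt_rec, xx = msd_tab[, 1],
                    yy = msd_tab[, 2], xy = msd_tab[, 3])
  boot <- with_seed(split_seed(seed, 43L), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_walkers, replace = TRUE)
      est_D(w$dx[idx, , drop = FALSE], w$dy[idx, , drop = FALSE])
    }, numeric(3))
  })
  se <- apply(boot, 1, sd)
  structure(list(D = D,
                 se = matrix(c(se[1], se[3], se[3], se[2]), 2, 2),
                 msd = msd, D_free = D_free, step_dt = step_dt,
                 n_walkers = n_walkers, rule = rule,
                 total_time = n_steps * step_dt),
            class = "mc_diffusivity")
}

#' @export
print.mc_diffusivity <- function(x, ...) {
  cat(sprintf("Monte Carlo effective diffusivity (%d walkers, rule '%s')\n",
              x$n_walkers, x$rule))
  cat(sprintf("  D11 = %.4g +/- %.2g, D22 = %.4g +/- %.2g um^2/s\n",
              x$D[1, 1], x$se[1, 1], x$D[2, 2], x$se[2, 2]))
  invisible(x)
}

#' One-dimensional oscillatory-coefficient verification problem
#'
#' Solves `-(d(x/eps) u')' = 0` on `[0, 1]` with `u(0) = u_left`,
#' `u(1) = u_right` by P1 finite elements (coefficient evaluated at
#' element midpoints), and compares with the exact solution
#' `u(x) = u_left + (u_right - u_left) F(x)/F(1)`,
#' `F(x) = int_0^x ds/d(s/eps)`.  The homogenized coefficient is the
#' harmonic mean of `d` over one period.
#'
#' @param d_fun positive coefficient function of the fast variable
#'   `y = x/eps` (1-periodic).
#' @param eps period of the oscillation.
#' @param n_elem number of elements (a warning is issued when the mesh
#'   does not resolve the oscillation, `h > eps/10`).
#' @param u_left,u_right Dirichlet values.
#' @return object of class `oscillatory_1d`: nodes `x`, FEM solution
#'   `u_h`, exact `u_exact`, `l2_error`, `flux` (discrete, constant in
#'   exact arithmetic), `D_hom` (harmonic mean).
#' @export
solve_1d_oscillatory <- function(d_fun, eps, n_elem, u_left = 0,
                                 u_right = 1) {
  stopifnot(eps > 0, n_elem >= 2)
  h <- 1 / n_elem
  if (h > eps / 10)
    warning("mesh does not resolve the oscillation (h > eps/10)")
  x <- seq(0, 1, length.out = n_elem + 1)
  xm <- (x[-1] + x[-length(x)]) / 2
  d <- d_fun(xm / eps)
  stopifnot(all(d > 0))
  # tridiagonal stiffness, interior solve
  n_in <- n_elem - 1
  main <- (d[-n_elem] + d[-1]) / h
  off <- -d[2:n_elem] / h
  A <- Matrix::bandSparse(n_in, k = c(-1, 0, 1),
                          diagonals = list(off[-n_in], main, off[-n_in]),
                          symmetric = FALSE)
  b <- numeric(n_in)
  b[1] <- d[1] / h * u_left
  b[n_in] <- d[n_elem] / h * u_right
  u <- c(u_left, as.numeric(Matrix::solve(A, b)), u_right)
  # exact solution by composite-midpoint quadrature of 1/d at fine scale
  nq <- max(2e4, n_elem * 20)
  xq <- (seq_len(nq) - 0.5) / nq
  invd <- 1 / d_fun(xq / eps)
  Fq <- (cumsum(invd) - invd / 2) / nq   # F at the quadrature midpoints
  Ftot <- sum(invd) / nq
  u_exact_fun <- function(xx)
    u_left + (u_right - u_left) *
      stats::approx(c(0, xq, 1), c(0, Fq, Ftot), xout = xx)$y / Ftot
  u_exact <- u_exact_fun(x)
  # L2 error by midpoint rule on elements
  um_h <- (u[-1] + u[-length(u)]) / 2
  l2 <- sqrt(sum((um_h - u_exact_fun(xm))^2) * h)
  flux <- d * diff(u) / h
  # harmonic mean over one period
  yq <- (seq_len(2e4) - 0.5) / 2e4
  D_hom <- 1 / mean(1 / d_fun(yq))
  structure(list(x = x, u_h = u, u_exact = u_exact, l2_error = l2,
                 flux = flux, D_hom = D_hom, eps = eps, h = h),
            class = "oscillatory_1d")
}

#' @export
print.oscillatory_1d <- function(x, ...) {
  cat(sprintf("1D oscillatory verification (eps = %g, h = %g)\n",
              x$eps, x$h))
  cat(sprintf("  L2 error vs analytic: %.3e; homogenized coefficient %.6g\n",
              x$l2_error, x$D_hom))
  invisible(x)
}
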