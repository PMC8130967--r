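# Homogenized whole-cell transport: P1 Galerkin FEM in space, backward
# Euler in time, on a 2D cell polygon whose per-element diffusivity comes
# from the inaccessible-area-fraction field through the power law.

#' Triangulate a cell polygon
#'
#' Structured grid triangulation restricted to the polygon (triangles
#' kept when their centroid is inside), with boundary nodes projected
#' onto the polygon boundary so that the discrete domain tracks the cell
#' outline.  The grid step is chosen so that no element edge exceeds `H`.
#'
#' @param polygon closed cell boundary, `m x 2` matrix (um).
#' @param H maximum element edge length in um (default 1).
#' @return object of class `macro_mesh`: `nodes`, `tri`,
#'   `boundary_nodes`, element `area`, gradients and centroids.
#' @export
mesh_cell_polygon <- function(polygon, H = 1) {
  stopifnot(H > 0)
  a <- H / sqrt(2)                        # grid step; diagonal = H
  bb <- c(range(polygon[, 1]), range(polygon[, 2]))
  gx <- seq(bb[1] - a, bb[2] + a, by = a)
  gy <- seq(bb[3] - a, bb[4] + a, by = a)
  np_x <- length(gx); np_y <- length(gy)
  nodes <- cbind(rep(gx, np_y), rep(gy, each = np_x))
  id <- function(i, j) (j - 1L) * np_x + i
  ci <- rep(seq_len(np_x - 1), np_y - 1)
  cj <- rep(seq_len(np_y - 1), each = np_x - 1)
  aa <- id(ci, cj); bbb <- id(ci + 1L, cj)
  cc <- id(ci + 1L, cj + 1L); dd <- id(ci, cj + 1L)
  tri <- rbind(cbind(aa, bbb, cc), cbind(aa, cc, dd))
  cx <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  cy <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  keep <- point_in_polygon(cbind(cx, cy), polygon)
  tri <- tri[keep, , drop = FALSE]
  if (nrow(tri) == 0) stop("polygon too small for the requested H")
  # boundary edges: edges used by exactly one kept triangle
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  bnd_edge <- ed[key %in% names(which(table(key) == 1)), , drop = FALSE]
  bnd_nodes <- sort(unique(as.vector(bnd_edge)))
  # project boundary nodes onto the polygon outline (skip if the move
  # would invert an incident triangle)
  proj <- .project_to_polygon(nodes[bnd_nodes, , drop = FALSE], polygon)
  tri_area <- function(nd) {
    abs((nd[tri[, 2], 1] - nd[tri[, 1], 1]) *
          (nd[tri[, 3], 2] - nd[tri[, 1], 2]) -
          (nd[tri[, 3], 1] - nd[tri[, 1], 1]) *
          (nd[tri[, 2], 2] - nd[tri[, 1], 2])) / 2
  }
  min_area <- 1e-3 * a^2
  for (k in seq_along(bnd_nodes)) {
    nd_try <- nodes
    nd_try[bnd_nodes[k], ] <- proj[k, ]
    inc <- which(tri[, 1] == bnd_nodes[k] | tri[, 2] == bnd_nodes[k] |
                   tri[, 3] == bnd_nodes[k])
    if (all(tri_area(nd_try)[inc] > min_area))
      nodes[bnd_nodes[k], ] <- proj[k, ]
  }
  # compact node numbering
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)
  bnd_nodes <- remap[bnd_nodes]
  bnd_edge <- matrix(remap[bnd_edge], ncol = 2)
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  structure(list(nodes = nodes, tri = tri,
                 boundary_nodes = bnd_nodes, boundary_edges = bnd_edge,
                 area = abs(det) / 2,
                 gx = cbind(y2 - y3, y3 - y1, y1 - y2) / det,
                 gy = cbind(x3 - x2, x1 - x3, x2 - x1) / det,
                 centroid = cbind((x1 + x2 + x3) / 3, (y1 + y2 + y3) / 3),
                 H = H, polygon = polygon),
            class = "macro_mesh")
}

.project_to_polygon <- function(pts, poly) {
  m <- nrow(poly)
  out <- pts
  for (i in seq_len(nrow(pts))) {
    best <- Inf; bp <- pts[i, ]
    for (e in seq_len(m)) {
      a <- poly[e, ]; b <- poly[if (e == m) 1 else e + 1, ]
      ab <- b - a
      t <- sum((pts[i, ] - a) * ab) / sum(ab^2)
      t <- min(1, max(0, t))
      q <- a + t * ab
      d2 <- sum((pts[i, ] - q)^2)
      if (d2 < best) { best <- d2; bp <- q }
    }
    out[i, ] <- bp
  }
  out
}

#' @export
print.macro_mesh <- function(x, ...) {
  cat(sprintf("Cell mesh: %d elements, %d nodes (H = %g um), %d boundary nodes\n",
              nrow(x$tri), nrow(x$nodes), x$H, length(x$boundary_nodes)))
  invisible(x)
}

#' Per-element inaccessible area fraction over a cell mesh
#'
#' For each macro element the local filament density is read from the
#' density field at the element centroid and turned into a phi value at
#' vesicle radius `R`.  `method = "direct"` generates one sampling
#' network per element (element-indexed child seeds) and computes phi on
#' a mid-box slice; `method = "lookup"` (default) tabulates the
#' density-to-phi response once (`lookup_levels` density levels x
#' `lookup_seeds` networks, monotone Hyman spline in between) and
#' interpolates, which keeps whole-cell runs fast.
#'
#' @param g a `gmm_density`.
#' @param R vesicle radius in um.
#' @param mesh a `macro_mesh`.
#' @param seed integer root seed.
#' @param method `"lookup"` or `"direct"`.
#' @param res slice raster resolution in um.
#' @param lookup_levels,lookup_seeds lookup-table resolution.
#' @param spec_args extra arguments for [network_spec()].
#' @return numeric vector of per-element phi values, with the lookup
#'   table (if any) as attribute `lookup`.
#' @export
build_phi_field <- function(g, R, mesh, seed = 1L,
                            method = c("lookup", "direct"),
                            res = 1e-3, lookup_levels = 25,
                            lookup_seeds = 5, spec_args = list()) {
  method <- match.arg(method)
  dens <- g$peak_density * gmm_value(g, mesh$centroid) / g$ref_peak
  mk_spec <- function(d, s)
    do.call(network_spec,
            c(list(filaments_per_um3 = d, seed = s), spec_args))
  # phi in the summed-component reporting convention, matching the
  # units the power law is calibrated in
  phi_once <- function(d, s) {
    net <- generate_network(mk_spec(d, s))
    inaccessible_region(net, R, z = net$box_edge / 2,
                        res = res)$phi_reported
  }
  if (method == "direct") {
    phi <- vapply(seq_along(dens), function(e)
      phi_once(dens[e], split_seed(seed, 23L, e)), numeric(1))
    return(phi)
  }
  levels <- seq(0, max(dens), length.out = lookup_levels)
  tab <- vapply(seq_along(levels), function(i) {
    if (levels[i] <= 0) return(0)
    mean(vapply(seq_len(lookup_seeds), function(s)
      phi_once(levels[i], split_seed(seed, 29L, i, s)), numeric(1)))
  }, numeric(1))
  tab <- cummax(tab)   # pool violations: phi is monotone in density
  f <- splinefun(levels, tab, method = "hyman")
  phi <- pmax(0, f(dens))
  attr(phi, "lookup") <- data.frame(density = levels, phi = tab)
  phi
}

#' Homogenized transport problem on a cell mesh
#'
#' @param mesh a `macro_mesh`.
#' @param D0_elem per-element scalar diffusivity (um^2/s).
#' @param g_D Dirichlet concentration on the cell membrane, in `[0, 1]`
#'   (whole boundary Dirichlet unless `dirichlet_nodes` is given;
#'   remaining boundary is zero-flux Neumann).
#' @param u0 initial nodal concentration (scalar or vector).
#' @param f source density (scalar or per-element).
#' @param dt backward-Euler step in s.
#' @param t_end final time in s.
#' @param dirichlet_nodes node indices for the Dirichlet part of the
#'   boundary (default: all boundary nodes).
#' @return object of class `transport_problem`.
#' @export
transport_problem <- function(mesh, D0_elem, g_D = 1, u0 = 0, f = 0,
                              dt = 0.01, t_end = 30,
                              dirichlet_nodes = NULL) {
  stopifnot(inherits(mesh, "macro_mesh"), dt > 0, t_end >= dt,
            all(g_D >= 0), all(g_D <= 1),
            length(D0_elem) %in% c(1L, nrow(mesh$tri)))
  if (length(D0_elem) == 1) D0_elem <- rep(D0_elem, nrow(mesh$tri))
  if (is.null(dirichlet_nodes)) dirichlet_nodes <- mesh$boundary_nodes
  structure(list(mesh = mesh, D = D0_elem, g_D = g_D, u0 = u0, f = f,
                 dt = dt, t_end = t_end,
                 dirichlet_nodes = dirichlet_nodes),
            class = "transport_problem")
}

#' Solve the homogenized transport problem
#'
#' Backward Euler with a lumped mass matrix (the implicit step is
#' unconditionally stable and, for small enough dt, satisfies a discrete
#' maximum principle); Dirichlet values are imposed strongly.  The sparse
#' system matrix is factorized once and reused for every step.
#'
#' @param p a [transport_problem()].
#' @param probes optional `k x 2` matrix of probe points (um); the
#'   concentration there is recorded every step by P1 interpolation.
#' @param snapshot_every record a full nodal snapshot every this many
#'   steps (`Inf` = none, final state always kept).
#' @return object of class `concentration_series`: `times`, `probe`
#'   (matrix steps x k), `snapshots`, `u_final`, `mass` (total integral
#'   of u per step).
#' @export
solve_transport <- function(p, probes = NULL, snapshot_every = Inf) {
  mesh <- p$mesh
  nn <- nrow(mesh$nodes)
  nt <- nrow(mesh$tri)
  wa <- p$D * mesh$area
  ii <- jj <- vv <- vector("list", 9)
  k <- 0
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1
    ii[[k]] <- mesh$tri[, i]; jj[[k]] <- mesh$tri[, j]
    vv[[k]] <- wa * (mesh$gx[, i] * mesh$gx[, j] +
                       mesh$gy[, i] * mesh$gy[, j])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(vv), dims = c(nn, nn))
  # lumped mass
  Md <- numeric(nn)
  for (i in 1:3) {
    s <- rowsum(mesh$area / 3, mesh$tri[, i])
    Md[as.integer(rownames(s))] <- Md[as.integer(rownames(s))] + s
  }
  f_nodal <- numeric(nn)
  if (any(p$f != 0)) {
    fe <- if (length(p$f) == 1) rep(p$f, nt) else p$f
    for (i in 1:3) {
      s <- rowsum(fe * mesh$area / 3, mesh$tri[, i])
      f_nodal[as.integer(rownames(s))] <-
        f_nodal[as.integer(rownames(s))] + s
    }
  }
  dir <- p$dirichlet_nodes
  gD <- if (length(p$g_D) == 1) rep(p$g_D, length(dir)) else p$g_D
  A <- K + Matrix::Diagonal(nn, Md / p$dt)
  if (length(dir)) {       # strong Dirichlet rows
    A[dir, ] <- 0
    A[cbind(dir, dir)] <- 1
  }
  fac <- Matrix::lu(A)
  u <- rep(p$u0, length.out = nn)
  u[dir] <- gD
  n_steps <- ceiling(p$t_end / p$dt)
  times <- seq_len(n_steps) * p$dt
  probe_bary <- if (!is.null(probes)) .locate_points(mesh, probes) else NULL
  probe_vals <- if (!is.null(probes))
    matrix(NA_real_, n_steps + 1, nrow(probes)) else NULL
  if (!is.null(probes)) probe_vals[1, ] <- .interp_p1(u, probe_bary)
  snaps <- list()
  mass <- numeric(n_steps + 1)
  mass[1] <- sum(Md * u)
  for (s in seq_len(n_steps)) {
    rhs <- Md * u / p$dt + f_nodal
    rhs[dir] <- gD
    u <- as.numeric(Matrix::solve(fac, rhs))
    mass[s + 1] <- sum(Md * u)
    if (!is.null(probes)) probe_vals[s + 1, ] <- .interp_p1(u, probe_bary)
    if (is.finite(snapshot_every) && s %% snapshot_every == 0)
      snaps[[length(snaps) + 1]] <- list(t = times[s], u = u)
  }
  structure(list(times = c(0, times), probe = probe_vals,
                 snapshots = snaps, u_final = u, mass = mass,
                 mesh = mesh, dt = p$dt),
            class = "concentration_series")
}

# containing triangle + barycentric weights for each probe point
.locate_points <- function(mesh, pts) {
  pts <- matrix(pts, ncol = 2)
  out <- vector("list", nrow(pts))
  for (q in seq_len(nrow(pts))) {
    x <- pts[q, 1]; y <- pts[q, 2]
    best <- NULL; best_pen <- Inf
    for (t in seq_len(nrow(mesh$tri))) {
      v <- mesh$nodes[mesh$tri[t, ], , drop = FALSE]
      det <- (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
        (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])
      l1 <- ((v[2, 1] - x) * (v[3, 2] - y) -
               (v[3, 1] - x) * (v[2, 2] - y)) / det
      l2 <- ((v[3, 1] - x) * (v[1, 2] - y) -
               (v[1, 1] - x) * (v[3, 2] - y)) / det
      l3 <- 1 - l1 - l2
      pen <- -min(l1, l2, l3)
      if (pen < best_pen) {
        best_pen <- pen
        best <- list(nodes = mesh$tri[t, ], w = c(l1, l2, l3))
      }
      if (pen <= 0) break
    }
    out[[q]] <- best
  }
  out
}

.interp_p1 <- function(u, bary) {
  vapply(bary, function(b) sum(u[b$nodes] * b$w), numeric(1))
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("Concentration series: %d steps to t = %g s\n",
              length(x$times) - 1, max(x$times)))
  if (!is.null(x$probe))
    cat(sprintf("  %d probe(s); final value(s): %s\n", ncol(x$probe),
                paste(round(x$probe[nrow(x$probe), ], 4), collapse = ", ")))
  invisible(x)
}

#' Time at which a probe reaches a concentration level
#'
#' Linear interpolation in time between the bracketing backward-Euler
#' steps of the first up-crossing.
#'
#' @param s a `concentration_series` solved with probes.
#' @param level target concentration in `[0, 1]`.
#' @param probe probe column index.
#' @return time in s (`Inf` with a warning if the level is never
#'   reached).
#' @export
time_to_threshold <- function(s, level, probe = 1) {
  stopifnot(inherits(s, "concentration_series"), !is.null(s$probe))
  u <- s$probe[, probe]
  if (u[1] >= level) return(0)
  k <- which(u >= level)
  if (!length(k)) {
    warning("threshold never reached by t_end")
    return(Inf)
  }
  k <- k[1]
  t0 <- s$times[k - 1]; t1 <- s$times[k]
  t0 + (level - u[k - 1]) / (u[k] - u[k - 1]) * (t1 - t0)
}

#' First-order fine-scale correction of a homogenized solution
#'
#' Reconstructs the fine-scale field
#' `u_eps(x) = u0(x) - sum_j chi_j(x) du0/dx_j` on the nodes of a
#' sampling-domain mesh, with the corrector periodically extended and the
#' macroscopic gradient taken as constant over the sampling cell.
#'
#' @param u0_center homogenized concentration at the cell center.
#' @param macro_gradient length-2 gradient of `u0` there.
#' @param mesh the sampling-domain `micro_mesh`.
#' @param sol the matching `cell_solution`.
#' @return nodal vector of corrected fine-scale values (`NA` on nodes of
#'   the blocked region).
#' @export
local_correction <- function(u0_center, macro_gradient, mesh, sol) {
  g <- as.numeric(macro_gradient)
  stopifnot(length(g) == 2, inherits(sol, "cell_solution"))
  xc <- mesh$nodes[, 1] - mesh$delta / 2
  yc <- mesh$nodes[, 2] - mesh$delta / 2
  u0 <- u0_center + g[1] * xc + g[2] * yc
  u0 - sol$chi[, 1] * g[1] - sol$chi[, 2] * g[2]
}
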