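# Numerical homogenization of obstructed diffusion on a periodic sampling
# domain.  The perforated square [0, delta]^2 minus the vesicle-blocked
# region is triangulated; two periodic cell problems
#   -div(D grad chi_j) = -div(D e_j),  chi_j periodic, zero mean,
# are solved with P1 elements, and the effective tensor is the cell
# average of D (I - grad chi).

#' Triangulate a sampling domain with periodic node pairing
#'
#' Builds a structured crossed-diagonal triangulation of `[0, delta]^2`
#' (`n x n` cells, two right triangles each; minimum angle 45 degrees)
#' and removes triangles lying in the blocked region (majority vote of
#' the three vertices, three edge midpoints and the centroid against the
#' blocked raster).  Opposite boundary nodes are identified, so periodic
#' constraints reduce to shared degrees of freedom; the blocked raster
#' must itself be periodic (see [inaccessible_region()] with
#' `periodic = TRUE`).
#'
#' @param blocked a `blocked_geometry`, or `NULL` for an unperforated
#'   domain.
#' @param target_h target element edge length in um.
#' @param delta domain edge in um (taken from `blocked` when present).
#' @param D_micro free-space diffusivity in um^2/s.
#' @param formulation `"perforated"` removes blocked triangles (natural
#'   zero-flux hole boundaries); `"low_contrast"` keeps them with
#'   diffusivity `1e-6 * D_micro` (fallback for degenerate geometries).
#' @return object of class `micro_mesh`.
#' @export
mesh_sampling_domain <- function(blocked = NULL, target_h = 0.01,
                                 delta = NULL, D_micro = 1,
                                 formulation = c("perforated",
                                                 "low_contrast")) {
  formulation <- match.arg(formulation)
  if (!is.null(blocked)) {
    stopifnot(inherits(blocked, "blocked_geometry"))
    delta <- blocked$box
  }
  stopifnot(!is.null(delta), delta > 0, target_h > 0)
  n <- max(2L, round(delta / target_h))
  h <- delta / n
  np <- n + 1L
  ij <- expand.grid(i = 1:np, j = 1:np)
  nodes <- cbind((ij$i - 1) * h, (ij$j - 1) * h)
  id <- function(i, j) (j - 1L) * np + i
  ci <- rep(1:n, n); cj <- rep(1:n, each = n)
  a <- id(ci, cj); b <- id(ci + 1L, cj)
  cc <- id(ci + 1L, cj + 1L); d <- id(ci, cj + 1L)
  tri <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  # blocked-region test on sample points
  if (!is.null(blocked)) {
    msk <- blocked$blocked
    m <- nrow(msk); res <- blocked$res
    lookup <- function(x, y) {
      i <- pmin(m, pmax(1L, floor(x / res) + 1L))
      j <- pmin(m, pmax(1L, floor(y / res) + 1L))
      msk[cbind(i, j)]
    }
    v1 <- nodes[tri[, 1], , drop = FALSE]
    v2 <- nodes[tri[, 2], , drop = FALSE]
    v3 <- nodes[tri[, 3], , drop = FALSE]
    pts <- list(v1, v2, v3, (v1 + v2) / 2, (v2 + v3) / 2, (v1 + v3) / 2,
                (v1 + v2 + v3) / 3)
    votes <- Reduce(`+`, lapply(pts, function(p) lookup(p[, 1], p[, 2])))
    tri_blocked <- votes >= 4
  } else tri_blocked <- rep(FALSE, nrow(tri))
  if (formulation == "perforated") {
    keep <- !tri_blocked
    tri <- tri[keep, , drop = FALSE]
    Dt <- rep(D_micro, nrow(tri))
    if (nrow(tri) == 0) stop("fully blocked sampling domain")
  } else {
    Dt <- ifelse(tri_blocked, 1e-6 * D_micro, D_micro)
  }
  # periodic representative for each node
  ri <- ifelse(ij$i == np, 1L, ij$i)
  rj <- ifelse(ij$j == np, 1L, ij$j)
  rep_node <- id(ri, rj)
  mm <- .micro_mesh_finish(nodes, tri, Dt, rep_node, delta, h, n)
  mm$formulation <- formulation
  mm$D_micro <- D_micro
  mm$phi <- if (!is.null(blocked)) blocked$phi else 0
  mm$blocked_frac_mesh <- if (formulation == "perforated")
    1 - sum(mm$area) / delta^2 else mean(tri_blocked)
  mm
}

# shared mesh post-processing: P1 gradients, areas, DOF numbering
.micro_mesh_finish <- function(nodes, tri, Dt, rep_node, delta, h, n) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- abs(det) / 2
  gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  dof_of_node <- integer(nrow(nodes))
  used <- sort(unique(as.vector(rep_node[tri])))
  dof_of_node[used] <- seq_along(used)
  structure(list(nodes = nodes, tri = tri, D = Dt, area = area,
                 gx = gx, gy = gy, rep_node = rep_node,
                 dof_of_node = dof_of_node, n_dof = length(used),
                 delta = delta, h = h, n = n),
            class = "micro_mesh")
}

#' Unperforated sampling domain with a spatially varying coefficient
#'
#' Convenience constructor for verification problems (laminates,
#' two-phase media): same structured periodic mesh, with the scalar
#' diffusivity evaluated at element centroids.
#'
#' @param delta domain edge in um.
#' @param n cells per side.
#' @param D_fun `function(x, y)` returning the scalar diffusivity.
#' @return a `micro_mesh`.
#' @export
micro_mesh_coefficient <- function(delta, n, D_fun) {
  mm <- mesh_sampling_domain(NULL, target_h = delta / n, delta = delta)
  cx <- (mm$nodes[mm$tri[, 1], 1] + mm$nodes[mm$tri[, 2], 1] +
           mm$nodes[mm$tri[, 3], 1]) / 3
  cy <- (mm$nodes[mm$tri[, 1], 2] + mm$nodes[mm$tri[, 2], 2] +
           mm$nodes[mm$tri[, 3], 2]) / 3
  mm$D <- D_fun(cx, cy)
  stopifnot(all(mm$D > 0))
  mm$D_micro <- max(mm$D)
  mm
}

#' @export
print.micro_mesh <- function(x, ...) {
  cat(sprintf("Periodic sampling-domain mesh: %d elements, %d DOFs, h = %g um\n",
              nrow(x$tri), x$n_dof, x$h))
  if (!is.null(x$phi))
    cat(sprintf("  inaccessible fraction phi = %.4f (mesh-resolved %.4f)\n",
                x$phi, x$blocked_frac_mesh))
  invisible(x)
}

#' Solve the two periodic cell problems on a sampling domain
#'
#' Assembles the P1 stiffness matrix with periodic degree-of-freedom
#' identification, pins one node per connected free component (the
#' zero-mean condition is enforced afterwards by subtracting the
#' area-weighted mean, which leaves the gradients untouched) and solves
#' by sparse direct factorization.
#'
#' @param mesh a `micro_mesh`.
#' @return object of class `cell_solution`: nodal fields `chi` (two
#'   columns, one per coordinate direction, zero mean) and per-element
#'   gradient arrays `grad` (`n_tri x 2 x 2`, `grad[, k, j]` is
#'   d chi_j / d x_k).
#' @export
solve_cell_problems <- function(mesh) {
  stopifnot(inherits(mesh, "micro_mesh"))
  nt <- nrow(mesh$tri)
  dofs <- matrix(mesh$dof_of_node[mesh$rep_node[mesh$tri]], nt, 3)
  wa <- mesh$D * mesh$area
  # stiffness: K[di, dj] += D*A*(gx_i gx_j + gy_i gy_j)
  ii <- jj <- vv <- vector("list", 9)
  k <- 0
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1
    ii[[k]] <- dofs[, i]; jj[[k]] <- dofs[, j]
    vv[[k]] <- wa * (mesh$gx[, i] * mesh$gx[, j] +
                       mesh$gy[, i] * mesh$gy[, j])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = unlist(vv),
                            dims = c(mesh$n_dof, mesh$n_dof))
  # rhs_j[di] += D*A*grad(phi_i).e_j
  accum <- function(w) {
    out <- numeric(mesh$n_dof)
    s <- rowsum(w, as.vector(dofs))
    out[as.integer(rownames(s))] <- s
    out
  }
  b <- cbind(accum(rep(wa, 3) * as.vector(mesh$gx)),
             accum(rep(wa, 3) * as.vector(mesh$gy)))
  # connected components of the free mesh (periodic identification applied)
  ed <- rbind(dofs[, c(1, 2)], dofs[, c(2, 3)], dofs[, c(1, 3)])
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)$membership[seq_len(mesh$n_dof)]
  pin <- vapply(seq_len(max(comp)), function(cmp)
    which(comp == cmp)[1], integer(1))
  freeD <- setdiff(seq_len(mesh$n_dof), pin)
  chi_d <- matrix(0, mesh$n_dof, 2)
  Kff <- K[freeD, freeD, drop = FALSE]
  sol <- Matrix::solve(Kff, b[freeD, , drop = FALSE])
  chi_d[freeD, ] <- as.matrix(sol)
  # relative residual check
  res <- sqrt(colSums((as.matrix(K %*% chi_d) - b)^2)) /
    pmax(sqrt(colSums(b^2)), 1e-300)
  # per-element gradients
  grad <- array(0, c(nt, 2, 2))
  for (j in 1:2) {
    ch <- matrix(chi_d[cbind(as.vector(dofs), j)], nt, 3)
    grad[, 1, j] <- rowSums(mesh$gx * ch)
    grad[, 2, j] <- rowSums(mesh$gy * ch)
  }
  # zero mean over the free domain
  nodal_w <- rep(mesh$area / 3, 3)
  for (j in 1:2) {
    vals <- chi_d[cbind(as.vector(dofs), j)]
    mn <- sum(nodal_w * vals) / sum(mesh$area)
    chi_d[, j] <- chi_d[, j] - mn
  }
  chi_nodes <- matrix(NA_real_, nrow(mesh$nodes), 2)
  act <- mesh$dof_of_node[mesh$rep_node] > 0
  chi_nodes[act, ] <- chi_d[mesh$dof_of_node[mesh$rep_node[act]], ]
  structure(list(chi = chi_nodes, chi_dof = chi_d, grad = grad,
                 residual = res, n_components = max(comp)),
            class = "cell_solution")
}

#' Effective diffusion tensor from a cell solution
#'
#' One-point quadrature of the cell average
#' `D0_ij = 1/|K| sum_T |T| D_T (delta_ij - d chi_j / d x_i)`, output
#' symmetrized.  On a perforated domain the normalizer `|K|` is
#' ambiguous; by default the free (hole-excluded) area is used, which
#' is the convention the printed reference tensors follow (their low-phi
#' values sit marginally above `1 - phi`, which is impossible under the
#' hole-inclusive normalization, whose Voigt bound is `1 - phi`).
#' `normalizer = "full"` divides by the full cell area `delta^2`
#' instead; the two differ exactly by the factor `1 - phi_mesh`.  Both
#' vanish when the free space stops percolating.
#'
#' @param mesh a `micro_mesh`.
#' @param sol the matching `cell_solution`.
#' @param normalizer `"free"` (default) or `"full"`.
#' @return object of class `effective_tensor`: `D0` (2 x 2, um^2/s),
#'   `phi`, eigenvalues `lambda` (decreasing) and fractional anisotropy
#'   `FA`.
#' @export
effective_tensor <- function(mesh, sol, normalizer = c("free", "full")) {
  normalizer <- match.arg(normalizer)
  wa <- mesh$D * mesh$area
  vol <- if (normalizer == "full") mesh$delta^2 else sum(mesh$area)
  if (mesh$formulation %||% "perforated" == "low_contrast")
    vol <- mesh$delta^2
  D0 <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    D0[i, j] <- sum(wa * ((i == j) - sol$grad[, i, j])) / vol
  D0 <- (D0 + t(D0)) / 2
  ev <- sort(eigen(D0, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  structure(list(D0 = D0, phi = mesh$phi %||% NA, lambda = ev,
                 FA = fractional_anisotropy(D0),
                 trapped = ev[1] < 1e-6 * max(mesh$D),
                 n_elements = nrow(mesh$tri), n_dof = mesh$n_dof),
            class = "effective_tensor")
}

#' @export
print.effective_tensor <- function(x, ...) {
  cat("Effective diffusion tensor (um^2/s)\n")
  print(round(x$D0, 6))
  cat(sprintf("  phi = %s, FA = %.4f%s\n",
              format(x$phi), x$FA,
              if (isTRUE(x$trapped)) "  [trapped]" else ""))
  invisible(x)
}

#' Fractional anisotropy of a 2x2 diffusion tensor
#'
#' `FA = (lambda1 - lambda2) / sqrt(lambda1^2 + lambda2^2)` with
#' `lambda1 >= lambda2 >= 0`; 0 means isotropic diffusion.
#'
#' @param D symmetric positive semidefinite 2x2 matrix.
#' @return value in `[0, 1]`; `NaN` (with a warning) for the zero tensor.
#' @export
fractional_anisotropy <- function(D) {
  stopifnot(is.matrix(D), all(dim(D) == 2))
  stopifnot(isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
  ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  den <- sqrt(sum(ev^2))
  if (den == 0) {
    warning("zero tensor: fractional anisotropy undefined")
    return(NaN)
  }
  (ev[1] - ev[2]) / den
}

#' Hill-Mandel (macro-homogeneity) residual
#'
#' Relative mismatch between the macroscopic dissipation
#' `grad(u0) . D0 grad(u0)` and the cell average of the microscopic one,
#' with the micro gradient reconstructed as `(I - J^T) grad(u0)`,
#' `J_ij = d chi_i / d x_j`.  For periodic boundary conditions the two
#' agree to solver precision.
#'
#' @param mesh a `micro_mesh`.
#' @param sol the matching `cell_solution`.
#' @param macro_gradient length-2 macroscopic concentration gradient.
#' @return nonnegative relative residual.
#' @export
hill_mandel_residual <- function(mesh, sol, macro_gradient) {
  g <- as.numeric(macro_gradient)
  stopifnot(length(g) == 2)
  # both sides averaged over the full cell |K| = delta^2
  D0 <- effective_tensor(mesh, sol, normalizer = "full")$D0
  macro <- as.numeric(g %*% D0 %*% g)
  # micro gradient per element: (I - J^T) g, J[i,j] = d chi_i / d x_j
  # grad[, k, j] = d chi_j / d x_k, so (J^T)[k, j] = grad[, k, j]
  gx <- g[1] - (sol$grad[, 1, 1] * g[1] + sol$grad[, 1, 2] * g[2])
  gy <- g[2] - (sol$grad[, 2, 1] * g[1] + sol$grad[, 2, 2] * g[2])
  micro <- sum(mesh$D * mesh$area * (gx^2 + gy^2)) / mesh$delta^2
  abs(micro - macro) / max(abs(macro), 1e-300)
}

#' Homogenize one network slice end-to-end
#'
#' Convenience chain: rasterize the slice, compute the vesicle-blocked
#' region, mesh the free space, solve the cell problems and return the
#' effective tensor.
#'
#' @param net an `actin_network`.
#' @param z slice height in um.
#' @param R vesicle radius in um.
#' @param D_micro free diffusivity in um^2/s.
#' @param res raster resolution in um.
#' @param target_h micro mesh size in um.
#' @param normalizer passed to [effective_tensor()].
#' @return an `effective_tensor` (with the raster `phi` attached).
#' @export
homogenize_slice <- function(net, z, R, D_micro = 1, res = 1e-3,
                             target_h = 0.01,
                             normalizer = c("free", "full")) {
  bg <- inaccessible_region(net, R, z = z, res = res, periodic = TRUE)
  mesh <- mesh_sampling_domain(bg, target_h = target_h, D_micro = D_micro)
  sol <- solve_cell_problems(mesh)
  effective_tensor(mesh, sol, normalizer = match.arg(normalizer))
}
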