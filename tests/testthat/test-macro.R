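circle_polygon <- function(r = 20, n = 128)
  cbind(r + r * cos(seq(0, 2 * pi, length.out = n + 1)[-1]),
        r + r * sin(seq(0, 2 * pi, length.out = n + 1)[-1]))

# truncated Bessel series for u(center, t) on a disk with u0 = 0, g_D = 1
disk_center_series <- function(t, a, D, n_terms = 30) {
  zeros <- numeric(n_terms)
  lo <- 2
  for (n in seq_len(n_terms)) {
    zeros[n] <- stats::uniroot(function(x) besselJ(x, 0),
                               c(lo, lo + 3.5))$root
    lo <- zeros[n] + 2.6
  }
  1 - 2 * sum(exp(-D * zeros^2 * t / a^2) / (zeros * besselJ(zeros, 1)))
}

test_that("cell polygon meshing respects H and traces the boundary", {
  poly <- circle_polygon(20)
  mesh <- mesh_cell_polygon(poly, H = 1)
  # edges at most H in the interior; boundary projection may stretch
  # the outermost ring somewhat
  ed <- rbind(mesh$tri[, 1:2], mesh$tri[, 2:3], mesh$tri[, c(3, 1)])
  len <- sqrt(rowSums((mesh$nodes[ed[, 1], ] - mesh$nodes[ed[, 2], ])^2))
  expect_lt(stats::quantile(len, 0.9), 1 + 1e-9)
  expect_lt(max(len), 1.7)
  # area close to the disk area
  expect_equal(sum(mesh$area), pi * 400, tolerance = 0.01)
  # most boundary nodes lie on the polygon; the few skipped to protect
  # element quality stay within one grid step
  d <- cytodiffuse:::.project_to_polygon(
    mesh$nodes[mesh$boundary_nodes, ], poly)
  gap <- sqrt(rowSums((d - mesh$nodes[mesh$boundary_nodes, ])^2))
  expect_gt(mean(gap < 1e-8), 0.85)
  expect_lt(max(gap), 1)
  # element count parity with the reference discretization (~4074 at
  # H = 1 um for a cell of this scale)
  expect_gt(nrow(mesh$tri), 2000)
  expect_lt(nrow(mesh$tri), 6000)
})

test_that("steady state and maximum principle", {
  mesh <- mesh_cell_polygon(circle_polygon(10), H = 2)
  p <- transport_problem(mesh, D0_elem = 10, g_D = 1, u0 = 1, dt = 0.1,
                         t_end = 1)
  s <- solve_transport(p, probes = matrix(c(10, 10), 1))
  expect_equal(max(abs(s$u_final - 1)), 0, tolerance = 1e-12)
  p2 <- transport_problem(mesh, D0_elem = 10, g_D = 1, u0 = 0, dt = 0.05,
                          t_end = 2)
  s2 <- solve_transport(p2)
  expect_true(all(s2$u_final >= -1e-9 & s2$u_final <= 1 + 1e-9))
})

test_that("transport on a disk matches the radial Bessel series at probe times", {
  a <- 20; D <- 32.8
  mesh <- mesh_cell_polygon(circle_polygon(a, 256), H = 0.8)
  p <- transport_problem(mesh, D0_elem = D, g_D = 1, u0 = 0, dt = 0.005,
                         t_end = 4)
  s <- solve_transport(p, probes = matrix(c(a, a), 1))
  for (tt in c(1, 2, 4)) {
    u_fem <- s$probe[round(tt / 0.005) + 1, 1]
    u_ref <- disk_center_series(tt, a, D)
    expect_lt(abs(u_fem - u_ref), 0.01)   # 1% of the concentration scale
  }
})

test_that("mass is conserved without sources under zero-flux boundaries", {
  mesh <- mesh_cell_polygon(circle_polygon(8), H = 1.5)
  u0 <- with_seed(3, runif(nrow(mesh$nodes)))
  p <- transport_problem(mesh, D0_elem = 5, g_D = 0, u0 = u0, dt = 0.02,
                         t_end = 1, dirichlet_nodes = integer(0))
  s <- solve_transport(p)
  expect_lt(max(abs(s$mass / s$mass[1] - 1)), 1e-8)
})

test_that("time_to_threshold interpolates and respects ordering", {
  mesh <- mesh_cell_polygon(circle_polygon(10), H = 1.2)
  probe <- matrix(c(10, 10), 1)
  t90 <- vapply(c(30, 10), function(D) {
    p <- transport_problem(mesh, D0_elem = D, g_D = 1, u0 = 0, dt = 0.02,
                           t_end = 30)
    time_to_threshold(solve_transport(p, probes = probe), 0.9)
  }, numeric(1))
  # smaller diffusivity: strictly later arrival, roughly 3x here
  expect_gt(t90[2], t90[1])
  expect_equal(t90[2] / t90[1], 3, tolerance = 0.05)
  # level already attained at t = 0 gives 0
  p <- transport_problem(mesh, D0_elem = 30, g_D = 1, u0 = 0.95, dt = 0.1,
                         t_end = 1)
  s <- solve_transport(p, probes = probe)
  expect_equal(time_to_threshold(s, 0.9), 0)
  expect_warning(tt <- time_to_threshold(s, 2))
  expect_equal(tt, Inf)
})

test_that("halving dt changes the traveling time by less than 1%", {
  mesh <- mesh_cell_polygon(circle_polygon(10), H = 1.2)
  probe <- matrix(c(10, 10), 1)
  tts <- vapply(c(0.02, 0.01), function(dt) {
    p <- transport_problem(mesh, D0_elem = 20, g_D = 1, u0 = 0, dt = dt,
                           t_end = 20)
    time_to_threshold(solve_transport(p, probes = probe), 0.9)
  }, numeric(1))
  expect_lt(abs(tts[2] / tts[1] - 1), 0.01)
})

test_that("phi field construction: zero density, clustering and lookup consistency", {
  g <- synth_cell_map(n_components = 8, diameter = 24, seed = 6)
  mesh <- mesh_cell_polygon(g$cell_polygon, H = 3)
  # zero density everywhere -> phi identically 0
  g0 <- perturb_gmm(g, b_scale = 1e-12)
  phi0 <- build_phi_field(g0, 0.01, mesh, seed = 1, method = "direct",
                          res = 4e-3)
  expect_true(all(phi0 == 0))
  # lookup agrees with direct evaluation within a small absolute error
  phiL <- build_phi_field(g, 0.01, mesh, seed = 1, res = 2e-3,
                          lookup_levels = 8, lookup_seeds = 2)
  phiD <- build_phi_field(g, 0.01, mesh, seed = 1, method = "direct",
                          res = 2e-3)
  expect_lt(mean(abs(phiL - phiD)), 0.015)
  expect_lt(max(abs(phiL - phiD)), 0.05)
})

test_that("repeated realizations at uniform max density cluster tightly", {
  phis <- vapply(1:8, function(s) {
    net <- generate_network(network_spec(1430, seed = 100 + s))
    inaccessible_region(net, 0.01, z = 0.5, res = 2e-3)$phi
  }, numeric(1))
  expect_lt(sd(phis) / mean(phis), 0.15)
})

test_that("local correction reduces to u0 for vanishing correctors and has matching cell mean", {
  mesh <- mesh_sampling_domain(NULL, target_h = 0.05, delta = 1)
  sol <- solve_cell_problems(mesh)          # chi = 0 on empty cell
  u <- local_correction(0.7, c(0.2, -0.1), mesh, sol)
  xc <- mesh$nodes[, 1] - 0.5; yc <- mesh$nodes[, 2] - 0.5
  expect_equal(u, 0.7 + 0.2 * xc - 0.1 * yc, tolerance = 1e-10)
  # perforated cell: corrector has zero mean, so the cell average of the
  # corrected field matches the linear part's average
  m <- disk_mask(5, 0.08, res = 2e-3, box = 1, seed = 2)
  bg <- inaccessible_region(m, R = 0)
  mesh2 <- mesh_sampling_domain(bg, target_h = 0.02)
  sol2 <- solve_cell_problems(mesh2)
  u2 <- local_correction(0.5, c(1, 0), mesh2, sol2)
  dofs <- matrix(mesh2$rep_node[mesh2$tri], ncol = 3)
  w <- rep(mesh2$area / 3, 3)
  mean_u <- sum(w * u2[as.vector(mesh2$tri)]) / sum(mesh2$area)
  mean_lin <- sum(w * (0.5 + mesh2$nodes[as.vector(mesh2$tri), 1] - 0.5)) /
    sum(mesh2$area)
  expect_equal(mean_u, mean_lin, tolerance = 1e-8)
})
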