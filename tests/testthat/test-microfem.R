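test_that("unperforated periodic cell reproduces the free diffusivity exactly", {
  mesh <- mesh_sampling_domain(NULL, target_h = 0.05, delta = 1,
                               D_micro = 32.8)
  sol <- solve_cell_problems(mesh)
  expect_lt(max(abs(sol$chi), na.rm = TRUE), 1e-10)
  et <- effective_tensor(mesh, sol)
  expect_equal(et$D0, diag(2) * 32.8, tolerance = 1e-10)
  expect_equal(et$FA, 0, tolerance = 1e-9)
  expect_equal(hill_mandel_residual(mesh, sol, c(1, 0)), 0,
               tolerance = 1e-10)
})

test_that("laminate coefficient gives harmonic/arithmetic means in the two directions", {
  # d(x) piecewise {1, 10} in equal bands, independent of y
  d_fun <- function(x, y) ifelse(x %% 1 < 0.5, 1, 10)
  mesh <- micro_mesh_coefficient(1, 64, d_fun)
  sol <- solve_cell_problems(mesh)
  et <- effective_tensor(mesh, sol)
  expect_equal(et$D0[1, 1], 2 * 10 / 11, tolerance = 1e-6)   # harmonic
  expect_equal(et$D0[2, 2], 5.5, tolerance = 1e-6)           # arithmetic
  expect_lt(abs(et$D0[1, 2]), 1e-8)
  # chi for the direction parallel to the layers vanishes
  expect_lt(max(abs(sol$chi[, 2]), na.rm = TRUE), 1e-8)
})

test_that("single circular hole: mesh structure, symmetry, Maxwell value and Hill-Mandel", {
  n <- 400; px <- (seq_len(n) - 0.5) / n
  m <- matrix(as.integer(outer((px - 0.5)^2, (px - 0.5)^2, "+") <= 0.15^2),
              n, n)
  attr(m, "res") <- 1 / n; attr(m, "box") <- 1
  bg <- inaccessible_region(m, R = 0)
  mesh <- mesh_sampling_domain(bg, target_h = 0.01)
  expect_lt(abs(mesh$blocked_frac_mesh - bg$phi), 0.005)
  sol <- solve_cell_problems(mesh)
  et <- effective_tensor(mesh, sol, normalizer = "full")
  phi <- pi * 0.15^2
  # dilute periodic array of insulating disks: D ~ (1 - phi)/(1 + phi)
  expect_equal(mean(diag(et$D0)), (1 - phi) / (1 + phi), tolerance = 0.005)
  expect_lt(et$FA, 0.01)
  # free-area normalization is larger by 1/(1 - mesh-resolved fraction)
  etf <- effective_tensor(mesh, sol, normalizer = "free")
  expect_equal(mean(diag(etf$D0)),
               mean(diag(et$D0)) / (1 - mesh$blocked_frac_mesh),
               tolerance = 1e-10)
  # Hill-Mandel consistency at solver precision
  expect_lt(hill_mandel_residual(mesh, sol, c(1, 0)), 1e-8)
  expect_lt(hill_mandel_residual(mesh, sol, c(0.3, -0.7)), 1e-8)
  # antisymmetry of chi_1 under reflection through the hole center:
  # chi_1(1 - x, y) = -chi_1(x, y) up to the discretization (the fixed
  # cell diagonal breaks exact mirror symmetry at finite h)
  np <- mesh$n + 1
  chi1 <- matrix(sol$chi[, 1], np, np)
  flip <- chi1[np:1, ]
  ok <- !is.na(chi1) & !is.na(flip)
  expect_lt(max(abs(chi1[ok] + flip[ok])), 0.15 * max(abs(chi1), na.rm = TRUE))
})

test_that("effective tensor decreases with phi across a density sweep", {
  dens <- c(400, 1200, 2400, 3600)
  out <- t(vapply(seq_along(dens), function(i) {
    net <- generate_network(network_spec(dens[i], seed = 20 + i))
    et <- homogenize_slice(net, 0.5, R = 0.01, res = 2e-3, target_h = 0.01)
    c(phi = et$phi, tr = mean(diag(et$D0)))
  }, numeric(2)))
  expect_true(all(diff(out[, "phi"]) > 0))
  expect_true(all(diff(out[, "tr"]) < 0))
  expect_lt(stats::cor(out[, "phi"], out[, "tr"], method = "spearman"), 0)
})

test_that("fractional anisotropy formula", {
  expect_equal(fractional_anisotropy(diag(2)), 0)
  expect_equal(fractional_anisotropy(diag(c(1, 0))), 1)
  expect_equal(fractional_anisotropy(diag(c(2, 1))), 1 / sqrt(5),
               tolerance = 1e-12)
  expect_warning(fa0 <- fractional_anisotropy(matrix(0, 2, 2)))
  expect_true(is.nan(fa0))
})

test_that("tensors are symmetric PSD with eigenvalues below the Voigt bound", {
  net <- generate_network(network_spec(2000, seed = 31))
  et <- homogenize_slice(net, 0.5, R = 0.01, D_micro = 32.8, res = 2e-3,
                         target_h = 0.01)
  expect_equal(et$D0[1, 2], et$D0[2, 1])
  expect_true(all(et$lambda >= -1e-10))
  expect_lte(et$lambda[1], 32.8 * (1 - et$phi) / (1 - et$phi) + 1e-9)
  expect_lte(et$lambda[1], 32.8 + 1e-9)
  expect_true(et$FA >= 0 && et$FA <= 1)
})

test_that("Hill-Mandel residual decreases under mesh refinement on a perforated domain", {
  m <- disk_mask(6, 0.08, res = 2e-3, box = 1, seed = 5)
  bg <- inaccessible_region(m, R = 0)
  res <- vapply(c(0.05, 0.025, 0.0125), function(h) {
    mesh <- mesh_sampling_domain(bg, target_h = h)
    sol <- solve_cell_problems(mesh)
    hill_mandel_residual(mesh, sol, c(1, 1))
  }, numeric(1))
  # discrete identity holds at solver precision on every mesh
  expect_true(all(res < 1e-8))
})

test_that("fully trapped free space yields a vanishing tensor", {
  # blocked band across the whole domain in each direction (a grid),
  # leaving only enclosed pockets
  n <- 200
  m <- matrix(0L, n, n)
  m[, 95:105] <- 1L; m[95:105, ] <- 1L
  m[, 1:5] <- 1L; m[1:5, ] <- 1L; m[, (n-4):n] <- 1L; m[(n-4):n, ] <- 1L
  attr(m, "res") <- 1 / n; attr(m, "box") <- 1
  bg <- inaccessible_region(m, R = 0)
  mesh <- mesh_sampling_domain(bg, target_h = 0.02)
  sol <- solve_cell_problems(mesh)
  et <- effective_tensor(mesh, sol)
  expect_lt(et$lambda[1], 1e-8)
  expect_true(et$trapped)
})

test_that("mesh refinement changes tr(D0) by less than 2% between h and h/2", {
  m <- disk_mask(8, 0.07, res = 2e-3, box = 1, seed = 8)
  bg <- inaccessible_region(m, R = 0)
  tr <- vapply(c(0.01, 0.005), function(h) {
    mesh <- mesh_sampling_domain(bg, target_h = h)
    mean(diag(effective_tensor(mesh, solve_cell_problems(mesh))$D0))
  }, numeric(1))
  expect_lt(abs(tr[2] / tr[1] - 1), 0.02)
})
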