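test_that("cylinder cross-sections have exact conic geometry", {
  # axis perpendicular to the slice: circle of the filament radius
  net <- manual_network(c(0.5, 0.5, 0.1, 0.5, 0.5, 0.9), radius = 0.05)
  obs <- slice_cross_sections(net, 0.5)
  expect_length(obs, 1)
  expect_equal(obs[[1]]$kind, "circle")
  expect_equal(obs[[1]]$area, pi * 0.05^2, tolerance = 2e-3)
  expect_equal(obs[[1]]$center, c(0.5, 0.5), tolerance = 1e-9)

  # axis at 45 degrees: ellipse with semi-axes (r, r/cos45), area
  # pi r^2 sqrt(2)
  net45 <- manual_network(c(0.2, 0.5, 0.2, 0.8, 0.5, 0.8), radius = 0.05)
  obs45 <- slice_cross_sections(net45, 0.5)
  expect_length(obs45, 1)
  expect_equal(obs45[[1]]$kind, "ellipse")
  expect_equal(obs45[[1]]$semi_axes[2], 0.05 * sqrt(2), tolerance = 1e-9)
  expect_equal(obs45[[1]]$area, pi * 0.05^2 * sqrt(2), tolerance = 5e-3)

  # near-parallel axis: elongated polygon
  netp <- manual_network(c(0.1, 0.5, 0.5, 0.9, 0.5, 0.52), radius = 0.03)
  obsp <- slice_cross_sections(netp, 0.5)
  expect_length(obsp, 1)
  expect_equal(obsp[[1]]$kind, "polygon")
  expect_gt(diff(range(obsp[[1]]$vertices[, 1])), 0.5)
})

test_that("total polygonal obstacle area matches the rasterized cylinder union", {
  net <- generate_network(network_spec(300, seed = 11))
  obs <- slice_cross_sections(net, 0.5)
  msk <- obstacle_mask(net, 0.5, res = 1e-3, periodic = FALSE)
  poly_area <- sum(vapply(obs, `[[`, numeric(1), "area"))
  # sections at this density rarely overlap; the union is within a few
  # percent of the summed areas
  expect_equal(poly_area, mean(msk), tolerance = 0.05)
  # rasterizing the polygons reproduces the mask up to boundary pixels
  msk2 <- rasterize_obstacles(obs, box = 1, res = 1e-3)
  expect_lt(mean(msk != msk2), 0.01)
})

test_that("inaccessible region reduces to the obstacle union at R = 0 and grows with R", {
  net <- generate_network(network_spec(800, seed = 3))
  bg0 <- inaccessible_region(net, 0, z = 0.5)
  expect_identical(unname(bg0$blocked), unname(bg0$obstacle))
  expect_equal(bg0$phi, bg0$phi_obstacle)
  bgR <- inaccessible_region(net, 0.01, z = 0.5)
  expect_gte(bgR$phi, bg0$phi)
  expect_true(all(bgR$blocked[bg0$obstacle == 1L] == 1L))
})

test_that("empty obstacle list gives phi 0", {
  net0 <- generate_network(network_spec(0))
  bg <- inaccessible_region(net0, 0.02, z = 0.5)
  expect_equal(bg$phi, 0)
})

test_that("wedge pockets between close disks are absorbed; opening matches the definition-based oracle", {
  # two circles radius 5 nm with a boundary gap of 8 nm, vesicle radius
  # 5 nm: the disk cannot reach the concave pockets flanking the gap,
  # so the blocked area exceeds the bare obstacle area.  (The corridor
  # midline itself remains reachable by the vesicle body from either
  # side: the opening blocks unreachable area, not passage.)
  box <- 0.06; res <- 0.5e-3
  n <- round(box / res)
  px <- (seq_len(n) - 0.5) * res
  m <- matrix(0L, n, n)
  for (c0 in list(c(0.020, 0.03), c(0.038, 0.03)))  # gap 0.008
    m <- pmax(m, matrix(as.integer(outer((px - c0[1])^2, (px - c0[2])^2,
                                         "+") <= 0.005^2), n, n))
  attr(m, "res") <- res; attr(m, "box") <- box
  bg <- inaccessible_region(m, R = 0.005, periodic = FALSE)
  expect_gt(bg$phi, bg$phi_obstacle)
  # the unreachable pockets are free space in the raw mask and lie in
  # the gap between the circles
  extra <- which(bg$blocked == 1L & m == 0L, arr.ind = TRUE)
  expect_gt(nrow(extra), 10)
  xs <- (extra[, 1] - 0.5) * res
  expect_true(all(xs > 0.024 & xs < 0.034))
  oracle <- opening_oracle(m, 0.005, res, periodic = FALSE)
  expect_lt(mean(bg$blocked != oracle), 0.02)
  expect_equal(bg$phi, mean(oracle), tolerance = 0.02)
})

test_that("opening matches the oracle on random fixtures and phi is monotone", {
  for (s in 1:4) {
    m <- disk_mask(10, 0.004, res = 1e-3, box = 0.1, seed = s)
    bg <- inaccessible_region(m, R = 0.005)
    oracle <- opening_oracle(m, 0.005, 1e-3)
    expect_lt(abs(bg$phi - mean(oracle)), 0.02)
    expect_true(all(bg$blocked >= m))
  }
})

test_that("phi(R) curves are monotone, start at the obstacle fraction and saturate", {
  net <- generate_network(network_spec(1430, seed = 6))
  radii <- c(0, 0.005, 0.01, 0.02, 0.04)
  pc <- phi_of_radius(net, 0.5, radii, res = 2e-3)
  expect_equal(pc$phi[1],
               inaccessible_region(net, 0, z = 0.5, res = 2e-3)$phi_obstacle,
               tolerance = 1e-12)
  expect_true(all(diff(pc$phi) >= -1e-12))
  # denser network: phi larger at every R (statistically robust here)
  net2 <- generate_network(network_spec(2860, seed = 6))
  pc2 <- phi_of_radius(net2, 0.5, radii, res = 2e-3)
  expect_true(all(pc2$phi[-1] > pc$phi[-1]))
  d <- max_passable_diameter(pc2, 0.5)
  expect_true(is.na(d) || d > 0)
})

test_that("stack-averaged inaccessible volume behaves", {
  expect_equal(stack_inaccessible_volume(generate_network(network_spec(0)),
                                         0.01, n_slices = 5), 0)
  # a z-invariant obstacle field: vertical cylinder spanning the box
  net <- manual_network(c(0.5, 0.5, 0, 0.5, 0.5, 1), radius = 0.1)
  v <- stack_inaccessible_volume(net, 0, n_slices = 11, res = 2e-3)
  expect_equal(v, inaccessible_region(net, 0, z = 0.5, res = 2e-3)$phi,
               tolerance = 1e-10)
  # refinement: slice counts 20 vs 40 agree within tolerance
  net2 <- generate_network(network_spec(400, seed = 9))
  v20 <- stack_inaccessible_volume(net2, 0.01, n_slices = 20, res = 4e-3)
  v40 <- stack_inaccessible_volume(net2, 0.01, n_slices = 40, res = 4e-3)
  expect_lt(abs(v20 - v40), 0.002)
})

test_that("blocked geometry serialization writes (z, R, phi) and a mask", {
  net <- generate_network(network_spec(100, seed = 2))
  bg <- inaccessible_region(net, 0.01, z = 0.5, res = 4e-3)
  f <- tempfile(fileext = ".csv"); fm <- tempfile(fileext = ".csv")
  write_blocked_geometry(bg, f, fm)
  df <- read.csv(f)
  expect_equal(df$phi, bg$phi)
  m <- as.matrix(read.csv(fm, header = FALSE))
  expect_equal(dim(m), dim(bg$blocked))
  unlink(c(f, fm))
})
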