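test_that("filament count, nominal volume fraction and mass density follow the spec analytically", {
  spec <- network_spec(1430, mean_length = 1.1, filament_radius = 0.005,
                       seed = 3)
  net <- generate_network(spec)
  expect_equal(nrow(net$p0), 1430)
  expect_equal(nominal_volume_fraction(net),
               1430 * pi * 0.005^2 * 1.1, tolerance = 1e-12)
  st <- network_statistics(net)
  # 370 monomers/um x 42 kDa over 1430 x 1.1 um in 1 um^3
  expect_equal(st$mass_density,
               1430 * 1.1 * 370 * 42e3 / 6.02214076e23 * 1e3 / 1e-12,
               tolerance = 1e-12)
  expect_gt(st$mass_density, 38)
  expect_lt(st$mass_density, 43)
})

test_that("empty and deterministic cases behave", {
  net0 <- generate_network(network_spec(0))
  expect_equal(nrow(net0$p0), 0)
  st0 <- network_statistics(net0)
  expect_true(st0$empty)
  expect_equal(st0$volume_fraction, 0)

  a <- generate_network(network_spec(200, seed = 42))
  b <- generate_network(network_spec(200, seed = 42))
  expect_identical(a$p0, b$p0)
  expect_identical(a$p1, b$p1)
  d <- generate_network(network_spec(200, seed = 43))
  expect_false(isTRUE(all.equal(a$p0, d$p0)))
})

test_that("all filaments stay inside the box and branch angles in range", {
  net <- generate_network(network_spec(500, seed = 5))
  expect_true(all(net$p0 >= -1e-12 & net$p0 <= 1 + 1e-12))
  expect_true(all(net$p1 >= -1e-12 & net$p1 <= 1 + 1e-12))
  ba <- net$branch_angle[!is.na(net$branch_angle)]
  expect_gt(length(ba), 0)
  expect_true(all(ba >= 65 - 1e-9 & ba <= 75 + 1e-9))
  # branch base lies on the parent's segment
  ids <- which(!is.na(net$parent))[1:10]
  for (i in ids) {
    p <- net$parent[i]
    d <- seg_dist_R(net$p0[i, ], net$p0[i, ], net$p0[p, ], net$p1[p, ])
    expect_lt(d, 1e-9)
  }
})

test_that("unbranched axis orientations are uniform on the sphere", {
  net <- generate_network(network_spec(3000, branch_fraction = 0, seed = 8))
  # use nominal (pre-clip) directions via p1 - p0 of unclipped interior
  # filaments; clipped ones keep their direction too
  d <- net$p1 - net$p0
  d <- d / sqrt(rowSums(d^2))
  # antipodally symmetrize (axes, not directions), then mean resultant
  # length of the doubled orientation should be ~0
  s <- sign(d[, 3]); s[s == 0] <- 1
  d <- d * s
  # test uniformity of z = |cos(theta)|: uniform on [0, 1]
  ks <- suppressWarnings(stats::ks.test(abs(d[, 3]), "punif"))
  expect_gt(ks$p.value, 1e-4)
})

test_that("neighbor statistics match a brute-force R oracle on a small network", {
  net <- generate_network(network_spec(50, seed = 7))
  n <- nrow(net$p0)
  dmin <- rep(Inf, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- seg_dist_R(net$p0[i, ], net$p1[i, ], net$p0[j, ], net$p1[j, ])
    dmin[i] <- min(dmin[i], d)
    dmin[j] <- min(dmin[j], d)
  }
  cs <- cytodiffuse:::cpp_contact_stats(net$p0, net$p1, 3 * 0.005)
  # sampled-parameter oracle overestimates the true minimum slightly
  expect_lt(max(abs(cs$min_dist - dmin)), 2e-3)
  st <- network_statistics(net)
  expect_true(is.finite(st$neighbor_dist_mean))
})

test_that("two parallel filaments 0.05 um apart give neighbor distance 0.05", {
  net <- manual_network(c(0.2, 0.5, 0.5, 0.8, 0.5, 0.5,
                          0.2, 0.55, 0.5, 0.8, 0.55, 0.5))
  st <- network_statistics(net)
  expect_equal(st$neighbor_dist_mean, 0.05, tolerance = 1e-12)
  expect_equal(st$neighbor_dist_sd, 0, tolerance = 1e-12)
})

test_that("scale_network_density scales only the density", {
  spec <- network_spec(1430, seed = 1)
  expect_equal(scale_network_density(spec, 1), spec)
  s2 <- scale_network_density(spec, 0.5)
  expect_equal(s2$filaments_per_um3, 715)
  expect_equal(s2$mean_length, spec$mean_length)
  s5 <- scale_network_density(spec, 5)
  expect_equal(s5$filaments_per_um3, 7150)
  net5 <- generate_network(s5)
  expect_equal(nominal_volume_fraction(net5),
               5 * 1430 * pi * 0.005^2 * 1.1, tolerance = 1e-12)
  expect_error(scale_network_density(spec, -1))
})

test_that("network serialization round-trips via JSON and CSV", {
  net <- generate_network(network_spec(30, seed = 2))
  for (ext in c("json", "csv")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_network(net, f)
    back <- read_network(f)
    expect_equal(unname(back$p0), unname(net$p0), tolerance = 1e-12)
    expect_equal(back$radius, net$radius)
    expect_equal(back$box_edge, net$box_edge)
    unlink(f)
  }
})
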