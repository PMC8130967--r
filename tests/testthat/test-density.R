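make_test_gmm <- function() {
  covs <- array(0, c(2, 2, 3))
  covs[, , 1] <- matrix(c(8, 2, 2, 6), 2)
  covs[, , 2] <- diag(c(4, 12))
  covs[, , 3] <- diag(c(10, 10))
  poly <- cbind(c(0, 50, 50, 0), c(0, 0, 40, 40))
  gmm_density(c(0.5, 0.3, 0.2),
              rbind(c(12, 10), c(35, 25), c(25, 30)), covs, poly)
}

test_that("mixture density integrates to the total weight and is anchored", {
  g <- make_test_gmm()
  # numeric integral over a wide grid
  h <- 0.5
  gx <- seq(-30, 90, by = h); gy <- seq(-40, 80, by = h)
  vals <- gmm_value(g, cbind(rep(gx, length(gy)), rep(gy, each = length(gx))))
  expect_equal(sum(vals) * h^2, sum(g$weights), tolerance = 1e-3)
  # density_to_spec maps the field maximum to the peak density
  peak_xy <- g$means[1, ]
  opt <- optim(peak_xy, function(x) -gmm_value(g, x))$par
  spec <- density_to_spec(g, opt)
  expect_equal(spec$filaments_per_um3, 1430, tolerance = 1e-3)
  expect_error(density_to_spec(g, c(200, 200)))
})

test_that("perturbations scale pointwise values and keep the anchor", {
  g <- make_test_gmm()
  pts <- with_seed(2, cbind(runif(20, 5, 45), runif(20, 5, 35)))
  v0 <- gmm_value(g, pts)
  gb <- perturb_gmm(g, b_scale = 0.5)
  expect_equal(gmm_value(gb, pts), 0.5 * v0, tolerance = 1e-12)
  g5 <- perturb_gmm(g, b_scale = 5)
  expect_equal(gmm_value(g5, pts), 5 * v0, tolerance = 1e-12)
  # +400% cumulative and +400% max filaments for b x 5 (anchor fixed)
  expect_equal(sum(g5$weights) / sum(g$weights), 5)
  x_max <- optim(g$means[1, ], function(x) -gmm_value(g, x))$par
  expect_equal(density_to_spec(g5, x_max)$filaments_per_um3,
               5 * density_to_spec(g, x_max)$filaments_per_um3,
               tolerance = 1e-9)
  # sigma scaling: 0.5 Sigma raises the peak, 5 Sigma lowers it
  expect_gt(max(gmm_value(perturb_gmm(g, 1, 0.5), pts)), max(v0))
  peak0 <- gmm_value(g, x_max)
  expect_gt(gmm_value(perturb_gmm(g, 1, 0.5), x_max), peak0)
  expect_lt(gmm_value(perturb_gmm(g, 1, 5), x_max), peak0)
  expect_error(perturb_gmm(g, -1, 1))
})

test_that("weighted EM fits a single Gaussian raster to its moments", {
  g1 <- gmm_density(1, matrix(c(20, 15), 1), array(diag(c(9, 4)), c(2, 2, 1)),
                    cbind(c(0, 40, 40, 0), c(0, 0, 30, 30)))
  r <- raster_from_gmm(g1, spacing = 0.4)
  fit <- fit_gmm(r, K = 1, seed = 3)
  expect_equal(as.numeric(fit$means), c(20, 15), tolerance = 0.05)
  expect_equal(fit$covs[1, 1, 1], 9, tolerance = 0.15)
  expect_equal(fit$covs[2, 2, 1], 4, tolerance = 0.15)
  expect_gt(attr(fit, "r_squared"), 0.999)
})

test_that("weighted EM recovers a known 3-component mixture with matched components", {
  g <- make_test_gmm()
  r <- raster_from_gmm(g, spacing = 0.4)
  fit <- fit_gmm(r, K = 3, seed = 7, restarts = 3)
  expect_gt(attr(fit, "r_squared"), 0.999)
  # match components by nearest mean
  perm <- apply(fit$means, 1, function(m)
    which.min(colSums((t(g$means) - m)^2)))
  expect_equal(sort(perm), 1:3)
  expect_equal(fit$means[order(perm), ], g$means, tolerance = 0.3)
  expect_equal(fit$weights[order(perm)], g$weights, tolerance = 0.02)
  # EM log-likelihood is nondecreasing
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) > -1e-8))
})

test_that("EM agrees with mclust on sampled points", {
  skip_if_not_installed("mclust")
  suppressMessages(require(mclust, quietly = TRUE))
  g <- make_test_gmm()
  r <- raster_from_gmm(g, spacing = 0.4)
  fit <- fit_gmm(r, K = 3, seed = 5)
  # independent route: sample points proportional to intensity, fit with
  # mclust, compare component means
  v <- r$values
  pts <- with_seed(9, {
    idx <- sample.int(length(v), 4000, replace = TRUE, prob = as.vector(v))
    i <- (idx - 1) %% nrow(v) + 1; j <- (idx - 1) %/% nrow(v) + 1
    cbind(r$origin[1] + (i - 0.5) * r$spacing,
          r$origin[2] + (j - 0.5) * r$spacing) +
      matrix(runif(8000, -r$spacing / 2, r$spacing / 2), ncol = 2)
  })
  mc <- mclust::Mclust(pts, G = 3, modelNames = "VVV", verbose = FALSE)
  mcm <- t(mc$parameters$mean)
  perm <- apply(fit$means, 1, function(m) which.min(colSums((t(mcm) - m)^2)))
  expect_equal(sort(perm), 1:3)
  expect_lt(max(abs(fit$means - mcm[perm, ])), 0.5)
})

test_that("synthetic cell maps are reproducible and plausibly scaled", {
  g1 <- synth_cell_map(n_components = 12, seed = 4)
  g2 <- synth_cell_map(n_components = 12, seed = 4)
  expect_identical(g1, g2)
  g3 <- synth_cell_map(n_components = 12, seed = 5)
  expect_false(isTRUE(all.equal(g1$means, g3$means)))
  expect_equal(sum(g1$weights), 1, tolerance = 1e-9)
  # cell around 45 um across
  expect_gt(diff(range(g1$cell_polygon[, 1])), 30)
  expect_lt(diff(range(g1$cell_polygon[, 1])), 70)
  # density at the anchor point maps to the anchor density, and phi for
  # R = 10 nm stays in a plausible cortical band
  x_pk <- g1$means[which.max(gmm_value(g1, g1$means)), ]
  spec <- density_to_spec(g1, x_pk)
  expect_lte(spec$filaments_per_um3, 1430 + 1e-6)
  net <- generate_network(density_to_spec(g1, x_pk, seed = 2))
  phi <- inaccessible_region(net, 0.01, z = 0.5, res = 2e-3)$phi
  expect_gte(phi, 0)
  expect_lte(phi, 0.2)
})

test_that("GMM parameters round-trip through JSON", {
  g <- make_test_gmm()
  f <- tempfile(fileext = ".json")
  write_gmm(g, f)
  h <- read_gmm(f)
  expect_equal(h$weights, g$weights)
  expect_equal(h$means, g$means, tolerance = 1e-12)
  expect_equal(h$covs, g$covs, tolerance = 1e-12)
  expect_equal(h$ref_peak, g$ref_peak)
  unlink(f)
})
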