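# Stochastic 3D actin-filament network generator.
#
# Filaments (F-actin) are abstracted as solid cylinders of fixed radius
# placed in a cubic sampling box.  Unbranched filaments are centered
# uniformly in the box with axes uniform on the sphere; a configurable
# fraction branches off an existing filament at an Arp2/3-like angle.

# linear mass density of F-actin: 370 monomers per um times 42 kDa per
# monomer, in mg per um of axis length
.ACTIN_MG_PER_UM <- 370 * 42e3 / 6.02214076e23 * 1e3

#' Specification of a stochastic actin-filament network
#'
#' @param filaments_per_um3 number density of filaments (count/um^3).
#' @param mean_length filament length in um; every filament gets this
#'   length (the reference data report only an average), unless
#'   `length_sampler` is supplied.
#' @param filament_radius cylinder radius in um (default 0.005, i.e. 5 nm).
#' @param box_edge edge length of the cubic sampling box in um.
#' @param branch_angle_range allowed branch angles in degrees (Arp2/3
#'   branching is observed near 70 degrees).
#' @param branch_fraction fraction of filaments attached to a parent
#'   filament rather than placed independently.  The branched fraction is
#'   not constrained by the reference data; 0.25 is a free default.
#' @param length_sampler optional `function(n)` returning `n` filament
#'   lengths in um; overrides the fixed `mean_length`.
#' @param seed integer seed.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(filaments_per_um3, mean_length = 1.1,
                         filament_radius = 0.005, box_edge = 1,
                         branch_angle_range = c(65, 75),
                         branch_fraction = 0.25,
                         length_sampler = NULL, seed = 1L) {
  stopifnot(filaments_per_um3 >= 0, mean_length > 0, box_edge > 0,
            filament_radius > 0, filament_radius < box_edge / 2,
            branch_fraction >= 0, branch_fraction <= 1,
            length(branch_angle_range) == 2,
            all(branch_angle_range > 0), all(branch_angle_range <= 90))
  structure(list(filaments_per_um3 = filaments_per_um3,
                 mean_length = mean_length,
                 filament_radius = filament_radius,
                 box_edge = box_edge,
                 branch_angle_range = as.numeric(branch_angle_range),
                 branch_fraction = branch_fraction,
                 length_sampler = length_sampler,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Actin network specification\n")
  cat(sprintf("  density        : %g filaments/um^3\n", x$filaments_per_um3))
  cat(sprintf("  length, radius : %g um, %g um\n", x$mean_length,
              x$filament_radius))
  cat(sprintf("  box edge       : %g um\n", x$box_edge))
  cat(sprintf("  branching      : fraction %g, angles [%g, %g] deg\n",
              x$branch_fraction, x$branch_angle_range[1],
              x$branch_angle_range[2]))
  invisible(x)
}

# uniform directions on the unit sphere
.runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  a <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(a), r * sin(a), z)
}

# clip segments (p0, p1) to [0, box]^3 (Liang-Barsky); rows fully outside
# get keep = FALSE
.clip_segments <- function(p0, p1, box) {
  n <- nrow(p0)
  t0 <- rep(0, n); t1 <- rep(1, n); keep <- rep(TRUE, n)
  d <- p1 - p0
  for (k in 1:3) {
    for (side in 1:2) {
      p <- if (side == 1) -d[, k] else d[, k]
      q <- if (side == 1) p0[, k] else box - p0[, k]
      par <- p != 0
      r <- ifelse(par, q / ifelse(p == 0, 1, p), 0)
      ent <- par & (p < 0)
      ext <- par & (p > 0)
      t0 <- ifelse(ent, pmax(t0, r), t0)
      t1 <- ifelse(ext, pmin(t1, r), t1)
      keep <- keep & !(!par & q < 0)
    }
  }
  keep <- keep & (t0 <= t1)
  list(p0 = p0 + d * t0, p1 = p0 + d * t1, keep = keep,
       frac = pmax(0, t1 - t0))
}

#' Generate a stochastic actin-filament network
#'
#' Draws exactly `round(density * box_volume)` filaments (the reference
#' counts are absolute, so an exact-count draw is used rather than a
#' Poisson draw).  Unbranched filaments have centers uniform in the box
#' and axes uniform on the sphere.  Branched filaments start at a
#' uniformly chosen point on a uniformly chosen earlier filament, with an
#' inter-axis angle uniform in `branch_angle_range` and uniform azimuth
#' around the parent axis.  Stored segments are clipped to the box.
#'
#' @param spec a [network_spec()].
#' @return an object of class `actin_network` with matrices `p0`, `p1`
#'   (clipped endpoints, um), `radius`, `length_nominal` (unclipped),
#'   `parent` (NA for unbranched), `branch_angle` (degrees, NA for
#'   unbranched).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  box <- spec$box_edge
  n <- round(spec$filaments_per_um3 * box^3)
  empty <- list(p0 = matrix(0, 0, 3), p1 = matrix(0, 0, 3),
                radius = numeric(0), length_nominal = numeric(0),
                parent = integer(0), branch_angle = numeric(0),
                box_edge = box, seed = spec$seed, spec = spec)
  if (n == 0) return(structure(empty, class = "actin_network"))
  with_seed(split_seed(spec$seed, 101L), {
    n_branch <- round(spec$branch_fraction * n)
    n_free <- n - n_branch
    len <- if (is.null(spec$length_sampler)) rep(spec$mean_length, n)
           else spec$length_sampler(n)
    # unbranched: center + axis
    ctr <- matrix(runif(3 * n_free, 0, box), n_free, 3)
    dir <- .runif_sphere(n_free)
    a0 <- ctr - dir * len[seq_len(n_free)] / 2
    a1 <- ctr + dir * len[seq_len(n_free)] / 2
    parent <- rep(NA_integer_, n)
    bang <- rep(NA_real_, n)
    # clip unbranched filaments (centers are inside, so a piece remains)
    cl <- .clip_segments(a0, a1, box)
    all0 <- matrix(0, n, 3); all1 <- matrix(0, n, 3)
    all0[seq_len(n_free), ] <- cl$p0
    all1[seq_len(n_free), ] <- cl$p1
    if (n_branch > 0) {
      for (i in seq_len(n_branch)) {
        id <- n_free + i
        par_id <- sample.int(id - 1L, 1L)
        # branch base uniform on the clipped (in-box) parent segment
        t <- runif(1)
        base <- all0[par_id, ] + t * (all1[par_id, ] - all0[par_id, ])
        dpar <- all1[par_id, ] - all0[par_id, ]
        dpar <- dpar / sqrt(sum(dpar^2))
        ang <- runif(1, spec$branch_angle_range[1],
                     spec$branch_angle_range[2]) * pi / 180
        # orthonormal frame around the parent axis
        ref <- if (abs(dpar[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        u <- ref - sum(ref * dpar) * dpar
        u <- u / sqrt(sum(u^2))
        v <- c(dpar[2]*u[3] - dpar[3]*u[2],
               dpar[3]*u[1] - dpar[1]*u[3],
               dpar[1]*u[2] - dpar[2]*u[1])
        az <- runif(1, 0, 2 * pi)
        dnew <- cos(ang) * dpar + sin(ang) * (cos(az) * u + sin(az) * v)
        clb <- .clip_segments(matrix(base, 1), matrix(base + dnew * len[id], 1),
                              box)
        all0[id, ] <- clb$p0
        all1[id, ] <- clb$p1
        parent[id] <- par_id
        bang[id] <- ang * 180 / pi
      }
    }
    structure(list(p0 = all0, p1 = all1,
                   radius = rep(spec$filament_radius, n),
                   length_nominal = len,
                   parent = parent,
                   branch_angle = bang,
                   box_edge = box, seed = spec$seed, spec = spec),
              class = "actin_network")
  })
}

#' @export
print.actin_network <- function(x, ...) {
  cat(sprintf("Actin network: %d filaments in a (%g um)^3 box (seed %d)\n",
              nrow(x$p0), x$box_edge, x$seed))
  cat(sprintf("  nominal volume fraction: %.4f\n",
              nominal_volume_fraction(x)))
  invisible(x)
}

#' Nominal filament volume fraction N pi r^2 L / V
#'
#' Uses the nominal (unclipped) filament lengths, i.e. overlaps and box
#' clipping are ignored; the union volume of the cylinders is therefore
#' bounded above by this value.
#'
#' @param net an `actin_network`.
#' @return dimensionless volume fraction.
#' @export
nominal_volume_fraction <- function(net) {
  if (nrow(net$p0) == 0) return(0)
  sum(pi * net$radius^2 * net$length_nominal) / net$box_edge^3
}

#' Summary statistics of an actin network
#'
#' The distance between neighboring filaments is measured as the network
#' mesh size: along each filament, the positions where other filaments
#' come into contact (axis-to-axis distance at most `contact_dist`,
#' default three filament radii, i.e. surfaces within one radius of
#' touching) are collected, and the spacings between consecutive
#' contacts are pooled over all filaments.  Filaments with fewer than
#' two contacts contribute their minimum axis distance to any other
#' filament instead, so in sparse networks the statistic reduces to the
#' nearest-neighbor distance.  The F-actin mass concentration is
#' computed from the total nominal axis length and the linear mass
#' density of F-actin (370 monomers/um at 42 kDa each).
#'
#' @param net an `actin_network`.
#' @param contact_dist axis-distance threshold (um) below which two
#'   filaments count as being in contact; default `3 * filament_radius`.
#' @return an object of class `network_stats`: `n_filaments`,
#'   `neighbor_dist_mean`, `neighbor_dist_sd` (um, over the pooled
#'   spacing samples), `min_axis_dist_mean` (um, plain nearest-neighbor
#'   axis distance), `branch_angle_mean`, `branch_angle_sd` (degrees),
#'   `volume_fraction` (nominal), `mass_density` (mg/ml).  An empty
#'   network returns all-`NA` stats with `empty = TRUE`.
#' @export
network_statistics <- function(net, contact_dist = NULL) {
  stopifnot(inherits(net, "actin_network"))
  n <- nrow(net$p0)
  if (n == 0) {
    return(structure(list(n_filaments = 0L, neighbor_dist_mean = NA_real_,
                          neighbor_dist_sd = NA_real_,
                          min_axis_dist_mean = NA_real_,
                          branch_angle_mean = NA_real_,
                          branch_angle_sd = NA_real_,
                          volume_fraction = 0, mass_density = 0,
                          empty = TRUE), class = "network_stats"))
  }
  if (is.null(contact_dist)) contact_dist <- 3 * net$radius[1]
  if (n >= 2) {
    cs <- cpp_contact_stats(net$p0, net$p1, contact_dist)
    # pooled spacing samples: contact gaps, plus the nearest-neighbor
    # distance of filaments too isolated to have two contacts
    pool <- c(cs$gaps, cs$min_dist[cs$n_contacts < 2])
    nd_mean <- mean(pool)
    nd_sd <- if (length(pool) > 1) sd(pool) else NA_real_
    mad_mean <- mean(cs$min_dist)
  } else {
    nd_mean <- nd_sd <- mad_mean <- NA_real_
  }
  ba <- net$branch_angle[!is.na(net$branch_angle)]
  total_len <- sum(net$length_nominal)           # um
  mass_mg <- total_len * .ACTIN_MG_PER_UM        # mg
  vol_ml <- net$box_edge^3 * 1e-12               # 1 um^3 = 1e-12 ml
  structure(list(n_filaments = n,
                 neighbor_dist_mean = nd_mean,
                 neighbor_dist_sd = nd_sd,
                 min_axis_dist_mean = mad_mean,
                 branch_angle_mean = if (length(ba)) mean(ba) else NA_real_,
                 branch_angle_sd = if (length(ba) > 1) sd(ba) else NA_real_,
                 volume_fraction = nominal_volume_fraction(net),
                 mass_density = mass_mg / vol_ml,
                 empty = FALSE), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("Actin network statistics\n")
  cat(sprintf("  filaments        : %d\n", x$n_filaments))
  cat(sprintf("  neighbor distance: %.4g +/- %.4g um\n",
              x$neighbor_dist_mean, x$neighbor_dist_sd))
  cat(sprintf("  branch angle     : %.4g +/- %.4g deg\n",
              x$branch_angle_mean, x$branch_angle_sd))
  cat(sprintf("  volume fraction  : %.4g (nominal)\n", x$volume_fraction))
  cat(sprintf("  F-actin density  : %.4g mg/ml\n", x$mass_density))
  invisible(x)
}

#' Scale the filament number density of a specification
#'
#' Multiplies `filaments_per_um3` by `factor`, leaving every other field
#' unchanged.  Used to map a macroscopic relative density value onto a
#' local sampling-box specification.
#'
#' @param x a `network_spec` or `actin_network` (its spec is used).
#' @param factor nonnegative multiplier.
#' @return a new `network_spec`.
#' @export
scale_network_density <- function(x, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor >= 0)
  spec <- if (inherits(x, "actin_network")) x$spec else x
  stopifnot(inherits(spec, "network_spec"))
  spec$filaments_per_um3 <- spec$filaments_per_um3 * factor
  spec
}

#' Write / read a network as JSON or CSV
#'
#' JSON stores endpoints (um), radii, parent ids and the generating
#' specification; CSV stores one filament per row.
#'
#' @param net an `actin_network`.
#' @param path output file; format chosen by extension (`.json`/`.csv`).
#' @return `path`, invisibly (`write_network`); an `actin_network`
#'   (`read_network`).
#' @export
write_network <- function(net, path) {
  fil <- data.frame(x0 = net$p0[, 1], y0 = net$p0[, 2], z0 = net$p0[, 3],
                    x1 = net$p1[, 1], y1 = net$p1[, 2], z1 = net$p1[, 3],
                    radius = net$radius, length_nominal = net$length_nominal,
                    parent = net$parent, branch_angle = net$branch_angle)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(box_edge = net$box_edge, seed = net$seed,
                              filaments = fil),
                         path, digits = NA, auto_unbox = TRUE, na = "null")
  } else {
    write.csv(cbind(fil, box_edge = net$box_edge, seed = net$seed),
              path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    fil <- obj$filaments
    box <- obj$box_edge; seed <- obj$seed
  } else {
    fil <- read.csv(path)
    box <- fil$box_edge[1]; seed <- fil$seed[1]
  }
  structure(list(p0 = as.matrix(fil[, c("x0", "y0", "z0")]),
                 p1 = as.matrix(fil[, c("x1", "y1", "z1")]),
                 radius = fil$radius,
                 length_nominal = fil$length_nominal,
                 parent = fil$parent, branch_angle = fil$branch_angle,
                 box_edge = box, seed = as.integer(seed), spec = NULL),
            class = "actin_network")
}
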