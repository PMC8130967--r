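# Orchestration: seeded end-to-end experiment runners writing plain-text
# outputs (CSV tables, JSON parameter files) plus a run manifest.

#' Homogenization sweep over generated filament networks
#'
#' For each filament density, generates a network, computes the
#' vesicle-blocked mid-box slice, homogenizes it by the periodic
#' cell-problem FEM and records the effective tensor.  This is the
#' input for the power-law calibration.
#'
#' @param densities filament densities (count/um^3).  The default spans
#'   0.3 x to 5 x the cortical reference density of 1430/um^3, which
#'   takes the inaccessible fraction from about 0.03 to about 0.5 for a
#'   10 nm vesicle.
#' @param R vesicle radius in um.
#' @param seed integer root seed.
#' @param res slice raster resolution in um.
#' @param target_h micro mesh size in um.
#' @param D_micro free diffusivity (um^2/s); results are also reported
#'   relative to it.
#' @param n_slices number of evenly spaced interior z-slices per network
#'   over which phi and the tensor are averaged (the stack-averaging the
#'   per-domain quantities are built from; 100 at publication scale, a
#'   dozen suffices for calibration).
#' @param spec_args extra [network_spec()] arguments.
#' @return data frame with columns `density`, `phi` (stack-averaged, in
#'   the summed-component reporting convention used by the power-law
#'   calibration), `phi_union` (stack-averaged union fraction), `D11`,
#'   `D22`, `D12` (stack-averaged tensor, um^2/s), `FA` (of the
#'   averaged tensor), `D_rel` (= tr(D0)/(2 D_micro)), `n_elements`,
#'   `n_dof` (mid-stack slice).
#' @export
homogenization_sweep <- function(densities = round(seq(430, 7150,
                                                       length.out = 20)),
                                 R = 0.01, seed = 1L, res = 1e-3,
                                 target_h = 0.01, D_micro = 1,
                                 n_slices = 12, spec_args = list()) {
  zs <- seq(0.5 / n_slices, 1 - 0.5 / n_slices, length.out = n_slices)
  rows <- lapply(seq_along(densities), function(i) {
    spec <- do.call(network_spec,
                    c(list(filaments_per_um3 = densities[i],
                           seed = split_seed(seed, 3L, i)), spec_args))
    net <- generate_network(spec)
    Dsum <- matrix(0, 2, 2)
    phis <- phis_rep <- numeric(length(zs))
    nel <- nd <- 0L
    for (k in seq_along(zs)) {
      bg <- inaccessible_region(net, R, z = zs[k] * net$box_edge,
                                res = res)
      phis[k] <- bg$phi
      phis_rep[k] <- bg$phi_reported
      et <- tryCatch({
        mesh <- mesh_sampling_domain(bg, target_h = target_h,
                                     D_micro = D_micro)
        effective_tensor(mesh, solve_cell_problems(mesh))
      }, error = function(e) NULL)     # fully blocked slice: D = 0
      if (!is.null(et)) {
        Dsum <- Dsum + et$D0
        if (k == ceiling(length(zs) / 2)) {
          nel <- et$n_elements; nd <- et$n_dof
        }
      }
    }
    D0 <- Dsum / length(zs)
    data.frame(density = densities[i], phi = mean(phis_rep),
               phi_union = mean(phis),
               D11 = D0[1, 1], D22 = D0[2, 2], D12 = D0[1, 2],
               FA = fractional_anisotropy(D0),
               D_rel = max(0, (D0[1, 1] + D0[2, 2]) / (2 * D_micro)),
               n_elements = nel, n_dof = nd)
  })
  do.call(rbind, rows)
}

#' Calibrate the power law from a homogenization sweep
#'
#' @param sweep data frame from [homogenization_sweep()].
#' @param component `"trace"` fits `tr(D0)/(2 D)` (the power law's left
#'   side), `"D11"`/`"D22"` fit a single diagonal component.
#' @param D_micro the free diffusivity the sweep was run with.
#' @return a `power_law` fit.
#' @export
calibrate_power_law <- function(sweep, component = c("trace", "D11",
                                                     "D22"),
                                D_micro = 1) {
  component <- match.arg(component)
  y <- switch(component, trace = sweep$D_rel,
              D11 = sweep$D11 / D_micro, D22 = sweep$D22 / D_micro)
  fit_power_law(sweep$phi, pmin(pmax(y, 0), 1))
}

#' Experiment configuration
#'
#' @param experiment one of `powerlaw_sweep`, `phi_of_radius`,
#'   `table1_like`, `cell_transport`, `table2_cases`, `mc_validation`,
#'   `verify_1d`.
#' @param seed root seed.
#' @param out_dir output directory (created if missing).
#' @param scale `"desk"` (small, minutes on one CPU) or `"paper"`
#'   (publication-scale resolutions).
#' @param params named list of overrides for the experiment's knobs.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(experiment, seed = 1L,
                              out_dir = tempfile("cytodiffuse_"),
                              scale = c("desk", "paper"),
                              params = list()) {
  experiment <- match.arg(experiment,
                          c("powerlaw_sweep", "phi_of_radius",
                            "table1_like", "cell_transport",
                            "table2_cases", "mc_validation", "verify_1d"))
  structure(list(experiment = experiment, seed = as.integer(seed),
                 out_dir = out_dir, scale = match.arg(scale),
                 params = params),
            class = "experiment_config")
}

# resolution knobs by scale preset
.scale_knobs <- function(scale) {
  if (scale == "paper")
    list(res = 1e-3, target_h = 0.01, n_sweep = 20, H = 1,
         lookup_levels = 25, lookup_seeds = 5, dt = 0.01, t_end = 30,
         n_walkers = 2000, n_radii = 16, n_elem_1d = 4000)
  else
    list(res = 2e-3, target_h = 0.02, n_sweep = 12, H = 2,
         lookup_levels = 10, lookup_seeds = 2, dt = 0.05, t_end = 30,
         n_walkers = 600, n_radii = 10, n_elem_1d = 1000)
}

#' Run a named experiment end-to-end
#'
#' Executes the pipeline for the configured experiment, writes CSV/JSON
#' outputs into `out_dir` and returns a manifest sufficient to re-run
#' the experiment reproducibly.
#'
#' @param cfg an [experiment_config()].
#' @return object of class `run_manifest`: config, seeds, produced
#'   files, wall-clock timings and the package version.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  kn <- utils::modifyList(.scale_knobs(cfg$scale), cfg$params)
  t0 <- Sys.time()
  files <- character(0)
  out <- function(name) {
    p <- file.path(cfg$out_dir, name)
    files <<- c(files, p)
    p
  }
  result <- switch(cfg$experiment,
    verify_1d = {
      d_fun <- kn$d_fun %||% function(y) 1 + 9 * (y %% 1 >= 0.5)
      sol <- solve_1d_oscillatory(d_fun, eps = kn$eps %||% 0.02,
                                  n_elem = kn$n_elem_1d)
      write.csv(data.frame(x = sol$x, u_h = sol$u_h,
                           u_exact = sol$u_exact),
                out("solution_1d.csv"), row.names = FALSE)
      jsonlite::write_json(list(l2_error = sol$l2_error,
                                D_hom = sol$D_hom,
                                harmonic_mean_check =
                                  abs(mean(sol$flux) - sol$D_hom) /
                                  sol$D_hom),
                           out("verify_1d.json"), auto_unbox = TRUE,
                           digits = NA)
      sol
    },
    powerlaw_sweep = {
      dens <- kn$densities %||%
        round(seq(430, 7150, length.out = kn$n_sweep))
      sw <- homogenization_sweep(dens, R = kn$R %||% 0.01,
                                 seed = cfg$seed, res = kn$res,
                                 target_h = kn$target_h)
      fit <- fit_power_law(sw$phi, pmin(sw$D_rel, 1))
      write.csv(sw, out("sweep.csv"), row.names = FALSE)
      write_power_law(fit, out("params.json"))
      list(sweep = sw, fit = fit)
    },
    phi_of_radius = {
      dens <- kn$densities %||% c(715, 1430, 2860)
      radii <- kn$radii %||%
        seq(0, 0.06, length.out = kn$n_radii + 1)[-1]
      curves <- lapply(seq_along(dens), function(i) {
        net <- generate_network(network_spec(dens[i],
                                             seed = split_seed(cfg$seed,
                                                               5L, i)))
        phi_of_radius(net, z = net$box_edge / 2, radii = radii,
                      res = kn$res)
      })
      df <- do.call(rbind, lapply(seq_along(curves), function(i)
        data.frame(density = dens[i], R = curves[[i]]$radii,
                   phi = curves[[i]]$phi)))
      write.csv(df, out("phi_of_radius.csv"), row.names = FALSE)
      curves
    },
    table1_like = {
      dens <- kn$densities %||% round(seq(430, 7150, length.out = 8))
      sw <- homogenization_sweep(dens, R = kn$R %||% 0.01,
                                 seed = cfg$seed, res = kn$res,
                                 target_h = kn$target_h)
      tab <- sw[, c("phi", "n_elements", "n_dof", "D11", "D22", "D12",
                    "FA")]
      write.csv(tab, out("effective_tensors.csv"), row.names = FALSE)
      tab
    },
    mc_validation = {
      dens <- kn$densities %||% c(1430, 2860, 4290)
      rows <- lapply(seq_along(dens), function(i) {
        net <- generate_network(network_spec(dens[i],
                                             seed = split_seed(cfg$seed,
                                                               7L, i)))
        bg <- inaccessible_region(net, kn$R %||% 0.01,
                                  z = net$box_edge / 2, res = kn$res)
        hm <- {
          mesh <- mesh_sampling_domain(bg, target_h = kn$target_h)
          # the random walk measures the physical (hole-inclusive) tensor
          effective_tensor(mesh, solve_cell_problems(mesh),
                           normalizer = "full")
        }
        mc <- mc_effective_D(bg, D_free = 1, n_walkers = kn$n_walkers,
                             total_time = kn$mc_time %||% 0.4,
                             step_dt = (kn$mc_step %||% 1.2e-3)^2 / 4,
                             seed = split_seed(cfg$seed, 8L, i))
        data.frame(density = dens[i], phi = bg$phi,
                   D_fem = mean(diag(hm$D0)), D_mc = mean(diag(mc$D)),
                   mc_se = mean(diag(mc$se)))
      })
      df <- do.call(rbind, rows)
      write.csv(df, out("mc_validation.csv"), row.names = FALSE)
      df
    },
    cell_transport = ,
    table2_cases = {
      g <- kn$density_map %||% synth_cell_map(seed = cfg$seed)
      law <- kn$law %||% {
        sw <- homogenization_sweep(round(seq(430, 7150,
                                             length.out = kn$n_sweep)),
                                   R = kn$R %||% 0.01, seed = cfg$seed,
                                   res = kn$res, target_h = kn$target_h)
        fit_power_law(sw$phi, pmin(sw$D_rel, 1))
      }
      mesh <- mesh_cell_polygon(g$cell_polygon, H = kn$H)
      D_invitro <- kn$D_invitro %||% stokes_einstein()
      probe <- matrix(kn$probe %||% colMeans(mesh$nodes), 1)
      cases <- if (cfg$experiment == "cell_transport")
        data.frame(case = "in_vitro", b = 1, s = 1)
      else rbind(data.frame(case = "in_vitro", b = 1, s = 1),
                 data.frame(case = c("I", "II", "III", "IV", "V", "VI",
                                     "VII", "VIII", "IX"),
                            b = c(0.5, 2, 5, 1, 1, 1, 5, 5, 5),
                            s = c(1, 1, 1, 0.5, 2, 5, 0.5, 2, 5)))
      rows <- lapply(seq_len(nrow(cases)), function(i) {
        gi <- perturb_gmm(g, cases$b[i], cases$s[i])
        phi <- build_phi_field(gi, kn$R %||% 0.01, mesh,
                               seed = cfg$seed, res = kn$res,
                               lookup_levels = kn$lookup_levels,
                               lookup_seeds = kn$lookup_seeds)
        D0 <- predict_D0(phi, law, D_invitro = D_invitro, floor = 1e-9)
        pr <- transport_problem(mesh, D0, g_D = 1, u0 = 0,
                                dt = kn$dt, t_end = kn$t_end)
        ser <- solve_transport(pr, probes = probe)
        data.frame(case = cases$case[i], b_scale = cases$b[i],
                   sigma_scale = cases$s[i],
                   cum_phi = sum(phi * mesh$area),
                   t90 = time_to_threshold(ser, kn$level %||% 0.9))
      })
      df <- do.call(rbind, rows)
      df$t90_rel_pct <- 100 * (df$t90 / df$t90[1] - 1)
      write.csv(df, out("traveling_times.csv"), row.names = FALSE)
      write_power_law(law, out("law_used.json"))
      df
    })
  manifest <- structure(list(experiment = cfg$experiment,
                             config = cfg, seed = cfg$seed,
                             knobs = kn[order(names(kn))],
                             files = files,
                             wall_clock_s =
                               as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")),
                             package_version =
                               as.character(utils::packageVersion(
                                 "cytodiffuse"))),
                        class = "run_manifest")
  mf <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(list(experiment = manifest$experiment,
                            seed = manifest$seed,
                            scale = cfg$scale,
                            knobs = Filter(Negate(is.function),
                                           manifest$knobs),
                            files = basename(files),
                            wall_clock_s = manifest$wall_clock_s,
                            package_version = manifest$package_version),
                       mf, auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$files <- c(manifest$files, mf)
  manifest$result <- result
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Experiment '%s' (seed %d): %d file(s) in %.1f s\n",
              x$experiment, x$seed, length(x$files), x$wall_clock_s))
  for (f in x$files) cat("  ", f, "\n")
  invisible(x)
}

#' Load a deposited inaccessible-area-fraction map
#'
#' Reads a `(x, y, phi)` grid exported from the deposited spreadsheet
#' as CSV and resamples it onto a cell mesh (nearest grid cell per
#' element centroid).
#'
#' @param path CSV file with columns `x`, `y`, `phi`.
#' @param mesh a `macro_mesh`.
#' @return per-element phi vector.
#' @export
load_supplementary_phi_map <- function(path, mesh) {
  df <- read.csv(path)
  need <- c("x", "y", "phi")
  if (!all(need %in% names(df)))
    stop("phi map must have columns x, y, phi")
  stopifnot(inherits(mesh, "macro_mesh"))
  vapply(seq_len(nrow(mesh$tri)), function(e) {
    d2 <- (df$x - mesh$centroid[e, 1])^2 + (df$y - mesh$centroid[e, 2])^2
    df$phi[which.min(d2)]
  }, numeric(1))
}

#' Export a per-element phi field as a (x, y, phi) CSV
#'
#' Round-trips with [load_supplementary_phi_map()].
#'
#' @param phi per-element values.
#' @param mesh the `macro_mesh`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_phi_map <- function(phi, mesh, path) {
  write.csv(data.frame(x = mesh$centroid[, 1], y = mesh$centroid[, 2],
                       phi = phi),
            path, row.names = FALSE)
  invisible(path)
}
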