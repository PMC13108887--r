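#' Write a field as legacy VTK STRUCTURED_POINTS
#'
#' ASCII legacy VTK with `DIMENSIONS N N N`, `SPACING h h h` and one scalar
#' array; readable by ParaView/VisIt for visualization. Values are written
#' in x-fastest order (matching both the VTK convention and R's array
#' layout).
#'
#' @param field A `pf_field`.
#' @param path Output file path.
#' @param name Scalar array name.
#' @export
write_snapshot_vtk <- function(field, path, name = "phi") {
  g <- field_grid(field)
  v <- field_values(field)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vesiclepf phase-field snapshot",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", g$N, g$N, g$N),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.17g %.17g %.17g", g$h, g$h, g$h),
               sprintf("POINT_DATA %d", g$N^3),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(formatC(as.vector(v), format = "g", digits = 9), con)
  invisible(path)
}

#' Exact-restart snapshot container
#'
#' Writes field values, grid geometry and arbitrary metadata to an
#' R-native serialized container (`.rds`); `read_snapshot()` is its exact
#' inverse (bit-identical values, verbatim metadata). Intended for restart
#' and exchange between R sessions; use [write_snapshot_vtk()] for
#' visualization.
#'
#' @param field A `pf_field`.
#' @param metadata A list of metadata (run configuration, step, time, ...).
#' @param path Output path (conventionally `.rds`).
#' @export
write_snapshot <- function(field, metadata = list(), path) {
  g <- field_grid(field)
  obj <- list(format = "vesiclepf-snapshot", version = 1L,
              L = g$L, N = g$N, values = field_values(field),
              metadata = metadata)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_snapshot
#' @param expect_N,expect_L Optional grid checks; mismatch is an error
#'   (guards against restarting on the wrong grid).
#' @return `read_snapshot()` returns a list with elements `field` (a
#'   `pf_field`) and `metadata`.
#' @export
read_snapshot <- function(path, expect_N = NULL, expect_L = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "vesiclepf-snapshot"))
    stop("not a vesiclepf snapshot: ", path)
  if (!is.null(expect_N) && obj$N != expect_N)
    stop(sprintf("snapshot grid N = %d does not match expected N = %d (%s)",
                 obj$N, expect_N, path))
  if (!is.null(expect_L) && obj$L != expect_L)
    stop(sprintf("snapshot domain L = %g does not match expected L = %g (%s)",
                 obj$L, expect_L, path))
  g <- make_grid(obj$L, obj$N)
  list(field = pf_field(obj$values, g), metadata = obj$metadata)
}

#' Write the energy/observable log of a run as CSV
#'
#' Columns: `step, t, W, G, T1, T2, E, V, A, dA, v, da`; every row
#' satisfies `E = W + G + T1 + T2` to roundoff.
#'
#' @param sim A `vesicle_sim`.
#' @param path Output CSV path.
#' @export
write_energy_log <- function(sim, path) {
  utils::write.csv(sim$energy_series, path, row.names = FALSE)
  invisible(path)
}

#' Execute a run configuration
#'
#' Instantiates a [run_config][preset()] (grid, parameters, initial shape,
#' derived targets), runs the gradient flow, and — if `output_dir` is given
#' — writes the configuration echo (`config.yaml`), the energy log
#' (`energy.csv`), periodic VTK/restart snapshots and the final state.
#'
#' @param config A `run_config` (from [preset()] or [read_run_config()]).
#' @param output_dir Optional output directory (created if missing).
#' @param max_steps Optional override of the step budget.
#' @param snapshot_every Snapshot cadence in steps (default from config).
#' @param quiet Suppress progress messages.
#' @return The `vesicle_sim` result, invisibly augmented with
#'   `output_dir`.
#' @export
run_from_config <- function(config, output_dir = NULL, max_steps = NULL,
                            snapshot_every = NULL, quiet = FALSE) {
  rr <- build_run(config)
  cfg <- rr$stepper
  if (!is.null(max_steps)) cfg$max_steps <- as.integer(max_steps)
  snap_every <- snapshot_every %||% config$output$snapshot_every %||% 10000L
  cb <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_config(rr$config, file.path(output_dir, "config.yaml"))
    write_snapshot_vtk(rr$phi0, file.path(output_dir, "snapshot_step0000000.vtk"))
    cb <- function(step, t, phi, eb) {
      if (step > 0 && step %% snap_every == 0L) {
        stem <- sprintf("snapshot_step%07d", step)
        write_snapshot_vtk(phi, file.path(output_dir, paste0(stem, ".vtk")))
        write_snapshot(phi, list(step = step, t = t, config = unclass(rr$config)),
                       file.path(output_dir, paste0(stem, ".rds")))
      }
      if (!quiet && step %% (10L * cfg$log_every) == 0L)
        message(sprintf("[%s] step %d  t = %.3g  E = %.8g", Sys.time(), step,
                        t, eb$E))
    }
  }
  sim <- run_simulation(rr$phi0, cfg, rr$params, rr$targets, callback = cb)
  if (!is.null(output_dir)) {
    write_energy_log(sim, file.path(output_dir, "energy.csv"))
    write_snapshot_vtk(sim$final_field, file.path(output_dir, "final.vtk"))
    write_snapshot(sim$final_field,
                   list(step = sim$steps_taken,
                        t = sim$steps_taken * cfg$dt,
                        termination = sim$termination_reason,
                        config = unclass(rr$config)),
                   file.path(output_dir, "final.rds"))
    sim$output_dir <- output_dir
  }
  sim
}

#' Sweep over a grid of (v, da0) targets
#'
#' Runs a preset over all combinations of the supplied reduced-volume and
#' reduced-area-difference targets. With `continuation = TRUE` each run is
#' seeded with the final field of the nearest previously completed
#' neighbor in the `(v, da0)` plane (parameter continuation); otherwise all
#' runs start from the preset's analytic shape.
#'
#' @param name Preset name.
#' @param v_values,da0_values Numeric vectors of targets.
#' @param output_dir Optional root output directory (one subdirectory per
#'   run).
#' @param continuation Seed each run from its nearest completed neighbor.
#' @param max_steps Step budget per run.
#' @param quiet Suppress progress messages.
#' @return A data frame with one row per run: targets, final energy,
#'   measured `(v, da)`, component counts and convergence flag.
#' @export
sweep_targets <- function(name, v_values, da0_values, output_dir = NULL,
                          continuation = TRUE, max_steps = 100000L,
                          quiet = FALSE) {
  grid_pts <- expand.grid(v = v_values, da0 = da0_values)
  done <- list()
  rows <- list()
  for (i in seq_len(nrow(grid_pts))) {
    vt <- grid_pts$v[i]; dt0 <- grid_pts$da0[i]
    config <- preset(name, v = vt, da0 = dt0)
    rr <- build_run(config)
    phi0 <- rr$phi0
    if (continuation && length(done)) {
      d2 <- vapply(done, function(d) (d$v - vt)^2 + (d$da0 - dt0)^2, numeric(1))
      phi0 <- done[[which.min(d2)]]$field
    }
    cfg <- rr$stepper
    cfg$max_steps <- as.integer(max_steps)
    tar <- derive_constraint_targets(phi0, vt, dt0, rr$params)
    sim <- run_simulation(phi0, cfg, rr$params, tar)
    if (!is.null(output_dir)) {
      sub <- file.path(output_dir, sprintf("v%.3f_da%.3f", vt, dt0))
      dir.create(sub, showWarnings = FALSE, recursive = TRUE)
      write_energy_log(sim, file.path(sub, "energy.csv"))
      write_snapshot_vtk(sim$final_field, file.path(sub, "final.vtk"))
    }
    es <- sim$energy_series
    last <- es[nrow(es), ]
    rows[[i]] <- data.frame(v_target = vt, da0_target = dt0,
                            E = last$E, v = last$v, da = last$da,
                            n_interior = count_regions(sim$final_field, "interior"),
                            asymmetry = reflection_asymmetry(sim$final_field),
                            converged = sim$converged,
                            steps = sim$steps_taken)
    done[[length(done) + 1L]] <- list(v = vt, da0 = dt0,
                                      field = sim$final_field)
    if (!quiet)
      message(sprintf("sweep %d/%d (v=%.3f, da0=%.3f): E=%.6g, %s",
                      i, nrow(grid_pts), vt, dt0, last$E,
                      sim$termination_reason))
  }
  do.call(rbind, rows)
}
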