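# Registry of the study's experiment configurations. Shared defaults:
# cubic domain [0,1]^3, N = 64, kappa = 1, kbar = 1.4, M1 = 1e5, M2 = 1e4,
# C = 0, D = (2/3) eps, semi-implicit stepping; overridden per experiment.

preset_registry <- function() {
  ell <- function(denoms, r0) list(kind = "ellipsoid",
                                   center = c(0.5, 0.5, 0.5),
                                   denoms = denoms, r0 = r0)
  # oblate ellipsoid used by the discocyte/torus runs
  sh_disc <- ell(c(0.5, 0.5, 0.1), 0.35)
  # prolate ellipsoid of the budding/chain series
  sh_bud <- ell(c(0.2^2, 0.2^2, 0.35^2), 0.5)
  sh_ball35 <- ell(rep(0.35^2, 3), 0.5)
  sh_oblate4 <- ell(c(0.35^2, 0.35^2, 0.15^2), 0.5)
  sh_ball6 <- ell(rep(0.35^2, 3), 0.6)
  base <- list(L = 1, N = 64L, kappa = 1, kbar = 1.4, C = 0,
               M1 = 1e5, M2 = 1e4, scheme = "semi_implicit")
  mk <- function(...) utils::modifyList(base, list(...))
  reg <- list(
    discocyte = mk(eps = 0.04, dt = 1e-6, v = 0.8, da0 = 1.2, shape = sh_disc),
    torus     = mk(eps = 0.04, dt = 1e-6, v = 0.8, da0 = 1.4, shape = sh_disc),
    chain     = mk(eps = 0.02, dt = 5e-7, v = 0.9, da0 = 1.4, shape = sh_bud),
    arms3     = mk(eps = 0.02, dt = 1e-7, v = 0.8, da0 = 1.4, shape = sh_ball35),
    arms4     = mk(eps = 0.02, dt = 2e-7, v = 0.8, da0 = 1.6, shape = sh_oblate4),
    arms6     = mk(eps = 0.02, dt = 1e-7, v = 0.6, da0 = 1.0, shape = sh_ball6),
    nested    = mk(L = 2, N = 100L, eps = 0.03, kbar = 4, M1 = 1e4, M2 = 1e4,
                   dt = 5e-7, v = 0.6, da0 = 1.1,
                   shape = list(kind = "ellipsoid", center = c(1, 1, 1),
                                denoms = rep(0.16, 3), r0 = 1)),
    # deliberately asymmetric two-sphere union; (v, da0) supplied by the user
    pear      = mk(eps = 0.02, dt = 5e-7, v = NA_real_, da0 = NA_real_,
                   shape = list(kind = "two_spheres",
                                centers = rbind(c(0.5, 0.5, 0.4),
                                                c(0.5, 0.5, 0.7)),
                                radii = c(0.22, 0.4))),
    cauchy_table1 = mk(eps = 0.04, dt = 2e-7, v = 0.8, da0 = 1.2,
                       shape = sh_disc)
  )
  # budding series: increasing preferred area difference at fixed v = 0.9
  da_series <- c(a = 1.1, b = 1.4, c = 1.5, d = 1.6, e = 1.7, f = 1.8)
  for (nm in names(da_series)) {
    reg[[paste0("budding_series_", nm)]] <-
      mk(eps = 0.02, dt = 5e-7, v = 0.9, da0 = unname(da_series[nm]),
         shape = sh_bud)
  }
  reg
}

#' Names of the available experiment presets
#' @export
preset_names <- function() names(preset_registry())

#' Experiment preset configurations
#'
#' Returns the full run configuration of a named experiment: grid, model
#' parameters, time step, reduced-parameter targets `(v, da0)` and the
#' analytic initial shape. The `pear` preset seeds an asymmetric union of
#' two unequal spheres and requires `v` and `da0` to be supplied (the
#' pear-shaped regime is explored by parameter continuation).
#'
#' @param name Preset name; see [preset_names()].
#' @param v,da0 Optional overrides of the reduced-volume / reduced-area-
#'   difference targets (required for `"pear"`).
#' @return A `run_config` object (nested named list with components `grid`,
#'   `params`, `stepper`, `shape`, `targets`, `preset`).
#' @examples
#' cfg <- preset("discocyte")
#' cfg$params$eps  # 0.04
#' @export
preset <- function(name, v = NULL, da0 = NULL) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                 paste(names(reg), collapse = ", ")))
  p <- reg[[name]]
  if (!is.null(v)) p$v <- v
  if (!is.null(da0)) p$da0 <- da0
  if (!is.finite(p$v) || !is.finite(p$da0))
    stop(sprintf("preset '%s' requires explicit v and da0 targets", name))
  structure(list(
    grid = list(L = p$L, N = p$N),
    params = list(eps = p$eps, kappa = p$kappa, kbar = p$kbar, C = p$C,
                  D = (2 / 3) * p$eps, M1 = p$M1, M2 = p$M2),
    stepper = list(scheme = p$scheme, dt = p$dt, max_steps = 100000L,
                   log_every = 100L),
    shape = p$shape,
    targets = list(v = p$v, da0 = p$da0),
    output = list(snapshot_every = 10000L),
    preset = name,
    perturbation_seed = NULL
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config%s: %d^3 grid on [0,%g)^3, eps=%g, dt=%g, %s\n",
              if (!is.null(x$preset)) paste0(" [", x$preset, "]") else "",
              x$grid$N, x$grid$L, x$params$eps, x$stepper$dt,
              x$stepper$scheme))
  cat(sprintf("targets: v=%g da0=%g; shape: %s\n",
              x$targets$v, x$targets$da0, x$shape$kind))
  invisible(x)
}

run_config_keys <- list(
  top = c("grid", "params", "stepper", "shape", "targets", "output",
          "preset", "perturbation_seed"),
  grid = c("L", "N"),
  params = c("eps", "kappa", "kbar", "C", "D", "M1", "M2"),
  stepper = c("scheme", "dt", "max_steps", "steady_rate_tol", "steady_window",
              "picard_tol", "picard_max_iter", "divergence_guard",
              "log_every"),
  shape = c("kind", "center", "denoms", "r0", "centers", "radii"),
  targets = c("v", "da0", "alpha", "beta", "dA0"),
  output = c("directory", "log_every", "snapshot_every"))

validate_run_config <- function(x) {
  chk <- function(lst, allowed, where) {
    bad <- setdiff(names(lst), allowed)
    if (length(bad))
      stop(sprintf("unknown configuration key(s) in %s: %s", where,
                   paste(bad, collapse = ", ")))
  }
  chk(x, run_config_keys$top, "run config")
  for (sec in c("grid", "params", "stepper", "shape", "targets", "output"))
    if (!is.null(x[[sec]])) chk(x[[sec]], run_config_keys[[sec]], sec)
  if (is.null(x$grid$L) || is.null(x$grid$N)) stop("config must set grid L and N")
  if (is.null(x$params$eps)) stop("config must set params$eps")
  if (is.null(x$stepper$dt)) stop("config must set stepper$dt")
  structure(x, class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' The configuration echo written next to each run's outputs re-runs the
#' simulation identically. Unknown keys are rejected to prevent silent
#' typos.
#'
#' @param path File path.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$shape$centers))
    x$shape$centers <- matrix(unlist(x$shape$centers), ncol = 3, byrow = TRUE)
  for (nm in c("center", "denoms", "radii"))
    if (!is.null(x$shape[[nm]])) x$shape[[nm]] <- as.numeric(x$shape[[nm]])
  validate_run_config(x)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$shape$centers))
    x$shape$centers <- lapply(seq_len(nrow(x$shape$centers)),
                              function(i) as.numeric(x$shape$centers[i, ]))
  # emit doubles with 17 significant digits so the echo re-runs bit-identically
  num_handler <- list(numeric = function(v)
    structure(sprintf("%.17g", v), class = "verbatim"))
  yaml::write_yaml(x, path, handlers = num_handler)
  invisible(path)
}

# instantiate grid/params/field/targets/stepper from a run_config
build_run <- function(config) {
  config <- validate_run_config(config)
  g <- make_grid(config$grid$L, config$grid$N)
  pl <- config$params
  par <- model_params(eps = pl$eps,
                      kappa = pl$kappa %||% 1, kbar = pl$kbar %||% 1.4,
                      C = pl$C %||% 0, D = pl$D %||% ((2 / 3) * pl$eps),
                      M1 = pl$M1 %||% 1e5, M2 = pl$M2 %||% 1e4)
  sh <- config$shape
  spec <- if (sh$kind == "two_spheres")
    shape_spec("two_spheres", centers = sh$centers, radii = sh$radii,
               epsilon = par$eps)
  else
    shape_spec("ellipsoid", center = sh$center, denoms = sh$denoms,
               r0 = sh$r0, epsilon = par$eps)
  phi0 <- make_shape(g, spec)
  if (!is.null(config$perturbation_seed))
    phi0 <- add_perturbation(phi0, seed = config$perturbation_seed)
  tar <- if (!is.null(config$targets$alpha)) {
    constraint_targets(config$targets$alpha, config$targets$beta,
                       config$targets$dA0)
  } else {
    derive_constraint_targets(phi0, config$targets$v, config$targets$da0, par)
  }
  st <- config$stepper
  cfg <- stepper_config(scheme = st$scheme %||% "semi_implicit", dt = st$dt,
                        max_steps = st$max_steps %||% 100000L,
                        steady_rate_tol = st$steady_rate_tol %||% 1e-3,
                        steady_window = st$steady_window %||% 100L,
                        picard_tol = st$picard_tol %||% 1e-10,
                        picard_max_iter = st$picard_max_iter %||% 200L,
                        divergence_guard = st$divergence_guard %||% 2.5,
                        log_every = st$log_every %||% 100L)
  list(grid = g, params = par, phi0 = phi0, targets = tar, stepper = cfg,
       config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
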