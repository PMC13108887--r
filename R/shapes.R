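#' Analytic tanh initial shapes
#'
#' Shape specifications for the analytic initial conditions: ellipsoids
#' (including spheres) defined by
#' `phi0 = tanh((r0 - sqrt(sum((x_i - c_i)^2 / d_i))) / (sqrt(2) * eps))`
#' and unions of two spheres defined by
#' `phi0 = tanh(max(r1 - dist1, r2 - dist2) / (sqrt(2) * eps))`.
#'
#' @param kind One of `"ellipsoid"` or `"two_spheres"`.
#' @param center Numeric length-3 center (ellipsoid) .
#' @param denoms Length-3 positive denominators `d_i` of the quadratic form
#'   (for a sphere of radius R use `denoms = rep(1, 3)` and `r0 = R`).
#' @param r0 Level-set offset of the ellipsoid profile.
#' @param centers For `two_spheres`: a 2 x 3 matrix of sphere centers.
#' @param radii For `two_spheres`: the two radii.
#' @param epsilon Interface width used in the tanh profile.
#' @return A `shape_spec` object.
#' @export
shape_spec <- function(kind = c("ellipsoid", "two_spheres"),
                       center = c(0.5, 0.5, 0.5), denoms = rep(1, 3), r0 = 0.35,
                       centers = NULL, radii = NULL, epsilon = 0.04) {
  kind <- match.arg(kind)
  stopifnot(epsilon > 0)
  if (kind == "ellipsoid") {
    stopifnot(length(center) == 3L, length(denoms) == 3L,
              all(denoms > 0), r0 > 0)
  } else {
    stopifnot(is.matrix(centers), identical(dim(centers), c(2L, 3L)),
              length(radii) == 2L, all(radii > 0))
  }
  structure(list(kind = kind, center = center, denoms = denoms, r0 = r0,
                 centers = centers, radii = radii, epsilon = epsilon),
            class = "shape_spec")
}

# warn when the shape gets within 3*eps of the periodic domain boundary
check_clearance <- function(extent_max, grid, eps) {
  if (extent_max > grid$L / 2 - 3 * eps)
    warning(sprintf(
      "shape extent %.3g leaves < 3*eps clearance to the periodic boundary (L = %g)",
      extent_max, grid$L), call. = FALSE)
}

#' Tanh ellipsoid initial condition
#'
#' Builds the phase field
#' `tanh((r0 - sqrt(sum_i (x_i - c_i)^2 / d_i)) / (sqrt(2) eps))`:
#' approximately +1 deep inside the ellipsoid, -1 far outside, with the
#' zero level set on the ellipsoidal surface.
#'
#' @param grid A `pf_grid`.
#' @param spec A `shape_spec` of kind `"ellipsoid"`.
#' @return A `pf_field` with values in \[-1, 1\] (tanh profile).
#' @export
tanh_ellipsoid <- function(grid, spec) {
  stopifnot(inherits(spec, "shape_spec"), spec$kind == "ellipsoid")
  x <- grid$x
  qx <- (x - spec$center[1])^2 / spec$denoms[1]
  qy <- (x - spec$center[2])^2 / spec$denoms[2]
  qz <- (x - spec$center[3])^2 / spec$denoms[3]
  q <- sqrt(outer(outer(qx, qy, `+`), qz, `+`))
  check_clearance(spec$r0 * sqrt(max(spec$denoms)), grid, spec$epsilon)
  pf_field(tanh((spec$r0 - q) / (sqrt(2) * spec$epsilon)), grid)
}

#' Tanh sphere initial condition
#'
#' Convenience wrapper for a sphere of radius `R`: an ellipsoid with unit
#' denominators and `r0 = R`.
#'
#' @inheritParams tanh_ellipsoid
#' @param R Sphere radius.
#' @param center Length-3 center.
#' @param epsilon Interface width.
#' @export
tanh_sphere <- function(grid, R, center = rep(grid$L / 2, 3), epsilon) {
  tanh_ellipsoid(grid, shape_spec("ellipsoid", center = center,
                                  denoms = rep(1, 3), r0 = R,
                                  epsilon = epsilon))
}

#' Union-of-two-spheres initial condition
#'
#' Builds `tanh(max(r1 - d1, r2 - d2) / (sqrt(2) eps))` where `d1`, `d2`
#' are the distances to the two sphere centers. Used to seed deliberately
#' asymmetric (pear-like) configurations.
#'
#' @inheritParams tanh_ellipsoid
#' @param spec A `shape_spec` of kind `"two_spheres"`.
#' @export
tanh_two_spheres <- function(grid, spec) {
  stopifnot(inherits(spec, "shape_spec"), spec$kind == "two_spheres")
  x <- grid$x
  lev <- NULL
  for (s in 1:2) {
    cs <- spec$centers[s, ]
    d <- sqrt(outer(outer((x - cs[1])^2, (x - cs[2])^2, `+`),
                    (x - cs[3])^2, `+`))
    li <- spec$radii[s] - d
    lev <- if (is.null(lev)) li else pmax(lev, li)
  }
  check_clearance(max(spec$radii) + max(abs(spec$centers - grid$L / 2)),
                  grid, spec$epsilon)
  pf_field(tanh(lev / (sqrt(2) * spec$epsilon)), grid)
}

#' Build a field from a shape spec
#'
#' Dispatches on the `kind` of the spec.
#' @inheritParams tanh_ellipsoid
#' @export
make_shape <- function(grid, spec) {
  switch(spec$kind,
         ellipsoid = tanh_ellipsoid(grid, spec),
         two_spheres = tanh_two_spheres(grid, spec),
         stop("unknown shape kind: ", spec$kind))
}

#' Derive constraint targets from an initial field
#'
#' Experiments are specified by the reduced volume `v` and reduced area
#' difference `da0`. The area target is taken from the initial field,
#' `beta = A(phi0)` (the membrane area is conserved during the evolution),
#' and the remaining targets follow from the sphere normalizations:
#' `Rs = sqrt(beta / 4 pi)`, `alpha = v * (4 pi / 3) Rs^3`,
#' `DeltaA0 = da0 * 8 pi D Rs`.
#'
#' @param phi0 Initial `pf_field`.
#' @param v_target Reduced volume target (1 for a sphere).
#' @param da0_target Reduced area difference target (1 for a sphere).
#' @param params A `pf_params`.
#' @param alpha_from_field If `TRUE`, override `alpha` with the measured
#'   volume `V(phi0)` instead of deriving it from `v_target`.
#' @return A `pf_targets`.
#' @export
derive_constraint_targets <- function(phi0, v_target, da0_target, params,
                                      alpha_from_field = FALSE) {
  beta <- surface_area(phi0, params)
  if (!is.finite(beta) || beta <= sqrt(.Machine$double.eps))
    stop("degenerate initial field: no interface (area ~ 0)")
  Rs <- sqrt(beta / (4 * pi))
  alpha <- if (alpha_from_field) interior_volume(phi0)
           else v_target * (4 * pi / 3) * Rs^3
  dA0 <- da0_target * 8 * pi * params$D * Rs
  constraint_targets(alpha = alpha, beta = beta, dA0 = dA0)
}

#' Add a smooth random perturbation to a field
#'
#' Optional small-amplitude, band-limited noise for symmetry breaking.
#' Deterministic given `seed`.
#'
#' @param phi A `pf_field`.
#' @param amplitude Max-norm of the perturbation.
#' @param seed Integer seed.
#' @param kcut Spectral cutoff wavenumber index of the noise.
#' @export
add_perturbation <- function(phi, amplitude = 0.01, seed = 1L, kcut = 6) {
  g <- field_grid(phi)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  noise <- field_values(random_smooth_field(g, amplitude = amplitude, kcut = kcut))
  pf_field(field_values(phi) + noise, g)
}
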