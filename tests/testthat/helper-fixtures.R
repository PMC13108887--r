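# Synthetic voxel fixtures built in code: tanh profiles of composed implicit
# shapes, used by the observables and morphology tests.

# periodic coordinate arrays for a grid
coord_arrays <- function(grid) {
  N <- grid$N
  one <- rep(1, N)
  list(x = outer(outer(grid$x, one), one),
       y = outer(outer(one, grid$x), one),
       z = outer(outer(one, one), grid$x))
}

# union of tanh balls given centers (rows) and radii; `wrap` uses
# minimal-image distances so balls straddle the periodic boundary
balls_field <- function(grid, centers, radii, eps, wrap = FALSE) {
  co <- coord_arrays(grid)
  mind <- function(d) if (wrap) ((d + grid$L / 2) %% grid$L) - grid$L / 2 else d
  lev <- NULL
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(mind(co$x - centers[i, 1])^2 + mind(co$y - centers[i, 2])^2 +
              mind(co$z - centers[i, 3])^2)
    li <- radii[i] - d
    lev <- if (is.null(lev)) li else pmax(lev, li)
  }
  pf_field(tanh(lev / (sqrt(2) * eps)), grid)
}

# spherical shell (nested membrane): interior is {R1 < r < R2}
nested_field <- function(grid, R1, R2, eps, center = rep(grid$L / 2, 3)) {
  co <- coord_arrays(grid)
  r <- sqrt((co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2)
  lev <- pmin(r - R1, R2 - r)
  pf_field(tanh(lev / (sqrt(2) * eps)), grid)
}

# central ball plus capsule-shaped arms along unit directions `dirs` (rows)
lobed_field <- function(grid, core_r, arm_len, arm_r, dirs, eps,
                        center = rep(grid$L / 2, 3)) {
  co <- coord_arrays(grid)
  px <- co$x - center[1]; py <- co$y - center[2]; pz <- co$z - center[3]
  lev <- core_r - sqrt(px^2 + py^2 + pz^2)
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    t <- pmin(pmax(px * u[1] + py * u[2] + pz * u[3], 0), arm_len)
    d <- sqrt((px - t * u[1])^2 + (py - t * u[2])^2 + (pz - t * u[3])^2)
    lev <- pmax(lev, arm_r - d)
  }
  pf_field(tanh(lev / (sqrt(2) * eps)), grid)
}

# roll a pf_field by whole grid cells (periodic translation)
roll_field <- function(phi, s) {
  g <- field_grid(phi)
  v <- field_values(phi)
  idx <- lapply(1:3, function(ax) ((seq_len(g$N) - 1L - s[ax]) %% g$N) + 1L)
  pf_field(v[idx[[1]], idx[[2]], idx[[3]]], g)
}

# band-limited random smooth field (internal generator)
rand_smooth <- function(grid, amplitude = 0.5, kcut = 4) {
  vesiclepf:::random_smooth_field(grid, amplitude = amplitude, kcut = kcut)
}

# the oblate-ellipsoid initial condition of the discocyte experiment
discocyte_phi0 <- function(grid, eps = 0.04) {
  tanh_ellipsoid(grid, shape_spec("ellipsoid", denoms = c(0.5, 0.5, 0.1),
                                  r0 = 0.35, epsilon = eps))
}
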