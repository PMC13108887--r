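#' Finite-difference gradient consistency check
#'
#' For each energy component (bending `W`, ADE `G`, volume penalty `T1`,
#' area penalty `T2`), compares the Richardson-extrapolated central
#' directional derivative `(E(phi + t psi) - E(phi - t psi)) / (2 t)`
#' against the inner product of the implemented variational derivative with
#' `psi`, on random smooth band-limited field pairs. This certifies the
#' analytic derivative fields, including the area constant `3 sqrt(2) / 4`,
#' the penalty-derivative constant `3 sqrt(2) / 2`, and the ADE prefactor
#' `kbar pi / (2 A0 D^2)`.
#'
#' @param N Grid points per axis (default 32).
#' @param n_pairs Number of random `(phi, psi)` pairs.
#' @param seed RNG seed.
#' @param eps,C,kbar Model parameters of the check configuration.
#' @param t0 Base step of the central difference.
#' @return A data frame with one row per pair and component, containing the
#'   two derivative values and their relative error.
#' @export
verify_gradients <- function(N = 32, n_pairs = 5, seed = 1L,
                             eps = 0.1, C = 0.3, kbar = 1.4, t0 = 1e-2) {
  set.seed(seed)
  g <- make_grid(1, N)
  par <- model_params(eps = eps, kappa = 1, kbar = kbar, C = C,
                      M1 = 10, M2 = 10)
  rows <- list()
  for (p in seq_len(n_pairs)) {
    phi <- random_smooth_field(g, amplitude = 0.8)
    psi <- random_smooth_field(g, amplitude = 1.0)
    # targets offset from the current field so penalty gradients are nonzero
    tar <- constraint_targets(alpha = interior_volume(phi) * 0.9,
                              beta = surface_area(phi, par) * 1.1,
                              dA0 = delta_area(phi, par) - 0.1)
    energies <- list(
      W = function(f) bending_energy(f, par),
      G = function(f) ade_energy(f, par, tar),
      T1 = function(f) penalties(f, par, tar)[["T1"]],
      T2 = function(f) penalties(f, par, tar)[["T2"]])
    pd <- penalty_derivatives(phi, par, tar)
    derivs <- list(
      W = par$kappa * field_values(variational_g(phi, par)),
      G = field_values(variational_h(phi, par, tar)),
      T1 = field_values(pd$dT1),
      T2 = field_values(pd$dT2))
    vphi <- field_values(phi); vpsi <- field_values(psi)
    for (nm in names(energies)) {
      En <- energies[[nm]]
      dd <- function(t) {
        (En(pf_field(vphi + t * vpsi, g)) - En(pf_field(vphi - t * vpsi, g))) /
          (2 * t)
      }
      rich <- (4 * dd(t0 / 2) - dd(t0)) / 3
      inner <- g$h^3 * sum(derivs[[nm]] * vpsi)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = p, component = nm, fd = rich, analytic = inner,
        rel_error = abs(rich - inner) / max(abs(inner), abs(rich), 1e-12))
    }
  }
  do.call(rbind, rows)
}

#' Sphere oracle check
#'
#' For a tanh sphere of radius `R`, the diffuse-interface functionals must
#' converge to the closed-form sphere values: `V -> 4 pi R^3 / 3`,
#' `A -> 4 pi R^2`, `DeltaA -> 8 pi D R` (the sharp-interface geometric
#' relation for the leaflet area difference), and the reduced parameters
#' `(v, da) -> (1, 1)`.
#'
#' @param R Sphere radius.
#' @param eps Interface width.
#' @param N Grid points per axis.
#' @param L Domain edge length.
#' @return A data frame with measured value, analytic value and relative
#'   error for `V`, `A`, `dA`, `v`, `da`.
#' @export
verify_sphere <- function(R = 0.35, eps = 0.02, N = 64, L = 1) {
  g <- make_grid(L, N)
  par <- model_params(eps = eps)
  phi <- tanh_sphere(g, R = R, epsilon = eps)
  rp <- reduced_parameters(phi, par)
  measured <- c(V = interior_volume(phi), A = surface_area(phi, par),
                dA = delta_area(phi, par), v = unname(rp["v"]),
                da = unname(rp["da"]))
  exact <- c(V = 4 * pi * R^3 / 3, A = 4 * pi * R^2, dA = 8 * pi * par$D * R,
             v = 1, da = 1)
  data.frame(quantity = names(exact), measured = unname(measured),
             exact = unname(exact),
             rel_error = unname(abs(measured - exact) / abs(exact)))
}

#' Exact difference identities of the symmetrized forms
#'
#' Verifies, on random smooth field pairs, the identities that underlie the
#' discrete energy law: the energy differences `W(phi) - W(eta)`,
#' `G(phi) - G(eta)`, `V(phi) - V(eta)` and `A(phi) - A(eta)` must equal
#' the inner products of `phi - eta` with `kappa g(phi, eta)`,
#' `h(phi, eta)`, `1/2` and `-(3 sqrt 2 / 4) f(phi, eta)` respectively.
#'
#' @inheritParams verify_gradients
#' @return A data frame of relative errors per pair and identity.
#' @export
verify_identities <- function(N = 48, n_pairs = 5, seed = 1L,
                              eps = 0.1, C = 0.3, kbar = 1.4) {
  set.seed(seed)
  g <- make_grid(1, N)
  par <- model_params(eps = eps, kappa = 1.3, kbar = kbar, C = C,
                      M1 = 10, M2 = 10)
  rows <- list()
  for (p in seq_len(n_pairs)) {
    phi <- random_smooth_field(g, amplitude = 0.7)
    eta <- random_smooth_field(g, amplitude = 0.7)
    tar <- constraint_targets(alpha = interior_volume(phi) * 0.95,
                              beta = surface_area(phi, par) * 1.05,
                              dA0 = delta_area(phi, par) - 0.05)
    sf <- symmetrized_forms(phi, eta, par, tar)
    w <- field_values(phi) - field_values(eta)
    ip <- function(fld) g$h^3 * sum(w * field_values(fld))
    checks <- list(
      W = c(bending_energy(phi, par) - bending_energy(eta, par),
            par$kappa * ip(sf$g2)),
      G = c(ade_energy(phi, par, tar) - ade_energy(eta, par, tar), ip(sf$h2)),
      V = c(interior_volume(phi) - interior_volume(eta), g$h^3 * sum(w / 2)),
      A = c(surface_area(phi, par) - surface_area(eta, par),
            -AREA_CONST * ip(sf$f2)))
    for (nm in names(checks)) {
      lhs <- checks[[nm]][1]; rhs <- checks[[nm]][2]
      rows[[length(rows) + 1L]] <- data.frame(
        pair = p, identity = nm, lhs = lhs, rhs = rhs,
        rel_error = abs(lhs - rhs) / max(abs(lhs), abs(rhs), 1e-12))
    }
  }
  do.call(rbind, rows)
}

#' Discrete energy law of the fully implicit scheme
#'
#' Steps the fully implicit symmetrized scheme and checks, per step, the
#' discrete dissipation identity
#' `E(phi^{n+1}) - E(phi^n) + (1/dt) * integral((phi^{n+1} - phi^n)^2) = 0`.
#' The residual is exactly zero for the exact solution of the scheme; in
#' practice it is bounded by the Picard tolerance.
#'
#' @param N Grid points per axis.
#' @param eps Interface width.
#' @param dt Time step.
#' @param n_steps Number of steps to check.
#' @param v,da0 Reduced-parameter targets of the fixture.
#' @param picard_tol Picard stopping tolerance.
#' @return A data frame with per-step energies, increments and the law
#'   residual (absolute and relative to `|E|`).
#' @export
verify_energy_law <- function(N = 32, eps = 0.04, dt = 1e-7, n_steps = 20,
                              v = 0.8, da0 = 1.2, picard_tol = 1e-12) {
  g <- make_grid(1, N)
  par <- model_params(eps = eps)
  phi <- tanh_ellipsoid(g, shape_spec("ellipsoid",
                                      denoms = c(0.5, 0.5, 0.1), r0 = 0.35,
                                      epsilon = eps))
  tar <- derive_constraint_targets(phi, v, da0, par)
  cfg <- stepper_config("fully_implicit", dt = dt, picard_tol = picard_tol)
  rows <- list()
  E_prev <- total_energy(phi, par, tar)$E
  for (n in seq_len(n_steps)) {
    phi_new <- step_fully_implicit(phi, cfg, par, tar)
    E_new <- total_energy(phi_new, par, tar)$E
    incr <- g$h^3 * sum((field_values(phi_new) - field_values(phi))^2)
    resid <- E_new - E_prev + incr / dt
    rows[[n]] <- data.frame(step = n, E = E_new, dE = E_new - E_prev,
                            dissipation = incr / dt, residual = resid,
                            rel_residual = abs(resid) / abs(E_new))
    phi <- phi_new
    E_prev <- E_new
  }
  do.call(rbind, rows)
}

#' Temporal Cauchy convergence test of the semi-implicit scheme
#'
#' Runs the discocyte configuration (ellipsoidal initial shape, `v = 0.8`,
#' `da0 = 1.2`, `eps = 0.04`) to a fixed horizon `T` with a halving ladder
#' of time steps, and forms the Cauchy errors
#' `e_dt = ||phi_dt - phi_{dt/2}||_{L2}` at `T` together with the observed
#' orders `log2(e_dt / e_{dt/2})`. The semi-implicit scheme is first-order
#' consistent, so the orders approach 1.
#'
#' @param N Grid points per axis (default 64).
#' @param eps Interface width.
#' @param T_end Fixed time horizon.
#' @param dts Decreasing ladder of time steps; each must halve the previous
#'   and divide `T_end` exactly.
#' @param v,da0 Reduced-parameter targets.
#' @param quiet Suppress progress output.
#' @return A data frame with columns `dt`, `error`, `order` (`NA` where
#'   undefined: the error at the finest `dt` has no halved partner, the
#'   order needs two errors).
#' @export
verify_cauchy <- function(N = 64, eps = 0.04, T_end = 2e-6,
                          dts = c(2e-7, 1e-7, 5e-8, 2.5e-8, 1.25e-8),
                          v = 0.8, da0 = 1.2, quiet = FALSE) {
  stopifnot(length(dts) >= 3, all(diff(dts) < 0),
            all(abs(dts[-length(dts)] / dts[-1] - 2) < 1e-12))
  g <- make_grid(1, N)
  par <- model_params(eps = eps)
  phi0 <- tanh_ellipsoid(g, shape_spec("ellipsoid",
                                       denoms = c(0.5, 0.5, 0.1), r0 = 0.35,
                                       epsilon = eps))
  tar <- derive_constraint_targets(phi0, v, da0, par)
  finals <- vector("list", length(dts))
  for (i in seq_along(dts)) {
    dt <- dts[i]
    nst <- round(T_end / dt)
    stopifnot(abs(nst * dt - T_end) < 1e-15)
    sym <- implicit_symbol(g, par, dt)
    phi <- field_values(phi0)
    for (n in seq_len(nst)) phi <- si_step_raw(phi, g, par, tar, dt, sym)
    finals[[i]] <- phi
    if (!quiet) message(sprintf("dt = %.3g: %d steps done", dt, nst))
  }
  err <- rep(NA_real_, length(dts))
  for (i in seq_len(length(dts) - 1L))
    err[i] <- sqrt(g$h^3 * sum((finals[[i]] - finals[[i + 1L]])^2))
  ord <- rep(NA_real_, length(dts))
  for (i in 2:(length(dts) - 1L)) ord[i] <- log2(err[i - 1L] / err[i])
  data.frame(dt = dts, error = err, order = ord)
}

#' Spectral-operator exactness checks
#'
#' Laplacian of single Fourier modes against the closed-form eigenvalue,
#' and the apply/solve round trip of the implicit operator on a random
#' band-limited field.
#'
#' @param N Grid points per axis.
#' @param L Domain edge.
#' @param seed RNG seed.
#' @return A named numeric vector of relative errors.
#' @export
verify_spectral <- function(N = 32, L = 1, seed = 1L) {
  set.seed(seed)
  g <- make_grid(L, N)
  x3 <- outer(outer(g$x, rep(1, N)), rep(1, N))
  u <- pf_field(sin(2 * pi * x3 / L), g)
  lap_err <- max(abs(field_values(laplacian(u)) -
                     (-(2 * pi / L)^2) * field_values(u))) /
    max(abs((2 * pi / L)^2 * field_values(u)))
  w <- random_smooth_field(g, amplitude = 1)
  s0 <- 3; s2 <- -0.7; s4 <- 0.2
  rt <- solve_implicit_operator(apply_implicit_operator(w, s0, s2, s4),
                                s0, s2, s4)
  rt_err <- max(abs(field_values(rt) - field_values(w))) /
    max(abs(field_values(w)))
  c(laplacian_eigenfunction = lap_err, solve_round_trip = rt_err)
}
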