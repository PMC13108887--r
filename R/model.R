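#' Model parameters
#'
#' Physical and interface parameters of the phase-field vesicle model.
#'
#' @param eps Interface width (length units of the domain). The membrane is
#'   the zero level set of the phase field, with a tanh transition layer of
#'   width ~ `eps`.
#' @param kappa Bending modulus of the relaxed Helfrich energy.
#' @param kbar Area-difference-elasticity (ADE) modulus.
#' @param C Twice the spontaneous curvature `c0` (1/length). `C = 0`
#'   isolates the ADE effect.
#' @param D Separation between the neutral surfaces of the two leaflets;
#'   defaults to the bilayer-geometry coupling `D = (2/3) * eps`.
#' @param M1 Penalty coefficient enforcing the interior-volume target.
#' @param M2 Penalty coefficient enforcing the surface-area target.
#' @return An object of class `pf_params`.
#' @export
model_params <- function(eps, kappa = 1, kbar = 1.4, C = 0,
                         D = (2 / 3) * eps, M1 = 1e5, M2 = 1e4) {
  stopifnot(eps > 0, kappa > 0, kbar >= 0, D > 0, M1 >= 0, M2 >= 0)
  structure(list(eps = eps, kappa = kappa, kbar = kbar, C = C, D = D,
                 M1 = M1, M2 = M2), class = "pf_params")
}

#' @export
print.pf_params <- function(x, ...) {
  cat(sprintf("phase-field params: eps=%g kappa=%g kbar=%g C=%g D=%g M1=%g M2=%g\n",
              x$eps, x$kappa, x$kbar, x$C, x$D, x$M1, x$M2))
  invisible(x)
}

#' Constraint targets
#'
#' Targets for the soft volume/area penalties and the preferred leaflet
#' area difference of the ADE term. `A0` (the reference area in the ADE
#' prefactor) equals the area target `beta`; `Rs = sqrt(beta / (4 pi))` is
#' the radius of the sphere with area `beta`, used to non-dimensionalize
#' into reduced volume and reduced area difference.
#'
#' @param alpha Target interior volume.
#' @param beta Target membrane area (must be positive).
#' @param dA0 Preferred (relaxed) leaflet area difference.
#' @return An object of class `pf_targets` with fields `alpha`, `beta`,
#'   `dA0`, `A0` and `Rs`.
#' @seealso [derive_constraint_targets()] to obtain targets from an initial
#'   field and prescribed reduced parameters.
#' @export
constraint_targets <- function(alpha, beta, dA0) {
  if (!is.finite(beta) || beta <= 0) stop("invalid targets: beta must be > 0")
  structure(list(alpha = alpha, beta = beta, dA0 = dA0,
                 A0 = beta, Rs = sqrt(beta / (4 * pi))),
            class = "pf_targets")
}

#' @export
print.pf_targets <- function(x, ...) {
  cat(sprintf("targets: alpha=%.6g beta=%.6g dA0=%.6g (Rs=%.6g)\n",
              x$alpha, x$beta, x$dA0, x$Rs))
  invisible(x)
}

# --- raw-array energy/derivative kernels -----------------------------------
# All model quantities are assembled from a small set of shared intermediates
# (phi^2, Delta phi, fft(phi), ...) computed once per call in `model_state`.

# f  = eps*Lap(phi) - (1/eps)(phi^2-1) phi
# fc = eps*Lap(phi) - (1/eps)(phi^2-1)(phi + C*eps)
model_state <- function(phi, grid, par) {
  phik <- fftn(phi)
  lap_phi <- ifftn_re(-grid$ksq * phik)
  phi2 <- phi * phi
  eps <- par$eps
  V <- integrate_raw((phi + 1) / 2, grid)
  Bgrad <- gradsq_integral_raw(phik, grid)
  B <- (eps / 2) * Bgrad + integrate_raw((phi2 - 1)^2, grid) / (4 * eps)
  A <- AREA_CONST * B
  dA <- -(3 * par$D / 4) *
    integrate_raw((1 - phi2) * lap_phi + phi * (1 - phi2)^2 / eps^2, grid)
  list(phik = phik, lap_phi = lap_phi, phi2 = phi2, V = V, B = B, A = A, dA = dA)
}

AREA_CONST <- 3 * sqrt(2) / 4   # A = (3 sqrt 2 / 4) B: unit-profile area factor

f_raw <- function(phi, lap_phi, eps) eps * lap_phi - (phi * phi - 1) * phi / eps

fc_raw <- function(phi, lap_phi, eps, C) {
  eps * lap_phi - (phi * phi - 1) * (phi + C * eps) / eps
}

#' Allen-Cahn operator fields f and f_c
#'
#' `f_field()` returns `eps * Delta(phi) - (1/eps)(phi^2 - 1) phi`, the
#' variational derivative of the interface (area) functional up to the area
#' normalization; `fc_field()` is the same with the double-well shifted by
#' the spontaneous-curvature term, `eps * Delta(phi) -
#' (1/eps)(phi^2 - 1)(phi + C * eps)`. The two coincide when `C = 0`.
#'
#' @param phi A `pf_field` (the phase field).
#' @param params A `pf_params`.
#' @return A `pf_field`.
#' @export
f_field <- function(phi, params) {
  g <- field_grid(phi)
  v <- field_values(phi)
  pf_field(f_raw(v, lap_raw(v, g), params$eps), g)
}

#' @rdname f_field
#' @export
fc_field <- function(phi, params) {
  g <- field_grid(phi)
  v <- field_values(phi)
  pf_field(fc_raw(v, lap_raw(v, g), params$eps, params$C), g)
}

#' Bending energy
#'
#' The relaxed (diffuse-interface) Helfrich bending energy
#' `W = (kappa * eps / 2) * integral( (Delta phi - (1/eps^2)(phi^2-1)(phi + C eps))^2 )`,
#' identically equal to `(kappa / (2 eps)) * integral(f_c^2)`. Non-negative;
#' vanishes on uniform phases and on the planar equilibrium tanh profile
#' (when `C = 0`).
#'
#' @inheritParams f_field
#' @return A number, `>= 0`.
#' @export
bending_energy <- function(phi, params) {
  g <- field_grid(phi)
  v <- field_values(phi)
  fc <- fc_raw(v, lap_raw(v, g), params$eps, params$C)
  (params$kappa / (2 * params$eps)) * integrate_raw(fc^2, g)
}

#' Interior volume
#'
#' `V = integral((phi + 1) / 2)`: the volume of the region `{phi > 0}` in
#' the sharp-interface limit (`phi` is ~ +1 inside, -1 outside).
#'
#' @param phi A `pf_field`.
#' @return A number.
#' @export
interior_volume <- function(phi) {
  g <- field_grid(phi)
  integrate_raw((field_values(phi) + 1) / 2, g)
}

#' Membrane surface area
#'
#' Diffuse-interface area
#' `A = (3 sqrt(2) / 4) * integral( (eps/2)|grad phi|^2 + (1/(4 eps))(phi^2-1)^2 )`,
#' with the gradient term evaluated spectrally. The constant makes the
#' contribution of a unit-area planar tanh interface exactly 1.
#'
#' @inheritParams f_field
#' @return A number, `>= 0`.
#' @export
surface_area <- function(phi, params) {
  g <- field_grid(phi)
  v <- field_values(phi)
  phik <- fftn(v)
  B <- (params$eps / 2) * gradsq_integral_raw(phik, g) +
    integrate_raw((v * v - 1)^2, g) / (4 * params$eps)
  AREA_CONST * B
}

#' Leaflet area difference
#'
#' Phase-field area difference between the outer and inner leaflets,
#' `DeltaA = -(3 D / 4) * integral( (1 - phi^2) Delta phi + (1/eps^2) phi (1 - phi^2)^2 )`,
#' the diffuse-interface form of the sharp-interface relation
#' `DeltaA = D * integral_surface(2 H) dA`. With interior `{phi > 0}`, a
#' sphere of radius `R` gives `+8 pi D R`.
#'
#' @inheritParams f_field
#' @return A number.
#' @export
delta_area <- function(phi, params) {
  g <- field_grid(phi)
  v <- field_values(phi)
  st <- model_state(v, g, params)
  st$dA
}

#' Area-difference-elasticity energy
#'
#' `G = (kbar * pi / (2 A0 D^2)) * (DeltaA - DeltaA0)^2`, the non-local ADE
#' penalty on the deviation of the leaflet area difference from its relaxed
#' value.
#'
#' @inheritParams f_field
#' @param targets A `pf_targets`.
#' @return A number, `>= 0`.
#' @export
ade_energy <- function(phi, params, targets) {
  if (!is.finite(targets$A0) || targets$A0 <= 0)
    stop("invalid targets: A0 must be > 0")
  dA <- delta_area(phi, params)
  ade_prefactor(params, targets) * (dA - targets$dA0)^2
}

ade_prefactor <- function(par, tar) par$kbar * pi / (2 * tar$A0 * par$D^2)

#' Volume and area penalty energies
#'
#' `T1 = M1 (V(phi) - alpha)^2` and `T2 = M2 (A(phi) - beta)^2`.
#'
#' @inheritParams ade_energy
#' @return A named numeric vector `c(T1, T2)`.
#' @export
penalties <- function(phi, params, targets) {
  V <- interior_volume(phi)
  A <- surface_area(phi, params)
  c(T1 = params$M1 * (V - targets$alpha)^2,
    T2 = params$M2 * (A - targets$beta)^2)
}

#' Total energy with observables
#'
#' Assembles the penalized total energy
#' `E = W + G + M1 (V - alpha)^2 + M2 (A - beta)^2`
#' and the geometric observables of the current field: interior volume `V`,
#' area `A`, leaflet area difference `dA`, and the reduced parameters
#' `v = V / ((4 pi / 3) (sqrt(A / 4 pi))^3)` and
#' `da = dA / (8 pi D sqrt(A / 4 pi))`.
#'
#' @inheritParams ade_energy
#' @return An object of class `energy_breakdown`: a list with fields
#'   `W`, `G`, `T1`, `T2`, `E`, `V`, `A`, `dA`, `v`, `da`.
#' @export
total_energy <- function(phi, params, targets) {
  g <- field_grid(phi)
  v <- field_values(phi)
  st <- model_state(v, g, params)
  fc <- fc_raw(v, st$lap_phi, params$eps, params$C)
  W <- (params$kappa / (2 * params$eps)) * integrate_raw(fc^2, g)
  G <- ade_prefactor(params, targets) * (st$dA - targets$dA0)^2
  T1 <- params$M1 * (st$V - targets$alpha)^2
  T2 <- params$M2 * (st$A - targets$beta)^2
  Rs <- sqrt(st$A / (4 * pi))
  structure(list(W = W, G = G, T1 = T1, T2 = T2, E = W + G + T1 + T2,
                 V = st$V, A = st$A, dA = st$dA,
                 v = st$V / ((4 * pi / 3) * Rs^3),
                 da = st$dA / (8 * pi * params$D * Rs)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("E = %.8g  (W %.6g | G %.6g | T1 %.6g | T2 %.6g)\n",
              x$E, x$W, x$G, x$T1, x$T2))
  cat(sprintf("V = %.6g  A = %.6g  dA = %.6g  v = %.4f  da = %.4f\n",
              x$V, x$A, x$dA, x$v, x$da))
  invisible(x)
}

#' @export
as.data.frame.energy_breakdown <- function(x, ...) {
  as.data.frame(unclass(x))
}

# --- variational derivatives ------------------------------------------------

# g = Lap(fc) - (1/eps^2)(3 phi^2 + 2 C eps phi - 1) fc ; dW/dphi = kappa g
variational_g_raw <- function(phi, lap_phi, grid, par) {
  eps <- par$eps; C <- par$C
  fc <- fc_raw(phi, lap_phi, eps, C)
  lap_raw(fc, grid) - (3 * phi * phi + 2 * C * eps * phi - 1) * fc / eps^2
}

#' Variational derivative of the bending energy
#'
#' Returns `g = Delta f_c - (1/eps^2)(3 phi^2 + 2 C eps phi - 1) f_c`, so
#' that `dW/dphi = kappa * g`.
#'
#' @inheritParams f_field
#' @return A `pf_field`.
#' @export
variational_g <- function(phi, params) {
  g <- field_grid(phi)
  v <- field_values(phi)
  pf_field(variational_g_raw(v, lap_raw(v, g), g, params), g)
}

# shared bracket of dG/dphi: -2 phi Lap(phi) - Lap(phi^2) + (1/eps^2)(1 - 6 phi^2 + 5 phi^4)
h_bracket_raw <- function(phi, phi2, lap_phi, lap_phi2, eps) {
  -2 * phi * lap_phi - lap_phi2 + (1 - 6 * phi2 + 5 * phi2 * phi2) / eps^2
}

#' Variational derivative of the ADE energy
#'
#' Returns
#' `h = -(3 kbar pi / (4 A0 D)) (DeltaA - DeltaA0) *
#'  (-2 phi Delta phi - Delta(phi^2) + (1/eps^2)(1 - 6 phi^2 + 5 phi^4))`.
#' The global scalar `DeltaA - DeltaA0` is computed once per call.
#'
#' @inheritParams ade_energy
#' @return A `pf_field`.
#' @export
variational_h <- function(phi, params, targets) {
  g <- field_grid(phi)
  v <- field_values(phi)
  st <- model_state(v, g, params)
  lap_phi2 <- lap_raw(st$phi2, g)
  br <- h_bracket_raw(v, st$phi2, st$lap_phi, lap_phi2, params$eps)
  pref <- -(3 * params$kbar * pi / (4 * targets$A0 * params$D)) *
    (st$dA - targets$dA0)
  pf_field(pref * br, g)
}

#' Variational derivatives of the penalty terms
#'
#' `dT1/dphi = M1 (V - alpha)` (a constant field) and
#' `dT2/dphi = (3 sqrt(2) / 2) M2 (A - beta) (-f)`. The global scalars
#' `V - alpha` and `A - beta` are evaluated once per call.
#'
#' @inheritParams ade_energy
#' @return A list with `pf_field` components `dT1` and `dT2`.
#' @export
penalty_derivatives <- function(phi, params, targets) {
  g <- field_grid(phi)
  v <- field_values(phi)
  st <- model_state(v, g, params)
  f <- f_raw(v, st$lap_phi, params$eps)
  dT1 <- params$M1 * (st$V - targets$alpha)
  dT2 <- 2 * AREA_CONST * params$M2 * (st$A - targets$beta) * (-f)
  list(dT1 = pf_field(array(dT1, dim(v)), g), dT2 = pf_field(dT2, g))
}

# --- two-argument symmetrized forms (fully implicit scheme) -----------------

# f(phi,eta) = (eps/2) Lap(phi+eta) - (1/4eps)(phi^2+eta^2-2)(phi+eta)
f2_raw <- function(phi, eta, grid, eps) {
  (eps / 2) * lap_raw(phi + eta, grid) -
    (phi * phi + eta * eta - 2) * (phi + eta) / (4 * eps)
}

# g(phi,eta) = (1/2) Lap(fc(phi)+fc(eta))
#   - (1/2eps^2)(phi^2+phi*eta+eta^2+C eps (phi+eta) - 1)(fc(phi)+fc(eta))
g2_raw <- function(phi, eta, lap_phi, lap_eta, grid, par) {
  eps <- par$eps; C <- par$C
  fcsum <- fc_raw(phi, lap_phi, eps, C) + fc_raw(eta, lap_eta, eps, C)
  0.5 * lap_raw(fcsum, grid) -
    (phi * phi + phi * eta + eta * eta + C * eps * (phi + eta) - 1) * fcsum /
      (2 * eps^2)
}

# Symmetric bracket of the two-argument ADE derivative. This is the unique
# swap-symmetric form satisfying the exact difference identity
#   DeltaA(phi) - DeltaA(eta) = -(3D/4) * integral((phi - eta) * bracket);
# it reduces to -2 phi Lap phi - Lap(phi^2) + (1/eps^2)(1 - 6 phi^2 + 5 phi^4)
# at phi = eta.
h2_bracket_raw <- function(phi, eta, lap_phi, lap_eta, grid, eps) {
  s <- phi + eta
  poly <- 1 - 2 * (phi * phi + phi * eta + eta * eta) +
    (phi^4 + phi^3 * eta + phi^2 * eta^2 + phi * eta^3 + eta^4)
  -0.5 * s * (lap_phi + lap_eta) - 0.5 * lap_raw(phi * phi + eta * eta, grid) +
    poly / eps^2
}

#' Symmetrized two-argument forms for the fully implicit scheme
#'
#' Returns the symmetric-in-arguments forms `f(phi, eta)`, `g(phi, eta)` and
#' `h(phi, eta)` used by the fully implicit stepper, chosen so that the
#' exact difference identities
#' `W(phi) - W(eta) = integral((phi - eta) kappa g(phi, eta))`,
#' `G(phi) - G(eta) = integral((phi - eta) h(phi, eta))` and
#' `A(phi) - A(eta) = integral((phi - eta) (-(3 sqrt 2 / 4)) f(phi, eta))`
#' hold, which is what yields the discrete energy dissipation law. Each form
#' reduces to its single-argument counterpart (`f_field`, `variational_g`,
#' `variational_h`) when `eta = phi`.
#'
#' @param phi,eta `pf_field`s on the same grid.
#' @inheritParams ade_energy
#' @return A list with `pf_field` components `f2`, `g2`, `h2`.
#' @export
symmetrized_forms <- function(phi, eta, params, targets) {
  g <- field_grid(phi)
  g2grid <- field_grid(eta)
  if (!identical(g$N, g2grid$N) || !identical(g$L, g2grid$L))
    stop("phi and eta must live on the same grid")
  p <- field_values(phi); e <- field_values(eta)
  lap_p <- lap_raw(p, g); lap_e <- lap_raw(e, g)
  f2 <- f2_raw(p, e, g, params$eps)
  g2 <- g2_raw(p, e, lap_p, lap_e, g, params)
  dAp <- delta_area(phi, params); dAe <- delta_area(eta, params)
  br <- h2_bracket_raw(p, e, lap_p, lap_e, g, params$eps)
  h2 <- -(3 * params$kbar * pi / (8 * targets$A0 * params$D)) *
    (dAp + dAe - 2 * targets$dA0) * br
  list(f2 = pf_field(f2, g), g2 = pf_field(g2, g), h2 = pf_field(h2, g))
}
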