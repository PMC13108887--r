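#' Time-stepper configuration
#'
#' @param scheme One of `"semi_implicit"` (default; linearly implicit
#'   spectral scheme), `"forward_euler"`, or `"fully_implicit"`
#'   (symmetrized scheme with the discrete energy law, solved by Picard
#'   iteration preconditioned by the semi-implicit operator).
#' @param dt Time step (> 0).
#' @param max_steps Maximum number of steps for [run_simulation()].
#' @param steady_rate_tol Steady-state threshold on the max-norm rate
#'   `max|phi^{n+1} - phi^n| / dt` (phi-units per unit time).
#' @param steady_window Number of consecutive steps the rate criterion must
#'   hold before declaring a steady state.
#' @param picard_tol Max-norm stopping tolerance of the Picard iteration
#'   (fully implicit scheme only).
#' @param picard_max_iter Maximum Picard iterations per step.
#' @param divergence_guard Abort when `max|phi|` exceeds this value (phi
#'   physically lives near \[-1, 1\]).
#' @param log_every Energy-log cadence (steps) of [run_simulation()].
#' @return A `stepper_config` object.
#' @export
stepper_config <- function(scheme = c("semi_implicit", "forward_euler",
                                      "fully_implicit"),
                           dt, max_steps = 100000L,
                           steady_rate_tol = 1e-3, steady_window = 100L,
                           picard_tol = 1e-10, picard_max_iter = 200L,
                           divergence_guard = 2.5, log_every = 100L) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0, max_steps >= 0, steady_rate_tol > 0, steady_window >= 1,
            picard_tol > 0, picard_max_iter >= 1, divergence_guard > 1,
            log_every >= 1)
  structure(list(scheme = scheme, dt = dt, max_steps = as.integer(max_steps),
                 steady_rate_tol = steady_rate_tol,
                 steady_window = as.integer(steady_window),
                 picard_tol = picard_tol,
                 picard_max_iter = as.integer(picard_max_iter),
                 divergence_guard = divergence_guard,
                 log_every = as.integer(log_every)),
            class = "stepper_config")
}

# symbol of the implicit linear operator 1/dt + kappa*(eps*Lap^2 + (2/eps)*Lap)
implicit_symbol <- function(grid, par, dt) {
  sym <- 1 / dt + par$kappa * (par$eps * grid$ksq^2 - (2 / par$eps) * grid$ksq)
  if (any(sym <= 0)) {
    bad <- which(sym <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "semi-implicit operator loses positivity at mode (%d,%d,%d): dt too large",
      grid$freqs[bad[1L]], grid$freqs[bad[2L]], grid$freqs[bad[3L]]))
  }
  sym
}

guard_raw <- function(phi, guard, step) {
  if (!all(is.finite(phi)) || max(abs(phi)) > guard)
    stop(sprintf("solution blow-up at step %d (max|phi| = %.3g)",
                 step, suppressWarnings(max(abs(phi)))))
}

# full gradient-flow right-hand side and diagnostics at phi
rhs_raw <- function(phi, grid, par, tar) {
  st <- model_state(phi, grid, par)
  kg <- par$kappa * variational_g_raw(phi, st$lap_phi, grid, par)
  lap_phi2 <- lap_raw(st$phi2, grid)
  br <- h_bracket_raw(phi, st$phi2, st$lap_phi, lap_phi2, par$eps)
  hfield <- -(3 * par$kbar * pi / (4 * tar$A0 * par$D)) * (st$dA - tar$dA0) * br
  f <- f_raw(phi, st$lap_phi, par$eps)
  dT1 <- par$M1 * (st$V - tar$alpha)
  dT2 <- 2 * AREA_CONST * par$M2 * (st$A - tar$beta) * (-f)
  rhs <- -(kg + hfield + dT1 + dT2)
  if (!all(is.finite(rhs))) stop("non-finite gradient-flow right-hand side")
  rhs
}

#' Gradient-flow right-hand side
#'
#' The Allen-Cahn relaxation `phi_t = -dE/dphi`, assembled as
#' `-(kappa g + h + dT1/dphi + dT2/dphi)`. A negative-gradient direction:
#' for small `tau > 0`, `E(phi + tau * rhs) < E(phi)` away from equilibria.
#'
#' @param phi A `pf_field`.
#' @param params A `pf_params`.
#' @param targets A `pf_targets`.
#' @return A `pf_field`.
#' @export
gradient_flow_rhs <- function(phi, params, targets) {
  g <- field_grid(phi)
  pf_field(rhs_raw(field_values(phi), g, params, targets), g)
}

#' One forward Euler step
#'
#' `phi^{n+1} = phi^n + dt * rhs(phi^n)`. Conditionally stable: requires a
#' very small `dt` (the biharmonic term limits `dt ~ eps * h^4`).
#'
#' @inheritParams gradient_flow_rhs
#' @param cfg A `stepper_config` (only `dt` and `divergence_guard` are used).
#' @export
step_forward_euler <- function(phi, cfg, params, targets) {
  g <- field_grid(phi)
  v <- field_values(phi)
  out <- v + cfg$dt * rhs_raw(v, g, params, targets)
  guard_raw(out, cfg$divergence_guard, 1L)
  pf_field(out, g)
}

# one semi-implicit step on raw arrays; sym precomputed by the caller
si_step_raw <- function(phi, grid, par, tar, dt, sym) {
  eps <- par$eps; C <- par$C
  phik <- fftn(phi)
  lap_phi <- ifftn_re(-grid$ksq * phik)
  phi2 <- phi * phi
  phi3 <- phi2 * phi
  lap_phi2 <- lap_raw(phi2, grid)
  lap_phi3 <- lap_raw(phi3, grid)
  # observables entering the explicitly treated non-local terms
  V <- integrate_raw((phi + 1) / 2, grid)
  B <- (eps / 2) * gradsq_integral_raw(phik, grid) +
    integrate_raw((phi2 - 1)^2, grid) / (4 * eps)
  A <- AREA_CONST * B
  dA <- -(3 * par$D / 4) *
    integrate_raw((1 - phi2) * lap_phi + phi * (1 - phi2)^2 / eps^2, grid)
  br <- h_bracket_raw(phi, phi2, lap_phi, lap_phi2, eps)
  hfield <- -(3 * par$kbar * pi / (4 * tar$A0 * par$D)) * (dA - tar$dA0) * br
  f <- f_raw(phi, lap_phi, eps)
  dT1 <- par$M1 * (V - tar$alpha)
  dT2 <- 2 * AREA_CONST * par$M2 * (A - tar$beta) * (-f)
  # explicit remainder of g^{n,n+1} (everything but eps*Lap^2 + (2/eps)*Lap)
  E_expl <- -lap_phi3 / eps - C * lap_phi2 - (3 / eps) * phi2 * lap_phi -
    2 * C * phi * lap_phi +
    (3 * phi2 + 2 * C * eps * phi - 1) * (phi2 - 1) * (phi + C * eps) / eps^3
  rhs <- phi / dt - par$kappa * E_expl - hfield - dT1 - dT2
  ifftn_re(fftn(rhs) / sym)
}

#' One semi-implicit (linearly implicit spectral) step
#'
#' Treats the stiff linear part of the bending force,
#' `kappa (eps Delta^2 + (2/eps) Delta) phi^{n+1}`, implicitly and all
#' remaining nonlinear, ADE and penalty terms explicitly at `phi^n`; the
#' linear system is diagonal in Fourier space. First-order accurate in
#' time; consistent with the same gradient flow as the other schemes.
#'
#' @inheritParams step_forward_euler
#' @export
step_semi_implicit <- function(phi, cfg, params, targets) {
  g <- field_grid(phi)
  sym <- implicit_symbol(g, params, cfg$dt)
  out <- si_step_raw(field_values(phi), g, params, targets, cfg$dt, sym)
  guard_raw(out, cfg$divergence_guard, 1L)
  pf_field(out, g)
}

# one fully implicit step by Picard iteration, preconditioned by the
# semi-implicit linear operator; returns list(phi, iters, delta)
fi_step_raw <- function(phi_n, grid, par, tar, cfg, sym) {
  eps <- par$eps; C <- par$C; dt <- cfg$dt
  lin <- par$kappa * (eps * grid$ksq^2 - (2 / eps) * grid$ksq)  # symbol of the preconditioner
  # quantities at phi^n, fixed over the iteration
  phik_n <- fftn(phi_n)
  lap_n <- ifftn_re(-grid$ksq * phik_n)
  phi2_n <- phi_n * phi_n
  fc_n <- fc_raw(phi_n, lap_n, eps, C)
  V_n <- integrate_raw((phi_n + 1) / 2, grid)
  A_n <- AREA_CONST * ((eps / 2) * gradsq_integral_raw(phik_n, grid) +
                       integrate_raw((phi2_n - 1)^2, grid) / (4 * eps))
  dA_n <- -(3 * par$D / 4) *
    integrate_raw((1 - phi2_n) * lap_n + phi_n * (1 - phi2_n)^2 / eps^2, grid)
  m <- phi_n
  delta <- Inf
  for (it in seq_len(cfg$picard_max_iter)) {
    phik_m <- fftn(m)
    lap_m <- ifftn_re(-grid$ksq * phik_m)
    phi2_m <- m * m
    fc_m <- fc_raw(m, lap_m, eps, C)
    V_m <- integrate_raw((m + 1) / 2, grid)
    A_m <- AREA_CONST * ((eps / 2) * gradsq_integral_raw(phik_m, grid) +
                         integrate_raw((phi2_m - 1)^2, grid) / (4 * eps))
    dA_m <- -(3 * par$D / 4) *
      integrate_raw((1 - phi2_m) * lap_m + m * (1 - phi2_m)^2 / eps^2, grid)
    fcsum <- fc_n + fc_m
    g2 <- 0.5 * lap_raw(fcsum, grid) -
      (phi2_n + phi_n * m + phi2_m + C * eps * (phi_n + m) - 1) * fcsum /
        (2 * eps^2)
    poly <- 1 - 2 * (phi2_n + phi_n * m + phi2_m) +
      (phi2_n^2 + phi2_n * phi_n * m + phi2_n * phi2_m + phi_n * m * phi2_m +
       phi2_m^2)
    br <- -0.5 * (phi_n + m) * (lap_n + lap_m) -
      0.5 * lap_raw(phi2_n + phi2_m, grid) + poly / eps^2
    h2 <- -(3 * par$kbar * pi / (8 * tar$A0 * par$D)) *
      (dA_n + dA_m - 2 * tar$dA0) * br
    f2 <- (eps / 2) * (lap_n + lap_m) -
      (phi2_n + phi2_m - 2) * (phi_n + m) / (4 * eps)
    rhs2 <- par$kappa * g2 + h2 + (par$M1 / 2) * (V_n + V_m - 2 * tar$alpha) +
      AREA_CONST * par$M2 * (A_n + A_m - 2 * tar$beta) * (-f2)
    newk <- (fftn(phi_n / dt - rhs2) + lin * phik_m) / sym
    m_new <- ifftn_re(newk)
    delta <- max(abs(m_new - m))
    if (!is.finite(delta))
      stop("Picard iteration diverged (non-finite update): dt too large")
    m <- m_new
    if (delta <= cfg$picard_tol) return(list(phi = m, iters = it, delta = delta))
  }
  stop(sprintf(
    "Picard iteration failed to converge in %d iterations (last update %.3g): dt too large",
    cfg$picard_max_iter, delta))
}

#' One fully implicit (symmetrized) step
#'
#' Solves the implicit scheme built from the symmetrized two-argument forms
#' (see [symmetrized_forms()]) with averaged penalty factors
#' `(V(phi^{n+1}) + V(phi^n) - 2 alpha)/2` and
#' `(A(phi^{n+1}) + A(phi^n) - 2 beta)/2`. Its solutions satisfy the exact
#' discrete energy law
#' `E(phi^{n+1}) - E(phi^n) + (1/dt) * integral((phi^{n+1} - phi^n)^2) = 0`
#' up to the Picard tolerance, so the energy never increases. The nonlinear
#' system is solved by Picard (fixed-point) iteration preconditioned by the
#' semi-implicit linear operator.
#'
#' @inheritParams step_forward_euler
#' @export
step_fully_implicit <- function(phi, cfg, params, targets) {
  g <- field_grid(phi)
  sym <- implicit_symbol(g, params, cfg$dt)
  res <- fi_step_raw(field_values(phi), g, params, targets, cfg, sym)
  guard_raw(res$phi, cfg$divergence_guard, 1L)
  pf_field(res$phi, g)
}

#' Run a gradient-flow simulation
#'
#' Iterates the configured stepper from `phi0`, logging an energy/observable
#' record every `cfg$log_every` steps (and at the initial and final states),
#' until a steady state is detected, `max_steps` is reached, or the solver
#' fails. Steady state means the max-norm rate
#' `max|phi^{n+1} - phi^n| / dt <= steady_rate_tol` for `steady_window`
#' consecutive steps. Deterministic for a given configuration.
#'
#' @inheritParams gradient_flow_rhs
#' @param phi0 Initial `pf_field`.
#' @param cfg A `stepper_config`.
#' @param callback Optional `function(step, time, phi, energy)` invoked at
#'   every log point.
#' @return A `vesicle_sim` object: list with `final_field`, `energy_series`
#'   (data frame with columns `step`, `t`, `W`, `G`, `T1`, `T2`, `E`, `V`,
#'   `A`, `dA`, `v`, `da`), `steps_taken`, `converged`,
#'   `termination_reason`, and the run configuration.
#' @export
run_simulation <- function(phi0, cfg, params, targets, callback = NULL) {
  g <- field_grid(phi0)
  phi <- field_values(phi0)
  sym <- if (cfg$scheme %in% c("semi_implicit", "fully_implicit"))
    implicit_symbol(g, params, cfg$dt) else NULL
  series <- list()
  log_state <- function(step, phi_arr) {
    eb <- total_energy(pf_field(phi_arr, g), params, targets)
    row <- data.frame(step = step, t = step * cfg$dt, as.data.frame(eb))
    series[[length(series) + 1L]] <<- row
    if (!is.null(callback)) callback(step, step * cfg$dt, pf_field(phi_arr, g), eb)
    eb
  }
  log_state(0L, phi)
  steady_run <- 0L
  converged <- FALSE
  reason <- "max_steps"
  steps_done <- 0L
  if (cfg$max_steps > 0L) {
    for (n in seq_len(cfg$max_steps)) {
      phi_new <- tryCatch(
        switch(cfg$scheme,
               forward_euler = phi + cfg$dt * rhs_raw(phi, g, params, targets),
               semi_implicit = si_step_raw(phi, g, params, targets, cfg$dt, sym),
               fully_implicit = fi_step_raw(phi, g, params, targets, cfg, sym)$phi),
        error = function(e) e)
      if (inherits(phi_new, "error")) {
        reason <- paste0("error: ", conditionMessage(phi_new))
        break
      }
      if (!all(is.finite(phi_new)) || max(abs(phi_new)) > cfg$divergence_guard) {
        reason <- sprintf("diverged at step %d (max|phi| = %.3g)", n,
                          suppressWarnings(max(abs(phi_new))))
        break
      }
      rate <- max(abs(phi_new - phi)) / cfg$dt
      phi <- phi_new
      steps_done <- n
      steady_run <- if (rate <= cfg$steady_rate_tol) steady_run + 1L else 0L
      at_log <- (n %% cfg$log_every == 0L)
      if (steady_run >= cfg$steady_window) {
        converged <- TRUE
        reason <- "steady_state"
        log_state(n, phi)
        break
      }
      if (at_log) log_state(n, phi)
    }
    if (!converged && !startsWith(reason, "error") && !startsWith(reason, "diverged") &&
        steps_done %% cfg$log_every != 0L)
      log_state(steps_done, phi)
  }
  structure(list(final_field = pf_field(phi, g),
                 energy_series = do.call(rbind, series),
                 steps_taken = steps_done,
                 converged = converged,
                 termination_reason = reason,
                 config = cfg, params = params, targets = targets),
            class = "vesicle_sim")
}

#' @export
print.vesicle_sim <- function(x, ...) {
  es <- x$energy_series
  cat(sprintf("vesicle gradient-flow run: %s scheme, %d steps (%s)\n",
              x$config$scheme, x$steps_taken, x$termination_reason))
  cat(sprintf("energy %.6g -> %.6g; final v = %.4f, da = %.4f\n",
              es$E[1L], es$E[nrow(es)], es$v[nrow(es)], es$da[nrow(es)]))
  invisible(x)
}

#' @export
summary.vesicle_sim <- function(object, ...) {
  es <- object$energy_series
  last <- es[nrow(es), ]
  cat(sprintf("Scheme: %s, dt = %g, steps: %d (%s, converged: %s)\n",
              object$config$scheme, object$config$dt, object$steps_taken,
              object$termination_reason, object$converged))
  cat(sprintf("Initial E = %.8g, final E = %.8g (drop %.3g)\n",
              es$E[1L], last$E, es$E[1L] - last$E))
  cat(sprintf("Final observables: V = %.6g, A = %.6g, dA = %.6g, v = %.4f, da = %.4f\n",
              last$V, last$A, last$dA, last$v, last$da))
  max_inc <- if (nrow(es) > 1) max(diff(es$E)) else NA_real_
  cat(sprintf("Max energy increase between log points: %.3g\n", max_inc))
  invisible(object)
}

#' Energy-evolution plot of a run
#'
#' @param x A `vesicle_sim`.
#' @param components Plot the component energies in addition to the total.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.vesicle_sim <- function(x, components = FALSE, ...) {
  es <- x$energy_series
  if (components) {
    graphics::matplot(es$t, cbind(es$E, es$W, es$G, es$T1, es$T2), type = "l",
                      lty = 1, xlab = "t", ylab = "energy", ...)
    graphics::legend("topright", c("E", "W", "G", "T1", "T2"), col = 1:5, lty = 1)
  } else {
    graphics::plot(es$t, es$E, type = "l", xlab = "t", ylab = "total energy E", ...)
  }
  invisible(x)
}
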