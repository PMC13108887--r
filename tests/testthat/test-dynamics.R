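# small shared fixture: the oblate-ellipsoid configuration on a coarse grid
dyn_fixture <- function(N = 24, eps = 0.04, v = 0.8, da0 = 1.2) {
  g <- make_grid(1, N)
  par <- model_params(eps = eps)
  phi <- suppressWarnings(discocyte_phi0(g, eps))
  tar <- derive_constraint_targets(phi, v, da0, par)
  list(g = g, par = par, phi = phi, tar = tar)
}

test_that("gradient-flow RHS assembles the four force pieces and descends", {
  fx <- dyn_fixture()
  rhs <- gradient_flow_rhs(fx$phi, fx$par, fx$tar)
  pd <- penalty_derivatives(fx$phi, fx$par, fx$tar)
  manual <- -(fx$par$kappa * field_values(variational_g(fx$phi, fx$par)) +
              field_values(variational_h(fx$phi, fx$par, fx$tar)) +
              field_values(pd$dT1) + field_values(pd$dT2))
  expect_equal(field_values(rhs), manual, tolerance = 1e-12)

  # uniform interior phase with matched targets is an equilibrium
  g <- fx$g
  phi1 <- pf_field(1, g)
  tar1 <- constraint_targets(alpha = g$L^3, beta = 1, dA0 = 0)
  tar1$beta <- 0  # exact uniform-phase area target
  rhs1 <- gradient_flow_rhs(phi1, fx$par, tar1)
  expect_equal(max(abs(field_values(rhs1))), 0, tolerance = 1e-10)

  # descent property of the negative gradient
  E0 <- total_energy(fx$phi, fx$par, fx$tar)$E
  tau <- 1e-9
  stepped <- pf_field(field_values(fx$phi) + tau * field_values(rhs), fx$g)
  expect_lt(total_energy(stepped, fx$par, fx$tar)$E, E0)
})

test_that("forward Euler is the exact explicit update and descends at tiny dt", {
  fx <- dyn_fixture()
  cfg <- stepper_config("forward_euler", dt = 1e-9)
  out <- step_forward_euler(fx$phi, cfg, fx$par, fx$tar)
  expect_equal(field_values(out),
               field_values(fx$phi) +
                 1e-9 * field_values(gradient_flow_rhs(fx$phi, fx$par, fx$tar)),
               tolerance = 1e-14)

  sim <- run_simulation(fx$phi, stepper_config("forward_euler", dt = 1e-9,
                                               max_steps = 10, log_every = 1),
                        fx$par, fx$tar)
  expect_equal(sim$steps_taken, 10L)
  expect_true(all(diff(sim$energy_series$E) < 0))
})

test_that("semi-implicit splitting is consistent: one step matches forward Euler to O(dt^2)", {
  fx <- dyn_fixture(N = 16, eps = 0.08)
  diffs <- sapply(c(1e-8, 5e-9, 2.5e-9), function(dt) {
    cfgd <- stepper_config("semi_implicit", dt = dt)
    si <- step_semi_implicit(fx$phi, cfgd, fx$par, fx$tar)
    fe <- step_forward_euler(fx$phi, stepper_config("forward_euler", dt = dt),
                             fx$par, fx$tar)
    max(abs(field_values(si) - field_values(fe))) / dt
  })
  # ||SI - FE|| / dt shrinks linearly with dt
  expect_lt(diffs[2] / diffs[1], 0.6)
  expect_lt(diffs[3] / diffs[2], 0.6)
})

test_that("steppers share equilibria: uniform state is a fixed point", {
  g <- make_grid(1, 16)
  par <- model_params(eps = 0.08)
  phi1 <- pf_field(1, g)
  tar1 <- constraint_targets(alpha = 1, beta = 1, dA0 = 0)
  tar1$beta <- 0
  for (scheme in c("forward_euler", "semi_implicit", "fully_implicit")) {
    cfg <- stepper_config(scheme, dt = 1e-7)
    out <- switch(scheme,
                  forward_euler = step_forward_euler(phi1, cfg, par, tar1),
                  semi_implicit = step_semi_implicit(phi1, cfg, par, tar1),
                  fully_implicit = step_fully_implicit(phi1, cfg, par, tar1))
    expect_equal(field_values(out), field_values(phi1), tolerance = 1e-9)
  }
})

test_that("fully implicit scheme obeys the discrete energy law and agrees with semi-implicit as dt -> 0", {
  fx <- dyn_fixture(N = 16, eps = 0.08)
  dt <- 1e-7
  cfg <- stepper_config("fully_implicit", dt = dt, picard_tol = 1e-13)
  phi_new <- step_fully_implicit(fx$phi, cfg, fx$par, fx$tar)
  E0 <- total_energy(fx$phi, fx$par, fx$tar)$E
  E1 <- total_energy(phi_new, fx$par, fx$tar)$E
  incr <- integrate_field(pf_field(
    (field_values(phi_new) - field_values(fx$phi))^2, fx$g))
  expect_lt(abs(E1 - E0 + incr / dt) / abs(E1), 1e-10)
  expect_lt(E1, E0)

  # SI and FI both limit to the same flow: difference shrinks like dt^2
  dd <- sapply(c(2e-8, 1e-8), function(dtt) {
    cfg2 <- stepper_config("fully_implicit", dt = dtt, picard_tol = 1e-14)
    fi <- step_fully_implicit(fx$phi, cfg2, fx$par, fx$tar)
    si <- step_semi_implicit(fx$phi, stepper_config("semi_implicit", dt = dtt),
                             fx$par, fx$tar)
    max(abs(field_values(fi) - field_values(si)))
  })
  expect_lt(dd[2] / dd[1], 0.35)  # ~ factor 4 for O(dt^2)
})

test_that("Picard failure and stability guards raise informative errors", {
  fx <- dyn_fixture(N = 16, eps = 0.05)
  # semi-implicit symbol loses positivity for a huge dt
  expect_error(step_semi_implicit(fx$phi, stepper_config("semi_implicit", dt = 1),
                                  fx$par, fx$tar),
               "positivity|mode")
  # Picard cannot contract with a too-large (but symbol-positive) time step
  expect_error(step_fully_implicit(fx$phi,
                                   stepper_config("fully_implicit", dt = 1e-4,
                                                  picard_max_iter = 5L),
                                   fx$par, fx$tar),
               "Picard")
})

test_that("run_simulation: no-op run, logging contract, steady detection, divergence capture", {
  fx <- dyn_fixture(N = 16, eps = 0.08)
  cfg0 <- stepper_config("semi_implicit", dt = 1e-7, max_steps = 0)
  sim0 <- run_simulation(fx$phi, cfg0, fx$par, fx$tar)
  expect_identical(field_values(sim0$final_field), field_values(fx$phi))
  expect_equal(nrow(sim0$energy_series), 1L)
  expect_equal(sim0$steps_taken, 0L)

  sim <- run_simulation(fx$phi,
                        stepper_config("semi_implicit", dt = 1e-7,
                                       max_steps = 120, log_every = 40),
                        fx$par, fx$tar)
  es <- sim$energy_series
  expect_true(all(diff(es$t) > 0))
  expect_equal(es$E, es$W + es$G + es$T1 + es$T2, tolerance = 1e-10)
  expect_equal(es$step[nrow(es)], 120)

  # starting at an equilibrium converges within the steady window
  phi1 <- pf_field(1, fx$g)
  tar1 <- constraint_targets(alpha = 1, beta = 1, dA0 = 0); tar1$beta <- 0
  sim1 <- run_simulation(phi1, stepper_config("semi_implicit", dt = 1e-7,
                                              max_steps = 50, steady_window = 5),
                         fx$par, tar1)
  expect_true(sim1$converged)
  expect_identical(sim1$termination_reason, "steady_state")
  expect_lte(sim1$steps_taken, 10L)

  # blow-up is recorded, not thrown, with a partial series
  simx <- run_simulation(fx$phi,
                         stepper_config("forward_euler", dt = 1e-3,
                                        max_steps = 50, log_every = 10),
                         fx$par, fx$tar)
  expect_false(simx$converged)
  expect_match(simx$termination_reason, "diverged|error")
  expect_gte(nrow(simx$energy_series), 1L)

  # determinism: identical configuration, bit-identical outcome
  sim_b <- run_simulation(fx$phi,
                          stepper_config("semi_implicit", dt = 1e-7,
                                         max_steps = 120, log_every = 40),
                          fx$par, fx$tar)
  expect_identical(field_values(sim$final_field), field_values(sim_b$final_field))
})
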