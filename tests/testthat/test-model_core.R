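par16 <- model_params(eps = 0.1, C = 0.3, M1 = 10, M2 = 10)

test_that("double-well roots and uniform phases annihilate f, fc and g", {
  g <- make_grid(1, 16)
  for (c0 in c(-1, 0, 1)) {
    phi <- pf_field(c0, g)
    expect_equal(max(abs(field_values(f_field(phi, par16)))), 0, tolerance = 1e-12)
  }
  # fc at phi = 0 is the constant C; at +/-1 it vanishes
  phi0 <- pf_field(0, g)
  expect_equal(field_values(fc_field(phi0, par16)),
               array(par16$C, rep(16, 3)), tolerance = 1e-12)
  expect_equal(max(abs(field_values(fc_field(pf_field(1, g), par16)))), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(field_values(variational_g(pf_field(-1, g), par16)))), 0,
               tolerance = 1e-10)

  # with C = 0 the shifted and unshifted operators coincide
  set.seed(3)
  parC0 <- model_params(eps = 0.1, C = 0)
  phi <- rand_smooth(g)
  expect_equal(field_values(fc_field(phi, parC0)),
               field_values(f_field(phi, parC0)), tolerance = 1e-14)
})

test_that("the planar tanh profile nearly annihilates the Allen-Cahn operator", {
  # slab composed of two interfaces at |x - 1/2| = 1/4; the residual away
  # from the composition kink is limited by spectral ringing, orders of
  # magnitude below the operator's natural scale 1/eps
  eps <- 0.05
  g <- make_grid(1, 64)
  par <- model_params(eps = eps)
  prof <- tanh((0.25 - abs(g$x - 0.5)) / (sqrt(2) * eps))
  phi <- pf_field(array(rep(prof, times = 64 * 64), rep(64, 3)), g)
  f <- field_values(f_field(phi, par))
  near_interface <- abs(abs(g$x - 0.5) - 0.25) < 0.06
  expect_lt(max(abs(f[near_interface, , ])), 1e-3)

  # flat interfaces: zero mean curvature, hence zero area difference
  expect_lt(abs(delta_area(phi, par)), 1e-8)
  # two unit-area interfaces
  expect_equal(surface_area(phi, par), 2, tolerance = 0.02)
})

test_that("sphere functionals approach closed forms and improve as eps halves", {
  R <- 0.35
  errs <- sapply(c(0.04, 0.02), function(eps) {
    g <- make_grid(1, 64)
    par <- model_params(eps = eps)
    phi <- tanh_sphere(g, R, epsilon = eps)
    c(V = abs(interior_volume(phi) - 4 * pi * R^3 / 3) / (4 * pi * R^3 / 3),
      A = abs(surface_area(phi, par) - 4 * pi * R^2) / (4 * pi * R^2),
      dA = abs(delta_area(phi, par) - 8 * pi * par$D * R) / (8 * pi * par$D * R))
  })
  # halving eps shrinks every oracle error
  expect_true(all(errs[, 2] < errs[, 1]))
  expect_lt(errs["V", 2], 0.02)
  expect_lt(errs["A", 2], 0.02)
  expect_lt(errs["dA", 2], 0.02)
  # orientation convention: interior {phi > 0} gives a positive dA
  g <- make_grid(1, 64)
  expect_gt(delta_area(tanh_sphere(g, R, epsilon = 0.02),
                       model_params(eps = 0.02)), 0)
})

test_that("bending energy: fc identity, uniform zero, and the sphere limit", {
  g <- make_grid(1, 24)
  set.seed(11)
  phi <- rand_smooth(g, amplitude = 0.8)
  par <- par16
  # energy from the squared-bracket integrand vs (kappa/2eps) * integral(fc^2)
  lap <- field_values(laplacian(phi))
  v <- field_values(phi)
  br <- lap - (v^2 - 1) * (v + par$C * par$eps) / par$eps^2
  W_direct <- (par$kappa * par$eps / 2) *
    integrate_field(pf_field(br^2, g))
  expect_equal(W_direct, bending_energy(phi, par), tolerance = 1e-12)

  expect_equal(bending_energy(pf_field(-1, g), par), 0, tolerance = 1e-13)

  # diffuse Willmore energy of a sphere approaches kappa * 16 sqrt(2) pi / 3,
  # independent of R and eps to leading order
  g64 <- make_grid(1, 64)
  par2 <- model_params(eps = 0.02)
  W <- bending_energy(tanh_sphere(g64, 0.35, epsilon = 0.02), par2)
  expect_equal(W, 16 * sqrt(2) * pi / 3, tolerance = 1e-3)
})

test_that("ADE energy and penalties are the stated quadratics", {
  g <- make_grid(1, 32)
  par <- model_params(eps = 0.02)
  phi <- tanh_sphere(g, 0.25, epsilon = 0.02)
  dA <- delta_area(phi, par)
  tar_at <- constraint_targets(alpha = 0.1, beta = 1, dA0 = dA)
  expect_equal(ade_energy(phi, par, tar_at), 0, tolerance = 1e-12)

  par0 <- model_params(eps = 0.02, kbar = 0)
  tar <- constraint_targets(alpha = 0.1, beta = 1, dA0 = 0)
  expect_equal(ade_energy(phi, par0, tar), 0)

  # independent oracle-chain value for a sphere: (kbar pi/(2 A0 D^2)) (8 pi D R)^2
  R <- 0.35
  phiR <- tanh_sphere(make_grid(1, 64), R, epsilon = 0.02)
  A0 <- 4 * pi * R^2
  tarR <- constraint_targets(alpha = 4 * pi * R^3 / 3, beta = A0, dA0 = 0)
  pred <- (1.4 * pi / (2 * A0 * par$D^2)) * (8 * pi * par$D * R)^2
  expect_equal(ade_energy(phiR, par, tarR), pred, tolerance = 0.05)

  # penalties: zero at target, zero prefactor, quadratic scaling
  tarV <- constraint_targets(alpha = interior_volume(phi), beta = 1, dA0 = 0)
  expect_equal(penalties(phi, par, tarV)[["T1"]], 0)
  parM0 <- model_params(eps = 0.02, M1 = 0, M2 = 0)
  expect_equal(unname(penalties(phi, parM0, tar)), c(0, 0))
  V <- interior_volume(phi)
  t1a <- penalties(phi, par, constraint_targets(V - 0.01, 1, 0))[["T1"]]
  t1b <- penalties(phi, par, constraint_targets(V - 0.02, 1, 0))[["T1"]]
  expect_equal(t1b / t1a, 4, tolerance = 1e-8)
})

test_that("total energy is consistent bookkeeping and matches the frozen pin", {
  g <- make_grid(1, 32)
  set.seed(5)
  phi <- rand_smooth(g, amplitude = 0.8)
  par <- par16
  tar <- constraint_targets(alpha = 0.3, beta = 2, dA0 = 0.05)
  eb <- total_energy(phi, par, tar)
  expect_equal(eb$E, eb$W + eb$G + eb$T1 + eb$T2, tolerance = 1e-14)
  expect_equal(eb$W, bending_energy(phi, par), tolerance = 1e-12)
  expect_equal(eb$G, ade_energy(phi, par, tar), tolerance = 1e-12)
  expect_equal(unname(penalties(phi, par, tar)), c(eb$T1, eb$T2),
               tolerance = 1e-12)
  expect_true(all(c(eb$W, eb$G, eb$T1, eb$T2) >= 0))

  # with penalties off and dA0 at the current value, E reduces to W
  parM0 <- model_params(eps = 0.1, C = 0.3, M1 = 0, M2 = 0)
  tar0 <- constraint_targets(alpha = 0, beta = 1, dA0 = delta_area(phi, parM0))
  expect_equal(total_energy(phi, parM0, tar0)$E, bending_energy(phi, parM0),
               tolerance = 1e-10)

  # frozen regression pin (sphere R=0.35, eps=0.04, N=64)
  g64 <- make_grid(1, 64)
  pin <- total_energy(tanh_sphere(g64, 0.35, epsilon = 0.04),
                      model_params(eps = 0.04),
                      constraint_targets(alpha = 0.15, beta = 1.5, dA0 = 0.1))
  expect_equal(pin$E, 257.362993, tolerance = 1e-8)
  expect_equal(pin$W, 23.86521133, tolerance = 1e-8)
  expect_equal(pin$G, 37.31774282, tolerance = 1e-8)
  expect_equal(pin$V, 0.1910847793, tolerance = 1e-8)
  expect_equal(pin$A, 1.552329848, tolerance = 1e-8)
  expect_equal(pin$dA, 0.2345389671, tolerance = 1e-7)
})

test_that("variational derivatives agree with finite differences", {
  res <- verify_gradients(N = 16, n_pairs = 2, seed = 42)
  expect_true(all(c("W", "G", "T1", "T2") %in% res$component))
  expect_lt(max(res$rel_error), 1e-7)
})

test_that("symmetrized forms reduce at equal arguments, swap, and satisfy the identities", {
  g <- make_grid(1, 24)
  set.seed(9)
  par <- par16
  phi <- rand_smooth(g, amplitude = 0.7)
  eta <- rand_smooth(g, amplitude = 0.7)
  tar <- constraint_targets(alpha = interior_volume(phi) * 0.9,
                            beta = surface_area(phi, par) * 1.1,
                            dA0 = delta_area(phi, par) - 0.1)

  sf_eq <- symmetrized_forms(phi, phi, par, tar)
  expect_equal(field_values(sf_eq$f2), field_values(f_field(phi, par)),
               tolerance = 1e-11)
  expect_equal(field_values(sf_eq$g2), field_values(variational_g(phi, par)),
               tolerance = 1e-11)
  expect_equal(field_values(sf_eq$h2), field_values(variational_h(phi, par, tar)),
               tolerance = 1e-11)

  sf <- symmetrized_forms(phi, eta, par, tar)
  sf_swap <- symmetrized_forms(eta, phi, par, tar)
  for (nm in c("f2", "g2", "h2"))
    expect_equal(field_values(sf[[nm]]), field_values(sf_swap[[nm]]),
                 tolerance = 1e-12)

  expect_error(symmetrized_forms(phi, rand_smooth(make_grid(1, 16)), par, tar),
               "same grid")

  res <- verify_identities(N = 24, n_pairs = 2, seed = 4)
  expect_lt(max(res$rel_error), 1e-8)
})

test_that("all energies are invariant under whole-cell translations", {
  g <- make_grid(1, 24)
  set.seed(21)
  phi <- rand_smooth(g, amplitude = 0.8)
  par <- par16
  tar <- constraint_targets(alpha = 0.2, beta = 1.5, dA0 = 0.05)
  ebs <- lapply(list(phi, roll_field(phi, c(7L, -2L, 13L))),
                total_energy, params = par, targets = tar)
  for (nm in c("W", "G", "T1", "T2", "E", "V", "A", "dA"))
    expect_equal(ebs[[1]][[nm]], ebs[[2]][[nm]], tolerance = 1e-10)
})
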