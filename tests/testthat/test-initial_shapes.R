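test_that("tanh shapes take the closed-form values at center, surface and far field", {
  g <- make_grid(1, 64)
  eps <- 0.04
  spec <- shape_spec("ellipsoid", center = c(0.5, 0.5, 0.5),
                     denoms = c(0.5, 0.5, 0.1), r0 = 0.35, epsilon = eps)
  phi <- tanh_ellipsoid(g, spec)
  v <- field_values(phi)
  # values live in [-1, 1]; tanh saturates to the endpoints only at
  # double-precision resolution, deep in the bulk phases
  expect_true(all(abs(v) <= 1))

  ic <- which.min(abs(g$x - 0.5))
  expect_lt(v[ic, ic, ic], 1)
  expect_equal(v[ic, ic, ic], tanh(0.35 / (sqrt(2) * eps)), tolerance = 1e-12)
  expect_gt(v[ic, ic, ic], 0.999)

  # zero level set sits on the ellipsoid: along x through the center the
  # sign changes across x = 0.5 +/- r0 * sqrt(d1)
  xs <- 0.5 + 0.35 * sqrt(0.5)
  below <- max(which(g$x < xs)); above <- below + 1L
  expect_gt(v[below, ic, ic], 0)
  expect_lt(v[above, ic, ic], 0)

  # analytic formula reproduced exactly at the nodes
  q <- sqrt((g$x[5] - 0.5)^2 / 0.5 + (g$x[20] - 0.5)^2 / 0.5 +
            (g$x[33] - 0.5)^2 / 0.1)
  expect_equal(v[5, 20, 33], tanh((0.35 - q) / (sqrt(2) * eps)))
})

test_that("two-sphere union profile matches its closed form", {
  g <- make_grid(1, 64)
  eps <- 0.02
  spec <- shape_spec("two_spheres",
                     centers = rbind(c(0.5, 0.5, 0.4), c(0.5, 0.5, 0.7)),
                     radii = c(0.22, 0.4), epsilon = eps)
  phi <- suppressWarnings(tanh_two_spheres(g, spec))
  v <- field_values(phi)
  ic <- which.min(abs(g$x - 0.5))

  # at the center of the larger sphere (z = 0.7): level = max(r2, ...) = 0.4
  iz7 <- which.min(abs(g$x - 0.7))
  d1 <- abs(0.7 - 0.4)
  expect_equal(v[ic, ic, iz7],
               tanh(max(0.22 - d1, 0.4) / (sqrt(2) * eps)), tolerance = 1e-12)
  expect_gt(v[ic, ic, iz7], 0.999)

  # far from both centers: deep exterior
  expect_lt(v[2, 2, 2], -0.999)

  # node-wise closed form
  p <- c(g$x[40], g$x[10], g$x[50])
  dd1 <- sqrt(sum((p - c(0.5, 0.5, 0.4))^2))
  dd2 <- sqrt(sum((p - c(0.5, 0.5, 0.7))^2))
  expect_equal(v[40, 10, 50],
               tanh(max(0.22 - dd1, 0.4 - dd2) / (sqrt(2) * eps)))
})

test_that("measured interface width follows the tanh scaling", {
  g <- make_grid(1, 128)
  eps <- 0.04
  phi <- tanh_sphere(g, 0.3, epsilon = eps)
  v <- field_values(phi)
  ic <- which.min(abs(g$x - 0.5))
  prof <- v[, ic, ic]
  # crossing distances of +/-0.9 on the outgoing x side
  xr <- g$x[ic:128]
  pr <- prof[ic:128]
  keep <- abs(pr) < 0.995   # strictly monotone part of the profile
  w_meas <- approx(pr[keep], xr[keep], xout = -0.9)$y -
    approx(pr[keep], xr[keep], xout = 0.9)$y
  w_pred <- 2 * atanh(0.9) * sqrt(2) * eps
  expect_lt(abs(w_meas - w_pred) / w_pred, 0.2)
})

test_that("constraint targets derive from the initial field via the sphere normalizations", {
  g <- make_grid(1, 64)
  eps <- 0.02
  par <- model_params(eps = eps)
  R <- 0.35
  phi <- tanh_sphere(g, R, epsilon = eps)

  tar <- derive_constraint_targets(phi, v_target = 1, da0_target = 1, par)
  expect_equal(tar$beta, surface_area(phi, par))
  expect_equal(tar$A0, tar$beta)
  expect_equal(tar$Rs^2 * 4 * pi, tar$beta, tolerance = 1e-12)
  expect_equal(tar$alpha, 4 * pi * R^3 / 3, tolerance = 0.01)
  expect_equal(tar$dA0, 8 * pi * par$D * R, tolerance = 0.02)

  # linear in da0; zero maps to zero
  tar0 <- derive_constraint_targets(phi, 1, 0, par)
  expect_equal(tar0$dA0, 0)
  tar2 <- derive_constraint_targets(phi, 1, 2.5, par)
  expect_equal(tar2$dA0 / tar$dA0, 2.5, tolerance = 1e-12)

  # alpha override from the measured volume
  tarV <- derive_constraint_targets(phi, 0.8, 1, par, alpha_from_field = TRUE)
  expect_equal(tarV$alpha, interior_volume(phi))

  # degenerate field has no interface
  expect_error(derive_constraint_targets(pf_field(-1, g), 1, 1, par),
               "degenerate")
})

test_that("clearance warning fires for shapes crowding the periodic boundary", {
  g <- make_grid(1, 32)
  expect_warning(tanh_sphere(g, 0.48, epsilon = 0.04), "clearance")
  expect_silent(tanh_sphere(g, 0.3, epsilon = 0.04))
})

test_that("seeded perturbation is deterministic, small, and seed-sensitive", {
  g <- make_grid(1, 16)
  phi <- tanh_sphere(g, 0.25, epsilon = 0.06)
  p1 <- add_perturbation(phi, amplitude = 0.01, seed = 7)
  p2 <- add_perturbation(phi, amplitude = 0.01, seed = 7)
  p3 <- add_perturbation(phi, amplitude = 0.01, seed = 8)
  expect_identical(field_values(p1), field_values(p2))
  expect_false(identical(field_values(p1), field_values(p3)))
  expect_lte(max(abs(field_values(p1) - field_values(phi))), 0.01 + 1e-12)
})
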