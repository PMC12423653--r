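# Swimming-speed kernel: structure, quadrature, shapes and the
# time-average oracle.

test_that("kernel parity structure holds for monophasic and travelling phases", {
  for (kern in list(kernel47(), compute_kernels(3, phase_travelling(0.72), n = 60))) {
    expect_lt(max(abs(kern$gs_matrix - t(kern$gs_matrix))), 1e-12)
    expect_lt(max(abs(kern$ga_matrix + t(kern$ga_matrix))), 1e-12)
    expect_lt(max(abs(kern$gswim_matrix - t(kern$gswim_matrix))), 1e-12)
  }
  # with zero phase the sine term vanishes and gswim reduces to gs
  k0 <- kernel47()
  expect_lt(max(abs(k0$gswim_matrix - (k0$gs_matrix + t(k0$gs_matrix)) / 2)), 1e-15)
})

test_that("uniform monophasic forcing cannot swim (scallop theorem)", {
  u <- speed_quadrature(kernel47(), fixture_profiles("constant"))
  expect_lt(abs(u), 1e-10)
})

test_that("the speed form is bilinear in the forcing", {
  kern <- kernel47()
  f1 <- fixture_profiles("random_smooth", seed = 7)
  f2 <- fixture_profiles("random_smooth", seed = 8)
  u1 <- speed_quadrature(kern, f1)
  expect_equal(speed_quadrature(kern,
    forcing_profile(f = function(x) 2 * f1$f(x))), 4 * u1, tolerance = 1e-12)
  # U[a f + b g] = a^2 U[f] + 2ab B[f,g] + b^2 U[g]
  a <- 1.3; b <- -0.7
  u2 <- speed_quadrature(kern, f2)
  upm <- speed_quadrature(kern,
    forcing_profile(f = function(x) f1$f(x) + f2$f(x)))
  cross <- (upm - u1 - u2) / 2
  umix <- speed_quadrature(kern,
    forcing_profile(f = function(x) a * f1$f(x) + b * f2$f(x)))
  expect_equal(umix, a^2 * u1 + 2 * a * b * cross + b^2 * u2,
               tolerance = 1e-10)
})

test_that("monophasic speed is antisymmetric under filament reflection", {
  kern <- kernel47()
  for (pr in random_profiles(3)) {
    u <- speed_quadrature(kern, pr)
    ur <- speed_quadrature(kern, forcing_profile(f = function(x) pr$f(1 - x)))
    expect_equal(ur, -u, tolerance = 1e-10 * max(1, abs(u)))
  }
})

test_that("a single actuator reproduces the sifted Green's function", {
  g <- build_greens(4.7)
  act <- forcing_profile(actuators = data.frame(xi = 0.3, strength = 1))
  s <- midpoint_nodes(10)
  expect_equal(solve_amplitude(g, act, s), eval_greens(g, s, 0.3, 0),
               tolerance = 1e-14)
})

test_that("kernel speed matches the time-averaged shape speed", {
  # the central correctness property: the double-quadrature form and the
  # -2 int <Psi_sss Psi_sst> ds form must agree
  cases <- list(
    list(sp = 3, phase = phase_travelling(0.72), prs = list(fixture_profiles("constant", phase = phase_travelling(0.72)))),
    list(sp = 2, phase = phase_constant(), prs = random_profiles(2, seed0 = 200)),
    list(sp = 4.7, phase = phase_constant(), prs = random_profiles(2, seed0 = 300)),
    list(sp = 4.7, phase = phase_travelling(1.5), prs = random_profiles(1, phase = phase_travelling(1.5), seed0 = 400))
  )
  for (cs in cases) {
    kern <- compute_kernels(cs$sp, cs$phase, n = 300)
    for (pr in cs$prs) {
      u_kernel <- speed_quadrature(kern, pr)
      sh <- filament_shape(cs$sp, pr, s_grid = midpoint_nodes(400), n_quad = 400)
      u_shape <- speed_time_average(sh)
      expect_lt(rel_diff(u_kernel, u_shape), 1e-4)
    }
  }
})

test_that("the leading-order global torque vanishes at all times", {
  for (pr in c(random_profiles(2, seed0 = 500),
               list(fixture_profiles("constant", phase = phase_travelling(1.5))))) {
    sh <- filament_shape(4, pr, s_grid = midpoint_nodes(50), n_quad = 100)
    expect_lt(max(abs(sh$torque)), 1e-8 * max(abs(sh$y)))
  }
})

test_that("tip velocity time-averages to zero over a period", {
  pr <- fixture_profiles("random_smooth", seed = 11)
  sh <- filament_shape(4.7, pr, s_grid = midpoint_nodes(30), n_quad = 100)
  expect_lt(abs(mean(sh$tip_velocity)), 1e-8 * max(abs(sh$tip_velocity)))
})

test_that("shape fields are consistent derivatives of the amplitude", {
  pr <- fixture_profiles("sin", freq = 1)
  sh <- filament_shape(3, pr, s_grid = midpoint_nodes(40),
                       t_grid = period_grid(128), n_quad = 100)
  t1 <- sh$t_grid[5]
  expect_equal(sh$y[, 5], Re(sh$psi_cap$phi2 * exp(1i * t1)), tolerance = 1e-12)
  expect_equal(sh$tangent_angle[, 5], Re(sh$psi_cap$phi3 * exp(1i * t1)),
               tolerance = 1e-12)
})

test_that("zero forcing gives a motionless straight filament", {
  zero <- forcing_profile(f = function(x) rep(0, length(x)))
  sh <- filament_shape(4.7, zero, s_grid = midpoint_nodes(20), n_quad = 50)
  expect_true(all(sh$y == 0))
  expect_true(all(sh$tip_velocity == 0))
  expect_equal(speed_time_average(sh), 0)
})

test_that("coarse time grids are refused by the averaging oracle", {
  pr <- fixture_profiles("sin")
  sh <- filament_shape(3, pr, s_grid = midpoint_nodes(20),
                       t_grid = period_grid(64), n_quad = 50)
  sh$t_grid <- sh$t_grid[1:32]
  sh$tangent_angle <- sh$tangent_angle[, 1:32]
  sh$psi_sst <- sh$psi_sst[, 1:32]
  expect_error(speed_time_average(sh), class = "swimmodes_invalid_parameter")
})
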