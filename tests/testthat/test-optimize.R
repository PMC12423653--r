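# Swimmer-design optimizers at the optimal sperm number.

test_that("the binary cutoff reproduces the printed optimum and is locally optimal", {
  res <- binary_cutoff(sys47())
  expect_equal(res$configuration$cutoff, 0.625, tolerance = 0.002 / 0.625)
  u_at <- function(c) swimmodes:::cutoff_speed(sys47(), c, 0)
  expect_gt(res$reduced_speed, u_at(res$configuration$cutoff + 0.01))
  expect_gt(res$reduced_speed, u_at(res$configuration$cutoff - 0.01))
  # the half-forced filament is strictly slower
  expect_gt(res$reduced_speed, u_at(0.5))
})

test_that("the ternary cutoff reproduces the printed optimum and speed factor", {
  res <- ternary_cutoff(sys47())
  expect_equal(res$configuration$cutoff, 0.701, tolerance = 0.002 / 0.701)
  expect_equal(res$speed_factor, 69.9, tolerance = 1 / 69.9)
  expect_gt(res$reduced_speed, binary_cutoff(sys47())$reduced_speed)
})

test_that("the four reference swimmers are ordered by speed", {
  sys <- sys47()
  u_uniform <- speed_monophasic(sys, fixture_profiles("constant"))
  u_half <- swimmodes:::cutoff_speed(sys, 0.5, 0)
  u_bin <- binary_cutoff(sys)$reduced_speed
  u_tern <- ternary_cutoff(sys)$reduced_speed
  expect_lt(abs(u_uniform), 1e-12)
  expect_true(abs(u_uniform) < u_half && u_half < u_bin && u_bin < u_tern)
})

test_that("a single unit actuator is optimally placed near the front third", {
  res <- optimize_actuators(sys47(), m = 1)
  expect_equal(res$configuration$actuators$xi, 0.309, tolerance = 0.002 / 0.309)
  expect_equal(res$speed_factor, 280.4, tolerance = 2 / 280.4)
})

test_that("the +1/2 -1/2 actuator pair lands at the printed locations", {
  res <- optimize_actuators(sys47(), m = 2, positive = 1)
  xi <- sort(res$configuration$actuators$xi)
  expect_equal(xi[1], 0.357, tolerance = 0.005 / 0.357)
  expect_equal(xi[2], 0.902, tolerance = 0.005 / 0.902)
  expect_equal(res$speed_factor, 104.1, tolerance = 2 / 104.1)
  # concentrating all the budget in one actuator beats splitting it
  expect_gt(optimize_actuators(sys47(), m = 1)$speed_factor, res$speed_factor)
})

test_that("distributing a fixed budget over more actuators is always slower", {
  sf <- sapply(c(1, 3, 5, 7, 9), function(m)
    optimize_actuators(sys47(), m = m, min_sep = 0.1)$speed_factor)
  expect_true(all(diff(sf) < 0))
})

test_that("optimizer outputs satisfy their variational conditions", {
  sys <- sys47()
  expect_true(variational_check(sys, binary_cutoff(sys)$configuration$profile,
                                c(0, 1))$pass)
  expect_true(variational_check(sys, ternary_cutoff(sys)$configuration$profile,
                                c(-1, 0, 1))$pass)
  bad <- variational_check(sys, fixture_profiles("constant"), c(0, 1))
  expect_false(bad$pass)
  expect_gt(nrow(bad$violations), 0)
})

test_that("actuator results re-score identically through the full kernel", {
  kern <- kernel47()
  for (res in list(optimize_actuators(sys47(), 1),
                   optimize_actuators(sys47(), 2, positive = 1))) {
    pr <- forcing_profile(actuators = res$configuration$actuators)
    expect_lt(rel_diff(speed_quadrature(kern, pr), res$reduced_speed), 1e-4)
  }
})

test_that("cell-aligned piecewise profiles re-score through the kernel", {
  # a cutoff on a cell boundary keeps the midpoint rule second order
  sys <- sys47()
  cut <- 0.63
  pr <- fixture_profiles("piecewise", breaks = c(0, cut, 1), values = c(1, 0))
  u_kernel <- speed_quadrature(compute_kernels(4.7, n = 200), pr)
  u_analytic <- swimmodes:::cutoff_speed(sys, cut, 0)
  expect_lt(rel_diff(u_kernel, u_analytic), 1e-4)
})

test_that("dominant-mode speed factors track the exact four-mode values", {
  # the dominant single-mode approximation undershoots the exact four-mode
  # speed by at most the subdominant share lambda-/lambda+ (~1.2%); its
  # values are the ones usually quoted for these reference designs
  sys <- sys47()
  sf <- function(pr, m) 100 * speed_monophasic(sys, pr, m, n_quad = 4000) /
    sys$lambda_plus
  tern <- ternary_cutoff(sys)$configuration$profile
  act1 <- forcing_profile(actuators = data.frame(xi = 0.309, strength = 1))
  act2 <- forcing_profile(actuators = data.frame(xi = c(0.357, 0.902),
                                                 strength = c(0.5, -0.5)))
  expect_equal(sf(tern, "dominant"), 69.9, tolerance = 0.002)
  expect_equal(sf(act1, "dominant"), 280.4, tolerance = 0.002)
  expect_equal(sf(act2, "dominant"), 104.1, tolerance = 0.002)
  gap <- sys$lambda_minus / sys$lambda_plus
  for (pr in list(tern, act1, act2)) {
    expect_lt(abs(sf(pr, "four_mode") - sf(pr, "dominant")) / sf(pr, "four_mode"),
              2 * gap)
  }
})

test_that("eigenfunction budgets match the printed values", {
  bud <- eigenfunction_budgets(sys47())
  expect_equal(bud$l1_norm, 0.84, tolerance = 0.01 / 0.84)
  expect_equal(bud$sf_unit_l1, 142.0, tolerance = 2 / 142)
  expect_equal(bud$sf_unit_mean_square, 100, tolerance = 1e-6)
})

test_that("infeasible constraints are rejected", {
  expect_error(optimize_actuators(sys47(), m = 12, min_sep = 0.1),
               class = "swimmodes_constraint_infeasible")
  expect_error(swimmodes:::bisect(function(x) 1 + x^2, 0.5, 1),
               class = "swimmodes_root_not_found")
})
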