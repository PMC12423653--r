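# Analytic four-mode eigensystem for in-phase forcing.

test_that("the natural pair has the advertised parity and satisfies the ODE", {
  p <- natural_pair(3)
  for (d in c(0.1, 0.3)) {
    expect_lt(Mod(p$fs(0.5 + d) - p$fs(0.5 - d)), 1e-10)
    expect_lt(Mod(p$fa(0.5 + d) + p$fa(0.5 - d)), 1e-10)
  }
  expect_lt(Mod(p$fa(0.5)), 1e-12)
  # numerical fourth derivative: Sp^4 i F + F'''' = 0
  h <- 1e-3
  for (fn in p) {
    for (x in c(0.3, 0.6)) {
      sten <- fn(x + h * (-2:2))
      d4 <- sum(c(1, -4, 6, -4, 1) * sten) / h^4
      expect_lt(Mod(3^4 * 1i * sten[3] + d4) / Mod(d4), 1e-4)
    }
  }
  # end conditions of the auxiliary field: fs and fa vanish at both ends
  expect_lt(max(Mod(c(p$fs(0), p$fs(1), p$fa(0), p$fa(1)))), 1e-12)
})

test_that("the auxiliary field I3 collapses onto the opposite-parity pair", {
  sp <- 4.7
  reps <- swimmodes:::natural_pair_reps(sp)
  grid <- seq(0.05, 0.95, by = 0.05)
  for (parity in c("s", "a")) {
    for (b in c(1 + 0i, 1i)) {
      out <- swimmodes:::monophasic_e3(sp, b, parity, reps)
      i3 <- (out$I2(grid, 0) - out$I1(grid, 1)) / (2i)
      target_rep <- if (parity == "s") reps$fa else reps$fs
      target <- swimmodes:::mode_eval(target_rep, grid)
      expect_lt(max(Mod(i3 - out$e3 * target)), 1e-8 * max(Mod(i3)))
    }
  }
})

test_that("boundary solves annihilate I1 and I2 at both ends", {
  reps <- swimmodes:::natural_pair_reps(2)
  bv <- swimmodes:::monophasic_bvp(2, 1i, reps$fa, deriv_rhs = FALSE)
  expect_lt(max(Mod(c(bv$eval(0, 0), bv$eval(1, 0), bv$eval(0, 1), bv$eval(1, 1)))),
            1e-10)
})

test_that("the monophasic spectrum matches the printed optimum", {
  sys <- sys47()
  expect_equal(sys$lambda_plus, 0.00170, tolerance = 0.02)
  ratio <- sys$lambda_plus / sys$lambda_minus
  expect_gt(ratio, 80)   # "approximately a hundred times larger", +/- 20%
  expect_lt(ratio, 120)
})

test_that("the 4x4 matrix spectrum forms plus/minus pairs with the sign symmetry", {
  sys <- sys47()
  vals <- sort(Re(eigen(sys$matrix4)$values))
  expect_equal(vals, sort(-vals), tolerance = 1e-10 * max(abs(vals)))
  # flipping the antisymmetric coefficients negates the eigenvalue
  v <- sys$gplus_coeffs
  flip <- c(v[1], -v[2], v[3], -v[4])
  expect_equal(drop(sys$matrix4 %*% flip), -sys$lambda_plus * flip,
               tolerance = 1e-10)
})

test_that("analytic eigenvalues match the numeric leading pair", {
  b <- eigendecompose(kernel47())
  lam <- b$eigenvalues
  expect_lt(rel_diff(max(lam), sys47()$lambda_plus), 1e-5)
  lam_pos2 <- sort(lam[lam > 0], decreasing = TRUE)[2]
  expect_lt(rel_diff(lam_pos2, sys47()$lambda_minus), 1e-5)
})

test_that("gs and ga have the advertised parity and monotone ratio", {
  sys <- sys47()
  x <- seq(0.01, 0.49, by = 0.02)
  expect_lt(max(abs(sys$gs_eval(x) - sys$gs_eval(1 - x))), 1e-10)
  expect_lt(max(abs(sys$ga_eval(x) + sys$ga_eval(1 - x))), 1e-10)
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(sys$gs_eval(grid) > 0))
  expect_true(all(diff(sys$ga_eval(grid) / sys$gs_eval(grid)) < 0))
})

test_that("eigenfunctions are unit mean square with positive front half", {
  sys <- sys47()
  grid <- midpoint_nodes(2000)
  expect_equal(mean(sys$gplus(grid)^2), 1, tolerance = 1e-8)
  expect_equal(mean(sys$gminus(grid)^2), 1, tolerance = 1e-8)
  expect_gt(mean(sys$gplus(grid)[grid < 0.5]), 0)
})

test_that("the exact running integral matches quadrature", {
  sys <- sys47()
  grid <- midpoint_nodes(4000)
  for (x in c(0.3, 0.625, 0.9)) {
    quad <- mean(sys$gplus(grid) * (grid <= x))
    expect_equal(Re(sys$gplus_int(x)), quad, tolerance = 1e-6)
  }
})

test_that("the eigenvalue curves peak where the paper's figure peaks", {
  lc <- lambda_curves(seq(4.2, 5.2, by = 0.01))
  expect_lt(abs(lc$sp[which.max(lc$lambda_plus)] - 4.70), 0.05)
  expect_true(all(lc$lambda_plus > 0) && all(lc$lambda_minus > 0))
  # ratio of the two maxima over the full range is about 20
  lc2 <- lambda_curves(seq(0.5, 10, by = 0.1))
  ratio <- max(lc2$lambda_plus) / max(lc2$lambda_minus)
  expect_gt(ratio, 16)
  expect_lt(ratio, 24)
})

test_that("monophasic speed formulas agree with each other and the kernel", {
  sys <- sys47()
  kern <- kernel47()
  # uniform forcing cannot swim, whatever the formula
  for (m in c("four_mode", "dominant", "diff_of_squares"))
    expect_lt(abs(speed_monophasic(sys, fixture_profiles("constant"), m)), 1e-12)
  for (pr in random_profiles(3, seed0 = 700)) {
    u4 <- speed_monophasic(sys, pr, "four_mode", n_quad = 100)
    expect_lt(rel_diff(u4, speed_quadrature(kern, pr)), 1e-5)
    ud <- speed_monophasic(sys, pr, "dominant")
    expect_equal(speed_monophasic(sys, pr, "diff_of_squares"), ud,
                 tolerance = 1e-10)
    refl <- forcing_profile(f = function(x) pr$f(1 - x))
    expect_equal(speed_monophasic(sys, refl, "four_mode"),
                 -speed_monophasic(sys, pr, "four_mode"), tolerance = 1e-10)
  }
})

test_that("printed speed factors reproduce for the reference swimmers", {
  sys <- sys47()
  act <- forcing_profile(actuators = data.frame(xi = 0.309, strength = 1))
  sf <- speed_monophasic(sys, act, "four_mode") / sys$lambda_plus
  expect_equal(sf, 2.804, tolerance = 0.01)
  grid <- midpoint_nodes(4000)
  l1 <- mean(abs(sys$gplus(grid)))
  pr <- forcing_profile(f = function(x) sys$gplus(x) / l1)
  sf2 <- speed_monophasic(sys, pr, "four_mode", n_quad = 4000) / sys$lambda_plus
  expect_equal(sf2, 1.420, tolerance = 0.01)
})

test_that("non-zero phase is refused by the monophasic formulas", {
  pr <- fixture_profiles("constant", phase = phase_travelling(1))
  expect_error(speed_monophasic(sys47(), pr), class = "swimmodes_invalid_use")
})
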