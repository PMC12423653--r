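# Swimmer-design optimizers for monophasic forcing.
#
# All optimizers work at a fixed sperm number through the analytic
# four-mode eigensystem.  Speeds are quoted both as the reduced speed U and
# as the speed factor SF = 100 U / lambda+, the percentage of the speed the
# unit-mean-square dominant eigenfunction would achieve at the same Sp.

new_optimization_result <- function(configuration, reduced_speed, lambda_plus,
                                    method) {
  structure(list(configuration = configuration,
                 reduced_speed = reduced_speed,
                 speed_factor = 100 * reduced_speed / lambda_plus,
                 method = method),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> U = %.6g, SF = %.1f%% (%s)\n",
              x$reduced_speed, x$speed_factor, x$method))
  utils::str(x$configuration, give.attr = FALSE)
  invisible(x)
}

# plain bisection to a fixed interval tolerance, as robust as it gets
bisect <- function(fn, lo, hi, tol = 1e-6) {
  flo <- fn(lo); fhi <- fn(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    sm_stop("root_not_found",
            "no sign change on (%g, %g): f = %g, %g", lo, hi, flo, fhi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- fn(mid)
    if (fm == 0) return(mid)
    if (flo * fm < 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

# exact projections of a front-cutoff / sign-switch profile on g+/g-:
# int f g and int f g(1-s) from the running integrals of the eigensystem.
cutoff_speed <- function(system, cutoff, tail_value) {
  proj <- function(g_int) {
    total <- g_int(1)
    front <- g_int(cutoff)
    refl_front <- total - g_int(1 - cutoff)   # int_0^cutoff g(1-s) ds
    a <- front + tail_value * (total - front)
    ar <- refl_front + tail_value * (g_int(1 - cutoff))
    c(a, ar)
  }
  p <- proj(system$gplus_int)
  m <- proj(system$gminus_int)
  (p[1]^2 - p[2]^2) * system$lambda_plus + (m[1]^2 - m[2]^2) * system$lambda_minus
}

#' Optimal forced-front-fraction swimmer
#'
#' For piecewise forcing f = 1 on \[0, cutoff\] and 0 after, the optimal
#' cutoff satisfies the implicit first-order condition
#' \deqn{\int_0^{\xi^*} g_a \big/ \int_0^{\xi^*} g_s = -g_a(\xi^*)/g_s(\xi^*),}
#' solved by bisection on (0.5, 1). The antisymmetric-to-symmetric ratio
#' \eqn{g_a/g_s} is strictly decreasing, so the bracket is safe.
#'
#' @param system An [analytic_system()].
#' @param tol Bisection interval tolerance (default 1e-6).
#' @return An `optimization_result`; `configuration$cutoff` is \eqn{\xi_1^*}.
#' @export
#' @examples
#' binary_cutoff(analytic_system(4.7))$configuration$cutoff  # ~0.625
binary_cutoff <- function(system, tol = 1e-6) {
  stopifnot(inherits(system, "analytic_eigensystem"))
  ga_cum <- function(x) system$gplus_int(x) - (system$gplus_int(1) - system$gplus_int(1 - x))
  gs_cum <- function(x) system$gplus_int(x) + (system$gplus_int(1) - system$gplus_int(1 - x))
  fn <- function(x) ga_cum(x) / gs_cum(x) + system$ga_eval(x) / system$gs_eval(x)
  root <- bisect(fn, 0.5 + 1e-9, 1 - 1e-9, tol)
  u <- cutoff_speed(system, root, tail_value = 0)
  new_optimization_result(
    list(type = "binary_cutoff", cutoff = root,
         profile = fixture_profiles("piecewise", breaks = c(0, root, 1),
                                    values = c(1, 0))),
    u, system$lambda_plus, "four_mode")
}

#' Optimal front-positive / rear-negative swimmer
#'
#' For piecewise forcing f = +1 on \[0, cutoff\] and -1 after (no passive
#' region is optimal for this family), the switch point satisfies
#' \deqn{\frac{\int_0^{\xi^*} g_a - \int_{\xi^*}^1 g_a}
#'            {\int_0^{\xi^*} g_s - \int_{\xi^*}^1 g_s}
#'       = -\frac{g_a(\xi^*)}{g_s(\xi^*)}.}
#'
#' @inheritParams binary_cutoff
#' @return An `optimization_result`; `configuration$cutoff` is \eqn{\xi_2^*}.
#' @export
ternary_cutoff <- function(system, tol = 1e-6) {
  stopifnot(inherits(system, "analytic_eigensystem"))
  ga_cum <- function(x) system$gplus_int(x) - (system$gplus_int(1) - system$gplus_int(1 - x))
  gs_cum <- function(x) system$gplus_int(x) + (system$gplus_int(1) - system$gplus_int(1 - x))
  ga1 <- ga_cum(1); gs1 <- gs_cum(1)
  fn <- function(x) (2 * ga_cum(x) - ga1) / (2 * gs_cum(x) - gs1) +
    system$ga_eval(x) / system$gs_eval(x)
  root <- bisect(fn, 0.5 + 1e-9, 1 - 1e-9, tol)
  u <- cutoff_speed(system, root, tail_value = -1)
  new_optimization_result(
    list(type = "ternary_cutoff", cutoff = root,
         profile = fixture_profiles("piecewise", breaks = c(0, root, 1),
                                    values = c(1, -1))),
    u, system$lambda_plus, "four_mode")
}

#' Optimal placement of discrete point actuators
#'
#' Places `m` point actuators, split into a positive group (always to the
#' left of the negative group) and a negative group, each group packed at
#' the minimum spacing, and optimizes the two group centres by a coarse
#' grid search (step 1e-3) with coordinate-wise local refinement to 1e-5.
#' Strengths follow the policy: `"unit_total_l1"` gives every actuator
#' magnitude `1/m` (total forcing magnitude 1), `"fixed_per_actuator"`
#' gives every actuator the magnitude `strength`.
#'
#' @param system An [analytic_system()].
#' @param m Number of actuators (>= 1).
#' @param strengths `"unit_total_l1"` or `"fixed_per_actuator"`.
#' @param min_sep Minimum spacing between adjacent actuators (default 0.1).
#' @param strength Per-actuator magnitude for `"fixed_per_actuator"`.
#' @param positive Fix the number of positive actuators (e.g. `positive = 1`
#'   with `m = 2` gives the +1/2, -1/2 pair); `NULL` searches all splits
#'   with at least as many positive as negative actuators.
#' @param all_sign_splits If `TRUE` and `positive` is `NULL`, also search
#'   splits with fewer positive than negative actuators (diagnostic; the
#'   mirrored configuration always does at least as well).
#' @return An `optimization_result`; `configuration$actuators` is the
#'   placed actuator table.
#' @export
#' @examples
#' optimize_actuators(analytic_system(4.7), m = 1)  # actuator near 0.309
optimize_actuators <- function(system, m,
                               strengths = c("unit_total_l1", "fixed_per_actuator"),
                               min_sep = 0.1, strength = 1, positive = NULL,
                               all_sign_splits = FALSE) {
  stopifnot(inherits(system, "analytic_eigensystem"))
  strengths <- match.arg(strengths)
  if (m < 1) sm_stop("invalid_parameter", "'m' must be at least 1")
  if (min_sep < 0) sm_stop("invalid_parameter", "'min_sep' must be non-negative")
  if ((m - 1) * min_sep >= 1)
    sm_stop("constraint_infeasible",
            "%d actuators with spacing %g do not fit in the unit filament", m, min_sep)
  mag <- if (strengths == "unit_total_l1") 1 / m else strength

  eps <- 1e-3
  group_offsets <- function(p) (seq_len(p) - (p + 1) / 2) * min_sep
  score_config <- function(p) {
    np <- p; nn <- m - p
    off_p <- group_offsets(np)
    half_p <- if (np > 0) (np - 1) / 2 * min_sep else 0
    half_n <- if (nn > 0) (nn - 1) / 2 * min_sep else 0
    grid <- seq(eps, 1 - eps, by = 1e-3)

    sum_g <- function(g, centre, off) {
      # one value per centre, summed over the group members
      out <- numeric(length(centre))
      for (o in off) out <- out + g(centre + o)
      out
    }
    gp <- system$gplus; gm <- system$gminus
    group_arrays <- function(centre, off, sign) {
      list(ap = sign * mag * sum_g(gp, centre, off),
           apr = sign * mag * sum_g(function(x) gp(1 - x), centre, off),
           am = sign * mag * sum_g(gm, centre, off),
           amr = sign * mag * sum_g(function(x) gm(1 - x), centre, off))
    }
    u_scalar <- function(c1, c2 = NULL) {
      s <- group_arrays(c1, off_p, 1)
      if (nn > 0) {
        sn <- group_arrays(c2, group_offsets(nn), -1)
        s <- Map(`+`, s, sn)
      }
      (s$ap^2 - s$apr^2) * system$lambda_plus +
        (s$am^2 - s$amr^2) * system$lambda_minus
    }

    c1_ok <- grid[grid - half_p >= eps & grid + half_p <= 1 - eps]
    if (length(c1_ok) == 0) return(NULL)
    if (nn == 0) {
      us <- u_scalar(c1_ok)
      best <- which.max(us)
      c1 <- c1_ok[best]
      # refine
      lo <- max(eps + half_p, c1 - 2e-3); hi <- min(1 - eps - half_p, c1 + 2e-3)
      op <- stats::optimize(function(x) u_scalar(x), c(lo, hi),
                            maximum = TRUE, tol = 1e-5)
      list(p = p, c1 = op$maximum, c2 = NA_real_, u = op$objective)
    } else {
      c2_ok <- grid[grid - half_n >= eps & grid + half_n <= 1 - eps]
      if (length(c2_ok) == 0) return(NULL)
      s1 <- group_arrays(c1_ok, off_p, 1)
      s2 <- group_arrays(c2_ok, group_offsets(nn), -1)
      u2 <- (outer(s1$ap, s2$ap, `+`)^2 - outer(s1$apr, s2$apr, `+`)^2) *
        system$lambda_plus +
        (outer(s1$am, s2$am, `+`)^2 - outer(s1$amr, s2$amr, `+`)^2) *
        system$lambda_minus
      # positive group strictly left of negative group, spacing respected
      gap <- outer(c1_ok + half_p, c2_ok - half_n,
                   function(a, b) b - a)
      u2[gap < min_sep - 1e-12] <- -Inf
      if (all(!is.finite(u2))) return(NULL)
      best <- arrayInd(which.max(u2), dim(u2))
      c1 <- c1_ok[best[1]]; c2 <- c2_ok[best[2]]
      for (it in 1:3) {   # coordinate-wise refinement
        lo1 <- max(eps + half_p, c1 - 2e-3)
        hi1 <- min(c2 - half_n - min_sep - half_p, c1 + 2e-3)
        if (hi1 > lo1) {
          c1 <- stats::optimize(function(x) u_scalar(x, c2), c(lo1, hi1),
                                maximum = TRUE, tol = 1e-5)$maximum
        }
        lo2 <- max(c1 + half_p + min_sep + half_n, c2 - 2e-3)
        hi2 <- min(1 - eps - half_n, c2 + 2e-3)
        if (hi2 > lo2) {
          c2 <- stats::optimize(function(x) u_scalar(c1, x), c(lo2, hi2),
                                maximum = TRUE, tol = 1e-5)$maximum
        }
      }
      list(p = p, c1 = c1, c2 = c2, u = u_scalar(c1, c2))
    }
  }

  p_values <- if (!is.null(positive)) {
    if (positive < 0 || positive > m)
      sm_stop("invalid_parameter", "'positive' must be between 0 and m")
    positive
  } else if (all_sign_splits) seq(0, m) else seq(ceiling(m / 2), m)
  cands <- Filter(Negate(is.null), lapply(p_values, score_config))
  if (length(cands) == 0)
    sm_stop("constraint_infeasible",
            "no feasible actuator configuration for m = %d, min_sep = %g", m, min_sep)
  best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "u"))]]

  xi <- best$c1 + group_offsets(best$p)
  fm <- rep(mag, best$p)
  if (m - best$p > 0) {
    xi <- c(xi, best$c2 + group_offsets(m - best$p))
    fm <- c(fm, rep(-mag, m - best$p))
  }
  act <- data.frame(xi = xi, strength = fm)
  u <- speed_monophasic(system, forcing_profile(actuators = act), "four_mode")
  new_optimization_result(
    list(type = "actuators", m = m, positive = best$p, actuators = act,
         min_sep = min_sep, strengths = strengths),
    u, system$lambda_plus, "four_mode")
}

#' Check the variational optimality conditions of a piecewise profile
#'
#' Evaluates the pointwise first-order conditions for piecewise-constant
#' monophasic profiles over an allowed value set: with
#' \eqn{r = \int f g_a / \int f g_s}, optimality requires
#' \eqn{r + g_a(\xi)/g_s(\xi) \ge 0} wherever \eqn{f = 1}, \eqn{\le 0}
#' wherever \eqn{f = -1}, and \eqn{\le 0} (binary family) or \eqn{= 0}
#' (ternary family, hence impossible on an interval) wherever \eqn{f = 0}.
#'
#' @param system An [analytic_system()].
#' @param profile A continuous piecewise-constant [forcing_profile()] whose
#'   values lie in `allowed_values`.
#' @param allowed_values Either `c(0, 1)` or `c(-1, 0, 1)`.
#' @param n_grid Number of check points (default 1000).
#' @param tol Slack on the inequalities.
#' @return List with `pass` (logical) and `violations` (data frame of
#'   offending points: `xi`, `f`, `condition`).
#' @export
variational_check <- function(system, profile, allowed_values = c(0, 1),
                              n_grid = 1000, tol = 1e-9) {
  stopifnot(inherits(system, "analytic_eigensystem"),
            inherits(profile, "forcing_profile"))
  if (profile$kind != "continuous")
    sm_stop("invalid_parameter", "variational check applies to continuous profiles")
  quad <- midpoint_nodes(4000)
  fq <- profile$f(quad)
  if (!all(vapply(fq, function(v) any(abs(v - allowed_values) < 1e-9), logical(1))))
    sm_stop("invalid_parameter", "profile takes values outside the allowed set")
  r <- mean(fq * system$ga_eval(quad)) / mean(fq * system$gs_eval(quad))
  xi <- midpoint_nodes(n_grid)
  fv <- profile$f(xi)
  cond <- r + system$ga_eval(xi) / system$gs_eval(xi)
  ternary <- any(abs(allowed_values - (-1)) < 1e-9)
  bad <- (abs(fv - 1) < 1e-9 & cond < -tol) |
    (abs(fv + 1) < 1e-9 & cond > tol) |
    (abs(fv) < 1e-9 & if (ternary) abs(cond) > tol else cond > tol)
  list(pass = !any(bad),
       violations = data.frame(xi = xi[bad], f = fv[bad], condition = cond[bad]))
}

#' Forcing budget of the dominant eigenfunction
#'
#' Reports the total forcing magnitude (L1 norm) of the unit-mean-square
#' dominant eigenfunction and the speed factors of eigenfunction forcing
#' under the two normalizations: unit mean square (100% by definition of
#' \eqn{\lambda_+}) and unit total magnitude.
#'
#' @param system An [analytic_system()].
#' @return One-row data frame: `sp`, `l1_norm`, `sf_unit_mean_square`,
#'   `sf_unit_l1`.
#' @export
eigenfunction_budgets <- function(system) {
  stopifnot(inherits(system, "analytic_eigensystem"))
  quad <- midpoint_nodes(4000)
  l1 <- mean(abs(system$gplus(quad)))
  prof_ms <- forcing_profile(f = system$gplus)
  prof_l1 <- forcing_profile(f = function(x) system$gplus(x) / l1)
  u_ms <- speed_monophasic(system, prof_ms, "four_mode", n_quad = 4000)
  u_l1 <- speed_monophasic(system, prof_l1, "four_mode", n_quad = 4000)
  data.frame(sp = system$sp, l1_norm = l1,
             sf_unit_mean_square = 100 * u_ms / system$lambda_plus,
             sf_unit_l1 = 100 * u_l1 / system$lambda_plus)
}
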