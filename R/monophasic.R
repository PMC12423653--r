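# Analytic eigensystem for monophasic forcing (phase identically zero).
#
# For in-phase forcing the kernel reduces to its symmetric part and only
# four eigenvalues are non-zero.  Any eigenfunction with non-zero
# eigenvalue is a real combination of the four natural modes exp(k s),
# k^4 = -Sp^4 i, organised into a symmetric / antisymmetric pair
# (fs, fa) that already satisfies the end conditions of the auxiliary
# field I3.  Writing the eigenfunction as
#
#   f = Af Re[fs] + Bf Re[fa] + Cf Re[i fs] + Df Re[i fa],
#
# the eigen-relation lambda f = Re[I3] closes into a real 4x4 eigenproblem
# whose coefficients E3 are assembled from two 4x4 complex boundary solves
# per forcing mode (8 solves, 32 homogeneous coefficients in total).
#
# Internally every natural-mode combination is stored in anchored form
# coef * exp(mu * (s - anchor)) with the anchor at the end where the mode
# is largest, so no growing exponential is ever evaluated; this keeps the
# assembly stable through Sp = 30.

eta_const <- function() exp(-1i * pi / 8)

# --- anchored natural-mode representations -------------------------------

mode_exponents <- function(sp) {
  k1 <- sp * eta_const()
  k2 <- sp * eta_const() * 1i
  c(k1, k2, -k1, -k2)
}

# rep: list(mu, coef, anchor); value(s) = sum coef * exp(mu * (s - anchor))
mode_eval <- function(rep, x, deriv = 0) {
  out <- complex(length(x))
  for (j in seq_along(rep$mu)) {
    out <- out + rep$coef[j] * rep$mu[j]^deriv *
      exp(rep$mu[j] * (x - rep$anchor[j]))
  }
  out
}

mode_deriv_rep <- function(rep) {
  list(mu = rep$mu, coef = rep$coef * rep$mu, anchor = rep$anchor)
}

# exact running integral int_0^x of a mode representation
mode_int_eval <- function(rep, x) {
  out <- complex(length(x))
  for (j in seq_along(rep$mu)) {
    out <- out + rep$coef[j] / rep$mu[j] *
      (exp(rep$mu[j] * (x - rep$anchor[j])) - exp(-rep$mu[j] * rep$anchor[j]))
  }
  out
}

# standard-basis coefficient of exp(mu * s) for each mode
mode_std_coef <- function(rep) rep$coef * exp(-rep$mu * rep$anchor)

natural_pair_reps <- function(sp) {
  mu <- mode_exponents(sp)
  k1 <- mu[1]; k2 <- mu[2]
  den_s <- c(1 + exp(-k1), 1 + exp(-k2))
  den_a <- c(exp(-k1) - 1, exp(-k2) - 1)
  if (any(Mod(c(den_s, den_a)) < 1e-12))
    sm_stop("invalid_parameter",
            "degenerate natural-mode denominator at sp = %g", sp)
  s1 <- 1 / den_s[1]; s2 <- 1 / den_s[2]
  t1 <- 1 / den_a[1]; t2 <- 1 / den_a[2]
  list(
    fs = list(mu = mu, coef = c(s1, -s2, s1, -s2), anchor = c(1, 1, 0, 0)),
    fa = list(mu = mu, coef = c(t1, -t2, -t1, t2), anchor = c(1, 1, 0, 0))
  )
}

#' Symmetric and antisymmetric natural-mode pair
#'
#' The two combinations of the four natural modes \eqn{e^{ks}},
#' \eqn{k^4 = -Sp^4 i}, that vanish at both ends of the filament:
#' `fs` is symmetric about \eqn{s = 1/2} and `fa` antisymmetric. Every
#' monophasic forcing eigenfunction with non-zero eigenvalue is a real
#' combination of `Re[fs]`, `Re[fa]`, `Re[i fs]`, `Re[i fa]`.
#'
#' @param sp Sperm number in (0, 30].
#' @return List of two vectorized complex-valued functions `fs`, `fa`.
#' @export
#' @examples
#' p <- natural_pair(3)
#' p$fs(0.3) - p$fs(0.7)  # symmetric: ~0
natural_pair <- function(sp) {
  check_sp(sp)
  reps <- natural_pair_reps(sp)
  list(fs = function(x) mode_eval(reps$fs, x),
       fa = function(x) mode_eval(reps$fa, x))
}

# --- the auxiliary boundary-value solves ---------------------------------

# Particular + homogeneous solution of Sp^4 i I + I'''' = rhs with
# I = I' = 0 at both ends, where rhs = Re[b * F] (deriv_rhs = FALSE) or
# rhs = d/ds Re[b * F] (deriv_rhs = TRUE), F a natural-mode combination.
# Returns the homogeneous anchored coefficients and an evaluator.
monophasic_bvp <- function(sp, b, f_rep, deriv_rhs = FALSE) {
  mu <- f_rep$mu
  src <- if (deriv_rhs) mode_deriv_rep(f_rep) else f_rep
  # resonant particular: natural-mode forcing c exp(mu s) lifts to
  # c s exp(mu s) / (4 mu^3)
  res <- list(mu = src$mu, coef = b * src$coef / (8 * src$mu^3),
              anchor = src$anchor)
  conj_scale <- Conj(b) / (4 * sp^4 * 1i)
  p_eval <- function(x, d = 0) {
    if (d == 0) {
      r <- vapply(x, function(xx) sum(res$coef * xx *
                                        exp(res$mu * (xx - res$anchor))), complex(1))
      r + conj_scale * Conj(mode_eval(f_rep, x, if (deriv_rhs) 1 else 0))
    } else {
      r <- vapply(x, function(xx) sum(res$coef * (1 + res$mu * xx) *
                                        exp(res$mu * (xx - res$anchor))), complex(1))
      r + conj_scale * Conj(mode_eval(f_rep, x, if (deriv_rhs) 2 else 1))
    }
  }
  anchor_h <- ifelse(Re(mu) > 0, 1, 0)
  basis_val <- function(x, d) mu^d * exp(mu * (x - anchor_h))
  a <- rbind(basis_val(0, 0), basis_val(1, 0), basis_val(0, 1), basis_val(1, 1))
  kap <- cond2(a)
  if (!is.finite(kap) || kap > 1e12)
    sm_stop("conditioning",
            "auxiliary boundary solve ill conditioned (cond = %.3g) at sp = %g", kap, sp)
  rhs <- -c(p_eval(0, 0), p_eval(1, 0), p_eval(0, 1), p_eval(1, 1))
  h <- solve(a, rhs)
  hom <- list(mu = mu, coef = h, anchor = anchor_h)
  list(hom = hom,
       eval = function(x, d = 0) p_eval(x, d) + mode_eval(hom, x, d),
       res = res)
}

# E3 coefficient for forcing mode b in {1, i} and parity in {"s", "a"}:
# the eigen-relation reads lambda f = Im[-I1' + I2] / 2 = Re[I3] with
# I3 = (I2 - I1') / (2i), which collapses onto the opposite-parity pair
# function; its standard-basis coefficient per natural mode is
#   (h2_mu - mu h1_mu - b c_mu / (8 mu^3)) / (2i),
# the conjugate particular parts cancelling identically and the resonant
# s-exp(mu s) terms cancelling between I1' and I2.
monophasic_e3 <- function(sp, b, parity, reps) {
  f_rep <- if (parity == "s") reps$fs else reps$fa
  target <- if (parity == "s") reps$fa else reps$fs
  bvp1 <- monophasic_bvp(sp, b, f_rep, deriv_rhs = FALSE)
  bvp2 <- monophasic_bvp(sp, b, f_rep, deriv_rhs = TRUE)
  mu <- f_rep$mu
  c_std <- mode_std_coef(f_rep)
  h1_std <- mode_std_coef(bvp1$hom)
  h2_std <- mode_std_coef(bvp2$hom)
  i3_std <- (h2_std - mu * h1_std - b * c_std / (8 * mu^3)) / (2i)
  t_std <- mode_std_coef(target)
  # read E3 off a decaying mode, whose coefficients are O(1)
  j <- which(Re(mu) < 0)[1]
  list(e3 = i3_std[j] / t_std[j], i3_std = i3_std, target_std = t_std,
       I1 = bvp1$eval, I2 = bvp2$eval)
}

# --- the 4x4 eigenproblem -------------------------------------------------

#' Analytic monophasic eigensystem
#'
#' Assembles the exact four-mode eigenproblem for in-phase forcing at a
#' given sperm number: the natural-mode pair, the four `E3` coupling
#' coefficients, the real 4x4 matrix whose spectrum is
#' \eqn{\{\lambda_+, \lambda_-, -\lambda_-, -\lambda_+\}}, and the two
#' dominant eigenfunctions \eqn{g_\pm} (normalized to unit mean square,
#' signed so \eqn{\int_0^{1/2} g > 0}) together with their symmetric and
#' antisymmetric parts \eqn{g_s(s) = g_+(s) + g_+(1-s)},
#' \eqn{g_a(s) = g_+(s) - g_+(1-s)}.
#'
#' @param sp Sperm number in (0, 30].
#' @return An object of class `analytic_eigensystem` with fields `sp`,
#'   `eta`, `fs_eval`, `fa_eval`, `e3`, `matrix4`, `lambda_plus`,
#'   `lambda_minus`, `gplus_coeffs`, `gminus_coeffs`, and vectorized
#'   evaluators `gplus`, `gminus`, `gs_eval`, `ga_eval`.
#' @export
#' @examples
#' sys <- analytic_system(4.7)
#' c(sys$lambda_plus, sys$lambda_minus)
analytic_system <- function(sp) {
  check_sp(sp)
  reps <- natural_pair_reps(sp)
  e3 <- list(
    s1 = monophasic_e3(sp, 1 + 0i, "s", reps)$e3,
    si = monophasic_e3(sp, 1i, "s", reps)$e3,
    a1 = monophasic_e3(sp, 1 + 0i, "a", reps)$e3,
    ai = monophasic_e3(sp, 1i, "a", reps)$e3
  )
  m4 <- rbind(
    c(0, Re(e3$a1), 0, Re(e3$ai)),
    c(Re(e3$s1), 0, Re(e3$si), 0),
    c(0, Im(e3$a1), 0, Im(e3$ai)),
    c(Im(e3$s1), 0, Im(e3$si), 0)
  )
  # The matrix couples the symmetric coefficients x = (Af, Cf) and the
  # antisymmetric ones y = (Bf, Df) as lambda x = P y, lambda y = Q x, so
  # lambda^2 are the eigenvalues of the 2x2 product P Q.  Solving in this
  # form keeps the exact +/- pairing and is markedly stabler than the raw
  # 4x4 eigensolve; at small Sp the subdominant lambda- still loses
  # significance to cancellation once it falls below ~1e-2 lambda+.
  p2 <- rbind(c(Re(e3$a1), Re(e3$ai)), c(Im(e3$a1), Im(e3$ai)))
  q2 <- rbind(c(Re(e3$s1), Re(e3$si)), c(Im(e3$s1), Im(e3$si)))
  es <- eigen(p2 %*% q2)
  ell <- Re(es$values)
  ord <- order(ell, decreasing = TRUE)
  lam_plus <- sqrt(max(ell[ord[1]], 0))
  lam_minus <- sqrt(abs(ell[ord[2]]))
  if (lam_plus == 0)
    sm_stop("conditioning", "degenerate monophasic spectrum at sp = %g", sp)
  vec4 <- function(j, lam) {
    x <- Re(es$vectors[, j])
    y <- drop(q2 %*% x) / lam
    c(x[1], y[1], x[2], y[2])
  }
  vec_plus <- vec4(ord[1], lam_plus)
  vec_minus <- vec4(ord[2], if (lam_minus > 0) lam_minus else 1)

  make_g <- function(cf) {
    function(x) {
      fs <- mode_eval(reps$fs, x)
      fa <- mode_eval(reps$fa, x)
      cf[1] * Re(fs) + cf[2] * Re(fa) - cf[3] * Im(fs) - cf[4] * Im(fa)
    }
  }
  # exact running integral int_0^x g, from the mode antiderivatives
  make_g_int <- function(cf) {
    function(x) {
      fs <- mode_int_eval(reps$fs, x)
      fa <- mode_int_eval(reps$fa, x)
      cf[1] * Re(fs) + cf[2] * Re(fa) - cf[3] * Im(fs) - cf[4] * Im(fa)
    }
  }
  # normalize to unit mean square, sign so the front half integrates positive
  grid <- midpoint_nodes(2000)
  norm_coeffs <- function(cf) {
    g <- make_g(cf)(grid)
    cf <- cf / sqrt(mean(g^2))
    if (mean(make_g(cf)(grid)[grid < 0.5]) < 0) cf <- -cf
    cf
  }
  vec_plus <- norm_coeffs(vec_plus)
  vec_minus <- norm_coeffs(vec_minus)
  gplus <- make_g(vec_plus)
  gminus <- make_g(vec_minus)

  structure(list(
    sp = sp, eta = eta_const(),
    fs_eval = function(x) mode_eval(reps$fs, x),
    fa_eval = function(x) mode_eval(reps$fa, x),
    e3 = e3, matrix4 = m4,
    lambda_plus = lam_plus, lambda_minus = lam_minus,
    gplus_coeffs = vec_plus, gminus_coeffs = vec_minus,
    gplus = gplus, gminus = gminus,
    gplus_int = make_g_int(vec_plus), gminus_int = make_g_int(vec_minus),
    gs_eval = function(x) gplus(x) + gplus(1 - x),
    ga_eval = function(x) gplus(x) - gplus(1 - x)
  ), class = "analytic_eigensystem")
}

#' @export
print.analytic_eigensystem <- function(x, ...) {
  cat(sprintf("<analytic_eigensystem> Sp = %g, lambda+ = %.5g, lambda- = %.5g\n",
              x$sp, x$lambda_plus, x$lambda_minus))
  invisible(x)
}

#' Eigenvalue curves of the monophasic system
#'
#' Tabulates the two positive analytic eigenvalues over a grid of sperm
#' numbers.
#'
#' @param sp_grid Sperm numbers in (0, 30].
#' @return Data frame `(sp, lambda_plus, lambda_minus)`.
#' @export
lambda_curves <- function(sp_grid) {
  rows <- lapply(sp_grid, function(sp) {
    sys <- analytic_system(sp)
    data.frame(sp = sp, lambda_plus = sys$lambda_plus,
               lambda_minus = sys$lambda_minus)
  })
  do.call(rbind, rows)
}

#' Monophasic swimming speed from the analytic eigensystem
#'
#' Evaluates the reduced speed of an in-phase forcing profile through the
#' four-mode expansion. `"four_mode"` keeps both eigenvalue pairs (exact);
#' `"dominant"` drops the small pair; `"diff_of_squares"` rewrites the
#' dominant approximation as
#' \eqn{\lambda_+ [\int f g_s][\int f g_a]} (algebraically identical to
#' `"dominant"`). Discrete actuator profiles evaluate \eqn{g_\pm} at the
#' actuator points exactly.
#'
#' @param system An [analytic_system()].
#' @param forcing A [forcing_profile()] with zero phase.
#' @param method One of `"four_mode"`, `"dominant"`, `"diff_of_squares"`.
#' @param n_quad Midpoint nodes for the projection integrals of continuous
#'   profiles (default 1000).
#' @return Reduced swimming speed.
#' @export
speed_monophasic <- function(system, forcing,
                             method = c("four_mode", "dominant", "diff_of_squares"),
                             n_quad = 1000) {
  stopifnot(inherits(system, "analytic_eigensystem"),
            inherits(forcing, "forcing_profile"))
  method <- match.arg(method)
  probe <- c(0, 0.25, 0.5, 0.75, 1)
  if (any(abs(forcing$phase(probe)) > 1e-12))
    sm_stop("invalid_use", "monophasic speed formulas require zero phase")

  if (forcing$kind == "discrete") {
    xi <- forcing$actuators$xi
    w <- forcing$actuators$strength
    ip <- function(g) sum(w * g(xi))
    ipr <- function(g) sum(w * g(1 - xi))
  } else {
    nodes <- midpoint_nodes(n_quad)
    fv <- forcing$f(nodes)
    ip <- function(g) mean(fv * g(nodes))
    ipr <- function(g) mean(fv * g(1 - nodes))
  }
  ap <- ip(system$gplus); apr <- ipr(system$gplus)
  switch(method,
    four_mode = {
      am <- ip(system$gminus); amr <- ipr(system$gminus)
      (ap^2 - apr^2) * system$lambda_plus + (am^2 - amr^2) * system$lambda_minus
    },
    dominant = (ap^2 - apr^2) * system$lambda_plus,
    diff_of_squares = {
      gs_int <- ap + apr
      ga_int <- ap - apr
      system$lambda_plus * gs_int * ga_int
    })
}
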