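# Eigenmode decomposition of the swimming-speed kernel.
#
# Gswim is real and symmetric, so it has an orthonormal basis of
# eigenfunctions g_n with real eigenvalues lambda_n; expanding the forcing
# as f = sum a_n g_n gives U = sum a_n^2 lambda_n.  Discretizing on N
# midpoint nodes, matrix eigenvalues relate to operator eigenvalues by a
# factor N, and eigenvectors v (unit Euclidean norm) sample g = sqrt(N) v
# so that int g^2 = 1 under the midpoint rule.

#' Eigendecompose a swimming-speed kernel
#'
#' @param kernel A [compute_kernels()] object.
#' @return An object of class `modal_basis`: `eigenvalues` (ordered by
#'   decreasing magnitude), `eigenfunctions` (columns sample the modes on
#'   the nodes, normalized to unit mean square, largest-magnitude sample
#'   positive), plus `sp`, `n`, `nodes`, `phase` and the source `kernel`.
#' @export
#' @examples
#' b <- eigendecompose(compute_kernels(4.7, n = 60))
#' b$eigenvalues[1:4]  # the four non-negligible monophasic modes
eigendecompose <- function(kernel) {
  stopifnot(inherits(kernel, "speed_kernel"))
  m <- kernel$gswim_matrix
  if (!all(is.finite(m)))
    sm_stop("invalid_input", "kernel matrix contains non-finite entries")
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  n <- kernel$n
  ord <- order(abs(es$values), decreasing = TRUE)
  lambda <- es$values[ord] / n
  vecs <- es$vectors[, ord, drop = FALSE] * sqrt(n)
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))   # ties resolve to the smaller index
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(sp = kernel$sp, phase = kernel$phase, n = n,
                 nodes = kernel$nodes, eigenvalues = lambda,
                 eigenfunctions = vecs, kernel = kernel),
            class = "modal_basis")
}

#' @export
print.modal_basis <- function(x, ...) {
  cat(sprintf("<modal_basis> Sp = %g, N = %d, lambda1 = %.4g\n",
              x$sp, x$n, x$eigenvalues[1]))
  invisible(x)
}

#' Project a forcing profile onto the eigenmode basis
#'
#' Computes the modal coefficients \eqn{a_n = \int_0^1 f g_n d\xi} by the
#' midpoint rule on the basis nodes.
#'
#' @param forcing A continuous [forcing_profile()].
#' @param basis A [eigendecompose()] result.
#' @return Numeric vector of coefficients, one per mode, in the basis's
#'   magnitude ordering.
#' @export
project <- function(forcing, basis) {
  stopifnot(inherits(forcing, "forcing_profile"), inherits(basis, "modal_basis"))
  if (forcing$kind != "continuous")
    sm_stop("invalid_parameter", "projection requires a continuous profile")
  f <- forcing$f(basis$nodes)
  if (length(f) != basis$n)
    sm_stop("invalid_parameter", "forcing did not evaluate on the basis grid")
  drop(crossprod(basis$eigenfunctions, f)) / basis$n
}

#' Modal swimming speed with truncation
#'
#' Partial sum \eqn{U \approx \sum_{n \le T} a_n^2 \lambda_n} over the
#' magnitude-ordered modes. With `truncation = N` this equals the kernel
#' quadrature speed identically.
#'
#' @param basis A `modal_basis`.
#' @param coeffs Modal coefficients from [project()].
#' @param truncation Number of retained modes (default all).
#' @return Reduced swimming speed.
#' @export
speed_modal <- function(basis, coeffs, truncation = basis$n) {
  stopifnot(inherits(basis, "modal_basis"))
  if (truncation < 1 || truncation > basis$n)
    sm_stop("invalid_parameter", "'truncation' must be in 1..N")
  idx <- seq_len(truncation)
  sum(coeffs[idx]^2 * basis$eigenvalues[idx])
}

#' Truncation-error curve for the modal speed
#'
#' Relative error of the `n`-term modal partial sum against the exact
#' kernel-quadrature speed, for every truncation level. Profiles whose
#' exact speed vanishes (e.g. uniform monophasic forcing, which cannot swim
#' by the scallop theorem) have no meaningful relative error and are
#' refused.
#'
#' @param basis A `modal_basis`.
#' @param forcing A continuous [forcing_profile()].
#' @return Data frame with columns `n` and `relative_error`.
#' @export
truncation_error_curve <- function(basis, forcing) {
  stopifnot(inherits(basis, "modal_basis"))
  a <- project(forcing, basis)
  u_exact <- speed_quadrature(basis$kernel, forcing)
  scale <- max(abs(basis$eigenvalues)) * sum(a^2)
  if (abs(u_exact) < 1e-10 * scale)
    sm_stop("undefined_reference",
            "exact speed is (numerically) zero; relative truncation error undefined")
  partial <- cumsum(a^2 * basis$eigenvalues)
  data.frame(n = seq_len(basis$n),
             relative_error = abs(partial - u_exact) / abs(u_exact))
}

#' Scan the travelling-wave parameter plane
#'
#' For each (Sp, k) pair, assembles the travelling-wave kernel
#' \eqn{G_{swim} = G_s\cos(2\pi k\Delta\xi) + G_a\sin(2\pi k\Delta\xi)} and
#' records its largest positive eigenvalue: the best achievable reduced
#' speed under a unit mean-square forcing constraint. `gs`/`ga` are built
#' once per Sp and reused across `k`.
#'
#' @param sp_grid Sperm numbers in (0, 30].
#' @param k_grid Wavenumbers (any sign).
#' @param n Discretization size (default 100).
#' @return Data frame `(sp, k, lambda_max)` sorted by `(sp, k)`.
#' @export
scan_travelling_wave <- function(sp_grid = seq(0.05, 6, by = 0.05),
                                 k_grid = seq(-3, 3, by = 0.02),
                                 n = 100) {
  sp_grid <- sort(sp_grid)
  k_grid <- sort(k_grid)
  res <- vector("list", length(sp_grid))
  for (i in seq_along(sp_grid)) {
    kern <- compute_kernels(sp_grid[i], phase_constant(), n)
    dxi <- outer(kern$nodes, kern$nodes, `-`)
    lmax <- vapply(k_grid, function(k) {
      gsw <- kern$gs_matrix * cos(2 * pi * k * dxi) +
        kern$ga_matrix * sin(2 * pi * k * dxi)
      gsw <- (gsw + t(gsw)) / 2
      max(eigen(gsw, symmetric = TRUE, only.values = TRUE)$values) / n
    }, numeric(1))
    res[[i]] <- data.frame(sp = sp_grid[i], k = k_grid, lambda_max = lmax)
  }
  do.call(rbind, res)
}
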