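# Dimensional conversion and plain-text serialization.
#
# The whole analysis is dimensionless: lengths scale with the filament
# length L, time with the inverse angular frequency 1/omega, moments with
# A/L.  The reduced speed U relates to the physical time-averaged speed by
# the drag-anisotropy prefactor and the square of the forcing amplitude.

#' Dimensional context of a physical filament
#'
#' Collects the dimensional parameters of a real swimmer and derives the
#' sperm number \eqn{Sp = L / l_e} with elastic penetration length
#' \eqn{l_e = (A / \omega c_\perp)^{1/4}}.
#'
#' @param length_l Filament length L in metres.
#' @param angular_freq Beat angular frequency \eqn{\omega} in rad/s.
#' @param bending_a Bending modulus A in N m^2.
#' @param drag_perp,drag_par Resistive-force-theory drag coefficients
#'   \eqn{c_\perp}, \eqn{c_\parallel} in N s/m^2.
#' @param amplitude_eps Dimensionless forcing amplitude \eqn{\epsilon}.
#' @return An object of class `dimensional_context` (list of the inputs
#'   plus `penetration_length` and `sp`).
#' @export
#' @examples
#' ctx <- dimensional_context(2e-3, 2 * pi * 1.5, 1e-14, 2.4e-3, 1.2e-3, 0.1)
#' ctx$sp
dimensional_context <- function(length_l, angular_freq, bending_a,
                                drag_perp, drag_par, amplitude_eps = 1) {
  vals <- c(length_l = length_l, angular_freq = angular_freq,
            bending_a = bending_a, drag_perp = drag_perp,
            drag_par = drag_par, amplitude_eps = amplitude_eps)
  if (any(!is.finite(vals)) || any(vals <= 0))
    sm_stop("invalid_parameter", "all dimensional parameters must be positive")
  le <- (bending_a / (angular_freq * drag_perp))^(1 / 4)
  structure(c(as.list(vals), list(penetration_length = le, sp = length_l / le)),
            class = "dimensional_context")
}

#' @export
print.dimensional_context <- function(x, ...) {
  cat(sprintf("<dimensional_context> L = %g m, omega = %g rad/s, Sp = %.3g\n",
              x$length_l, x$angular_freq, x$sp))
  invisible(x)
}

#' Convert a reduced speed to a dimensional swimming speed
#'
#' \deqn{U_{dim} = \epsilon^2 \frac{c_\perp - c_\parallel}{2 c_\parallel}
#'       \, U \, L \omega \quad [m/s].}
#' Isotropic drag (\eqn{c_\perp = c_\parallel}) produces no thrust at this
#' order and returns zero with a warning.
#'
#' @param ctx A [dimensional_context()].
#' @param reduced_u Reduced swimming speed from any of the speed routines.
#' @return Speed in metres per second.
#' @export
redimensionalize <- function(ctx, reduced_u) {
  stopifnot(inherits(ctx, "dimensional_context"))
  aniso <- (ctx$drag_perp - ctx$drag_par) / (2 * ctx$drag_par)
  if (aniso == 0) {
    warning("isotropic drag (c_perp == c_par): no thrust at leading order")
    return(0)
  }
  ctx$amplitude_eps^2 * aniso * reduced_u * ctx$length_l * ctx$angular_freq
}

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Export kernel matrices to CSV
#'
#' Long format, one row per node pair: `xi1, xi2, gs, ga, gswim`, written
#' with 17 significant digits so a round trip is bit exact.
#'
#' @param kernel A [compute_kernels()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_kernel_csv <- function(kernel, path) {
  stopifnot(inherits(kernel, "speed_kernel"))
  idx <- expand.grid(i = seq_len(kernel$n), j = seq_len(kernel$n))
  df <- data.frame(
    xi1 = fmt17(kernel$nodes[idx$i]), xi2 = fmt17(kernel$nodes[idx$j]),
    gs = fmt17(kernel$gs_matrix[cbind(idx$i, idx$j)]),
    ga = fmt17(kernel$ga_matrix[cbind(idx$i, idx$j)]),
    gswim = fmt17(kernel$gswim_matrix[cbind(idx$i, idx$j)]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export filament beat frames to CSV
#'
#' Long format `(frame, s, x, y)` with one frame per time sample;
#' `x(s) = s` at leading order. Values carry 17 significant digits so a
#' read-back reproduces them exactly.
#'
#' @param shape A [filament_shape()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_shape_frames <- function(shape, path) {
  stopifnot(inherits(shape, "filament_shape"))
  nt <- length(shape$t_grid)
  ns <- length(shape$s_grid)
  df <- data.frame(
    frame = rep(seq_len(nt), each = ns),
    s = fmt17(rep(shape$s_grid, nt)),
    x = fmt17(rep(shape$s_grid, nt)),
    y = fmt17(as.vector(shape$y)))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) sm_stop("io", "could not write frames to '%s'", path)
  invisible(path)
}

#' Read a sampled forcing profile from CSV
#'
#' Expects columns `xi` and `f`; values are linearly interpolated between
#' samples (constant extrapolation at the ends).
#'
#' @param path CSV file with columns `xi`, `f`.
#' @param phase Phase function to attach.
#' @return A continuous [forcing_profile()].
#' @export
read_profile_csv <- function(path, phase = phase_constant()) {
  df <- utils::read.csv(path)
  if (!all(c("xi", "f") %in% names(df)))
    sm_stop("invalid_parameter", "profile CSV needs columns 'xi' and 'f'")
  forcing_profile(f = stats::approxfun(df$xi, df$f, rule = 2), phase = phase)
}
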