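# Forcing profiles: the internal moment distribution driving the filament.
#
# A profile represents the single-frequency moment forcing
#   m(s, t) = Re[f(s) exp(-i phi(s)) exp(it)],
# either as a continuous magnitude f on [0, 1] with phase phi, or as a list
# of point actuators (delta-function moments) with locations and strengths.

#' Create a forcing profile
#'
#' @param f For a continuous profile, a vectorized function of arc length on
#'   \[0, 1\] giving the forcing magnitude.
#' @param phase Phase function \eqn{\phi(\xi)} (vectorized). Defaults to the
#'   monophasic case \eqn{\phi \equiv 0}; a backwards travelling wave of
#'   wavenumber `k` is [phase_travelling()]`(k)`.
#' @param actuators For a discrete profile, a data frame (or two-column
#'   object) with columns `xi` (locations in \[0, 1\]) and `strength`.
#' @return An object of class `forcing_profile` with fields `kind`
#'   (`"continuous"` or `"discrete"`), `f`, `phase` and `actuators`.
#' @export
#' @examples
#' forcing_profile(f = function(x) sin(2 * pi * x))
#' forcing_profile(actuators = data.frame(xi = 0.309, strength = 1))
forcing_profile <- function(f = NULL, phase = phase_constant(), actuators = NULL) {
  if (!is.function(phase))
    sm_stop("invalid_parameter", "'phase' must be a function on [0, 1]")
  if (is.null(f) == is.null(actuators))
    sm_stop("invalid_parameter",
            "supply exactly one of 'f' (continuous) or 'actuators' (discrete)")
  if (!is.null(actuators)) {
    actuators <- as.data.frame(actuators)
    if (!all(c("xi", "strength") %in% names(actuators)))
      sm_stop("invalid_parameter", "'actuators' needs columns 'xi' and 'strength'")
    if (any(actuators$xi < 0 | actuators$xi > 1))
      sm_stop("invalid_parameter", "actuator locations must lie in [0, 1]")
    out <- list(kind = "discrete", f = NULL, phase = phase,
                actuators = actuators[c("xi", "strength")])
  } else {
    if (!is.function(f))
      sm_stop("invalid_parameter", "'f' must be a function on [0, 1]")
    out <- list(kind = "continuous", f = f, phase = phase, actuators = NULL)
  }
  class(out) <- "forcing_profile"
  out
}

#' @export
print.forcing_profile <- function(x, ...) {
  if (x$kind == "discrete") {
    cat(sprintf("<forcing_profile> discrete, %d actuator(s)\n", nrow(x$actuators)))
  } else {
    cat("<forcing_profile> continuous\n")
  }
  invisible(x)
}

#' Phase functions
#'
#' `phase_constant()` gives monophasic forcing (everything in phase);
#' `phase_travelling(k)` gives \eqn{\phi(\xi) = 2\pi k \xi}, a wave of
#' forcing with `k` wavelengths along the filament travelling towards the
#' distal end for `k > 0`.
#'
#' @param value Constant phase value (default 0).
#' @param k Wavenumber (wavelengths per filament length).
#' @return A vectorized function of arc length.
#' @export
phase_constant <- function(value = 0) {
  force(value)
  function(x) rep_len(value, length(x))
}

#' @rdname phase_constant
#' @export
phase_travelling <- function(k) {
  force(k)
  function(x) 2 * pi * k * x
}

#' Built-in forcing-profile fixtures
#'
#' Deterministic profiles used throughout the examples and tests: the
#' uniform profile observed approximately in spermatozoa, sinusoids,
#' piecewise-constant designs, actuator lists, and seeded random smooth
#' profiles (a low-order Fourier series with uniform coefficients in
#' \[-1, 1\]).
#'
#' @param name One of `"constant"`, `"sin"`, `"piecewise"`, `"actuators"`,
#'   `"random_smooth"`.
#' @param freq For `"sin"`: `f(x) = sin(2 pi freq x)` (default 1).
#' @param breaks,values For `"piecewise"`: `values[i]` on
#'   `[breaks[i], breaks[i+1])`.
#' @param actuators For `"actuators"`: data frame with `xi`, `strength`.
#' @param seed For `"random_smooth"`: integer seed (default 20240256).
#' @param n_modes For `"random_smooth"`: number of Fourier modes (default 3).
#' @param phase Phase function attached to the profile.
#' @return A [forcing_profile()].
#' @export
#' @examples
#' fixture_profiles("sin", freq = 4)          # f = sin(8 pi x)
#' fixture_profiles("piecewise", breaks = c(0, 0.625, 1), values = c(1, 0))
fixture_profiles <- function(name, freq = 1, breaks = NULL, values = NULL,
                             actuators = NULL, seed = 20240256, n_modes = 3,
                             phase = phase_constant()) {
  known <- c("constant", "sin", "piecewise", "actuators", "random_smooth")
  if (!is.character(name) || length(name) != 1L || !name %in% known)
    sm_stop("invalid_parameter", "unknown fixture '%s'; valid names: %s",
            paste(name, collapse = ","), paste(known, collapse = ", "))
  switch(name,
    constant = forcing_profile(f = function(x) rep_len(1, length(x)), phase = phase),
    sin = {
      force(freq)
      forcing_profile(f = function(x) sin(2 * pi * freq * x), phase = phase)
    },
    piecewise = {
      if (is.null(breaks) || is.null(values) || length(breaks) != length(values) + 1)
        sm_stop("invalid_parameter",
                "'piecewise' needs breaks (length m+1) and values (length m)")
      force(breaks); force(values)
      forcing_profile(f = function(x) {
        idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
        values[idx]
      }, phase = phase)
    },
    actuators = {
      if (is.null(actuators))
        sm_stop("invalid_parameter", "'actuators' fixture needs an actuator table")
      forcing_profile(actuators = actuators, phase = phase)
    },
    random_smooth = {
      cf <- withr_seed(seed, function() stats::runif(2 * n_modes + 1, -1, 1))
      force(n_modes)
      forcing_profile(f = function(x) {
        out <- rep_len(cf[1], length(x))
        for (m in seq_len(n_modes)) {
          out <- out + cf[2 * m] * sin(2 * pi * m * x) +
            cf[2 * m + 1] * cos(2 * pi * m * x)
        }
        out
      }, phase = phase)
    })
}

# Run fn with a local RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}
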