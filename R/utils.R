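# Internal helpers shared across modules.

#' @keywords internal
sm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("swimmodes_", class), "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_sp <- function(sp) {
  if (!is.numeric(sp) || length(sp) != 1L || !is.finite(sp) || sp <= 0)
    sm_stop("invalid_parameter", "'sp' must be a single positive finite number")
  if (sp > 30)
    sm_stop("invalid_parameter",
            "'sp' = %g exceeds the certified range (0, 30]", sp)
  invisible(sp)
}

#' Midpoint quadrature nodes on the unit interval
#'
#' Returns the nodes (2n - 1) / (2N), n = 1..N, used throughout the package
#' both as quadrature abscissae (midpoint rule, weight 1/N each) and as the
#' sampling grid on which the swimming-speed kernel is discretized.
#'
#' @param n Number of nodes (positive integer).
#' @return Numeric vector of length `n`, strictly inside (0, 1).
#' @export
#' @examples
#' midpoint_nodes(4)
midpoint_nodes <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    sm_stop("invalid_parameter", "'n' must be a positive integer")
  n <- as.integer(n)
  (2 * seq_len(n) - 1) / (2 * n)
}

# 2-norm condition number of a (possibly complex) dense matrix.
cond2 <- function(a) {
  d <- svd(a, nu = 0, nv = 0)$d
  if (min(d) == 0) return(Inf)
  max(d) / min(d)
}
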