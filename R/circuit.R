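#' Hill response function
#'
#' Sigmoidal firing-rate response `f(x) = x^n / (s^n + x^n)` mapping a
#' population activity to a normalised rate in `[0, 1)`. The response is
#' monotonically increasing on `x >= 0` with `f(0) = 0`, `f(s) = 1/2` and
#' `f -> 1` as `x -> Inf`; its derivative at the threshold is `n / (4 s)`.
#' For `x < 0` the algebraic formula is followed unchanged (for even `n` the
#' response is symmetric and physiologically meaningless there; trajectory
#' integration flags such excursions with a validity warning).
#'
#' @param x activity (vectorised).
#' @param s Hill threshold, `> 0`.
#' @param n Hill exponent, integer `>= 1`.
#' @return Response values, same shape as `x`.
#' @export
hill_response <- function(x, s = 2, n = 2) {
  stopifnot(s > 0, n >= 1)
  x^n / (s^n + x^n)
}

#' @rdname hill_response
#' @export
hill_derivative <- function(x, s = 2, n = 2) {
  stopifnot(s > 0, n >= 1)
  n * s^n * x^(n - 1) / (s^n + x^n)^2
}

.check_state <- function(x) {
  if (length(x) != 7) stop("state must have length 7")
  if (!all(is.finite(x))) stop("state must be finite")
  invisible(x)
}

#' Drift of the circuit
#'
#' Evaluates the deterministic driving force `F(x)` of the seven-population
#' firing-rate model: each population obeys
#' `C_i dx_i/dt = I_i - x_i / R_i + sum_j (+/-) T_ij f(x_j) (+/- D_input)`,
#' with the dopamine input entering the striatal D1 equation positively and
#' the D2 equation negatively, and the signs of the coupling terms fixed by
#' the excitatory/inhibitory wiring of the circuit. With a stimulation
#' protocol, the soma offset is added inside the target's bracket and, in
#' decoupled mode, every term sourced at the target is scaled by the
#' efferent gain.
#'
#' @param x length-7 activity vector.
#' @param params a [bg_params()] object.
#' @param protocol optional [bg_protocol()].
#' @return Length-7 rate of change (1/ms).
#' @export
bg_drift <- function(x, params, protocol = NULL) {
  .check_state(x)
  bg_drift_cpp(as.numeric(x), .pack_params(params), .pack_protocol(protocol))
}

#' Jacobian of the circuit drift
#'
#' Analytic 7x7 matrix `A` with `A[i, j] = dF_i / dx_j`: the diagonal carries
#' the leak rate `-1 / (C_i R_i) = -1 / tau` and off-diagonal entries are
#' `+/- T_ij f'(x_j) / C_i`.
#'
#' @inheritParams bg_drift
#' @return 7x7 numeric matrix.
#' @export
bg_jacobian <- function(x, params, protocol = NULL) {
  .check_state(x)
  bg_jacobian_cpp(as.numeric(x), .pack_params(params), .pack_protocol(protocol))
}

# Drift on many states at once (rows of X), used by the 2-D grid closure.
.drift_rows <- function(X, params, protocol = NULL) {
  bg_drift_grid_cpp(X, .pack_params(params), .pack_protocol(protocol))
}
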