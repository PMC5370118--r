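#' Brute-force Langevin simulation of the circuit
#'
#' Euler-Maruyama integration of `dx = F(x) dt + zeta`, where the Gaussian
#' white noise has autocorrelation `2 D delta(t - t')` per coordinate, i.e.
#' increments of variance `2 D_diff dt` per step. Runs are reproducible under
#' `set.seed()`; `D_diff = 0` reduces to (first-order accurate) deterministic
#' integration.
#'
#' @param params a [bg_params()] object (`D_diff` is the noise level).
#' @param x0 initial state.
#' @param duration simulated time in ms.
#' @param dt Euler-Maruyama step in ms (default 0.01; a warning is issued if
#'   `dt > tau/20`).
#' @param thin record every `thin`-th step (default 1).
#' @param protocol optional [bg_protocol()].
#' @param bound divergence guard: the run aborts with a diagnostic when any
#'   coordinate exceeds this magnitude.
#' @return A `bg_trajectory` with the recorded samples.
#' @export
simulate_langevin <- function(params, x0 = rep(1, 7), duration, dt = 0.01,
                              thin = 1L, protocol = NULL, bound = 1e3) {
  stopifnot(duration > 0, dt > 0, thin >= 1)
  .check_state(x0)
  if (dt > params$tau / 20)
    warning(sprintf("dt = %g ms is large relative to tau = %g ms", dt,
                    params$tau))
  res <- bg_langevin_cpp(as.numeric(x0), .pack_params(params),
                         .pack_protocol(protocol), duration, dt,
                         as.integer(thin), bound)
  if (res$status != 0)
    stop(sprintf(
      "Langevin trajectory diverged (|x| > %g) at t = %.3f ms; %d samples recorded",
      bound, res$t_last, res$n_rec))
  S <- res$states
  colnames(S) <- params$module_names
  structure(list(time = res$time, states = S, dt_out = dt * thin,
                 dt = dt, D_diff = params$D_diff),
            class = "bg_trajectory")
}

#' @rdname simulate_langevin
#' @param object a [bg_params()] object.
#' @param nsim number of independent trajectories.
#' @param seed optional seed passed to `set.seed()`.
#' @param ... arguments forwarded to `simulate_langevin()` (must include
#'   `duration`).
#' @return For the `simulate` method, a list of `nsim` trajectories.
#' @export
simulate.bg_params <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) simulate_langevin(object, ...))
}

#' Empirical potential landscape from sampled trajectories
#'
#' Oracle for `U = -ln P_ss`: 2-D histogram of post-burn-in samples on the
#' projection grid, normalised, floored, and log-transformed — the same type
#' contract as [potential_from_probability()].
#'
#' @param traj a `bg_trajectory` or list of trajectories (ensemble).
#' @param projection pair of module indices.
#' @param grid a [grid_spec()].
#' @param burn_in discarded initial time in ms. Default `NULL`: ten times the
#'   slowest linear relaxation time at the relaxed attractor (a principled,
#'   parameter-free choice), which for this circuit's uniform leak is
#'   `10 * tau`, computed from the Jacobian when parameters are supplied.
#' @param params optional [bg_params()] used to derive the default burn-in.
#' @param floor probability floor as a fraction of `max(P)`.
#' @param min_samples minimal number of post-burn-in samples (default 1e5).
#' @return A list with the `bg_prob_grid` (`P`) and `bg_landscape_grid` (`U`).
#' @export
empirical_landscape <- function(traj, projection = c(1, 6), grid,
                                burn_in = NULL, params = NULL,
                                floor = 1e-12, min_samples = 1e5) {
  trajs <- if (inherits(traj, "bg_trajectory")) list(traj) else traj
  if (is.null(burn_in)) {
    burn_in <- if (!is.null(params)) {
      xr <- trajs[[1]]$states[nrow(trajs[[1]]$states), ]
      ev <- eigen(bg_jacobian(xr, params), only.values = TRUE)$values
      rates <- abs(Re(ev))
      10 / max(min(rates), 1e-6)
    } else 10 * 6
  }
  pts <- do.call(rbind, lapply(trajs, function(tr) {
    keep <- tr$time >= burn_in
    tr$states[keep, projection, drop = FALSE]
  }))
  if (nrow(pts) < min_samples)
    stop(sprintf("only %d post-burn-in samples (< %g)", nrow(pts),
                 min_samples))
  ix <- floor((pts[, 1] - grid$xlim[1]) / grid$dx) + 1L
  iy <- floor((pts[, 2] - grid$ylim[1]) / grid$dy) + 1L
  keep <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny
  H <- matrix(0, grid$nx, grid$ny)
  tab <- table(factor(ix[keep], levels = 1:grid$nx),
               factor(iy[keep], levels = 1:grid$ny))
  H[] <- as.numeric(tab)
  P <- .new_prob_grid(H, grid, projection)
  list(P = P, U = potential_from_probability(P, floor = floor),
       n_samples = nrow(pts), burn_in = burn_in)
}

#' Dominant stochastic oscillation period
#'
#' Spectral estimate on a stationary trajectory segment: dominant peak of the
#' Welch-averaged periodogram of the mean-subtracted reference signal (cortex
#' by default), with an error bar from the half-power peak width (phase
#' diffusion broadens a stochastic oscillation peak well beyond one frequency
#' bin). Returns `NULL` when no peak rises above the noise floor.
#'
#' @param traj a `bg_trajectory`.
#' @param module reference module index (default 1, cortex).
#' @param burn_in discarded initial time in ms.
#' @param snr peak-to-median power threshold.
#' @param nseg Welch segments averaged (default 8).
#' @return List with `period` (ms) and `bin` (ms), or `NULL`.
#' @export
stochastic_period <- function(traj, module = 1, burn_in = 0, snr = 25,
                              nseg = 8) {
  keep <- traj$time >= burn_in
  y <- traj$states[keep, module]
  signal_period(y, traj$dt_out, snr = snr, nseg = nseg)
}
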