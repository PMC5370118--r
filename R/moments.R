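#' Time derivatives of the Gaussian moment closure
#'
#' Mean-field moment equations: the mean vector follows the deterministic
#' drift, `du/dt = F(u)`, and under the product (diagonal) ansatz each
#' retained variance obeys the diagonal of `sigma A^T + A sigma + 2 D`, i.e.
#' `dsigma_ii/dt = 2 A_ii(u) sigma_ii + 2 D_diff` with `A` the drift
#' Jacobian. In this circuit no population couples to itself through the Hill
#' response, so `A_ii = -1/tau` and the stationary variance is
#' `D_diff * tau` for every module.
#'
#' @param u length-7 mean vector.
#' @param sigma length-7 vector of diagonal variances (componentwise `>= 0`).
#' @param params a [bg_params()] object.
#' @param protocol optional [bg_protocol()].
#' @return List with `du` and `dsigma`.
#' @export
moment_derivatives <- function(u, sigma, params, protocol = NULL) {
  .check_state(u)
  if (length(sigma) != 7 || any(sigma < 0))
    stop("sigma must be a length-7 nonnegative vector")
  A <- bg_jacobian(u, params, protocol)
  list(du = bg_drift(u, params, protocol),
       dsigma = 2 * diag(A) * sigma + 2 * params$D_diff)
}

#' Evolve means and variances of the moment closure
#'
#' Integrates the coupled mean/variance system with the same adaptive
#' integrator (and contract) as [integrate_circuit()]. A negative variance
#' below `-1e-12` signals closure breakdown and raises an error carrying the
#' time and component index.
#'
#' @param params a [bg_params()] object.
#' @param u0 initial means (default all ones).
#' @param sigma0 initial variances (default all zero).
#' @param duration integration time in ms.
#' @param protocol optional [bg_protocol()].
#' @param dt_out,atol,rtol integrator settings.
#' @return A `bg_moments` object: `time`, `u` (steps x 7), `sigma`
#'   (steps x 7).
#' @export
evolve_moments <- function(params, u0 = rep(1, 7), sigma0 = rep(0, 7),
                           duration, protocol = NULL, dt_out = 0.05,
                           atol = 1e-9, rtol = 1e-7) {
  stopifnot(duration > 0)
  if (any(sigma0 < 0)) stop("initial variances must be >= 0")
  res <- bg_integrate_cpp(1L, c(as.numeric(u0), as.numeric(sigma0)),
                          .pack_params(params), .pack_protocol(protocol),
                          0, duration, dt_out, atol, rtol, numeric(0))
  if (res$status != 0)
    stop(sprintf("moment integrator failure at t = %.4f ms", res$t_last))
  sig <- res$states[, 8:14, drop = FALSE]
  bad <- which(sig < -1e-12, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "moment closure breakdown: sigma[%d] = %.3e at t = %.3f ms",
      bad[1, 2], sig[bad[1, 1], bad[1, 2]], res$time[bad[1, 1]]))
  }
  u <- res$states[, 1:7, drop = FALSE]
  colnames(u) <- colnames(sig) <- params$module_names
  structure(list(time = res$time, u = u, sigma = pmax(sig, 0)),
            class = "bg_moments")
}

#' @export
print.bg_moments <- function(x, ...) {
  n <- nrow(x$u)
  cat(sprintf("bg_moments: %d samples over [0, %g] ms\n", n, max(x$time)))
  cat("  final mean:    ", paste(sprintf("%.4f", x$u[n, ]), collapse = " "), "\n")
  cat("  final variance:", paste(sprintf("%.4g", x$sigma[n, ]), collapse = " "), "\n")
  invisible(x)
}

#' Regular 2-D grid specification
#'
#' Cell-centred grid on a projection plane. When ranges are omitted they are
#' auto-set from an attractor projection as
#' `[min - pad*sqrt(sigma_max), max + pad*sqrt(sigma_max)]` (default
#' `pad = 4`).
#'
#' @param xlim,ylim axis ranges.
#' @param nx,ny cell counts (default 200 x 200).
#' @return A `bg_grid_spec` list with cell centres `x`, `y` and spacings
#'   `dx`, `dy`.
#' @export
grid_spec <- function(xlim, ylim, nx = 200, ny = 200) {
  stopifnot(nx >= 4, ny >= 4, xlim[2] > xlim[1], ylim[2] > ylim[1])
  dx <- diff(xlim) / nx
  dy <- diff(ylim) / ny
  structure(list(
    xlim = xlim, ylim = ylim, nx = as.integer(nx), ny = as.integer(ny),
    dx = dx, dy = dy,
    x = xlim[1] + dx * (seq_len(nx) - 0.5),
    y = ylim[1] + dy * (seq_len(ny) - 0.5)), class = "bg_grid_spec")
}

.auto_grid <- function(u_proj, sigma_proj, nx = 200, ny = 200, pad = 4) {
  s <- sqrt(max(sigma_proj))
  grid_spec(c(min(u_proj[, 1]) - pad * s, max(u_proj[, 1]) + pad * s),
            c(min(u_proj[, 2]) - pad * s, max(u_proj[, 2]) + pad * s),
            nx, ny)
}

#' Two-dimensional Gaussian probability snapshot
#'
#' Under the mean-field product ansatz the joint probability factorises over
#' modules, so its projection onto two coordinates is the product of the two
#' Gaussian marginals:
#' `P(x_a, x_b) = N(x_a; u_a, sigma_a) N(x_b; u_b, sigma_b)`, evaluated at
#' cell centres and renormalised on the grid.
#'
#' @param u,sigma length-7 means and variances (a moment snapshot).
#' @param grid a [grid_spec()].
#' @param projection ordered pair of module indices, default `c(1, 6)`.
#' @param sigma_floor minimum admissible variance; smaller values are an
#'   error advising a variance floor.
#' @return A `bg_prob_grid`: the grid plus matrix `P` (nx x ny) with
#'   `sum(P) * dx * dy = 1`.
#' @export
gaussian_probability_2d <- function(u, sigma, grid, projection = c(1, 6),
                                    sigma_floor = 1e-8) {
  sa <- sigma[projection[1]]; sb <- sigma[projection[2]]
  if (sa < sigma_floor || sb < sigma_floor)
    stop("projected variance below ", sigma_floor,
         "; apply a minimum-variance floor before projecting")
  P <- outer(stats::dnorm(grid$x, u[projection[1]], sqrt(sa)),
             stats::dnorm(grid$y, u[projection[2]], sqrt(sb)))
  .new_prob_grid(P, grid, projection)
}

.new_prob_grid <- function(P, grid, projection) {
  tot <- sum(P) * grid$dx * grid$dy
  if (tot <= 0) stop("probability grid has no mass")
  structure(c(grid[c("xlim", "ylim", "nx", "ny", "dx", "dy", "x", "y")],
              list(P = P / tot, projection = projection)),
            class = "bg_prob_grid")
}

#' @export
print.bg_prob_grid <- function(x, ...) {
  cat(sprintf(
    "bg_prob_grid: %d x %d cells on [%.3g, %.3g] x [%.3g, %.3g], proj (%d, %d)\n",
    x$nx, x$ny, x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2],
    x$projection[1], x$projection[2]))
  invisible(x)
}

#' Steady-state probability on a 2-D projection
#'
#' Runs the full mean-field pipeline. The dynamics are first classified
#' (via [detect_limit_cycle()], unless a classification is supplied). In the
#' mono-stable case the moments are relaxed to convergence and the converged
#' Gaussian snapshot is returned. In the oscillatory case the moments are
#' relaxed onto their periodic orbit and the steady-state distribution is the
#' uniform time average of `n_snapshots` evenly phased Gaussian snapshots
#' over exactly one period, renormalised on the grid.
#'
#' @param params a [bg_params()] object.
#' @param projection ordered pair of module indices, default cortex/thalamus.
#' @param grid optional [grid_spec()]; auto-ranged from the attractor when
#'   omitted.
#' @param protocol optional [bg_protocol()].
#' @param n_snapshots snapshots per period in the oscillatory average
#'   (default 200).
#' @param nx,ny grid resolution used when `grid` is auto-ranged.
#' @param cycle optional pre-computed `bg_cycle` (or `NULL` for mono-stable)
#'   to skip re-classification; use `missing` to classify internally.
#' @param transient settle time in ms before sampling moments.
#' @param sigma_floor variance floor applied before projecting.
#' @return A `bg_prob_grid` with extra fields: `snapshots` (list of matrices
#'   `u`, `sigma`, one row per phase), `oscillating`, `period`, `cycle`.
#' @export
steady_state_probability <- function(params, projection = c(1, 6),
                                     grid = NULL, protocol = NULL,
                                     n_snapshots = 200, nx = 200, ny = 200,
                                     cycle, transient = 2500,
                                     sigma_floor = 1e-8) {
  if (missing(cycle))
    cycle <- detect_limit_cycle(params, protocol = protocol,
                                transient = transient)
  sig_stat <- params$D_diff * params$tau
  if (is.null(cycle)) {
    # mono-stable: relax the moments to convergence
    mo <- evolve_moments(params, duration = transient, protocol = protocol,
                         dt_out = 1)
    n <- nrow(mo$u)
    u <- mo$u[n, ]; sg <- pmax(mo$sigma[n, ], sigma_floor)
    d <- moment_derivatives(u, sg, params, protocol)
    if (max(abs(d$du)) > 1e-6 || max(abs(d$dsigma)) > 1e-8)
      stop("unclassifiable dynamics: moments neither converged nor periodic")
    if (is.null(grid))
      grid <- .auto_grid(matrix(u[projection], 1), sg[projection], nx, ny)
    out <- gaussian_probability_2d(u, sg, grid, projection, sigma_floor)
    out$snapshots <- list(u = matrix(u, 1, dimnames = list(NULL, params$module_names)),
                          sigma = matrix(sg, 1))
    out$oscillating <- FALSE
    out$period <- NA_real_
    out$cycle <- NULL
    return(out)
  }
  # oscillatory: relax onto the periodic moment orbit, then sample one period
  Tp <- cycle$period
  dt_s <- Tp / n_snapshots
  mo <- evolve_moments(params, duration = transient + Tp, protocol = protocol,
                       dt_out = dt_s)
  phase_idx <- which(mo$time >= transient)[seq_len(n_snapshots)]
  U <- mo$u[phase_idx, , drop = FALSE]
  SG <- pmax(mo$sigma[phase_idx, , drop = FALSE], sigma_floor)
  if (is.null(grid))
    grid <- .auto_grid(U[, projection, drop = FALSE],
                       max(SG[, projection]), nx, ny)
  acc <- matrix(0, grid$nx, grid$ny)
  for (k in seq_len(n_snapshots)) {
    Pk <- outer(stats::dnorm(grid$x, U[k, projection[1]], sqrt(SG[k, projection[1]])),
                stats::dnorm(grid$y, U[k, projection[2]], sqrt(SG[k, projection[2]])))
    tot <- sum(Pk) * grid$dx * grid$dy
    if (tot > 0) acc <- acc + Pk / tot
  }
  out <- .new_prob_grid(acc / n_snapshots, grid, projection)
  out$snapshots <- list(u = U, sigma = SG)
  out$oscillating <- TRUE
  out$period <- Tp
  out$cycle <- cycle
  out
}
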