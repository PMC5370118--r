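#' Integrate the deterministic circuit
#'
#' Solves `dx/dt = F(x)` with an adaptive Dormand-Prince 5(4) integrator,
#' returning the solution on a regular output grid. Integration is
#' deterministic given identical inputs. If any coordinate drops below
#' `-s/10` a validity warning is emitted: the even-exponent Hill response is
#' symmetric about zero, so negative activities are outside the
#' physiologically meaningful regime (the equations themselves are integrated
#' unclamped).
#'
#' @param params a [bg_params()] object.
#' @param x0 initial state (length 7), default all ones.
#' @param duration integration time in ms.
#' @param protocol optional [bg_protocol()].
#' @param dt_out output sampling interval in ms.
#' @param atol,rtol absolute/relative integration tolerances.
#' @return A `bg_trajectory`: list with `time`, `states` (steps x 7 matrix,
#'   columns named by module) and integrator metadata.
#' @export
integrate_circuit <- function(params, x0 = rep(1, 7), duration,
                              protocol = NULL, dt_out = 0.05,
                              atol = 1e-9, rtol = 1e-7) {
  stopifnot(duration > 0)
  .check_state(x0)
  res <- bg_integrate_cpp(0L, as.numeric(x0), .pack_params(params),
                          .pack_protocol(protocol), 0, duration, dt_out,
                          atol, rtol, numeric(0))
  if (res$status != 0) {
    n <- max(res$n_out, 1)
    stop(sprintf(
      "integrator failure at t = %.4f ms; last valid state: (%s)",
      res$t_last,
      paste(sprintf("%.6g", res$states[n, ]), collapse = ", ")))
  }
  colnames(res$states) <- params$module_names
  if (min(res$states) < -params$s / 10)
    warning("trajectory left the physiological regime: some activity < -s/10")
  structure(list(time = res$time, states = res$states,
                 dt_out = dt_out, atol = atol, rtol = rtol),
            class = "bg_trajectory")
}

#' @export
print.bg_trajectory <- function(x, ...) {
  cat(sprintf("bg_trajectory: %d samples over [0, %g] ms (dt_out = %g)\n",
              length(x$time), max(x$time), x$dt_out))
  invisible(x)
}

#' Integrate the Hopf normal form (analytic test system)
#'
#' `dx = mu*x - omega*y - x r^2; dy = omega*x + mu*y - y r^2` through the same
#' adaptive integrator as the circuit. For `mu > 0` the system settles on a
#' limit cycle of radius `sqrt(mu)` with period `2*pi/omega`; used as an
#' analytic oracle for cycle detection and geometry.
#'
#' @param mu,omega normal-form parameters.
#' @param x0 initial state (length 2).
#' @param duration,dt_out,atol,rtol as in [integrate_circuit()].
#' @return List with `time` and two-column `states`.
#' @export
integrate_hopf <- function(mu, omega, x0 = c(0.1, 0), duration,
                           dt_out = 0.05, atol = 1e-10, rtol = 1e-8) {
  res <- bg_integrate_cpp(2L, as.numeric(x0), numeric(34), numeric(0),
                          0, duration, dt_out, atol, rtol, c(mu, omega))
  if (res$status != 0) stop("integrator failure in Hopf normal form")
  list(time = res$time, states = res$states)
}

#' Locate fixed points of the circuit
#'
#' Newton iteration with the analytic Jacobian from a deterministic lattice
#' of starting points in the positive orthant (`lattice_points` per axis on
#' `[0, 2 I_i R_i]`) plus the endpoint of a relaxation trajectory. Converged
#' roots are deduplicated within Euclidean radius `tol` and classified by the
#' eigenvalues of the Jacobian: `stable` if all real parts are negative,
#' `unstable` if the leading unstable eigenvalues form a complex pair (or all
#' real parts are positive), `saddle` otherwise.
#'
#' @param params a [bg_params()] object.
#' @param protocol optional [bg_protocol()].
#' @param lattice_points starting points per axis (default 3).
#' @param tol duplicate-merge radius and residual tolerance scale.
#' @param extra_starts optional matrix of additional starting states (rows).
#' @return A `bg_fixed_points` object: list of records with `location`,
#'   `eigenvalues`, `stability`; empty list if no root is found.
#' @export
find_fixed_points <- function(params, protocol = NULL, lattice_points = 3,
                              tol = 1e-4, extra_starts = NULL) {
  stopifnot(lattice_points >= 1)
  hi <- 2 * params$I * params$R
  axes <- lapply(1:7, function(i) seq(0, hi[i], length.out = lattice_points))
  starts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  relax <- tryCatch({
    tr <- suppressWarnings(integrate_circuit(params, duration = 3000,
                                             protocol = protocol, dt_out = 1))
    tr$states[nrow(tr$states), ]
  }, error = function(e) NULL)
  if (!is.null(relax)) starts <- rbind(starts, relax)
  if (!is.null(extra_starts)) starts <- rbind(starts, extra_starts)

  roots <- list()
  for (k in seq_len(nrow(starts))) {
    x <- .newton_root(starts[k, ], params, protocol, tol)
    if (is.null(x)) next
    dup <- FALSE
    for (r in roots) if (sqrt(sum((r - x)^2)) < tol) { dup <- TRUE; break }
    if (!dup) roots[[length(roots) + 1]] <- x
  }
  records <- lapply(roots, function(x) {
    ev <- eigen(bg_jacobian(x, params, protocol), only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    re <- Re(ev)
    lab <- if (max(re) < 0) "stable"
           else if (all(re > 0) || abs(Im(ev[1])) > 1e-12) "unstable"
           else "saddle"
    list(location = as.numeric(x), eigenvalues = ev, stability = lab)
  })
  structure(records, class = "bg_fixed_points")
}

#' @export
print.bg_fixed_points <- function(x, ...) {
  cat(sprintf("%d fixed point(s)\n", length(x)))
  for (r in x)
    cat(sprintf("  [%s] %s, leading Re(lambda) = %.5f\n",
                paste(sprintf("%.4f", r$location), collapse = ", "),
                r$stability, max(Re(r$eigenvalues))))
  invisible(x)
}

# Damped Newton solve of F(x) = 0; NULL on failure.
.newton_root <- function(x, params, protocol, tol, max_iter = 80) {
  pv <- .pack_params(params); pr <- .pack_protocol(protocol)
  for (it in seq_len(max_iter)) {
    Fx <- bg_drift_cpp(x, pv, pr)
    if (max(abs(Fx)) < 1e-11) return(x)
    J <- bg_jacobian_cpp(x, pv, pr)
    step <- tryCatch(solve(J, Fx), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    lam <- 1
    f0 <- sum(Fx^2)
    repeat {
      xn <- x - lam * step
      Fn <- bg_drift_cpp(xn, pv, pr)
      if (all(is.finite(Fn)) && sum(Fn^2) < f0) break
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    x <- xn
    if (max(abs(x)) > 1e4) return(NULL)
  }
  NULL
}

# Indices and refined positions of strict local maxima of a sampled signal,
# with quadratic (three-point parabola) refinement of peak times.
.find_peaks <- function(t, y) {
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  if (!length(idx)) return(list(idx = integer(0), t = numeric(0)))
  tp <- vapply(idx, function(i) {
    a <- y[i - 1]; b <- y[i]; c <- y[i + 1]
    den <- a - 2 * b + c
    off <- if (abs(den) > 1e-300) 0.5 * (a - c) / den else 0
    t[i] + off * (t[i + 1] - t[i])
  }, 0)
  list(idx = idx, t = tp)
}

#' Detect a limit cycle of the circuit
#'
#' Integrates past a transient and detects periodicity from successive maxima
#' of the cortex coordinate. The period is the mean inter-peak interval; a
#' cycle is reported only when the peak-to-peak amplitude exceeds
#' `amplitude_tol` and the envelope is sustained. Damped ringing near a Hopf
#' point keeps a consistent period and, under critical slowing, can decay
#' arbitrarily slowly, so the check is adaptive: while the envelope is still
#' shrinking by more than 1% per window the transient is extended (doubling,
#' up to `max_time`), continuing from the last state; a window that decays
#' below `amplitude_tol`, or is still shrinking at `max_time`, is classified
#' as no cycle. Inconsistent inter-peak intervals (coefficient of variation
#' above `cv_tol`) raise an error reporting failure to lock onto a cycle.
#' The returned cycle is one closed period, resampled uniformly in time.
#'
#' @param params a [bg_params()] object.
#' @param protocol optional [bg_protocol()].
#' @param x0 initial state.
#' @param transient discarded settle time in ms.
#' @param record analysed window in ms.
#' @param dt_out sampling interval in ms.
#' @param amplitude_tol minimal cortex peak-to-peak amplitude (default 1e-3).
#' @param cv_tol maximal coefficient of variation of inter-peak intervals.
#' @param n_points samples per period in the returned cycle.
#' @param max_time total integration budget in ms for the adaptive transient.
#' @return A `bg_cycle` (closed one-period trajectory with `period` in ms and
#'   per-module `envelope`), or `NULL` when the attractor is stationary.
#' @export
detect_limit_cycle <- function(params, protocol = NULL, x0 = rep(1, 7),
                               transient = 2500, record = 1500,
                               dt_out = 0.02, amplitude_tol = 1e-3,
                               cv_tol = 0.01, n_points = 2000,
                               max_time = 2e5) {
  stopifnot(transient > 0, record > 0)
  x <- x0
  total <- 0
  extend <- transient
  repeat {
    tr <- suppressWarnings(
      integrate_circuit(params, x0 = x, duration = extend + record,
                        protocol = protocol, dt_out = dt_out))
    total <- total + extend + record
    keep <- tr$time >= extend
    tt <- tr$time[keep]
    X <- tr$states[keep, , drop = FALSE]
    y <- X[, 1]
    if (diff(range(y)) < amplitude_tol) return(NULL)
    third <- floor(length(y) / 3)
    amp_first <- diff(range(y[seq_len(third)]))
    amp_last <- diff(range(y[(length(y) - third + 1):length(y)]))
    if (amp_last < amplitude_tol) return(NULL)
    if (amp_last >= 0.99 * amp_first) break       # sustained envelope
    if (total >= max_time) return(NULL)           # still shrinking: damped
    x <- tr$states[nrow(tr$states), ]
    extend <- min(2 * extend, max_time - total)
  }
  pk <- .find_peaks(tt, y)
  if (length(pk$idx) < 3) return(NULL)
  intervals <- diff(pk$t)
  period <- mean(intervals)
  cv <- stats::sd(intervals) / period
  if (!is.finite(cv) || cv > cv_tol)
    stop(sprintf(
      "failed to lock onto a cycle: inter-peak interval CV = %.3g > %.3g",
      cv, cv_tol))
  # One closed period ending at the last detected peak.
  t_end <- pk$t[length(pk$t)]
  t_start <- t_end - period
  ts <- seq(t_start, t_end, length.out = n_points + 1)
  S <- apply(X, 2, function(col) stats::approx(tt, col, xout = ts)$y)
  S[n_points + 1, ] <- S[1, ]  # close the loop exactly
  colnames(S) <- params$module_names
  structure(list(time = ts - t_start, states = S, period = period,
                 envelope = apply(X, 2, range),
                 closure_gap = sqrt(sum((S[1, ] - S[n_points + 1, ])^2))),
            class = "bg_cycle")
}

#' @export
print.bg_cycle <- function(x, ...) {
  cat(sprintf("bg_cycle: period = %.3f ms (%.2f Hz), %d samples/period\n",
              x$period, 1000 / x$period, nrow(x$states) - 1))
  invisible(x)
}

#' Dopamine phase scan
#'
#' For each dopamine level, locates fixed points and tests for a limit cycle,
#' reporting the attractor-mean cortex activity (time average over one period
#' when oscillatory, the stable fixed-point value otherwise), the oscillation
#' flag, the cortex envelope, the period, and the leading eigenvalue real
#' part of the interior fixed point (the Hopf indicator).
#'
#' @param params a [bg_params()] object (its `D_input` is overridden).
#' @param D_grid ascending vector of dopamine input levels.
#' @param protocol optional [bg_protocol()].
#' @param ... passed to [detect_limit_cycle()].
#' @return A `bg_phase_scan` data frame with one row per level.
#' @export
scan_dopamine <- function(params, D_grid, protocol = NULL, ...) {
  stopifnot(length(D_grid) >= 1)
  rows <- lapply(D_grid, function(D) {
    p <- params; p$D_input <- D
    out <- list(D_input = D, oscillating = NA, mean_cortex = NA_real_,
                env_min = NA_real_, env_max = NA_real_, period = NA_real_,
                leading_re = NA_real_, n_fixed_points = NA_integer_,
                error = NA_character_)
    tryCatch({
      cyc <- detect_limit_cycle(p, protocol = protocol, ...)
      fps <- find_fixed_points(p, protocol = protocol, lattice_points = 2)
      out$n_fixed_points <- length(fps)
      if (length(fps)) {
        interior <- fps[[which.max(vapply(fps, function(r)
          max(Re(r$eigenvalues)), 0))]]
        out$leading_re <- max(Re(interior$eigenvalues))
      }
      if (!is.null(cyc)) {
        out$oscillating <- TRUE
        w <- diff(cyc$time)                     # uniform, but be exact
        xm <- (cyc$states[-1, 1] + cyc$states[-nrow(cyc$states), 1]) / 2
        out$mean_cortex <- sum(w * xm) / sum(w) # trapezoid over one period
        out$env_min <- cyc$envelope[1, 1]
        out$env_max <- cyc$envelope[2, 1]
        out$period <- cyc$period
      } else {
        out$oscillating <- FALSE
        st <- fps[vapply(fps, function(r) r$stability == "stable", TRUE)]
        if (length(st)) {
          out$mean_cortex <- st[[1]]$location[1]
          out$env_min <- out$env_max <- out$mean_cortex
        }
      }
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(lapply(r, unname), stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  class(df) <- c("bg_phase_scan", "data.frame")
  df
}

#' Locate Hopf bifurcation points by eigenvalue bisection
#'
#' Refines a bracketing interval of dopamine levels in which the leading
#' eigenvalue real part of the tracked interior fixed point changes sign,
#' by bisection to width `width`. The fixed point is continued by Newton
#' iteration from the previous level's root.
#'
#' @param params a [bg_params()] object.
#' @param D_lo,D_hi dopamine levels bracketing one sign change.
#' @param width final bracket width (default 1e-3).
#' @return List with the refined `D` (midpoint), bracket, and leading real
#'   parts at the bracket ends.
#' @export
hopf_point <- function(params, D_lo, D_hi, width = 1e-3) {
  lead_re <- function(D, x_guess) {
    p <- params; p$D_input <- D
    x <- .newton_root(x_guess, p, NULL, 1e-4)
    if (is.null(x)) {
      fps <- find_fixed_points(p, lattice_points = 2)
      if (!length(fps)) stop("no fixed point found at D = ", D)
      x <- fps[[1]]$location
    }
    list(re = max(Re(eigen(bg_jacobian(x, p), only.values = TRUE)$values)),
         x = x)
  }
  p0 <- params; p0$D_input <- D_lo
  fps <- find_fixed_points(p0, lattice_points = 2)
  if (!length(fps)) stop("no fixed point at the lower bracket end")
  x <- fps[[1]]$location
  lo <- lead_re(D_lo, x); hi <- lead_re(D_hi, lo$x)
  if (sign(lo$re) == sign(hi$re))
    stop("no sign change of the leading eigenvalue in [D_lo, D_hi]")
  x <- lo$x
  while (D_hi - D_lo > width) {
    Dm <- (D_lo + D_hi) / 2
    mid <- lead_re(Dm, x)
    x <- mid$x
    if (sign(mid$re) == sign(lo$re)) {
      D_lo <- Dm; lo <- mid
    } else {
      D_hi <- Dm; hi <- mid
    }
  }
  list(D = (D_lo + D_hi) / 2, bracket = c(D_lo, D_hi),
       leading_re = c(lo$re, hi$re))
}

#' Loop length of a projected cycle
#'
#' Polyline arc length of the one-period orbit projected onto a pair of
#' module coordinates. Errors if the projected curve is not closed within
#' `closure_tol` (relative to the curve extent); a degenerate (single-point)
#' cycle has length 0.
#'
#' @param cycle a `bg_cycle` (or any list with `states` whose first/last rows
#'   coincide).
#' @param projection ordered pair of module indices, default cortex/thalamus
#'   `c(1, 6)`.
#' @param closure_tol relative closure tolerance.
#' @return Loop length (scalar).
#' @export
cycle_geometry <- function(cycle, projection = c(1, 6), closure_tol = 1e-3) {
  P <- cycle$states[, projection, drop = FALSE]
  ext <- max(apply(P, 2, function(z) diff(range(z))))
  gap <- sqrt(sum((P[1, ] - P[nrow(P), ])^2))
  if (ext > 0 && gap > closure_tol * ext)
    stop("projected curve is not closed: gap = ", signif(gap, 4))
  seg <- sqrt(rowSums(diff(P)^2))
  sum(seg)
}

#' Dominant oscillation period of a sampled signal
#'
#' Spectral oracle: period of the dominant discrete-Fourier peak of the
#' mean-subtracted signal, `NULL` when no peak rises above the noise floor
#' (peak power < `snr` times the median non-DC power; for white noise the
#' max/median power ratio grows only like `log n`, so the default 25 rejects
#' noise for any realistic record length).
#'
#' @param y sampled signal (regular sampling).
#' @param dt sampling interval in ms.
#' @param snr peak-to-median power threshold (default 25).
#' @param nseg number of Welch segments averaged into the periodogram
#'   (default 1, the raw periodogram: full resolution for deterministic
#'   signals; stochastic callers average several segments so that the
#'   phase-diffusion-broadened peak is smooth and its width meaningful).
#' @return List with `period` (ms) and `bin` (the period uncertainty in ms:
#'   half-width of the half-power interval around the peak, at least one
#'   frequency bin — stochastic oscillations are phase-diffusion broadened,
#'   so the peak width, not the bin width, is the honest resolution), or
#'   `NULL`.
#' @export
signal_period <- function(y, dt, snr = 25, nseg = 1) {
  n0 <- length(y)
  L <- floor(n0 / nseg)
  sp <- 0
  for (k in seq_len(nseg)) {
    seg <- y[((k - 1) * L + 1):(k * L)]
    seg <- seg - mean(seg)
    sp <- sp + Mod(stats::fft(seg))^2
  }
  n <- L
  half <- 2:floor(n / 2)
  pw <- sp[half]
  k <- which.max(pw)
  if (pw[k] < snr * stats::median(pw)) return(NULL)
  df <- 1 / (n * dt)                    # frequency bin, cycles per ms
  freq <- (half[k] - 1) * df
  # half-power interval around the peak
  lo <- k; while (lo > 1 && pw[lo - 1] >= pw[k] / 2) lo <- lo - 1
  hi <- k; while (hi < length(pw) && pw[hi + 1] >= pw[k] / 2) hi <- hi + 1
  f_lo <- max(freq - max(k - lo, 1) * df, df)
  f_hi <- freq + max(hi - k, 1) * df
  list(period = 1 / freq,
       bin = max(1 / f_lo - 1 / freq, 1 / freq - 1 / f_hi))
}
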