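# Shared fixtures, memoised: several tests reuse the same expensive objects
# (detected cycles, landscapes, dopamine scans).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# All connection strengths zero: seven uncoupled leak (Ornstein-Uhlenbeck)
# units, the analytically solvable limit.
uncoupled_params <- function(D_input = 0, D_diff = 0.01) {
  Tz <- c(T16 = 0, T47 = 0, T21 = 0, T26 = 0, T31 = 0, T36 = 0, T57 = 0,
          T42 = 0, T53 = 0, T64 = 0, T45 = 0, T75 = 0, T71 = 0, T17 = 0)
  bg_params(T = Tz, D_input = D_input, D_diff = D_diff)
}

cycle08 <- function() cached("cycle08",
  detect_limit_cycle(bg_params(D_input = 0.8)))

landscape08 <- function() cached("landscape08",
  bg_landscape(bg_params(D_input = 0.8), nx = 100, ny = 100,
               n_snapshots = 120))

landscape14 <- function() cached("landscape14",
  bg_landscape(bg_params(D_input = 1.4), nx = 100, ny = 100))

# Fine dopamine scan shared by the regime-structure, monotonicity and period
# acceptance checks (41 levels, step 0.02).
scan_fine <- function() cached("scan_fine",
  scan_dopamine(bg_params(), seq(0.6, 1.4, by = 0.02)))

# Independent transcription of the seven circuit equations, used as the
# term-by-term drift oracle (kept deliberately separate from the package
# implementation).
oracle_drift <- function(x, D_input, I = c(0.1, 0.05, 1.2, 4.4, 2.8, 2, 1.2),
                         R = 1.67, tau = 6, s = 2, n = 2) {
  f <- x^n / (s^n + x^n)
  C <- tau / R
  c(I[1] - x[1] / R + 2.0 * f[6],
    I[2] - x[2] / R + 1.4 * f[1] + 1.4 * f[6] + D_input,
    I[3] - x[3] / R + 1.4 * f[1] + 1.4 * f[6] - D_input,
    I[4] - x[4] / R + 2.0 * f[7] - 3.2 * f[2] - 3.0 * f[5],
    I[5] - x[5] / R + 1.0 * f[7] - 3.2 * f[3],
    I[6] - x[6] / R - 3.2 * f[4],
    I[7] - x[7] / R + 1.8 * f[1] - 1.8 * f[5]) / C
}

# Unit circle sampled as a closed two-column cycle (analytic geometry toy).
circle_cycle <- function(r = 1, n = 1e4, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  list(states = cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
       period = 100)
}

# 3-point running median (used by the rise-then-fall acceptance checks).
med3 <- function(x) vapply(seq_along(x), function(i)
  stats::median(x[max(1, i - 1):min(length(x), i + 1)]), 0)
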