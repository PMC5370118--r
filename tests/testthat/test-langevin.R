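test_that("noiseless Langevin reduces to the deterministic flow", {
  p <- bg_params(D_input = 0.9, D_diff = 0)
  tr_em <- simulate_langevin(p, duration = 100, dt = 0.005)
  tr_rk <- integrate_circuit(p, duration = 100, dt_out = 0.005)
  n <- nrow(tr_em$states)
  # Euler is first order: endpoint error O(dt)
  expect_lt(max(abs(tr_em$states[n, ] - tr_rk$states[n, ])), 0.01)
})

test_that("Langevin runs are seed-reproducible and guard against divergence", {
  p <- bg_params(D_input = 0.8)
  set.seed(11); a <- simulate_langevin(p, duration = 50, dt = 0.01)
  set.seed(11); b <- simulate_langevin(p, duration = 50, dt = 0.01)
  expect_identical(a$states, b$states)
  expect_warning(simulate_langevin(p, duration = 1, dt = 1), "large")
  pns <- bg_params(D_input = 0.8, D_diff = 5)
  set.seed(1)
  expect_error(suppressWarnings(
    simulate_langevin(pns, duration = 500, dt = 0.05, bound = 4)), "diverged")
  # simulate() method returns an ensemble
  ens <- simulate(bg_params(D_input = 0.8), nsim = 2, seed = 3, duration = 10)
  expect_length(ens, 2)
  expect_s3_class(ens[[1]], "bg_trajectory")
})

test_that("uncoupled stationary law matches the Ornstein-Uhlenbeck moments", {
  p0 <- uncoupled_params(D_diff = 0.01)
  set.seed(21)
  tr <- simulate_langevin(p0, x0 = p0$I * p0$R, duration = 30000, dt = 0.01,
                          thin = 10)
  keep <- tr$time > 60
  X <- tr$states[keep, ]
  Ttot <- 30000 - 60
  sig2 <- p0$D_diff * p0$tau
  se_mean <- sqrt(2 * sig2 * p0$tau / Ttot)
  se_var <- sig2 * sqrt(4 * p0$tau / Ttot)
  for (i in 1:7) {
    expect_lt(abs(mean(X[, i]) - (p0$I * p0$R)[i]), 3 * se_mean)
    expect_lt(abs(stats::var(X[, i]) - sig2), 3 * se_var)
  }
})

test_that("different seeds give statistically indistinguishable stationary samples", {
  p0 <- uncoupled_params(D_diff = 0.01)
  draw <- function(seed) {
    set.seed(seed)
    tr <- simulate_langevin(p0, x0 = p0$I * p0$R, duration = 15000,
                            dt = 0.01, thin = 3000)  # one sample per 5 tau
    tr$states[tr$time > 60, 1]
  }
  ks <- suppressWarnings(stats::ks.test(draw(101), draw(202)))
  expect_gt(ks$p.value, 0.01)
})

test_that("halving the step changes stationary moments within Monte-Carlo error", {
  p0 <- uncoupled_params(D_diff = 0.01)
  run <- function(dt) {
    set.seed(5)
    tr <- simulate_langevin(p0, x0 = p0$I * p0$R, duration = 20000, dt = dt,
                            thin = round(0.1 / dt))
    colMeans(tr$states[tr$time > 60, ])
  }
  se_mean <- sqrt(2 * 0.06 * 6 / 20000)
  expect_lt(max(abs(run(0.01) - run(0.005))), 3 * sqrt(2) * se_mean)
})

test_that("stochastic trajectories circulate coherently around the ring", {
  p <- bg_params(D_input = 0.8)
  set.seed(31)
  tr <- simulate_langevin(p, duration = 20000, dt = 0.01, thin = 10)
  keep <- tr$time > 200
  xy <- tr$states[keep, c(1, 6)]
  # 5 ms moving average (~1/12 period) strips sample-to-sample noise jitter
  xy <- apply(xy, 2, function(z)
    as.numeric(stats::filter(z, rep(1 / 51, 51), sides = 2)))
  xy <- xy[!is.na(xy[, 1]), ]
  cyc <- cycle08()
  ring <- bgflux:::.resample_loop(cyc$states[, c(1, 6)], 1000)
  ctr <- colMeans(ring)   # geometric ring centre
  ang <- atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1])
  dang <- diff(ang)
  dang <- (dang + pi) %% (2 * pi) - pi
  # window at the trajectory's own mean rotation period (noise lengthens it)
  period <- stochastic_period(tr, burn_in = 200)$period
  per_window <- floor(period / tr$dt_out)
  nwin <- floor(length(dang) / per_window)
  wind <- vapply(seq_len(nwin), function(k)
    sum(dang[((k - 1) * per_window + 1):(k * per_window)]), 0)
  expect_gt(mean(sign(wind) == sign(sum(dang))), 0.95)
})

test_that("empirical landscape localises the uncoupled basin and enforces sampling", {
  p0 <- uncoupled_params(D_diff = 0.01)
  target <- (p0$I * p0$R)[c(1, 6)]
  sdv <- sqrt(p0$D_diff * p0$tau)
  g <- grid_spec(target[1] + c(-4, 4) * sdv, target[2] + c(-4, 4) * sdv,
                 30, 30)
  set.seed(41)
  tr <- simulate_langevin(p0, x0 = p0$I * p0$R, duration = 20000, dt = 0.01,
                          thin = 10)
  emp <- empirical_landscape(tr, projection = c(1, 6), grid = g, params = p0)
  mn <- which(emp$U$U == min(emp$U$U), arr.ind = TRUE)[1, ]
  expect_lt(abs(emp$U$x[mn[1]] - target[1]), 1.5 * g$dx)
  expect_lt(abs(emp$U$y[mn[2]] - target[2]), 1.5 * g$dy)
  short <- simulate_langevin(p0, duration = 50, dt = 0.01)
  expect_error(empirical_landscape(short, grid = g, params = p0),
               "post-burn-in")
})

test_that("stochastic period matches the deterministic cycle at weak noise", {
  t <- seq(0, 3000, by = 0.5)
  tone <- list(time = t, states = matrix(sin(2 * pi * t / 50), ncol = 1),
               dt_out = 0.5)
  class(tone) <- "bg_trajectory"
  sp <- stochastic_period(tone, module = 1)
  expect_lt(abs(sp$period - 50), sp$bin + 0.5)
  set.seed(51)
  noise <- list(time = t, states = matrix(rnorm(length(t)), ncol = 1),
                dt_out = 0.5)
  class(noise) <- "bg_trajectory"
  expect_null(stochastic_period(noise, module = 1))
  # weak-noise circuit: spectral peak within resolution of the ODE period
  p <- bg_params(D_input = 0.8, D_diff = 0.001)
  set.seed(61)
  tr <- simulate_langevin(p, duration = 30000, dt = 0.01, thin = 10)
  sp2 <- stochastic_period(tr, burn_in = 200)
  det_period <- cycle08()$period
  expect_lt(abs(sp2$period - det_period), sp2$bin + 0.5)
})
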