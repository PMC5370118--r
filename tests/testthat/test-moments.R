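test_that("moment derivatives follow the diagonal closure", {
  p0 <- uncoupled_params(D_diff = 0.01)
  u <- p0$I * p0$R
  d <- moment_derivatives(u, rep(0.02, 7), p0)
  # uncoupled: dsigma/dt = -(2/tau) sigma + 2 D
  expect_equal(d$dsigma, rep(-2 / 6 * 0.02 + 2 * 0.01, 7))
  expect_equal(d$du, rep(0, 7))
  # stationary variance D tau
  dstat <- moment_derivatives(u, rep(0.01 * 6, 7), p0)
  expect_equal(dstat$dsigma, rep(0, 7), tolerance = 1e-14)
  # noiseless invariance
  pz <- uncoupled_params(D_diff = 0)
  expect_equal(moment_derivatives(u, rep(0, 7), pz)$dsigma, rep(0, 7))
  expect_error(moment_derivatives(u, rep(-0.1, 7), p0), "nonnegative")
})

test_that("moment evolution matches the linear closed form and an independent RK4 oracle", {
  p0 <- uncoupled_params(D_diff = 0.01)
  mo <- evolve_moments(p0, u0 = p0$I * p0$R, sigma0 = rep(0, 7),
                       duration = 30, dt_out = 0.5)
  sig_exact <- 0.01 * 6 * (1 - exp(-2 * mo$time / 6))
  for (i in 1:7)
    expect_equal(unname(mo$sigma[, i]), sig_exact, tolerance = 1e-7)
  # stationary start stays put
  mo2 <- evolve_moments(p0, u0 = p0$I * p0$R, sigma0 = rep(0.06, 7),
                        duration = 20, dt_out = 1)
  expect_lt(max(abs(sweep(mo2$u, 2, p0$I * p0$R))), 1e-9)
  expect_lt(max(abs(mo2$sigma - 0.06)), 1e-9)

  # coupled case against a small-step RK4 oracle written here from scratch
  p <- bg_params(D_input = 1.2)
  rhs <- function(y) {
    u <- y[1:7]; s <- y[8:14]
    du <- oracle_drift(u, 1.2)
    h <- 1e-5
    Aii <- vapply(1:7, function(i) {
      e <- rep(0, 7); e[i] <- h
      (oracle_drift(u + e, 1.2)[i] - oracle_drift(u - e, 1.2)[i]) / (2 * h)
    }, 0)
    c(du, 2 * Aii * s + 2 * p$D_diff)
  }
  y <- c(rep(1, 7), rep(0.02, 7))
  dt <- 1e-3
  for (k in 1:1000) {
    k1 <- rhs(y); k2 <- rhs(y + dt / 2 * k1); k3 <- rhs(y + dt / 2 * k2)
    k4 <- rhs(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  mo3 <- evolve_moments(p, u0 = rep(1, 7), sigma0 = rep(0.02, 7),
                        duration = 1, dt_out = 1)
  expect_equal(unname(mo3$u[2, ]), y[1:7], tolerance = 1e-6)
  expect_equal(unname(mo3$sigma[2, ]), y[8:14], tolerance = 1e-6)
  expect_error(evolve_moments(p, sigma0 = rep(-1, 7), duration = 1), ">= 0")
})

test_that("oscillatory moment means track the deterministic limit cycle", {
  p <- bg_params(D_input = 0.8)
  cyc <- cycle08()
  mo <- evolve_moments(p, duration = 2500 + cyc$period, dt_out = cyc$period / 400)
  keep <- mo$time >= 2500
  u_win <- mo$u[keep, , drop = FALSE][1:400, ]
  n <- nrow(cyc$states)
  cyc_mean <- colMeans(cyc$states[-n, , drop = FALSE])
  expect_equal(colMeans(u_win), cyc_mean, tolerance = 1e-3)
})

test_that("2-D Gaussian snapshots are normalised products of the marginals", {
  g <- grid_spec(c(-5, 5), c(-5, 5), 120, 120)
  P <- gaussian_probability_2d(rep(0, 7), rep(1, 7), g, projection = c(1, 2))
  expect_lt(abs(sum(P$P) * P$dx * P$dy - 1), 1e-8)
  peak <- which(P$P == max(P$P), arr.ind = TRUE)[1, ]
  expect_lt(abs(P$x[peak[1]]), P$dx)
  expect_lt(abs(P$y[peak[2]]), P$dy)
  # dnorm-product oracle
  oracle <- outer(dnorm(g$x), dnorm(g$y))
  oracle <- oracle / (sum(oracle) * g$dx * g$dy)
  expect_equal(P$P, oracle, tolerance = 1e-12)
  # truncating grid still renormalises to one
  gn <- grid_spec(c(-0.5, 0.5), c(-0.5, 0.5), 40, 40)
  Pn <- gaussian_probability_2d(rep(0, 7), rep(1, 7), gn, projection = c(1, 2))
  expect_lt(abs(sum(Pn$P) * Pn$dx * Pn$dy - 1), 1e-8)
  expect_error(gaussian_probability_2d(rep(0, 7), rep(0, 7), g, c(1, 2)),
               "variance")
})

test_that("steady-state probability: mono-stable case centres on the fixed point", {
  p0 <- uncoupled_params(D_diff = 0.01)
  P <- steady_state_probability(p0, projection = c(1, 6), nx = 80, ny = 80)
  expect_false(P$oscillating)
  peak <- which(P$P == max(P$P), arr.ind = TRUE)[1, ]
  target <- (p0$I * p0$R)[c(1, 6)]
  expect_lt(abs(P$x[peak[1]] - target[1]), P$dx)
  expect_lt(abs(P$y[peak[2]] - target[2]), P$dy)
  expect_lt(abs(sum(P$P) * P$dx * P$dy - 1), 1e-8)
})

test_that("period-averaged ridge hugs the deterministic cycle to within the noise width", {
  p <- bg_params(D_input = 0.8)
  cyc <- cycle08()
  P <- landscape08()$P
  U <- landscape08()$U
  ctr <- colMeans(cyc$states[-nrow(cyc$states), c(1, 6)])
  angles <- seq(0, 2 * pi, length.out = 49)[-49]
  rr <- seq(0.05, 2.2, by = 0.004)
  crest <- t(vapply(angles, function(a) {
    px <- ctr[1] + rr * cos(a); py <- ctr[2] + rr * sin(a)
    keep <- px >= P$xlim[1] & px <= P$xlim[2] &
      py >= P$ylim[1] & py <= P$ylim[2]
    vU <- bgflux:::.bilinear(U$x, U$y, U$U, px[keep], py[keep])
    k <- which.min(vU)
    c(px[keep][k], py[keep][k])
  }, numeric(2)))
  ring <- bgflux:::.resample_loop(cyc$states[, c(1, 6)], 4000)
  d <- vapply(seq_len(nrow(crest)), function(i)
    sqrt(min((ring[, 1] - crest[i, 1])^2 + (ring[, 2] - crest[i, 2])^2)), 0)
  noise_sd <- sqrt(p$D_diff * p$tau)
  # the crest is biased toward slow arcs by up to ~1 noise sd at fast arcs;
  # it never detaches from the cycle by more than 1.5 sd
  expect_lt(median(d), 0.5 * noise_sd)
  expect_lt(max(d), 1.5 * noise_sd)
})

test_that("doubling the snapshot count leaves the period average unchanged", {
  p <- bg_params(D_input = 0.8)
  cyc <- cycle08()
  g <- grid_spec(landscape08()$P$xlim, landscape08()$P$ylim, 80, 80)
  P200 <- steady_state_probability(p, grid = g, cycle = cyc, n_snapshots = 200)
  P400 <- steady_state_probability(p, grid = g, cycle = cyc, n_snapshots = 400)
  tv <- 0.5 * sum(abs(P200$P - P400$P)) * g$dx * g$dy
  expect_lt(tv, 1e-4)
})
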