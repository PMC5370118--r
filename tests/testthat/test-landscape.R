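# Helper: wrap a raw probability matrix into the grid container used by the
# landscape operations (bypasses the moment pipeline for analytic toys).
prob_grid <- function(M, g, proj = c(1, 2)) bgflux:::.new_prob_grid(M, g, proj)

# Helper: landscape container with prescribed potential values.
u_grid <- function(Uvals, g, proj = c(1, 2)) {
  structure(list(xlim = g$xlim, ylim = g$ylim, nx = g$nx, ny = g$ny,
                 dx = g$dx, dy = g$dy, x = g$x, y = g$y, U = Uvals,
                 floor = 0, at_floor = matrix(FALSE, g$nx, g$ny),
                 projection = proj), class = "bg_landscape_grid")
}

test_that("potential is the negative log probability with a finite floor", {
  g <- grid_spec(c(0, 1), c(0, 1), 10, 10)
  P <- prob_grid(matrix(1, 10, 10), g)
  U <- potential_from_probability(P)
  expect_equal(max(U$U) - min(U$U), 0)
  expect_equal(U$U[1, 1], -log(1))  # uniform density on the unit square
  # log-ratio of a two-level field
  M <- matrix(exp(-1), 10, 10); M[6:10, ] <- 1 - exp(-1)
  P2 <- prob_grid(M, g)
  U2 <- potential_from_probability(P2)
  expect_equal(U2$U[1, 1] - U2$U[10, 10], log((1 - exp(-1)) / exp(-1)))
  # argmin U = argmax P
  expect_identical(which.min(U2$U), which.max(P2$P))
  # unnormalised input refused
  P_bad <- P; P_bad$P <- P$P * 2
  expect_error(potential_from_probability(P_bad), "not normalized")
})

test_that("a Gaussian landscape is an upward paraboloid of curvature 1/(2 sigma)", {
  sig <- 0.06
  g <- grid_spec(c(-0.8, 0.8), c(-0.8, 0.8), 200, 200)
  M <- outer(dnorm(g$x, 0, sqrt(sig)), dnorm(g$y, 0, sqrt(sig)))
  U <- potential_from_probability(prob_grid(M, g))
  j0 <- which.min(abs(g$y))
  keep <- abs(g$x) < 0.5
  fit <- stats::lm(U$U[keep, j0] ~ I(g$x[keep]^2))
  expect_lt(abs(stats::coef(fit)[2] - 1 / (2 * sig)) / (1 / (2 * sig)), 0.01)
})

test_that("equilibrium Ornstein-Uhlenbeck flux vanishes at matched variance", {
  # gradient drift F = -x/tau with sigma^2 = D tau: detailed balance, J = 0
  tau <- 1; Dd <- 1
  g <- grid_spec(c(-4.5, 4.5), c(-4.5, 4.5), 2251, 2251)
  M <- outer(dnorm(g$x, 0, sqrt(Dd * tau)), dnorm(g$y, 0, sqrt(Dd * tau)))
  P <- prob_grid(M, g)
  F2d <- list(Fx = matrix(rep(-g$x / tau, g$ny), g$nx, g$ny),
              Fy = matrix(rep(-g$y / tau, each = g$nx), g$nx, g$ny))
  J <- flux_field(P, F2d, Dd)
  expect_lt(max(sqrt(J$Jx^2 + J$Jy^2)), 1e-6)
  # entropy production of the equilibrium state is numerically zero
  expect_lt(entropy_production_rate(P, J, Dd), 1e-8)
  # flux is zeroed on floored cells by contract
  expect_true(all(J$Jx[J$at_floor] == 0) && all(J$Jy[J$at_floor] == 0))
  expect_error(flux_field(P, list(Fx = F2d$Fx[1:5, 1:5], Fy = F2d$Fy),
                          Dd), "same grid")
})

test_that("Hopf normal-form flux rotates tangentially along the analytic ring", {
  # stationary density P ~ exp((mu r^2/2 - r^4/4)/D) is exact for the normal
  # form with isotropic additive noise; the flux must be purely azimuthal
  mu <- 0.25; om <- 2 * pi / 100; Dd <- 0.01
  g <- grid_spec(c(-1, 1), c(-1, 1), 400, 400)
  r2 <- outer(g$x^2, rep(1, g$ny)) + outer(rep(1, g$nx), g$y^2)
  M <- exp((mu * r2 / 2 - r2^2 / 4) / Dd)
  P <- prob_grid(M, g)
  X <- outer(g$x, rep(1, g$ny)); Y <- outer(rep(1, g$nx), g$y)
  F2d <- list(Fx = (mu - r2) * X - om * Y, Fy = om * X + (mu - r2) * Y)
  J <- flux_field(P, F2d, Dd)
  on_ring <- abs(sqrt(r2) - sqrt(mu)) < 0.02
  rad <- (J$Jx * X + J$Jy * Y)[on_ring] / sqrt(r2[on_ring])
  tang <- (-J$Jx * Y + J$Jy * X)[on_ring] / sqrt(r2[on_ring])
  expect_lt(max(abs(rad)) / max(abs(tang)), 0.01)
})

test_that("force decomposition residual is pure discretization error", {
  # OU configuration: the identity F = J/P - D grad U holds exactly in the
  # continuum, so the grid residual must be tiny and floor cells excluded
  tau <- 20; Dd <- 0.05
  g <- grid_spec(c(-1, 1), c(-1, 1), 400, 400)
  M <- outer(dnorm(g$x, 0, sqrt(Dd * tau)), dnorm(g$y, 0, sqrt(Dd * tau)))
  P <- prob_grid(M, g)
  F2d <- list(Fx = matrix(rep(-g$x / tau, g$ny), g$nx, g$ny),
              Fy = matrix(rep(-g$y / tau, each = g$nx), g$nx, g$ny))
  J <- flux_field(P, F2d, Dd)
  U <- potential_from_probability(P)
  r <- decomposition_residual(F2d, J, U, P)
  # interior cells: the identity holds to the central-difference error; the
  # outermost ring uses one-sided (first-order) stencils and is checked by
  # the refinement study instead
  interior <- r$residual[2:(g$nx - 1), 2:(g$ny - 1)]
  expect_lt(max(interior, na.rm = TRUE), 1e-6)
  expect_identical(r$n_excluded, sum(is.na(r$residual)))
})

test_that("barrier height recovers the Mexican-hat closed form", {
  g <- grid_spec(c(-1.6, 1.6), c(-1.6, 1.6), 641, 641)
  r2 <- outer(g$x^2, rep(1, g$ny)) + outer(rep(1, g$nx), g$y^2)
  U <- u_grid((r2 - 1)^2, g)
  bh <- barrier_height(U, circle_cycle(r = 1, n = 4000), projection = c(1, 2))
  expect_equal(bh$U_min, 0, tolerance = 1e-3)
  expect_equal(bh$U_max, 1, tolerance = 1e-3)
  expect_equal(bh$barrier, 1, tolerance = 1e-3)
  # constant potential has zero barrier
  bh0 <- barrier_height(u_grid(matrix(3, g$nx, g$ny), g),
                        circle_cycle(r = 1, n = 1000), projection = c(1, 2))
  expect_equal(bh0$barrier, 0)
  expect_error(barrier_height(U, NULL), "mono-stable")
})

test_that("average flux along the cycle is the arc-length mean of |J|", {
  g <- grid_spec(c(-2, 2), c(-2, 2), 201, 201)
  geom <- list(xlim = g$xlim, ylim = g$ylim, nx = g$nx, ny = g$ny,
               dx = g$dx, dy = g$dy, x = g$x, y = g$y,
               at_floor = matrix(FALSE, g$nx, g$ny), D_diff = 0.01,
               projection = c(1, 2))
  zero <- matrix(0, g$nx, g$ny)
  J0 <- structure(c(geom, list(Jx = zero, Jy = zero)), class = "bg_flux_field")
  circ <- circle_cycle(r = 1, n = 3000)
  expect_equal(average_flux(J0, circ, projection = c(1, 2)), 0)
  # constant tangential magnitude c on circles -> J_Average = c
  X <- outer(g$x, rep(1, g$ny)); Y <- outer(rep(1, g$nx), g$y)
  r <- pmax(sqrt(X^2 + Y^2), 1e-9)
  cval <- 0.37
  Jc <- structure(c(geom, list(Jx = -cval * Y / r, Jy = cval * X / r)),
                  class = "bg_flux_field")
  expect_equal(average_flux(Jc, circ, projection = c(1, 2)), cval,
               tolerance = 1e-4)
  expect_error(average_flux(Jc, NULL), "undefined")
})

test_that("entropy production is a quadratic functional of the flux", {
  g <- grid_spec(c(-2, 2), c(-2, 2), 101, 101)
  M <- outer(dnorm(g$x), dnorm(g$y))
  P <- prob_grid(M, g)
  X <- outer(g$x, rep(1, g$ny)); Y <- outer(rep(1, g$nx), g$y)
  J1 <- structure(list(xlim = g$xlim, ylim = g$ylim, nx = g$nx, ny = g$ny,
                       dx = g$dx, dy = g$dy, x = g$x, y = g$y,
                       Jx = -Y * P$P, Jy = X * P$P,
                       at_floor = matrix(FALSE, g$nx, g$ny),
                       D_diff = 0.05, projection = c(1, 2)),
                  class = "bg_flux_field")
  e1 <- entropy_production_rate(P, J1, 0.05)
  J2 <- J1; J2$Jx <- 2 * J1$Jx; J2$Jy <- 2 * J1$Jy
  expect_gt(e1, 0)
  expect_equal(entropy_production_rate(P, J2, 0.05), 4 * e1)
})

test_that("flux along the ring acts as the velocity that drives the oscillation", {
  L <- landscape08()
  cyc <- L$cycle
  ring <- bgflux:::.resample_loop(cyc$states[, c(1, 6)], 400)
  jx <- bgflux:::.bilinear(L$J$x, L$J$y, L$J$Jx, ring[, 1], ring[, 2])
  jy <- bgflux:::.bilinear(L$J$x, L$J$y, L$J$Jy, ring[, 1], ring[, 2])
  pv <- bgflux:::.bilinear(L$P$x, L$P$y, L$P$P, ring[, 1], ring[, 2])
  # deterministic projected speed at the matching cycle points
  idx <- round(seq(1, nrow(cyc$states) - 1, length.out = 400))
  V <- bgflux:::.drift_rows(cyc$states[idx, ], L$params)
  speed <- sqrt(V[, 1]^2 + V[, 6]^2)
  # J/P plays the role of the velocity along the ring
  jp <- sqrt(jx^2 + jy^2) / pv
  expect_gt(stats::cor(jp, speed), 0.8)
  # flux direction is parallel to the oscillation path (median angle < 15 deg)
  closed <- rbind(ring, ring[1, ])
  tang <- diff(closed)
  tang <- tang / sqrt(rowSums(tang^2))
  cosang <- (jx * tang[, 1] + jy * tang[, 2]) / sqrt(jx^2 + jy^2)
  ang <- acos(pmin(pmax(abs(cosang), -1), 1)) * 180 / pi
  expect_lt(median(ang), 15)
})

test_that("steady-state flux is numerically divergence free away from the floor", {
  L <- landscape08()
  Lf <- cached("landscape08_200", bg_landscape(bg_params(D_input = 0.8),
    grid = grid_spec(L$P$xlim, L$P$ylim, 200, 200), n_snapshots = 120))
  div1 <- bgflux:::.grad_x(L$J$Jx, L$J$dx) + bgflux:::.grad_y(L$J$Jy, L$J$dy)
  div2 <- bgflux:::.grad_x(Lf$J$Jx, Lf$J$dx) + bgflux:::.grad_y(Lf$J$Jy, Lf$J$dy)
  core1 <- !L$U$at_floor; core2 <- !Lf$U$at_floor
  m1 <- mean(abs(div1[core1])); m2 <- mean(abs(div2[core2]))
  expect_lt(m2, m1)
})

test_that("the assembled landscape object reports coherent metrics", {
  L <- landscape08()
  expect_true(L$metrics$oscillating)
  expect_gt(L$metrics$barrier, 0)
  expect_gt(L$metrics$J_average, 0)
  expect_gt(L$metrics$epr, 0)
  expect_gt(L$metrics$loop_length, 0)
  expect_equal(L$metrics$period, L$cycle$period)
  # barrier endpoints: U_max inside the ring exceeds U_min on it
  expect_gt(L$metrics$U_max, L$metrics$U_min)
  L14 <- landscape14()
  expect_false(L14$metrics$oscillating)
  expect_identical(L14$metrics$J_average, 0)
  expect_gt(L14$metrics$epr, 0)  # weak non-equilibrium currents remain
  s <- summary(L)
  expect_s3_class(s, "data.frame")
  expect_identical(s$oscillating, TRUE)
})
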