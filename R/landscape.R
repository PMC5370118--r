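#' Potential landscape from a probability grid
#'
#' Non-equilibrium potential `U = -ln(max(P, floor))`, with the floor set
#' relative to the grid maximum so that `U` is finite everywhere. The argmin
#' of `U` coincides with the argmax of `P`.
#'
#' @param P a `bg_prob_grid` (normalised; checked).
#' @param floor probability floor as a fraction of `max(P)` (default 1e-12).
#' @return A `bg_landscape_grid`: grid geometry plus potential matrix `U`,
#'   the absolute floor used, and the logical matrix `at_floor`.
#' @export
potential_from_probability <- function(P, floor = 1e-12) {
  if (!inherits(P, "bg_prob_grid")) stop("P must be a bg_prob_grid")
  if (abs(sum(P$P) * P$dx * P$dy - 1) > 1e-8)
    stop("probability grid is not normalized")
  pf <- floor * max(P$P)
  U <- -log(pmax(P$P, pf))
  structure(list(xlim = P$xlim, ylim = P$ylim, nx = P$nx, ny = P$ny,
                 dx = P$dx, dy = P$dy, x = P$x, y = P$y,
                 U = U, floor = pf, at_floor = P$P <= pf,
                 projection = P$projection),
            class = "bg_landscape_grid")
}

#' @export
print.bg_landscape_grid <- function(x, ...) {
  cat(sprintf(
    "bg_landscape_grid: %d x %d, U in [%.3f, %.3f], %d cells at floor\n",
    x$nx, x$ny, min(x$U), max(x$U), sum(x$at_floor)))
  invisible(x)
}

# Central differences in the grid interior, one-sided first-order differences
# at the boundary rows/columns. M is nx x ny indexed [x, y].
.grad_x <- function(M, dx) {
  n <- nrow(M)
  G <- M
  G[2:(n - 1), ] <- (M[3:n, ] - M[1:(n - 2), ]) / (2 * dx)
  G[1, ] <- (M[2, ] - M[1, ]) / dx
  G[n, ] <- (M[n, ] - M[n - 1, ]) / dx
  G
}
.grad_y <- function(M, dy) t(.grad_x(t(M), dy))

#' Two-dimensional drift field on a grid (projection closure)
#'
#' The circuit drift lives in seven dimensions while landscapes are plotted
#' on a two-coordinate projection, so the five off-projection coordinates
#' must be closed. `"conditional"` (default) sets them, per cell, to their
#' probability-weighted conditional means across the phase snapshots (the
#' weight of phase k at a cell is that phase's Gaussian probability there);
#' `"nearest"` uses the off-projection coordinates of the snapshot whose
#' projected mean is nearest to the cell. Mono-stable distributions have a
#' single snapshot, so both closures reduce to fixing the off-projection
#' coordinates at their converged means.
#'
#' @param P a `bg_prob_grid` from [steady_state_probability()] (carries the
#'   phase snapshots).
#' @param params a [bg_params()] object.
#' @param protocol optional [bg_protocol()].
#' @param closure `"conditional"` or `"nearest"`.
#' @return List of matrices `Fx`, `Fy` (nx x ny): the two projected drift
#'   components.
#' @export
drift_field_2d <- function(P, params, protocol = NULL,
                           closure = c("conditional", "nearest")) {
  closure <- match.arg(closure)
  if (is.null(P$snapshots)) stop("P carries no moment snapshots")
  proj <- P$projection
  off <- setdiff(1:7, proj)
  U <- P$snapshots$u
  SG <- P$snapshots$sigma
  nph <- nrow(U)
  ncell <- P$nx * P$ny
  xa <- rep(P$x, times = P$ny)
  xb <- rep(P$y, each = P$nx)
  X <- matrix(0, ncell, 7)
  X[, proj[1]] <- xa
  X[, proj[2]] <- xb
  if (nph == 1) {
    for (j in off) X[, j] <- U[1, j]
  } else if (closure == "conditional") {
    W <- matrix(0, ncell, nph)
    for (k in seq_len(nph)) {
      W[, k] <- stats::dnorm(xa, U[k, proj[1]], sqrt(SG[k, proj[1]])) *
        stats::dnorm(xb, U[k, proj[2]], sqrt(SG[k, proj[2]]))
    }
    rs <- rowSums(W)
    # cells far from every snapshot: fall back to the phase-average closure
    flat <- rs <= 1e-300
    if (any(flat)) {
      W[flat, ] <- 1
      rs[flat] <- nph
    }
    for (j in off) X[, j] <- as.numeric(W %*% U[, j]) / rs
  } else {
    D2 <- outer(xa, U[, proj[1]], "-")^2 + outer(xb, U[, proj[2]], "-")^2
    nearest <- max.col(-D2, ties.method = "first")
    for (j in off) X[, j] <- U[nearest, j]
  }
  Fm <- .drift_rows(X, params, protocol)
  list(Fx = matrix(Fm[, proj[1]], P$nx, P$ny),
       Fy = matrix(Fm[, proj[2]], P$nx, P$ny))
}

#' Probability flux field on the projection grid
#'
#' Steady-state probability flux `J = F P - D grad P`, evaluated with central
#' differences (one-sided at grid boundaries). Cells at the probability floor
#' carry zero flux by contract.
#'
#' @param P a `bg_prob_grid`.
#' @param drift2d list with matrices `Fx`, `Fy` on the same grid (see
#'   [drift_field_2d()]).
#' @param D_diff diffusion coefficient (constant, isotropic).
#' @param floor probability floor as a fraction of `max(P)`.
#' @return A `bg_flux_field`: grid geometry plus `Jx`, `Jy`, the drift used,
#'   and the floor mask.
#' @export
flux_field <- function(P, drift2d, D_diff, floor = 1e-12) {
  if (!identical(dim(drift2d$Fx), dim(P$P)) ||
      !identical(dim(drift2d$Fy), dim(P$P)))
    stop("drift2d is not on the same grid as P")
  pf <- floor * max(P$P)
  at_floor <- P$P <= pf
  Jx <- drift2d$Fx * P$P - D_diff * .grad_x(P$P, P$dx)
  Jy <- drift2d$Fy * P$P - D_diff * .grad_y(P$P, P$dy)
  Jx[at_floor] <- 0
  Jy[at_floor] <- 0
  structure(list(xlim = P$xlim, ylim = P$ylim, nx = P$nx, ny = P$ny,
                 dx = P$dx, dy = P$dy, x = P$x, y = P$y,
                 Jx = Jx, Jy = Jy, Fx = drift2d$Fx, Fy = drift2d$Fy,
                 D_diff = D_diff, at_floor = at_floor,
                 projection = P$projection),
            class = "bg_flux_field")
}

#' @export
print.bg_flux_field <- function(x, ...) {
  cat(sprintf("bg_flux_field: %d x %d, max |J| = %.4g\n",
              x$nx, x$ny, max(sqrt(x$Jx^2 + x$Jy^2))))
  invisible(x)
}

#' Residual of the force decomposition
#'
#' In the continuum the driving force decomposes exactly as
#' `F = J_ss / P_ss - D grad U`; on a finite grid the cell-wise residual
#' `|| F - (J/P - D grad U) ||` is pure discretization error and shrinks
#' under grid refinement (first order at the one-sided boundary stencils,
#' second order in the interior). A cell is evaluated only when the whole
#' finite-difference stencil is above the probability floor: the floor clamp
#' creates an artificial crease in `U`, so gradients at cells adjacent to
#' floored cells are clamp artefacts, not discretization error. Excluded
#' cells are counted and reported.
#'
#' @param F2d list with `Fx`, `Fy`.
#' @param J a `bg_flux_field`.
#' @param U a `bg_landscape_grid`.
#' @param P a `bg_prob_grid`.
#' @return List with the residual magnitude matrix (NA on excluded cells),
#'   `max`, `mean`, and `n_excluded`.
#' @export
decomposition_residual <- function(F2d, J, U, P) {
  if (!identical(c(J$nx, J$ny), c(U$nx, U$ny)) ||
      !identical(c(J$nx, J$ny), c(P$nx, P$ny)))
    stop("fields are not on a common grid")
  af <- U$at_floor | J$at_floor
  touch <- af
  touch[-1, ] <- touch[-1, ] | af[-nrow(af), ]
  touch[-nrow(af), ] <- touch[-nrow(af), ] | af[-1, ]
  touch[, -1] <- touch[, -1] | af[, -ncol(af)]
  touch[, -ncol(af)] <- touch[, -ncol(af)] | af[, -1]
  keep <- !touch
  Rx <- F2d$Fx - (J$Jx / P$P - J$D_diff * .grad_x(U$U, U$dx))
  Ry <- F2d$Fy - (J$Jy / P$P - J$D_diff * .grad_y(U$U, U$dy))
  R <- sqrt(Rx^2 + Ry^2)
  R[!keep] <- NA_real_
  list(residual = R, max = max(R[keep]), mean = mean(R[keep]),
       n_excluded = sum(!keep))
}

# Bilinear interpolation of grid matrix M (cell-centred) at points (px, py).
# Points outside the cell-centre hull are clamped to it.
.bilinear <- function(gx, gy, M, px, py) {
  nx <- length(gx); ny <- length(gy)
  px <- pmin(pmax(px, gx[1]), gx[nx])
  py <- pmin(pmax(py, gy[1]), gy[ny])
  ix <- pmin(pmax(findInterval(px, gx), 1L), nx - 1L)
  iy <- pmin(pmax(findInterval(py, gy), 1L), ny - 1L)
  tx <- (px - gx[ix]) / (gx[ix + 1] - gx[ix])
  ty <- (py - gy[iy]) / (gy[iy + 1] - gy[iy])
  M[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    M[cbind(ix + 1, iy)] * tx * (1 - ty) +
    M[cbind(ix, iy + 1)] * (1 - tx) * ty +
    M[cbind(ix + 1, iy + 1)] * tx * ty
}

# Even-odd ray-casting point-in-polygon, vectorised over query points.
# poly: 2-column matrix of vertices (closed or open).
.in_polygon <- function(px, py, poly) {
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Resample a closed polyline to n points uniformly in arc length.
.resample_loop <- function(poly, n) {
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(poly)^2))
  keep <- c(TRUE, seg > 0)          # drop zero-length segments
  poly <- poly[keep, , drop = FALSE]
  s <- c(0, cumsum(seg[seg > 0]))
  total <- s[length(s)]
  if (total == 0 || nrow(poly) < 2) return(matrix(poly[1, ], n, 2, byrow = TRUE))
  target <- seq(0, total, length.out = n + 1)[seq_len(n)]
  cbind(stats::approx(s, poly[, 1], xout = target, ties = "ordered")$y,
        stats::approx(s, poly[, 2], xout = target, ties = "ordered")$y)
}

#' Barrier height of an oscillation ring landscape
#'
#' For a Mexican-hat landscape the barrier is `U_max - U_min`, where `U_min`
#' is the minimum potential along the ring (the projected limit cycle,
#' bilinearly interpolated along its polyline) and `U_max` is the local
#' maximum potential inside the ring (maximum over grid cells strictly inside
#' the cycle polygon).
#'
#' @param U a `bg_landscape_grid`.
#' @param cycle a `bg_cycle` (errors if `NULL`: mono-stable landscapes have
#'   no ring; use basin summaries instead).
#' @param projection pair of module indices matching the grid projection
#'   (defaults to the grid's own projection). For analytic test grids, a
#'   two-column `cycle$states` is used as-is.
#' @param n_ring points at which the ring is sampled.
#' @return List with `U_max`, `U_min`, `barrier`, the location of `U_max`
#'   and of `U_min`.
#' @export
barrier_height <- function(U, cycle, projection = NULL, n_ring = 2000) {
  if (is.null(cycle))
    stop("no limit cycle: barrier height is defined only for oscillatory ",
         "landscapes; use the mono-stable basin summaries instead")
  if (is.null(projection)) projection <- U$projection
  S <- cycle$states
  poly <- if (ncol(S) == 2) S else S[, projection, drop = FALSE]
  ring <- .resample_loop(poly, n_ring)
  u_ring <- .bilinear(U$x, U$y, U$U, ring[, 1], ring[, 2])
  i_min <- which.min(u_ring)
  cells_x <- rep(U$x, times = U$ny)
  cells_y <- rep(U$y, each = U$nx)
  inside <- .in_polygon(cells_x, cells_y, .resample_loop(poly, 800))
  if (!any(inside)) {  # degenerate ring smaller than one cell
    u_max <- .bilinear(U$x, U$y, U$U, mean(poly[, 1]), mean(poly[, 2]))
    loc_max <- c(mean(poly[, 1]), mean(poly[, 2]))
  } else {
    Uin <- U$U[inside]
    k <- which.max(Uin)
    u_max <- Uin[k]
    loc_max <- c(cells_x[inside][k], cells_y[inside][k])
  }
  list(U_max = u_max, U_min = u_ring[i_min],
       barrier = u_max - u_ring[i_min],
       loc_max = loc_max, loc_min = ring[i_min, ])
}

#' Average flux along the cycle
#'
#' `J_Average = (integral of |J| dl along the ring) / (integral of dl)`: the
#' flux magnitude is bilinearly interpolated along the projected one-period
#' cycle polyline and averaged with respect to arc length. (A signed
#' tangential variant is available via `signed = TRUE`.)
#'
#' @param J a `bg_flux_field`.
#' @param cycle a `bg_cycle` (error if `NULL`).
#' @param projection pair of module indices (defaults to the flux grid's).
#' @param n_ring sampling points along the ring (default 2000).
#' @param signed integrate the signed tangential component instead of the
#'   magnitude.
#' @return Scalar `J_Average`.
#' @export
average_flux <- function(J, cycle, projection = NULL, n_ring = 2000,
                         signed = FALSE) {
  if (is.null(cycle))
    stop("no limit cycle: average flux along the cycle is undefined")
  if (is.null(projection)) projection <- J$projection
  S <- cycle$states
  poly <- if (ncol(S) == 2) S else S[, projection, drop = FALSE]
  ring <- .resample_loop(poly, n_ring)
  jx <- .bilinear(J$x, J$y, J$Jx, ring[, 1], ring[, 2])
  jy <- .bilinear(J$x, J$y, J$Jy, ring[, 1], ring[, 2])
  closed <- rbind(ring, ring[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))         # length of segment k -> k+1
  if (sum(seg) == 0) return(0)
  if (signed) {
    tang <- diff(closed) / pmax(seg, 1e-300)
    val <- jx * tang[, 1] + jy * tang[, 2]
  } else {
    val <- sqrt(jx^2 + jy^2)
  }
  sum(val * seg) / sum(seg)
}

#' Ring-ridge cells of a landscape
#'
#' Cells within `depth` nats of the ring minimum (the minimum potential along
#' the projected limit cycle): the valley band that hosts the oscillation.
#' Used to compare mean-field and empirical (histogram) landscapes.
#'
#' @param U a `bg_landscape_grid`.
#' @param cycle a `bg_cycle` locating the ring.
#' @param projection pair of module indices (defaults to the grid's).
#' @param depth band depth in nats (default 0.5).
#' @return Logical nx x ny matrix marking ridge cells.
#' @export
landscape_ridge <- function(U, cycle, projection = NULL, depth = 0.5) {
  if (is.null(projection)) projection <- U$projection
  S <- cycle$states
  poly <- if (ncol(S) == 2) S else S[, projection, drop = FALSE]
  ring <- .resample_loop(poly, 400)
  u_min <- min(.bilinear(U$x, U$y, U$U, ring[, 1], ring[, 2]))
  U$U <= u_min + depth
}

#' Entropy production rate
#'
#' Standard non-equilibrium steady-state dissipation functional
#' `EPR = sum_cells J . J / (D P) * cell_area`, nonnegative and zero iff the
#' flux vanishes on all counted cells. Cells at the probability floor are
#' excluded (guarding the division).
#'
#' @param P a `bg_prob_grid`.
#' @param J a `bg_flux_field`.
#' @param D_diff diffusion coefficient.
#' @param floor probability floor as a fraction of `max(P)`.
#' @return Scalar EPR (per ms).
#' @export
entropy_production_rate <- function(P, J, D_diff, floor = 1e-12) {
  pf <- floor * max(P$P)
  keep <- P$P > pf
  J2 <- J$Jx^2 + J$Jy^2
  sum(J2[keep] / (D_diff * P$P[keep])) * P$dx * P$dy
}

#' Landscape and flux analysis of the circuit
#'
#' The central pipeline: classifies the deterministic dynamics, evolves the
#' Gaussian moment closure, assembles the steady-state probability on a 2-D
#' projection grid (period-averaged when oscillatory), and constructs the
#' potential `U = -ln P_ss`, the flux field `J = F P - D grad P`, and the
#' scalar stability metrics: barrier height (`U_max` inside the ring minus
#' `U_min` along it), average flux along the cycle, entropy production rate,
#' period and projected loop length.
#'
#' @param params a [bg_params()] object.
#' @param projection ordered pair of module indices, default cortex/thalamus
#'   `c(1, 6)`; use `c(4, 7)` for the GPi/STN replicate.
#' @param protocol optional [bg_protocol()].
#' @param grid optional [grid_spec()]; auto-ranged when omitted.
#' @param nx,ny auto-grid resolution (default 200 x 200).
#' @param n_snapshots phase snapshots per period (default 200).
#' @param closure off-projection drift closure, see [drift_field_2d()].
#' @param floor probability floor fraction (default 1e-12).
#' @param transient settle time in ms.
#' @return A `bg_landscape` object bundling `P`, `U`, `J`, `F2d`, the cycle
#'   (or `NULL`), and `metrics` (list: `oscillating`, `barrier`, `U_max`,
#'   `U_min`, `J_average`, `epr`, `period`, `loop_length`).
#' @examples
#' \donttest{
#' p <- bg_params(D_input = 0.8)
#' L <- bg_landscape(p, nx = 100, ny = 100, n_snapshots = 100)
#' summary(L)
#' }
#' @export
bg_landscape <- function(params, projection = c(1, 6), protocol = NULL,
                         grid = NULL, nx = 200, ny = 200, n_snapshots = 200,
                         closure = c("conditional", "nearest"),
                         floor = 1e-12, transient = 2500) {
  closure <- match.arg(closure)
  cycle <- detect_limit_cycle(params, protocol = protocol,
                              transient = transient)
  P <- steady_state_probability(params, projection = projection, grid = grid,
                                protocol = protocol,
                                n_snapshots = n_snapshots, nx = nx, ny = ny,
                                cycle = cycle, transient = transient)
  U <- potential_from_probability(P, floor = floor)
  F2d <- drift_field_2d(P, params, protocol, closure = closure)
  J <- flux_field(P, F2d, params$D_diff, floor = floor)
  if (!is.null(cycle)) {
    bh <- barrier_height(U, cycle, projection)
    ja <- average_flux(J, cycle, projection)
    ll <- cycle_geometry(cycle, projection)
    metrics <- list(oscillating = TRUE, barrier = bh$barrier,
                    U_max = bh$U_max, U_min = bh$U_min, J_average = ja,
                    epr = entropy_production_rate(P, J, params$D_diff, floor),
                    period = cycle$period, loop_length = ll)
  } else {
    metrics <- list(oscillating = FALSE, barrier = NA_real_,
                    U_max = NA_real_, U_min = min(U$U), J_average = 0,
                    epr = entropy_production_rate(P, J, params$D_diff, floor),
                    period = NA_real_, loop_length = NA_real_)
  }
  structure(list(params = params, protocol = protocol,
                 projection = projection, closure = closure,
                 P = P, U = U, J = J, F2d = F2d, cycle = cycle,
                 metrics = metrics),
            class = "bg_landscape")
}

#' @export
print.bg_landscape <- function(x, ...) {
  m <- x$metrics
  nm <- x$params$module_names[x$projection]
  cat(sprintf("Landscape-flux analysis on (%s, %s), D_input = %g\n",
              nm[1], nm[2], x$params$D_input))
  if (m$oscillating) {
    cat(sprintf(
      "  oscillatory: period %.2f ms (%.1f Hz), barrier %.3f, J_avg %.4g, EPR %.4g\n",
      m$period, 1000 / m$period, m$barrier, m$J_average, m$epr))
  } else {
    cat(sprintf("  mono-stable basin: U_min %.3f, EPR %.4g\n", m$U_min, m$epr))
  }
  invisible(x)
}

#' @export
summary.bg_landscape <- function(object, ...) {
  m <- object$metrics
  out <- data.frame(
    D_input = object$params$D_input, oscillating = m$oscillating,
    barrier = m$barrier, J_average = m$J_average, epr = m$epr,
    period = m$period, loop_length = m$loop_length)
  class(out) <- c("summary.bg_landscape", "data.frame")
  out
}

#' @export
print.summary.bg_landscape <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a landscape-flux analysis
#'
#' Filled contours of the potential `U` with flux arrows subsampled on the
#' grid and the deterministic limit cycle overlaid (when present).
#'
#' @param x a `bg_landscape`.
#' @param arrows number of flux arrows per axis (default 20).
#' @param ... passed to [graphics::filled.contour()]-style image plotting.
#' @export
plot.bg_landscape <- function(x, arrows = 20, ...) {
  nm <- x$params$module_names[x$projection]
  graphics::image(x$U$x, x$U$y, x$U$U, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = nm[1], ylab = nm[2],
                  main = sprintf("U = -ln P (D_input = %g)", x$params$D_input), ...)
  graphics::contour(x$U$x, x$U$y, x$U$U, add = TRUE, nlevels = 12,
                    col = "grey30", drawlabels = FALSE)
  ix <- unique(round(seq(2, x$J$nx - 1, length.out = arrows)))
  iy <- unique(round(seq(2, x$J$ny - 1, length.out = arrows)))
  px <- rep(x$J$x[ix], times = length(iy))
  py <- rep(x$J$y[iy], each = length(ix))
  jx <- x$J$Jx[ix, iy]; jy <- x$J$Jy[ix, iy]
  mg <- sqrt(jx^2 + jy^2)
  sc <- 0.04 * max(diff(x$J$xlim), diff(x$J$ylim)) / max(mg, 1e-300)
  keep <- mg > 0.01 * max(mg)
  graphics::arrows(px[keep], py[keep], (px + jx * sc)[keep],
                   (py + jy * sc)[keep], length = 0.04, col = "magenta")
  if (!is.null(x$cycle))
    graphics::lines(x$cycle$states[, x$projection[1]],
                    x$cycle$states[, x$projection[2]], lwd = 2, col = "white")
  invisible(x)
}
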