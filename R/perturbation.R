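# Shared single-condition pipeline evaluation used by the sensitivity and
# DBS scans. With metrics = FALSE only the oscillation flag / period /
# attractor means are computed (no landscape), which is much cheaper.
.evaluate_condition <- function(params, protocol = NULL, grid_n = 100,
                                n_snapshots = 120, metrics = TRUE,
                                projection = c(1, 6)) {
  out <- list(oscillating = NA, period = NA_real_, barrier = NA_real_,
              J_average = NA_real_, epr = NA_real_,
              attractor_mean = rep(NA_real_, 7), error = NA_character_)
  tryCatch({
    cyc <- detect_limit_cycle(params, protocol = protocol)
    if (!is.null(cyc)) {
      out$oscillating <- TRUE
      out$period <- cyc$period
      n <- nrow(cyc$states)
      out$attractor_mean <- colMeans(cyc$states[-n, , drop = FALSE])
    } else {
      out$oscillating <- FALSE
      fps <- find_fixed_points(params, protocol = protocol,
                               lattice_points = 2)
      st <- fps[vapply(fps, function(r) r$stability == "stable", TRUE)]
      if (length(st)) out$attractor_mean <- st[[1]]$location
      out$J_average <- 0
    }
    if (metrics && !is.null(cyc)) {
      L <- bg_landscape(params, projection = projection, protocol = protocol,
                        nx = grid_n, ny = grid_n, n_snapshots = n_snapshots)
      out$barrier <- L$metrics$barrier
      out$J_average <- L$metrics$J_average
      out$epr <- L$metrics$epr
    }
  }, error = function(e) out$error <<- conditionMessage(e))
  out
}

#' Global sensitivity scan over connection strengths
#'
#' Perturbs one connection strength at a time over a grid of percentage
#' changes and rebuilds the stability metrics through the full pipeline
#' (deterministic classification, moment closure, landscape and flux).
#' The percent grid always covers 0; the unperturbed baseline is computed
#' once and reused bit-for-bit for every connection's 0% row. Per-point
#' pipeline failures are recorded in the `error` column and the scan
#' continues.
#'
#' @param params a [bg_params()] object.
#' @param connections character vector of connection names (default: the
#'   eight labelled pathway arrows `T21, T31, T42, T53, T45, T75, T47, T57`).
#' @param percent_grid percentage changes (default -50 to 50 by 10).
#' @param D_input dopamine level of the scan (default 0.95).
#' @param grid_n landscape grid resolution per axis (default 100).
#' @param n_snapshots phase snapshots per period.
#' @param metrics compute landscape metrics (`TRUE`) or only the oscillation
#'   flag and period (`FALSE`, much faster).
#' @param projection projection pair for the landscape metrics.
#' @return A `bg_sensitivity` data frame: one row per (connection, percent).
#' @export
sensitivity_scan <- function(params,
                             connections = c("T21", "T31", "T42", "T53",
                                             "T45", "T75", "T47", "T57"),
                             percent_grid = seq(-50, 50, by = 10),
                             D_input = 0.95, grid_n = 100, n_snapshots = 120,
                             metrics = TRUE, projection = c(1, 6)) {
  bad <- setdiff(connections, names(params$T))
  if (length(bad)) stop("unknown connections: ", paste(bad, collapse = ", "))
  percent_grid <- sort(unique(c(0, percent_grid)))
  base <- params
  base$D_input <- D_input
  baseline <- .evaluate_condition(base, grid_n = grid_n,
                                  n_snapshots = n_snapshots,
                                  metrics = metrics, projection = projection)
  rows <- list()
  for (conn in connections) {
    for (pct in percent_grid) {
      res <- if (pct == 0) baseline else {
        p <- base
        p$T[[conn]] <- p$T[[conn]] * (1 + pct / 100)
        .evaluate_condition(p, grid_n = grid_n, n_snapshots = n_snapshots,
                            metrics = metrics, projection = projection)
      }
      rows[[length(rows) + 1]] <- data.frame(
        connection = conn, percent = pct, oscillating = res$oscillating,
        period = res$period, barrier = res$barrier,
        J_average = res$J_average, epr = res$epr, error = res$error,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  attr(df, "baseline") <- baseline
  attr(df, "D_input") <- D_input
  class(df) <- c("bg_sensitivity", "data.frame")
  df
}

.dbs_curve <- function(params, target, offsets, gains, mode, D_input,
                       grid_n, n_snapshots, projection) {
  p <- params
  p$D_input <- D_input
  tidx <- c(GPi_SNr = 4L, GPe = 5L, STN = 7L)[[target]]
  rows <- list()
  for (k in seq_along(offsets)) {
    proto <- if (offsets[k] == 0 && gains[k] == 1) NULL else
      bg_protocol(target, mode = mode, soma_offset = offsets[k],
                  efferent_gain = gains[k])
    res <- .evaluate_condition(p, protocol = proto, grid_n = grid_n,
                               n_snapshots = n_snapshots, metrics = TRUE,
                               projection = projection)
    if (identical(res$oscillating, FALSE)) res$J_average <- 0
    rows[[length(rows) + 1]] <- data.frame(
      target = target, mode = mode, soma_offset = offsets[k],
      efferent_gain = gains[k], oscillating = res$oscillating,
      target_activity = unname(res$attractor_mean[tidx]), period = res$period,
      J_average = res$J_average, barrier = res$barrier, error = res$error,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  attr(df, "D_input") <- D_input
  class(df) <- c("bg_dbs_curve", "data.frame")
  df
}

#' DBS by direct somatic inhibition
#'
#' Models the direct-inhibition hypothesis of deep brain stimulation: a
#' constant negative input is added to the stimulated nucleus, and the
#' attractor-mean activity of the target and the average flux along the
#' cycle are reported per stimulation level. Loss of oscillation is flagged
#' with `J_average = 0`.
#'
#' @param params a [bg_params()] object.
#' @param target `"GPi_SNr"`, `"GPe"` or `"STN"`.
#' @param offsets grid of soma offsets (all `<= 0`, including 0 = baseline).
#' @param D_input dopamine level; the baseline must be oscillatory. The
#'   default 1.10 sits on the upper (mild-depletion) side of the oscillatory
#'   block: somatic inhibition of the pallidal/subthalamic targets then moves
#'   the circuit through the regimes in the direction the DBS literature
#'   describes (GPe inhibition acts like further dopamine depletion, so its
#'   flux first rises then falls; GPi/STN inhibition suppresses flux).
#' @param grid_n,n_snapshots landscape resolution settings.
#' @param projection projection pair for the flux metric.
#' @return A `bg_dbs_curve` data frame, one row per stimulation level.
#' @export
dbs_direct_inhibition <- function(params, target = c("GPi_SNr", "GPe", "STN"),
                                  offsets = seq(0, -1.2, by = -0.15),
                                  D_input = 1.10, grid_n = 100,
                                  n_snapshots = 120, projection = c(1, 6)) {
  target <- match.arg(target)
  if (any(offsets > 0)) stop("soma offsets must be <= 0")
  offsets <- offsets[order(-offsets)]  # baseline first, then deeper inhibition
  df <- .dbs_curve(params, target, offsets, rep(1, length(offsets)),
                   "direct_inhibition", D_input, grid_n, n_snapshots,
                   projection)
  if (!isTRUE(df$oscillating[1]))
    warning("baseline (offset 0) is not oscillatory at D_input = ", D_input)
  df
}

#' DBS with decoupled somatic inhibition and efferent activation
#'
#' Models the output-activation (decoupling) hypothesis: somatic inhibition
#' of the target is applied together with a multiplicative gain `>= 1` on
#' every efferent coupling term sourced at the target.
#'
#' @inheritParams dbs_direct_inhibition
#' @param soma_offsets grid of soma offsets (all `<= 0`).
#' @param efferent_gains gains aligned with `soma_offsets` (all `>= 1`).
#' @return A `bg_dbs_curve` data frame.
#' @export
dbs_decoupled <- function(params, target = c("GPi_SNr", "GPe", "STN"),
                          soma_offsets = seq(0, -2.4, by = -0.3),
                          efferent_gains = seq(1, 1.4, by = 0.05),
                          D_input = 1.10, grid_n = 100, n_snapshots = 120,
                          projection = c(1, 6)) {
  target <- match.arg(target)
  if (length(soma_offsets) != length(efferent_gains))
    stop("soma_offsets and efferent_gains must be aligned")
  if (any(soma_offsets > 0)) stop("soma offsets must be <= 0")
  if (any(efferent_gains < 1)) stop("efferent gains must be >= 1")
  ord <- order(-soma_offsets)
  .dbs_curve(params, target, soma_offsets[ord], efferent_gains[ord],
             "decoupled", D_input, grid_n, n_snapshots, projection)
}
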