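#' Experiment configuration
#'
#' A fully serialisable description of one reproducible experiment. Re-running
#' a config reproduces its outputs (stochastic experiments: identical given
#' the same seed).
#'
#' @param kind one of `"phase_scan"`, `"landscape"`, `"dopamine_sweep"`,
#'   `"sensitivity"`, `"dbs"`, `"oracle_check"`.
#' @param seed integer RNG seed (used by stochastic experiments).
#' @param projection pair of module indices.
#' @param D_input dopamine level (experiments at a single level).
#' @param D_grid dopamine grid (scans/sweeps).
#' @param grid_n landscape grid resolution per axis.
#' @param n_snapshots phase snapshots per period.
#' @param connections,percent_grid sensitivity settings.
#' @param target,mode,offsets,gains DBS settings.
#' @param duration,dt Langevin settings (oracle check).
#' @param params_overrides named list applied over [bg_params()] defaults
#'   (e.g. `list(D_diff = 0.02, T = c(T53 = 4))`).
#' @return A `bg_experiment_config` list (schema version 1).
#' @export
bg_experiment_config <- function(kind = c("phase_scan", "landscape",
                                          "dopamine_sweep", "sensitivity",
                                          "dbs", "oracle_check"),
                                 seed = 1L, projection = c(1, 6),
                                 D_input = 0.8,
                                 D_grid = seq(0.6, 1.4, by = 0.05),
                                 grid_n = 100, n_snapshots = 120,
                                 connections = c("T42", "T53"),
                                 percent_grid = seq(-50, 50, by = 25),
                                 target = "GPi_SNr",
                                 mode = "direct_inhibition",
                                 offsets = seq(0, -3, by = -0.5),
                                 gains = NULL,
                                 duration = 20000, dt = 0.01,
                                 params_overrides = list()) {
  kind <- match.arg(kind)
  structure(list(schema_version = 1L, kind = kind, seed = as.integer(seed),
                 projection = projection, D_input = D_input, D_grid = D_grid,
                 grid_n = grid_n, n_snapshots = n_snapshots,
                 connections = connections, percent_grid = percent_grid,
                 target = target, mode = mode, offsets = offsets,
                 gains = gains, duration = duration, dt = dt,
                 params_overrides = params_overrides),
            class = "bg_experiment_config")
}

#' Read an experiment configuration from a key/value file
#'
#' One `key = value` per line; vectors comma-separated; parameter overrides
#' use a `params.` prefix (e.g. `params.D_diff = 0.02`, `params.T53 = 4`).
#' The file must declare a supported `schema_version`.
#'
#' @param path config file path.
#' @return A `bg_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  kv <- .read_kv(path)
  if (is.null(kv[["schema_version"]]) || as.integer(kv[["schema_version"]]) != 1L)
    stop("config must declare schema_version = 1")
  if (is.null(kv[["kind"]])) stop("config must declare kind")
  args <- list(kind = kv[["kind"]])
  num_keys <- c("seed", "D_input", "grid_n", "n_snapshots", "duration", "dt")
  for (key in num_keys) if (!is.null(kv[[key]]))
    args[[key]] <- as.numeric(kv[[key]])
  vec_keys <- c("projection", "D_grid", "percent_grid", "offsets", "gains")
  for (key in vec_keys) if (!is.null(kv[[key]]))
    args[[key]] <- .parse_num_vec(kv[[key]])
  for (key in c("target", "mode")) if (!is.null(kv[[key]]))
    args[[key]] <- kv[[key]]
  if (!is.null(kv[["connections"]]))
    args$connections <- trimws(strsplit(kv[["connections"]], ",")[[1]])
  pk <- grep("^params\\.", names(kv), value = TRUE)
  if (length(pk)) {
    ov <- list()
    Tn <- c("T16", "T47", "T21", "T26", "T31", "T36", "T57", "T42", "T53",
            "T64", "T45", "T75", "T71", "T17")
    Tv <- c()
    for (key in pk) {
      name <- sub("^params\\.", "", key)
      if (name %in% Tn) Tv[name] <- as.numeric(kv[[key]])
      else if (name == "include_T17")
        ov$include_T17 <- tolower(kv[[key]]) %in% c("true", "1", "yes")
      else ov[[name]] <- as.numeric(kv[[key]])
    }
    if (length(Tv)) ov$T <- Tv
    args$params_overrides <- ov
  }
  do.call(bg_experiment_config, args)
}

#' Write an experiment configuration to a key/value file
#'
#' @param config a `bg_experiment_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  fmt <- function(v) paste(format(v, digits = 15, trim = TRUE),
                           collapse = ", ")
  lines <- c(paste("schema_version =", config$schema_version),
             paste("kind =", config$kind))
  for (key in c("seed", "D_input", "grid_n", "n_snapshots", "duration",
                "dt")) lines <- c(lines, paste(key, "=", fmt(config[[key]])))
  for (key in c("projection", "D_grid", "percent_grid", "offsets"))
    lines <- c(lines, paste(key, "=", fmt(config[[key]])))
  if (!is.null(config$gains))
    lines <- c(lines, paste("gains =", fmt(config$gains)))
  lines <- c(lines,
             paste("connections =", paste(config$connections, collapse = ", ")),
             paste("target =", config$target),
             paste("mode =", config$mode))
  ov <- config$params_overrides
  if (length(ov)) {
    if (!is.null(ov$T))
      for (nm in names(ov$T))
        lines <- c(lines, sprintf("params.%s = %s", nm, fmt(ov$T[[nm]])))
    for (nm in setdiff(names(ov), "T"))
      lines <- c(lines, sprintf("params.%s = %s", nm, fmt(ov[[nm]])))
  }
  writeLines(lines, path)
  invisible(path)
}

.config_params <- function(config) {
  ov <- config$params_overrides
  args <- ov[names(ov) != ""]
  p <- do.call(bg_params, args)
  p
}

#' Run a named experiment
#'
#' Executes the pipeline named by the config `kind` and returns a result
#' bundle: tables (data frames), grids (landscape matrices with geometry),
#' and a provenance record (config echo and hash, package version,
#' wall-clock). Per-condition errors are logged in the tables and mark the
#' bundle incomplete rather than aborting.
#'
#' @param config a [bg_experiment_config()].
#' @return A `bg_result_bundle`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "bg_experiment_config"))
  t0 <- Sys.time()
  params <- .config_params(config)
  tables <- list()
  grids <- list()
  complete <- TRUE
  proj <- config$projection

  if (config$kind == "phase_scan") {
    sc <- scan_dopamine(params, config$D_grid)
    tables$phase_scan <- as.data.frame(sc)
    complete <- all(is.na(sc$error))
  } else if (config$kind == "landscape") {
    params$D_input <- config$D_input
    L <- bg_landscape(params, projection = proj, nx = config$grid_n,
                      ny = config$grid_n, n_snapshots = config$n_snapshots)
    tables$metrics <- summary(L)
    grids$U <- L$U
    grids$P <- L$P
    grids$Jx <- list(x = L$J$x, y = L$J$y, M = L$J$Jx)
    grids$Jy <- list(x = L$J$x, y = L$J$y, M = L$J$Jy)
  } else if (config$kind == "dopamine_sweep") {
    rows <- lapply(config$D_grid, function(D) {
      p <- params
      p$D_input <- D
      r <- tryCatch({
        L <- bg_landscape(p, projection = proj, nx = config$grid_n,
                          ny = config$grid_n,
                          n_snapshots = config$n_snapshots)
        cbind(summary(L), error = NA_character_)
      }, error = function(e)
        data.frame(D_input = D, oscillating = NA, barrier = NA,
                   J_average = NA, epr = NA, period = NA, loop_length = NA,
                   error = conditionMessage(e)))
      r
    })
    tables$sweep <- do.call(rbind, rows)
    complete <- all(is.na(tables$sweep$error))
  } else if (config$kind == "sensitivity") {
    sv <- sensitivity_scan(params, connections = config$connections,
                           percent_grid = config$percent_grid,
                           D_input = config$D_input, grid_n = config$grid_n,
                           n_snapshots = config$n_snapshots,
                           projection = proj)
    tables$sensitivity <- as.data.frame(sv)
    complete <- all(is.na(sv$error))
  } else if (config$kind == "dbs") {
    df <- if (config$mode == "decoupled") {
      gains <- config$gains
      if (is.null(gains))
        gains <- seq(1, 1.6, length.out = length(config$offsets))
      dbs_decoupled(params, target = config$target,
                    soma_offsets = config$offsets, efferent_gains = gains,
                    D_input = config$D_input, grid_n = config$grid_n,
                    n_snapshots = config$n_snapshots, projection = proj)
    } else {
      dbs_direct_inhibition(params, target = config$target,
                            offsets = config$offsets,
                            D_input = config$D_input, grid_n = config$grid_n,
                            n_snapshots = config$n_snapshots,
                            projection = proj)
    }
    tables$dbs <- as.data.frame(df)
    complete <- all(is.na(df$error))
  } else if (config$kind == "oracle_check") {
    params$D_input <- config$D_input
    set.seed(config$seed)
    tr <- simulate_langevin(params, duration = config$duration,
                            dt = config$dt, thin = 10L)
    L <- bg_landscape(params, projection = proj, nx = config$grid_n,
                      ny = config$grid_n, n_snapshots = config$n_snapshots)
    g <- grid_spec(L$P$xlim, L$P$ylim, L$P$nx, L$P$ny)
    emp <- empirical_landscape(tr, projection = proj, grid = g,
                               params = params)
    mf_min <- which(L$U$U == min(L$U$U), arr.ind = TRUE)[1, ]
    em_min <- which(emp$U$U == min(emp$U$U), arr.ind = TRUE)[1, ]
    tables$oracle <- data.frame(
      D_input = config$D_input, n_samples = emp$n_samples,
      minima_cell_distance = max(abs(mf_min - em_min)),
      mf_min_x = L$U$x[mf_min[1]], mf_min_y = L$U$y[mf_min[2]],
      emp_min_x = emp$U$x[em_min[1]], emp_min_y = emp$U$y[em_min[2]])
    grids$U_meanfield <- L$U
    grids$U_empirical <- emp$U
  }

  cfg_file <- tempfile(fileext = ".cfg")
  write_experiment_config(config, cfg_file)
  prov <- list(kind = config$kind, seed = config$seed,
               config_hash = unname(tools::md5sum(cfg_file)),
               package_version = as.character(utils::packageVersion("bgflux")),
               r_version = R.version.string,
               wall_clock_s = as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")),
               complete = complete)
  unlink(cfg_file)
  structure(list(config = config, tables = tables, grids = grids,
                 provenance = prov),
            class = "bg_result_bundle")
}

#' @export
print.bg_result_bundle <- function(x, ...) {
  cat(sprintf("bg_result_bundle: %s (%s), %d table(s), %d grid(s)\n",
              x$config$kind,
              if (x$provenance$complete) "complete" else "INCOMPLETE",
              length(x$tables), length(x$grids)))
  invisible(x)
}

#' Export a result bundle to plain-text files
#'
#' Tables become CSV with stable column ordering; grids become plain-text
#' matrix files with a JSON sidecar holding the grid geometry, projection and
#' provenance; the provenance record is written as JSON.
#'
#' @param bundle a `bg_result_bundle`.
#' @param dir output directory (created if needed).
#' @param format only `"csv"` is supported for tables.
#' @return Character vector of the files written, invisibly.
#' @export
export_results <- function(bundle, dir, format = "csv") {
  if (!identical(format, "csv")) stop("unsupported format: ", format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(bundle$tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(bundle$tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  for (nm in names(bundle$grids)) {
    g <- bundle$grids[[nm]]
    M <- if (!is.null(g$M)) g$M else if (!is.null(g$U)) g$U else g$P
    f <- file.path(dir, paste0("grid_", nm, ".txt"))
    utils::write.table(M, f, row.names = FALSE, col.names = FALSE)
    side <- list(name = nm, x = g$x, y = g$y,
                 projection = if (!is.null(g$projection)) g$projection else
                   bundle$config$projection)
    jf <- file.path(dir, paste0("grid_", nm, ".json"))
    jsonlite::write_json(side, jf, auto_unbox = TRUE, digits = NA)
    files <- c(files, f, jf)
  }
  pf <- file.path(dir, "provenance.json")
  jsonlite::write_json(bundle$provenance, pf, auto_unbox = TRUE, digits = NA)
  files <- c(files, pf)
  invisible(files)
}
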