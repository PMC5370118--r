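#' Circuit parameters for the basal ganglia-thalamo-cortical model
#'
#' Constructs the single source of truth for the seven-population firing-rate
#' circuit: connection strengths, Hill response coefficients, membrane
#' constants, external inputs, the dopamine input level and the diffusion
#' coefficient of the stochastic dynamics. Defaults are the published
#' parameter set for which the circuit is mono-stable at high and very low
#' dopamine and shows beta-band limit-cycle oscillations in between.
#'
#' Modules are ordered: 1 cortex, 2 striatum D1 (direct pathway), 3 striatum
#' D2 (indirect pathway), 4 GPi/SNr, 5 GPe, 6 thalamus, 7 STN.
#'
#' Connection strengths are stored as nonnegative magnitudes named
#' `"T<target><source>"`; the sign of each coupling term is fixed by the
#' equation structure (excitatory vs inhibitory), not by the stored value.
#' `T17` (an STN to cortex term) is listed among the published strengths but
#' appears in no equation; it is stored for completeness and only enters the
#' drift when `include_T17 = TRUE`.
#'
#' @param T named numeric vector of connection strengths; any subset of the
#'   default names may be supplied to override defaults.
#' @param s Hill threshold (dimensionless activity), default 2.
#' @param n Hill exponent (integer >= 1), default 2.
#' @param R per-module membrane resistance, scalar or length 7, default 1.67.
#' @param tau membrane time constant in ms (tau = R*C), default 6. The
#'   capacitances are derived as `C_i = tau / R_i`.
#' @param I per-module external inputs, length 7.
#' @param D_input dopamine input level (dimensionless); excites the D1 and
#'   inhibits the D2 striatal population.
#' @param D_diff diffusion coefficient applied identically to all seven
#'   coordinates, default 0.01.
#' @param include_T17 logical; add the unused published `T17` term to the
#'   cortex equation (default `FALSE`).
#' @return An object of class `bg_params` (a validated list).
#' @seealso [bg_protocol()], [bg_drift()], [integrate_circuit()]
#' @examples
#' p <- bg_params(D_input = 0.8)
#' p$T[["T53"]]
#' @export
bg_params <- function(T = NULL, s = 2, n = 2, R = 1.67, tau = 6,
                      I = c(0.1, 0.05, 1.2, 4.4, 2.8, 2, 1.2),
                      D_input = 1.0, D_diff = 0.01, include_T17 = FALSE) {
  T_def <- c(T16 = 2, T47 = 2, T21 = 1.4, T26 = 1.4, T31 = 1.4, T36 = 1.4,
             T57 = 1, T42 = 3.2, T53 = 3.2, T64 = 3.2, T45 = 3.0,
             T75 = 1.8, T71 = 1.8, T17 = 1.8)
  if (!is.null(T)) {
    if (is.null(names(T)) || !all(names(T) %in% names(T_def)))
      stop("T must be a named vector with names among: ",
           paste(names(T_def), collapse = ", "))
    T_def[names(T)] <- T
  }
  if (n < 1 || n != round(n)) stop("Hill exponent n must be an integer >= 1")
  if (length(R) == 1) R <- rep(R, 7)
  if (length(I) != 7 || length(R) != 7)
    stop("I and R must have length 7")
  p <- structure(list(
    module_names = c("cortex", "striatum_D1", "striatum_D2", "GPi_SNr",
                     "GPe", "thalamus", "STN"),
    T = as.list(T_def), s = s, n = as.integer(n), R = R, tau = tau,
    C = tau / R, I = I, D_input = D_input, D_diff = D_diff,
    include_T17 = isTRUE(include_T17)), class = "bg_params")
  validate_bg_params(p)
  p
}

validate_bg_params <- function(p) {
  Tv <- unlist(p$T)
  if (any(Tv < 0)) stop("all connection strengths T must be >= 0")
  if (p$s <= 0) stop("Hill threshold s must be > 0")
  if (p$n < 1 || p$n != round(p$n)) stop("Hill exponent n must be an integer >= 1")
  if (any(p$R <= 0)) stop("membrane resistances R must be > 0")
  if (p$tau <= 0) stop("time constant tau must be > 0")
  if (p$D_diff < 0) stop("diffusion coefficient D_diff must be >= 0")
  if (!is.finite(p$D_input)) stop("D_input must be finite")
  invisible(p)
}

#' @export
print.bg_params <- function(x, ...) {
  cat("Basal ganglia-thalamo-cortical circuit parameters\n")
  cat(sprintf("  modules: %s\n", paste(x$module_names, collapse = ", ")))
  cat(sprintf("  D_input = %g, D_diff = %g, s = %g, n = %d, tau = %g ms\n",
              x$D_input, x$D_diff, x$s, x$n, x$tau))
  cat("  T:", paste(sprintf("%s=%g", names(x$T), unlist(x$T)),
                    collapse = " "), "\n")
  cat("  I:", paste(sprintf("%g", x$I), collapse = " "), "\n")
  if (x$include_T17) cat("  (T17 term included in the cortex equation)\n")
  invisible(x)
}

# Fixed-layout numeric vector consumed by the C++ kernels.
.pack_params <- function(p) {
  ord <- c("T16", "T47", "T21", "T26", "T31", "T36", "T57", "T42", "T53",
           "T64", "T45", "T75", "T71", "T17")
  c(unlist(p$T[ord], use.names = FALSE), as.numeric(p$include_T17),
    p$s, p$n, p$R, p$tau, p$I, p$D_input, p$D_diff)
}

.pack_protocol <- function(proto) {
  if (is.null(proto)) return(numeric(0))
  stopifnot(inherits(proto, "bg_protocol"))
  c(proto$target_index, proto$soma_offset, proto$efferent_gain,
    as.numeric(proto$mode == "decoupled"))
}

#' Deep-brain-stimulation protocol
#'
#' Describes how constant (DC) stimulation modifies the circuit drift.
#' In `direct_inhibition` mode a nonpositive offset current is added inside
#' the target population's input bracket. In `decoupled` mode the somatic
#' inhibition is combined with axonal excitation: every coupling term whose
#' *source* is the target is additionally multiplied by `efferent_gain >= 1`,
#' modelling increased efferent output despite reduced somatic activity.
#'
#' @param target one of `"GPi_SNr"`, `"GPe"`, `"STN"`.
#' @param mode `"direct_inhibition"` (default) or `"decoupled"`.
#' @param soma_offset additive current applied to the target's input; must be
#'   `<= 0`.
#' @param efferent_gain multiplier (`>= 1`) on every drift term sourced at the
#'   target; must be 1 in `direct_inhibition` mode.
#' @return An object of class `bg_protocol`.
#' @examples
#' bg_protocol("GPi_SNr", soma_offset = -0.5)
#' bg_protocol("STN", mode = "decoupled", soma_offset = -0.5, efferent_gain = 1.3)
#' @export
bg_protocol <- function(target = c("GPi_SNr", "GPe", "STN"),
                        mode = c("direct_inhibition", "decoupled"),
                        soma_offset = 0, efferent_gain = 1) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  if (soma_offset > 0) stop("soma_offset must be <= 0")
  if (efferent_gain < 1) stop("efferent_gain must be >= 1")
  if (mode == "direct_inhibition" && efferent_gain != 1)
    stop("direct_inhibition implies efferent_gain = 1")
  idx <- c(GPi_SNr = 4L, GPe = 5L, STN = 7L)[[target]]
  structure(list(target = target, target_index = idx, mode = mode,
                 soma_offset = soma_offset, efferent_gain = efferent_gain),
            class = "bg_protocol")
}

#' @export
print.bg_protocol <- function(x, ...) {
  cat(sprintf("DBS protocol: %s on %s, soma_offset = %g, efferent_gain = %g\n",
              x$mode, x$target, x$soma_offset, x$efferent_gain))
  invisible(x)
}

#' Read circuit parameters from a flat key/value file
#'
#' The file holds one `key = value` pair per line (`#` comments allowed).
#' Recognised keys are the field names of [bg_params()]: the connection
#' strengths `T16 ... T71, T17`, `s`, `n`, `tau`, `D_input`, `D_diff`,
#' `include_T17`, the scalars or comma-separated length-7 vectors `R` and
#' `I1 ... I7` (or `I`). Missing keys fall back to the published defaults;
#' the result is validated against the parameter invariants.
#'
#' @param path path to the configuration file.
#' @return A `bg_params` object.
#' @export
read_bg_params <- function(path) {
  kv <- .read_kv(path)
  T_names <- c("T16", "T47", "T21", "T26", "T31", "T36", "T57", "T42", "T53",
               "T64", "T45", "T75", "T71", "T17")
  Tov <- unlist(kv[names(kv) %in% T_names])
  args <- list()
  if (length(Tov)) args$T <- vapply(Tov, as.numeric, 0)
  for (key in c("s", "n", "tau", "D_input", "D_diff")) {
    if (!is.null(kv[[key]])) args[[key]] <- as.numeric(kv[[key]])
  }
  if (!is.null(kv[["include_T17"]]))
    args$include_T17 <- tolower(kv[["include_T17"]]) %in% c("true", "1", "yes")
  if (!is.null(kv[["R"]])) args$R <- .parse_num_vec(kv[["R"]])
  if (!is.null(kv[["I"]])) {
    args$I <- .parse_num_vec(kv[["I"]])
  } else {
    Ikeys <- paste0("I", 1:7)
    if (any(Ikeys %in% names(kv))) {
      I <- c(0.1, 0.05, 1.2, 4.4, 2.8, 2, 1.2)
      for (i in 1:7) if (!is.null(kv[[Ikeys[i]]])) I[i] <- as.numeric(kv[[Ikeys[i]]])
      args$I <- I
    }
  }
  do.call(bg_params, args)
}

.read_kv <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

.parse_num_vec <- function(x) as.numeric(trimws(strsplit(x, ",")[[1]]))
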