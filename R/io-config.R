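#' Load a run configuration
#'
#' Reads a YAML configuration and returns a validated `run_config` with
#' all defaults filled in.  Recognised keys: `condition` ("Dpp" or
#' "Dpp-rescue", sets the kinetic defaults), the [gradient_params()]
#' fields (`n`, `D`, `k`, `J0`, `ell`, `h`, `dt`, `p`, `b`,
#' `source_on`), `initial_profile` (vector of per-cell counts), `times`
#' (transient comparison times, multiples of `dt`), `tolerance`
#' (steady-state token tolerance), `cycle_cap`, and `verbosity` (0-2).
#' Parameter validation (including the stability bounds) happens here,
#' so an unstable configuration fails at load time with a message naming
#' the offending quantity.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return an object of class `run_config`.
#' @examples
#' cfg <- load_config(NULL)   # Dpp defaults
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration must be a key-value mapping")
  known <- c("condition", "n", "D", "k", "J0", "ell", "h", "dt", "p", "b",
             "source_on", "initial_profile", "times", "tolerance",
             "cycle_cap", "verbosity")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  condition <- raw$condition %||% "Dpp"
  if (!condition %in% c("Dpp", "Dpp-rescue"))
    stop("invalid value for key 'condition': ", condition)
  args <- case_study_params(condition)
  pnames <- intersect(names(raw), names(args))
  args[pnames] <- raw[pnames]
  params <- do.call(gradient_params, args)
  times <- raw$times %||% c(600, 2400)
  if (any(times %% params$dt != 0))
    stop("invalid value for key 'times': must be multiples of dt")
  profile <- raw$initial_profile
  if (!is.null(profile) && length(profile) != params$n)
    stop("invalid value for key 'initial_profile': needs one count per cell")
  structure(list(condition = condition, params = params,
                 initial_profile = profile, times = times,
                 tolerance = raw$tolerance %||% 0,
                 cycle_cap = raw$cycle_cap %||% 20000,
                 verbosity = raw$verbosity %||% 1),
            class = "run_config")
}

#' Write a run configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  p <- cfg$params
  out <- list(condition = cfg$condition, n = p$n, D = p$D, k = p$k,
              J0 = p$J0, ell = p$ell, h = p$h, dt = p$dt, p = p$p, b = p$b,
              source_on = p$source_on, times = cfg$times,
              tolerance = cfg$tolerance, cycle_cap = cfg$cycle_cap,
              verbosity = cfg$verbosity)
  if (!is.null(cfg$initial_profile)) out$initial_profile <- cfg$initial_profile
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration (", x$condition, ")\n")
  print(x$params)
  cat("comparison times:", paste(x$times, collapse = ", "), "s;",
      "cycle cap:", x$cycle_cap, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory to CSV
#'
#' One data row per executed cycle with columns
#' `cycle,time_s,cell_1..cell_n` (integer counts; zero counts are written
#' as 0, never blank).
#'
#' @param traj a `gradient_trajectory`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gradient_trajectory"))
  if (length(traj$cycle) == 0) stop("trajectory is empty")
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return data frame with columns `cycle`, `time_s`, `cell_1..cell_n`.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
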