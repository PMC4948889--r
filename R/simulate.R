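#' Steady state of the network
#'
#' Finds the equilibrium of the reduced system for a given parameter set,
#' by stiff integration from a fixed nominal initial state (or a supplied
#' one) followed by damped-Newton polishing. Deterministic: no randomness is
#' involved.
#'
#' @param params parameter set.
#' @param wnt0 total Wnt3a (nM); overrides `params[["WNT0"]]` when given.
#' @param init optional full state (or internal coordinate vector) to start
#'   from; defaults to a fixed nominal state.
#' @param t_relax integration horizon (min) before Newton polishing.
#' @return Full `rcn_state` vector with attributes `residual` (scaled
#'   residual norm, 1/min) and `params` (the parameter set used).
#' @export
find_steady_state <- function(params, wnt0 = NULL, init = NULL,
                              t_relax = 50000) {
  if (!is.null(wnt0)) params <- set_parameters(params, WNT0 = wnt0)
  y0 <- if (is.null(init)) default_initial_y(params)
        else if (length(init) == length(.y_names) &&
                 all(.y_names %in% names(init))) init[.y_names]
        else state_to_y(as_rcn_state(init))
  f <- function(y) dae_rhs_y(0, y, params)[[1]]
  ns <- steady_newton(f, y0)
  if (!ns$converged || any(ns$x < -1e-9)) {
    out <- integrate_y(params, y0, times = c(0, t_relax / 4, t_relax))
    yr <- out[nrow(out), -1]
    ns <- steady_newton(f, yr)
    if (!ns$converged || any(ns$x < -1e-9)) {
      out <- integrate_y(params, pmax(yr, 0), times = c(0, 10 * t_relax))
      ns <- steady_newton(f, out[nrow(out), -1])
    }
  }
  if (!ns$converged)
    stop("steady state did not converge; scaled residual = ",
         format(ns$residual))
  if (any(ns$x < -1e-9))
    stop("steady state has negative components; no physical equilibrium found")
  st <- y_to_state(pmax(ns$x, 0), params)
  attr(st, "residual") <- ns$residual
  attr(st, "params") <- params
  st
}

#' Default output time grid for activation time courses
#'
#' Time 0, every 100 min through the first 900 min, then every 12 h from
#' 24 h to 72 h.
#'
#' @return Numeric vector of times (min).
#' @export
default_time_grid <- function() {
  c(0, 1, seq(100, 900, by = 100), c(24, 36, 48, 60, 72) * 60)
}

#' Wnt-activation time course
#'
#' Integrates the reduced system from an initial state (by default the Wnt
#' OFF equilibrium of `params`) after an instantaneous step of total Wnt3a
#' to `wnt0_on` at time 0.
#'
#' @param params parameter set (its `WNT0` defines the OFF state).
#' @param initial initial full state; defaults to the Wnt OFF equilibrium.
#' @param wnt0_on total Wnt3a after the step (nM); `NULL` keeps `WNT0`.
#' @param t_grid output times (min).
#' @return An `rcn_trajectory`: data.frame with `time` (min) and one column
#'   per state variable, with the ON-parameter set and initial state as
#'   attributes.
#' @export
time_course <- function(params, initial = NULL, wnt0_on = NULL,
                        t_grid = default_time_grid()) {
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing")
  if (is.null(initial)) initial <- find_steady_state(params)
  params_on <- if (is.null(wnt0_on)) params
               else set_parameters(params, WNT0 = wnt0_on)
  y0 <- state_to_y(as_rcn_state(initial))
  times <- if (t_grid[1] > 0) c(0, t_grid) else t_grid
  out <- integrate_y(params_on, y0, times)
  keep <- match(t_grid, out[, 1])
  states <- t(vapply(keep, function(i)
    as.numeric(y_to_state(out[i, -1], params_on)),
    numeric(length(species_names()))))
  colnames(states) <- species_names()
  traj <- data.frame(time = t_grid, states, check.names = FALSE)
  class(traj) <- c("rcn_trajectory", "data.frame")
  attr(traj, "params") <- params_on
  attr(traj, "initial") <- initial
  traj
}

#' Time to reach steady state after Wnt activation
#'
#' Integrates the activation response on a dense grid and reports the
#' earliest time at which every differential variable's relative rate
#' `|dx/dt| / (|x| + eps)` falls below `threshold` (per hour), with linear
#' refinement between grid points.
#'
#' @param params parameter set (OFF condition).
#' @param wnt0_on total Wnt3a after activation (nM).
#' @param initial initial state; defaults to the Wnt OFF equilibrium.
#' @param threshold detection threshold (1/h).
#' @param t_max search horizon (min).
#' @param dt dense-grid spacing (min).
#' @return Detected steady-state time in hours (`NA` with a warning if the
#'   criterion is not met within `t_max`).
#' @export
steady_state_time <- function(params, wnt0_on, initial = NULL,
                              threshold = 1e-4, t_max = 120 * 60, dt = 6) {
  if (is.null(initial)) initial <- find_steady_state(params)
  params_on <- set_parameters(params, WNT0 = wnt0_on)
  y0 <- state_to_y(as_rcn_state(initial))
  times <- seq(0, t_max, by = dt)
  out <- integrate_y(params_on, y0, times)
  relrate <- vapply(seq_len(nrow(out)), function(i) {
    y <- out[i, -1]
    dy <- dae_rhs_y(out[i, 1], y, params_on)[[1]]
    max(abs(dy) * 60 / (abs(y) + 1e-6))
  }, numeric(1))
  below <- relrate < threshold
  idx <- which(below)[1]
  if (is.na(idx)) {
    warning("steady state not detected within ", t_max / 60, " h")
    return(NA_real_)
  }
  if (idx == 1L) return(0)
  # refine on log rate between the bracketing grid points
  t0 <- times[idx - 1]; t1 <- times[idx]
  r0 <- log(relrate[idx - 1]); r1 <- log(pmax(relrate[idx], 1e-300))
  tc <- if (r0 > r1) t0 + (t1 - t0) * (r0 - log(threshold)) / (r0 - r1) else t1
  tc / 60
}

#' Fold change relative to the Wnt OFF equilibrium
#'
#' Fold change is the ratio of a variable's concentration after Wnt3a
#' stimulation to its equilibrium concentration before stimulation.
#'
#' @param on_traj `rcn_trajectory` of the activated (Wnt ON) response.
#' @param off_state Wnt OFF equilibrium state (the denominator).
#' @param times times (min) at which to report; defaults to all trajectory
#'   times.
#' @param variables variables to report; defaults to all 24.
#' @return Data.frame with columns `time`, `variable`, `fold`.
#' @export
fold_change <- function(on_traj, off_state, times = NULL, variables = NULL) {
  if (is.null(variables)) variables <- species_names()
  if (is.null(times)) times <- on_traj$time
  miss <- setdiff(times, on_traj$time)
  if (length(miss))
    stop("times not in trajectory: ", paste(miss, collapse = ", "))
  off <- unlist(off_state)[variables]
  if (any(off <= 0))
    stop("fold change undefined: zero OFF-state concentration for ",
         paste(variables[off <= 0], collapse = ", "))
  rows <- as.matrix(on_traj[match(times, on_traj$time), variables,
                            drop = FALSE])
  fold <- sweep(rows, 2, off, "/")
  data.frame(time = rep(times, times = length(variables)),
             variable = rep(variables, each = length(times)),
             fold = as.vector(fold))
}

#' Steady-state fold change for all variables
#'
#' Ratio of the Wnt ON steady state to the Wnt OFF steady state, the
#' quantity the sensitivity analysis is built on (activation responses are
#' evaluated at steady state, with time courses capped at 72 h reaching it
#' in the reference condition).
#'
#' @param params parameter set (OFF condition uses its `WNT0`).
#' @param wnt0_on total Wnt3a in the ON state (nM).
#' @param off_init,on_init optional warm-start states for the two steady
#'   states (used internally by the sensitivity sweep).
#' @return Named numeric vector of fold changes over all 24 variables, with
#'   the two steady states attached as attributes `off` and `on`.
#' @export
steady_fold_change <- function(params, wnt0_on = 28.062,
                               off_init = NULL, on_init = NULL) {
  off <- find_steady_state(params, init = off_init)
  on <- find_steady_state(params, wnt0 = wnt0_on,
                          init = if (is.null(on_init)) off else on_init)
  f <- as.numeric(on) / as.numeric(off)
  names(f) <- species_names()
  attr(f, "off") <- off
  attr(f, "on") <- on
  f
}

#' Condition presets
#'
#' The four simulated conditions: `reference` (physiological parameters)
#' or `dysregulated` (ICG-001-like disruption of beta-catenin/TCF complex
#' formation, modeled as doubling the dissociation equilibrium constant
#' K11), each in the Wnt OFF (total Wnt3a 1 nM) or Wnt ON (28.062 nM)
#' state.
#'
#' @param condition `"reference"` or `"dysregulated"`.
#' @param wnt `"wnt_off"` or `"wnt_on"`.
#' @param params base parameter set (default the reference set).
#' @return List with `condition`, `wnt`, `params`, the steady `state`, and
#'   `observables` (adherens junctions `aj`, junctional adhesivity `sigma`,
#'   cytoplasmic beta-catenin `bcat`, and `gpt`).
#' @export
run_preset <- function(condition = c("reference", "dysregulated"),
                       wnt = c("wnt_off", "wnt_on"),
                       params = reference_parameters()) {
  condition <- match.arg(condition)
  wnt <- match.arg(wnt)
  if (condition == "dysregulated")
    params <- set_parameters(params, K11 = 2 * params[["K11"]])
  wnt0 <- if (wnt == "wnt_on") 28.062 else 1
  st <- find_steady_state(params, wnt0 = wnt0)
  list(condition = condition, wnt = wnt,
       params = set_parameters(params, WNT0 = wnt0), state = st,
       observables = c(aj = st[["ecad_aj"]], sigma = st[["sigma_aj"]],
                       bcat = st[["bcat"]], gpt = st[["gpt"]]))
}

#' Write a trajectory as tidy CSV
#'
#' @param traj an `rcn_trajectory`.
#' @param path output path; columns `time`, `variable`, `value`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  vars <- setdiff(names(traj), "time")
  long <- data.frame(
    time = rep(traj$time, times = length(vars)),
    variable = rep(vars, each = nrow(traj)),
    value = unlist(traj[vars], use.names = FALSE))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
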