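#' Solver settings
#'
#' Tolerances and output grid for the ODE integration.  The defaults are
#' tight (periods are reported to 0.1 h, which demands relative errors well
#' below that over hundreds of simulated hours) and the output grid of
#' 0.05 h is fine enough for quadratic peak refinement to be limited by the
#' integration error, not the sampling.
#'
#' @param rel_tol relative tolerance
#' @param abs_tol absolute tolerance (uM)
#' @param max_step maximum internal step (h)
#' @param t_end final time (h)
#' @param sample_dt output grid spacing (h)
#' @return An object of class `solver_settings`.
#' @examples
#' solver_settings(t_end = 240)
#' @export
solver_settings <- function(rel_tol = 1e-8, abs_tol = 1e-10, max_step = Inf,
                            t_end = 100, sample_dt = 0.05) {
  if (rel_tol <= 0 || abs_tol <= 0) stop_config("tolerances must be positive")
  if (t_end <= 0) stop_config("'t_end' must be positive")
  if (sample_dt <= 0) stop_config("'sample_dt' must be positive")
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 t_end = t_end, sample_dt = sample_dt),
            class = "solver_settings")
}

#' Integrate a right-hand side with discontinuity-aware restarts
#'
#' Runs the stiff-capable adaptive integrator (lsoda) from t = 0 to
#' `settings$t_end`, restarting at every declared breakpoint so that
#' discontinuous stimuli (feeding switches, light pulses) never degrade the
#' step-size control.  The output is sampled on the uniform grid plus the
#' breakpoints themselves.
#'
#' @param rhs function `(t, y) -> dy` over the full state vector
#' @param y0 named initial state
#' @param settings a [solver_settings()]
#' @param breakpoints times in `(0, t_end)` at which to restart
#' @return A `clock_trajectory`: data frame with column `t` followed by one
#'   column per state variable; solver settings attached as attribute
#'   `settings`.
#' @export
integrate_clock <- function(rhs, y0, settings = solver_settings(),
                            breakpoints = numeric(0)) {
  if (!all(is.finite(y0))) stop_config("initial state must be finite")
  bp <- sort(unique(breakpoints))
  bp <- bp[bp > 0 & bp < settings$t_end]
  grid <- sort(unique(c(seq(0, settings$t_end, by = settings$sample_dt),
                        settings$t_end)))
  # sampling points indistinguishable from a breakpoint would make the
  # integrator's output times collide; keep the breakpoint
  tol <- 1e-8 * max(1, settings$t_end)
  for (b in bp) grid <- grid[abs(grid - b) > tol]
  grid <- sort(c(grid, bp))
  edges <- c(0, bp, settings$t_end)
  func <- function(t, y, parms) list(rhs(t, y))

  pieces <- vector("list", length(edges) - 1L)
  y <- y0
  for (k in seq_along(pieces)) {
    tt <- grid[grid >= edges[k] & grid <= edges[k + 1L]]
    if (tt[1] > edges[k]) tt <- c(edges[k], tt)
    out <- try(suppressWarnings(
      deSolve::lsoda(y, tt, func, parms = NULL,
                     rtol = settings$rel_tol,
                     atol = settings$abs_tol,
                     hmax = if (is.finite(settings$max_step))
                       settings$max_step else NULL)),
      silent = TRUE)
    if (inherits(out, "try-error") || anyNA(out) || !all(is.finite(out)) ||
        nrow(out) != length(tt) ||
        attr(out, "istate")[1L] < 0)
      stop_integration(sprintf("integration failed in [%g, %g]",
                               edges[k], edges[k + 1L]),
                       time = edges[k])
    pieces[[k]] <- if (k == 1L) out else out[-1L, , drop = FALSE]
    y <- out[nrow(out), -1L]
    names(y) <- names(y0)
  }
  m <- do.call(rbind, pieces)
  traj <- as.data.frame(m)
  names(traj) <- c("t", names(y0))
  class(traj) <- c("clock_trajectory", "data.frame")
  attr(traj, "settings") <- settings
  traj
}

#' Simulate a single (possibly stimulus-driven) oscillator
#'
#' Convenience wrapper building the right-hand side for one oscillator with
#' its variant and stimulus and integrating it.  For the
#' `"mammal_machinery"` variant the state is extended by the machinery pool
#' (columns `T` and `Tstar`, with `T(0) = T0` and `Tstar(0) = 0`).
#'
#' @param params [core_parameters()]
#' @param state initial [oscillator_state()]
#' @param variant [variant_spec()]
#' @param stimulus `clock_stimulus` (closed-form; taps need a network)
#' @param settings [solver_settings()]
#' @param hill_form Hill-term form, see [core_rhs()]
#' @return A `clock_trajectory` with columns `t`, `M`, `P0`, `P1`, `P2`,
#'   `PN` (plus `T`, `Tstar` for machinery variants).
#' @examples
#' traj <- simulate_oscillator(settings = solver_settings(t_end = 60))
#' head(traj)
#' @export
simulate_oscillator <- function(params = core_parameters(),
                                state = oscillator_state(),
                                variant = variant_spec("none"),
                                stimulus = stim_zero(),
                                settings = solver_settings(),
                                hill_form = "KI") {
  if (stimulus$kind == "signal_tap")
    stop_config("signal taps require simulate_network()")
  machinery <- identical(variant$kind, "mammal_machinery")
  if (machinery) {
    mach <- variant$machinery
    y0 <- c(unclass(state), T = mach$T0, Tstar = 0)
    rhs <- function(t, y) {
      s <- y[1:5]; names(s) <- state_vars
      u <- stim_eval(stimulus, t)
      aux <- c(T = y[[6]], Tstar = y[[7]])
      c(variant_rhs(s, params, variant, u, hill_form, aux = aux),
        machinery_rhs(aux[["T"]], aux[["Tstar"]], u, mach$rho_m, mach$xi))
    }
  } else {
    y0 <- unclass(state)
    rhs <- function(t, y) {
      names(y) <- state_vars
      variant_rhs(y, params, variant, stim_eval(stimulus, t), hill_form)
    }
  }
  integrate_clock(rhs, y0, settings,
                  discontinuity_times(stimulus, settings$t_end))
}

#' Simulate a coupled network
#'
#' @param spec a [network_spec()]
#' @param settings [solver_settings()]
#' @return A `clock_trajectory` with columns `t` and `<id>.<var>`.
#' @export
simulate_network <- function(spec, settings = solver_settings()) {
  net <- assemble_network(spec)
  integrate_clock(net$rhs, net$y0, settings, net$breakpoints)
}

#' @export
print.clock_trajectory <- function(x, ...) {
  s <- attr(x, "settings")
  cat(sprintf("<clock_trajectory: %d samples, t in [%g, %g] h, %d variables>\n",
              nrow(x), min(x$t), max(x$t), ncol(x) - 1L))
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Write / read a trajectory as TSV
#'
#' Tab-separated text with a header row, first column `t`, floats with 9
#' significant digits.
#'
#' @param traj a `clock_trajectory`
#' @param path file path
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `clock_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(lapply(as.data.frame(traj), signif, digits = 9L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  class(df) <- c("clock_trajectory", "data.frame")
  df
}
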