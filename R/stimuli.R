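#' Stimulus waveforms
#'
#' Constructors for the time -> intensity functions u(t) >= 0 that drive an
#' oscillator's stimulus port.  A phase `phi` (radians) corresponds to a
#' Zeitgeber advance of `phi * period / (2*pi)` hours; this convention is
#' used by every periodic stimulus.
#'
#' * `stim_zero()`: u identically 0.
#' * `stim_periodic(phi, period, gain)`: `gain * (cos(2*pi*t/period + phi) + 1)`,
#'   range `[0, 2*gain]`; the reference light-dark cycle has `gain = 1`.
#' * `stim_scaled_periodic(phi, period)`: quarter-amplitude periodic
#'   stimulus, `(cos(2*pi*t/period + phi) + 1) / 4`, range `[0, 0.5]`.
#' * `stim_constant(c)`: constant intensity c (constant-light protocols).
#' * `stim_food_switch(phi_tilde, phi, t_switch, period)`: scaled periodic
#'   stimulus with phase `phi_tilde` up to and including `t_switch`, phase
#'   `phi` afterwards (feeding schedule moved back from night to day).
#' * `stim_pulse(t_start, duration, magnitude)`: `magnitude` on the
#'   half-open interval `[t_start, t_start + duration)`, else 0.
#' * `stim_log(inner)`: `log(1 + u_inner(t))`, compressing a stimulus that
#'   spans orders of magnitude of illuminance.
#' * `stim_tap(id, var)`: not a closed-form waveform; reads state variable
#'   `var` of oscillator `id` in a coupled network, realizing the
#'   input-output interface.  It can only be evaluated inside
#'   [assemble_network()].
#'
#' @param phi,phi_tilde phase offsets (radians)
#' @param period Zeitgeber period (h)
#' @param gain amplitude multiplier (half the peak intensity)
#' @param c constant intensity (>= 0)
#' @param t_switch switch time (h, > 0)
#' @param t_start pulse onset (h)
#' @param duration pulse length (h, > 0)
#' @param magnitude pulse intensity (>= 0)
#' @param inner a stimulus object to be log-transformed
#' @param id,var oscillator id and state-variable name to tap
#'
#' @return An object of class `clock_stimulus`.
#' @examples
#' u <- stim_periodic(phi = pi)
#' stim_eval(u, c(0, 6, 12))
#' @name stimuli
NULL

new_stimulus <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "clock_stimulus")
}

#' @rdname stimuli
#' @export
stim_zero <- function() new_stimulus("zero")

#' @rdname stimuli
#' @export
stim_periodic <- function(phi = 0, period = 24, gain = 1) {
  if (period <= 0) stop_config("stimulus 'period' must be positive")
  if (gain < 0) stop_config("stimulus 'gain' must be non-negative")
  new_stimulus("periodic", phi = phi, period = period, gain = gain)
}

#' @rdname stimuli
#' @export
stim_scaled_periodic <- function(phi = 0, period = 24) {
  if (period <= 0) stop_config("stimulus 'period' must be positive")
  new_stimulus("scaled_periodic", phi = phi, period = period)
}

#' @rdname stimuli
#' @export
stim_constant <- function(c = 0.5) {
  if (!is.finite(c) || c < 0)
    stop_config("constant stimulus intensity 'c' must be >= 0")
  new_stimulus("constant", c = c)
}

#' @rdname stimuli
#' @export
stim_food_switch <- function(phi_tilde = pi, phi = 0, t_switch = 160,
                             period = 24) {
  if (t_switch <= 0) stop_config("'t_switch' must be positive")
  if (period <= 0) stop_config("stimulus 'period' must be positive")
  new_stimulus("food_switch", phi_tilde = phi_tilde, phi = phi,
               t_switch = t_switch, period = period)
}

#' @rdname stimuli
#' @export
stim_pulse <- function(t_start, duration = 1, magnitude = 1) {
  if (duration <= 0) stop_config("pulse 'duration' must be positive")
  if (!is.finite(magnitude) || magnitude < 0)
    stop_config("pulse 'magnitude' must be >= 0")
  new_stimulus("pulse", t_start = t_start, duration = duration,
               magnitude = magnitude)
}

#' @rdname stimuli
#' @export
stim_log <- function(inner) {
  if (!inherits(inner, "clock_stimulus"))
    stop_config("'inner' must be a clock_stimulus")
  if (inner$kind == "signal_tap")
    stop_config("a signal tap cannot be log-transformed outside a network")
  new_stimulus("log_transformed", inner = inner)
}

#' @rdname stimuli
#' @export
stim_tap <- function(id, var = "P0") {
  if (!var %in% state_vars)
    stop_config(sprintf("unknown state variable '%s' in signal tap", var))
  new_stimulus("signal_tap", id = as.character(id), var = var)
}

#' Evaluate a stimulus waveform
#'
#' @param spec a `clock_stimulus`
#' @param t numeric vector of times (h)
#' @return Numeric vector of intensities, same length as `t`.
#' @examples
#' stim_eval(stim_constant(0.5), 0:3)
#' @export
stim_eval <- function(spec, t) {
  switch(spec$kind,
    zero            = rep(0, length(t)),
    periodic        = spec$gain * (cos(2 * pi * t / spec$period + spec$phi) + 1),
    scaled_periodic = 0.25 * (cos(2 * pi * t / spec$period + spec$phi) + 1),
    constant        = rep(spec$c, length(t)),
    food_switch     = ifelse(t <= spec$t_switch,
      0.25 * (cos(2 * pi * t / spec$period + spec$phi_tilde) + 1),
      0.25 * (cos(2 * pi * t / spec$period + spec$phi) + 1)),
    pulse           = ifelse(t >= spec$t_start &
                             t < spec$t_start + spec$duration,
                             spec$magnitude, 0),
    log_transformed = log1p(stim_eval(spec$inner, t)),
    signal_tap      = stop_config(
      "a signal_tap stimulus can only be evaluated inside a coupled network"),
    stop_config(sprintf("unknown stimulus kind '%s'", spec$kind)))
}

#' Breakpoints of a stimulus
#'
#' Times at which the waveform is discontinuous (pulse edges, feeding-
#' schedule switches).  The integrator restarts at these times so that the
#' adaptive step size never straddles a jump.
#'
#' @param spec a `clock_stimulus`
#' @param t_end only breakpoints in `(0, t_end)` are returned
#' @return Sorted numeric vector (possibly empty).
#' @examples
#' discontinuity_times(stim_pulse(10, 1, 3), 100)
#' @export
discontinuity_times <- function(spec, t_end = Inf) {
  b <- switch(spec$kind,
    food_switch     = spec$t_switch,
    pulse           = c(spec$t_start, spec$t_start + spec$duration),
    log_transformed = discontinuity_times(spec$inner, t_end),
    numeric(0))
  sort(unique(b[b > 0 & b < t_end]))
}

#' @export
print.clock_stimulus <- function(x, ...) {
  flds <- setdiff(names(x), c("kind", "inner"))
  vals <- vapply(flds, function(f) paste0(f, "=", format(x[[f]])), "")
  cat("<stimulus:", x$kind, paste(vals, collapse = " "), ">\n")
  invisible(x)
}
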