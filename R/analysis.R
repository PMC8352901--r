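#' Locate oscillation peaks
#'
#' Finds the interior local maxima of a sampled series and refines each
#' peak time by fitting a parabola through the three samples around the
#' grid maximum (ties on flat tops break toward the earlier time).  Maxima
#' whose height above the window minimum falls below `floor` are discarded
#' as numerical ripple.
#'
#' @param traj a `clock_trajectory`
#' @param variable column name to analyse
#' @param window `c(from, to)` in hours; `NULL` uses the full span
#' @param floor minimum height above the window minimum for a peak to count
#' @return Data frame with columns `time` and `height` (possibly 0 rows).
#' @examples
#' traj <- synth_trajectory(period = 24, t_end = 120)
#' find_peaks(traj, "M", window = c(80, 120))
#' @export
find_peaks <- function(traj, variable = "M", window = NULL, floor = 0) {
  if (!variable %in% names(traj))
    stop_config(sprintf("trajectory has no variable '%s'", variable))
  t <- traj$t
  v <- traj[[variable]]
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; v <- v[keep]
  }
  if (length(v) < 3L)
    return(data.frame(time = numeric(0), height = numeric(0)))
  idx <- which(v[2:(length(v) - 1L)] > v[1:(length(v) - 2L)] &
               v[2:(length(v) - 1L)] >= v[3:length(v)]) + 1L
  if (floor > 0) {
    base <- min(v)
    idx <- idx[v[idx] - base >= floor]
  }
  if (!length(idx))
    return(data.frame(time = numeric(0), height = numeric(0)))
  ref <- vapply(idx, function(i) {
    a <- t[i - 1L]; b <- t[i]; cc <- t[i + 1L]
    fa <- v[i - 1L]; fb <- v[i]; fc <- v[i + 1L]
    d1 <- (fb - fa) / (b - a)
    d2 <- (fc - fb) / (cc - b)
    curv <- (d2 - d1) / (cc - a)
    if (curv >= 0) return(c(b, fb))
    tp <- 0.5 * (a + b) - d1 / (2 * curv)
    hp <- fa + d1 * (tp - a) + curv * (tp - a) * (tp - b)
    c(tp, hp)
  }, numeric(2))
  data.frame(time = ref[1, ], height = ref[2, ])
}

#' Estimate the oscillation period from peak spacing
#'
#' The period is the mean spacing of successive refined peaks of the
#' variable inside the measurement window.  When the window contains fewer
#' than two peaks (periods longer than half the window), the search is
#' extended to the nearest peaks beyond the right window edge, then beyond
#' the left edge, until two successive peaks are available.
#'
#' @inheritParams find_peaks
#' @param window measurement window, default `c(80, 120)` h
#' @return An object of class `period_estimate`: list with `period` (h),
#'   `peak_times` and `window`.  Signals a classed error
#'   (`clockstim_arrhythmic_error`) when fewer than two peaks exist.
#' @examples
#' traj <- synth_trajectory(period = 24, t_end = 140)
#' estimate_period(traj, "M")$period
#' @export
estimate_period <- function(traj, variable = "M", window = c(80, 120),
                            floor = 0) {
  pk <- find_peaks(traj, variable, window = NULL, floor = floor)$time
  if (length(pk) < 2L)
    stop_arrhythmic("fewer than two peaks in the trajectory: arrhythmic signal")
  sel <- which(pk >= window[1] & pk <= window[2])
  if (length(sel) < 2L) {
    right <- which(pk > window[2])
    while (length(sel) < 2L && length(right)) {
      sel <- c(sel, right[1L]); right <- right[-1L]
    }
    left <- rev(which(pk < window[1]))
    while (length(sel) < 2L && length(left)) {
      sel <- c(left[1L], sel); left <- left[-1L]
    }
    sel <- sort(sel)
  }
  if (length(sel) < 2L)
    stop_arrhythmic("fewer than two peaks near the measurement window")
  times <- pk[sel]
  structure(list(period = mean(diff(times)), peak_times = times,
                 window = window),
            class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("period %.4f h from %d peaks in window [%g, %g]\n",
              x$period, length(x$peak_times), x$window[1], x$window[2]))
  invisible(x)
}

circular_mean <- function(d, period) {
  th <- 2 * pi * d / period
  atan2(mean(sin(th)), mean(cos(th))) * period / (2 * pi)
}

wrap_signed <- function(d, period) ((d + period / 2) %% period) - period / 2

#' Phase shift between two rhythmic trajectories
#'
#' Matches each peak of `traj` (after the transient) to the nearest peak of
#' `ref` and returns the circular mean of the differences.  Positive shift
#' means `traj` peaks later than `ref` (lags).  `wrap = "signed"` maps the
#' shift to `(-T/2, T/2]`; `wrap = "lag"` to `[0, T)`.
#'
#' @param ref,traj `clock_trajectory` objects (reference first)
#' @param variable column to compare
#' @param transient_cut hours discarded at the start (default 72, about
#'   three cycles)
#' @param window optional `c(from, to)` restricting the peaks of `traj`
#'   that enter the average (defaults to everything after the transient)
#' @param period_tol both series must be rhythmic with mean peak spacings
#'   equal within this tolerance (h), otherwise a
#'   `clockstim_not_entrained_error` is signalled
#' @param wrap `"signed"` or `"lag"`
#' @return An object of class `phase_shift_estimate`: list with `shift`
#'   (h), `period` (reference period, h) and `transient_cut`.
#' @export
estimate_phase_shift <- function(ref, traj, variable = "M",
                                 transient_cut = 72, window = NULL,
                                 period_tol = 0.2,
                                 wrap = c("signed", "lag")) {
  wrap <- match.arg(wrap)
  pa <- find_peaks(ref, variable)$time
  pb <- find_peaks(traj, variable)$time
  pa <- pa[pa >= transient_cut]
  pb <- pb[pb >= transient_cut]
  if (length(pa) < 2L || length(pb) < 2L)
    stop_arrhythmic("both trajectories must have >= 2 peaks after the transient")
  Ta <- mean(diff(pa)); Tb <- mean(diff(pb))
  if (abs(Ta - Tb) > period_tol)
    stop_not_entrained(sprintf(
      "periods differ by %.2f h (> %.2f): trajectories are not mutually entrained",
      abs(Ta - Tb), period_tol))
  if (!is.null(window)) pb <- pb[pb >= window[1] & pb <= window[2]]
  if (!length(pb))
    stop_arrhythmic("no peaks of the second trajectory in the window")
  d <- vapply(pb, function(b) b - pa[which.min(abs(pa - b))], 0)
  m <- circular_mean(d, Ta)
  shift <- if (wrap == "signed") wrap_signed(m, Ta) else m %% Ta
  structure(list(shift = shift, period = Ta, transient_cut = transient_cut,
                 convention = "positive = second trajectory peaks later"),
            class = "phase_shift_estimate")
}

#' @export
print.phase_shift_estimate <- function(x, ...) {
  cat(sprintf("phase shift %+.3f h (reference period %.3f h; %s)\n",
              x$shift, x$period, x$convention))
  invisible(x)
}

.clockstim_cache <- new.env(parent = emptyenv())

#' Free-running amplitude of the reference oscillator
#'
#' Peak-to-trough amplitude of the default core model in the standard
#' measurement window; used as the reference against which arrhythmicity
#' is judged.  The value is computed once per session and cached.
#'
#' @param variable state variable (default `"M"`)
#' @return Amplitude in uM.
#' @export
free_running_amplitude <- function(variable = "M") {
  key <- paste0("amp_", variable)
  if (is.null(.clockstim_cache[[key]])) {
    traj <- simulate_oscillator(settings = solver_settings(t_end = 120))
    sel <- traj$t >= 80 & traj$t <= 120
    .clockstim_cache[[key]] <- diff(range(traj[[variable]][sel]))
  }
  .clockstim_cache[[key]]
}

#' Detect arrhythmic (faded) oscillations
#'
#' A signal is classified arrhythmic when its peak-to-trough amplitude in
#' the window drops below `floor_fraction` of the free-running amplitude of
#' the same variable.  Under a strong constant stimulus the limit cycle is
#' lost and the trajectory spirals into a fixed point; this detector
#' formalizes "the oscillations fade".
#'
#' @inheritParams find_peaks
#' @param window amplitude window (>= 48 h recommended)
#' @param floor_fraction amplitude floor relative to free-running (default
#'   0.05)
#' @param reference_amplitude free-running amplitude to compare against;
#'   default [free_running_amplitude()] of the same variable
#' @return List with `arrhythmic` (logical), `amplitude` and `threshold`.
#' @export
detect_arrhythmia <- function(traj, variable = "M", window = c(72, 120),
                              floor_fraction = 0.05,
                              reference_amplitude = NULL) {
  if (is.null(reference_amplitude))
    reference_amplitude <- free_running_amplitude(variable)
  sel <- traj$t >= window[1] & traj$t <= window[2]
  amp <- diff(range(traj[[variable]][sel]))
  thr <- floor_fraction * reference_amplitude
  list(arrhythmic = amp < thr, amplitude = amp, threshold = thr)
}

#' Constant-light period scan (Aschoff's rule)
#'
#' For each constant stimulus intensity c, simulates the chosen variant and
#' estimates the period from peak spacing of per mRNA in the measurement
#' window.  Weak constant light first shortens the period; beyond a
#' turning point it lengthens it, until the oscillation fades entirely --
#' the model's account of Aschoff's rule.  Entries whose windowed amplitude
#' falls below the arrhythmicity floor are flagged; the windowed period is
#' still reported whenever two peaks are measurable.
#'
#' @param variant `"fly"` (stimulus degrades P0) or `"mammal"` (stimulus
#'   induces transcription)
#' @param c_grid increasing vector of intensities
#' @param alpha,gamma,rho variant constants
#' @param params [core_parameters()]
#' @param window period-measurement window (h)
#' @param floor_fraction arrhythmicity floor, see [detect_arrhythmia()]
#' @param settings [solver_settings()]; the default integrates to 160 h so
#'   that the peak following the window is available for long periods
#' @return A `scan_result` data frame with columns `c`, `period`,
#'   `amplitude`, `status`; the intensity minimizing the period is attached
#'   as attribute `turning_point`.
#' @examples
#' \donttest{
#' scan <- scan_constant_light("fly", c_grid = c(0, 0.5))
#' scan$period
#' }
#' @export
scan_constant_light <- function(variant = c("fly", "mammal"),
                                c_grid = seq(0, 0.9, by = 0.1),
                                alpha = 1, gamma = 2, rho = 1,
                                params = core_parameters(),
                                window = c(80, 120),
                                floor_fraction = 0.05,
                                settings = solver_settings(t_end = 160)) {
  variant <- match.arg(variant)
  if (is.unsorted(c_grid, strictly = TRUE) || any(c_grid < 0))
    stop_config("'c_grid' must be non-negative and strictly increasing")
  vs <- if (variant == "fly") variant_spec("fly", alpha = alpha)
        else variant_spec("mammal", gamma = gamma, rho = rho)
  ref_amp <- free_running_amplitude("M")
  rows <- lapply(c_grid, function(cc) {
    traj <- simulate_oscillator(params = params, variant = vs,
                                stimulus = stim_constant(cc),
                                settings = settings)
    arr <- detect_arrhythmia(traj, "M", window = window,
                             floor_fraction = floor_fraction,
                             reference_amplitude = ref_amp)
    per <- tryCatch(estimate_period(traj, "M", window = window,
                                    floor = 1e-4)$period,
                    clockstim_arrhythmic_error = function(e) NA_real_)
    data.frame(c = cc, period = per, amplitude = arr$amplitude,
               status = if (arr$arrhythmic) "arrhythmic" else "rhythmic")
  })
  res <- do.call(rbind, rows)
  class(res) <- c("scan_result", "data.frame")
  if (any(is.finite(res$period)))
    attr(res, "turning_point") <- res$c[which.min(res$period)]
  res
}

#' Phase shift induced by the Zeitgeber phase
#'
#' Measures how far a periodically driven oscillator is displaced when the
#' Zeitgeber phase is `phi`, relative to the same oscillator entrained with
#' `phi = 0` (whose post-transient rhythm coincides with the unperturbed
#' clock's phase).  Both runs are entrained to the same Zeitgeber period,
#' so the offset is a well-defined steady-state quantity; measuring against
#' the free-running clock instead would drift by the difference between the
#' 23.7 h intrinsic and the 24 h entrained period every cycle.
#'
#' @param phi Zeitgeber phase (radians)
#' @param variant [variant_spec()] with an input port (default: mRNA-decay
#'   port with `alpha = 0.05`)
#' @param period Zeitgeber period (h)
#' @param gain stimulus amplitude multiplier, see [stim_periodic()]
#' @param params [core_parameters()]
#' @param settings [solver_settings()] (default integrates to 240 h)
#' @param transient_cut hours discarded before measuring (default 96)
#' @return A `phase_shift_estimate`; positive shift means the `phi`-driven
#'   clock peaks later than the `phi = 0` reference.
#' @examples
#' \donttest{
#' entrainment_phase_shift(pi)$shift   # about 12 h
#' }
#' @export
entrainment_phase_shift <- function(phi,
                                    variant = variant_spec("mrna_decay",
                                                           alpha = 0.05),
                                    period = 24, gain = 1,
                                    params = core_parameters(),
                                    settings = solver_settings(t_end = 240),
                                    transient_cut = 96) {
  run <- function(ph) simulate_oscillator(
    params = params, variant = variant,
    stimulus = stim_periodic(phi = ph, period = period, gain = gain),
    settings = settings)
  estimate_phase_shift(run(0), run(phi), "M", transient_cut = transient_cut)
}

#' Phase-response curve to a single stimulus pulse
#'
#' For each circadian time (CT, in hours of the free-running cycle, CT 0
#' anchored at a post-transient peak of per mRNA), applies one square pulse
#' through the variant's stimulus port and measures the steady-state shift
#' of the post-pulse peaks against the unpulsed control.  Shifts are in
#' `(-T/2, T/2]`; positive values are delays.
#'
#' @param variant [variant_spec()] with an input port
#' @param pulse_duration pulse length (h)
#' @param pulse_magnitude pulse intensity
#' @param ct_grid circadian times (h in `[0, 24)`)
#' @param params [core_parameters()]
#' @param settings [solver_settings()]; default integrates to 288 h
#' @param anchor_after CT 0 is the first control peak after this time
#' @return Data frame with columns `ct`, `shift`, `status` (`"rhythmic"`
#'   or `"arrhythmic"`).
#' @export
phase_response_curve <- function(variant = variant_spec("fly"),
                                 pulse_duration = 1, pulse_magnitude = 1,
                                 ct_grid = seq(0, 21, by = 3),
                                 params = core_parameters(),
                                 settings = solver_settings(t_end = 288),
                                 anchor_after = 72) {
  control <- simulate_oscillator(params = params, variant = variant,
                                 settings = settings)
  cpk <- find_peaks(control, "M")$time
  T0 <- mean(diff(cpk[cpk >= anchor_after]))
  ct0 <- cpk[cpk >= anchor_after][1L]
  rows <- lapply(ct_grid, function(ct) {
    t_pulse <- ct0 + ct * T0 / 24
    traj <- simulate_oscillator(
      params = params, variant = variant,
      stimulus = stim_pulse(t_pulse, pulse_duration, pulse_magnitude),
      settings = settings)
    sh <- tryCatch(
      estimate_phase_shift(control, traj, "M",
                           transient_cut = t_pulse + 3 * T0,
                           period_tol = 0.2)$shift,
      clockstim_error = function(e) NA_real_)
    data.frame(ct = ct, shift = sh,
               status = if (is.na(sh)) "arrhythmic" else "rhythmic")
  })
  do.call(rbind, rows)
}

#' Range of entrainment to Zeitgeber periods
#'
#' Drives the variant with a periodic stimulus of each trial period T and
#' tests for stable locking: the observed post-transient period must equal
#' T within `period_tol` and the peak phase relative to the Zeitgeber must
#' drift less than `drift_tol` over the last five cycles.  The contiguous
#' locked interval containing 24 h is reported.
#'
#' @param variant [variant_spec()] with an input port
#' @param amplitude stimulus gain (peak intensity is `2 * amplitude`)
#' @param T_grid increasing vector of Zeitgeber periods (h)
#' @param params [core_parameters()]
#' @param settings [solver_settings()]; default integrates to 240 h
#' @param period_tol,drift_tol locking tolerances (h)
#' @return A `scan_result` data frame with columns `T_zeit`, `period`,
#'   `drift`, `status` (`"locked"`/`"unlocked"`); attribute
#'   `locked_interval` gives the contiguous locked range containing 24 h
#'   (NULL if none).
#' @export
entrainment_range <- function(variant = variant_spec("fly"),
                              amplitude = 1,
                              T_grid = seq(20, 28, by = 1),
                              params = core_parameters(),
                              settings = solver_settings(t_end = 240),
                              period_tol = 0.1, drift_tol = 0.5) {
  if (any(T_grid <= 0)) stop_config("'T_grid' must be positive")
  rows <- lapply(T_grid, function(Tz) {
    traj <- simulate_oscillator(
      params = params, variant = variant,
      stimulus = stim_periodic(phi = 0, period = Tz, gain = amplitude),
      settings = settings)
    pk <- find_peaks(traj, "M")$time
    pk <- pk[pk >= settings$t_end - 6 * Tz]
    if (length(pk) < 5L)
      return(data.frame(T_zeit = Tz, period = NA_real_, drift = NA_real_,
                        status = "unlocked"))
    per <- mean(diff(pk))
    ph <- vapply(utils::tail(pk, 5L), function(p) p %% Tz, 0)
    drift <- diff(range(wrap_signed(ph - ph[1L], Tz)))
    locked <- abs(per - Tz) <= period_tol && drift <= drift_tol
    data.frame(T_zeit = Tz, period = per, drift = drift,
               status = if (locked) "locked" else "unlocked")
  })
  res <- do.call(rbind, rows)
  class(res) <- c("scan_result", "data.frame")
  locked <- res$status == "locked"
  i24 <- which.min(abs(res$T_zeit - 24))
  if (locked[i24]) {
    lo <- i24; while (lo > 1L && locked[lo - 1L]) lo <- lo - 1L
    hi <- i24; while (hi < nrow(res) && locked[hi + 1L]) hi <- hi + 1L
    attr(res, "locked_interval") <- c(res$T_zeit[lo], res$T_zeit[hi])
  }
  res
}

#' Resynchronization time after a Zeitgeber schedule change
#'
#' After the feeding schedule switches back, the peripheral clock re-locks
#' to the central one.  For each peak of the second trajectory after
#' `t_switch`, the signed circular offset to the nearest peak of the first
#' is computed; the resynchronization time is the elapsed time from
#' `t_switch` until the absolute offset first falls below `threshold`.
#'
#' @param ref,traj `clock_trajectory` columns are compared via `variable`
#' @param variable column name present in both (e.g. `"scn.M"` vs
#'   `"liver.M"` from the same network trajectory: pass the trajectory
#'   twice with different `variable`s via `ref_variable`)
#' @param ref_variable column of `ref` (defaults to `variable`)
#' @param t_switch schedule switch time (h)
#' @param threshold offset threshold (h, default 1)
#' @param period cycle length for circular wrapping (h, default 24)
#' @return List with `time` (h from `t_switch`; NA if never reached),
#'   `offsets` and `peak_times`.
#' @export
resynchronization_time <- function(ref, traj = ref, variable,
                                   ref_variable = variable,
                                   t_switch, threshold = 1, period = 24) {
  pa <- find_peaks(ref, ref_variable)$time
  pb <- find_peaks(traj, variable)$time
  pb <- pb[pb > t_switch]
  if (!length(pb) || length(pa) < 2L)
    return(list(time = NA_real_, offsets = numeric(0),
                peak_times = numeric(0)))
  off <- vapply(pb, function(b)
    wrap_signed(b - pa[which.min(abs(pa - b))], period), 0)
  hit <- which(abs(off) < threshold)
  list(time = if (length(hit)) pb[hit[1L]] - t_switch else NA_real_,
       offsets = off, peak_times = pb)
}

#' Synthetic rhythmic fixtures
#'
#' Generates sinusoidal (optionally exponentially damped) or constant test
#' waveforms with known period, amplitude and phase, packaged as a
#' `clock_trajectory` so that every analysis operation can be unit-tested
#' without integrating the model.
#'
#' @param period oscillation period (h); ignored when `amplitude = 0`
#' @param amplitude half peak-to-trough amplitude
#' @param phase phase offset (radians); a peak sits at
#'   `t = -phase * period / (2*pi)` modulo the period
#' @param damping exponential decay rate of the envelope (1/h)
#' @param offset additive baseline
#' @param t_end,dt time span and sampling (h)
#' @param variable column name for the generated series
#' @return A `clock_trajectory` with columns `t` and `variable`.
#' @examples
#' synth_trajectory(period = 25, t_end = 60)[1:3, ]
#' @export
synth_trajectory <- function(period = 24, amplitude = 1, phase = 0,
                             damping = 0, offset = 2, t_end = 120,
                             dt = 0.05, variable = "M") {
  if (period <= 0) stop_config("'period' must be positive")
  t <- seq(0, t_end, by = dt)
  v <- offset + amplitude * exp(-damping * t) * cos(2 * pi * t / period + phase)
  traj <- data.frame(t = t, v = v)
  names(traj)[2L] <- variable
  class(traj) <- c("clock_trajectory", "data.frame")
  traj
}
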