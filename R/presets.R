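#' Canonical two-oscillator networks
#'
#' Builders for the central/peripheral configurations studied with the
#' coupling framework.  The central oscillator is light-entrained; the
#' peripheral one receives no light and is driven purely through the
#' input-output interface.
#'
#' * `"antiphase"`: central with the mRNA-decay light port (`alpha = 0.05`,
#'   Zeitgeber phase `pi`); peripheral coupled by product decay
#'   (`alpha_t = 0.5`) from the central P0 -- locks in antiphase.
#' * `"inphase"`: same central; peripheral coupled by gated decay
#'   (`alpha_t = 0.5`, `beta = 2`) -- locks in phase.
#' * `"p2"`: same central; peripheral product-decay driven by the central
#'   P2 (`alpha_t = 0.5`) -- locks at an intermediate phase.
#' * `"food"`: central with the fly light port (`alpha = 1`) under the
#'   quarter-amplitude Zeitgeber (phase 0); peripheral integrates the
#'   central signal (gated, `alpha_t = 0.3`, `beta = 2`) and a feeding
#'   stimulus (`delta = 0.4`) that runs at night until `t_switch = 160` h
#'   and at daytime afterwards.
#'
#' @param coupling which configuration to build
#' @param t_switch feeding switch time for `"food"` (h)
#' @return A [network_spec()] with oscillators `"central"` and `"periph"`.
#' @examples
#' net <- coupled_clock_network("inphase")
#' @export
coupled_clock_network <- function(coupling = c("antiphase", "inphase", "p2",
                                               "food"),
                                  t_switch = 160) {
  coupling <- match.arg(coupling)
  if (coupling == "food") {
    central <- oscillator_unit("central",
                               variant = variant_spec("fly", alpha = 1),
                               stimulus = stim_scaled_periodic(phi = 0))
    cp <- coupling_term("periph", "dual_input", source = c("central", "P0"),
                        alpha_t = 0.3, beta = 2, delta = 0.4,
                        food = stim_food_switch(phi_tilde = pi, phi = 0,
                                                t_switch = t_switch))
  } else {
    central <- oscillator_unit("central",
                               variant = variant_spec("mrna_decay",
                                                      alpha = 0.05),
                               stimulus = stim_periodic(phi = pi))
    cp <- switch(coupling,
      antiphase = coupling_term("periph", "product_decay",
                                source = c("central", "P0"), alpha_t = 0.5),
      inphase   = coupling_term("periph", "gated_decay",
                                source = c("central", "P0"), alpha_t = 0.5,
                                beta = 2),
      p2        = coupling_term("periph", "product_decay",
                                source = c("central", "P2"), alpha_t = 0.5))
  }
  network_spec(list(central, oscillator_unit("periph")), list(cp))
}

#' Names of the bundled experiment presets
#' @return Character vector of preset names accepted by [run_preset()].
#' @export
preset_names <- function() {
  c("freerun", "entrain-phase", "fly-shift", "constant-light-scan",
    "couple-antiphase", "couple-inphase", "couple-p2", "food-entrain",
    "prc", "entrain-range", "ensemble-singularity")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 9L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

preset_log <- function(path, name, lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("preset: %s", name),
               sprintf("clockstim: %s",
                       as.character(utils::packageVersion("clockstim"))),
               lines), con)
}

#' Run a bundled experiment preset
#'
#' Executes one of the canonical experiments end to end, writes the
#' trajectory and analysis tables as TSV files into `out_dir` together with
#' a short run log, and returns the measured summaries invisibly.  Every
#' preset is deterministic.
#'
#' @param name one of [preset_names()]
#' @param out_dir output directory (created if needed)
#' @return Invisibly, a named list of the measured summary quantities.
#' @export
run_preset <- function(name, out_dir = ".") {
  if (!name %in% preset_names())
    stop_config(sprintf("unknown preset '%s'; valid presets: %s",
                        name, paste(preset_names(), collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pfile <- function(f) file.path(out_dir, f)
  summaries <- list()
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  if (name == "freerun") {
    traj <- simulate_oscillator(settings = solver_settings(t_end = 120))
    pe <- estimate_period(traj, "M")
    write_trajectory(traj, pfile("freerun_trajectory.tsv"))
    summaries$period_h <- pe$period
    note("free-running period: %.2f h", pe$period)

  } else if (name == "entrain-phase") {
    phis <- c(0, pi / 2, pi)
    rows <- lapply(phis, function(ph) {
      sh <- entrainment_phase_shift(ph)
      data.frame(phi = ph, shift_h = sh$shift)
    })
    df <- do.call(rbind, rows)
    write_tsv(df, pfile("entrain_phase_shifts.tsv"))
    summaries$shifts_h <- stats::setNames(df$shift_h, format(phis))
    note("phase shifts vs phi=0 clock: %s",
         paste(sprintf("phi=%.2f -> %+0.2f h", df$phi, df$shift_h),
               collapse = "; "))

  } else if (name == "fly-shift") {
    sh <- entrainment_phase_shift(pi, variant = variant_spec("fly", alpha = 1))
    summaries$shift_h <- sh$shift
    write_tsv(data.frame(phi = pi, shift_h = sh$shift),
              pfile("fly_shift.tsv"))
    note("fly-variant phase shift for phi=pi: %+0.2f h", sh$shift)

  } else if (name == "constant-light-scan") {
    for (v in c("fly", "mammal")) {
      scan <- scan_constant_light(v)
      write_tsv(as.data.frame(scan), pfile(paste0("scan_", v, ".tsv")))
      summaries[[paste0(v, "_periods_h")]] <- scan$period
      summaries[[paste0(v, "_turning_point")]] <- attr(scan, "turning_point")
      note("%s scan periods: %s (turning point c=%.1f)", v,
           paste(sprintf("%.1f", scan$period), collapse = ", "),
           attr(scan, "turning_point"))
    }

  } else if (name %in% c("couple-antiphase", "couple-inphase", "couple-p2")) {
    kind <- sub("couple-", "", name)
    net <- coupled_clock_network(kind)
    # the weakly driven central (alpha = 0.05) needs ~10 cycles to settle,
    # so these runs are longer than the single-oscillator experiments
    traj <- simulate_network(net, solver_settings(t_end = 360))
    write_trajectory(traj, pfile(paste0("network_", kind, ".tsv")))
    sh <- network_phase_shift(traj)
    summaries$shift_h <- sh
    note("peripheral lags central by %.2f h", sh)

  } else if (name == "food-entrain") {
    net <- coupled_clock_network("food")
    traj <- simulate_network(net, solver_settings(t_end = 240))
    write_trajectory(traj, pfile("network_food.tsv"))
    sh <- food_shift(traj)
    rs <- resynchronization_time(traj, traj, variable = "periph.M",
                                 ref_variable = "central.M", t_switch = 160)
    summaries$night_shift_h <- sh
    summaries$resync_h <- rs$time
    note("night-feeding shift: %+0.2f h; resynchronized %.1f h after switch",
         sh, rs$time)

  } else if (name == "prc") {
    prc <- phase_response_curve(ct_grid = seq(0, 21, by = 3))
    write_tsv(prc, pfile("prc.tsv"))
    summaries$prc <- prc
    note("PRC shifts: %s",
         paste(sprintf("ct=%g: %+0.2f", prc$ct, prc$shift), collapse = "; "))

  } else if (name == "entrain-range") {
    for (v in c("fly", "mammal")) {
      vs <- if (v == "fly") variant_spec("fly", alpha = 1)
            else variant_spec("mammal", gamma = 2, rho = 1)
      res <- entrainment_range(vs, T_grid = seq(21, 27, by = 1))
      write_tsv(as.data.frame(res), pfile(paste0("entrain_range_", v, ".tsv")))
      li <- attr(res, "locked_interval")
      summaries[[paste0(v, "_locked")]] <- li
      note("%s locked interval: [%s] h", v,
           if (is.null(li)) "none" else paste(li, collapse = ", "))
    }

  } else if (name == "ensemble-singularity") {
    # a 1 h pulse ~3 h after the shared mRNA peak lands the units near the
    # phaseless set, so their inhomogeneous couplings fan the phases out
    spec <- build_ensemble(5, alpha = 1, spread = 0.5,
                           stimulus = stim_pulse(87.8, 1, 2))
    traj <- ensemble_readout(simulate_network(spec,
                                              solver_settings(t_end = 200)))
    write_trajectory(traj, pfile("ensemble.tsv"))
    amp <- function(w) {
      sel <- traj$t >= w[1] & traj$t <= w[2]
      diff(range(traj$readout[sel]))
    }
    summaries$amplitude_before <- amp(c(30, 80))
    summaries$amplitude_after <- amp(c(140, 190))
    note("readout amplitude before pulse %.2f, after pulse %.2f",
         summaries$amplitude_before, summaries$amplitude_after)
  }

  preset_log(pfile(paste0(gsub("-", "_", name), ".log")), name, log_lines)
  invisible(summaries)
}

#' Steady phase lag of the peripheral clock behind the central one
#'
#' Circular mean, over the post-transient window, of the lag (in `[0, T)`)
#' of the peripheral mRNA peaks behind the nearest central mRNA peaks in a
#' network trajectory.
#'
#' @param traj trajectory from [simulate_network()] with columns
#'   `central.M` and `periph.M`
#' @param window measurement window (h); default: the last third of the run
#' @param period cycle length (h)
#' @return Lag in hours, in `[0, period)`.
#' @export
network_phase_shift <- function(traj, window = NULL, period = 24) {
  if (is.null(window)) window <- c(2 / 3 * max(traj$t), max(traj$t))
  pa <- find_peaks(traj, "central.M")$time
  pb <- find_peaks(traj, "periph.M")$time
  pb <- pb[pb >= window[1] & pb <= window[2]]
  if (length(pb) < 1L || length(pa) < 2L)
    stop_arrhythmic("network trajectory has too few peaks in the window")
  d <- vapply(pb, function(b) b - pa[which.min(abs(pa - b))], 0)
  circular_mean(d, period) %% period
}

food_shift <- function(traj, window = c(96, 160), period = 24) {
  pa <- find_peaks(traj, "central.M")$time
  pb <- find_peaks(traj, "periph.M")$time
  pb <- pb[pb >= window[1] & pb <= window[2]]
  d <- vapply(pb, function(b) b - pa[which.min(abs(pa - b))], 0)
  wrap_signed(circular_mean(d, period), period)
}
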