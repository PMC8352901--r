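#' Experiment configuration files
#'
#' Experiments are declared in YAML.  All sections are optional; omitted
#' numeric fields fall back to the reference values, so the minimal config
#' `{}` describes the default free-running oscillator.  Recognized
#' top-level sections:
#'
#' * `model`: named overrides of [core_parameters()] plus `hill_form`.
#' * `variant`: `kind` and the constants of [variant_spec()].
#' * `stimulus`: `kind` and the fields of the corresponding `stim_*()`
#'   constructor.
#' * `oscillators` / `couplings`: a coupled network; each oscillator has
#'   `id`, optional `variant`, `stimulus`, `state`, `params`; each coupling
#'   has `target`, `form`, `source` (`[id, var]`), `alpha_t` and the
#'   form-specific constants (`beta`, `delta`, `food`).
#' * `solver`: fields of [solver_settings()].
#' * `analysis`: `period_window` (two numbers) and `transient_cut`.
#' * `output`: `dir` for TSV results.
#'
#' Unknown keys anywhere are rejected with an error naming the key.
#'
#' @param path file path
#' @return `load_config()` returns an `experiment_config`;
#'   `save_config()` writes one and returns the path invisibly.
#' @name config
NULL

known_keys_list <- function() list(
  top = c("model", "variant", "stimulus", "oscillators", "couplings",
          "solver", "analysis", "output"),
  model = c(names(formals(core_parameters)), "hill_form"),
  variant = c("kind", "alpha", "gamma", "rho", "machinery"),
  machinery = c("rho_m", "xi", "T0"),
  stimulus = c("kind", "phi", "phi_tilde", "period", "gain", "c",
               "t_switch", "t_start", "duration", "magnitude", "inner",
               "id", "var"),
  oscillator = c("id", "variant", "stimulus", "state", "params",
                 "hill_form"),
  state = c("M", "P0", "P1", "P2", "PN"),
  coupling = c("target", "form", "source", "alpha_t", "beta", "delta",
               "food", "target_var"),
  solver = names(formals(solver_settings)),
  analysis = c("period_window", "transient_cut"),
  output = "dir")

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible())
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop_config(sprintf("unknown key '%s' in section '%s'", bad[1L], where))
  invisible()
}

config_stimulus <- function(s, where = "stimulus") {
  if (is.null(s)) return(stim_zero())
  check_keys(s, known_keys()$stimulus, where)
  kinds <- c("zero", "periodic", "scaled_periodic", "constant",
             "food_switch", "pulse", "log_transformed", "signal_tap")
  if (is.null(s$kind) || !s$kind %in% kinds)
    stop_config(sprintf("unknown stimulus kind '%s' in '%s'",
                        if (is.null(s$kind)) "<missing>" else s$kind, where))
  a <- function(nm, default) if (is.null(s[[nm]])) default else s[[nm]]
  switch(s$kind,
    zero = stim_zero(),
    periodic = stim_periodic(a("phi", 0), a("period", 24), a("gain", 1)),
    scaled_periodic = stim_scaled_periodic(a("phi", 0), a("period", 24)),
    constant = stim_constant(a("c", 0.5)),
    food_switch = stim_food_switch(a("phi_tilde", pi), a("phi", 0),
                                   a("t_switch", 160), a("period", 24)),
    pulse = stim_pulse(a("t_start", 100), a("duration", 1),
                       a("magnitude", 1)),
    log_transformed = stim_log(config_stimulus(s$inner,
                                               paste0(where, ".inner"))),
    signal_tap = stim_tap(a("id", stop_config(
      sprintf("signal_tap in '%s' needs an 'id'", where))), a("var", "P0")))
}

config_variant <- function(v, where = "variant") {
  if (is.null(v)) return(variant_spec("none"))
  check_keys(v, known_keys()$variant, where)
  kinds <- c("none", "mrna_decay", "fly", "mammal", "mammal_machinery")
  if (is.null(v$kind) || !v$kind %in% kinds)
    stop_config(sprintf("unknown variant kind '%s' in '%s'",
                        if (is.null(v$kind)) "<missing>" else v$kind, where))
  if (!is.null(v$machinery))
    check_keys(v$machinery, known_keys()$machinery,
               paste0(where, ".machinery"))
  variant_spec(v$kind, alpha = v$alpha, gamma = v$gamma, rho = v$rho,
               machinery = v$machinery)
}

config_params <- function(m, where = "model") {
  if (is.null(m)) return(core_parameters())
  ov <- m[setdiff(names(m), "hill_form")]
  do.call(core_parameters, ov)
}

config_state <- function(s, where = "state") {
  if (is.null(s)) return(oscillator_state())
  check_keys(s, known_keys()$state, where)
  do.call(oscillator_state, s)
}

#' @rdname config
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_config(sprintf("config file '%s' does not exist", path))
  raw <- yaml::yaml.load_file(path)
  if (is.null(raw)) raw <- list()
  check_keys(raw, known_keys()$top, "<top level>")
  check_keys(raw$model, known_keys()$model, "model")
  check_keys(raw$solver, known_keys()$solver, "solver")
  check_keys(raw$analysis, known_keys()$analysis, "analysis")
  check_keys(raw$output, known_keys()$output, "output")

  hill_form <- raw$model$hill_form
  if (is.null(hill_form)) hill_form <- "KI"
  if (!hill_form %in% c("KI", "K1", "mixed"))
    stop_config(sprintf("unknown hill_form '%s' in 'model'", hill_form))
  params <- config_params(raw$model)

  network <- NULL
  if (!is.null(raw$oscillators)) {
    oscs <- lapply(seq_along(raw$oscillators), function(i) {
      o <- raw$oscillators[[i]]
      where <- sprintf("oscillators[%d]", i)
      check_keys(o, known_keys()$oscillator, where)
      if (is.null(o$id))
        stop_config(sprintf("missing 'id' in %s", where))
      oscillator_unit(
        o$id,
        params = if (is.null(o$params)) params
                 else config_params(o$params, paste0(where, ".params")),
        state = config_state(o$state, paste0(where, ".state")),
        variant = config_variant(o$variant, paste0(where, ".variant")),
        stimulus = config_stimulus(o$stimulus, paste0(where, ".stimulus")),
        hill_form = if (is.null(o$hill_form)) hill_form else o$hill_form)
    })
    cps <- lapply(seq_along(raw$couplings), function(i) {
      cp <- raw$couplings[[i]]
      where <- sprintf("couplings[%d]", i)
      check_keys(cp, known_keys()$coupling, where)
      coupling_term(
        cp$target,
        form = cp$form,
        source = unlist(cp$source),
        alpha_t = cp$alpha_t, beta = cp$beta, delta = cp$delta,
        food = if (is.null(cp$food)) NULL
               else config_stimulus(cp$food, paste0(where, ".food")),
        target_var = if (is.null(cp$target_var)) "P0" else cp$target_var)
    })
    network <- network_spec(oscs, cps)
  } else if (!is.null(raw$couplings)) {
    stop_config("'couplings' given without 'oscillators'")
  }

  sv <- raw$solver
  settings <- solver_settings(
    rel_tol = if (is.null(sv$rel_tol)) 1e-8 else sv$rel_tol,
    abs_tol = if (is.null(sv$abs_tol)) 1e-10 else sv$abs_tol,
    max_step = if (is.null(sv$max_step)) Inf else sv$max_step,
    t_end = if (is.null(sv$t_end)) 100 else sv$t_end,
    sample_dt = if (is.null(sv$sample_dt)) 0.05 else sv$sample_dt)

  an <- raw$analysis
  analysis <- list(
    period_window = if (is.null(an$period_window)) c(80, 120)
                    else as.numeric(unlist(an$period_window)),
    transient_cut = if (is.null(an$transient_cut)) 72 else an$transient_cut)

  structure(list(raw = raw, params = params, hill_form = hill_form,
                 variant = config_variant(raw$variant),
                 stimulus = config_stimulus(raw$stimulus),
                 network = network, settings = settings,
                 analysis = analysis,
                 output_dir = raw$output$dir),
            class = "experiment_config")
}

#' @param config an `experiment_config`
#' @rdname config
#' @export
save_config <- function(config, path) {
  raw <- if (inherits(config, "experiment_config")) config$raw else config
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Execute a configured experiment
#'
#' Integrates the configured oscillator or network and estimates the period
#' of each mRNA series in the configured analysis window.  When the config
#' names an output directory, the trajectory and period table are written
#' there as TSV.
#'
#' @param config an `experiment_config` from [load_config()]
#' @param out_dir optional override of the configured output directory
#' @return List with the `trajectory` and a `periods` data frame.
#' @export
run_config <- function(config, out_dir = NULL) {
  if (!inherits(config, "experiment_config"))
    stop_config("'config' must come from load_config()")
  traj <- if (!is.null(config$network)) {
    simulate_network(config$network, config$settings)
  } else {
    simulate_oscillator(params = config$params, variant = config$variant,
                        stimulus = config$stimulus,
                        settings = config$settings,
                        hill_form = config$hill_form)
  }
  mcols <- grep("(^|\\.)M$", names(traj), value = TRUE)
  periods <- do.call(rbind, lapply(mcols, function(v) {
    per <- tryCatch(
      estimate_period(traj, v, window = config$analysis$period_window)$period,
      clockstim_arrhythmic_error = function(e) NA_real_)
    data.frame(variable = v, period = per,
               status = if (is.na(per)) "arrhythmic" else "rhythmic")
  }))
  dir <- if (!is.null(out_dir)) out_dir else config$output_dir
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory(traj, file.path(dir, "trajectory.tsv"))
    write_tsv(periods, file.path(dir, "periods.tsv"))
  }
  list(trajectory = traj, periods = periods)
}

known_keys <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- known_keys_list()
    cache
  }
})
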