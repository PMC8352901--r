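#' Coupling terms between oscillators
#'
#' Rate contributions through which one oscillator's state drives another.
#' All three forms act as an extra degradation of the target's
#' unphosphorylated PER pool (the injection point is configurable in
#' [coupling_term()] but defaults to P0, which is where the coupled models
#' place it):
#'
#' * `antiphase_coupling_term()`: product decay `-alpha_t * x_target * x_source`.
#'   Degradation is strongest when both pools are high simultaneously, which
#'   locks the target in antiphase to the source.
#' * `inphase_coupling_term()`: gated decay
#'   `-alpha_t * x_target * exp(-beta * x_source)`.  A high source level
#'   suppresses the degradation, which locks the target in phase.
#' * `p2_coupling_term()`: product decay driven by the source oscillator's
#'   biphosphorylated pool P2, whose phase lag relative to P0 yields
#'   intermediate phase relationships between the locked oscillators.
#' * `dual_input_term()`: the gated term plus a bilinear food-stimulus term
#'   `-delta * u_food * x_target`; the target integrates both inputs.
#'
#' @param P0_tilde,P0p_tilde target oscillator's P0 amount (uM)
#' @param P0_source,P2_source source oscillator's P0 / P2 amount (uM)
#' @param alpha_t,alpha_p coupling constants (1/h per uM)
#' @param beta gating exponent constant (1/uM)
#' @param u_food food stimulus intensity (>= 0)
#' @param delta food coupling constant (1/h per intensity unit)
#'
#' @return Rate contribution in uM/h (non-positive).
#' @examples
#' antiphase_coupling_term(1, 2, alpha_t = 0.5)
#' inphase_coupling_term(1, 2, alpha_t = 0.5, beta = 2)
#' @name coupling_terms
NULL

#' @rdname coupling_terms
#' @export
antiphase_coupling_term <- function(P0_tilde, P0_source, alpha_t) {
  -alpha_t * P0_tilde * P0_source
}

#' @rdname coupling_terms
#' @export
inphase_coupling_term <- function(P0_tilde, P0_source, alpha_t, beta) {
  -alpha_t * P0_tilde * exp(-beta * P0_source)
}

#' @rdname coupling_terms
#' @export
p2_coupling_term <- function(P0p_tilde, P2_source, alpha_p) {
  -alpha_p * P0p_tilde * P2_source
}

#' @rdname coupling_terms
#' @export
dual_input_term <- function(P0_tilde, P0_source, alpha_t, beta, u_food, delta) {
  inphase_coupling_term(P0_tilde, P0_source, alpha_t, beta) -
    delta * u_food * P0_tilde
}

#' One oscillator in a coupled network
#'
#' @param id unique oscillator identifier (character)
#' @param params [core_parameters()]
#' @param state initial [oscillator_state()]
#' @param variant [variant_spec()] describing the stimulus port
#' @param stimulus `clock_stimulus` driving the port (may be a [stim_tap()]
#'   reading another oscillator)
#' @param hill_form Hill-term form, see [core_rhs()]
#' @return An object of class `oscillator_unit`.
#' @examples
#' oscillator_unit("scn", variant = variant_spec("fly"),
#'                 stimulus = stim_periodic(phi = pi))
#' @export
oscillator_unit <- function(id, params = core_parameters(),
                            state = oscillator_state(),
                            variant = variant_spec("none"),
                            stimulus = stim_zero(),
                            hill_form = "KI") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_config("oscillator 'id' must be a non-empty string")
  if (variant$kind == "mammal_machinery")
    stop_config("machinery variants are supported in simulate_oscillator(), not in networks")
  structure(list(id = id, params = params, state = state, variant = variant,
                 stimulus = stimulus, hill_form = hill_form),
            class = "oscillator_unit")
}

#' Declare a coupling between two oscillators
#'
#' @param target id of the oscillator whose equation receives the term
#' @param form one of `"product_decay"` (antiphase lock),
#'   `"gated_decay"` (in-phase lock), `"dual_input"` (gated + food term)
#' @param source `c(id, var)`: oscillator id and state variable read as the
#'   driving signal
#' @param alpha_t coupling constant (> 0)
#' @param beta gating constant, required for `gated_decay` / `dual_input`
#' @param delta food coupling constant, required for `dual_input`
#' @param food `clock_stimulus` for the food input (required for
#'   `dual_input`)
#' @param target_var state variable of the target receiving the term
#'   (default `"P0"`)
#' @return An object of class `coupling_term`.
#' @examples
#' coupling_term("liver", "product_decay", source = c("scn", "P0"),
#'               alpha_t = 0.5)
#' @export
coupling_term <- function(target,
                          form = c("product_decay", "gated_decay",
                                   "dual_input"),
                          source, alpha_t, beta = NULL, delta = NULL,
                          food = NULL, target_var = "P0") {
  form <- match.arg(form)
  if (!is.numeric(alpha_t) || alpha_t <= 0)
    stop_config("coupling constant 'alpha_t' must be positive")
  if (!target_var %in% state_vars)
    stop_config(sprintf("unknown coupling target variable '%s'", target_var))
  if (length(source) != 2L || !source[[2]] %in% state_vars)
    stop_config("coupling 'source' must be c(id, var) with a valid state variable")
  if (form %in% c("gated_decay", "dual_input")) {
    if (is.null(beta) || beta <= 0)
      stop_config("'beta' must be positive for gated couplings")
  }
  if (form == "dual_input") {
    if (is.null(delta) || delta <= 0)
      stop_config("'delta' must be positive for dual-input couplings")
    if (!inherits(food, "clock_stimulus"))
      stop_config("dual-input coupling needs a 'food' stimulus")
  }
  structure(list(target = as.character(target), target_var = target_var,
                 form = form, source_id = as.character(source[[1]]),
                 source_var = source[[2]], alpha_t = alpha_t, beta = beta,
                 delta = delta, food = food),
            class = "coupling_term")
}

#' Assemble a multi-oscillator network
#'
#' @param oscillators list of [oscillator_unit()]s with unique ids
#' @param couplings list of [coupling_term()]s referencing declared ids
#' @return An object of class `network_spec`.
#' @examples
#' net <- network_spec(list(
#'   oscillator_unit("scn", variant = variant_spec("mrna_decay", alpha = 0.05),
#'                   stimulus = stim_periodic(phi = pi)),
#'   oscillator_unit("liver")),
#'   list(coupling_term("liver", "product_decay", c("scn", "P0"), 0.5)))
#' @export
network_spec <- function(oscillators, couplings = list()) {
  ids <- vapply(oscillators, function(o) o$id, "")
  if (anyDuplicated(ids))
    stop_config("oscillator ids must be unique")
  for (cp in couplings) {
    if (!cp$target %in% ids)
      stop_config(sprintf("coupling targets undeclared oscillator '%s'", cp$target))
    if (!cp$source_id %in% ids)
      stop_config(sprintf("coupling reads undeclared oscillator '%s'", cp$source_id))
  }
  for (o in oscillators) {
    if (o$stimulus$kind == "signal_tap" && !o$stimulus$id %in% ids)
      stop_config(sprintf("signal tap references undeclared oscillator '%s'",
                          o$stimulus$id))
  }
  structure(list(oscillators = oscillators, couplings = couplings, ids = ids),
            class = "network_spec")
}

#' Build the combined right-hand side of a network
#'
#' Concatenates all oscillators' states (named `<id>.M`, `<id>.P0`, ...)
#' and returns a single derivative function over the global state.  Each
#' coupling term and each signal tap reads the source value from the current
#' global state, so the derivative is a pure function of `(t, y)` and the
#' declaration order of oscillators does not affect trajectories.
#'
#' @param spec a [network_spec()]
#' @return List with `rhs(t, y)`, the initial state `y0`, the variable
#'   names, and the union of stimulus `breakpoints`.
#' @export
assemble_network <- function(spec) {
  oscs <- spec$oscillators
  nosc <- length(oscs)
  offs <- (seq_len(nosc) - 1L) * 5L
  names(offs) <- spec$ids
  vars <- unlist(lapply(spec$ids, function(id) paste(id, state_vars, sep = ".")))
  y0 <- unlist(lapply(oscs, function(o) unclass(o$state)))
  names(y0) <- vars

  idx_of <- function(id, var) offs[[id]] + match(var, state_vars)

  cp_fun <- lapply(spec$couplings, function(cp) {
    ti <- idx_of(cp$target, cp$target_var)
    si <- idx_of(cp$source_id, cp$source_var)
    switch(cp$form,
      product_decay = function(t, y) {
        list(i = ti, v = antiphase_coupling_term(y[ti], y[si], cp$alpha_t))
      },
      gated_decay = function(t, y) {
        list(i = ti, v = inphase_coupling_term(y[ti], y[si], cp$alpha_t, cp$beta))
      },
      dual_input = function(t, y) {
        list(i = ti,
             v = dual_input_term(y[ti], y[si], cp$alpha_t, cp$beta,
                                 stim_eval(cp$food, t), cp$delta))
      })
  })

  osc_u <- lapply(oscs, function(o) {
    st <- o$stimulus
    if (st$kind == "signal_tap") {
      si <- idx_of(st$id, st$var)
      function(t, y) y[si]
    } else {
      function(t, y) stim_eval(st, t)
    }
  })

  rhs <- function(t, y) {
    d <- numeric(5L * nosc)
    for (k in seq_len(nosc)) {
      o <- oscs[[k]]
      s <- y[(offs[k] + 1L):(offs[k] + 5L)]
      names(s) <- state_vars
      d[(offs[k] + 1L):(offs[k] + 5L)] <-
        variant_rhs(s, o$params, o$variant, osc_u[[k]](t, y), o$hill_form)
    }
    for (f in cp_fun) {
      ct <- f(t, y)
      d[ct$i] <- d[ct$i] + ct$v
    }
    d
  }

  bp <- sort(unique(c(
    unlist(lapply(oscs, function(o) discontinuity_times(o$stimulus))),
    unlist(lapply(spec$couplings, function(cp)
      if (!is.null(cp$food)) discontinuity_times(cp$food) else numeric(0))))))

  list(rhs = rhs, y0 = y0, vars = vars, breakpoints = bp)
}

#' Ensemble of inhomogeneously coupled oscillators
#'
#' Builds `n` identical oscillators that all receive the same stimulus but
#' with individually different coupling constants (a deterministic linear
#' spread over `alpha * (1 - spread)` to `alpha * (1 + spread)`, or a
#' uniform random spread when `seed` is given).  Because each unit couples
#' with a slightly different strength, a single well-timed pulse pushes the
#' units to different phases and the summed macroscopic rhythm collapses --
#' the mechanism behind "points of singularity"; a second pulse can
#' re-align them.
#'
#' @param n number of oscillators (>= 1)
#' @param alpha central coupling constant
#' @param spread relative half-width of the coupling spread (0 gives a
#'   homogeneous ensemble)
#' @param stimulus shared `clock_stimulus`
#' @param variant_kind stimulus-port kind for every unit
#' @param seed if non-NULL, draw the spread uniformly at random instead of
#'   linearly
#' @return A [network_spec()] whose oscillators are named `osc1 ... oscn`.
#' @seealso [ensemble_readout()]
#' @export
build_ensemble <- function(n, alpha = 1, spread = 0.1,
                           stimulus = stim_zero(),
                           variant_kind = "fly", seed = NULL) {
  if (n < 1) stop_config("'n' must be at least 1")
  if (spread < 0 || spread >= 1) stop_config("'spread' must be in [0, 1)")
  if (!is.null(seed)) {
    set.seed(seed)
    alphas <- stats::runif(n, alpha * (1 - spread), alpha * (1 + spread))
  } else if (n == 1L) {
    alphas <- alpha
  } else {
    alphas <- seq(alpha * (1 - spread), alpha * (1 + spread), length.out = n)
  }
  oscs <- lapply(seq_len(n), function(i)
    oscillator_unit(paste0("osc", i),
                    variant = variant_spec(variant_kind, alpha = alphas[i],
                                           gamma = alphas[i]),
                    stimulus = stimulus))
  network_spec(oscs)
}

#' Macroscopic readout of an ensemble
#'
#' Sum of all oscillators' mRNA trajectories; the observable a tissue-level
#' rhythm assay would report.
#'
#' @param traj trajectory returned by [simulate_network()]
#' @param variable per-unit variable to sum (default `"M"`)
#' @return The trajectory with an added `readout` column.
#' @export
ensemble_readout <- function(traj, variable = "M") {
  cols <- grep(paste0("\\.", variable, "$"), names(traj), value = TRUE)
  if (!length(cols)) stop_config("trajectory has no per-oscillator columns")
  traj$readout <- rowSums(traj[, cols, drop = FALSE])
  traj
}
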