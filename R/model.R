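#' Right-hand side of the core PER oscillator
#'
#' Evaluates the time derivatives of the five-variable negative-feedback
#' oscillator: nuclear PER represses per transcription through a Hill term,
#' the protein is reversibly phosphorylated twice, degraded in its
#' biphosphorylated form, and shuttled between cytosol and nucleus.
#'
#' Three algebraic forms of the transcription (Hill) term are supported via
#' `hill_form`.  The default `"KI"` uses `vs*KI^n/(KI^n + PN^n)` (threshold
#' constant in both numerator and denominator), which is the form whose
#' reference parameterization free-runs at about 23.7 h.  `"K1"` uses
#' `vs*K1^n/(K1^n + PN^n)` and `"mixed"` uses `vs*K1^n/(KI^n + PN^n)`; both
#' are provided for auditability of the alternative printed forms but change
#' the dynamics substantially.
#'
#' @param state named numeric vector with components M, P0, P1, P2, PN (uM)
#' @param params a [core_parameters()] object
#' @param hill_form one of `"KI"`, `"K1"`, `"mixed"`
#'
#' @return Named numeric vector of derivatives (uM/h) for M, P0, P1, P2, PN.
#' @examples
#' core_rhs(oscillator_state(), core_parameters())
#' @export
core_rhs <- function(state, params = core_parameters(), hill_form = "KI") {
  if (!all(is.finite(state)))
    stop_config("oscillator state contains non-finite values")
  p <- params
  M <- state[["M"]]; P0 <- state[["P0"]]; P1 <- state[["P1"]]
  P2 <- state[["P2"]]; PN <- state[["PN"]]
  hill <- hill_term(PN, p, hill_form)
  f01 <- p$V1 * P0 / (p$K1 + P0)
  f10 <- p$V2 * P1 / (p$K2 + P1)
  f12 <- p$V3 * P1 / (p$K3 + P1)
  f21 <- p$V4 * P2 / (p$K4 + P2)
  c(M  = hill - p$vm * M / (p$Km + M),
    P0 = p$ks * M - f01 + f10,
    P1 = f01 - f10 - f12 + f21,
    P2 = f12 - f21 - p$k1 * P2 + p$k2 * PN - p$vd * P2 / (p$Kd + P2),
    PN = p$k1 * P2 - p$k2 * PN)
}

hill_term <- function(PN, p, hill_form = "KI") {
  switch(match.arg(hill_form, c("KI", "K1", "mixed")),
         KI    = p$vs * p$KI^p$n / (p$KI^p$n + PN^p$n),
         K1    = p$vs * p$K1^p$n / (p$K1^p$n + PN^p$n),
         mixed = p$vs * p$K1^p$n / (p$KI^p$n + PN^p$n))
}

#' Stimulus-port specification for one oscillator
#'
#' Declares how an external stimulus u(t) >= 0 enters the oscillator's
#' equations.  Each kind adds exactly one term to the core right-hand side:
#'
#' * `"none"`: no input port; supplying a non-zero stimulus is an error.
#' * `"mrna_decay"`: `-alpha*u*M` on dM/dt (stimulus degrades per mRNA).
#' * `"fly"`: `-alpha*u*P0` on dP0/dt (light degrades PER protein, as in
#'   Drosophila via light-sensitive CRY/TIM).
#' * `"mammal"`: `+gamma*u*exp(-rho*M)` on dM/dt (light induces per
#'   transcription, saturating when mRNA is already abundant).
#' * `"mammal_machinery"`: as `"mammal"` but the saturation factor is
#'   replaced by an explicit transcription-machinery pool: the induction
#'   term becomes `+gamma*Tstar` with T/Tstar dynamics from
#'   [machinery_rhs()].
#'
#' @param kind one of `"none"`, `"mrna_decay"`, `"fly"`, `"mammal"`,
#'   `"mammal_machinery"`
#' @param alpha bilinear coupling constant for the decay kinds (1/h per
#'   intensity unit); default 1
#' @param gamma transcription-induction gain for the mammalian kinds
#'   (uM/h per intensity unit); default 2
#' @param rho saturation exponent constant (1/uM); default 1
#' @param machinery for `"mammal_machinery"`: list with `rho_m`
#'   (stimulation rate constant, 1/h per intensity unit), `xi` (relaxation
#'   rate, 1/h) and `T0` (total machinery pool, uM)
#'
#' @return An object of class `variant_spec`.
#' @examples
#' variant_spec("fly", alpha = 1)
#' variant_spec("mammal", gamma = 2, rho = 1)
#' @export
variant_spec <- function(kind = c("none", "mrna_decay", "fly", "mammal",
                                  "mammal_machinery"),
                         alpha = NULL, gamma = NULL, rho = NULL,
                         machinery = NULL) {
  kind <- match.arg(kind)
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop_config(sprintf("variant constant '%s' must be a single positive number", nm))
    x
  }
  v <- list(kind = kind)
  if (kind %in% c("mrna_decay", "fly"))
    v$alpha <- chk(if (is.null(alpha)) 1 else alpha, "alpha")
  if (kind %in% c("mammal", "mammal_machinery")) {
    v$gamma <- chk(if (is.null(gamma)) 2 else gamma, "gamma")
    if (kind == "mammal")
      v$rho <- chk(if (is.null(rho)) 1 else rho, "rho")
  }
  if (kind == "mammal_machinery") {
    if (is.null(machinery))
      machinery <- list(rho_m = 1, xi = 0.5, T0 = 1)
    for (nm in c("rho_m", "xi", "T0"))
      machinery[[nm]] <- chk(machinery[[nm]], nm)
    v$machinery <- machinery[c("rho_m", "xi", "T0")]
  }
  structure(v, class = "variant_spec")
}

#' Right-hand side of a stimulus-extended oscillator
#'
#' [core_rhs()] plus the single additive stimulus term selected by the
#' variant (see [variant_spec()]).  With `u = 0` every variant reduces
#' exactly to the core model.
#'
#' @inheritParams core_rhs
#' @param variant a [variant_spec()]
#' @param u stimulus intensity at the evaluation time (dimensionless, >= 0)
#' @param aux for `"mammal_machinery"`: named vector with `T` and `Tstar`
#'
#' @return Named numeric vector of derivatives for M, P0, P1, P2, PN.
#' @examples
#' s <- oscillator_state()
#' variant_rhs(s, variant = variant_spec("fly"), u = 1)
#' @export
variant_rhs <- function(state, params = core_parameters(),
                        variant = variant_spec("none"), u = 0,
                        hill_form = "KI", aux = NULL) {
  if (!is.finite(u) || u < 0)
    stop_config("stimulus intensity u must be finite and non-negative")
  d <- core_rhs(state, params, hill_form)
  switch(variant$kind,
    none = {
      if (u != 0)
        stop_config("stimulus supplied but variant 'none' has no input port")
    },
    mrna_decay = {
      d[["M"]] <- d[["M"]] - variant$alpha * u * state[["M"]]
    },
    fly = {
      d[["P0"]] <- d[["P0"]] - variant$alpha * u * state[["P0"]]
    },
    mammal = {
      d[["M"]] <- d[["M"]] + variant$gamma * u * exp(-variant$rho * state[["M"]])
    },
    mammal_machinery = {
      if (is.null(aux))
        stop_config("variant 'mammal_machinery' needs aux = c(T=, Tstar=)")
      d[["M"]] <- d[["M"]] + variant$gamma * aux[["Tstar"]]
    })
  d
}

#' Transcription-machinery subsystem
#'
#' Two-species pool that replaces the exponential saturation of the
#' mammalian light-induction term by mass-action kinetics: the stimulus
#' converts unstimulated machinery T into stimulated machinery T*, which
#' relaxes back at rate xi.  The total T + T* is conserved, so the
#' transcription capacity that can be recruited is bounded by the initial
#' pool.
#'
#' @param T unstimulated machinery (uM)
#' @param Tstar stimulated machinery (uM)
#' @param u stimulus intensity (>= 0)
#' @param rho_m stimulation rate constant (1/h per intensity unit)
#' @param xi relaxation rate constant (1/h)
#'
#' @return Named numeric vector `c(T = dT/dt, Tstar = dT*/dt)`; the two
#'   always sum to zero.
#' @examples
#' machinery_rhs(T = 1, Tstar = 0.2, u = 1, rho_m = 1, xi = 0.5)
#' @export
machinery_rhs <- function(T, Tstar, u, rho_m, xi) {
  if (rho_m <= 0 || xi <= 0)
    stop_config("machinery rate constants rho_m and xi must be positive")
  if (!is.finite(u) || u < 0)
    stop_config("stimulus intensity u must be finite and non-negative")
  dT <- -rho_m * u * T + xi * Tstar
  c(T = dT, Tstar = -dT)
}

#' Cooperativity subsystem for quadratic stimulus action
#'
#' Auxiliary pair of species that expresses a squared stimulus effect
#' (two light-activated molecules acting cooperatively) through bilinear
#' mass-action terms: each species grows with the stimulus and decays at a
#' common rate, and the product M1*M2 stands in for u^2 as a stimulus
#' signal for downstream equations.
#'
#' @param M1,M2 amounts of the two activated species (uM)
#' @param u stimulus intensity (>= 0)
#' @param gamma_h common decay rate (1/h)
#'
#' @return List with `deriv = c(M1 = , M2 = )` and `signal = M1*M2`.
#' @examples
#' cooperativity_rhs(1, 1, u = 2, gamma_h = 0.5)
#' @export
cooperativity_rhs <- function(M1, M2, u, gamma_h) {
  if (!all(is.finite(c(M1, M2, u, gamma_h))))
    stop_config("cooperativity_rhs inputs must be finite")
  list(deriv = c(M1 = (u - gamma_h) * M1, M2 = (u - gamma_h) * M2),
       signal = M1 * M2)
}
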