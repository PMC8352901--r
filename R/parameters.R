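#' Kinetic parameters of the five-variable PER oscillator
#'
#' Constructs the parameter set of the Goldbeter-type negative-feedback
#' oscillator for PER mRNA and protein.  Called without arguments it returns
#' the reference parameterization that yields a free-running period of about
#' 23.7 h; individual constants can be overridden by name.
#'
#' @param vs maximum mRNA accumulation rate (uM/h)
#' @param vm maximum mRNA degradation rate (uM/h)
#' @param Km Michaelis constant of mRNA degradation (uM)
#' @param ks first-order translation rate constant (1/h)
#' @param vd maximum degradation rate of biphosphorylated PER (uM/h)
#' @param k1 nuclear import rate constant (1/h)
#' @param k2 nuclear export rate constant (1/h)
#' @param KI threshold constant for transcriptional inhibition (uM)
#' @param Kd Michaelis constant of P2 degradation (uM)
#' @param n Hill degree of cooperativity (positive integer)
#' @param K1,K2,K3,K4 Michaelis constants of the (de)phosphorylation steps (uM)
#' @param V1,V2,V3,V4 maximum rates of the (de)phosphorylation steps (uM/h)
#'
#' @return An object of class `core_parameters`: a named list of the 18
#'   kinetic constants.
#' @examples
#' p <- core_parameters()
#' p$vs
#' core_parameters(vd = 1.1)$vd
#' @export
core_parameters <- function(vs = 0.76, vm = 0.65, Km = 0.5, ks = 0.38,
                            vd = 0.95, k1 = 1.9, k2 = 1.3, KI = 1,
                            Kd = 0.2, n = 4, K1 = 2, K2 = 2, K3 = 2, K4 = 2,
                            V1 = 3.2, V2 = 1.58, V3 = 5, V4 = 2.5) {
  p <- list(vs = vs, vm = vm, Km = Km, ks = ks, vd = vd, k1 = k1, k2 = k2,
            KI = KI, Kd = Kd, n = n, K1 = K1, K2 = K2, K3 = K3, K4 = K4,
            V1 = V1, V2 = V2, V3 = V3, V4 = V4)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_config(sprintf("parameter '%s' must be a single positive finite number", nm))
  }
  if (n < 1 || abs(n - round(n)) > 1e-8)
    stop_config("Hill degree 'n' must be a positive integer")
  p$n <- as.integer(round(n))
  structure(p, class = "core_parameters")
}

#' State of one PER oscillator
#'
#' The five dynamical amounts of the oscillator.  Defaults are the reference
#' initial values used throughout.
#'
#' @param M cytosolic per mRNA (uM)
#' @param P0 unphosphorylated PER protein (uM)
#' @param P1 monophosphorylated PER protein (uM)
#' @param P2 biphosphorylated PER protein (uM)
#' @param PN nuclear biphosphorylated PER protein (uM)
#'
#' @return A named numeric vector of class `oscillator_state`.
#' @examples
#' oscillator_state()
#' @export
oscillator_state <- function(M = 0.5, P0 = 0.5, P1 = 0.5, P2 = 0.6, PN = 1.5) {
  s <- c(M = M, P0 = P0, P1 = P1, P2 = P2, PN = PN)
  if (!all(is.finite(s)))
    stop_config("oscillator state must be finite")
  if (any(s < -1e-9))
    stop_config("oscillator state must be non-negative")
  structure(s, class = "oscillator_state")
}

state_vars <- c("M", "P0", "P1", "P2", "PN")

#' @export
print.core_parameters <- function(x, ...) {
  cat("PER oscillator parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}

# classed error helpers shared across modules
stop_config <- function(msg) {
  stop(structure(class = c("clockstim_config_error", "clockstim_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_arrhythmic <- function(msg) {
  stop(structure(class = c("clockstim_arrhythmic_error", "clockstim_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_not_entrained <- function(msg) {
  stop(structure(class = c("clockstim_not_entrained_error", "clockstim_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_integration <- function(msg, time = NA_real_) {
  stop(structure(class = c("clockstim_integration_error", "clockstim_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1), time = time)))
}
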