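# Independent arithmetic oracle for the oscillator derivatives: the model is
# re-expressed as a stoichiometric sum of elementary fluxes, so any slip in
# the production-code formulas would show up as a disagreement.
oracle_rhs <- function(state, p, hill_num = p$KI) {
  mm <- function(Vmax, K, x) Vmax * x / (K + x)
  M <- state[["M"]]; P0 <- state[["P0"]]; P1 <- state[["P1"]]
  P2 <- state[["P2"]]; PN <- state[["PN"]]
  fluxes <- c(
    transcribe = p$vs * hill_num^p$n / (p$KI^p$n + PN^p$n),
    m_decay    = mm(p$vm, p$Km, M),
    translate  = p$ks * M,
    phos1      = mm(p$V1, p$K1, P0),
    dephos1    = mm(p$V2, p$K2, P1),
    phos2      = mm(p$V3, p$K3, P1),
    dephos2    = mm(p$V4, p$K4, P2),
    degrade    = mm(p$vd, p$Kd, P2),
    import     = p$k1 * P2,
    export     = p$k2 * PN)
  S <- rbind(
    M  = c(1, -1,  0,  0,  0,  0,  0,  0,  0,  0),
    P0 = c(0,  0,  1, -1,  1,  0,  0,  0,  0,  0),
    P1 = c(0,  0,  0,  1, -1, -1,  1,  0,  0,  0),
    P2 = c(0,  0,  0,  0,  0,  1, -1, -1, -1,  1),
    PN = c(0,  0,  0,  0,  0,  0,  0,  0,  1, -1))
  drop(S %*% fluxes)
}

random_states <- function(n, seed = 421) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    oscillator_state(M = runif(1, 0, 3), P0 = runif(1, 0, 3),
                     P1 = runif(1, 0, 3), P2 = runif(1, 0, 3),
                     PN = runif(1, 0, 3)))
}

# trajectories reused across several acceptance checks; computed lazily once
acceptance_env <- new.env()

acceptance_traj <- function(key, builder) {
  if (is.null(acceptance_env[[key]])) acceptance_env[[key]] <- builder()
  acceptance_env[[key]]
}
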