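---
title: "Modeling external stimuli acting on circadian clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling external stimuli acting on circadian clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The oscillator

clockstim is built around the classic five-variable negative-feedback
oscillator for the *Drosophila* period gene.  Cytosolic *per* mRNA $M$ is
produced under Hill-type repression by nuclear PER protein $P_N$ and
degraded enzymatically; PER protein is translated ($P_0$), reversibly
phosphorylated twice ($P_0 \leftrightarrow P_1 \leftrightarrow P_2$) by
Michaelis–Menten kinase/phosphatase steps, degraded in its biphosphorylated
form, and shuttled between cytosol and nucleus:

$$
\begin{aligned}
\dot M &= v_s\frac{K_I^n}{K_I^n+P_N^n}-v_m\frac{M}{K_m+M},\qquad
\dot P_0 = k_sM-V_1\frac{P_0}{K_1+P_0}+V_2\frac{P_1}{K_2+P_1},\\
\dot P_1 &= V_1\frac{P_0}{K_1+P_0}-V_2\frac{P_1}{K_2+P_1}
          -V_3\frac{P_1}{K_3+P_1}+V_4\frac{P_2}{K_4+P_2},\\
\dot P_2 &= V_3\frac{P_1}{K_3+P_1}-V_4\frac{P_2}{K_4+P_2}
          -k_1P_2+k_2P_N-v_d\frac{P_2}{K_d+P_2},\qquad
\dot P_N = k_1P_2-k_2P_N.
\end{aligned}
$$

With the reference constants (`core_parameters()`: $v_s=0.76$, $v_m=0.65$,
$K_m=0.5$, $k_s=0.38$, $v_d=0.95$, $k_1=1.9$, $k_2=1.3$, $K_I=1$,
$K_d=0.2$, $n=4$, $K_{1..4}=2$, $V_1=3.2$, $V_2=1.58$, $V_3=5$, $V_4=2.5$;
µM and hours throughout, amounts interpretable as concentrations per cell
volume) and initial state $(0.5,0.5,0.5,0.6,1.5)$, the system settles on a
limit cycle with a free-running period of about 23.7 h.

**Hill-term forms.**  Printed statements of this model family disagree on
whether the numerator (and denominator) of the transcription term uses the
inhibition threshold $K_I$ or the phosphorylation constant $K_1$.  We make
the $K_I$ form the default because it is the only one of the three
candidates that free-runs at 23.7 h with the reference constants — the
calibration anchor for everything else in the package (the $K_1$ form runs
at 33.2 h; the mixed form, numerator $K_1^n$ over denominator
$K_I^n+P_N^n$, does not sustain a comparable rhythm).  `hill_form` in
`core_rhs()` and the config layer switches to the alternatives for audit
purposes.

## External stimuli as bilinear terms

A stimulus is a function $u(t)\ge 0$ entering exactly one equation through
a bilinear control term (`variant_spec()`):

* **mRNA decay** (`mrna_decay`): $-\alpha u M$ on $\dot M$ — a generic
  degradation route (e.g. an miRNA or drug), default $\alpha = 0.05$ in
  the entrainment experiments.
* **Fly light port** (`fly`): $-\alpha u P_0$ on $\dot P_0$ — light
  degrades PER protein, as in *Drosophila* where light-activated CRY
  removes TIM; default $\alpha = 1$.
* **Mammalian light port** (`mammal`): $+\gamma u\,e^{-\varrho M}$ on
  $\dot M$ — light induces *per* transcription; the exponential saturates
  the induction when mRNA is already abundant ($\gamma = 2$,
  $\varrho = 1$ by default).
* **Machinery variant** (`mammal_machinery`): replaces the exponential by
  an explicit two-species transcription-machinery pool $T \to T^*$
  (`machinery_rhs()`), with $T+T^*$ conserved, so the induction
  $+\gamma T^*$ is capacity-limited by mass action instead of by a
  phenomenological exponential.
* A `cooperativity_rhs()` pair $M_1, M_2$ expresses a squared stimulus
  ($u^2 \to M_1M_2$) through bilinear terms only.

Stimulus waveforms (`stim_*()`) cover the periodic light–dark cycle
$u(t)=\cos(2\pi t/\text{period}+\varphi)+1$, its quarter-amplitude version,
constants (constant-light protocols), square pulses (PRC protocols,
half-open $[t_0, t_0+d)$ so abutting pulses never double-count), a
feeding-schedule switch, and a $\ln(1+u)$ transform for stimuli spanning
orders of magnitude of illuminance.  A phase $\varphi$ always corresponds
to a Zeitgeber advance of $\varphi\cdot\text{period}/2\pi$ hours.

## Coupling oscillators

The same interface couples clocks: one oscillator's state variable becomes
another's stimulus.  The three couplings (all injected into the
peripheral $\dot{\tilde P}_0$ by default) are the product decay
$-\tilde\alpha\tilde P_0 P_0$ (locks in antiphase), the gated decay
$-\tilde\alpha\tilde P_0 e^{-\beta P_0}$ (locks in phase), and the
$P_2$-driven product decay $-\alpha^P\tilde P_0 P_2$, whose source lags
$P_0$ and therefore produces intermediate phase relationships.  The
dual-input form appends a food term $-\delta\tilde u\tilde P_0$, so a
peripheral clock integrates the central signal and the feeding schedule at
once.  `stim_tap()` exposes the same mechanism as a stimulus kind:
a fly-port oscillator driven by a tap of the central $P_0$ is algebraically
identical to the product-decay coupling (and the test suite checks this).

**Which central clock drives the canonical networks?**  The published
description of the central/peripheral experiments is ambiguous about
whether the light-sensitive first oscillator carries the protein-decay port
($\alpha=1$) or the mRNA-decay port ($\alpha=0.05$) of the earlier
entrainment experiment.  We resolved it by calibration against the printed
phase lags: with the mRNA-decay central the P0-driven and P2-driven
peripherals lock 12.3 h and 15.7 h behind the central clock
(printed: about 12.7 h and 15.8 h), whereas the protein-decay central
gives 11.7 h and 15.0 h.  `coupled_clock_network()` therefore uses the
mRNA-decay central ($\alpha=0.05$, Zeitgeber phase $\pi$).  The residual
0.3–0.4 h discrepancy on the antiphase lag survives every measurement
window we tried and is reported as-is.

Because this central clock is weakly forced, its entrainment transient
lasts on the order of ten cycles; the bundled network experiments
therefore integrate 360 h and measure over the final 120 h, while
single-oscillator experiments use 100–240 h.

## Measurement procedures

* **Period** (`estimate_period()`): mean spacing of successive local
  maxima of the dense output, each maximum refined by a parabola through
  the three samples around it (ties break toward the earlier time).  The
  canonical window is $t\in[80,120]$ h; when a long period leaves only one
  peak there, the search extends to the first peak beyond the right edge.
  On pure sinusoids with periods 20–30 h the estimator is accurate to
  better than 0.01 h (property test).
* **Phase shift** (`estimate_phase_shift()`): circular mean of
  nearest-peak time differences after a transient cut (default 72 h,
  about three cycles), wrapped to $(-T/2, T/2]$ or $[0,T)$; positive
  means the second trajectory lags.  The periods of the two series must
  agree within `period_tol` (default 0.2 h) — a phase offset between
  rhythms of different periods is not a steady-state quantity.
* **Zeitgeber-phase shifts** (`entrainment_phase_shift()`): the
  displacement induced by a Zeitgeber phase $\varphi$ is measured against
  the *same oscillator entrained with* $\varphi=0$, not against the
  free-running clock: the free-runner's 23.66 h period beats against the
  24 h entrained period by 0.34 h per cycle, so a peak offset against it
  depends on the measurement window and converges to nothing.  Against
  the $\varphi=0$ reference the shifts are steady and come out at
  $\varphi\cdot 24/2\pi$ hours (12 h for $\varphi=\pi$, 6 h for $\pi/2$),
  which is also what "the clock re-synchronizes to the external time"
  means operationally.
* **Arrhythmicity** (`detect_arrhythmia()`): peak-to-trough amplitude in
  the window below 5% (default) of the free-running amplitude.  A caveat
  the constant-light scan makes visible: for strong constant stimuli
  (c at and above roughly 0.8) the limit cycle is in fact gone and the
  trajectory spirals into a fixed point; what the 80–120 h window shows
  there is a slowly decaying transient whose peak spacing is still
  well-defined.  The scan therefore always reports the windowed period
  when two peaks are measurable and carries the amplitude classification
  in a separate status column; at the 5% floor, intensity c = 1 is
  arrhythmic for both organism variants.
* **Constant-light scan** (`scan_constant_light()`): period vs intensity
  with the grid argmin reported as the turning point — the model's account
  of Aschoff's rule: weak constant light shortens the period, stronger
  light lengthens it, and the turning point moves with the effective
  light sensitivity ($\alpha$ or $\gamma$).
* **PRC** (`phase_response_curve()`): one square pulse per run at a given
  circadian time (CT 0 anchored at a post-transient mRNA peak of the
  control), shift measured against the unpulsed control three periods
  after the pulse.  Pulse defaults (1 h, magnitude 1) are exposed
  parameters, not calibrated values.
* **Entrainment range** (`entrainment_range()`): locked iff the observed
  period matches the Zeitgeber period within 0.1 h *and* the peak phase
  drifts less than 0.5 h over the last five cycles.  A finding worth
  stating: at equal stimulus amplitude the $\gamma=2$ mammalian port is
  the *stronger* forcing and locks over a wider grid than the $\alpha=1$
  fly port, so organism-level statements about narrow mammalian
  entrainment ranges require organism-calibrated gains, which are not
  available here.
* **Resynchronization** (`resynchronization_time()`): first time after a
  schedule switch at which the per-cycle peripheral–central peak offset
  drops below 1 h (a declared threshold; the underlying per-cycle offsets
  are returned for inspection).

## Numerical choices

Integration uses the stiff-capable adaptive `lsoda` with `rel_tol = 1e-8`,
`abs_tol = 1e-10` (the Michaelis constants $K_d = 0.2$ µM make the
degradation terms locally stiff; periods are quoted to 0.1 h, which
demands much tighter integration error over 10–15 cycles).  Output is
sampled every 0.05 h and peaks are quadratically refined; the test suite
checks self-convergence under 10× tolerance refinement and that declared
breakpoints (where the integrator restarts to avoid stepping across a
stimulus discontinuity) change trajectories by less than $10^{-6}$ µM.
State positivity is asserted (to $-10^{-9}$), never enforced by clamping.

The ensemble "singularity" demonstration uses five fly-port units with a
deterministic linear coupling spread of ±50% around $\alpha=1$ and one 1 h
pulse of magnitude 2 placed 3 h after a free-running mRNA peak: this
intermediate, critically timed pulse fans the unit phases out and roughly
collapses the summed rhythm to a third of its amplitude, whereas a strong
pulse resets all units to nearly the same phase (type-0 resetting) and a
mistimed one does little.  A homogeneous ensemble stays phase-identical
under any pulse (symmetry test).

## Synthetic fixtures, and what passing tests do not show

`synth_trajectory()` generates sinusoids, damped sinusoids and constants
with known period/amplitude/phase so that every analysis operation is
unit-tested against closed forms without touching the ODE solver.  These
fixtures (and the model itself) are noise-free, strictly periodic and
single-component; real rhythm recordings carry measurement noise,
drifting baselines and mixed periodicities, so passing these tests says
nothing about robustness to such data — spectral estimators and actogram
fitting are deliberately out of scope.

## Known limitations

* The stimulus ports are effective terms: temperature and any agent that
  changes the kinetic constants themselves are outside the framework's
  assumptions (all rate constants are held fixed).
* Alternative oscillator cores (PER/TIM, detailed mammalian, DDE models)
  are not implemented; `integrate_clock()` accepts any RHS, which is the
  plug-in seam where they would go.
* Signal transmission between coupled oscillators is instantaneous; there
  is no signalling-pathway delay and no stochasticity anywhere.
* The 12.7 h published antiphase lag is reproduced only to 0.3–0.4 h
  under every configuration reading and measurement window we examined;
  the neighbouring P2-driven lag (15.8 h) reproduces to 0.1 h.
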