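---
title: "Markov modelling of voltage-dependent HCN2 gating and its cAMP modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov modelling of voltage-dependent HCN2 gating and its cAMP modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcn2kinetics)
```

## The model

HCN2 pacemaker channels open on hyperpolarization and are potentiated by
cAMP. This package models their activation gating as a continuous-time
Markov chain over a small set of channel conformations. The working model
for the cAMP-free channel (`build_model_1n()`) has two rows of three
states, closed C0–C1–C2 and open O0–O1–O2. The two horizontal steps of
each row are voltage-dependent conformational changes of the voltage
sensors; the vertical closed–open isomerizations (C0–O0 and C2–O2) are
voltage independent, reflecting the view that pore opening itself moves no
gating charge. At saturating cAMP (`build_model_1a()`) one additional
non-conducting "buffer" state C1\* hangs off C1, outside the activation
pathway; its slow, voltage-dependent filling and draining produces the
slow activation component seen at moderate hyperpolarization with cAMP.

Each voltage-dependent step carries an effective gating charge $z$
(elementary charges) and follows a single-barrier Eyring law. With the
thermal voltage $V_T = RT/F$ and a charge partition $\pi$ between the two
directions of a step,

$$k_f(V) = k_f^0\, e^{-z \pi V / V_T}, \qquad
  k_b(V) = k_b^0\, e^{+z (1-\pi) V / V_T},$$

so that the step equilibrium $k_f/k_b = (k_f^0/k_b^0)e^{-zV/V_T}$ is
independent of the partition. The sign convention makes hyperpolarization
(negative $V$) accelerate the forward, activating direction. The default
partition is symmetric ($\pi = 0.5$), the canonical single-barrier choice;
it is a per-transition field, so asymmetric barriers can be explored, and
the acceptance checks report how the computed gating-current peaks react
to $\pi \in \{0.4, 0.5, 0.6\}$ (equilibrium quantities do not react at
all). The charge partition affects only kinetics, and the computed peak
gating currents are quite sensitive to it at strong hyperpolarization, so
those outputs should be read as scale estimates rather than sharp
predictions.

State occupancies $p(t)$ evolve by the master equation $dp/dt = pQ(V)$,
with the generator $Q$ rebuilt per voltage from the rate laws
(`generator_matrix()`).

### Constraints

Two constraint kinds reduce the free-parameter count and keep the model
physical (`apply_constraints()`):

* **Microscopic reversibility.** Around the single loop
  C0–C1–C2–O2–O1–O0 the product of clockwise rates must equal the product
  of counter-clockwise rates; the rate O0→C0 (`k6`) is designated as the
  derived one. Because the vertical steps are voltage independent and the
  open row reuses the closed-row charges `z1` and `z2`, the signed step
  charges cancel around the loop and the constraint, imposed at 0 mV,
  holds identically at every voltage. Cycles whose net charge does not
  cancel are rejected outright, since no choice of rates could satisfy
  detailed balance at all voltages.
* **Saturating open probability.** The final closed–open equilibrium is
  pinned by the saturating open probability measured at full activation:
  $k_8 = k_7 (1 - P_{o,sat})/P_{o,sat}$, with $P_{o,sat}$ = 0.71 without
  and 0.99 with cAMP. After constraint application
  $k_7/(k_7+k_8) = P_{o,sat}$ exactly.

With the published parameter tables (`params_1n()`, `params_1a()`) the two
derived rates evaluate to $k_6 = 29.3\,\mathrm{s^{-1}}$,
$k_8 = 1.27\,\mathrm{s^{-1}}$ (no cAMP) and $k_6 = 38.0\,\mathrm{s^{-1}}$,
$k_8 = 4.49\times10^{-2}\,\mathrm{s^{-1}}$ (cAMP):

```{r derived}
m <- catalog_model("1n")
a <- catalog_model("1a")
round(c(k6_n = m$params$values[["k6"]], k8_n = m$params$values[["k8"]],
        k6_a = a$params$values[["k6"]], k8_a = a$params$values[["k8"]]), 4)
```

### Alternative topologies

The catalog also ships two model families used in gating-model
competitions, mainly to exercise the ranking workflow:

* `build_model_mwc(n, f)` — an allosteric model with `n` independent,
  identical voltage sensors (stoichiometric multiplicities on each step, a
  single shared charge) coupled to a concerted closed–open isomerization
  by a constant allosteric factor `f`. The allosteric split is symmetric:
  open-row sensor rates are scaled by $\sqrt f$ forward and $1/\sqrt f$
  backward and the opening rate at sensor level $j$ by $f^{j/2}$, so the
  level-$j$ open equilibrium is $L_0 f^j$ and every rung cycle balances by
  construction. (A full-$f$ split on the rates would square the coupling
  per level, i.e. $L_j = L_0 f^{2j}$; the $\sqrt f$ convention is the one
  under which the saturating open probability approaches
  $L_0 f^n/(1+L_0 f^n)$.) `f` is baked into the scheme's numeric scale
  factors at build time; fitting different couplings means rebuilding the
  scheme, which is cheap.
* `build_model_cd()` — a coupled-dimer model: the four subunits act as two
  identical dimers with resting/activated/flipped status, the channel
  conducting only when both dimers are flipped. Composite states are
  unordered pairs and transitions where either dimer may move carry a
  combinatorial factor 2.

Parameters shipped for these two are illustrative defaults, not fitted
values, and the corresponding files in `inst/extdata/` are labelled
`_synthetic`.

## Simulation

`simulate_protocol()` propagates occupancies through piecewise-constant
voltage protocols. Within a segment the solution is evaluated exactly (to
numerical precision) from the eigendecomposition of $Q^T$, cached per
voltage; when the eigenbasis is ill-conditioned (condition number above
$10^8$, e.g. near-defective generators) the propagator falls back to
scaling-and-squaring matrix exponentials. Segment boundaries are
propagated exactly, so occupancies are continuous and probability is
conserved to better than $10^{-9}$ over tens of seconds. The default
output grid is uniform at 1 ms; `log_dense = TRUE` adds log-spaced samples
after each segment start (from 10 ns), which matters whenever a
trapezoidal integral has to capture a fast post-step transit — OFF-gating
charge at depolarized potentials is the main case, where transit times can
reach microseconds.

The default initial condition is the stationary distribution at the
holding potential (0 mV), and deactivation segments continue directly from
the end-of-activation occupancies rather than refitting an initial vector;
with double-pulse data this is the natural reading of a continuous
recording.

```{r simulate}
pr <- double_pulse(Va = -140, ta = 4, Vd = -40, td = 2)
traj <- simulate_protocol(m$scheme, m$params, pr)
max(abs(rowSums(traj$occupancy) - 1))          # conservation
round(open_probability(traj)[traj$times == 4], 3)  # end of the 4 s pulse
```

## Observables

* `flux_density()` — net probability flux density
  $J = k_f p_{from} - k_b p_{to}$ per reversible transition (s$^{-1}$),
  activation-positive. At −130 mV the activation flux of the cAMP-free
  model runs through C0→C1→C2→O2; the direct C0→O0 route is negligible
  because the open-row activation rates are tiny.
* `gating_current()` — per-channel gating current
  $I_g(t) = e \sum_x z_x J_x(t)$ (amperes) and its running integral in
  elementary charges. The sign convention is activation-positive; only
  magnitudes are physically meaningful. For a saturating pulse the
  integral approaches the summed charge actually moved: 8.10 $e$ without
  cAMP and 5.12 $e$ with cAMP (z1+z2; the C1–C1\* contribution is minor
  and can be excluded with `exclude_charges = "zc"`).
* `steady_state_activation()` / `boltzmann_fit()` — voltage dependence of
  the open probability at the end of finite pulses or at true steady
  state, and a weighted fit of
  $P_o(V) = A/(1+\exp(z_B(V-V_h)/V_T))$. The slope-charge form was chosen
  because it reproduces the measured slope scale ($z_B \approx 5$); fits
  start from a midpoint interpolation and run Levenberg–Marquardt with
  loose bounds. Finite-pulse curves approach the steady-state curve from
  below; 1 and 4 s pulses fall well short of it and 15 s pulses come
  close, which is why pulse-limited activation curves underestimate the
  true equilibrium midpoint.

```{r boltzmann}
curve <- steady_state_activation(m$scheme, m$params,
                                 seq(-160, -60, by = 5), t_pulse = 4)
bf <- boltzmann_fit(curve, VT = m$params$VT)
round(c(z = bf$z, Vh = bf$Vh, amplitude = bf$amplitude), 2)
```

Peak detection on gating currents takes the grid maximum with parabolic
refinement through the neighbouring samples and no smoothing; on the
recommended grids (0.5 ms for the slow cAMP-free model, 0.1 ms with cAMP)
the refinement is a sub-percent correction.

## Global fitting

`global_fit()` fits the free parameters of a scheme to all traces of a
`trace_set` simultaneously by weighted least squares: residuals are
divided by the per-point uncertainty, rates are optimized in log space,
charges linearly (bounded [0, 12]), and the derived rates are recomputed
from the constraints for every candidate, never penalized. The optimizer
is multistart Levenberg–Marquardt (start 1 is the supplied initial value;
further starts are seeded log-normal perturbations), deterministic for a
fixed seed. Two figures of merit are reported: the plain residual sum of
squares RSS and the normalized mean square error
$MSE^* = N^{-1}\sum_i (r_i/\sigma_i)^2$, which is $\approx 1$ for a
correct model with honestly declared uncertainties and is the ranking
criterion of `rank_models()` (ties broken by fewer free parameters, then
fewer undetermined ones). Both definitions are isolated in `objective()`
so they can be swapped.

Parameter uncertainties (`parameter_errors()`) are asymptotic: the
Jacobian of the weighted residual vector at the optimum gives
$\mathrm{cov} = s^2 (J^T J)^{-1}$ with $s^2 = RSS_w/(N-p)$, reported as
percent of the parameter value (for log-fitted rates the delta method
makes this 100 × the standard error of the log parameter). A parameter
with se above 60% — or lying in a singular direction of the curvature —
is flagged "n.d." (not determined). On synthetic data from the cAMP-free
model the parameters that get flagged are the open-row activation rates
(`k9`, `k11`, occasionally the barely-used `k5`): the activation pathway
through the open row carries essentially no flux, so those rates are
constrained only weakly (mainly through the reversibility-derived `k6`).

The fitting landscape is genuinely multimodal: distant starts settle in
local minima with clearly worse $MSE^*$, which is why the multistart
launches and the $MSE^*$ scale (≈1 at the global optimum on synthetic
data) are both worth watching. The shipped parameter-recovery experiment
(in the test suite) is a local identifiability and calibration check: ten
27-trace synthetic sets are fitted starting from the generating values,
and determined parameters must land within three reported standard errors
of the truth, with the median relative error of determined rates well
under 20%.

## The synthetic-data generator

`make_protocols()` reproduces the study design: per condition, nine
(activation voltage, duration) pairs crossed with deactivation at −40,
+20 and +80 mV — 27 double-pulse protocols from a 0 mV holding potential.
The published protocol description does not state the deactivation
segment length; the default is 2 s, comfortably longer than the tail
relaxations at these voltages, and configurable.

`generate_traceset()` emulates averaged multi-patch recordings: for each
protocol the clean model curve is simulated at 1 kHz, `n` per-patch
replicates are drawn (`n` uniform in 5–18, as in the study), each the
clean curve times a patch scale factor (Normal with s.d. 0.02, standing
in for expression/rundown variability) plus additive Gaussian noise with
s.d. $a + b\sqrt{P_o(1-P_o)}$ ($a = 0.005$, $b = 0.03$), and the mean and
empirical s.e.m. per point form the trace (s.e.m. floored at $10^{-3}$ to
avoid infinite weights). The noise defaults were chosen once to emulate
the s.e.m. shading of the published trace figures and are documented as
synthetic-only. Two features of real data are deliberately not emulated:
systematic model mismatch (the generator draws from the fitted model
itself) and correlated recording artefacts (leak, series resistance,
rundown trends). Passing recovery tests on these data therefore
demonstrate identifiability and estimator calibration under the model,
not robustness to model error. One measurable consequence of the small
patch counts: with the empirical s.e.m. as weights, $MSE^*$ at the true
parameters sits near 1.3 rather than 1.0, because the reciprocal of a
small-sample variance estimate is biased upward.

An ohmic current layer (`current_from_po()` / `po_from_current()`)
converts between open probabilities and macroscopic currents,
$I = N g (V - V_{rev}) P_o$; it is a simple stand-in for the current
normalization used with real recordings and inverts exactly in the
noise-free case.

## Numerical choices and problem sizes

* Thermal voltage $V_T$ = 25.4 mV (≈22 °C, typical for excised *Xenopus*
  oocyte patches); the recording temperature is not stated in the source
  study, so $V_T$ is a configurable constant of `parameter_set()`.
* The open-row steps reuse the closed-row charges `z1`/`z2`: the printed
  parameter table lists only `z1`, `z2`, `z_c`, and with voltage-
  independent vertical steps the loop can only balance at all voltages if
  the row charges match per step; per-step equality is the minimal
  reading.
* Charge integrals use a 100 s pulse to −160 mV on a 2 ms grid with 400
  additional log-spaced early samples; the integral then agrees with the
  direct net-transit count to ~0.1%.
* Fits in the test suite thin the 1 kHz traces to 50 ms and use single
  starts from the generating values; a full 10-seed recovery experiment
  runs in under a minute. These sizes are the package's own defaults for
  its shipped experiments; the functions accept arbitrary grids.
* Degenerate inputs: reducible generators raise a no-unique-stationary
  error; non-sigmoidal activation curves raise a fit-failure error with
  diagnostics; simulation failures during fitting return a large penalty
  residual and are logged per start.

## Limitations

* The exact rate–voltage equation and charge partition of the original
  analysis are not reproduced in the main text of the source study; the
  symmetric single-barrier form used here reproduces the published
  equilibrium quantities exactly and the published gating-current peaks
  to within a few percent, but the peaks shift noticeably for asymmetric
  partitions.
* The published model-competition error tables cannot be reproduced
  without the original recordings; model ranking is exercised on
  synthetic data only.
* Slow mode shifts, single-channel stochastics, and instrumentation
  effects (filtering, capacitive transients) are out of scope.
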