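# hcn2kinetics

Markov kinetic modelling of voltage-dependent activation gating in HCN2
pacemaker channels, and of its modulation by cAMP.

HCN2 channels open on membrane hyperpolarization and drive rhythmic
electrical activity in heart and brain; cAMP binding speeds and
potentiates their activation. This package is for biophysicists who want
to work with small constrained Markov state models of that gating: build
or load kinetic schemes, simulate open-probability time courses through
voltage-clamp protocols, fit many traces globally, and compute the
derived observables that are not directly measurable — state occupancies,
probability flux densities, per-channel gating currents and moved gating
charge, and true steady-state activation curves.

## The model in brief

The working scheme for the cAMP-free channel has six states in two rows,

```
C0 <-> C1 <-> C2        (closed)
 |             |
O0 <-> O1 <-> O2        (open)
```

with voltage-dependent horizontal steps obeying single-barrier Eyring
laws, k_f(V) = k_f⁰·exp(−zπV/V_T) and k_b(V) = k_b⁰·exp(+z(1−π)V/V_T)
(z the effective gating charge of the step, π the charge partition,
V_T = RT/F), and voltage-independent closed–open isomerizations. Two
constraints are enforced by construction: microscopic reversibility
around the loop (the rate k₆ is derived so that clockwise and
counter-clockwise rate products match at every voltage) and the
saturating open probability (k₈ = k₇(1−P_o,sat)/P_o,sat, with
P_o,sat = 0.71 without and 0.99 with cAMP). The saturating-cAMP scheme
adds one buffer closed state C1* outside the activation pathway. State
occupancies follow the master equation dp/dt = pQ(V); the per-channel
gating current is I_g(t) = e·Σ z_x·J_x(t), where J_x is the net
probability flux density through step x.

## Worked example

```r
library(hcn2kinetics)

m <- catalog_model("1n")             # cAMP-free model, published parameters
round(c(k6 = m$params$values[["k6"]], k8 = m$params$values[["k8"]]), 3)
#>     k6     k8
#> 29.299  1.270
```

The derived rates: k₆ from microscopic reversibility, k₈ from the
saturating open probability. The stationary open probability at strong
hyperpolarization:

```r
ss <- stationary_distribution(m$scheme, m$params, -140)
round(sum(ss[c("O0", "O1", "O2")]), 3)
#> [1] 0.71
```

A saturating pulse from the 0 mV holding potential moves the full gating
charge z₁ + z₂:

```r
round(total_gating_charge(m$scheme, m$params, V = -160), 2)
#> [1] 8.1
```

and the activation curve measured with 4 s pulses has the familiar
Boltzmann shape:

```r
curve <- steady_state_activation(m$scheme, m$params,
                                 seq(-160, -60, by = 5), t_pulse = 4)
bf <- boltzmann_fit(curve, VT = 25.4)
round(c(z = bf$z, Vh = bf$Vh, amp = bf$amplitude), 2)
#>       z      Vh     amp
#>    5.54 -118.80    0.71
```

— a half-activation voltage of −118.8 mV and a slope charge of ~5, i.e.
the midpoint and steepness an experimenter would report from 4 s pulse
measurements, with an amplitude capped at the saturating open
probability.

For fitting, `make_protocols()` builds the 27-protocol double-pulse
catalog per condition, `generate_traceset()` draws synthetic averaged
recordings from a model, and `global_fit()` fits all traces at once with
multistart Levenberg–Marquardt, reporting RSS, the normalized error MSE*,
and per-parameter standard errors with "n.d." flags (se > 60%).
`rank_models()` tabulates competing fits. A thin command-line wrapper
with `synth` / `simulate` / `fit` / `observe` / `rank` subcommands lives
in `inst/cli/hcn2kinetics.R`.

See the vignette (`vignettes/hcn2-gating-kinetics.Rmd`) for the model
assumptions, constraint handling, numerical choices and limitations.

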