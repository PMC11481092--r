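---
title: "Methods: the virtual rig, the BOAEI optimizer and the green metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the virtual rig, the BOAEI optimizer and the green metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`flowbo` packages three things: a calibrated virtual flow rig for the
two-step synthesis of acetaminophen (paracetamol), a closed-loop Bayesian
optimizer with an adaptive expected-improvement acquisition (BOAEI), and
mass-flow/green-metrics accounting for comparing one-step-at-a-time (OSAT)
optimization against fully telescoped optimization. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
package's tests do and do not demonstrate about real laboratory systems.

## The chemistry being emulated

Step one is a three-phase packed-bed hydrogenation of 4-nitrophenol (**1**)
to 4-aminophenol (**2**) over a solid catalyst with hydrogen at 7 bar. Step
two is a homogeneous amidation of **2** by acetic anhydride (**3**) to
acetaminophen (**4**) in a heated coil, with two side reactions: hydrolysis
of the anhydride by water carried in the (non-anhydrous) 2-MeTHF solvent,
and slow double acylation of the product to 4′-acetoxyacetanilide (**5**).
In the telescoped configuration the bed outlet passes an ideal gas–liquid
separator (the liquid phase is unchanged) and merges with the anhydride
stream before the coil.

## The virtual rig

The rig is an *emulator*, not a mechanistic model: the simplest rate laws
that reproduce every qualitative behaviour of the real system, calibrated so
its in-bounds optima equal the reported campaign optima.

**Step one.** With hydrogen in excess at constant pressure, conversion is
first order in substrate:

$$X = 1 - \exp(-k_\mathrm{eff}\, a\, \tau_1), \qquad
k_\mathrm{eff} = \frac{A_1 m_\mathrm{cat} e^{-E_{a,1}/RT_1}}{1 + K_\mathrm{inh} C_1},$$

where $a$ is the fractional catalyst activity and $\tau_1$ the bed residence
time (void volume / flow). The weak inhibition term $K_\mathrm{inh} = 2$
L mol$^{-1}$ makes feed concentration the least influential variable
(a 5-point yield swing across its bounds versus > 50 points for temperature
and flow), matching the observed ranking. $E_{a,1} = 45$ kJ mol$^{-1}$ is a
typical nitroarene-hydrogenation value.

**Step two.** A plug-flow ODE system over residence time $\tau_2$:
amidation $2 + 3 \to 4$ (rate constant $k_2$), hydrolysis
$3 + \mathrm{H_2O} \to 2\,\mathrm{AcOH}$ (constant $k_h$), double acylation
$4 + 3 \to 5$ ($k_{da}$), with **1** inert (a control in the underlying
study found unreacted nitrophenol has no effect on the amidation, and the
rig reproduces this exactly). The amidation is deliberately *fast* across
the whole coil-temperature range ($A_2 = 2\times10^5$ L mol$^{-1}$
min$^{-1}$, $E_{a,2} = 20$ kJ mol$^{-1}$): the yield is then governed by
the anhydride budget (equivalents) and its competition with hydrolysis
rather than by reaction completion. This is the design choice that makes
anhydride equivalents the dominant variable and the coil temperature the
weakest one, which is the importance ordering the optimizer should
discover; a slow amidation would instead make temperature dominate through
reaction completion. $k_{da} = 0.01$ keeps the byproduct below 0.5% of the
phenolic core anywhere in bounds, so the double acylation exists in the
model but never within the optimization window.

**Calibration.** Three free knobs are fitted by `calibrate_rig()` and
frozen in the shipped `"paper"` preset:

* $A_1$ — closed form at the step-1 bound corner (the model is monotone in
  all three variables, so the in-bounds maximum sits at max $T_1$, min
  $Q_1$, min $C_1$), pinned to 65% conversion;
* $k_h$ — 1-D root find pinning the step-2 maximum on the
  intermediate-mixture feed (65:35 **2**:**1**) to 97% consumption of **2**;
* the anhydride stock concentration — 1-D root find pinning the telescoped
  in-bounds maximum (evaluated on a grid over flow and flow ratio at the
  temperature corner) to 85% overall yield.

Each returned configuration is verified by a full grid search to ±0.5
percentage points. The residuals of the shipped preset are ~10⁻¹⁰.

**Catalyst deactivation.** Activity decays as $e^{-k_\mathrm{slow} t}$ with
$k_\mathrm{slow} = \ln(1/0.96)/28$ h$^{-1}$, i.e. 4% lost over 28 h of
continuous operation — comfortably inside the <5% band a monitored campaign
should tolerate. An abrupt failure event (30% activity loss) can be
scheduled by experiment index (off by default); each shutdown/restart
recovers 5% (relative). Every experiment, of any kind, consumes 2 h of rig
time, so an 18-experiment campaign with its monitoring runs spans roughly
40 h.

**Measurement.** HPLC yields receive additive Gaussian noise
(`sigma_abs = 0.01` by default, i.e. 1 yield point) and are clipped to
[0, 1]. With probability `p_fault = 0.02` a failed gas–liquid separation
produces a blank chromatogram (both yields under 2%).

**Units.** Temperatures are entered in °C and converted to kelvin only
inside the rate laws; yields are fractions internally and percentages in
reports; flows are mL min$^{-1}$ and residence times minutes.

## Design spaces and initialization

The shipped presets are: step 1 — $T_1 \in [60, 150]$ °C, $Q_1 \in [0.1,
1.0]$ mL min$^{-1}$, $C_1 \in [0.025, 0.10]$ mol L$^{-1}$; step 2 — $T_2
\in [30, 100]$ °C, $\tau_2 \in [0.5, 5]$ min, equivalents $\in [1, 3]$;
telescoped — $T_1, T_2, Q_1$ as above plus the substrate-to-anhydride pump
ratio $Q_1{:}Q_3 \in [2, 10]$. The numeric bounds are package assumptions
(the original rig's bound values are not available in text form); they are
chosen so the reported optima are reachable: high $T_1$, equivalents above
2 at the low-ratio end, $\tau_2 \approx 1$ min feasible, 100 °C reachable.
Under the shipped convention the anhydride flow is $Q_3 = Q_1/\mathrm{ratio}$,
so *low* ratio means *high* equivalents; the calibrated optimum sits at the
high-equivalents bound (ratio = 2), preserving the substantive finding that
the optimum lies where equivalents are largest.

Campaigns start from a seeded random-permutation Latin hypercube with
$2n+1$ points (7 for three variables, 9 for four): one point per
equal-width stratum per dimension, jittered within its stratum, with no
space-filling optimization. Bed void volume is 0.5 mL per 0.9 g catalyst,
scaled linearly (so the 1.5 g telescoped bed has 0.833 mL), keeping step-1
residence times in the 0.5–8 min range.

## The surrogate

A Gaussian process with a Matérn-5/2 ARD kernel on unit-scaled inputs,
objective standardized to zero mean and unit variance. Hyperparameters
(amplitude, per-variable length scales in [0.01, 100], noise variance
floored at 10⁻⁸) maximize the log marginal likelihood with one default
start plus five seeded log-uniform restarts of L-BFGS-B. Small campaigns
(7–30 points) need exactly this kind of regularized, reproducible fit; the
noise variance is fitted rather than fixed because the measurement noise of
a real rig is not known a priori. Cholesky factorizations receive escalating
jitter up to 10⁻⁶ before declaring the design degenerate.

Variable importance is read directly from the ARD length scales: the
smaller the length scale, the faster the objective varies along that
variable, the more important it is. Length scales within 5% of each other
are reported as tied. One caveat applies to post-campaign importance: a
heavily exploited campaign leaves little spread along the variables it
pinned early, and the corresponding length scales can run away to the
upper search bound (maximum likelihood correctly reports "no information
along this axis"). A length scale at the bound should be read as
*unidentified*, not unimportant; rankings computed from space-filling data
do not have this failure mode.

## The BOAEI loop

Each refinement iteration fits the surrogate on all accepted optimization
experiments (never on monitoring or rejected records — asserted in the
tests), then maximizes expected improvement

$$\mathrm{EI}(x) = (\mu(x) - y^* - \xi)\,\Phi(z) + \sigma(x)\,\phi(z),
\qquad z = \frac{\mu(x) - y^* - \xi}{\sigma(x)}$$

over the unit cube with 64 seeded local searches (32 uniform starts, 32
perturbations of the incumbent, sd 0.1), ties broken by smallest
lexicographic order and a flat acquisition falling back to the maximum-sd
point. The exploration offset $\xi$ (standardized units) adapts
geometrically: ×0.7 after an improving experiment, ×1.15 after a
stagnating one, clipped to [0.005, 0.15], starting at 0.05. The named
BOAEI method defines only the *behaviour* (a dynamically shifting
exploration–exploitation ratio); this concrete adaptation law is the
package's own documented stand-in. The up-multiplier is deliberately mild:
near a noisy optimum genuine improvements become rare, so a steep
stagnation multiplier (an early candidate was 1.5 with a 0.5 cap)
saturates $\xi$ within about five experiments and sends proposals to
far-corner regions the surrogate has already confidently ruled out — the
opposite of the exploit-after-initialization behaviour a tight
experimental budget needs. With ×1.15 the exploration pressure grows on
the timescale of a whole campaign instead.

**Termination.** The campaign never stops during the LHS. It stops when
(a) five consecutive refinement experiments fail to improve the best yield
by more than 0.005, (b) optionally, the maximum posterior sd over a
1024-point sample drops below a user threshold (off by default, mirroring
manual termination), or (c) the budget (default 25 OSAT / 18 telescoped
optimization experiments) is spent. The plateau window counts *refinement*
experiments only: counting the LHS tail would end roughly half of all
campaigns at the design stage purely by the luck of where the LHS placed
its best point.

**Monitoring and anomaly rejection.** After every fourth optimization
experiment the rig runs a fixed standard condition (bound midpoints);
these records track catalyst health but never train the surrogate. A
measurement below 2% yield is treated as a failed separation when the
operator would expect more (during the LHS, any such reading; later, a
model prediction above 10%): the record is marked rejected and the same
conditions are repeated, at most twice, after which the reading is
accepted as genuinely low. During the initialization phase, before a model
exists, only a visibly blank chromatogram triggers rejection — a
separation failure shows no peaks at all, while a genuinely unreactive
condition still shows the substrate peak, so the two are distinguishable
at the instrument. `experiments_to_optimum` is the smallest
optimization-experiment index whose measured yield is within 1 point of
the campaign's final best — the study's closeness convention.

## Green metrics

`mass_flows()` converts steady-state rig state into a material breakdown:
solvent mass is liquid feed mass (flow × 0.854 g mL$^{-1}$) minus dissolved
solutes, solutes follow from stock concentrations and molar masses
(139.11, 109.13, 102.09, 151.16 g mol$^{-1}$ for **1**–**4**), hydrogen is
the preset gas feed (0.02 g h$^{-1}$, stoichiometric plus excess, kept
under 1% of total mass so solvent dominates as in any dilute flow process).
PMI is total input mass rate over product mass rate; the 20%-solvent
scenario counts only a fifth of the solvent as consumed, the best-case
recycling assumption. The OSAT-combined entry chains the two steps at
their separately found optima: step-1 feed streams plus the anhydride dosed
at the step-2 optimum equivalents, with the product taken from running the
step-1 outlet through step two.

The absolute mass-flow scale of the published comparison table cannot be
reproduced by the shipped presets — it depends on reactor volumes and stock
concentrations that are not available in text form — so desk re-analysis of
the printed rows goes through `breakdown_from_totals()` (total mass rate,
product rate, solvent percentage), and tolerances there are ±3% because the
printed solvent percentages are rounded to integers.

## Problem sizes and numerical choices

* Amidation ODEs: `deSolve::lsoda` with a compiled C right-hand side,
  `atol = 1e-9`, `rtol = 1e-7`; verified against a 10×-finer fixed-step RK4
  reference to 10⁻⁵ and against the closed-form second-order solution when
  the side reactions are switched off.
* Grid searches: 41 points per dimension for the closed-form step-1 model,
  21 per dimension for the ODE-based step-2 (21³) and telescoped (21⁴)
  maxima. The calibrated maxima sit at bound corners, which every grid
  contains, so these resolutions determine runtime, not accuracy.
* Efficiency studies: 20 telescoped campaigns (seeds 1–20) and 10–20 OSAT
  studies at 1% measurement noise with faults disabled.
* All randomness flows through derived seeds (one stream per campaign,
  design, fit and proposal), so campaign logs are byte-identical across
  runs with the same seed.

## What the tests do and do not show

The virtual rig reproduces the *qualitative structure* of the real system —
monotone step-1 response, equivalents-dominated step-2 yield, weak coil
temperature influence, slow catalyst decay with abrupt failure and shutdown
recovery, blank-sample faults — and is calibrated to the reported optima.
Passing tests therefore show that the optimizer and metrics pipeline work
on a system *of this structure at this noise level*. They do not validate
the rate laws against laboratory kinetics: dispersion, gas–liquid mass
transfer, separator physics, solvent oxidation of the aminophenol, and
hydrogen partial-pressure effects are all outside the model, and the
kinetic constants are calibration artifacts, not measured quantities.
Likewise the experiment counts measure performance on the emulator's
response surface; a real surface with the same optima but different
curvature could need more experiments.
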