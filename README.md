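# flowbo

Closed-loop Bayesian self-optimization of a telescoped two-step flow
synthesis, on a calibrated virtual rig.

## The problem

Multistep flow syntheses are usually optimized one step at a time (OSAT):
each reaction gets its own campaign, and the separately found optima are
chained. Optimizing all steps *simultaneously* in the telescoped
configuration can reach a better joint optimum in fewer total experiments —
but closed-loop optimization of a three-phase system (solid catalyst,
hydrogen gas, liquid stream) has to cope with catalyst deactivation,
measurement faults and tight experimental budgets. `flowbo` packages the
complete computational side of such a study for the two-step synthesis of
acetaminophen (4-nitrophenol → 4-aminophenol → acetaminophen):

* **a virtual rig** (`simulate_step1()`, `simulate_step2()`,
  `simulate_telescoped()`): first-order packed-bed hydrogenation with weak
  feed-concentration inhibition; plug-flow amidation with competing
  anhydride hydrolysis and trace double acylation, integrated with
  `deSolve`; slow catalyst deactivation with abrupt failure and shutdown
  recovery; HPLC-like measurement noise with blank-sample faults. The
  kinetics are calibrated (`calibrate_rig()`) so the noise-free in-bounds
  maxima are 65% (step 1), 97% (step 2 on the intermediate mixture) and
  85% (telescoped overall);
* **a Bayesian optimizer** (`run_campaign()`, `run_osat()`): Latin
  hypercube initialization with 2n+1 points, a Matérn-5/2 ARD Gaussian
  process fitted by seeded multistart maximum likelihood, an adaptive
  expected-improvement acquisition whose exploration offset shrinks on
  improvement and grows on stagnation, plateau termination, scheduled
  catalyst-monitoring runs (excluded from training) and anomaly rejection;
* **green metrics** (`mass_flows()`, `pmi()`, `pmi_solvent_scenario()`,
  `throughput()`, `comparison_report()`): process mass intensity
  PMI = total input mass rate / product mass rate, its 20%-solvent-retained
  recycling scenario, and the OSAT-versus-telescoped comparison table.

The core acquisition is standard expected improvement with an offset ξ,

EI(x) = (μ(x) − y\* − ξ) Φ(z) + σ(x) φ(z),  z = (μ(x) − y\* − ξ)/σ(x),

with ξ walked geometrically (×0.7 on improvement, ×1.5 on stagnation,
clipped to [0.005, 0.5]). Variable importance is read from the ARD kernel
length scales: smaller length scale = more important variable.

## Worked example

```r
library(flowbo)

# one telescoped campaign at 1% measurement noise
cp <- run_campaign("telescoped", noise = noise_model(0.01, 0),
                   config = campaign_config(budget = 18), seed = 3)
cp
#> BOAEI campaign (telescoped): 18 optimization experiments, best yield 83.4%
#>   reached within 1 point of the final best after 12 experiments (budget termination)

cp$importance
#>   variable length_scale rank  tied
#> 1    ratio    0.6930714    1 FALSE
#> 2       Q1    0.7442718    2 FALSE
#> 3       T1    1.0178373    3 FALSE
#> 4       T2    2.5278190    4 FALSE
```

The campaign finds 83.4% of the rig's 85% true optimum, needs 12
optimization experiments (9 LHS + 3 refinement) to get within one point of
its final best, and correctly identifies the coil temperature (`T2`,
largest length scale) as the least important variable — the
substrate:anhydride flow ratio and the liquid flow, which control
equivalents and residence time, matter most.

Green metrics from the printed comparison-table rows:

```r
bd <- breakdown_from_totals(total_rate = 44.8, product_rate = 0.190,
                            solvent_pct = 95)
pmi(bd)                   # 235.8  — every gram of product costs ~236 g of input
pmi_solvent_scenario(bd)  # 56.6   — if 80% of the solvent is recycled
throughput(bd, 40)        # 7.6 g  — product over a 40 h run
```

The full study (four campaigns, comparison table, importance summary):

```r
bundle <- run_study(validate_config(list(seed = 1)))
bundle$comparison
```

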