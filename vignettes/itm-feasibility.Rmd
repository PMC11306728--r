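---
title: "Modelling intra-target microdosing feasibility with itmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intra-target microdosing feasibility with itmsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

A regulatory microdose — at most 1/100 of the pharmacologically active dose
and at most 100 µg — is by design too small to produce a therapeutic effect
when given systemically. Intra-target microdosing (ITM) administers that same
microdose directly into the interstitial space (or feeding artery) of the
target tissue, hoping that the locally concentrated exposure engages the
target at therapeutic levels and so yields very early human evidence of
target engagement. `itmsim` asks, in silico: *for what kinds of compounds and
target tissues does that hope hold?*

The unit of analysis is a virtual compound: a vector of pharmacokinetic and
binding parameters drawn from distributions calibrated to marketed small
molecules. For each compound the package finds the estimated therapeutic IV
dose, derives the legal microdose, simulates intra-target administration, and
declares "ITM success" if the 24-hour average receptor occupancy (RO) meets
the same criterion the therapeutic dose was required to meet. Monte Carlo
aggregation over thousands of compounds then gives success probabilities and
their sensitivities.

```{r setup}
library(itmsim)
```

## The PBPK–RO model

The disposition model (`simulate_pbpk()`) has nine state variables, all molar
amounts (µmol):

* a well-mixed **blood** pool receiving all venous returns and carrying renal
  elimination `CLr · Cb`;
* three flow-limited tissues — **adipose, muscle, skin** — with
  `dA_i/dt = Q_i (Cb − C_i/Kp_i)`;
* a **liver** split into a perfused extracellular space (volume `Vhe`) and an
  intracellular space (`Vh − Vhe`). Uptake into hepatocytes is saturable plus
  passive, `Vmax·Cu/(Km + Cu) + PS·Cu`, driven by the *unbound* extracellular
  concentration `Cu = fub·A_ec/Vhe`; passive backflux is `PS·C_ic`
  (intracellular unbound fraction 1); metabolism is Michaelis–Menten in
  `C_ic`;
* a **target tissue** with the same extracellular/intracellular structure
  (volumes `Vt`, `Vt_ic`, flow `Qt`, its own uptake/permeability/metabolism
  parameters), plus second-order receptor binding in the intracellular space:

  `dRC/dt = kon · C_free · (X_TotalR − RC) − koff · RC`, with `kon = koff/Kd`.

Receptor occupancy is `RO(t) = RC(t)/X_TotalR`, and the decision statistic is
its trapezoidal average over the 24 h following the dose.

Three genuinely open structural choices were settled as follows:

* **Receptor location.** The receptor sits in the target *intracellular*
  space by default — consistent with modelling active target uptake and
  intracellular target metabolism, which would be pointless if the receptor
  faced the interstitium. Because the alternative is defensible for cell-
  surface targets, `receptor_site = "extracellular"` is available everywhere
  (binding then draws on the unbound extracellular concentration).
* **Driving concentration for target uptake.** Saturable uptake uses the
  *unbound* extracellular concentration, matching the hepatic convention.
* **Occupancy evaluation window.** The criterion is evaluated over the 24 h
  after a *single* dose (window `c(0, 24)`), not at steady state of repeated
  dosing. A single-dose window is what an actual phase-0 ITM study would
  observe, and it keeps the IV and ITM arms symmetric. For compounds with
  half-lives short relative to 24 h the two conventions nearly coincide; for
  very persistent compounds the single-dose criterion is the stricter one on
  the IV side (it inflates the estimated therapeutic dose slightly, and with
  it the microdose), a conservative direction for ITM success.

The physiology (`itm_physiology()`) is a fixed 75 kg reference subject;
tissue volumes and flows scale linearly with weight. The target tissue is
deliberately small and poorly perfused — a 5 mL organ (half extracellular,
half intracellular) receiving 0.686 mL/min per 5 mL, values typical of PBPK
models of solid tumours. Blood volume (needed to convert the blood amount to
concentration) uses the reference-human 79 mL/kg. There is no rest-of-body
compartment: the five explicit tissues are the model's whole disposition
space, so the effective distribution volume of a compound comes from its
`Kp` values and binding.

```{r physiology}
itm_physiology()
```

## Numerical choices

The system is stiff: association rates `kon·C·R_free` can exceed 10^3 h^-1
while terminal elimination proceeds over tens of hours. Integration uses
`lsoda` (automatic stiff/non-stiff switching) with `rtol = 1e-8` and
`atol = 1e-12` µmol, on a 0.05 h output grid; boluses are instantaneous
amount jumps in the dosed compartment (events, never forcing spikes), and
doses at `t = 0` are folded into the initial state. The right-hand side is
implemented twice — once in R as the readable reference
(`pbpk_derivatives()`) and once in C for the solver — and the test suite
holds the two trajectories identical. Solver failures are caught and
returned as flagged objects; the study layer counts them separately and
excludes them from denominators rather than aborting a 2,000-compound run.

Three analytic reductions anchor the integrator in the tests: mass
conservation with all elimination off (drift < 10·rtol over 240 h), collapse
to one-compartment IV kinetics when all tissue exchange is removed (matches
`D·exp(−CLr·t/Vb)` to 0.1 %), and the linear-regime infusion steady state
`Cb = rate/CL_total` (2 %).

## Virtual compounds

`sample_compounds()` draws each kinetic parameter from a log-normal
distribution specified by its interquartile range (`lognormal_from_iqr()`
inverts the IQR: median `sqrt(q25·q75)`, log-sd `log(q75/median)/0.67449`).
The configured ranges put hepatic uptake `Vmax` between 10 and 1000 µmol/h,
metabolism between 25 and 2500 µmol/h, Kd between 0.3 and 6 nM, koff between
0.25 and 4 h^-1 and receptor abundance between 0.001 and 0.1 µmol at the
quartiles — drug-like, high-affinity chemistry against a solid-tissue
target.

Three quantities are sampled jointly on the log scale: the protein-binding
ratio `B` (which sets `fub = 1/(1+B)`), renal clearance `CLr`, and the
distribution volume `Vss` from which the partition-coefficient scaling is
derived as `Kp_scaling = (Vss − Vb)/(0.1·Va + 0.2·Vm + 0.5·Vs)`, floored at
0.01 so that a sampled `Vss` below blood volume cannot produce non-positive
partition coefficients. The published correlation structure for this triple
is not reproduced here; the package ships a documented approximation —
`B`: median 1, `sigma_log` 1.5 (median `fub` 0.5); `CLr`: median 3 L/h,
`sigma_log` 1.5; `Vss`: median 50 L, `sigma_log` 1.0; zero pairwise
correlations — and every piece of it is overridable through the generation
config (YAML-serialisable, `read_generation_config()`). Populations intended
for quantitative comparison with marketed-drug property lists should be
validated with `ecdf_compare()` against user-supplied reference CSVs; those
reference compilations are not bundled.

Target-tissue uptake and metabolism draws are independent of the hepatic
draws (their printed ranges already encode the "1/5 of hepatic activity,
scaled to organ size" reasoning); coupling them is a config change, not a
code change.

Each parameter draws from its own named RNG substream derived from the base
seed, so extending the config never perturbs existing draws, and populations
are reproducible bit-for-bit from `(seed, config)`.

What the generator does *not* emulate: structural correlations beyond the
(B, CLr, Vss) triple, any relation between affinity and clearance chemistry,
inter-individual physiological variability (all subjects are the 75 kg
reference), or oral absorption. Passing tests therefore certify the method
under these study conditions, not the marketed-compound universe.

## The per-compound trial

`evaluate_compound()` chains three steps:

1. **Dose finding** (`find_therapeutic_dose()`): scan a 13-point log grid
   from 1e-4 to 1e5 µmol (sub-µg to multi-gram) for the first IV bolus whose
   24-h average RO reaches the target (default 60 %), then bisect in log
   dose to a 1 % relative tolerance. The upper bracket end is returned, so
   the reported dose always satisfies the criterion; "the dose that achieves
   the target" is thus implemented as *the minimal such dose* at 1 %
   tolerance, which the monotonicity of average RO in dose (a tested
   property) makes well defined. If 1e5 µmol fails, the compound is recorded
   as unachievable.
2. **Microdose** (`compute_microdose()`): `min(dose/100, 100 µg / MW)`; at
   the fixed MW of 400 g/mol the cap equals 0.25 µmol and binds exactly when
   the therapeutic dose exceeds 25 µmol (10 mg).
3. **ITM simulation** (`run_itm()`): the whole microdose enters the target
   extracellular space as a bolus at `t = 0`; success means the 24-h average
   RO meets the same target.

Unachievable and solver-failed compounds are excluded from success-
probability denominators and reported separately (`n_unachievable`,
`n_failed`). Counting unachievable compounds as failures instead would
lower all reported probabilities by the unachievable fraction (about 5 %
of compounds under the default config); the filtered convention was chosen
because a compound with no therapeutic dose has no microdose either — the
ITM question is not posed for it.

## Study-level analyses

`run_study(n, seed)` samples, evaluates and aggregates; probabilities carry
Wilson 95 % intervals (a deliberate addition — at a few thousand compounds
the sampling noise on a probability is a few percentage points and should be
visible). `decile_subgroups()` bins evaluated compounds into ten equal-count
bins by the empirical deciles of a derived quantity (therapeutic dose,
hepatic clearance `CLh`, target clearance `CL_target` — the linear-limit
extended-clearance/well-stirred scalars from `linear_clearances()`, computed
once per compound without extra simulation); ties are broken by stable
`(value, id)` sort. `parameter_sweep()` pins one parameter (`Qt`, `Kd`,
`X_TotalR`) at each of seven fixed values — by default log-spaced over the
sampled 1st–99th percentile range, or 0.01–100× the reference flow for `Qt`
— resampling everything else per value. `ro_threshold_sweep()` re-runs the
entire procedure (dose finding included, since the therapeutic dose depends
on the required occupancy) per threshold on one shared population.

Problem sizes: the package's standard study is 2,000 compounds, and sweeps
use seven values × 300 compounds; both are the scales exercised by the test
suite and the bundled `scripts/acceptance.R`. The per-compound procedure
costs roughly 15–25 stiff solves (~30 ms), so a 2,000-compound study runs in
a couple of minutes on one core; `cores > 1` parallelises over compounds and
is bitwise-identical to serial execution because evaluation is deterministic
given the sampled population.

## A worked example

```{r example}
cmpd <- itm_compound(
  Vmax_uptake = 100, Km_uptake = 1, Vmax_met = 250, Km_met = 10,
  PSdif_inf = 30, Vmax_targetUptake = 0.192, Km_targetUptake = 1,
  PSdiff_target = 0.115, Vmax_targetMet = 0.192, Km_targetMet = 10,
  Kd = 0.00134, koff = 1, X_TotalR = 0.01, fub = 0.5, CLr = 3,
  Kp_scaling = 4, id = "demo"
)
linear_clearances(cmpd)
tr <- evaluate_compound(cmpd)
tr[, c("therapeutic_dose_umol", "microdose_umol", "avg_ro_iv",
       "avg_ro_itm", "itm_success")]
```

This mid-range compound needs a few µmol IV to hold 60 % average occupancy;
its microdose is 1/100 of that, and intra-target delivery gets close to — but
in this case just under — the 60 % bar, illustrating how sharply the outcome
depends on the interplay of local clearance, binding kinetics and the
microdose cap.

```{r study}
st <- run_study(100, seed = 1)
st
decile_subgroups(st$results, "therapeutic_dose_umol")[, c("bin", "lower",
                                                          "upper", "n",
                                                          "probability")]
```

## Known limitations

* The link from receptor occupancy to a measurable biomarker is outside the
  model; occupancy is assumed directly observable.
* The joint distribution of protein binding, renal clearance and volume of
  distribution is an approximation with independent components; conclusions
  that hinge on correlations within that triple should re-run the study with
  a user-supplied correlation matrix.
* One target-tissue geometry (5 mL, low flow) is the default; other targets
  need `Qt_override` or edited physiology.
* Single-bolus regimens only; repeated-dose ITM and infusions are out of
  scope.
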