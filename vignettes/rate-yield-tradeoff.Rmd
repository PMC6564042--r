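---
title: "Modeling the two-dimensional rate-yield tradeoff with a small-scale ME model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the two-dimensional rate-yield tradeoff with a small-scale ME model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssme)
```

## The model

`ssme` implements a small-scale metabolism-and-expression (SSME) model of
aerobic glucose growth. The metabolic network has three catalyzed
pathways and a handful of boundary reactions:

* **respiration** `RES`: glc + 6 O2 -> 6 CO2 + a_res ATP, enzyme `E_res`;
* **fermentation** `FER`: glc -> n_ac acetate + (6 - 2 n_ac) CO2 +
  a_fer ATP, enzyme `E_fer`;
* **biomass synthesis** `BMS`: c_bms glc + GAM ATP -> biomass, enzyme
  `E_bms`, with its flux pinned to the growth rate mu;
* glucose, acetate, O2 and CO2 exchanges, and a fixed ATP drain of NGAM.

Each catalyzed flux is tied to its enzyme mass by an effective turnover
rate, `v_i <= k_eff_i * e_i`, and the enzymes compete for a shared
proteome budget `sum(e_i) <= (1 - UPF) * P_total`, where UPF is the
unmodeled protein fraction — the share of proteome the model does not
account for. This is the ME-model construction in miniature: metabolism
and the cost of expressing its catalysts in one linear system. At fixed
mu every constraint is linear, so phenotypes are linear programs; across
mu the system is nonlinear (mu multiplies both the biomass pinning and
the GAM demand), and the maximum growth rate is located by bisection
over LP feasibility.

The two pathways embody the central tension: respiration extracts more
ATP per glucose (`a_res > a_fer`), fermentation more ATP per unit of
proteome (`a_fer * k_eff_fer > a_res * k_eff_res`). Maximizing yield at
a given mu (equivalently, minimizing glucose uptake) uses respiration
until the proteome budget binds, then mixes in fermentation — hence the
threshold-linear acetate line, and the first (mu-Y) dimension of the
rate-yield tradeoff. The second (q_glc-Y) dimension appears when
anything decouples ATP yield from oxygen use: proton leak, lower-P/O
alternative pathways, or knockouts.

## Equivalence with the coarse-grained allocation model

Dividing the couplings and the budget by `P_total` turns enzyme masses
into proteome fractions: `v_i <= eps_i * phi_i` with proteome efficiency
`eps_i = k_eff_i * P_total`, budget `sum(phi_i) <= 1 - UPF`, and a
biomass-machinery charge `b * mu` with `b = 1 / (k_eff_bms * P_total)`.
That is exactly the coarse-grained proteome-allocation description of
overflow metabolism, so the two parameterizations are related by a
bijection (`coarse_params()` / `coarse_to_ssme()`), and the
yield-maximized phenotypes have a closed form (`analytic_phenotype()`):
below the threshold

mu_t = (A (1-UPF) - NGAM) / (GAM + A b),   A = a_res eps_res,

demand `D = GAM mu + NGAM` is covered by respiration alone
(`J_res = D / a_res`, no acetate); above it the budget also binds and
fermentation grows linearly in mu up to exhaustion at

mu_max = (F (1-UPF) - NGAM) / (GAM + F b),   F = a_fer eps_fer.

The package treats the closed form as an independent oracle for the LP
path: the equivalence (identical mu-Y and mu-q_ac predictions) is
asserted in the test suite at 1e-6 relative tolerance over a 100-point
growth grid, and in practice agrees to ~1e-15. This duality is also used
the other way: the calibration routines evaluate the closed form (fast,
no LP per observation) while the tests pin it to the LP.

## Parameters, units, defaults

Fluxes are mmol gDW^-1 h^-1, enzymes g gDW^-1, `k_eff` mmol per g enzyme
per h; uptake (q_glc) and secretion (q_ac) are both reported positive;
`Y = mu / (M_glc * q_glc)` with `M_glc = 0.180156` g/mmol.

| parameter | default | meaning |
|---|---|---|
| a_res, a_fer | 26, 12 | ATP per glucose through each pathway |
| n_ac | 2 | acetate per glucose fermented |
| o2_per_glc | 6 | O2 per glucose respired |
| P_total | 0.55 g/gDW | total protein fraction of biomass |
| UPF | 0.36 | unmodeled protein fraction |
| GAM | 35 mmol ATP/gDW | growth-associated maintenance |
| NGAM | 1 mmol ATP/gDW/h | non-growth maintenance |
| c_bms | 6.7 mmol glc-eq/gDW | biomass carbon demand (~40 mmol C/gDW over 6 C) |
| k_eff_res, k_eff_fer, k_eff_bms | 4.7, 21.2, 6 | pathway turnover rates |
| atp_per_leak | 0.25 | ATP-equivalents per leaked proton |

The stoichiometric/energetic values are standard-textbook-scale choices;
the turnover rates were chosen once so that the default phenotypes are
biologically sensible — overflow threshold ~0.76 h^-1, maximum growth
~1.14 h^-1, acetate slope ~17.8 — matching the scale of published
wild-type and evolved *E. coli* phenotypes. They are not fitted
constants: the calibration module exists precisely to tune `k_eff_res`,
UPF, GAM and NGAM to data, and every default is config-overridable
(`ssme_set_params()`, YAML round trip via `ssme_write_model()`).

Two modeling choices deserve explanation because the design was open:

* **Where maintenance lives.** GAM is charged as an ATP term of the
  biomass reaction (scaled by mu through the pinned biomass flux) and
  NGAM as a fixed drain, so the ATP mass-balance row *is* the energy
  balance `a_res v_res + a_fer v_fer - GAM mu - NGAM - leaks = 0`.
* **Enzyme synthesis cost.** Rather than explicit translation reactions,
  the biomass pathway's coupling `mu <= k_eff_bms * e_bms` carries the
  growth-proportional machinery cost; its proteome charge `b * mu` is
  exactly the coarse model's dilution term, keeping the equivalence
  exact with three couplings. `k_eff_bms` should therefore be read as
  "growth supported per gram of growth machinery", enzyme dilution
  included.

## Perturbations

`add_proton_leak(model, L)` adds an uncatalyzed reaction draining
`atp_per_leak` ATP-equivalents per unit flux, pinned at L (a bounded
free-leak mode is available but not default, matching the induced-level
design of the leak experiments). The default cost of 0.25 ATP per leaked
proton reflects roughly four protons translocated per ATP by ATP
synthase; it is a config knob, and with it the standard induction levels
0/50/100 mmol gDW^-1 h^-1 remain feasible at mid-range growth. The
P/O proxy reported by `diagnostics()` — ATP from O2-consuming pathways
net of leak, per two electron-pair-equivalents of O2 — falls strictly
with leak; note it is an aggregate analog of the genome-scale ATPS/O2
flux ratio, not the same quantity.

`add_extension(model, kind)` adds one of four classes of metabolically
inefficient reactions, each with its own enzyme: (1) glucose to a
non-acetate byproduct at reduced ATP, (2) glucose to acetate plus
byproduct at reduced ATP, (3) alternative respiration at lower ATP per
glucose (lower effective P/O; this is also the package's abstract stand-in
for redirecting flux between glycolysis and the pentose phosphate
pathway, which the three-pathway model cannot represent mechanistically),
and (4) a futile ATP cycle. Default parameters place each class *off*
the minimum-glucose Pareto frontier spanned by respiration (best ATP per
glucose) and fermentation (best ATP per proteome): an energy pathway
enters the yield-maximized vertex only if it is extremal in that
tradeoff, so a class with `a < a_res` and `eps * a < eps_fer * a_fer`
and a per-ATP proteome cost above the respiration-fermentation chord can
never activate there. `add_extension()` re-verifies this post hoc
against the base curve on a growth-rate grid at 1e-9 and rejects
parameters that would move the optimum. Classes (1) and (3) open
low-acetate solutions at high growth (they supply proteome-cheap ATP
without acetate); classes (2) and (4) open high-acetate solutions at all
growth rates (more acetate per ATP, or a sink for surplus ATP).
`knockout()` zeroes both flux bounds.

## Numerical choices

* LP solving uses the two-phase simplex from the `boot` package at
  tolerance 1e-9; every reported vertex is re-verified against all
  constraints at 1e-8 before acceptance. Degenerate optima are resolved
  by reporting the solver's vertex; only objective values are asserted
  unique, never flux vectors.
* `max_growth()` brackets `[0, mu_hi]` with geometric expansion and
  bisects to 1e-6 h^-1.
* Growth grids stop at `mu_max - 1e-6` and the default contour grid is
  pulled ~1e-7 of its span inside the feasible uptake range: pinning a
  flux exactly at its optimum leaves a fully degenerate LP on which the
  simplex can fail, and the boundary point carries no extra information.
* Infeasible grid points are carried in outputs with an explicit status
  rather than dropped, so envelope/contour boundaries remain plottable.
* The hinge fit in `extract_acetate_line()` scans 201 candidate
  thresholds (closed-form slope for each) and refines the best cell with
  `optimize()`; noiseless hinge data are recovered exactly.
* `fit_global_params()` runs three coordinate-descent sweeps (1-D
  minimizations of the full loss in the order k_eff_res, UPF, GAM, NGAM,
  mirroring which curve feature each parameter controls) and then a
  joint Nelder-Mead polish on a transformed unconstrained scale (logit
  for UPF, log otherwise), restarted once, relative tolerance 1e-14.
  Weights are inverse squared replicate SDs with a variance floor at the
  median positive SD per variable — multiplicative noise gives zero SD
  to exact-zero acetate records below the threshold, and unfloored
  inverse-variance weights would degenerate there. Without SDs, unit
  weights with a dynamic-range rescaling between acetate and yield are
  used. The fit is deterministic given data and options.

## The synthetic generator

`synth_config()` / `generate_phenotypes()` emulate the structure of the
measured phenotype tables the analysis consumes: a wild-type point, a
low-growth chemostat series whose yield rise is NGAM-driven, an uptake
titration lying on the yield-maximized curve across the acetate
threshold, and ALE-like endpoint strains with near-constant mu (band
0.95-1.10 h^-1) and widely varying uptake along a linear q_glc-q_ac
edge whose defaults span acetate 3.9-11.4 mmol gDW^-1 h^-1 — values
chosen to echo published ranges, documented as illustrative. Noise is
multiplicative Gaussian with per-variable CV (rates span an order of
magnitude, so relative replicate error is the natural model), applied to
mu, q_glc and q_ac, with duplicate-SD columns populated from the same
CV. Generation is deterministic given the config (seed mandatory) and
leaves the caller's RNG stream untouched.

What passing tests on these data do **not** show about real data: the
generator has no systematic measurement bias, no strain-specific
parameter heterogeneity (all model-based presets share one global
parameter set), no correlation between replicate errors of different
variables, and the ALE preset is a geometric construction, not a
simulation of adaptive evolution. Calibration results on synthetic data
bound what the method can do when the model family is correct; on real
tables the residuals additionally absorb model misspecification.

## Problem sizes and recovery accuracy

The test suite and the acceptance script use 40-100 point growth grids,
20-point titration/chemostat datasets at 2% CV, and 50 seeded
replicates for parameter recovery — sizes at which every stage is exact
or statistically stable while the whole suite runs in well under a
minute. Under those conditions k_eff_res, UPF and GAM recover with
median relative errors of a few percent. NGAM is the hard parameter: it
is identified almost entirely by the low-growth yield rise, and a
Cramér-Rao computation at the truth under the same design puts its
median relative error near 0.11 (it is strongly anti-correlated with
GAM, r ~ -0.66). The estimator reaches a loss below the loss at the true
parameters, i.e. it is at the weighted-least-squares optimum; NGAM
recovery at this noise level is information-limited, not
algorithm-limited, and tightening it requires more (or lower-growth)
chemostat observations, not a better fit.

## Known limitations

* Three pathways cannot resolve pathway-level mechanisms (specific
  electron-transport-chain choices, glycolysis/PPP split); extensions
  represent such alternatives only as abstract efficiency classes.
* The proteome budget is static; growth-rate-dependent unmodeled
  fractions or crowding constraints are out of scope.
* All kinetics are linear couplings (no saturation, no regulation); the
  model describes feasible allocation, and optimal vertices of it, not
  dynamics.
* The P/O proxy aggregates over all O2-consuming pathways and is not
  comparable in absolute value to genome-scale flux-ratio definitions.
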