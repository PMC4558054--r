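---
title: "Dynamic metabolic modelling of CHO cultures: model, calibration and flux analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic metabolic modelling of CHO cultures: model, calibration and flux analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`choflux` implements a single-parameter-set dynamic kinetic model of
monoclonal-antibody producing CHO cells, together with the analysis pipeline
that such a model supports: batch and fed-batch bioreactor simulation, Morris
elementary-effects screening, weighted least-squares calibration with
linearized confidence intervals, and dynamic metabolic flux analysis (dMFA).
This vignette is the package's account of the science: the model and its
assumptions, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The model

The cell is described by per-cell kinetic fluxes over a metabolic network
covering glycolysis, the TCA cycle, the pentose phosphate pathway, amino acid
metabolism (glutaminolysis, the alanine/aspartate transaminases, serine
deamination, lumped conversion of five amino acids toward the TCA cycle and
of histidine/arginine to alpha-ketoglutarate), oxidative phosphorylation,
an ATPase drain, a proton leak and adenylate kinase, plus growth and mAb
synthesis as stoichiometric drains on precursor pools. Isoleucine and leucine
are carried as a single pooled species (their chromatographic peaks are not
separable), so `ILE` in the model means ILE+LEU.

Every reaction rate is a product:

$$v = V_{max} \cdot \prod_j \frac{S_j}{S_j + K_{m,j}} \cdot \prod_l f_l$$

with one Michaelis-Menten saturation term per substrate and a regulation
factor per allosteric interaction. Energetic cofactors enter through pool
ratios (AMP/ATP, ATP/ADP, NADH/NAD, NADP/NADPH and inverses) rather than
absolute amounts, saturating as $r/(r+K)$. Non-competitive inhibition
contributes the factor $1/(1+I/K_d)$; non-essential activation replaces the
leading substrate term with

$$\frac{S\,(1+\beta A/\alpha K_a)}{K_s(1+A/K_a) + S(1+A/\alpha K_a)},$$

which reduces to plain saturation at $A=0$ or $\alpha=\beta=1$ and
accelerates the reaction when $\beta > 1$. The regulation wiring follows the
biology of glycolytic control: hexokinase is feedback-inhibited by
glucose-6-phosphate and activated (with PFK and LDH, sharing one constant
set) by the AMP/ATP ratio; phosphoglucose isomerase is inhibited by PEP; PFK
is additionally inhibited by intracellular citrate and extracellular lactate;
pyruvate kinase is activated by fructose-6-phosphate and inhibited by
alanine; the reverse LDH is inhibited by pyruvate; the reverse alanine
transaminase is inhibited by glutamine, which encodes the switch from
alanine production to consumption at glutamine depletion. Reversible enzymes
(PGI, LDH, glutaminase/glutamine synthetase, glutamate dehydrogenase,
glutamate transport, adenylate kinase, alanine transaminase) are represented
as paired irreversible reactions with separate forward and reverse maximal
rates; the aspartate transaminase is irreversible because extracellular
aspartate is only ever consumed.

The specific growth rate is a multiplicative saturation function over all
modelled extracellular amino acids plus the intracellular precursors of the
main biomass constituents — glucose-6-phosphate (glycogen), citrate (lipids)
and ribulose-5-phosphate (nucleotides) — each with its own affinity constant,
times non-competitive inhibition factors for lactate and ammonia (with
affinity constants distinct from those on PFK). The mAb production rate has
the same structure over the antibody's amino-acid precursors with its own
constant set. Growth and mAb synthesis additionally carry ATP/ADP and
NADPH/NADP saturation terms so that anabolism stalls rather than driving
cofactor pools negative when energy or reducing power runs out.

Biomass stoichiometry converts the per-cell protein content (dry weight
$3.15\times10^{-4}$ g per $10^6$ cells at a mean residue mass of 107.5 g/mol,
i.e. $2.93\times10^{-3}$ mmol amino acids per $10^6$ new cells — the two are
required to agree within 1% by a validation rule) into per-amino-acid
demands; mAb synthesis consumes $9.17\times10^{-3}$ mmol amino acids per mg
of antibody. ATP demands for growth and product synthesis are lumped
coefficients on the same reactions.

### Units

Extracellular species are mM; intracellular pools are mmol per $10^6$ cells;
cells are $10^6$ cells/mL; mAb is mg/L; fluxes are mmol per $10^6$ cells per
hour. The culture balances are

$$\frac{dX_v}{dt} = \mu X_v,\qquad
\frac{dS}{dt} = 1000\,X_v \sum_j \nu_{Sj} v_j,\qquad
\frac{dC}{dt} = \sum_j \nu_{Cj} v_j - \mu C,$$

the factor 1000 converting mmol/mL to mmol/L, and the $-\mu C$ term diluting
per-cell pools through division. That dilution term is not strictly implied
by the per-cell bookkeeping (one could argue the growth reaction's precursor
drain already accounts for it); it is on by default and exposed as a
`dilution` flag on the simulator so the alternative can be tested.

### Model as data

The network — metabolites, stoichiometry, rate-law specs, regulation — lives
in a YAML file (`cho_network.yaml`), and parameters in a CSV, so any
discrepancy between the shipped reconstruction and a preferred variant is a
file edit, not a code change. The shipped reference model is a
**reconstruction**: the reaction set, regulation wiring, conversion factors
and printed culture conditions follow the published description of this
model family, but several rate equations and nearly all parameter values are
not printed in any accessible source. Those reactions carry a
`reconstructed: true` flag; parameter values were chosen once so that the
nominal mid-exponential fluxes sit in the reported ranges (glucose uptake
$\sim2\times10^{-4}$, pyruvate dehydrogenase $\sim1.6\times10^{-5}$, pentose
phosphate flux $\sim3.5\times10^{-6}$ mmol per $10^6$ cells per h) — the
maximal rates are derived in `data-raw/make_reference_model.R` by evaluating
each rate law's saturation terms at a nominal reference state and solving
for $V_{max}$. The model reports 144 parameters, close to the full model's
139; exact equality is not enforced because the full supplementary equation
set is not enumerable from the main text.

## Simulator

Integration uses `deSolve::lsoda` (stiff-capable, adaptive) with relative
tolerance $10^{-8}$ and per-species absolute tolerances at $10^{-10}$ of each
species' typical magnitude — intracellular pools live near $10^{-7}$ and
extracellular species near 1–10, so a single absolute tolerance would be
meaningless. The inner flux evaluation and right-hand side are compiled
(Rcpp); a pure-R reference evaluator is kept and the two are cross-checked to
machine precision in the tests. Negative concentrations arising from solver
overshoot are clamped to zero inside every rate term, so rates are always
well-defined and the overshoot decays.

Fed-batch feeding is a sequence of exact discontinuities: integration stops
at each daily trigger, a bolus volume is computed, mixed in with exact mass
conservation (per-cell pools unchanged, cell density and every concentration
diluted), and integration restarts. The study protocol states daily feeding
keeping glucose above 10 mM but not the fed volumes, so the default policy
feeds unconditionally each day to a glucose set-point (the culture's initial
glucose by default), with the 10 mM floor acting as the trigger in an
optional conditional mode; the set-point rule is a stand-in for the
unreported volumes. Concentrations at feed instants are reported post-bolus.
Sampling losses, evaporation, base addition and pH/DO/temperature dynamics
are ignored (held constant experimentally); cell death is out of scope, so
simulations are not interpreted past the 95%-viability window that also
bounds the calibration data.

## Morris screening

Global sensitivity uses the Morris elementary-effects method: each parameter
is perturbed on a 4-level grid spanning ±25% of its nominal value, unit-scaled
to $[0,1]$ with the canonical step $\Delta = p/(2(p-1)) = 2/3$, along
randomized one-at-a-time trajectories (35 repetitions at full scale). The
step is taken on the unit-scaled axis — the standard pairing with a 4-level
grid. The screened output is a single scalar: the mean over the selected 32
observables and all sampling times of $|y/\sigma|$, the same
standard-deviation weighting the calibration objective uses; computing
elementary effects on this scalar (rather than per output, then aggregating)
directly yields one sensitivity value per parameter. Parameters are ranked
by the absolute mean of their elementary effects; the standard deviation
flags nonlinearity and interactions. The selection rule keeps parameters
with $|\text{mean EE}| \ge 0.6$, capped at the 20 best — the published
selection table's smallest retained mean is exactly 0.6, which resolves the
source text's self-contradictory phrasing ("significantly high (i.e. lower
than 0.6)") in favour of the table.

## Calibration

The objective is the weighted sum of squared residuals
$\sum ((y^{exp}-y(p))/\sigma)^2$ over all cultures, outputs and retained
sampling times. Data enter from 24 h after inoculation until each culture's
viability first drops below 95%; censored (below-LOD) records are excluded.
Free parameters — by default the 20 flagged most-sensitive ones — are
normalized to their order of magnitude ($p/10^n$) so each is $O(1)$, bounded
below by 0, and optimized with bounded Levenberg-Marquardt
(`minpack.lm::nls.lm`) from the supplied initial guess (single start;
simulation failures inside the optimizer return a finite penalty of
$10^{12}$ rather than raising). Confidence intervals are linearized (Wald):
$s^2 (J^\top J)^{-1}$ with $s^2 = \text{SSR}/(N-k)$ and the Jacobian computed
by central finite differences (relative step $10^{-4}$) at the optimum;
rank-deficient Jacobians flag the affected parameters as non-identifiable
with infinite intervals. Degrees of freedom use the total record count
across all cultures in the scheme.

The subset-comparison scheme fits all data first, then re-fits on the
batch-only, fed-batch-only, and per-medium subsets (and a 72-h growth-phase
split), each seeded from the all-data estimates; for every parameter,
interval overlap between two subsets decides whether the estimates differ
significantly.

## Dynamic MFA

Fluxes are evaluated along the simulated trajectory (and re-evaluated from
states as a consistency check). Derived quantities are data
(`derived_fluxes.yaml`), asserted verbatim in a fixture test: ammonia
production $V_{GLDH}+V_{GlnT}+V_{SDHH}+V_{ASN}+V_{HISARGTA}$; TCA influx
$V_{GLDH}+V_{PDH}+V_{AlaTA}+V_{PC}+5V_{AAtoSUC}$; net ATP production
$V_{PGK}+V_{PK}+V_{AKGDH}+V_{PC}+V_{GlnT}+2\cdot2.5\,V_{resp}$; plus the
contribution fractions (the three TCA contributions partition unity by
construction), the glycolytic and respiratory ATP shares, and the
$V_{PDH}/V_{PK}$ and $V_{LDH}/V_{PK}$ ratios. Two conventions are
implemented exactly as printed in the source figure definitions even though
they are biochemically surprising — the "ATP from glycolysis" numerator
$V_{HK}+V_{PFK}$ (both ATP consumers) and the inclusion of $V_{GlnT}$ and
$V_{PC}$ among ATP producers; being data, alternatives are a file edit.
Ratio time points with a non-positive denominator are reported missing, not
zero. Inhibition-term time courses evaluate $1/(1+I(t)/K)$ along the
trajectory; the lactate-on-glycolysis report emits both fed-batch cultures
since the source attributes the quoted values to fed-batch conditions
collectively.

Flux confidence bands propagate the calibration covariance by the delta
method: $v \pm t\sqrt{g^\top \Sigma g}$ with $g$ the central
finite-difference gradient (relative step $10^{-4}$) of the flux with
respect to the free parameters; the tests check agreement with Monte-Carlo
parameter resampling within 15% on the toy model.

## Synthetic data

No measurement data are deposited for this system, so the package generates
pseudo-experimental datasets with the study's statistical structure: four
cultures (two media × batch/fed-batch) inoculated at $2\times10^5$ cells/mL,
daily sampling (12-hourly for the Biogro batch, the shortest culture),
multiplicative truncated-Gaussian noise whose magnitude scales with the
signal (default CVs: 10% extracellular, 15% intracellular, 10% cells/mAb —
true per-analyte CVs are not printed anywhere, so these are stated
placeholders), reported $\sigma = \text{CV}\cdot y$ floored at a small
per-class assay scale, and limit-of-detection censoring of the species that
were undetectable in the matching cultures (alpha-ketoglutarate in the
Biogro batch, pyruvate in the Biogro fed-batch). Viability is 100% until a
configurable decline onset (default 65% of the culture duration, 0.25%/h
linear decline) — enough to exercise the data-window rule without modelling
death. The PowerCHO-2 base-medium glucose is not printed in the main text;
the shipped experiment files use 40 mM, consistent with the 2.5× concentrate
carrying 100 mM, and mark it as reconstructed. Base-medium amino acid
profiles are likewise synthetic, respecting the reported ordering (PowerCHO-2
richer in aspartate, asparagine, serine, isoleucine and arginine).

What passing tests show — and what they do not: the generator draws from the
model itself, so end-to-end tests demonstrate that the pipeline recovers
what it is pointed at (correct windowing, weighting, optimization,
uncertainty propagation), not that the shipped parameter values describe any
real culture. Structural misfit, assay-specific error (HPLC drift, plate
effects), and replicate correlation are deliberately not emulated.

A three-reaction toy model (saturating uptake into a per-cell pool,
product-inhibited conversion to a secreted product, and a degradation drain)
ships alongside the full network for fast oracle tests: parameter recovery,
CI coverage and the delta-method cross-checks all run on it in seconds.

## Numerical choices and problem sizes

- Solver: `lsoda`, rtol $10^{-8}$, per-species atol at $10^{-10}$ of typical
  magnitude; halving tolerances moves toy-model observables by well under
  0.1% of their scale (tested).
- Negative-state clamping in rate laws; exhausted ratio denominators give a
  saturated (1) term when the numerator persists, 0 when both pools are
  empty.
- Optimizer: single-start bounded Levenberg-Marquardt; iteration caps are
  recorded in the result rather than raised as warnings.
- The default analysis scripts run reduced problem sizes — the flagged
  20-parameter subset at 2–3 Morris repetitions, and 3–5 free parameters at
  small iteration caps in the calibration drivers — chosen so each driver
  completes in minutes on one core; `--full` switches the screening and
  calibration drivers to the full 140-parameter × 35-repetition and
  20-free-parameter problems.
- All randomness flows from one top-level seed, fanned out per culture and
  per replicate; datasets and designs are bitwise reproducible per seed.

## Known limitations

The shipped parameterization is a calibrated reconstruction, not the
published estimate set; quantitative flux values are in the reported ranges
but individual trajectories will differ from the original study's figures.
The model excludes cell death and viability, glycosylation, gas-phase mass
transfer and the previously modelled creatine/phosphocreatine/CoA/phosphate/
intracellular-oxygen species; simulations past the 95%-viability window are
extrapolation. Linearized CIs understate uncertainty for strongly nonlinear
or practically non-identifiable parameters — the usual caveat for
Jacobian-based intervals.
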