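---
title: "Methods: the oxygen column model and the MIDA estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the oxygen column model and the MIDA estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxymida)
```

This vignette is the package's account of its two models — what they assume,
which parameters matter, how the numerics are handled, and where the design
was genuinely open.

## 1. The oxygen column model

### Physical picture and assumptions

A monolayer of cells sits under a stagnant column of medium of depth $x$.
Oxygen enters only at the air–medium interface, where the dissolved
concentration is held at $C$ by equilibrium with the incubator headspace,
and is consumed only at the monolayer. At steady state the diffusive flux is
then the same at every height, so Fick's first law gives a linear profile
and an areal consumption rate

$$J = \frac{D\,(C - C_\mathrm{peri})}{x},$$

with the ceiling $J_{\max} = D\,C/x$ reached when pericellular oxygen
$C_\mathrm{peri}$ is drawn to zero. The model's assumptions, each of which
can fail in ways discussed under limitations:

* **steady state** — no transient after a medium change;
* **stagnant medium** — no convective mixing (thermal gradients and plate
  movement stir real wells);
* **consumption confined to an infinitesimally thin monolayer** — valid
  when cell height (tens of µm) is small against column depth (mm);
* **zero-order consumption with a hard cutoff** — demand is independent of
  oxygen down to a critical concentration (default 4 µM), below which
  respiration is delivery-capped. Closed-system respirometry of adipocyte
  monolayers supports this near-step dependence; a Michaelis–Menten form
  would smooth the corner but barely move the predictions, because the
  apparent $K_m$ is far below incubator concentrations.

`solve_pericellular()` implements the resulting piecewise solution: demand
below capacity is met exactly ($C_\mathrm{peri} = C - Jx/D$); demand above
capacity pins $C_\mathrm{peri}$ at the critical concentration and caps the
realised OCR at $D(C - C_\mathrm{crit})/x$. An interface concentration at or
below the critical value yields the no-respiration solution rather than an
error, since it is a physically meaningful state.

### Parameters, units, defaults

| parameter | units | default | rationale |
|---|---|---|---|
| $D$ | mm²/s | 2.69e-3 | oxygen in aqueous medium at 37 °C lies at ~2.7–3.0e-5 cm²/s; the default is pinned so that 181 µM over 2.43 mm delivers exactly 200 fmol/mm²/s, keeping the depth-ceiling arithmetic self-consistent |
| $C$ (interface) | µM | 181 | dissolved O₂ under humidified ~18% incubator gas at 37 °C (140 mmHg) |
| $\alpha$ (Henry) | µM/mmHg | 181/140 ≈ 1.2929 | calibrated from the 181 µM / 140 mmHg pair so the two reporting scales are mutually consistent |
| critical O₂ | µM | 4 | concentration down to which monolayers respire maximally in closed-system measurements |
| flux | fmol/mm²/s | — | areal convention: 1 µM = 1000 fmol/mm³ |

All are configurable at every entry point. Note that
`incubator_o2_um(18)` — the textbook dry-gas computation
$\alpha \cdot 0.18\,(760-47)$ — gives ~166 µM, not 181 µM; the 181 µM
default corresponds to ~19.6% of the water-corrected pressure. The package
keeps 181 µM as the default interface concentration because it is the value
the calibrated Henry coefficient and the depth-ceiling arithmetic are
anchored to, and provides `incubator_o2_um()` for users who prefer to derive
the concentration from their own headspace percentage.

mmHg outputs are rounded half-away-from-zero to integers (`round_mmhg()`),
matching the convention of reporting oxygen tensions as whole mmHg.

### Geometry

Depth is volume over growth area (`nominal_depth()`), minus a meniscus
depression at the well centre (`minimum_depth()`). The default depression,
0.23 mm, is a *calibration*: it makes 1 mL in a 12-well plate (nominal
2.63 mm) reproduce the directly measured ~2.4 mm minimum depth. It is not a
capillary-physics model — the real surface is curved, and depth near the
wall is larger. Because measured depths for that configuration span roughly
2.4–2.9 mm, `oxygen_report()` always reports both the minimum-depth and
nominal-depth solutions rather than choosing one: whether the centre
(minimum) or mean depth better represents delivery to a whole monolayer is
genuinely unresolved, and the two bracket the answer.

### Numerical verification

The analytic solution is cross-checked in the test suite against an
independent 1-D finite-difference steady-state solver (uniform grid,
flux boundary at the monolayer, Dirichlet interface, 401 nodes, with the
delivery-capped regime handled by switching to a pinned Dirichlet condition)
to 0.1% over randomised parameter sets.

## 2. The MIDA estimator

### Forward model

For a fatty acid synthesised during labelling with deuterated water at
enrichment $p$, with $N$ hydrogen positions able to acquire deuterium:

1. **label pattern** $M'_x = \binom{N}{x} p^x (1-p)^{N-x}$;
2. **natural-abundance correction** $M_{xn} = \sum_{i+j=x} M'_i M_j$, the
   convolution of the label pattern with the natural envelope $M$ of the
   molecular formula (for methyl palmitate C₁₇H₃₄O₂: $M_0 \approx 0.826$,
   $M_1 \approx 0.156$, computed from fixed isotope abundances — ¹³C 1.07%,
   ²H 0.0115%, ¹⁷O 0.038%, ¹⁸O 0.205% — by per-element polynomial expansion);
3. **mixture** $M_x^{obs\prime} = f\,M_{xn} + (1-f)\,M_x$, where $f$ is the
   fraction of the pool synthesised during the window.

The estimator minimises $\sum_{x=0}^{4}(M_x^{obs} - M_x^{obs\prime})^2$ over
$(f, p) \in [0,1] \times [0,1)$.

### The window-normalisation decision

Only the ions M+0…M+4 are extracted, so both data and model live on a
truncated window. Internally, theoretical patterns are **not** renormalised
after truncation — the tail mass beyond M+4 is real, and renormalising
mid-pipeline would distort the convolution arithmetic. Observed data,
however, arrive as *fractional concentrations of the extracted ions*, which
are inherently window-normalised; they are normalised on ingestion (this
also makes the objective invariant to raw-intensity rescaling). Model
predictions are therefore window-normalised **only at the comparison step**
of the fit. This asymmetry is the key interpretive decision in the package;
the alternative (comparing against the unnormalised truncated model) is
available via `mida_config(normalise_model = FALSE)` for sensitivity
analysis. At the default parameter scales (p ≈ 0.08, N ≤ 24) the window
captures >98% of the label pattern's mass, so the two choices differ only
in the third decimal of $f$.

### Optimisation

The objective has a known ridge: at low label incorporation, $f$ and $p$
trade off (small $f$·strong label ≈ large $f$·weak label). The fit therefore
runs a bounded quasi-Newton optimiser (`stats::nlminb`, PORT routines;
`rel.tol` 1e-15, `x.tol` 1e-12) from a fixed 5 × 5 grid of starts over
$(f_0, p_0) \in \{0.05..0.95\} \times \{0.01..0.25\}$, keeping the best
minimum. The grid is fixed, not random, so fits are deterministic. nlminb's
"singular convergence" status — the expected diagnosis on a ridge that is
flat at machine precision — is treated as converged. The suite verifies the
optimiser is never beaten by a 101 × 101 brute-force grid, and that
noise-free round trips recover $(f, p)$ to better than 1e-5.

### Determining N

The water enrichment is set by the experimenter (8% here), so $p$ is known
*a priori* — but fitting it freely provides a consistency check that pins
down $N$: `determine_N()` fits $(f, p)$ at every candidate $N$ (default
8–24) and selects the $N$ whose fitted $p$ lands closest to the target
enrichment, ties breaking toward smaller $N$. This makes the manual
"adjust N until p matches" workflow total and reproducible. The alternative
reading — pin $p$ at the target, fit $f$ alone, select $N$ by residual — is
provided as `mida_config(mode = "fix_p")`; on noise-free synthetic data both
modes select the generating $N$.

### Identifiability guard

If the observed envelope differs from the natural envelope by less than
3 × the configured noise level (`noise_level`, default 0.001 per ion — an
instrument-precision scale for fractional abundances) in every ion, there is
no label signal to fit: the observation is flagged `unidentifiable` and
reported with $f = 0$ rather than an arbitrary point on the $f \approx 0$,
$p \approx 0$ ridge. $N$ is then indeterminate; the scan still returns a
value (the tie rule) but carries the flag.

### Absolute DNL

`absolute_dnl()` multiplies $f$ by the fatty-acid pool (nmol/well). Any
uncertainty in the pool measurement propagates linearly and is outside the
estimator.

## 3. Flux arithmetic

Concentration changes (mM) times volume (µL) give nmol directly;
normalising by growth area (mm²) and duration (h) gives fluxes in
nmol/mm²/h. The headline "lactate relative to glucose" summary is defined
as lactate production / (2 × glucose uptake) — the fraction of consumed
glucose *carbon* exported as lactate, which is 1.0 for fully anaerobic
glycolysis. This convention is the package's own, chosen because it makes
culture values (~0.5 under standard conditions) directly comparable with
the 15–30% range reported for adipose tissue in vivo; the raw molar ratio
(which can reach 2.0) is always emitted alongside. Wrong-way concentration
changes produce negative fluxes that are flagged, not clamped; no
evaporation correction is applied (volumes are taken as nominal).

## 4. Synthetic data: what it does and does not emulate

The generators produce exactly the statistical structure the estimators
assume: multiplicative lognormal noise (mean 1, configurable CV) on GC-MS
ion intensities — the standard model for peak-area noise; additive Gaussian
noise on optical oxygen readings; lognormal noise on the four measured
assay concentrations. Defaults mirror the study conditions the package
targets: 8% water enrichment, N = 14 palmitate (C₁₇H₃₄O₂), a 16 h window,
12-well/1 mL and 96-well/100 µL geometries, probe heights 0.55–0.95 mm.

They deliberately do **not** emulate: chromatographic interference and
baseline drift, detector saturation, ion-count (Poisson) statistics at low
abundance, isotope effects on synthesis kinetics, position-dependent
deuterium incorporation, medium evaporation, or convective mixing. Passing
round-trip tests therefore demonstrates *estimator correctness under the
assumed noise model*, not robustness to every artefact of real instrument
data. Seeds are mandatory — a generator without a seed is an error — and
generation never perturbs the caller's RNG stream.

Test problem sizes are desk-scale by design: 200 replicate fits at 1% CV
for the noisy-recovery property (median $|\hat f - f| < 0.02$), 100
simulated assays for flux-fraction recovery, 401-node grids for the
finite-difference oracle; the full suite runs in well under a minute.

## 5. Known limitations

* The Fick model is 1-D: it ignores the curved meniscus surface, lateral
  gradients near well walls, and oxygen entry through plate plastic (real
  polystyrene is slightly permeable; gas-permeable plates are entirely
  outside the model).
* Measured OCRs can exceed the idealised flat-column capacity (e.g.
  ~200 fmol/mm²/s observed where a 3.125 mm flat column caps at ~156) —
  meniscus thinning and sensor-lid volume displacement are the likely
  reconciliation. The package reports measured-vs-predicted gaps; it does
  not attempt to absorb them into fitted parameters.
* The MIDA window (M+0…M+4) discards information in higher isotopologues;
  at high $p$ or large $N$ the retained fraction of the label pattern
  shrinks and the truncation becomes consequential.
* Whether the natural envelope should come from theory or from a measured
  unlabelled control is instrument-dependent (derivatisation artefacts,
  detector nonlinearity); both paths are supported
  (`mida_observation(..., natural = )`), with theory as the default.
* Elongation/desaturation flux partitioning and positional (¹³C) isotopomer
  analysis are out of scope.
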