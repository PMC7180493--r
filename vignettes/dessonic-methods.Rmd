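---
title: "Estimating speeds of sound in deep eutectic solvents: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating speeds of sound in deep eutectic solvents: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dessonic)
```

## The problem and the model

Deep eutectic solvents (DESs) are mixtures of a hydrogen-bond acceptor
(HBA) and one or more donors (HBDs) at a fixed molar ratio. Because any
HBA/HBD pairing at any ratio defines a new solvent, experimental coverage
of their thermophysical properties will always lag behind the space of
candidates. `dessonic` predicts one such property — the speed of sound —
from structure alone, in three stages.

**Stage 1: group contribution.** Every pure component is decomposed into
structural fragments under the modified Lydersen–Joback–Reid (mLJR)
scheme, a group-contribution method extended to ionic and strongly
hydrogen-bonded species. With group counts $n_k$ and increments
$\Delta T_{bM}, \Delta T_M, \Delta P_M, \Delta V_M$:

$$T_b = 198.2\,\mathrm{K} + \sum_k n_k \Delta T_{bM,k}$$
$$T_c = \frac{T_b}{0.5703 + 1.0121 S - S^2}, \qquad S = \sum_k n_k \Delta T_{M,k}$$
$$P_c = \frac{M_w}{(0.2573 + \sum_k n_k \Delta P_{M,k})^2} \;[\mathrm{bar}],
\qquad V_c = 6.75 + \sum_k n_k \Delta V_{M,k} \;[\mathrm{cm^3/mol}]$$

The acentric factor comes from a two-point Clausius–Clapeyron fit of the
vapour-pressure curve through $(T_b, P_b)$ and $(T_c, P_c)$ with a 43 K
temperature offset, evaluated at the reduced temperature 0.7 that defines
$\omega$:

$$\omega = \log_{10}\!\left(\frac{P_c}{P_b}\right)
  \frac{0.3\,T_c\,(T_b - 43)}{(T_c - T_b)(0.7\,T_c - 43)} - 1,
  \qquad P_b = 1.01325\ \mathrm{bar}.$$

This is the boiling-point-based corresponding-states expression used
throughout the ionic-liquid/DES mLJR literature; the method prints no
other route to $\omega$. Its validity requires $T_c > T_b$, which holds
for every registry compound and is enforced by error otherwise.

**Stage 2: Lee–Kesler mixing.** Pure-component values are combined at the
DES mole fractions $x_i$ (derived from the integer molar-ratio parts)
into pseudo-critical mixture properties:

$$V_{c,m} = \sum_i \sum_j x_i x_j V_{c,ij}, \qquad
  V_{c,ij} = \left(\tfrac{1}{2}\left(V_{c,i}^{1/3} + V_{c,j}^{1/3}\right)\right)^3$$
$$T_{c,m} = V_{c,m}^{-1/4} \sum_i \sum_j x_i x_j V_{c,ij}^{1/4}
  \sqrt{T_{c,i} T_{c,j}}$$
$$\omega_m = \sum_i x_i \omega_i, \qquad
  P_{c,m} = (0.2905 - 0.085\,\omega_m)\,\frac{R\,T_{c,m}}{V_{c,m}},
  \qquad M_{w,m} = \sum_i x_i M_{w,i}$$

with $R = 83.14$ cm³·bar·mol⁻¹·K⁻¹ so that $P_{c,m}$ comes out in bar.
Two variants of the $T_{c,m}$ rule circulate: one weights the geometric
mean of the critical temperatures by $V_{c,ij}$ itself, the other — the
canonical Lee–Kesler/Plöcker–Knapp form — by $V_{c,ij}^{1/4}$. We ship
the quarter-power form: numerical reconstruction of the packaged 39-DES
reference table showed it reproduces every row to better than 0.1%,
whereas the linear-weight variant cannot do better than about 1.2% on
several rows. A side effect worth knowing: the quarter-power $T_{c,m}$ is
not an exact interpolation and can undershoot the smaller pure-component
$T_c$ by a few tenths of a percent when the components' molar volumes are
very dissimilar; the property tests allow a 1% guard band for this (the
$V_{c,m}$ rule, a true convex combination, interpolates strictly). A
boiling point of the mixture is never needed downstream and is not mixed.

**Stage 3: the correlation.** The speed of sound of the pseudo-component
at temperature $T$ is

$$u = \omega\,(c_1 M_w + c_2 T) + c_3 V_c + c_4,$$

with published coefficients $c_1 = 7.378$, $c_2 = -2.012$,
$c_3 = -2.911$, $c_4 = 2514.2$ ($u$ in m/s, $M_w$ in g/mol, $V_c$ in
cm³/mol, $T$ in K). The form implies an exactly linear temperature
dependence with slope $-2.012\,\omega$ m/(s·K) per DES, and a degenerate
limit $u = 2514.2$ m/s when $\omega = 0$ and $V_c = 0$; both are used as
closed-form checks in the tests and the acceptance script.

## The packaged registry and the calibrated group table

The registry covers 39 DESs (28 training, 11 test, mirroring the
literature compilation's assignment) built from 29 pure components.
Group decompositions are *stored as data*, not computed from structure:
the package deliberately ships no SMILES/InChI parsing or automatic
fragmentation, because decomposition choices for ionic species are
genuinely ambiguous and are better kept inspectable and editable. Users
can override any decomposition via `read_compounds()`.

The mLJR increment tables themselves are scattered across the original
publications and their ionic-liquid extensions, and the reference table
the package validates against prints only mixture-level results. The
shipped `group_parameters.csv` was therefore produced in two steps:
increments were first transcribed from the published scheme from memory
of the canonical values, then refined numerically so that the complete
chain — stored decompositions, the four formulas above, quarter-power
Lee–Kesler mixing — reproduces the packaged reference table. The
refinement used back-solved per-compound targets obtained from the 39
mixture rows (the mixture equations are invertible to per-compound
$T_c, V_c, \omega$ up to small residuals) followed by a least-squares fit
of the increments with weak priors at the transcribed values. The result
reproduces all 195 reference cells to within 0.08% (tolerance: 1%
relative, 0.02 g/mol on molecular weights); `validate_fixtures()`
recomputes this on demand. Two caveats are documented rather than hidden:

* The increments for groups that occur only in one or two registry
  compounds (e.g. the sulfonic-acid group, the aromatic N⁺) are only
  weakly identified — they reproduce the reference chemistry but should
  not be read as transferable constants.
* Two substituted-ring entries (phenolic OH, ring-ether O) carry small
  *negative* volume increments; the reference table cannot be reproduced
  within tolerance under a positivity constraint. All aliphatic and
  functional-group volume increments are positive, and the monotonicity
  property (adding a group increases $V_c$) is asserted for those.

Water, which appears in two ternary DESs, is flagged "properties supplied
directly" and carries experimental critical constants
($T_c = 647.10$ K, $P_c = 220.64$ bar, $V_c = 55.95$ cm³/mol,
$\omega = 0.3449$): a group scheme has nothing sensible to say about a
single H₂O, and the mixture-level reconstruction confirms direct values
were used. Atomic weights are fixed to one packaged table so
molecular-weight fixtures are reproducible to the 0.01 g/mol level.

## Literature models and their configuration

Four ionic-liquid models are implemented for comparison:

* Gardas–Coutinho: $\log_{10} u = \alpha \log_{10}(\sigma\rho) + \beta$;
* Singh–Singh: same form with constants $(\psi, \xi)$;
* Hekayati–Esmaeilzadeh:
  $\ln u = (a + b M_w)\ln(\sigma\rho) + c M_w + d M_w^2 - e T + f$;
* Haghbakhsh et al. (atomic contribution): $u = A M_w + B T$ with
  $A = \sum n_i \Delta A_i$, $B = \sum n_i \Delta B_i$ over atom counts
  (for a DES, mole-fraction-weighted counts, see `mixture_formula()`).

Their fitted constants belong to the original publications and ship
*empty*: `literature_constants()` loads a unit-annotated template and
every model errors informatively until the user transcribes the values.
Two typesetting ambiguities in the source forms — whether the
Hekayati leading term is $a + bM_w$ or $a + b/M_w$, and whether the
atomic-contribution model reads $A M_w$ or $A/M_w$ — are resolved by a
`mw_term` switch defaulting to the product reading, which is consistent
with the unambiguous $cM_w + dM_w^2$ terms of the same equation.

Surface tension for the first three models comes from the Curl–Pitzer
corresponding-states formula,

$$\sigma = P_c^{2/3} T_c^{1/3}\,\frac{1.86 + 1.18\,\omega}{19.05}
 \left[\frac{3.75 + 0.91\,\omega}{0.291 - 0.08\,\omega}\right]^{2/3}
 (1 - T_r)^{11/9},$$

which yields mN/m with $P_c$ in bar and $T_c$ in K; the mN/m convention
is assumed (and declared in the config) since the source is silent. The
formula requires $T < T_c$ and $\omega < 0.291/0.08$; both are enforced.
Density is a *pluggable provider* (a number or any function of
temperature): published DES density models have their own coefficient
tables, which this package does not reproduce.

## Evaluation and refitting

`AARD% = (100/N)\sum |u_{exp} - u_{cal}|/u_{exp}` is implemented once and
exposed both as the scoring metric (`aard()`) and as the optimization
objective (`objective()`); the signed per-record deviation is
`RD% = 100 (u_{exp} - u_{cal})/u_{exp}`. `evaluate_models()` reports
per-record RD%, per-DES AARD% and AARD% by training/test/overall split,
with split labels from the registry (or from the dataset itself if it
carries a `dataset` column).

`refit()` re-estimates the four correlation coefficients by minimizing
AARD%. The published fit used a genetic algorithm whose settings are not
recorded; since the correlation is linear in its coefficients and the
objective is smooth almost everywhere, exact GA fidelity is immaterial
and any competent derivative-free minimizer lands in the same optimum.
The default is a seeded differential-evolution search
(rand/1/bin, population 40, 200 generations, $F = 0.7$, $CR = 0.9$)
whose population is initialized around the ordinary least-squares
solution of the linearized problem plus random perturbations
(relative spread 0.5), followed by a deterministic Nelder–Mead polish
(relative tolerance $10^{-14}$). On noise-free synthetic data the
least-squares seed is already exact, so recovery to machine precision is
guaranteed rather than lucky; on noisy data the DE stage explores
genuine AARD (an L1-type functional whose optimum differs from least
squares). All randomness flows through one required integer seed; the
result is invariant to dataset row order because records are sorted
before fitting.

## The synthetic-data generator

`generate_synthetic()` produces datasets with exactly the structure the
correlation assumes: $u_{exp} = u_{model}(1 + \varepsilon)$,
$\varepsilon \sim N(0, s)$, on a DES × temperature grid. The default
grid, 293.15–333.15 K in 5 K steps, spans the range over which DES
speed-of-sound measurements are typically reported and over which the
linear temperature dependence is an established experimental observation.
With `registry_sizes = TRUE` the generator instead emulates the
literature compilation: each DES contributes its registry record count
(420 records in total; 292 training, 128 test), enabling
compilation-scale exercises of the evaluation harness. The default noise
level in the examples, $s = 0.01$, makes the attainable AARD% equal to
the folded-normal mean $100\,s\sqrt{2/\pi} \approx 0.80\%$ — a useful
closed-form cross-check.

What the generator deliberately does *not* emulate: real measurement
error is not multiplicative-Gaussian, real DESs deviate from the
correlation in structured, per-DES ways (the compiled experimental data
show per-DES AARDs from under 1% to over 20%), and the generator shares
the model's functional form. Passing the parameter-recovery and
harness tests therefore demonstrates the *machinery* — identifiability,
determinism, correct bookkeeping — not predictive accuracy on real
measurements. Reproducing the published accuracy tables requires the
compiled experimental speeds of sound, which live in their original
publications and are not redistributed here; when a user supplies them as
a CSV (`des_id, T_K, u_exp_ms, source`), `evaluate_models()` produces
the same per-DES and per-split tables.

## Numerical choices and problem sizes

* Tolerances: reference-table validation uses 1% relative (0.02 g/mol for
  $M_w$), matching the rounding of the printed reference values; the
  parameter-recovery test asserts coefficients within 0.1% and objective
  below $10^{-6}$%.
* Degenerate inputs error early with specific messages: unknown element
  symbols, unknown groups and unknown DES ids are named; a group sum
  pushing the $T_c$ denominator to zero or below reports the method's
  validity range; refitting demands at least two DESs and two
  temperatures.
* Mole fractions must reproduce 1 to $10^{-12}$ by construction
  (ratio-part normalization); mixing checks the sum to $10^{-8}$ to
  tolerate user-supplied fractions.
* Test problem sizes: the suite runs the full 39-DES chain (instant),
  refits on 39 × 9 = 351 noise-free records and on the 420-record
  compilation-sized synthetic set, and uses reduced optimizer settings
  (population 20, 30 generations) where only the mechanics are under
  test. The complete suite runs in well under a minute on one CPU.

## Known limitations

* Predictions inherit every bias of the group-contribution estimates;
  for sugars, polyacids and ionic species the estimated $T_c$ and
  $\omega$ are extrapolations far outside the regions where
  group-contribution methods are parameterized, and should be read as
  correlation *inputs*, not as physical critical constants.
* The calibrated increment table is tied to the packaged decompositions;
  editing one without the other will degrade the reference-table
  reproduction (run `validate_fixtures()` after any edit).
* The correlation is for atmospheric pressure and the liquid range; no
  pressure dependence is modelled, and extrapolation outside roughly
  278–338 K leaves the temperature window the coefficients were fitted
  in.
* The literature models are only as good as the constants the user
  transcribes, and their unit conventions must match the declarations in
  the config.
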