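# dessonic

Speed of sound in deep eutectic solvents (DESs), estimated from molecular
structure alone.

DESs — mixtures of a hydrogen-bond acceptor (HBA) and one or more
hydrogen-bond donors (HBDs) whose melting point lies far below those of the
pure components — are designer solvents: new combinations and molar ratios
appear far faster than their thermophysical properties can be measured. The
speed of sound is a particularly useful property because isentropic
compressibility, heat capacity and related quantities can be derived from
it. `dessonic` implements a fully predictive chain that needs nothing but
the structures of the constituents:

1. **Group contribution.** Each pure component is decomposed into
   structural groups (CH3, CH2, COOH, ...) under the modified
   Lydersen–Joback–Reid scheme, giving its normal boiling point
   `Tb = 198.2 K + Σ n·ΔTbM`, critical temperature
   `Tc = Tb / (0.5703 + 1.0121·S − S²)` with `S = Σ n·ΔTM`, critical
   pressure `Pc = Mw / (0.2573 + Σ n·ΔPM)²` (bar), critical molar volume
   `Vc = 6.75 + Σ n·ΔVM` (cm³/mol), and a boiling-point-based acentric
   factor ω.
2. **Lee–Kesler mixing.** Pure-component values are combined at the DES
   molar ratio into pseudo-critical properties `Tc,m`, `Pc,m`, `Vc,m`,
   `ω_m` and the mean molecular weight `Mw,m`.
3. **Corresponding-states correlation.** The speed of sound is

   ```
   u = ω (7.378 Mw − 2.012 T) − 2.911 Vc + 2514.2      [m/s]
   ```

   with `Mw` in g/mol, `Vc` in cm³/mol and `T` in K.

The package ships a registry of 39 DESs (28 training / 11 test) with stored
group decompositions, a reference pseudo-critical property table that the
chain is validated against cell by cell, four ionic-liquid literature
models (Gardas–Coutinho, Singh–Singh, Hekayati–Esmaeilzadeh and the
atomic-contribution model of Haghbakhsh et al.) behind a constants config,
the Curl–Pitzer surface-tension formula, AARD%/RD% evaluation, seeded
coefficient refitting and a synthetic-data generator.

## Worked example

```r
library(dessonic)

des_properties(c("DES21", "DES31"))
#> # A tibble: 2 × 7
#>   des_id dataset     tc_k  pc_bar vc_cm3_mol    omega mw_g_mol
#>   <chr>  <chr>      <dbl>   <dbl>      <dbl>    <dbl>    <dbl>
#> 1 DES21  training 644.471 49.5386    254.366 0.650892  86.5783
#> 2 DES31  training 736.861 24.6976    559.257 0.765172 158.241
```

DES21 is choline chloride : urea 1:2 ("reline"); DES31 is dodecanoic acid :
octanoic acid 1:3. The row is the full pseudo-component record: estimated
critical temperature (K), critical pressure (bar), critical molar volume
(cm³/mol), acentric factor and mean molecular weight (g/mol).

```r
predict_speed("DES21", t_k = c(298.15, 308.15, 318.15))
#> # A tibble: 3 × 4
#>   des_id model       t_k    u_ms
#>   <chr>  <chr>     <dbl>   <dbl>
#> 1 DES21  proposed 298.15 1799.06
#> 2 DES21  proposed 308.15 1785.96
#> 3 DES21  proposed 318.15 1772.87
```

The predicted speed of sound falls linearly with temperature at the rate
`−2.012·ω` ≈ −1.31 m/(s·K) for this DES.

Evaluating against a dataset (here a synthetic stand-in generated from the
model itself with 1% multiplicative noise, sized like the literature
compilation: 292 training + 128 test records):

```r
d  <- generate_synthetic(NULL, noise = 0.01, seed = 7, registry_sizes = TRUE)
ev <- evaluate_models(d)
ev
#> Speed-of-sound evaluation: 420 records, 39 DES(s), model(s): proposed
#>     model    split   n  aard_pct
#>  proposed training 292 0.7987314
#>  proposed     test 128 0.8244863
#>  proposed  overall 420 0.8065805
```

`aard_pct` is the average absolute relative deviation
`AARD% = 100/N Σ |u_exp − u_cal| / u_exp`; with 1% noise the attainable
optimum is `100·0.01·√(2/π) ≈ 0.80%`, which the table recovers.
`tidy(ev)` gives the per-DES breakdown, `autoplot(ev)` the signed-deviation
diagnostics.

Refitting the four correlation coefficients on noise-free model data
recovers them to machine precision (the package's headline self-test):

```r
fit <- refit(generate_synthetic(NULL, noise = 0), seed = 1)
fit
#> Refitted speed-of-sound correlation
#>   u = omega (7.378 Mw -2.012 T) -2.911 Vc +2514
#>   objective (AARD%): 1.183e-14 on 351 records, 39 DESs (seed 1)
```

A command-line interface wraps the same functions
(`inst/cli/dessonic properties DES21`, `... predict DES21 -T 298.15`,
`... validate-fixtures`, `... synth`, `... evaluate`, `... refit`); see
`?run_cli`.

The three surface-tension/density literature models need their fitted
constants (property of the original publications) and a density provider;
the packaged constants config is an empty, unit-annotated template — see
`?literature_constants`.

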