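# bindkin

Kinetic and equilibrium analysis of receptor–ligand binding assays, built
around the question of how strongly the immune checkpoint receptor LAG-3
binds its ligand, peptide–HLA class II. Measuring that affinity is awkward:
the only stable soluble LAG-3 reagent is a dimeric Fc fusion, so surface
plasmon resonance (SPR) sensorgrams mix the monovalent site affinity with
avidity from bivalent engagement of the immobilized pHLA-II surface.
`bindkin` implements the full analysis chain that disentangles the two, for
anyone analysing SPR data from dimeric/bivalent analytes, plus the companion
plate and flow-cytometry quantifications used to corroborate such an
interaction.

## What it computes

**Bivalent-analyte kinetics.** A dimeric analyte A binds a first immobilized
ligand B (rates `k_on1`, `k_off1`, M⁻¹s⁻¹ / s⁻¹) and the complex can engage a
second ligand (`k_on2`, RU⁻¹s⁻¹; `k_off2`, s⁻¹):

    dAB/dt  = k_on1·C·B_free − k_off1·AB − k_on2·AB·B_free + k_off2·AB2
    dAB2/dt = k_on2·AB·B_free − k_off2·AB2,   B_free = R_max − AB − AB2

with response `R(t) = AB + AB2 (+ RI while analyte flows)`. The package
simulates this scheme (compiled ODE right-hand side, lsoda, rtol 1e-8),
fits it to one (local) or many (global) injection cycles by simultaneous
k_on/k_off nonlinear least squares on log-rates (shared rates and `R_max`,
per-cycle refractive-index offset), and derives

    K_D1 = k_off1 / k_on1,   K_D2 = k_off2 / (k_on2[RU⁻¹s⁻¹] · 100 · MW)

the monovalent and bivalent equilibrium constants. A closed-form 1:1
Langmuir model, χ²/SSR/residual-autocorrelation model comparison, and a
steady-state route (`extract_plateau()` → `fit_one_site()`, the one-site
specific binding isotherm `R = B_max·C/(K_D + C)`) complete the SPR side.

**Companion assays.** Bead-proximity (AlphaScreen-style) cross-titration
summaries with hook-effect detection and fold-over-background binding calls;
four-parameter logistic IC50 fitting of antibody-fab blockade titrations;
and multimer-staining flow quantification (geometric MFI, FMO subtraction,
percent-positive gating at a reference quantile, blockade normalization).

**Synthetic data.** Every assay has a seeded generator
(`gen_sensorgrams()`, `gen_titration_plate()`, `gen_inhibition_series()`,
`gen_flow_events()`) that embeds its ground truth, so the whole pipeline is
validated by parameter recovery.

## Worked example

```r
library(bindkin)

# published global-fit rate set for LAG-3:Fc on HLA-DR1(HA306-318)
truth <- lag3_bivalent_params("global")

# synthetic twofold injection series, 0.11-7.1 uM, noise sd 2 RU
sg <- gen_sensorgrams(truth, concs_M = 7.1e-6 / 2^(6:0), seed = 1,
                      noise_sd_ru = 2, ligand_density_ru = 525)

fit <- fit_kinetics(sg, model = "bivalent", scope = "global", mw = 2e5)
glance(fit)
#> # A tibble: 1 × 10
#>   model    scope  chisq    ssr n_obs n_cycles converged k_on2_molar    K_D1    K_D2
#>   <chr>    <chr>  <dbl>  <dbl> <int>    <int> <lgl>           <dbl>   <dbl>   <dbl>
#> 1 bivalent global 2666. 10015.  2317        7 TRUE             97.2 7.29e-6 4.26e-5
```

The fit recovers the generating constants: `K_D1 = 7.29 µM` against a true
monovalent constant of 7.28 µM (k_off1/k_on1 = 0.380/5.22e4), and a much
weaker bivalent component (`K_D2 ≈ 43 µM`) — the signature that observed
binding is dominated by the 1:1 interaction. `autoplot(fit)` overlays the
fitted curves on the traces; `tidy(fit)` lists every parameter.

The end-to-end analysis cross-validates the kinetic constant against the
steady-state isotherm from a low-density surface:

```r
run_binding_analysis(seed = 1)
#> <binding_report>
#>   kinetic bivalent/global fit: chisq=2666, K_D1=7.29 uM
#>   steady-state: K_D=5.92 uM
#>   kinetic/steady-state K_D ratio = 1.23 (consistent: TRUE)
```

The two routes agree within a factor of ~1.2, which is what licenses reading
the low-density steady-state constant as the monovalent affinity (the
steady-state value runs slightly strong because even a 244-RU surface
retains a little avidity).

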