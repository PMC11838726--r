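# trogoscale

Quantitative analysis of the macrophage decision between **trogocytosis**
(nibbling sub-micron membrane "bites" off a target) and **phagocytosis**
(complete engulfment) of antibody-opsonized targets.

Macrophages engaging an IgG-coated cell or vesicle through Fc receptors can
either engulf it whole or pinch off small pieces of its membrane. Two
measurable properties of the *target* control the outcome: its cortical (or
membrane) tension γ_t, and the antibody surface density ρ_AB. This package
implements the full desk-side analysis that connects them:

1. **Tension estimation** — micropipette aspiration records (suction
   pressure ΔP, pipette radius R_p, cell radius R_c) are converted to
   interfacial tension with the Young-Laplace law
   γ = ΔP / [2 (1/R_p − 1/R_c)], with tongue-length quality control.
2. **Cytometric classification** — three-channel event tables (CellTracker
   green = macrophage, pHrodo orange = acidified volume, AF647 red =
   antibody) are gated against control samples; events that are
   green+/red+/orange− are trogocytic, green+/red+/orange+ phagocytic.
   Efficiencies are percentages of all green+ events.
3. **Antibody surface density** — MESF calibration beads give a linear
   intensity → fluorophore map; densities are fluorophores / (fluorophores
   per IgG) / (π D²) in antibodies/µm².
4. **Dose-response** — trogocytic efficiency vs density is fitted with the
   logistic y = a / (1 + e^{−(x−ρ_crit)/d}); the inflection ρ_crit is the
   critical antibody density, with case-resampling bootstrap CIs, and
   ρ_crit scales linearly with target tension.
5. **Mechanical scaling model** — active normal stress σ ∝ ρ_AB balanced
   against tension gives a minimum deformation scale **R_min = γ_t / σ(ρ)**:
   bites can pinch off when R_min is smaller than the interface size R
   (trogocytosis), engulfment takes over when it is not (phagocytosis), and
   below ρ_min ≈ 100 antibodies/µm² there is no engagement. The package
   builds the full (γ, ρ) phase diagram and its analytic boundaries.
6. **Statistics** — Pearson correlation (efficiency vs tension) and one-way
   ANOVA with Tukey HSD pairwise comparisons, plus a structured JSON/Markdown
   report.

Every input can be simulated with known ground truth (`population_spec()`,
`aspiration_spec()`, `calibration_spec()`, `dose_response_spec()`,
`bite_size_spec()`), so the complete pipeline is testable without
experimental data.

## Worked example

```r
library(trogoscale)

# 20 aspiration measurements of a 0.1 mN/m cell, 5 Pa pressure noise
est <- estimate_tensions(generate_aspiration_table(aspiration_spec(
  true_tension = 0.1, pressure_noise_sd = 5, n_cells = 20, seed = 1)))
summarize_tensions(est)
#>   group  n mean_mN_per_m sd_mN_per_m
#> 1   all 20     0.1015877 0.007610448

# dose-response generated at (a = 70%, rho_crit = 300, d = 50), refitted
tab <- generate_dose_response(dose_response_spec(seed = 1))
bootstrap_rho_crit(tab, n_boot = 2000, seed = 2)
#> sigmoid fit (increasing form): a = 70.204%, rho_crit = 301.89 /um^2, d = 51.07 /um^2
#>   RSS = 17.66 over 30 points; converged: TRUE
#>   rho_crit 95% CI: [298.41, 305.02]

# scaling model: at gamma = 0.1 mN/m and 400 antibodies/um^2 (sigma = 100 Pa)
r_min(0.1, 400)                  # 1 (um) — the predicted bite scale
classify_regime(0.1, 400)        # "phagocytosis"  (R_min == R boundary)
classify_regime(0.02, 400)       # "trogocytosis"  (R_min = 0.2 um < R)

phase_diagram(10^seq(-2, 1, length.out = 50), 10^seq(1, 3.5, length.out = 50))
#> phase diagram: 50 x 50 grid
#>   no_engagement  1000 cells
#>   phagocytosis   920 cells
#>   trogocytosis   580 cells
```

The recovered tension (0.102 ± 0.008 mN/m) and inflection point (301.9,
CI [298.4, 305.0] against a generating 300) show the estimators recovering
their ground truth; `r_min` reproduces the model's 0.1–1 µm bite-scale
window across the measured tension range 0.01–0.1 mN/m.

An end-to-end run (simulate → tension → classify → density → fit-dose →
phase → report, all stages file-based with a hash manifest):

```r
res <- run_all(demo_config(seed = 1))   # writes CSVs, report.json/.md, manifest.json
```

or from the command line via the bundled script:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts","trogoscale",package="trogoscale"))') \
    run-all --seed 1 --outdir out/
```

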