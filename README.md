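# idpnmr

Quantitative analysis of intrinsically disordered proteins (IDPs) from
solution NMR and complementary biophysics, built tidyverse-style: data
frames in, tibbles out, ggplot2 figures, broom-style `tidy()`/`glance()`
methods.

The package targets the standard workup of a disordered RNA-binding
protein — a mostly unstructured chain with one stable α-helix and an
arginine-glycine (RGG) RNA-binding region, studied as truncated constructs
in full-length residue numbering:

* **15N relaxation** — per-residue R1 and R1ρ from monoexponential peak
  decays, `I(t) = I0·e^(−Rt)`, and conversion of R1ρ to R2 with the
  spin-lock tilt-angle correction
  `R1ρ = R1·cos²θ + R2·sin²θ`, `θ = arctan(ω1/Ω)`; heteronuclear NOE as
  the saturated/unsaturated intensity ratio with error propagation.
* **Ligand binding by CSP** — gyromagnetically weighted perturbations
  `Δδ = √(Δδ_H² + 0.1·Δδ_N²)`, per-residue maxima over a titration with an
  SD-of-Δδmax significance rule, normalized intensity/broadening profiles,
  and a global two-state fast-exchange Kd fit using the exact quadratic
  bound fraction.
* **Helicity from chemical shifts** — secondary shifts against a
  random-coil reference, a windowed helical-propensity estimator, and
  contiguous-segment calling.
* **Exact calculators** — IDP hydrodynamic radius scaling
  `Rh = 2.49·N^0.509` Å, sequence molecular weight, log-linear SEC
  calibration, mean residue ellipticity, alignment-column conservation
  masking, and FRAP recovery fitting.
* **Synthetic data with ground truth** — `synthetic_truth()` +
  `simulate_*()` generate residue-resolved datasets (relaxation decays,
  NOE pairs, titrations, shift tables) so every estimator is tested by
  parameter recovery; `run_pipeline()` chains the whole workflow under one
  seed and `recovery_report()` scores it against truth.

See the vignette (`vignettes/idp-nmr-analysis.Rmd`) for the models,
defaults and design choices.

## Worked example

A full synthetic study at the default conditions (212-residue construct
189–400, helix 289–299, RNA-binding segment 383–398, 1% intensity noise):

```r
library(idpnmr)

truth <- synthetic_truth(seed = 7)

# relaxation: fit R1 per residue, summarise helix vs whole chain
t1 <- simulate_relaxation(truth, experiment = "T1", seed = 8)
r1 <- fit_rates(t1)
profile_summary(r1, region = c(289, 299), col = "rate")
#>    mean     sd     n
#> 1  1.19 0.0215    11
profile_summary(r1, region = "all", col = "rate")
#> 1  1.49 0.0763   212
```

The helix relaxes at R1 ≈ 1.2 s⁻¹ against a chain average of ≈ 1.5 s⁻¹ —
the generated truth, recovered from noisy decays.

```r
# binding: CSP significance and a global Kd fit
tit <- simulate_titration(truth, seed = 9)
dmax <- delta_max_profile(tit)
attr(dmax, "threshold")
#> 0.0384
dmax$residue_number[dmax$significant]
#> 383 384 ... 398          # exactly the RNA-binding segment
fit <- fit_kd(tit, protein_conc = 50e-6)
fit
#> <kd_fit> Kd = 0.5 uM; 16 residues, 64 observations, RSS 9.603e-22

# helicity: propensity profile and segment calling
prop <- helix_propensity(simulate_shift_table(truth))
detect_segments(prop)
#>   first_residue last_residue length mean_propensity
#> 1           289          299     11           0.757

# hydrodynamics: polymer-scaling prediction vs a measured radius (Å)
hydro_summary(n_residues(construct("189-400", 189, 400)), rh_measured = 38)
#>   n_residues rh_predicted rh_predicted_nm rh_measured compaction_ratio
#> 1        212         38.0             3.8          38            0.999
```

The significance threshold (0.038 ppm) isolates exactly the 16 residues
carrying bound-state shifts; the fitted Kd reproduces the generator's
0.5 µM; the detected helix matches 289–299 with mean propensity 0.76
(population 0.85, eroded at the edges by the 5-residue window); and a
212-residue disordered chain is predicted at Rh = 3.8 nm.

Per-residue tracks plot directly:

```r
plot_residue_track(fit_rates(t1), col = "rate",
                   highlight = list(c(289, 299)), ylab = "R1 (1/s)")
autoplot(fit)   # binding isotherms, observed vs fitted
```

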