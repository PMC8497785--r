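---
title: "Quantitative NMR and biophysical analysis of disordered proteins with idpnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative NMR and biophysical analysis of disordered proteins with idpnmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpnmr)
```

## Scope and intended use

`idpnmr` implements the quantitative analysis layer used to characterise an
intrinsically disordered protein (IDP) by solution NMR and complementary
biophysics: per-residue 15N relaxation rates, chemical shift perturbation
(CSP) maps of ligand binding, chemical-shift-based helicity, and a set of
small exact calculators (hydrodynamic radius scaling, sequence molecular
weight, SEC calibration, mean residue ellipticity, alignment conservation,
FRAP recovery). The motivating system is an RGG-box RNA-binding protein: a
mostly disordered chain of a few hundred residues carrying one stable
\(\alpha\)-helix and a C-terminal RNA-interacting region, studied as
truncated constructs that keep full-length residue numbering.

The package operates downstream of spectral processing: its inputs are peak
lists, assigned chemical shift tables, and per-condition peak intensities,
not spectra. Peak picking, NUS reconstruction, and assignment are out of
scope, as are model-free dynamics analysis and Bloch–McConnell exchange
fitting.

Because the raw spectra behind a published study are usually not available,
the package ships a first-class synthetic-data generator
(`synthetic_truth()` and the `simulate_*()` family) that produces
residue-resolved datasets with known ground truth, so every analysis stage
is validated by parameter recovery rather than by eyeballing.

## Relaxation analysis

Peak intensities in a T1 or T1rho experiment decay monoexponentially with
the relaxation delay, \(I(t) = I_0 e^{-R t}\). `fit_monoexponential()` fits
this model by unweighted nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`), initialised from a log-linear regression on the positive
intensities. Negative intensities — legitimate at long delays under noise —
are excluded only from the initialiser, never from the fit. The rate
uncertainty comes from the fit covariance; a jackknife over delays is
available through `uncertainty = "jackknife"` for series where the
covariance estimate is distrusted. Residues measured at fewer than half the
delays are reported not-computed rather than fitted from too few points.

The rotating-frame rate mixes longitudinal and transverse relaxation
according to the tilt angle \(\theta\) of the effective field:

\[ R_{1\rho} = R_1\cos^2\theta + R_2\sin^2\theta, \qquad
   \theta = \arctan(\omega_1/\Omega), \]

where \(\omega_1\) is the spin-lock field strength (1400 Hz in the default
schedules) and \(\Omega\) the residue's offset from the spin-lock carrier.
`r2_from_r1rho()` inverts this exactly; both frequencies are taken in Hz
(the units cancel), the sign of \(\Omega\) is irrelevant, and the inversion
refuses offsets so far from resonance that \(\sin^2\theta < 10^{-12}\). The
forward model in the generator and this inversion are tested as an identity
across the full parameter range.

The heteronuclear NOE is the plain intensity ratio of the
proton-saturated to the unsaturated interleaved experiment
(`hetnoe_ratio()`), with first-order error propagation when per-peak noise
estimates are supplied. The default delay schedules
(`t1_delay_schedule()`: 40–800 ms; `t1rho_delay_schedule()`: 1–161 ms) are
the measurement schedules the analysis was designed around.

## Binding maps and the fast-exchange Kd

For a ligand in fast exchange, each observed peak sits at the
population-weighted average of its free and bound positions. Amide 1H and
15N shift changes are combined with the gyromagnetic weighting

\[ \Delta\delta = \sqrt{\Delta\delta_H^2 + 0.1\,\Delta\delta_N^2}, \]

and `delta_max_profile()` reports, per residue, the maximum \(\Delta\delta\)
over the titration relative to the apo spectrum — the maximum rather than
the endpoint, since broadening can make the last point unusable. A residue
is called significant when its \(\Delta\delta_{max}\) exceeds the standard
deviation of \(\Delta\delta_{max}\) over all residues. That threshold uses
the population standard deviation (divisor \(n\)) over every residue with a
computed value, zeros included; an `exclude` argument lets overlapped peaks
be removed from the threshold pool while still receiving a value.

Intensity broadening is summarised by `intensity_profile()`: intensities at
one titration point divided by the *average* apo intensity (one scalar, so
the apo reference line is flat), with each peak's ratio to its own apo
intensity as a secondary track.

`fit_kd()` estimates a shared dissociation constant by modelling each
candidate residue's CSP as \(f_b(\mathrm{ratio}; K_d)\,B_r\), with the
bound fraction \(f_b\) from the exact quadratic solution of the two-state
mass balance (`bound_fraction()`; protein dilution over the titration is
ignored, as the added volumes are negligible). The per-residue amplitudes
\(B_r\) are profiled out analytically, leaving a one-dimensional
optimisation over \(\log_{10} K_d\). When the titration never approaches
saturation the profile likelihood is flat from below and only a lower bound
on \(K_d\) is identified; the fit flags this (`non_identifiable`) instead of
reporting a spuriously precise number.

## Helicity from chemical shifts

`secondary_shifts()` subtracts residue-specific random-coil reference values
(`coil_shifts()`, embedded constants from the standard published
random-coil tables) from observed shifts. `helix_propensity()` converts
these to a per-residue population estimate: each atom's secondary shift is
divided by its canonical full-helix value (CA +2.8, CB −0.5, C′ +1.8,
Hα −0.3 ppm), atoms are averaged with weights proportional to the magnitude
of those reference shifts (larger reference deviations are more reliable),
and the per-residue scores are smoothed with a centred running mean of odd
width (default 5 residues, shrinking at chain ends) and clipped to
\([-1, 1]\). This is a deliberately transparent propensity estimator in the
spirit of SSP, not a port of it: published propensity algorithms differ in
reference tables and weighting, so values near a calling threshold may
differ between implementations. No re-referencing correction is applied —
inputs are assumed correctly referenced, and a referencing offset common to
observed and reference shifts cancels exactly.

`detect_segments()` calls maximal runs of residues at or above a propensity
threshold (default 0.5) of minimum length 4, bridging a single
sub-threshold residue flanked by passing ones. With a 5-residue smoothing
window, an 11-residue helix erodes by at most about one residue at each
edge; the defaults are chosen so a helix of that size survives calling.

## Exact calculators

* `rh_idp()` — hydrodynamic radius of a disordered chain,
  \(R_h = 2.49\,N^{0.509}\) Å; `rh_idp_nm()` reports nm at one decimal, the
  convention used when comparing with DLS. For the 212-residue construct it
  gives 3.8 nm.
* `mw_from_sequence()` — average-mass molecular weight (residue masses plus
  one water). The sequence is taken exactly as given; whether cloning-scar
  residues are included is the caller's decision.
* `sec_calibrate()` / `sec_predict()` — the standard log-linear SEC
  calibration, \(\log_{10} MW = a + bV\); with two standards the line is
  exact through both.
* `mean_residue_ellipticity()` — CD conversion
  \(\theta / (10\,l\,c\,(N-1))\), using the \(N-1\) peptide-bond
  convention for the residue count.
* `conservation_mask()` — an alignment column is conserved when the
  reference row's amino acid occurs, by strict identity (gaps never count),
  in at least `min_species` sequences (default 7). Similarity classes are
  deliberately out of scope.
* `fit_frap_recovery()` — single-exponential fluorescence recovery
  \(A(1 - e^{-kt}) + I_{post}\) on pre-bleach-normalised data; mobile
  fraction \(A + I_{post}\) relative to pre-bleach, plateau time
  \(\ln(20)/k\) (95% of the recoverable amplitude). Flat traces are flagged
  rate-unidentifiable rather than fitted.

## The synthetic generator and what it does (not) emulate

`synthetic_truth()` fixes a residue-resolved ground truth; the
`simulate_*()` functions produce datasets from it. Defaults encode the
study conditions of the motivating system:

| parameter | default | meaning |
|---|---|---|
| construct | 189–400 (212 residues) | full-length numbering |
| coil R1 / R2 / NOE | 1.5 s⁻¹ / 9.6 s⁻¹ / 0.4 | disordered baseline |
| helix 289–299 R1 / R2 / NOE | 1.2 s⁻¹ / 22.5 s⁻¹ / 0.75 | stable helix |
| helicity | 0.85 | helical population of 289–299 |
| binding segment | 383–398 | residues with bound-state shift offsets |
| broadened segment | 366–386 | RGG box with exchange broadening |
| Kd | 0.5 µM | sub-micromolar ligand affinity |
| titration | ratios 0, 2:5 … 8:5 at 50 µM protein | ligand:protein series |
| noise_sd | 0.01 | intensity noise, fraction of reference peak |
| spin-lock offsets | uniform ±700 Hz | exercises the tilt-angle correction nontrivially |

Noise is additive Gaussian on intensities; peak positions are exact unless
shift jitter is requested explicitly (`shift_noise_sd`, `jitter_ppm`).
Randomly drawn residue-level quantities (sequence, free peak positions,
offsets, bound-shift magnitudes) come from the truth's seed; noise comes
from a separate seed, so datasets simulated from one truth under different
noise seeds share an identical noiseless component. Random sequences avoid
proline, which carries no amide and would only punch holes in every track.

Exchange broadening is modelled phenomenologically — intensities inside the
broadened segment lose \(e^{-\beta f_b}\) with \(\beta\) the `extra_decay`
strength — not through Bloch–McConnell dynamics; the analyses that consume
it are rank-based or qualitative. Consequently, passing recovery tests
demonstrates correctness of the estimators under the stated statistical
model (monoexponential decays, Gaussian intensity noise, two-state fast
exchange, uniform helix population), not robustness to the pathologies of
real spectra: peak overlap, assignment errors, referencing offsets,
intermediate exchange lineshapes, or temperature-dependent effects.

## Numerical choices and degenerate inputs

* Monoexponential and FRAP fits run Levenberg–Marquardt with a maximum of
  200/500 iterations; failures and degenerate series return
  `converged = FALSE`, never an exception, so one bad residue cannot abort
  a pipeline run.
* The Kd profile search runs on \(\log_{10} K_d \in [-12, -2]\) with
  `optimize()` at tolerance 1e-10; an optimum within 0.05 log units of a
  boundary, or a curvature-based sd above ten times the estimate, flags
  non-identifiability.
* `bound_fraction()` clips the quadratic root into \([0, 1]\) to absorb
  floating-point excursions at the stoichiometric corner (\(K_d = 0\)).
* Ties and gaps in segment calling: runs split at numbering gaps, a single
  bridged residue must be numerically contiguous with both flanks, and
  intervals are reported in ascending order.
* Profile summaries use the arithmetic mean and sample sd over computed
  residues only; the CSP significance threshold uses the population sd, as
  stated above.

## Pipeline and recovery reporting

`run_pipeline()` chains the seven stages (simulate; T1; T1rho→R2; hetNOE;
CSP/broadening/Kd; helicity/segments; hydrodynamic summary) under one seed,
writes every per-residue track across the full construct range with
explicit `NA` markers, and emits a `manifest.json` recording the seed,
every parameter (including defaults applied implicitly), stage statuses and
output names; runs are byte-reproducible from the config.
`recovery_report()` closes the loop against the generating truth with bias,
RMSE and ±2 sd coverage per parameter. The bundled test suite exercises the
pipeline on a 60-residue construct and parameter-recovery batteries on
80–500 synthetic residues with up to a few hundred Monte-Carlo repeats —
sizes at which the whole suite runs in well under a minute while the
Monte-Carlo medians are stable.

## Known limitations

* The propensity estimator approximates SSP-style analysis; absolute values
  within ~0.1 of a threshold should not be over-interpreted, and β-strand
  or polyproline-II populations are not modelled.
* The Kd fit assumes pure fast exchange; residues in intermediate exchange
  (broadening) violate the model and should be excluded from
  `candidate_residues`.
* `read_nmrstar_shifts()` implements only the minimal atom-shift loop of
  NMR-STAR v3 (read-only); deposition numbering is resolved by an explicit
  `offset` argument, never guessed.
* The AUC, DLS-regularisation and droplet-imaging stages of a full
  biophysical workup are bookkeeping-only here: the package consumes their
  printed outputs (e.g. a measured \(R_h\)) but does not fit them.
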