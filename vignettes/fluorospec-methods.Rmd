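---
title: "fluorospec: methods, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluorospec: methods, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorospec)
```

## The measurement being modelled

A scanning spectrofluorometer excites a fresh tissue slice at a fixed
wavelength (266, 300 or 340 nm; 2 nm slit bandpass, 0.2 s integration) and
records the emitted intensity over an emission grid up to 650 nm. Three
endogenous fluorophores dominate: tryptophan in proteins (UV emission,
peak ~331–335 nm depending on excitation), the redox coenzyme NADH
(~435–492 nm — its apparent peak moves with the excitation context), and FAD
(~557 nm). Replicate scans are taken at several spots of the region of
interest. The discriminating observables between diseased (AD) and normal (N)
tissue are (i) peak intensities after normalizing to the AD group average
maximum, (ii) the peak-intensity ratio tryptophan/NADH (or NADH/FAD at
340 nm), and (iii) the extrema of the first derivative dI/dλ.

## Analysis pipeline and its conventions

1. **Averaging** (`average_group`): pointwise mean and *sample* SD across
   replicates; SD is defined as 0 for a single replicate.
2. **Normalization** (`normalize_to_ad_max`): every spectrum in the AD/N pair
   is divided by the maximum of the AD averaged spectrum. The AD average then
   peaks at exactly 1 (enforced to 1e-12); N intensities are unconstrained
   (an N average peak of 0.497 stays 0.497). The operation is idempotent.
   If only AD data exist, normalization still proceeds and the group
   comparison is skipped with a warning.
3. **Peak extraction** (`extract_peak`): argmax of intensity inside a
   fluorophore's assigned window, ties broken toward the shorter wavelength —
   deterministic and grid-independent. Default windows per excitation:
   266 nm → Trp [315, 355], NADH [420, 470]; 300 nm → Trp [320, 360],
   NADH [430, 510]; 340 nm → NADH [430, 480], FAD [525, 575].
4. **Ratios and folds** (`ratio_statistic`, `fold_change`): per-replicate
   peak ratios with mean and SD (scale-invariant by construction), and AD/N
   fold changes of mean peak intensities.
5. **Derivatives** (`first_derivative`): central differences on the raw
   averaged spectrum by default (the reference procedure's exact
   preprocessing is unstated, so the default adds nothing); one-sided
   differences at the two edge points, so the profile has full grid length.
   An optional Savitzky–Golay first derivative (quadratic local fit, odd
   window, default 5) is exposed for noisy data; it requires a uniform grid.
6. **Comparison** (`compare_groups`): two-sided Welch (unequal-variance)
   t-test. The reference work names no test; Welch is the defensible default
   because the two tissue conditions share no variance estimate.

### Rounding for reproduction

Printed tables round half *away from zero* (`round_half_up`), 3 decimals for
intensities, 2 for ratios and folds. Two conventions coexist for fold
changes: `"unrounded"` divides the raw replicate means, `"printed"` first
rounds each mean to 3 decimals. The published folds mix both — 1.58 (NADH,
266 nm) is only reproduced unrounded, 1.61 (NADH, 300 nm) only from the
printed means — so both modes are exposed and the regression table records
which mode each printed fold uses. The published *mean ratio* rows equal the
mean of the per-replicate ratio column, not the ratio of mean intensities
(these differ in the third decimal for some blocks); `table1_report` follows
the column-mean path.

### Known inconsistencies in the packaged table

Recomputing the printed mean rows from the printed replicate rows exposes two
cells that disagree with their own columns: the AD/340 nm peak-2 intensity
(recomputed 0.351 vs printed 0.352) and the N/340 nm ratio (recomputed 2.926
vs printed 2.928). The fixture ships the printed values verbatim, declares
both cells in `inconsistent_mean_cells`, and the regression check skips them;
everything else is reproduced exactly.

## The photophysical model

Brightness follows the textbook chain: quantum yield
$Q = K_r/(K_r + K_{nr})$ and detected intensity
$I = (\Omega/4\pi)\,Q\,n$ for $n$ excited molecules into solid angle
$\Omega$. $K_{nr}$ encodes coupling to the host environment — weaker coupling
means a smaller $K_{nr}$ and brighter emission. Tryptophan emission overlaps
NADH absorption, so the pair is FRET-coupled with transfer rate
$K_{DA} = (1/\tau_D)(R_0/R)^6$. The package completes this with the standard
transfer efficiency $E = K_{DA}/(K_{DA} + 1/\tau_D) = 1/(1+(R/R_0)^6)$ —
the only formula extrapolated beyond the printed model, flagged as such in
`fret_efficiency`'s documentation — and redistributes amplitudes as
$A_{Trp} \mapsto A_{Trp}(1-E)$, $A_{NADH} \mapsto A_{NADH} + g\,E\,A_{Trp}$
(transfer gain $g = 1$). The rate relation is printed as a proportionality;
treating it as equality is harmless here because constant factors are
absorbed into the calibrated amplitudes.

## What the simulator emulates, and what it does not

Each fluorophore is a single Gaussian band (width = σ): tryptophan σ = 25 nm,
NADH σ = 35 nm, FAD σ = 30 nm. The reference emission curves were not
digitized; broad single bands reproduce the smooth single-peaked tissue
profiles, and the NADH center is tabulated *per excitation* (435/492/462 nm)
exactly as the peak assignments label it. The 266 nm second-singlet
contribution to NADH is absorbed into the NADH base amplitude rather than
modelled separately.

Replicate variability is one multiplicative lognormal factor per replicate
(mean 1, CV 2.5%), shared across wavelengths — matching the replicate table,
where whole rows scale together — plus additive i.i.d. Gaussian noise with
SD 0.5% of the signal maximum (detector-dominated at fixed integration
time). Both levels are calibration choices on the order of the few-percent
scatter visible in the replicate table; neither is printed anywhere.
Negative draws are clipped at zero; in the far red tail the signal is
essentially zero, so clipping individual noise draws there is unavoidable —
the regression contract is that clipping never touches the peak-analysis
windows while noise < 5% and amplitudes ≥ 0.1.

Seeding: one root seed; each (condition, excitation, replicate) triple gets a
private stream via a stable polynomial string hash (all arithmetic below
2^36, exactly representable and platform-independent), so adding replicates
never perturbs existing ones and the caller's RNG state is never modified.

Deliberately **not** modelled: scattering and radiative transfer (emission is
collected from a thin surface layer and the scattering background is flat),
absorption/re-emission cascades, time-resolved kinetics, instrument drivers,
and the numeric derivative extrema of the reference figures (their source
spectra were never deposited — the package treats AD-vs-N derivative ordering
as a qualitative property only). A green simulator test therefore
establishes that the *pipeline* recovers what the generator encodes, not that
real AD tissue behaves like the presets.

## Preset calibration (frozen)

No amplitudes are printed, so presets are calibration artifacts of this
package, fixed once and not revisited:

* Geometry/photophysics constants: $\Omega = 0.5$ sr, $K_r = 10^8$ s⁻¹,
  $\tau_D = 2.6$ ns, $R_0 = 2.5$ nm (literature-scale for a Trp→NADH pair),
  $R_{AD} = 4.4$ nm, $R_N = 3.6$ nm. The AD distance is larger — the encoded
  disease hypothesis (tryptophan "caged", fewer host interactions, weaker
  transfer). The distances were chosen under a feasibility constraint:
  stronger coupling (e.g. $R_N = 3.2$ nm) would require a *negative* NADH
  base amplitude at 300 nm to hit the printed 0.100 peak, which is
  unphysical.
* Per-fluorophore excited populations $n$ and nonradiative rates $K_{nr}$
  were obtained by a fixed-point calibration of the *noiseless* simulator —
  run through the full pipeline (FRET, AD-max normalization, windowed
  extraction) — against the printed mean peak intensities, then frozen in
  `R/presets.R`. AD $K_{nr}$ is smaller than N $K_{nr}$ for every
  fluorophore; $n$ is shared across conditions. Because the printed AD/N
  brightness folds differ between excitations, the resulting Q values are
  effective per-excitation quantities, not intrinsic constants.
* Emission grids: 300–650 nm (266 nm excitation), 312–650 (300 nm),
  352–650 (340 nm), step 2 nm — matching the 2 nm slit bandpass (finer
  sampling than the bandpass carries no information) and respecting the
  scatter-exclusion rule λ_em > λ_ex + bandpass.

```{r presets}
cfg <- default_presets(266, "AD")
round(cfg$band_amplitudes, 4)
round(effective_amplitudes(cfg), 4)
```

## Numerical and degenerate-input choices

* Scan files: CSV `wavelength_nm,intensity`, `#` comments, one optional
  header; values written with 17 significant digits so write→read is the
  identity. Rows at or below λ_ex + bandpass are dropped at read time with a
  logged count; the second-order grating line at 2λ_ex is *not* dropped by
  default (266 nm scans carry genuine signal near 532 nm) but can be via
  `drop_second_order = TRUE`.
* Group grids must match exactly (1e-6 nm): replicates come from one
  programmed scan, so any mismatch is a data error, not float noise.
* Peak ties → shortest wavelength; `which.max` semantics, verified against
  an exhaustive-scan oracle on 1000 random spectra.
* Replicate counts: the acquisition description mentions both 3 and 5
  replicates per group; the packaged table has 5. The package fixes neither —
  groups accept any n ≥ 1, the fixture follows the table (n = 5), and the
  default presets simulate 5.
* Parameter recovery: the group-level ratio estimator used in the recovery
  tests is the peak ratio of the group-*averaged* spectrum (the reference
  procedure's own averaging-first order). Per-replicate argmax extraction on
  a weak denominator peak carries an order-statistic bias of roughly 3–4% at
  1% noise, which averaging over replicates before extraction reduces below
  2%; both paths are exposed, and the per-replicate path is what the
  table-style report uses.

## Known limitations

The presets reproduce printed *summary* statistics, not raw spectra; any
spectral feature beyond three smooth bands (Raman lines, water absorption,
grating artifacts) is absent. The printed significance value and derivative
extrema are not reproducible without the original scans and are deliberately
excluded from numeric checks. Absorbance correction, lamp referencing and
dark counts are out of scope — intensities are arbitrary units throughout.
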