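# fluorospec

Label-free fluorescence spectroscopy analysis for tissue autofluorescence,
plus a photophysics-based simulator of emission scans.

## What problem this package addresses

Native tissue fluorophores — tryptophan (emission ~330–350 nm), NADH
(~430–490 nm, excitation-dependent) and FAD (~530–560 nm) — report on protein
content and mitochondrial redox state without any exogenous label. In brain
tissue from an Alzheimer's-disease (AD) mouse model, emission scans taken on a
scanning spectrofluorometer at 266, 300 and 340 nm excitation are brighter
than in normal (N) tissue, and the *ratio* of the tryptophan peak to the NADH
peak increases. `fluorospec` is for spectroscopists who want to run that
analysis chain on their own scan files, and for methodologists who want a
fully simulated test bed for it.

## The model and statistics at the core

**Analysis.** Replicate scans per (condition, excitation) are averaged
pointwise (mean ± SD); all spectra in an AD/N pair are divided by the maximum
of the AD *averaged* spectrum, so the AD average peaks at exactly 1; peaks are
the windowed argmax per fluorophore; groups are summarised by per-replicate
peak ratios (e.g. I(Trp)/I(NADH)), AD/N fold changes of mean peak
intensities, first-derivative profiles dI/dλ with their ascending maximum and
descending minimum, and a two-sided Welch t-test on peak intensities.

**Simulation.** Each fluorophore contributes a Gaussian band whose amplitude
follows the standard photophysical chain

- quantum yield Q = K_r / (K_r + K_nr),
- detected intensity I = (Ω / 4π) · Q · n,

and the tryptophan→NADH donor–acceptor pair exchanges energy by Förster
resonance transfer, rate K_DA = (1/τ_D)(R₀/R)⁶, applied through the transfer
efficiency E = 1/(1 + (R/R₀)⁶): the donor amplitude is quenched by (1 − E)
and the acceptor gains E·A_donor. AD-like presets encode a larger
donor–acceptor distance R (weaker transfer → higher Trp/NADH ratio) and
smaller K_nr (weaker host-environment coupling → brighter emission).
Replicates share one multiplicative lognormal factor (CV 2.5%) plus additive
Gaussian noise (0.5% of the signal maximum).

## Worked example

```r
library(fluorospec)

td  <- file.path(tempdir(), "demo")
man <- run_simulate(td, seed = 42)          # 30 scan CSVs + manifest.yaml
s   <- run_analyze(man, file.path(td, "out"))

e <- s$excitations[["266"]]
cat(sprintf("Trp/NADH ratio (266 nm): AD %.2f +- %.2f | N %.2f +- %.2f\n",
            e$AD$ratio_mean, e$AD$ratio_sd, e$N$ratio_mean, e$N$ratio_sd))
cat(sprintf("Welch t = %.2f, p = %.2g; tryptophan fold change %.2f\n",
            e$comparison$statistic, e$comparison$p_value, e$fold_change_peak1))
```

prints

```
Trp/NADH ratio (266 nm): AD 3.65 +- 0.04 | N 2.91 +- 0.02
Welch t = 65.27, p = 1.7e-09; tryptophan fold change 1.99
```

i.e. the simulated AD group shows the published contrasts: a Trp/NADH ratio
near 3.7 vs 2.9 in the normal group, a ~2-fold brighter tryptophan peak, and
an overwhelmingly significant Welch comparison. The published summary table
itself is packaged and reproduced by

```r
run_reproduce_table1()      # prints the full table; "Regression check: PASS"
```

A command-line front end with the same three subcommands
(`simulate`, `analyze`, `reproduce-table1`) lives at
`system.file("exec", "fluorospec", package = "fluorospec")`.

## Layout

- `R/` — spectrum containers and scan/manifest I/O, photophysics, band
  shapes, simulator + calibrated presets, analysis pipeline, derivative
  module, CLI.
- `inst/extdata/table1.json` — the packaged published replicate table.
- `vignettes/fluorospec-methods.Rmd` — model, calibration and design notes.
- `tests/testthat/` — unit, property and acceptance suites.
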