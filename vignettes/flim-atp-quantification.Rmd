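---
title: "Quantifying intracellular ATP from FLIM-FRET biosensor images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracellular ATP from FLIM-FRET biosensor images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimatp)
```

## The measurement model

A FRET-based ATP sensor carries a donor fluorophore whose excited-state
lifetime is shortened when ATP binding brings the acceptor close. In a
pixel containing many sensor molecules, a fraction `f` is ATP-bound (donor
lifetime `tau_fret`) and `1 - f` is free (`tau_free`), so the photon-arrival
histogram is a two-component exponential mixture. Two features of the
acquisition shape the model:

* **Incomplete decay.** With lifetimes of 0.7–1.8 ns and a repetition
  period of 12.5 ns (80 MHz class), fluorescence excited by earlier pulses
  has not fully decayed when the next pulse arrives. Summing a
  mono-exponential over all prior pulses is a geometric series with the
  closed form `exp(-t/tau) / (1 - exp(-T/tau))` on `t in [0, T)`. The
  package uses this closed form everywhere
  (`model_incomplete_biexp()`); its correctness is checked against a
  literal summation over 12,000 pulses to a relative error below 1e-10.
* **No offset, no scatter.** Both are fixed at zero in the model, matching
  the analysis convention for this instrument class. Dark counts and
  scattered excitation light are therefore assumed negligible or removed
  upstream; data with substantial uncorrelated background will bias fits
  and should be background-subtracted first.

The per-pixel summary statistic is the amplitude-weighted mean lifetime
`Tm = a1% * t1 + a2% * t2`. It is deliberately the inference target rather
than the individual components: the bi-exponential likelihood is shallow
along trade-offs between `(a, t)` pairs, so `t1`/`t2` individually are
poorly identified at realistic photon budgets while `Tm` is stable (the
mono-exponential degeneracy test asserts `Tm` within 1% even when the
components are meaningless). FRET efficiency is `E = 1 - Tm/Tm_ref`, with
`Tm_ref` measured on a binding-dead sensor variant; values with
`Tm > Tm_ref` produce negative `E` that is flagged, never clamped.

## Fitting: numerical choices

* **Objective.** Variance-weighted least squares with
  `weight = 1/max(obs, 1)`, the standard TCSPC convention; the reduced
  chi-squared reported is this objective divided by
  `n_window_bins - 5` (two lifetimes, two amplitudes, one shift). An exact
  Poisson-deviance objective is available (`poisson_mle = TRUE`) but is
  not the default, to keep the reported chi-squared on its conventional
  scale.
* **Variable projection.** For fixed `(t1, t2, shift)` the two amplitudes
  solve a 2x2 weighted linear system in closed form (with a
  single-component fallback when the unconstrained solution goes
  negative), so the outer optimizer works in only three dimensions.
* **Multistart.** Nelder-Mead from three fixed initializations whose
  lifetime guesses come from the log-slope of the early and late tail.
  Remaining starts are skipped once a start reaches reduced chi-squared
  <= 1.3 — a speed device only; it cannot change which fits pass the
  acceptance gate, because any fit at or below 1.3 is already inside the
  0.7–2 band.
* **Fit window.** From the histogram peak channel to the last bin (tail
  fit), evaluated on the absolute time axis so that amplitude fractions
  keep their pulse-origin meaning. No instrument-response deconvolution is
  attempted; for simulated cubes with a Gaussian IRF the forward model
  convolves instead.
* **Spatial binning.** `fit_cube()` fits each pixel on the summed
  histogram of its 3x3 neighborhood by default (`spatial_bin = 1`), the
  same device instrument software uses to reach workable per-pixel photon
  counts. This matters for calibration: at 5000 photons/pixel unbinned,
  roughly a third of the 256 bins hold 0–1 photons, and with
  observation-based weights those bins dilute the chi-squared well below
  1 (median ~0.75), spilling outside the 0.7–2 acceptance band. At the
  ~45k binned photons the statistic centres on 1.0. The cost is spatial
  smoothing at compartment boundaries, acceptable because compartments are
  many pixels wide; set `spatial_bin = 0` to disable.
* **Gates.** Converged fit, reduced chi-squared in `[0.7, 2]`, and at
  least 100 photons (binned when binning is on). Both the photon floor
  and the binning radius are explicit configuration, since the original
  instrument-software settings for these are not recorded anywhere we
  could follow; defaults are documented choices, not reconstructions.

## Image pipeline

The photon (total-counts) image is normalized by local contrast —
`(I - mu_w)/max(sigma_w, eps)` over a square window via integral images,
then rescaled to [0, 1] — to flatten expression-level differences before
thresholding. The window must be *larger than a cell diameter*: a window
smaller than the structures it normalizes flattens cell interiors into the
noise. The pipeline default is 31 px for the default cell sizes and is
clamped to the image when scenes are small. The choice only affects which
pixels are segmented; all downstream statistics use fitted lifetimes, never
normalized intensities.

Nucleus pixels are zeroed before segmentation (the sensor in the nucleus
does not report cytosolic ATP), so they can never enter the ROI pool.
Segmentation is a global Otsu threshold followed by 8-connected components
with a minimum-size filter; both choices are configurable and deliberately
unclever — the synthetic scenes and typical sparse-labelling images have
high foreground contrast, and nothing downstream depends on segmentation
being better than "find the labelled cells". Compartment identity
(soma/axon) comes from the scene ground truth for synthetic data and from a
user-drawn mask for real data; telling a soma from an axon in a micrograph
is a judgement the text we follow made visually, and we do not pretend to
automate it.

ROIs are single pixels: each segmented, non-nucleus pixel whose fit passed
the gates contributes one row of `(cell_id, compartment, x, y)`, joined
against the fitted maps into a tidy parameter table.

## Statistics

* **Inference unit.** Pixels within a cell are strongly dependent
  (shared biology, shared optics, plus the deliberate spatial binning), so
  hypothesis tests default to cell-level means; pixel-level pooling is
  available for distribution displays. Published group sizes of the form
  "n = 36" are treated as cells.
* **Welch's t-test** in both raw-sample and summary-statistic
  `(mean, SEM, n)` forms; the two agree to 1e-10 on the same data (tested)
  and the summary form lets printed results be checked. Two-sided
  throughout.
* **Two-way ANOVA** uses Type II sums of squares, which reduce to the
  classical decomposition on balanced designs (tested against textbook
  arithmetic) and behave sensibly when cell counts are unequal, with the
  interaction dropped (and said so) when empty design cells make it
  inestimable. Pairwise follow-ups are Welch tests between levels of the
  first factor within each level of the second, Sidak-adjusted
  `p_adj = 1 - (1-p)^m`; Bonferroni is available.
* **KDE** curves integrate to 1 regardless of n — that is the whole point
  of "sample-size normalized" — with Silverman bandwidth by default and a
  fixed-bandwidth option for comparing conditions on equal smoothing.

## Metabolic assay calculators

Chromatogram peaks are integrated trapezoidally above a straight baseline
drawn between the retention-window endpoints; with a +/-4 sigma window this
under-recovers a pure Gaussian by ~0.11% (tail mass plus baseline
trapezoid), which the tests assert analytically rather than hide.
Calibration is least-squares through the origin per analyte. The derived
quantities are `ATP/ADP` and the adenylate energy charge
`(ATP + 0.5 ADP)/(ATP + ADP + AMP)`.

Flux (OCR/ECAR) rates use the Theil–Sen estimator — median of pairwise
slopes, deterministic, exact on clean lines, 29% breakdown — because the
source text says only "robust regression"; a Huber option is provided.
Cycle rates are averaged per injection block, technical-replicate wells are
pooled with equal weight, and the five-block protocol decomposes into:
non-mitochondrial OCR (post rotenone/antimycin), basal (pre-oligomycin
minus non-mito), ATP-linked (pre minus post oligomycin), proton leak (post
oligomycin minus non-mito), maximal capacity (post FCCP minus non-mito),
glycolytic increase and non-glycolytic ECAR. The oligomycin step supports
two readouts — the before/after difference and the above-non-mito
remainder — and the source material is ambiguous about which its leak
figure plots; both are therefore always reported, the identity
`basal = atp_linked + proton_leak` holds by construction, and group
comparisons of membrane leakiness should use `proton_leak_ocr`. Well
exclusion ("abnormal run behavior") is an explicit input flag, not an
automatic rule.

MTT viability normalizes each well to the mean of mock-treated wells of
the same cell line, keeping lines independent.

## The synthetic generator: what a green test establishes

The generator produces the *stated world* the pipeline is validated in:
disk somata with concentric nuclei and straight, fixed-width axons; ATP
set per compartment (default 4 mM soma, 2 mM axon — the soma-high gradient
the pipeline must resolve; magnitudes are configuration, not claims) with
Gaussian spatial jitter (0.15 mM SD); a Hill-curve sensor (kd 3.3 mM,
n = 2 — placeholder dose-response constants, since the real sensor's curve
is not pinned down by our sources; every check compares against generator
ground truth, never literature values); lifetimes 1750/700 ps chosen to
sit on the scale of published donor lifetimes; 256 bins of 48.8 ps at
T = 12.5 ns; Poisson photon noise around a 5000-photon default budget.
All randomness flows through explicit seeds; re-renders are bit-identical.

It does **not** emulate: optical blur, photobleaching, detector
afterpulsing or pile-up, autofluorescence background spectra, realistic
neuronal morphology, or vendor file formats. A green end-to-end test
therefore establishes that *the computation chain is correct and sensitive
at realistic photon statistics* — not that any biological effect size is
reproduced. Published absolute lifetime differences are measured data and
are out of reach of a desk-scale simulation; the end-to-end check instead
asserts the qualitative contract (a 25% somatic ATP reduction appears as a
significantly higher somatic `Tm` at 20 cells/group).

One deliberate choice in the recovery benchmark: the 32x32 cube used to
measure `Tm` recovery error holds ATP spatially constant, so that the 3x3
binning's neighborhood averaging measures pure estimator error rather than
mixing in smoothing of a spatially varying truth.

## Serialization

Decay cubes travel as sparse long-format CSV plus a JSON sidecar
(`n_bins`, `bin_width_ps`, `rep_period_ps`, seed/provenance), maps as CSV
matrices, tables as CSV with a `# units:` header line. Image-format
containers (TIFF) were dropped deliberately: no TIFF codec is available in
the supported dependency set, and plain text round-trips bit-exactly,
diffs, and needs no codec. Coordinates are 0-based `(x, y)` =
(column, row), origin top-left.

## Known limitations

* No instrument-response deconvolution: real data with a broad IRF needs
  its rising edge excluded (the tail fit does this) and very short
  lifetimes will bias.
* No global (image-wide shared-lifetime) fitting; every pixel is
  independent, which is honest but noisier than shared-parameter schemes.
* Segmentation is threshold-based; dense cultures with touching cells will
  merge labels.
* The ANOVA is fixed-effects only; nested designs (pixels in cells in
  wells in lines) beyond the cell-level collapse are out of scope.
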