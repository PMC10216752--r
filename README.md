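# flimatp

Compartment-resolved quantification of intracellular ATP from FLIM-FRET
biosensor images, plus the bulk metabolic-assay calculators that usually
accompany such experiments.

## The problem

Genetically encoded ATP sensors place an ATP-binding domain between a donor
(CFP) and an acceptor (YFP) fluorophore. ATP binding pulls the pair together
and increases FRET, which *shortens the donor's fluorescence lifetime* — so
the lifetime, imaged pixel by pixel with time-correlated single-photon
counting (TCSPC), is an intensity-independent readout of relative ATP. A
binding-dead sensor variant provides the donor lifetime without FRET, making
the measurement internally calibrated. Neurons make this interesting:
somata and axons of the same motoneuron can sit at different ATP levels, and
disease models (e.g. ALS mutations) shift them further.

`flimatp` implements the full analysis chain for such data:

1. **TCSPC fitting** — each pixel's photon-arrival histogram is fitted with
   a two-component *incomplete-decay* model. When lifetimes are comparable
   to the laser repetition period `T`, photons from earlier pulses pile into
   the histogram; summing the decay over all prior pulses gives

   `f(t) = Σᵢ aᵢ · exp(−t/τᵢ) / (1 − exp(−T/τᵢ))`, offset and scatter fixed
   at 0, with the channel shift optimized jointly. Fits are gated by reduced
   χ² (default 0.7–2) and a photon floor.

2. **Mean lifetime and FRET efficiency** — `Tm = a₁%·t₁ + a₂%·t₂` and
   `E = 1 − Tm/Tm_ref`, referenced to the non-binding sensor.

3. **Image pipeline** — local-contrast normalization of the photon image,
   nucleus zeroing, Otsu + connected-component segmentation, and
   single-pixel ROIs labelled soma/axon, joined back onto the fitted maps.

4. **Statistics** — cell-level aggregation (pixels within a cell are not
   independent), Welch's unequal-variance t-test (raw and summary-statistic
   forms), two-way ANOVA with Sidak-adjusted pairwise comparisons, and
   sample-size-normalized kernel density estimates.

5. **Metabolic assays** — HPLC peak integration and external-standard
   calibration, ATP/ADP ratio and adenylate energy charge
   `AEC = (ATP + 0.5·ADP)/(ATP + ADP + AMP)`, extracellular-flux
   (OCR/ECAR) rates by Theil–Sen robust regression with proton-leak /
   respiratory-capacity decomposition, and MTT viability normalization.

6. **Synthetic data** — a ground-truth-annotated generator for TCSPC neuron
   scenes (Hill-curve sensor, Poisson photon noise, soma/axon/nucleus
   geometry), chromatograms and flux plates, used to validate every stage
   end to end.

## Worked example

```r
library(flimatp)

sensor <- sensor_model()                    # kd 3.3 mM, Hill n 2,
atp_to_bound_fraction(4, sensor)            # tau 1750/700 ps
#> 0.595                                    # 4 mM ATP -> 59.5% bound

# fit one 45k-photon pixel simulated at 60% FRET fraction
acq <- acquisition_config()                 # 256 x 48.8 ps bins, T = 12.5 ns
tt  <- (1:256 - 0.5) * 48.8
mu  <- model_incomplete_biexp(tt, 0.6, 0.4, 700, 1750, 12500)
set.seed(1)
fit_pixel(rpois(256, mu / sum(mu) * 45000), acq)
#> <pixel_fit> t1 = 587 ps (50.7%), t2 = 1603 ps (49.3%), Tm = 1088 ps, chi2 = 0.89
```

The individual components wobble (the bi-exponential likelihood is shallow)
but `Tm` lands within ~3% of the true 1120 ps — which is why downstream
statistics run on `Tm`, not on `t1`/`t2`.

FRET efficiencies from published group means (reference sensor 1745 ps,
untreated 1283 ps, uncoupler-treated 1581 ps):

```r
fret_efficiency(1283, 1745)                       #> 0.2648
fret_efficiency(1581, 1745)                       #> 0.0940
relative_efficiency_change(0.0940, 0.2648)        #> 64.5  (% reduction)
welch_from_summary(1283, 32.05, 36, 1530, 44.99, 39)
#> t = 4.47, df = 67.5, p = 3.1e-05   (soma vs axon, consistent with p < 0.001)
```

A full synthetic experiment — two groups of 20 neurons, the "mutant" group
with 25% less somatic ATP — runs end to end with:

```r
res <- run_pipeline(pipeline_config(seed = 7))
res$effects   # mutant soma: delta Tm ~ +140 ps, p << 0.05, "lower relative ATP"
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "flimatp.R", package = "flimatp"))')
Rscript $CLI simulate --out sim --seed 1       # scenes, cubes, assay traces
Rscript $CLI fit      --cube sim/control/cube --out fits
Rscript $CLI stats    --table run/parameters.csv --ref control
Rscript $CLI assays   --chromatogram sim/chromatogram.csv
Rscript $CLI all      --out run --seed 1
```

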