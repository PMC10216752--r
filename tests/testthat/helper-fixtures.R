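# Shared fixtures, built once per test run (pixel fitting is the slow part).
# Everything is generated in code at fixed seeds; nothing is stored on disk.

.fixture_env <- new.env(parent = emptyenv())

# small two-cell scene fitted end to end; used by image-pipeline and stats
# tests that need a realistic fitted cube without refitting each time
fixture_fitted_scene <- function() {
  if (!is.null(.fixture_env$fitted)) return(.fixture_env$fitted)
  lay <- layout_cells(2, soma_radius = 4, nucleus_radius = 1,
                      axon_len = 8, soma_atp = 4, axon_atp = 2)
  scene <- build_scene(lay, sensor = sensor_model(), seed = 11)
  acq <- acquisition_config(photons_per_pixel = 5000, seed = 12)
  cube <- render_decay_cube(scene, acq)
  fm <- filter_fits(fit_cube(cube))
  img <- photon_image(cube)
  win <- min(31L, 2L * (min(dim(img)) %/% 2L) - 1L)
  nrm <- zero_nucleus(normalize_local_contrast(img, window = win),
                      scene$compartment_map)
  labels <- segment_cells(nrm, min_size = 10)
  .fixture_env$fitted <- list(scene = scene, acq = acq, cube = cube,
                              fm = fm, labels = labels, nrm = nrm)
  .fixture_env$fitted
}

# noise-free histogram on the default time base
noise_free_hist <- function(a1_pct = 0.6, t1 = 700, t2 = 1750,
                            total = 1e6, n_bins = 256, bin_width = 48.8,
                            rep_period = 12500) {
  tt <- (seq_len(n_bins) - 0.5) * bin_width
  curve <- model_incomplete_biexp(tt, a1_pct, 1 - a1_pct, t1, t2, rep_period)
  curve / sum(curve) * total
}

# independent trapezoidal quadrature for density checks
trapz_test <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2

# explicit summation over prior excitation pulses: the independent oracle
# for the closed-form incomplete model (geometric series summed literally)
brute_force_incomplete <- function(t_axis, tau, rep_period,
                                   n_pulses = 12000L) {
  vapply(t_axis, function(t)
    sum(exp(-(t + (0:(n_pulses - 1L)) * rep_period) / tau)), numeric(1))
}
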