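test_that("bound fraction follows the Hill curve and its edge cases", {
  s <- sensor_model(kd = 3.3, hill_n = 2)
  expect_equal(atp_to_bound_fraction(0, s), 0)
  expect_equal(atp_to_bound_fraction(3.3, s), 0.5)
  expect_equal(atp_to_bound_fraction(c(0, 3.3, 1e6), s)[3], 1, tolerance = 1e-9)
  # non-binding reference is flat zero
  mut <- sensor_model(kd = 3.3, hill_n = 2, binding_competent = FALSE)
  expect_equal(atp_to_bound_fraction(c(0, 3.3, 50), mut), c(0, 0, 0))
  # monotone non-decreasing
  atp <- seq(0, 12, by = 0.25)
  expect_true(all(diff(atp_to_bound_fraction(atp, s)) >= 0))
  expect_error(atp_to_bound_fraction(-1, s), "non-negative")
  expect_error(sensor_model(tau_free = 700, tau_fret = 1750), "tau_fret")
})

test_that("build_scene rasterizes geometry with exact ground truth", {
  cell <- cell_spec(c(16, 16), soma_radius = 6, nucleus_radius = 0)
  sc <- build_scene(cell, width = 32, height = 32, seed = 5)
  codes <- compartment_codes()
  # soma pixels are exactly the disk
  xs <- col(sc$cell_labels) - 1; ys <- row(sc$cell_labels) - 1
  disk <- (xs - 16)^2 + (ys - 16)^2 <= 36
  expect_identical(sc$compartment_map == codes[["soma"]], disk)
  expect_true(all(sc$atp_map >= 0))
  # expected_tm identity holds per pixel
  gt <- sc$ground_truth
  expect_equal(gt$expected_tm,
               gt$bound_fraction * gt$tau_fret +
                 (1 - gt$bound_fraction) * gt$tau_free)
  # determinism
  sc2 <- build_scene(cell_spec(c(16, 16), 6, 0), 32, 32, seed = 5)
  expect_identical(sc$atp_map, sc2$atp_map)
  expect_identical(sc$ground_truth, sc2$ground_truth)
})

test_that("nucleus pixels are inside their cell and axon Tm exceeds soma Tm at lower axon ATP", {
  lay <- layout_cells(3, soma_atp = 4, axon_atp = 2)
  sc <- build_scene(lay, seed = 2)
  codes <- compartment_codes()
  expect_true(all(sc$cell_labels[sc$compartment_map == codes[["nucleus"]]] > 0))
  gt <- sc$ground_truth
  # lower ATP -> less FRET -> longer lifetime in the axon
  expect_gt(mean(gt$expected_tm[gt$compartment == "axon"]),
            mean(gt$expected_tm[gt$compartment == "soma"]))
})

test_that("overlapping cells are rejected with a diagnostic", {
  cells <- list(cell_spec(c(10, 10), 5, 1), cell_spec(c(13, 10), 5, 1))
  expect_error(build_scene(cells, 32, 32), "overlaps")
})

test_that("raising ATP uniformly never increases expected Tm", {
  lay <- layout_cells(2, soma_atp = 2, axon_atp = 1)
  lo <- build_scene(lay, seed = 9)
  lay_hi <- layout_cells(2, soma_atp = 3, axon_atp = 2)
  hi <- build_scene(lay_hi, seed = 9)
  # same seed: identical noise draws, shifted means
  expect_true(all(hi$ground_truth$expected_tm <=
                    lo$ground_truth$expected_tm + 1e-9))
})

test_that("rendered cubes honour photon budget, background and determinism", {
  cell <- cell_spec(c(8, 8), soma_radius = 4, nucleus_radius = 0)
  sc <- build_scene(cell, 16, 16, seed = 1)
  acq <- acquisition_config(photons_per_pixel = 5000, seed = 21)
  cube <- render_decay_cube(sc, acq)
  tot <- photon_image(cube)
  cellpx <- sc$cell_labels > 0
  # Poisson mean: cube-average within 3 SD of budget
  n_cell <- sum(cellpx)
  expect_lt(abs(mean(tot[cellpx]) - 5000), 3 * sqrt(5000 / n_cell))
  # background contains only background counts (zero at default rate)
  expect_true(all(tot[!cellpx] == 0))
  # bit-identical re-render at the same seed, different at another
  expect_identical(cube$counts, render_decay_cube(sc, acq)$counts)
  acq2 <- acq; acq2$seed <- 22
  expect_false(identical(cube$counts, render_decay_cube(sc, acq2)$counts))
})

test_that("non-binding sensor renders a mono-exponential decay with the free lifetime", {
  mut <- sensor_model(binding_competent = FALSE)
  cell <- cell_spec(c(8, 8), soma_radius = 5, nucleus_radius = 0)
  sc <- build_scene(cell, 16, 16, sensor = mut, seed = 3)
  acq <- acquisition_config(photons_per_pixel = 20000, seed = 4)
  cube <- render_decay_cube(sc, acq)
  # empirical mean arrival time over cell pixels vs the moment of the
  # wrapped (incomplete) mono-exponential on the same discrete time base
  tt <- (seq_len(acq$n_bins) - 0.5) * acq$bin_width
  pooled <- apply(cube$counts, 3, function(sl) sum(sl[sc$cell_labels > 0]))
  emp_mean <- sum(tt * pooled) / sum(pooled)
  th <- model_incomplete_biexp(tt, 0, 1, 700, mut$tau_free, acq$rep_period)
  th_mean <- sum(tt * th) / sum(th)
  expect_lt(abs(emp_mean - th_mean), 3 * sd(rep(tt, pooled)) / sqrt(sum(pooled)))
})

test_that("chromatogram peaks integrate to amount x factor and reproduce deterministically", {
  ch <- generate_chromatogram(c(ATP = 2.5), calib = 1.7, noise_sd = 0)
  w <- attr(ch, "windows")
  a <- integrate_peaks(ch, w)
  expect_equal(unname(a), 2.5 * 1.7, tolerance = 2e-3)
  ch1 <- generate_chromatogram(c(ATP = 2, ADP = 1), noise_sd = 0.05, seed = 31)
  ch2 <- generate_chromatogram(c(ATP = 2, ADP = 1), noise_sd = 0.05, seed = 31)
  expect_identical(ch1$signal, ch2$signal)
  expect_warning(
    generate_chromatogram(c(A = 1, B = 1), retention = c(A = 3, B = 3.1),
                          peak_sigma = 0.2),
    "3 sigma")
})

test_that("flux generator encodes block levels in trace slopes", {
  d <- flux_design("wt", ocr_levels = c(60, 100, 40, 160, 10),
                   ecar_levels = c(10, 30, 35, 35, 8), n_wells = 2,
                   noise_sd = 0)
  plate <- generate_flux_traces(d, seed = 1)
  lv <- block_levels(plate)
  expect_equal(lv$pooled$ocr[match(flux_blocks(), lv$pooled$block)],
               c(60, 100, 40, 160, 10))
  # determinism with noise
  dn <- flux_design("wt", noise_sd = 0.4, n_wells = 3)
  p1 <- generate_flux_traces(dn, seed = 6)
  p2 <- generate_flux_traces(dn, seed = 6)
  expect_identical(p1$traces, p2$traces)
  expect_error(generate_flux_traces(d, points_per_cycle = 1), "2 time points")
})
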