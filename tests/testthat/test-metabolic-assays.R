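test_that("peak integration recovers Gaussian areas with baseline subtraction", {
  tt <- seq(0, 10, by = 0.002)
  tr <- data.frame(time = tt,
                   signal = 4.2 * dnorm(tt, 3, 0.1) + 0.5)  # flat baseline
  a <- integrate_peaks(tr, list(p = c(3 - 0.4, 3 + 0.4)))
  # analytic deficit of a +/- 4 sigma window with endpoint baseline:
  # tail mass 2*pnorm(-4) plus the baseline trapezoid 8*dnorm(4)
  expected <- 4.2 * (1 - 2 * pnorm(-4) - 8 * dnorm(4))
  expect_equal(a[["p"]], expected, tolerance = 1e-4)
  expect_lt(abs(a[["p"]] - 4.2) / 4.2, 2e-3)
  expect_equal(unname(integrate_peaks(
    data.frame(time = tt, signal = 0), list(p = c(1, 2)))), 0)
  # disjoint peaks integrate independently of each other's amplitude
  two <- function(amp2) data.frame(
    time = tt, signal = 3 * dnorm(tt, 2, 0.08) + amp2 * dnorm(tt, 6, 0.08))
  w <- list(p1 = c(1.6, 2.4), p2 = c(5.6, 6.4))
  expect_equal(integrate_peaks(two(1), w)[["p1"]],
               integrate_peaks(two(50), w)[["p1"]], tolerance = 1e-9)
  expect_error(integrate_peaks(tr, list(p = c(9, 12))), "outside")
  expect_error(integrate_peaks(tr, list(a = c(1, 3), b = c(2, 4))),
               "overlap")
})

test_that("through-origin calibration is linear and robust to mild noise", {
  expect_equal(as.numeric(calibrate(c(ATP = 10), 10, 2)), 2)
  expect_equal(as.numeric(calibrate(c(ATP = 20), 10, 2)), 4)
  # 3-point standards with 1% noise recover the factor within 2%
  set.seed(55)
  k_true <- 1.8
  amounts <- c(1, 5, 10)
  areas <- k_true * amounts * (1 + rnorm(3, 0, 0.01))
  cc <- calibrate(c(ATP = 9), areas, amounts)
  expect_lt(abs(attr(cc, "factors")[["ATP"]] - k_true) / k_true, 0.02)
  expect_error(calibrate(c(ATP = 1), 0, 1), "zero standard")
})

test_that("adenylate energy charge and ATP/ADP ratio follow their definitions", {
  expect_equal(adenylate_energy_charge(5, 0, 0), 1)
  expect_equal(adenylate_energy_charge(0, 3, 0), 0.5)
  expect_equal(adenylate_energy_charge(16.25, 1, 0.25), 16.75 / 17.5)
  expect_equal(round(adenylate_energy_charge(16.25, 1, 0.25), 4), 0.9571)
  expect_error(adenylate_energy_charge(0, 0, 0), "empty")
  expect_error(adenylate_energy_charge(-1, 1, 1), "non-negative")
  # bounded and monotone in ATP at fixed ADP + AMP
  atp <- seq(0, 30, by = 0.5)
  aec <- adenylate_energy_charge(atp, 2, 1)
  expect_true(all(aec >= 0 & aec <= 1))
  expect_true(all(diff(aec) > 0))
  expect_equal(atp_adp_ratio(16.25, 1), 16.25)
  expect_equal(atp_adp_ratio(3, 3), 1)
  expect_equal(atp_adp_ratio(0, 2), 0)
  expect_error(atp_adp_ratio(1, 0), "undefined")
  p <- nucleotide_panel(16.25, 1, 0.25)
  expect_equal(p$atp_adp_ratio, 16.25)
  expect_equal(p$aec, 16.75 / 17.5)
})

test_that("noise-free chromatogram round trip reproduces generator AEC", {
  concs <- c(AMP = 1, ADP = 1, ATP = 16.25)
  ch <- generate_chromatogram(concs, calib = c(1.3, 0.8, 1.1), noise_sd = 0)
  areas <- integrate_peaks(ch, attr(ch, "windows"))
  truth <- attr(ch, "ground_truth")
  std <- list(AMP = truth$area[truth$analyte == "AMP"],
              ADP = truth$area[truth$analyte == "ADP"],
              ATP = truth$area[truth$analyte == "ATP"])
  amt <- list(AMP = 1, ADP = 1, ATP = 16.25)
  conc <- calibrate(areas, std, amt)
  aec <- adenylate_energy_charge(conc[["ATP"]], conc[["ADP"]], conc[["AMP"]])
  aec_true <- (16.25 + 0.5) / 18.25
  expect_lt(abs(aec - aec_true) / aec_true, 0.005)
})

test_that("Theil-Sen slope is exact on lines, outlier-proof, robust option agrees", {
  t7 <- 0:6
  expect_equal(rate_robust(t7, 3 * t7 + 1), 3)
  y <- 3 * t7 + 1; y[4] <- y[4] + 100
  expect_equal(rate_robust(t7, y), 3)
  expect_equal(rate_robust(t7, rep(5, 7)), 0)
  expect_equal(rate_robust(t7, 2.5 * t7 - 4, method = "huber"), 2.5,
               tolerance = 1e-8)
  expect_error(rate_robust(rep(1, 5), 1:5), "identical")
  # equals OLS on noiseless collinear data
  expect_equal(rate_robust(t7, -1.2 * t7 + 7),
               unname(coef(lm(I(-1.2 * t7 + 7) ~ t7))[2]))
})

test_that("block levels pool technical replicates with equal well weights", {
  d <- flux_design("wt", ocr_levels = c(60, 100, 40, 160, 10), n_wells = 3,
                   noise_sd = 0)
  plate <- generate_flux_traces(d, seed = 2)
  lv <- block_levels(plate)
  expect_equal(nrow(lv$well_levels), 15)  # 3 wells x 5 blocks
  expect_equal(sort(unique(lv$pooled$n_wells)), 3)
  # excluded wells are absent from pooling
  plate2 <- exclude_wells(plate, "wt_w01")
  lv2 <- block_levels(plate2)
  expect_false("wt_w01" %in% lv2$well_levels$well)
  expect_equal(sort(unique(lv2$pooled$n_wells)), 2)
  expect_error(exclude_wells(plate, "nope"), "unknown wells")
  plate3 <- exclude_wells(plate, unique(plate$traces$well))
  expect_warning(block_levels(plate3), "all wells excluded")
})

test_that("respiration metrics follow the stress-test arithmetic identically", {
  lv <- data.frame(block = flux_blocks(),
                   ocr = c(60, 100, 40, 160, 10),
                   ecar = c(10, 30, 35, 35, 8))
  m <- respiration_metrics(lv)
  expect_equal(m$proton_leak_ocr, 30)
  expect_equal(m$atp_linked_ocr, 60)
  expect_equal(m$basal_ocr, 90)
  expect_equal(m$max_capacity_ocr, 150)
  expect_equal(m$non_mito_ocr, 10)
  expect_equal(m$glycolytic_increase_ecar, 20)
  expect_equal(m$non_glycolytic_ecar, 8)
  # identity by construction
  expect_equal(m$basal_ocr, m$atp_linked_ocr + m$proton_leak_ocr)
  # leak of zero when post-oligomycin equals non-mitochondrial
  lv0 <- lv; lv0$ocr[3] <- 10
  expect_equal(respiration_metrics(lv0)$proton_leak_ocr, 0)
  expect_error(respiration_metrics(lv[-3, ]), "five blocks")
})

test_that("a mutant plate with extra leak is detected by the Welch test", {
  wt <- flux_design("wt", ocr_levels = c(60, 100, 40, 160, 10),
                    n_wells = 8, noise_sd = 0.6, well_sd = 2)
  mu <- flux_design("mutant", ocr_levels = c(60, 100, 55, 160, 10),
                    n_wells = 8, noise_sd = 0.6, well_sd = 2)
  plate <- generate_flux_traces(list(wt, mu), seed = 19)
  lv <- block_levels(plate)
  leaks <- lapply(split(lv$well_levels, lv$well_levels$group),
                  function(g) {
                    oligo <- g$ocr[g$block == "oligomycin"]
                    nm <- g$ocr[g$block == "rot_aa_2dg"]
                    oligo - nm
                  })
  w <- welch_ttest(leaks$mutant, leaks$wt)
  expect_gt(w$mean_diff, 0)
  expect_lt(w$p, 0.05)
})

test_that("MTT normalization is per line against mock wells", {
  plate <- data.frame(
    line = rep(c("wt", "mut"), each = 4),
    treatment = rep(c("mock", "mock", "cccp", "rotenone"), 2),
    absorbance = c(1.0, 1.2, 0.55, 0.9, 0.5, 0.6, 0.11, 0.3))
  out <- mtt_normalize(plate)
  expect_equal(mean(out$viability[out$line == "wt" &
                                    out$treatment == "mock"]), 1)
  expect_equal(mean(out$viability[out$line == "mut" &
                                    out$treatment == "mock"]), 1)
  expect_equal(out$viability[out$line == "mut" & out$treatment == "cccp"],
               0.11 / 0.55)
  # half-signal treatment reads 0.5
  half <- data.frame(line = "l", treatment = c("mock", "drug"),
                     absorbance = c(2, 1))
  expect_equal(mtt_normalize(half)$viability[2], 0.5)
  expect_error(mtt_normalize(data.frame(line = "l", treatment = "drug",
                                        absorbance = 1)), "no mock")
})
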