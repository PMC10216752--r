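#' Generate a synthetic chromatogram
#'
#' Sum of Gaussian elution peaks (area proportional to amount times a
#' per-analyte response factor) over a flat baseline, plus optional
#' Gaussian detector noise. Ground-truth amounts, factors, areas and the
#' default integration windows (retention time +/- 4 sigma) are attached,
#' so the peak-integration/calibration chain can be validated round-trip.
#' Default elution order is AMP < ADP < ATP, configurable.
#'
#' @param concs Named amounts per analyte (arbitrary units).
#' @param calib Named area-per-amount response factors (recycled if
#'   length 1).
#' @param noise_sd Detector noise SD (signal units).
#' @param seed Integer seed for the noise draw.
#' @param retention Named retention times (same order/names as `concs`).
#' @param peak_sigma Peak SD(s), time units.
#' @param baseline Constant baseline level.
#' @param t_max,dt Trace extent and sampling interval.
#' @return A `chromatogram` object: data.frame `time`/`signal` with
#'   attributes `ground_truth` (analyte, retention, sigma, amount, factor,
#'   area), `windows`, and `overlap_warning` if any two peaks sit closer
#'   than 3 combined sigmas.
#' @export
generate_chromatogram <- function(concs,
                                  calib = 1,
                                  noise_sd = 0, seed = 1,
                                  retention = NULL,
                                  peak_sigma = 0.08,
                                  baseline = 0, t_max = 8, dt = 0.004) {
  stopifnot(!is.null(names(concs)), all(concs >= 0))
  k <- length(concs)
  if (is.null(retention)) {
    default_rt <- c(AMP = 2, ADP = 3.5, ATP = 5)
    retention <- if (all(names(concs) %in% names(default_rt)))
      default_rt[names(concs)]
    else seq(1.5, t_max - 1.5, length.out = k)
    names(retention) <- names(concs)
  }
  stopifnot(length(retention) == k)
  if (anyDuplicated(retention))
    stop("retention times must be distinct per analyte", call. = FALSE)
  calib <- rep_len(calib, k); peak_sigma <- rep_len(peak_sigma, k)

  ord <- order(retention)
  gap <- diff(retention[ord])
  sig_sum <- peak_sigma[ord][-1] + peak_sigma[ord][-k]
  overlap <- k > 1 && any(gap < 3 * sig_sum)
  if (isTRUE(overlap))
    warning("peaks closer than 3 sigma: integration windows overlap",
            call. = FALSE)

  tt <- seq(0, t_max, by = dt)
  area <- as.numeric(concs) * calib
  signal <- rep(baseline, length(tt))
  for (i in seq_len(k))
    signal <- signal + area[i] * stats::dnorm(tt, retention[i], peak_sigma[i])
  if (noise_sd > 0)
    signal <- signal + with_seed(seed,
                                 stats::rnorm(length(tt), 0, noise_sd))

  truth <- data.frame(analyte = names(concs), retention = as.numeric(retention),
                      sigma = peak_sigma, amount = as.numeric(concs),
                      factor = calib, area = area, stringsAsFactors = FALSE)
  windows <- lapply(seq_len(k), function(i)
    c(max(retention[i] - 4 * peak_sigma[i], 0),
      min(retention[i] + 4 * peak_sigma[i], t_max)))
  names(windows) <- names(concs)

  out <- data.frame(time = tt, signal = signal)
  attr(out, "ground_truth") <- truth
  attr(out, "windows") <- windows
  attr(out, "overlap_warning") <- isTRUE(overlap)
  class(out) <- c("chromatogram", "data.frame")
  out
}

#' Design one group of flux-assay wells
#'
#' True per-block OCR/ECAR levels for a set of replicate wells of one
#' biological group, in injection order (see [flux_blocks()]).
#'
#' @param group Group (biological replicate / condition) label.
#' @param ocr_levels,ecar_levels Numeric length-5 true levels per block.
#' @param n_wells Technical-replicate wells.
#' @param noise_sd Sensor noise SD added to each raw trace point.
#' @param well_sd Between-well SD of the true level.
#' @return A `flux_design` row list.
#' @export
flux_design <- function(group = "wt",
                        ocr_levels = c(60, 100, 40, 160, 10),
                        ecar_levels = c(10, 30, 35, 35, 8),
                        n_wells = 6L, noise_sd = 0, well_sd = 0) {
  stopifnot(length(ocr_levels) == 5L, length(ecar_levels) == 5L,
            n_wells >= 1L, noise_sd >= 0, well_sd >= 0)
  structure(list(group = group, ocr_levels = ocr_levels,
                 ecar_levels = ecar_levels, n_wells = as.integer(n_wells),
                 noise_sd = noise_sd, well_sd = well_sd),
            class = "flux_design")
}

#' Generate synthetic extracellular-flux plate traces
#'
#' Emulates the five-block injection protocol (baseline; glucose/pyruvate;
#' oligomycin; FCCP; rotenone/antimycin A + 2-DG), each block measured in
#' three cycles. Each measurement cycle yields a short raw sensor trace
#' whose slope encodes the rate: the oxygen and pH signals fall linearly
#' at the well's true OCR/ECAR (signal units per minute) plus noise, so
#' downstream robust regression recovers the level. Ground truth is
#' attached per well and block.
#'
#' @param designs A [flux_design()] or list of them (one per group).
#' @param seed Integer seed.
#' @param n_cycles Measurement cycles per block.
#' @param points_per_cycle Samples per measurement trace (>= 2).
#' @param cycle_minutes Duration of one measurement, minutes.
#' @return A `flux_plate` object: `traces` (long data.frame: well, group,
#'   block, cycle, time, o2, ph), `truth` (well x block true levels),
#'   `excluded` (character vector of well ids, empty by default).
#' @export
generate_flux_traces <- function(designs, seed = 1, n_cycles = 3L,
                                 points_per_cycle = 5L,
                                 cycle_minutes = 3) {
  if (inherits(designs, "flux_design")) designs <- list(designs)
  stopifnot(length(designs) >= 1L, n_cycles >= 1L)
  if (points_per_cycle < 2L)
    stop("need at least 2 time points per measurement to define a slope",
         call. = FALSE)
  blocks <- flux_blocks()
  tt <- seq(0, cycle_minutes, length.out = points_per_cycle)

  traces <- list(); truth <- list()
  with_seed(seed, {
    for (d in designs) {
      stopifnot(inherits(d, "flux_design"))
      for (wi in seq_len(d$n_wells)) {
        well <- sprintf("%s_w%02d", d$group, wi)
        ocr_w <- d$ocr_levels + stats::rnorm(5, 0, d$well_sd)
        ecar_w <- d$ecar_levels + stats::rnorm(5, 0, d$well_sd)
        truth[[length(truth) + 1L]] <- data.frame(
          well = well, group = d$group, block = blocks,
          ocr_true = ocr_w, ecar_true = ecar_w, stringsAsFactors = FALSE)
        for (b in seq_along(blocks)) for (cy in seq_len(n_cycles)) {
          o2 <- 150 - ocr_w[b] * tt
          ph <- 80 - ecar_w[b] * tt
          if (d$noise_sd > 0) {
            o2 <- o2 + stats::rnorm(length(tt), 0, d$noise_sd)
            ph <- ph + stats::rnorm(length(tt), 0, d$noise_sd)
          }
          traces[[length(traces) + 1L]] <- data.frame(
            well = well, group = d$group, block = blocks[b], cycle = cy,
            time = tt, o2 = o2, ph = ph, stringsAsFactors = FALSE)
        }
      }
    }
    NULL
  })
  structure(list(traces = do.call(rbind, traces),
                 truth = do.call(rbind, truth),
                 excluded = character(0), seed = seed),
            class = "flux_plate")
}

#' @export
print.flux_plate <- function(x, ...) {
  cat(sprintf("<flux_plate> %d wells x %d blocks, %d excluded\n",
              length(unique(x$traces$well)),
              length(unique(x$traces$block)), length(x$excluded)))
  invisible(x)
}

#' Flag wells for exclusion from pooling
#' @param plate A `flux_plate`.
#' @param wells Character well ids to exclude (abnormal run behavior).
#' @return The plate with the exclusion list extended.
#' @export
exclude_wells <- function(plate, wells) {
  stopifnot(inherits(plate, "flux_plate"))
  unknown <- setdiff(wells, unique(plate$traces$well))
  if (length(unknown))
    stop("unknown wells: ", paste(unknown, collapse = ", "), call. = FALSE)
  plate$excluded <- union(plate$excluded, wells)
  plate
}
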