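#' TCSPC acquisition settings
#'
#' Describes the photon-counting acquisition used to render (and later
#' interpret) a decay cube. Defaults correspond to a typical 80 MHz-class
#' pulsed-diode setup: 12.5 ns repetition period sampled into 256 bins of
#' 48.8 ps. The photon budget, instrument-response width and background are
#' stand-ins -- real acquisition metadata is rarely published -- and are all
#' configurable.
#'
#' @param n_bins Number of histogram bins.
#' @param bin_width Bin width, ps. `n_bins * bin_width` must not exceed
#'   `rep_period`.
#' @param rep_period Laser repetition period, ps.
#' @param photons_per_pixel Mean photon count per cell pixel.
#' @param irf_shift Instrument shift in channels (may be fractional).
#' @param irf_sigma Gaussian instrument-response SD, ps; 0 = ideal pulse.
#' @param background_rate Background counts per bin per pixel.
#' @param seed Integer seed for the Poisson draw.
#' @return An `acquisition_config` object.
#' @export
acquisition_config <- function(n_bins = 256L, bin_width = 48.8,
                               rep_period = 12500, photons_per_pixel = 5000,
                               irf_shift = 0, irf_sigma = 0,
                               background_rate = 0, seed = 1) {
  stopifnot(n_bins >= 8, bin_width > 0, photons_per_pixel > 0,
            irf_sigma >= 0, background_rate >= 0)
  if (n_bins * bin_width > rep_period)
    stop("n_bins * bin_width must not exceed rep_period", call. = FALSE)
  structure(list(n_bins = as.integer(n_bins), bin_width = bin_width,
                 rep_period = rep_period,
                 photons_per_pixel = photons_per_pixel,
                 irf_shift = irf_shift, irf_sigma = irf_sigma,
                 background_rate = background_rate, seed = seed),
            class = "acquisition_config")
}

#' Construct a decay cube
#'
#' A decay cube is the raw FLIM data container: a 3-D array of photon
#' counts indexed `[y, x, bin]` plus the acquisition metadata needed to
#' interpret the bin axis.
#'
#' @param counts Non-negative integer array, dim `c(height, width, n_bins)`.
#' @param bin_width Bin width, ps.
#' @param rep_period Repetition period, ps.
#' @param provenance Free-text provenance string.
#' @return A `decay_cube` object.
#' @export
decay_cube <- function(counts, bin_width, rep_period, provenance = "") {
  stopifnot(is.array(counts), length(dim(counts)) == 3L,
            all(counts >= 0), bin_width > 0)
  if (dim(counts)[3] * bin_width > rep_period)
    stop("n_bins * bin_width must not exceed rep_period", call. = FALSE)
  structure(list(counts = counts, bin_width = bin_width,
                 rep_period = rep_period,
                 n_bins = dim(counts)[3],
                 provenance = provenance),
            class = "decay_cube")
}

#' @export
print.decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<decay_cube> %dx%d px, %d bins x %.3g ps (T = %.4g ps), %.3g photons total\n",
    d[2], d[1], d[3], x$bin_width, x$rep_period, sum(x$counts)))
  invisible(x)
}

#' Total photon image of a cube
#' @param cube A [decay_cube()].
#' @return Matrix `[y, x]` of per-pixel total counts.
#' @export
photon_image <- function(cube) {
  stopifnot(inherits(cube, "decay_cube"))
  apply(cube$counts, c(1, 2), sum)
}

# circular Gaussian convolution along the channel axis (kernel sums to 1)
irf_kernel <- function(n_bins, bin_width, sigma_ps) {
  half <- (seq_len(n_bins) - 1)
  d <- pmin(half, n_bins - half) * bin_width
  k <- exp(-0.5 * (d / sigma_ps)^2)
  k / sum(k)
}

circ_convolve <- function(curve, kernel) {
  Re(stats::fft(stats::fft(curve) * stats::fft(kernel), inverse = TRUE)) /
    length(curve)
}

#' Render a synthetic TCSPC decay cube from a scene
#'
#' Each cell pixel's expected decay is the bound-fraction-weighted mixture
#' of two incomplete mono-exponential decays (FRET and free lifetime of the
#' sensor), optionally convolved with a Gaussian instrument response and
#' shifted along the channel axis, scaled so the expected total equals
#' `photons_per_pixel`, with `background_rate` counts per bin added
#' everywhere. Background pixels carry only background counts. Counts are
#' drawn Poisson under the acquisition seed; the draw is bit-reproducible.
#'
#' @param scene A [build_scene()] result.
#' @param acq An [acquisition_config()].
#' @param sensor A [sensor_model()]; defaults to the scene's own sensor.
#' @return A [decay_cube()] whose provenance records the seed.
#' @export
render_decay_cube <- function(scene, acq = acquisition_config(),
                              sensor = NULL) {
  stopifnot(inherits(scene, "scene"), inherits(acq, "acquisition_config"))
  if (is.null(sensor)) sensor <- scene$sensor
  stopifnot(inherits(sensor, "sensor_model"))

  h <- scene$height; w <- scene$width; nb <- acq$n_bins
  tt <- (seq_len(nb) - 0.5) * acq$bin_width
  e_fret <- model_incomplete_biexp(tt, 1, 0, sensor$tau_fret, sensor$tau_free,
                                   acq$rep_period)
  e_free <- model_incomplete_biexp(tt, 0, 1, sensor$tau_fret, sensor$tau_free,
                                   acq$rep_period)
  if (acq$irf_sigma > 0) {
    k <- irf_kernel(nb, acq$bin_width, acq$irf_sigma)
    e_fret <- pmax(circ_convolve(e_fret, k), 0)
    e_free <- pmax(circ_convolve(e_free, k), 0)
  }
  if (acq$irf_shift != 0) {
    e_fret <- apply_shift(e_fret, acq$irf_shift)
    e_free <- apply_shift(e_free, acq$irf_shift)
  }

  bf_map <- matrix(0, h, w)
  cellpx <- scene$cell_labels != 0L
  bf_map[cellpx] <- atp_to_bound_fraction(scene$atp_map[cellpx], sensor)

  # expected curves: [pixel, bin]; row-normalized to the photon budget
  npx <- h * w
  lam <- outer(as.vector(bf_map), e_fret) +
    outer(1 - as.vector(bf_map), e_free)
  lam <- lam / rowSums(lam) * acq$photons_per_pixel
  lam[!as.vector(cellpx), ] <- 0
  lam <- lam + acq$background_rate

  counts <- with_seed(acq$seed,
                      stats::rpois(npx * nb, as.vector(lam)))
  counts <- array(as.integer(counts), dim = c(h, w, nb))
  decay_cube(counts, acq$bin_width, acq$rep_period,
             provenance = sprintf("synthetic render, seed=%s", acq$seed))
}
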