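#' Local-contrast normalization via integral images
#'
#' Subtracts the local mean and divides by the local standard deviation,
#' both computed over a square window with box sums (truncated at the image
#' border), then rescales the result affinely to `[0, 1]`. This compensates
#' for varying expression levels/illumination before segmentation; it is
#' invariant to global affine intensity changes `I -> a*I + b` (a > 0) away
#' from the `eps` floor. Downstream statistics use fitted lifetimes, never
#' these normalized intensities, so the normalization only affects which
#' pixels are segmented.
#'
#' @param image Numeric matrix.
#' @param window Odd window side length, >= 3, no larger than the image.
#' @param eps Floor on the local SD to avoid division blow-up in flat
#'   regions.
#' @return Matrix of the same size, values in `[0, 1]` (constant input
#'   yields a constant output).
#' @export
normalize_local_contrast <- function(image, window = 15, eps = 1e-6) {
  stopifnot(is.matrix(image))
  if (window < 3 || window %% 2 != 1)
    stop("window must be odd and at least 3", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  if (window > h || window > w)
    stop("window must not exceed the image size", call. = FALSE)
  r <- (window - 1L) %/% 2L

  box_sum <- function(m) {
    # summed-area table with zero padding, then clamped window sums
    sat <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed SAT
    sat <- t(sat)
    sat <- rbind(0, cbind(0, sat))
    y0 <- pmax(seq_len(h) - r - 1L, 0L); y1 <- pmin(seq_len(h) + r, h)
    x0 <- pmax(seq_len(w) - r - 1L, 0L); x1 <- pmin(seq_len(w) + r, w)
    s <- sat[y1 + 1L, x1 + 1L, drop = FALSE] -
      sat[y0 + 1L, x1 + 1L, drop = FALSE] -
      sat[y1 + 1L, x0 + 1L, drop = FALSE] +
      sat[y0 + 1L, x0 + 1L, drop = FALSE]
    cnt <- outer(y1 - y0, x1 - x0)
    list(sum = s, n = cnt)
  }

  b1 <- box_sum(image)
  b2 <- box_sum(image^2)
  mu <- b1$sum / b1$n
  v <- pmax(b2$sum / b1$n - mu^2, 0)
  z <- (image - mu) / pmax(sqrt(v), eps)
  rng <- range(z)
  if (diff(rng) == 0) return(matrix(0.5, h, w))
  (z - rng[1]) / diff(rng)
}

#' Zero the nucleus region of an image
#'
#' Nuclear pixels contain sensor but no cytosolic signal of interest; they
#' are zeroed before segmentation so they never enter the ROI pool.
#'
#' @param image Numeric matrix.
#' @param nucleus_mask Logical matrix of the same size (or a compartment
#'   map, in which case pixels equal to the `nucleus` code are zeroed).
#' @return The image with masked pixels set to 0.
#' @export
zero_nucleus <- function(image, nucleus_mask) {
  if (!is.logical(nucleus_mask))
    nucleus_mask <- nucleus_mask == compartment_codes()[["nucleus"]]
  stopifnot(is.matrix(image), identical(dim(image), dim(nucleus_mask)))
  image[nucleus_mask] <- 0
  image
}

#' Otsu threshold of an image in [0, 1]
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param n_levels Histogram resolution.
#' @return Threshold value.
#' @export
otsu_threshold <- function(image, n_levels = 256L) {
  v <- as.vector(image)
  stopifnot(all(v >= 0), all(v <= 1))
  breaks <- seq(0, 1, length.out = n_levels + 1L)
  cnt <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                       n_levels), nbins = n_levels)
  p <- cnt / sum(cnt)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_levels]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# connected components, 8-connectivity, iterative flood fill
label_components <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  labels <- matrix(0L, h, w)
  nb_dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- 0L
  for (start in which(fg & labels == 0L)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    labels[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      py <- (p - 1L) %% h + 1L; px <- (p - 1L) %/% h + 1L
      ny <- py + nb_dy; nx <- px + nb_dx
      okn <- ny >= 1L & ny <= h & nx >= 1L & nx <= w
      q <- (nx[okn] - 1L) * h + ny[okn]
      q <- q[fg[q] & labels[q] == 0L]
      if (length(q)) { labels[q] <- cur; stack <- c(stack, q) }
    }
  }
  labels
}

#' Segment cells from a normalized image
#'
#' Global threshold (Otsu by default) followed by 8-connected component
#' labelling; components smaller than `min_size` pixels are discarded and
#' labels renumbered consecutively. Background is label 0.
#'
#' @param image Numeric matrix in `[0, 1]` (e.g. from
#'   [normalize_local_contrast()]).
#' @param threshold `"otsu"` or a numeric threshold in `[0, 1]`.
#' @param min_size Minimum component size in pixels.
#' @return Integer label matrix.
#' @export
segment_cells <- function(image, threshold = "otsu", min_size = 20L) {
  stopifnot(is.matrix(image), min_size >= 1)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(image)
  else as.numeric(threshold)
  fg <- image > thr
  if (!any(fg)) {
    warning("empty foreground after thresholding", call. = FALSE)
    return(matrix(0L, nrow(image), ncol(image)))
  }
  labels <- label_components(fg)
  sizes <- tabulate(labels)
  keep <- which(sizes >= min_size)
  relab <- integer(max(labels, 1L))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(image), ncol(image))
  nz <- labels > 0L
  out[nz] <- relab[labels[nz]]
  out
}

#' Build the single-pixel ROI set
#'
#' One ROI entry per segmented, non-nucleus pixel whose decay fit was
#' accepted, labelled with its compartment (soma or axon) from the
#' compartment map. Segmented pixels with no compartment assignment are
#' dropped (their count is reported in the `dropped_no_compartment`
#' attribute); nucleus pixels never appear.
#'
#' @param label_map Integer label matrix from [segment_cells()].
#' @param compartment_map Integer compartment-code matrix (see
#'   [compartment_codes()]); for real data, a user-drawn mask rasterized to
#'   the same codes.
#' @param fitmap A [filter_fits()] result (must carry `accepted`).
#' @return A data.frame of class `pixel_roi_set` with columns `cell_id`,
#'   `compartment`, `x`, `y` (0-based, x = column).
#' @export
make_pixel_rois <- function(label_map, compartment_map, fitmap) {
  stopifnot(inherits(fitmap, "fitmap"),
            identical(dim(label_map), dim(compartment_map)),
            identical(dim(label_map), dim(fitmap$tm)))
  if (is.null(fitmap$accepted))
    stop("fitmap must be gated with filter_fits() first", call. = FALSE)
  codes <- compartment_codes()
  in_cell <- label_map > 0L
  cyto <- compartment_map == codes[["soma"]] |
    compartment_map == codes[["axon"]]
  keep <- in_cell & cyto & fitmap$accepted
  dropped <- sum(in_cell & fitmap$accepted &
                   compartment_map == codes[["background"]])
  if (!any(keep))
    warning("no accepted in-cell pixels; ROI set is empty", call. = FALSE)
  idx <- which(keep)
  out <- data.frame(
    cell_id = label_map[idx],
    compartment = ifelse(compartment_map[idx] == codes[["soma"]],
                         "soma", "axon"),
    x = (col(label_map))[idx] - 1L,
    y = (row(label_map))[idx] - 1L,
    stringsAsFactors = FALSE
  )
  attr(out, "dropped_no_compartment") <- dropped
  class(out) <- c("pixel_roi_set", "data.frame")
  out
}

#' Extract the per-pixel FLIM parameter table
#'
#' Joins the ROI set onto the fitted parameter maps: one row per ROI pixel
#' with all fit parameters. This is the "data pool" consumed by the
#' statistics layer.
#'
#' @param fitmap A [fit_cube()] / [filter_fits()] result.
#' @param rois A [make_pixel_rois()] result.
#' @return data.frame with columns `cell_id`, `compartment`, `x`, `y`,
#'   `t1`, `t2`, `a1_pct`, `a2_pct`, `chi2`, `tm`, `n_photons`
#'   (lifetimes in ps).
#' @export
extract_parameter_table <- function(fitmap, rois) {
  stopifnot(inherits(fitmap, "fitmap"), nrow(rois) >= 1L)
  h <- nrow(fitmap$tm)
  idx <- rois$x * h + rois$y + 1L
  data.frame(
    cell_id = rois$cell_id, compartment = rois$compartment,
    x = rois$x, y = rois$y,
    t1 = fitmap$t1[idx], t2 = fitmap$t2[idx],
    a1_pct = fitmap$a1_pct[idx], a2_pct = fitmap$a2_pct[idx],
    chi2 = fitmap$chi2[idx], tm = fitmap$tm[idx],
    n_photons = fitmap$n_photons[idx],
    stringsAsFactors = FALSE
  )
}

#' Mean intensity within a thresholded (mitochondrial) mask
#'
#' Builds a binary mask by thresholding the intensity image and returns the
#' mean intensity inside the mask together with the mask area -- the
#' membrane-potential-dye readout used for compartment comparisons.
#'
#' @param intensity_image Numeric matrix.
#' @param mask_threshold Pixels strictly above this value enter the mask.
#' @return List with `mean` (NA and `empty = TRUE` when the mask is empty),
#'   `area` (pixels) and `empty` flag.
#' @export
mito_mask_mean <- function(intensity_image, mask_threshold) {
  stopifnot(is.matrix(intensity_image), length(intensity_image) > 0)
  mask <- intensity_image > mask_threshold
  if (!any(mask))
    return(list(mean = NA_real_, area = 0L, empty = TRUE))
  list(mean = mean(intensity_image[mask]), area = sum(mask), empty = FALSE)
}
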