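#' Specify one neuron for a synthetic scene
#'
#' Geometry is deliberately simple: a disk soma with a concentric disk
#' nucleus and an optional straight axon of fixed width leaving the soma.
#' That is enough to carry the property the imaging pipeline must resolve --
#' different ATP levels in different sub-compartments of the same cell --
#' without pretending to emulate real neuronal morphology.
#'
#' @param soma_center `c(x, y)` pixel coordinates (0-based, x = column).
#' @param soma_radius Soma radius in pixels (>= 2).
#' @param nucleus_radius Nucleus radius in pixels (< `soma_radius`); 0 for
#'   no nucleus.
#' @param axon_to `c(x, y)` end point of the axon, or `NULL` for no axon.
#' @param axon_width Axon thickness in pixels.
#' @param soma_atp,axon_atp Mean ATP concentration (mM) in each compartment.
#'   Axons default lower than somas, mirroring the compartment gradient the
#'   pipeline is designed to detect; magnitudes are configuration, not claims.
#' @param atp_sd Pixel-to-pixel spatial SD of ATP around the compartment
#'   mean (mM).
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(soma_center, soma_radius = 6, nucleus_radius = 2,
                      axon_to = NULL, axon_width = 2,
                      soma_atp = 4, axon_atp = 2, atp_sd = 0.15) {
  stopifnot(length(soma_center) == 2L, soma_radius >= 2,
            nucleus_radius >= 0, nucleus_radius < soma_radius,
            soma_atp >= 0, axon_atp >= 0, atp_sd >= 0)
  if (!is.null(axon_to)) stopifnot(length(axon_to) == 2L, axon_width >= 1)
  structure(list(soma_center = as.numeric(soma_center),
                 soma_radius = soma_radius, nucleus_radius = nucleus_radius,
                 axon_to = if (is.null(axon_to)) NULL else as.numeric(axon_to),
                 axon_width = axon_width, soma_atp = soma_atp,
                 axon_atp = axon_atp, atp_sd = atp_sd),
            class = "cell_spec")
}

#' Lay out a column of cells for a group simulation
#'
#' Packs `n_cells` somata on a jittered grid with rightward axons, for use
#' with [build_scene()] when simulating one experimental group of neurons.
#'
#' @param n_cells Number of cells.
#' @param width,height Scene size in pixels (chosen automatically when `NULL`).
#' @param soma_radius,nucleus_radius,axon_len,axon_width Geometry parameters.
#' @param soma_atp,axon_atp,atp_sd Passed to [cell_spec()].
#' @return List with `cells` (list of [cell_spec()]), `width`, `height`.
#' @export
layout_cells <- function(n_cells, width = NULL, height = NULL,
                         soma_radius = 4, nucleus_radius = 1,
                         axon_len = 10, axon_width = 2,
                         soma_atp = 4, axon_atp = 2, atp_sd = 0.15) {
  stopifnot(n_cells >= 1)
  pitch_x <- 2 * soma_radius + axon_len + 6
  pitch_y <- 2 * soma_radius + 4
  ncol_grid <- max(1L, ceiling(sqrt(n_cells)))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  if (is.null(width)) width <- ncol_grid * pitch_x + 4
  if (is.null(height)) height <- nrow_grid * pitch_y + 4
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    gx <- (i - 1L) %% ncol_grid
    gy <- (i - 1L) %/% ncol_grid
    cx <- 2 + gx * pitch_x + soma_radius + 1
    cy <- 2 + gy * pitch_y + soma_radius + 1
    axon_to <- if (axon_len > 0) c(cx + soma_radius + axon_len, cy) else NULL
    cells[[i]] <- cell_spec(c(cx, cy), soma_radius, nucleus_radius,
                            axon_to = axon_to, axon_width = axon_width,
                            soma_atp = soma_atp, axon_atp = axon_atp,
                            atp_sd = atp_sd)
  }
  list(cells = cells, width = width, height = height)
}

#' Compartment codes used in scene maps
#' @return Named integer vector mapping compartment names to map codes.
#' @export
compartment_codes <- function() {
  c(background = 0L, soma = 1L, axon = 2L, nucleus = 3L)
}

# pixel masks for one cell on a width x height canvas; returns a list of
# index vectors into the [height x width] matrix
cell_masks <- function(cell, width, height) {
  xs <- matrix(rep(0:(width - 1L), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1L), times = width), nrow = height)
  dx <- xs - cell$soma_center[1]; dy <- ys - cell$soma_center[2]
  soma <- dx^2 + dy^2 <= cell$soma_radius^2
  nucleus <- if (cell$nucleus_radius > 0)
    dx^2 + dy^2 <= cell$nucleus_radius^2 else soma & FALSE
  axon <- soma & FALSE
  if (!is.null(cell$axon_to)) {
    p0 <- cell$soma_center; p1 <- cell$axon_to
    v <- p1 - p0; len2 <- sum(v^2)
    if (len2 > 0) {
      tproj <- ((xs - p0[1]) * v[1] + (ys - p0[2]) * v[2]) / len2
      tproj <- pmin(pmax(tproj, 0), 1)
      ddx <- xs - (p0[1] + tproj * v[1]); ddy <- ys - (p0[2] + tproj * v[2])
      axon <- (ddx^2 + ddy^2 <= (cell$axon_width / 2)^2) & !soma
    }
  }
  list(soma = which(soma & !nucleus), nucleus = which(nucleus),
       axon = which(axon))
}

#' Build a ground-truth annotated synthetic neuron scene
#'
#' Rasterizes a list of [cell_spec()]s onto a `width` x `height` canvas,
#' producing cell-label and compartment maps, a per-pixel ATP map with
#' spatial noise, and a ground-truth table giving each cell pixel's ATP,
#' sensor bound fraction and expected amplitude-weighted mean lifetime
#' `f * tau_fret + (1 - f) * tau_free`. Nucleus pixels belong to their cell
#' but carry no sensor signal downstream (they are zeroed by the image
#' pipeline); they still receive the soma ATP value in the map.
#'
#' @param cells List of [cell_spec()]s (or the result of [layout_cells()],
#'   in which case `width`/`height` are taken from it).
#' @param width,height Canvas size in pixels.
#' @param sensor A [sensor_model()].
#' @param seed Integer seed controlling the spatial ATP noise.
#' @return A `scene` object: `width`, `height`, `cell_labels` (integer
#'   matrix, 0 = background), `compartment_map` (codes per
#'   [compartment_codes()]), `atp_map` (mM), `ground_truth` (data.frame),
#'   `sensor`, `seed`. Matrices are indexed `[y + 1, x + 1]` for 0-based
#'   pixel coordinates `(x, y)` with x = column, origin top-left.
#' @export
build_scene <- function(cells, width = 64, height = 64,
                        sensor = sensor_model(), seed = 1) {
  if (is.list(cells) && !is.null(cells$cells)) {
    width <- cells$width; height <- cells$height; cells <- cells$cells
  }
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  stopifnot(length(cells) >= 1, inherits(sensor, "sensor_model"),
            width >= 8, height >= 8)
  lapply(cells, function(cl)
    if (!inherits(cl, "cell_spec")) stop("cells must be cell_spec objects"))

  labels <- matrix(0L, height, width)
  comp <- matrix(0L, height, width)
  atp <- matrix(0, height, width)
  codes <- compartment_codes()
  truth <- vector("list", length(cells))

  with_seed(seed, {
    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      m <- cell_masks(cl, width, height)
      own <- c(m$soma, m$nucleus, m$axon)
      if (length(m$soma) < 1L)
        stop(sprintf("cell %d has no soma pixels inside the canvas", i),
             call. = FALSE)
      if (any(labels[own] != 0L))
        stop(sprintf("cell %d overlaps cell %d; adjust the layout", i,
                     labels[own][labels[own] != 0L][1L]), call. = FALSE)
      labels[own] <- i
      comp[m$soma] <- codes[["soma"]]
      comp[m$nucleus] <- codes[["nucleus"]]
      comp[m$axon] <- codes[["axon"]]
      atp[m$soma] <- pmax(cl$soma_atp + stats::rnorm(length(m$soma), 0, cl$atp_sd), 0)
      atp[m$nucleus] <- pmax(cl$soma_atp + stats::rnorm(length(m$nucleus), 0, cl$atp_sd), 0)
      atp[m$axon] <- pmax(cl$axon_atp + stats::rnorm(length(m$axon), 0, cl$atp_sd), 0)
    }
    NULL
  })

  idx <- which(labels != 0L)
  comp_names <- names(codes)[match(comp[idx], codes)]
  bf <- atp_to_bound_fraction(atp[idx], sensor)
  truth <- data.frame(
    cell_id = labels[idx],
    compartment = comp_names,
    x = (col(labels))[idx] - 1L,
    y = (row(labels))[idx] - 1L,
    atp = atp[idx],
    bound_fraction = bf,
    tau_free = sensor$tau_free,
    tau_fret = sensor$tau_fret,
    expected_tm = expected_tm(bf, sensor),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$cell_id, truth$y, truth$x), , drop = FALSE]
  rownames(truth) <- NULL

  structure(list(width = width, height = height, cell_labels = labels,
                 compartment_map = comp, atp_map = atp,
                 ground_truth = truth, sensor = sensor, seed = seed),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %dx%d px, %d cell(s), %d annotated pixel(s)\n",
              x$width, x$height, max(x$cell_labels), nrow(x$ground_truth)))
  invisible(x)
}
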