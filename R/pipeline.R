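#' Configure an end-to-end simulation + analysis run
#'
#' One configuration object drives the whole chain: scene generation,
#' decay-cube rendering, pixel fitting, chi-squared gating, image
#' segmentation, ROI extraction and group statistics. Every stage's seed
#' is derived deterministically from the single `seed`, so a config
#' reproduces its outputs exactly.
#'
#' @param groups Named list; each element is a list of arguments for
#'   [layout_cells()] (e.g. `n_cells`, `soma_atp`, `axon_atp`). Group
#'   names become the `group` column of all outputs.
#' @param seed Master seed.
#' @param sensor A [sensor_model()].
#' @param acq An [acquisition_config()]; its seed is re-derived per group.
#' @param fit A [fit_options()] list.
#' @param chi2_lo,chi2_hi,min_photons Gate passed to [filter_fits()].
#' @param window Local-contrast window (odd); should exceed the cell
#'   diameter so cell interiors are not flattened away.
#' @param min_size Minimum segment size in pixels.
#' @param reference Name of the reference group for effect tables.
#' @param level Inference unit for summaries/tests ("cell" or "pixel").
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(groups = list(
                              control = list(n_cells = 20, soma_atp = 4,
                                             axon_atp = 2),
                              mutant = list(n_cells = 20, soma_atp = 3,
                                            axon_atp = 2)),
                            seed = 1,
                            sensor = sensor_model(),
                            acq = acquisition_config(),
                            fit = fit_options(),
                            chi2_lo = 0.7, chi2_hi = 2.0,
                            min_photons = 100,
                            window = 31, min_size = 10,
                            reference = names(groups)[1],
                            level = "cell") {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)),
            reference %in% names(groups))
  structure(list(groups = groups, seed = seed, sensor = sensor, acq = acq,
                 fit = fit, chi2_lo = chi2_lo, chi2_hi = chi2_hi,
                 min_photons = min_photons, window = window,
                 min_size = min_size, reference = reference, level = level),
            class = "pipeline_config")
}

#' Run the full pipeline on synthetic scenes
#'
#' For each group: build the scene, render the decay cube, fit every
#' pixel, gate fits, normalize the photon image, zero the nucleus, segment
#' cells, build single-pixel ROIs and extract the parameter table. Then
#' summarize by group and compartment and compare every group against the
#' reference within each compartment.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, parameter tables,
#'   summaries, effect tables and a JSON run manifest are written there.
#' @return List: `table` (pooled parameter table), `summary`
#'   (group x compartment), `effects` (per compartment vs reference),
#'   `scenes`, `fitmaps`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  tables <- list(); scenes <- list(); fitmaps <- list()
  stage_counts <- list()

  for (i in seq_along(config$groups)) {
    gname <- names(config$groups)[i]
    lay <- do.call(layout_cells, config$groups[[i]])
    scene <- build_scene(lay, sensor = config$sensor,
                         seed = child_seed(config$seed, 2L * i))
    acq <- config$acq
    acq$seed <- child_seed(config$seed, 2L * i + 1L)
    cube <- render_decay_cube(scene, acq)
    fm <- filter_fits(fit_cube(cube, config$fit),
                      config$chi2_lo, config$chi2_hi, config$min_photons)
    img <- photon_image(cube)
    nrm <- normalize_local_contrast(img, window = min(config$window,
                                                      2L * (min(dim(img)) %/% 2L) - 1L))
    nrm <- zero_nucleus(nrm, scene$compartment_map)
    labels <- segment_cells(nrm, min_size = config$min_size)
    rois <- make_pixel_rois(labels, scene$compartment_map, fm)
    tab <- extract_parameter_table(fm, rois)
    tab$cell_id <- sprintf("%s_c%03d", gname, tab$cell_id)
    tab$group <- gname
    tables[[gname]] <- tab
    scenes[[gname]] <- scene
    fitmaps[[gname]] <- fm
    stage_counts[[gname]] <- list(
      truth_pixels = nrow(scene$ground_truth),
      fitted = sum(fm$reason == "ok" | fm$reason == "chi2"),
      accepted = sum(fm$accepted),
      roi_pixels = nrow(tab))
  }

  table <- do.call(rbind, tables)
  rownames(table) <- NULL
  summary <- aggregate_by(table, keys = c("group", "compartment"),
                          level = config$level)
  effects <- do.call(rbind, lapply(unique(table$compartment), function(cp) {
    sub <- table[table$compartment == cp, , drop = FALSE]
    if (!config$reference %in% sub$group) return(NULL)
    ef <- compare_conditions(sub, config$reference, group = "group",
                             level = config$level)
    ef$compartment <- cp
    ef
  }))
  manifest <- list(package = "flimatp",
                   version = as.character(utils::packageVersion("flimatp")),
                   seed = config$seed,
                   groups = names(config$groups),
                   reference = config$reference,
                   level = config$level,
                   stage_counts = stage_counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_parameter_table(table, file.path(out_dir, "parameters.csv"))
    data.table::fwrite(summary, file.path(out_dir, "summary.csv"))
    data.table::fwrite(effects, file.path(out_dir, "effects.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(table = table, summary = summary, effects = effects,
       scenes = scenes, fitmaps = fitmaps, manifest = manifest)
}

#' Write a full synthetic dataset to disk
#'
#' Generates and serializes one scene + decay cube per group, a demo
#' chromatogram and a demo flux plate, with every ground-truth table --
#' the `simulate` entry point of the command-line interface.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
simulate_dataset <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory exists and is not empty; use force = TRUE",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(config$groups)) {
    gname <- names(config$groups)[i]
    lay <- do.call(layout_cells, config$groups[[i]])
    scene <- build_scene(lay, sensor = config$sensor,
                         seed = child_seed(config$seed, 2L * i))
    acq <- config$acq
    acq$seed <- child_seed(config$seed, 2L * i + 1L)
    cube <- render_decay_cube(scene, acq)
    write_scene(scene, file.path(out_dir, gname))
    write_decay_cube(cube, file.path(out_dir, gname, "cube"))
  }
  chrom <- generate_chromatogram(c(AMP = 0.25, ADP = 1, ATP = 16.25),
                                 calib = c(1.1, 1.0, 0.9),
                                 noise_sd = 0.02,
                                 seed = child_seed(config$seed, 101L))
  data.table::fwrite(as.data.frame(chrom),
                     file.path(out_dir, "chromatogram.csv"))
  data.table::fwrite(attr(chrom, "ground_truth"),
                     file.path(out_dir, "chromatogram_truth.csv"))
  plate <- generate_flux_traces(
    list(flux_design("wt"),
         flux_design("mutant", ocr_levels = c(60, 100, 55, 160, 10))),
    seed = child_seed(config$seed, 102L), n_cycles = 3L)
  data.table::fwrite(plate$traces, file.path(out_dir, "flux_traces.csv"))
  data.table::fwrite(plate$truth, file.path(out_dir, "flux_truth.csv"))
  invisible(out_dir)
}
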