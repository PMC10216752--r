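#' Write a decay cube to disk
#'
#' Serializes the cube as a sparse long-format CSV of non-zero counts
#' (`x`, `y`, `bin`, `count`; all 0-based coordinates) next to a JSON
#' sidecar carrying the geometry and acquisition metadata
#' (`width`, `height`, `n_bins`, `bin_width_ps`, `rep_period_ps`,
#' `provenance`). Plain-text on purpose: portable, diffable, and
#' round-trips bit-exactly.
#'
#' @param cube A [decay_cube()].
#' @param path_prefix Output path without extension; writes
#'   `<prefix>_counts.csv` and `<prefix>.json`.
#' @return `path_prefix`, invisibly.
#' @export
write_decay_cube <- function(cube, path_prefix) {
  stopifnot(inherits(cube, "decay_cube"))
  d <- dim(cube$counts)
  idx <- which(cube$counts > 0L)
  y <- (idx - 1L) %% d[1]
  x <- ((idx - 1L) %/% d[1]) %% d[2]
  b <- (idx - 1L) %/% (d[1] * d[2])
  dt <- data.table::data.table(x = x, y = y, bin = b,
                               count = cube$counts[idx])
  data.table::fwrite(dt, paste0(path_prefix, "_counts.csv"))
  meta <- list(width = d[2], height = d[1], n_bins = d[3],
               bin_width_ps = cube$bin_width,
               rep_period_ps = cube$rep_period,
               provenance = cube$provenance)
  jsonlite::write_json(meta, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}

#' Read a decay cube from disk
#'
#' Counterpart of [write_decay_cube()]. The counts file and the JSON
#' sidecar must agree: any bin index at or beyond the sidecar's `n_bins`
#' (or pixel outside `width` x `height`) is rejected with both values
#' named.
#'
#' @param path_prefix Path prefix used at write time.
#' @return A [decay_cube()].
#' @export
read_decay_cube <- function(path_prefix) {
  csv <- paste0(path_prefix, "_counts.csv")
  js <- paste0(path_prefix, ".json")
  if (!file.exists(js))
    stop(sprintf("metadata sidecar '%s' not found", js), call. = FALSE)
  if (!file.exists(csv))
    stop(sprintf("counts file '%s' not found", csv), call. = FALSE)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  need <- c("width", "height", "n_bins", "bin_width_ps", "rep_period_ps")
  if (!all(need %in% names(meta)))
    stop("sidecar missing fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  dt <- data.table::fread(csv)
  if (nrow(dt) > 0) {
    if (max(dt$bin) >= meta$n_bins)
      stop(sprintf("counts reference bin %d but sidecar declares n_bins = %d",
                   max(dt$bin), meta$n_bins), call. = FALSE)
    if (max(dt$x) >= meta$width || max(dt$y) >= meta$height)
      stop(sprintf(
        "counts reference pixel (%d, %d) outside sidecar size %d x %d",
        max(dt$x), max(dt$y), meta$width, meta$height), call. = FALSE)
  }
  counts <- array(0L, dim = c(meta$height, meta$width, meta$n_bins))
  counts[cbind(dt$y + 1L, dt$x + 1L, dt$bin + 1L)] <- dt$count
  decay_cube(counts, meta$bin_width_ps, meta$rep_period_ps,
             provenance = meta$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write scene maps and ground truth as plain text
#'
#' Label, compartment and ATP maps as headerless CSV matrices; the
#' ground-truth table as CSV.
#'
#' @param scene A [build_scene()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(scene$cell_labels, file.path(dir, "cell_labels.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(scene$compartment_map,
                     file.path(dir, "compartment_map.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(scene$atp_map, file.path(dir, "atp_map.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  data.table::fwrite(scene$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Write a fitted parameter table with unit-annotated header
#'
#' Column units (ps, fraction, counts) are recorded in a `# units:`
#' comment line so downstream consumers can validate the schema.
#'
#' @param table Parameter table from [extract_parameter_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(table, path) {
  units <- c(cell_id = "id", compartment = "category", x = "px", y = "px",
             t1 = "ps", t2 = "ps", a1_pct = "fraction", a2_pct = "fraction",
             chi2 = "reduced", tm = "ps", n_photons = "counts",
             group = "category")
  u <- units[names(table)]
  u[is.na(u)] <- "unknown"
  con <- file(path, "w")
  writeLines(paste0("# units: ", paste(names(table), u, sep = "=",
                                       collapse = ", ")), con)
  close(con)
  data.table::fwrite(table, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a parameter table written by [write_parameter_table()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_parameter_table <- function(path) {
  as.data.frame(data.table::fread(path, skip = 1L))
}
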