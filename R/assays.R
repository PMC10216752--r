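#' Integrate chromatogram peaks within retention windows
#'
#' Baseline-subtracted trapezoidal peak areas: within each retention
#' window the baseline is the straight line between the signal values at
#' the window endpoints, and the area is the trapezoidal integral of the
#' signal above it.
#'
#' @param chromatogram data.frame with `time` and `signal` columns (or a
#'   [generate_chromatogram()] object).
#' @param retention_windows Named list of `c(t_lo, t_hi)` windows, one per
#'   analyte; windows must be disjoint and lie within the trace.
#' @return Named numeric vector of areas.
#' @export
integrate_peaks <- function(chromatogram, retention_windows) {
  tr <- as.data.frame(chromatogram)
  stopifnot(all(c("time", "signal") %in% names(tr)),
            length(retention_windows) >= 1L)
  w <- do.call(rbind, retention_windows)
  if (any(w[, 1] >= w[, 2]))
    stop("each window needs t_lo < t_hi", call. = FALSE)
  if (any(w[, 1] < min(tr$time)) || any(w[, 2] > max(tr$time)))
    stop("retention window outside the trace", call. = FALSE)
  ord <- order(w[, 1])
  if (any(w[ord[-1], 1] < w[ord[-length(ord)], 2]))
    stop("retention windows must not overlap", call. = FALSE)
  vapply(retention_windows, function(win) {
    sel <- tr$time >= win[1] & tr$time <= win[2]
    tt <- tr$time[sel]; yy <- tr$signal[sel]
    base <- yy[1] + (yy[length(yy)] - yy[1]) *
      (tt - tt[1]) / (tt[length(tt)] - tt[1])
    trapz(tt, yy - base)
  }, numeric(1))
}

#' Calibrate peak areas against external standards
#'
#' Least-squares through-origin response factor per analyte
#' (`area = k * amount`), fitted from one or more external standards of
#' known amounts; sample concentrations are then `area / k`.
#'
#' @param areas Named numeric vector of sample peak areas.
#' @param standard_areas,standard_amounts Either numeric vectors (same
#'   standards for every analyte) or named lists keyed like `areas`.
#' @return Named numeric vector of concentrations, with the per-analyte
#'   response factors in the `"factors"` attribute.
#' @export
calibrate <- function(areas, standard_areas, standard_amounts) {
  stopifnot(length(areas) >= 1L, !is.null(names(areas)))
  get_std <- function(std, nm) {
    if (is.list(std)) {
      if (is.null(std[[nm]])) stop(sprintf("no standards for '%s'", nm),
                                   call. = FALSE)
      std[[nm]]
    } else std
  }
  k <- vapply(names(areas), function(nm) {
    sa <- get_std(standard_areas, nm)
    sx <- get_std(standard_amounts, nm)
    stopifnot(length(sa) == length(sx), length(sa) >= 1L)
    if (any(sa == 0)) stop("zero standard area", call. = FALSE)
    sum(sa * sx) / sum(sx^2)
  }, numeric(1))
  out <- areas / k
  attr(out, "factors") <- k
  out
}

#' Adenylate energy charge
#'
#' `AEC = (ATP + 0.5 * ADP) / (AMP + ADP + ATP)`: the filled fraction of
#' the adenylate phosphorylation pool, 1 when all adenylate is ATP, 0.5
#' when all is ADP. Healthy cells sit near 1.
#'
#' @param atp,adp,amp Concentrations in any single consistent unit,
#'   non-negative, not all zero.
#' @return Fraction in `[0, 1]`. Vectorized.
#' @examples
#' adenylate_energy_charge(16.25, 1, 0.25)
#' @export
adenylate_energy_charge <- function(atp, adp, amp) {
  if (any(atp < 0) || any(adp < 0) || any(amp < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  tot <- atp + adp + amp
  if (any(tot <= 0))
    stop("adenylate pool is empty: AEC undefined", call. = FALSE)
  (atp + 0.5 * adp) / tot
}

#' ATP/ADP ratio
#' @param atp,adp Concentrations; `adp` must be strictly positive.
#' @return `atp / adp`. Vectorized.
#' @export
atp_adp_ratio <- function(atp, adp) {
  if (any(adp <= 0))
    stop("ATP/ADP ratio undefined for adp <= 0", call. = FALSE)
  atp / adp
}

#' Assemble a nucleotide panel
#'
#' Bundles measured ATP/ADP/AMP concentrations with the two derived
#' energy-status summaries.
#'
#' @param atp,adp,amp Concentrations (consistent units).
#' @return A `nucleotide_panel` list: concentrations, `atp_adp_ratio`
#'   (NA when adp = 0) and `aec`.
#' @export
nucleotide_panel <- function(atp, adp, amp) {
  structure(list(
    atp = atp, adp = adp, amp = amp,
    atp_adp_ratio = if (adp > 0) atp / adp else NA_real_,
    aec = adenylate_energy_charge(atp, adp, amp)
  ), class = "nucleotide_panel")
}

#' @export
print.nucleotide_panel <- function(x, ...) {
  cat(sprintf(
    "<nucleotide_panel> ATP %.4g, ADP %.4g, AMP %.4g | ATP/ADP = %.4g, AEC = %.4g\n",
    x$atp, x$adp, x$amp, x$atp_adp_ratio, x$aec))
  invisible(x)
}

#' Robust rate estimate for one flux measurement
#'
#' Theil-Sen estimator: the median of all pairwise slopes, exact on
#' noiseless lines and immune to up to ~29% gross outliers. A Huber
#' M-estimator (iteratively reweighted least squares) is available as an
#' alternative.
#'
#' @param times Time points (>= 3, not all identical).
#' @param values Measured signal at `times`.
#' @param method `"theil-sen"` (default) or `"huber"`.
#' @return Slope in signal units per time unit.
#' @export
rate_robust <- function(times, values, method = c("theil-sen", "huber")) {
  method <- match.arg(method)
  n <- length(times)
  stopifnot(n >= 3L, length(values) == n)
  if (method == "theil-sen") {
    ij <- utils::combn(n, 2)
    dt_ <- times[ij[2, ]] - times[ij[1, ]]
    ok <- dt_ != 0
    if (!any(ok))
      stop("all time points identical: slope undefined", call. = FALSE)
    return(stats::median((values[ij[2, ]] - values[ij[1, ]])[ok] / dt_[ok]))
  }
  # Huber IRLS, k = 1.345 * MAD
  if (length(unique(times)) < 2L)
    stop("all time points identical: slope undefined", call. = FALSE)
  b <- stats::coef(stats::lm(values ~ times))
  for (it in 1:50) {
    r <- values - b[1] - b[2] * times
    s <- stats::mad(r, constant = 1.4826)
    if (s == 0) break
    k <- 1.345 * s
    w <- pmin(1, k / pmax(abs(r), 1e-12))
    fit <- stats::lm(values ~ times, weights = w)
    if (max(abs(stats::coef(fit) - b)) < 1e-10) { b <- stats::coef(fit); break }
    b <- stats::coef(fit)
  }
  unname(b[2])
}

#' Per-well, per-block flux rates with replicate pooling
#'
#' For every well and measurement cycle the oxygen-consumption and
#' acidification rates are estimated by robust regression on the raw
#' sensor trace (consumption/acidification reported positive, i.e. the
#' negated signal slope), cycle rates are averaged within each injection
#' block, and technical-replicate wells are pooled (equal weight per well)
#' to one value per biological replicate group. Wells flagged as excluded
#' (abnormal run behavior, e.g. cell detachment -- a user call, not
#' automatable) are dropped before pooling.
#'
#' @param plate A [generate_flux_traces()] object, or a long data.frame
#'   with columns `well`, `group`, `block`, `cycle`, `time`, `o2`, `ph`
#'   and optionally a logical `excluded` per well.
#' @param method Passed to [rate_robust()].
#' @return List with `well_levels` (well x block OCR/ECAR) and `pooled`
#'   (group x block means across wells).
#' @export
block_levels <- function(plate, method = "theil-sen") {
  tr <- if (inherits(plate, "flux_plate")) plate$traces else
    as.data.frame(plate)
  excl <- if (inherits(plate, "flux_plate")) plate$excluded else
    character(0)
  need <- c("well", "group", "block", "cycle", "time", "o2", "ph")
  stopifnot(all(need %in% names(tr)))
  tr <- tr[!(tr$well %in% excl), , drop = FALSE]
  if (nrow(tr) == 0L) {
    warning("all wells excluded: no levels computed", call. = FALSE)
    return(list(well_levels = NULL, pooled = NULL))
  }
  dt <- data.table::as.data.table(tr)
  if (any(dt[, .N, by = c("well", "block", "cycle")]$N < 2L))
    stop("fewer than 2 time points in a measurement: slope undefined",
         call. = FALSE)
  cyc <- dt[, list(ocr = -rate_robust(time, o2, method),
                   ecar = -rate_robust(time, ph, method)),
            by = c("group", "well", "block", "cycle")]
  well_levels <- cyc[, list(ocr = mean(ocr), ecar = mean(ecar)),
                     by = c("group", "well", "block")]
  pooled <- well_levels[, list(ocr = mean(ocr), ecar = mean(ecar),
                               n_wells = .N),
                        by = c("group", "block")]
  list(well_levels = data.table::setDF(well_levels),
       pooled = data.table::setDF(pooled))
}

#' Flux block names in injection order
#' @return Character vector of the five measurement blocks.
#' @export
flux_blocks <- function() {
  c("baseline", "glucose", "oligomycin", "fccp", "rot_aa_2dg")
}

#' Respiration and glycolysis metrics from block levels
#'
#' Standard mitochondrial stress-test decomposition from the five-block
#' protocol (baseline; glucose/pyruvate; oligomycin; FCCP;
#' rotenone/antimycin A + 2-DG):
#' \itemize{
#'   \item `non_mito_ocr`: OCR after rotenone/antimycin A.
#'   \item `basal_ocr`: pre-oligomycin OCR minus non-mitochondrial.
#'   \item `atp_linked_ocr`: OCR drop across the oligomycin injection
#'     (before minus after) -- the before/after-oligomycin difference.
#'   \item `proton_leak_ocr`: post-oligomycin OCR above non-mitochondrial
#'     -- oxygen still consumed with ATP synthase blocked, i.e. protons
#'     re-entering the matrix without making ATP. Flagged when negative.
#'   \item `max_capacity_ocr`: post-FCCP OCR above non-mitochondrial.
#'   \item `glycolytic_increase_ecar`: ECAR gain from glucose injection.
#'   \item `non_glycolytic_ecar`: ECAR after 2-DG.
#' }
#' By construction `basal = atp_linked + proton_leak`. Both oligomycin
#' readouts (`atp_linked` and `proton_leak`) are reported; group
#' comparisons of membrane leakiness should use `proton_leak_ocr`.
#'
#' @param levels Pooled block levels: data.frame with `block`, `ocr`,
#'   `ecar` and optionally `group` (metrics computed per group).
#' @return data.frame of class `respiration_metrics`, one row per group.
#' @export
respiration_metrics <- function(levels) {
  lv <- as.data.frame(levels)
  stopifnot(all(c("block", "ocr", "ecar") %in% names(lv)))
  if (!"group" %in% names(lv)) lv$group <- "all"
  out <- lapply(split(lv, lv$group), function(g) {
    if (!all(flux_blocks() %in% g$block))
      stop("all five blocks are required to derive metrics", call. = FALSE)
    ocr <- g$ocr[match(flux_blocks(), g$block)]
    ecar <- g$ecar[match(flux_blocks(), g$block)]
    names(ocr) <- names(ecar) <- flux_blocks()
    pre_oligo <- ocr[["glucose"]]     # block immediately before oligomycin
    non_mito <- ocr[["rot_aa_2dg"]]
    leak <- ocr[["oligomycin"]] - non_mito
    data.frame(
      group = g$group[1],
      basal_ocr = pre_oligo - non_mito,
      atp_linked_ocr = pre_oligo - ocr[["oligomycin"]],
      proton_leak_ocr = leak,
      max_capacity_ocr = ocr[["fccp"]] - non_mito,
      non_mito_ocr = non_mito,
      glycolytic_increase_ecar = ecar[["glucose"]] - ecar[["baseline"]],
      non_glycolytic_ecar = ecar[["rot_aa_2dg"]],
      leak_negative = leak < 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("respiration_metrics", "data.frame")
  out
}

#' Normalize an MTT viability plate to mock-treated wells
#'
#' Each well's absorbance is divided by the mean absorbance of the
#' mock-treated wells of the same cell line, so normalization is
#' independent across lines.
#'
#' @param plate data.frame with `line`, `treatment`, `absorbance` columns.
#' @param mock_label Treatment label identifying mock wells.
#' @return The plate with a `viability` column appended.
#' @export
mtt_normalize <- function(plate, mock_label = "mock") {
  stopifnot(all(c("line", "treatment", "absorbance") %in% names(plate)))
  out <- lapply(split(plate, plate$line), function(g) {
    mock <- g$absorbance[g$treatment == mock_label]
    if (length(mock) < 1L)
      stop(sprintf("line '%s' has no %s wells", g$line[1], mock_label),
           call. = FALSE)
    mm <- mean(mock)
    if (mm == 0) stop("zero mock mean: normalization undefined",
                      call. = FALSE)
    g$viability <- g$absorbance / mm
    g
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
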