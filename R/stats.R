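#' Summarize lifetimes by experimental grouping
#'
#' Collapses a per-pixel parameter table into group summaries. At
#' `level = "cell"` pixels are first averaged within each cell (pixels in a
#' cell are not independent, so cells -- not pixels -- are the default
#' inference unit); at `level = "pixel"` every pixel counts.
#'
#' @param table data.frame with a `tm` column, a `cell_id` column and the
#'   grouping columns in `keys` (e.g. line, genotype, treatment,
#'   compartment, timepoint).
#' @param keys Character vector of grouping column names.
#' @param level `"cell"` or `"pixel"`.
#' @param value Name of the value column (default `"tm"`).
#' @return data.frame with one row per key combination: `n`, `mean`,
#'   `median`, `sd`, `sem` (`sd / sqrt(n)`). Empty groups are omitted.
#' @export
aggregate_by <- function(table, keys, level = c("cell", "pixel"),
                         value = "tm") {
  level <- match.arg(level)
  stopifnot(all(keys %in% names(table)), value %in% names(table))
  dt <- data.table::as.data.table(table)
  v <- value
  if (level == "cell") {
    stopifnot("cell_id" %in% names(table))
    dt <- dt[, list(.val = mean(.SD[[v]])),
             by = c(keys, "cell_id"), .SDcols = v]
  } else {
    dt <- dt[, list(.val = .SD[[v]]), by = keys, .SDcols = v]
  }
  out <- dt[, list(n = .N, mean = mean(.val),
                   median = stats::median(.val),
                   sd = stats::sd(.val),
                   sem = stats::sd(.val) / sqrt(.N)), by = keys]
  data.table::setDF(out)
  out
}

#' Welch's two-sample t-test (unequal variances)
#'
#' The "two-sample assuming unequal variances" t-test:
#' `t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 2 values.
#' @return List with `t`, `df`, `p`, `mean_diff` (a minus b).
#' @export
welch_ttest <- function(sample_a, sample_b) {
  na <- length(sample_a); nb <- length(sample_b)
  stopifnot(na >= 2L, nb >= 2L)
  va <- stats::var(sample_a) / na
  vb <- stats::var(sample_b) / nb
  d <- mean(sample_a) - mean(sample_b)
  se2 <- va + vb
  if (se2 == 0) {
    # both samples constant: identical means carry no evidence
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = na + nb - 2, p = if (d == 0) 1 else 0,
                mean_diff = d))
  }
  t_stat <- d / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t_stat, df = df,
       p = 2 * stats::pt(-abs(t_stat), df), mean_diff = d)
}

#' Welch's t-test from summary statistics
#'
#' Same test as [welch_ttest()] but computed from published summaries
#' (mean, SEM, n per group), for checking printed group comparisons.
#'
#' @param m1,m2 Group means.
#' @param sem1,sem2 Standard errors of the means (> 0).
#' @param n1,n2 Group sizes (> 1).
#' @return List with `t` (sign of `m2 - m1`), `df`, `p` (two-sided).
#' @examples
#' welch_from_summary(1283, 32.05, 36, 1530, 44.99, 39)
#' @export
welch_from_summary <- function(m1, sem1, n1, m2, sem2, n2) {
  stopifnot(sem1 > 0, sem2 > 0)
  if (n1 <= 1 || n2 <= 1) stop("group sizes must exceed 1", call. = FALSE)
  se2 <- sem1^2 + sem2^2
  t_stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

#' Two-way fixed-effects ANOVA with Sidak-adjusted pairwise comparisons
#'
#' Type II sums of squares (each main effect adjusted for the other; the
#' interaction adjusted for both), which reduce to the classical sequential
#' decomposition on balanced designs. Pairwise follow-up comparisons are
#' Welch tests between levels of `factor_a` within each level of
#' `factor_b`, family-wise adjusted by the Sidak formula
#' `p_adj = 1 - (1 - p)^m` (`"bonferroni"` available).
#'
#' If some factor-level combinations are empty the interaction is
#' inestimable and is dropped with a message.
#'
#' @param table data.frame.
#' @param factor_a,factor_b Names of the two factor columns.
#' @param response Name of the response column (default `"tm"`).
#' @param adjust `"sidak"` or `"bonferroni"`.
#' @return List with `anova` (term, df, sumsq, meansq, statistic, p) and
#'   `pairwise` (group, level pair, mean_diff, p, p_adj, m).
#' @export
two_way_anova <- function(table, factor_a, factor_b, response = "tm",
                          adjust = c("sidak", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c(factor_a, factor_b, response) %in% names(table)))
  df <- data.frame(y = table[[response]],
                   A = factor(table[[factor_a]]),
                   B = factor(table[[factor_b]]))
  if (nlevels(df$A) < 2 || nlevels(df$B) < 2)
    stop("each factor needs at least two levels", call. = FALSE)

  has_empty <- any(table(df$A, df$B) == 0)
  if (has_empty)
    message("empty factor-level cells: interaction term dropped")

  rss <- function(form) sum(stats::resid(stats::lm(form, data = df))^2)
  rss_a <- rss(y ~ A); rss_b <- rss(y ~ B); rss_ab <- rss(y ~ A + B)
  full_form <- if (has_empty) y ~ A + B else y ~ A * B
  fit_full <- stats::lm(full_form, data = df)
  rss_full <- sum(stats::resid(fit_full)^2)
  df_res <- fit_full$df.residual

  ss_a <- rss_b - rss_ab          # SS(A | B)
  ss_b <- rss_a - rss_ab          # SS(B | A)
  df_a <- nlevels(df$A) - 1L; df_b <- nlevels(df$B) - 1L
  terms <- data.frame(
    term = c(factor_a, factor_b),
    df = c(df_a, df_b),
    sumsq = c(ss_a, ss_b),
    stringsAsFactors = FALSE
  )
  if (!has_empty) {
    ss_int <- rss_ab - rss_full   # SS(A:B | A, B)
    terms <- rbind(terms, data.frame(term = paste(factor_a, factor_b,
                                                  sep = ":"),
                                     df = df_a * df_b, sumsq = ss_int))
  }
  ms_res <- rss_full / df_res
  terms$meansq <- terms$sumsq / terms$df
  terms$statistic <- terms$meansq / ms_res
  terms$p <- stats::pf(terms$statistic, terms$df, df_res,
                       lower.tail = FALSE)
  terms <- rbind(terms, data.frame(term = "Residuals", df = df_res,
                                   sumsq = rss_full, meansq = ms_res,
                                   statistic = NA, p = NA))

  # pairwise A-level comparisons within each B level
  pw <- list()
  for (b in levels(df$B)) {
    sub <- df[df$B == b, ]
    lv <- levels(droplevels(sub$A))
    if (length(lv) < 2) next
    for (i in seq_len(length(lv) - 1L)) for (j in (i + 1L):length(lv)) {
      xa <- sub$y[sub$A == lv[i]]; xb <- sub$y[sub$A == lv[j]]
      if (length(xa) < 2 || length(xb) < 2) next
      wt <- welch_ttest(xa, xb)
      pw[[length(pw) + 1L]] <- data.frame(
        within = b, level_1 = lv[i], level_2 = lv[j],
        mean_diff = wt$mean_diff, p = wt$p, stringsAsFactors = FALSE)
    }
  }
  pairwise <- if (length(pw)) do.call(rbind, pw) else
    data.frame(within = character(), level_1 = character(),
               level_2 = character(), mean_diff = numeric(), p = numeric())
  m <- nrow(pairwise)
  if (m > 0) {
    pairwise$m <- m
    pairwise$p_adj <- if (adjust == "sidak") 1 - (1 - pairwise$p)^m
    else pmin(pairwise$p * m, 1)
  }
  list(anova = terms, pairwise = pairwise)
}

#' Sample-size-normalized kernel density estimate
#'
#' Gaussian-kernel density whose curve integrates to 1 whatever the sample
#' size, so distributions from groups of different n can be overlaid and
#' compared directly. Bandwidth defaults to Silverman's rule; pass a fixed
#' bandwidth for cross-condition comparability of the curves.
#'
#' @param values Numeric sample, n >= 2.
#' @param bandwidth Kernel SD, or `NULL` for Silverman's rule-of-thumb.
#' @param n_grid Number of grid points.
#' @return data.frame with `x` and `density`; attribute `degenerate` is
#'   `TRUE` for zero-variance input (delta-like spike at the value).
#' @export
kde_normalized <- function(values, bandwidth = NULL, n_grid = 512L) {
  stopifnot(length(values) >= 2L, all(is.finite(values)))
  degenerate <- stats::var(values) == 0
  if (degenerate && is.null(bandwidth)) {
    bandwidth <- max(abs(values[1]) * 1e-4, 1e-8)
    warning("zero-variance sample: returning a delta-like spike",
            call. = FALSE)
  }
  d <- if (is.null(bandwidth))
    stats::density(values, bw = "nrd0", n = n_grid)
  else stats::density(values, bw = bandwidth, n = n_grid)
  out <- data.frame(x = d$x, density = d$y)
  attr(out, "degenerate") <- degenerate
  attr(out, "bandwidth") <- d$bw
  out
}

#' Compare condition groups against a reference
#'
#' Collapses the parameter table to cell-level mean lifetimes, then for
#' each group reports the mean-lifetime difference versus the reference
#' group with a Welch test. For this sensor higher mean lifetime means less
#' FRET and therefore lower relative ATP, which is the `direction` column.
#'
#' @param table Parameter table with `tm`, `cell_id` and a group column.
#' @param reference_group Name of the reference level.
#' @param group Column holding the group labels (default `"group"`).
#' @param level Aggregation level passed to [aggregate_by()].
#' @return data.frame: group, n, mean_tm, delta_tm (group minus reference),
#'   t, df, p, direction.
#' @export
compare_conditions <- function(table, reference_group, group = "group",
                               level = "cell") {
  stopifnot(group %in% names(table))
  if (!reference_group %in% table[[group]])
    stop(sprintf("reference group '%s' not present", reference_group),
         call. = FALSE)
  dt <- data.table::as.data.table(table)
  if (level == "cell") {
    cells <- dt[, list(val = mean(tm)), by = c(group, "cell_id")]
  } else {
    cells <- dt[, list(val = tm, cell_id = cell_id), by = group]
  }
  cells <- data.table::setDF(cells)
  ref <- cells$val[cells[[group]] == reference_group]
  groups <- unique(cells[[group]])
  rows <- lapply(groups, function(g) {
    gv <- cells$val[cells[[group]] == g]
    if (g == reference_group) {
      data.frame(group = g, n = length(gv), mean_tm = mean(gv),
                 delta_tm = 0, t = 0, df = NA_real_, p = 1,
                 direction = "reference", stringsAsFactors = FALSE)
    } else {
      wt <- welch_ttest(gv, ref)
      data.frame(group = g, n = length(gv), mean_tm = mean(gv),
                 delta_tm = wt$mean_diff, t = wt$t, df = wt$df, p = wt$p,
                 direction = if (wt$mean_diff > 0)
                   "higher Tm (lower relative ATP)"
                 else "lower Tm (higher relative ATP)",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
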