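make_table <- function(cells, px_per_cell, tm, group = "g", comp = "soma") {
  data.frame(cell_id = rep(seq_len(cells), each = px_per_cell),
             compartment = comp, group = group,
             tm = tm, stringsAsFactors = FALSE)
}

test_that("aggregate_by summarizes at cell and pixel level correctly", {
  tab <- make_table(3, 10, tm = rep(1500, 30))
  s <- aggregate_by(tab, keys = "group", level = "cell")
  expect_equal(s$n, 3)
  expect_equal(s$mean, 1500)
  expect_equal(s$sd, 0)
  # unbalanced cells: pixel mean weights by pixel count, cell mean does not
  tab2 <- data.frame(cell_id = c(rep(1, 9), 2), group = "g",
                     tm = c(rep(1000, 9), 2000))
  sp <- aggregate_by(tab2, "group", level = "pixel")
  sc <- aggregate_by(tab2, "group", level = "cell")
  expect_equal(sp$mean, 1100)
  expect_equal(sc$mean, 1500)
  expect_equal(sc$sem, sc$sd / sqrt(sc$n))
})

test_that("welch_ttest agrees with stats::t.test and a permutation oracle", {
  set.seed(13)
  a <- rnorm(12, 0, 1); b <- rnorm(9, 0.5, 2.5)
  ours <- welch_ttest(a, b)
  ref <- t.test(a, b)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # fixed toy vectors vs Monte-Carlo permutation reference
  av <- c(11.37, 9.44, 10.36, 10.63, 10.4, 9.89, 11.51, 9.91)
  bv <- c(14.43, 10.69, 13.15, 14.92, 8.3, 10.3, 10.56, 11.94)
  w <- welch_ttest(av, bv)
  pool <- c(av, bv)
  set.seed(7)
  perm <- replicate(20000, {
    i <- sample(16, 8)
    x <- pool[i]; y <- pool[-i]
    abs((mean(x) - mean(y)) / sqrt(var(x) / 8 + var(y) / 8))
  })
  p_perm <- mean(perm >= abs(w$t) - 1e-12)
  expect_lt(abs(w$p - p_perm), 0.03)
  # degenerate branches
  expect_equal(welch_ttest(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_equal(welch_ttest(c(2, 2, 2), c(1, 1, 1))$p, 0)
  big <- welch_ttest(rnorm(20) + 100, rnorm(20))
  expect_lt(big$p, 1e-12)
})

test_that("welch_from_summary matches the raw-sample test and flips symmetrically", {
  set.seed(29)
  a <- rnorm(14, 5, 1); b <- rnorm(23, 5.6, 2)
  raw <- welch_ttest(b, a)   # note: summary form uses (m2 - m1)
  sm <- welch_from_summary(mean(a), sd(a) / sqrt(14), 14,
                           mean(b), sd(b) / sqrt(23), 23)
  expect_equal(sm$t, raw$t, tolerance = 1e-10)
  expect_equal(sm$df, raw$df, tolerance = 1e-10)
  expect_equal(sm$p, raw$p, tolerance = 1e-10)
  flip <- welch_from_summary(mean(b), sd(b) / sqrt(23), 23,
                             mean(a), sd(a) / sqrt(14), 14)
  expect_equal(flip$t, -sm$t)
  expect_equal(flip$p, sm$p)
  # vanishing information limit
  wide <- welch_from_summary(0, 1, 10, 0.5, 1e6, 10)
  expect_gt(wide$p, 0.99)
  expect_error(welch_from_summary(0, 1, 1, 1, 1, 10), "exceed 1")
})

test_that("two-way ANOVA matches textbook sums of squares on a balanced design", {
  set.seed(3)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                   rep = 1:6, KEEP.OUT.ATTRS = FALSE)
  mu <- c(a1.b1 = 10, a2.b1 = 12, a1.b2 = 11, a2.b2 = 16)
  d$y <- mu[paste(d$A, d$B, sep = ".")] + rnorm(nrow(d), 0, 1)
  res <- two_way_anova(d, "A", "B", response = "y")
  # classical balanced-design decomposition, computed independently
  n <- 6; gm <- mean(d$y)
  ma <- tapply(d$y, d$A, mean); mb <- tapply(d$y, d$B, mean)
  mab <- tapply(d$y, paste(d$A, d$B), mean)
  ss_a <- 2 * n * sum((ma - gm)^2)
  ss_b <- 2 * n * sum((mb - gm)^2)
  ss_cells <- n * sum((mab - gm)^2)
  ss_int <- ss_cells - ss_a - ss_b
  tab <- res$anova
  expect_equal(tab$sumsq[tab$term == "A"], ss_a, tolerance = 1e-8)
  expect_equal(tab$sumsq[tab$term == "B"], ss_b, tolerance = 1e-8)
  expect_equal(tab$sumsq[tab$term == "A:B"], ss_int, tolerance = 1e-8)
  # a factor whose level means are identical gets F ~ 0
  d2 <- d
  noise <- rnorm(12)[match(paste(d$B, d$rep), unique(paste(d$B, d$rep)))]
  d2$y <- ifelse(d2$B == "b2", 5, 0) + noise  # y ignores A entirely
  res2 <- two_way_anova(d2, "A", "B", response = "y")
  expect_lt(res2$anova$statistic[res2$anova$term == "A"], 1e-12)
  # Sidak with m = 1 leaves p untouched
  expect_equal(1 - (1 - 0.37)^1, 0.37)
  sid <- res$pairwise
  expect_equal(sid$p_adj, 1 - (1 - sid$p)^sid$m)
})

test_that("KDE integrates to one regardless of sample size and finds structure", {
  set.seed(17)
  for (n in c(10, 200, 5000)) {
    k <- kde_normalized(rnorm(n, 3, 2))
    expect_lt(abs(trapz_test(k$x, k$density) - 1), 1e-3)
  }
  k0 <- kde_normalized(rnorm(1000))
  expect_lt(abs(k0$x[which.max(k0$density)]), 0.1)
  bim <- c(rnorm(400, -4), rnorm(400, 4))
  kb <- kde_normalized(bim)
  dy <- diff(kb$density)
  n_max <- sum(diff(sign(dy)) == -2)
  expect_gte(n_max, 2)
  expect_warning(kde_normalized(c(2, 2, 2)), "zero-variance")
})

test_that("compare_conditions reports directions and a null self-comparison", {
  set.seed(23)
  tab <- rbind(
    make_table(8, 5, tm = rnorm(40, 1300, 40), group = "control"),
    within(make_table(8, 5, tm = rnorm(40, 1400, 40), group = "mutant"),
           cell_id <- cell_id + 100))
  ef <- compare_conditions(tab, "control")
  expect_equal(ef$p[ef$group == "control"], 1)
  expect_equal(ef$delta_tm[ef$group == "control"], 0)
  mu <- ef[ef$group == "mutant", ]
  expect_gt(mu$delta_tm, 0)
  expect_lt(mu$p, 0.05)
  expect_match(mu$direction, "lower relative ATP")
  expect_error(compare_conditions(tab, "missing"), "not present")
})

test_that("null p-values are uniform across repeated generator seeds", {
  ps <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    welch_ttest(rnorm(15, 1200, 50), rnorm(12, 1200, 90))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
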