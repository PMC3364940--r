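# Exact and classical cohort statistics.

test_that("fisher_exact reproduces the printed cohort comparisons", {
  # Ts65Dn vs Ts65Dn/Ms5Yah feature table, two-sided
  expect_equal(fisher_exact(matrix(c(4, 8, 27, 2), 2, byrow = TRUE)),
               1.850112e-4, tolerance = 1e-6)
  # wt vs Ts65Dn/Ms5Yah, lower tail
  expect_equal(fisher_exact(matrix(c(8, 23, 4, 8), 2, byrow = TRUE), "lower"),
               0.4445644, tolerance = 1e-6)
  expect_equal(fisher_exact(matrix(1, 2, 2)), 1)
})

test_that("fisher_exact matches the enumeration oracle over random tables", {
  set.seed(42)
  for (i in 1:150) {
    n <- sample(4:200, 1)
    repeat {
      cuts <- sort(sample(0:n, 3, replace = TRUE))
      tab <- matrix(c(cuts[1], cuts[2] - cuts[1],
                      cuts[3] - cuts[2], n - cuts[3]), 2, byrow = TRUE)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    for (tail in c("two_sided", "lower", "upper")) {
      expect_equal(fisher_exact(tab, tail), fisher_oracle(tab, tail),
                   tolerance = 1e-12)
    }
    # independent cross-check against the reference implementation
    expect_equal(fisher_exact(tab, "two_sided"),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    expect_equal(fisher_exact(tab, "lower"),
                 stats::fisher.test(tab, alternative = "less")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("fisher_exact two-sided p is invariant to table symmetries", {
  set.seed(7)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 12) + 1, 2)
    p <- fisher_exact(tab)
    expect_equal(fisher_exact(tab[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact(tab[, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisher_exact(t(tab)), p, tolerance = 1e-12)
  }
})

test_that("hypergeometric point probabilities sum to one", {
  for (tab in list(matrix(c(8, 23, 27, 2), 2), matrix(c(1, 9, 5, 60), 2))) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    support <- max(0, c1 - r2):min(r1, c1)
    expect_equal(sum(stats::dhyper(support, r1, r2, c1)), 1,
                 tolerance = 1e-12)
  }
})

test_that("fisher_exact rejects degenerate tables", {
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero margin")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integers")
  expect_error(fisher_exact(matrix(1, 3, 3)), "2x2")
})

test_that("chi-square GOF matches the closed-form Pearson statistic", {
  gc <- genotype_counts("ts", c(carrier = 210, wt = 407),
                        c(carrier = 0.5, wt = 0.5))
  res <- chi_square_gof(gc)
  expect_equal(res$chi2, 2 * 98.5^2 / 308.5, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_equal(sum(res$contributions), res$chi2)
  # independent oracle
  ct <- stats::chisq.test(c(210, 407), p = c(0.5, 0.5))
  expect_equal(res$chi2, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)

  gc2 <- genotype_counts("ms", c(carrier = 17, wt = 85),
                         c(carrier = 0.5, wt = 0.5))
  expect_equal(chi_square_gof(gc2)$chi2, 45.3333, tolerance = 1e-4)

  # order invariance and exact-null behaviour
  gc_r <- genotype_counts("ts", c(wt = 407, carrier = 210),
                          c(wt = 0.5, carrier = 0.5))
  expect_equal(chi_square_gof(gc_r)$chi2, res$chi2)
  gc0 <- genotype_counts("null", c(a = 50, b = 50), c(a = 0.5, b = 0.5))
  expect_equal(chi_square_gof(gc0)$chi2, 0)
  expect_equal(chi_square_gof(gc0)$p, 1)
})

test_that("Yates correction shrinks the statistic for 2-class tables", {
  gc <- genotype_counts("x", c(a = 30, b = 18), c(a = 0.5, b = 0.5))
  expect_lt(chi_square_gof(gc, yates = TRUE)$chi2, chi_square_gof(gc)$chi2)
})

test_that("compound expected ratios follow the independence model", {
  r <- expected_compound_ratios(0.34, 0.167)
  expect_equal(unname(round(r, 3)), c(0.550, 0.283, 0.110, 0.057))
  expect_equal(sum(r), 1)
  # marginals reproduce the inputs
  expect_equal(unname(r["a_only"] + r["a_b"]), 0.34)
  expect_equal(unname(r["b_only"] + r["a_b"]), 0.167)
  expect_equal(unname(expected_compound_ratios(0.5, 0.5)), rep(0.25, 4))
  # within each B stratum the A split is preserved
  r2 <- expected_compound_ratios(0.34, 0.5)
  expect_equal(unname(r2["a_only"] / (r2["a_only"] + r2["wt"])), 0.34)
  expect_error(expected_compound_ratios(0, 0.5), "in \\(0, 1\\)")
})

test_that("transmission rates reproduce the printed weaning percentages", {
  wc <- weaning_counts()
  expect_equal(transmission_rate(wc$Ts65Dn_x_F1B6C3B, "Ts65Dn"), 34.0)
  expect_equal(transmission_rate(wc$Ms5Yah_x_F1B6C3B, "Ms5Yah"), 16.7)
  expect_equal(transmission_rate(wc$Ts65Dn_x_Ms5Yah, "Ts65Dn/Ms5Yah"), 24.9)
  expect_equal(transmission_rate(wc$Ts65Dn_x_Ms5Yah, "Ts65Dn"), 27.0)
  expect_error(transmission_rate(wc$Ts65Dn_x_F1B6C3B, "Ms5Yah"),
               "missing class")
  gc0 <- genotype_counts("z", c(a = 0, b = 10), c(a = 0.5, b = 0.5))
  expect_equal(transmission_rate(gc0, "a"), 0)
})

test_that("axis interval membership uses the arc through -90 degrees", {
  s <- data.frame(genotype = c("wt", "Ts65Dn", "wt", "wt"),
                  axis = c(-42.4, 60.6, -7, -124))
  res <- axis_interval_test(s, c(-7, -124), c("wt", "Ts65Dn"))
  expect_true(res$inside[1])   # wt mean axis inside
  expect_false(res$inside[2])  # Ts65Dn mean axis outside
  expect_true(res$inside[3])   # closed endpoints
  expect_true(res$inside[4])
  expect_equal(sum(res$table), 4)
  expect_error(axis_interval_test(s, c(-7, -7), c("wt", "Ts65Dn")),
               "degenerate")
  expect_error(axis_interval_test(s, c(-7, -124), c("wt", "Ms5Yah")),
               "no samples")
})

test_that("axis-interval test separates synthetic genotype axes", {
  set.seed(5)
  s <- data.frame(
    genotype = rep(c("wt", "Ts65Dn"), each = 30),
    axis = c(rnorm(30, -42, 25),
             ((runif(30, -180, 180) + 180) %% 360) - 180)
  )
  res <- axis_interval_test(s, c(-7, -124), c("wt", "Ts65Dn"))
  expect_lt(res$p, 0.05)
})

test_that("compare_groups t-test matches the pooled-variance reference", {
  set.seed(9)
  a <- rnorm(12, 10, 2); b <- rnorm(15, 11.5, 2)
  res <- compare_groups(list(a = a, b = b), "t")
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(abs(res$statistic), abs(unname(ref$statistic)), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)

  same <- rnorm(10)
  res0 <- compare_groups(list(x = same, y = same), "t")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_error(compare_groups(list(a = 1:5), "t"), "two groups")
  expect_error(compare_groups(list(a = 1, b = 1:3), "t"), ">= 2 values")
})

test_that("ANOVA + Tukey agree with the reference implementations", {
  set.seed(10)
  vals <- list(g1 = rnorm(8, 0), g2 = rnorm(9, 1), g3 = rnorm(7, 3))
  res <- compare_groups(vals, "anova_tukey")
  df <- data.frame(y = unlist(vals),
                   g = factor(rep(names(vals), lengths(vals))))
  fit <- stats::aov(y ~ g, df)
  expect_equal(res$statistic, unname(summary(fit)[[1]]$F[1]),
               tolerance = 1e-10)
  tk <- as.data.frame(stats::TukeyHSD(fit)$g)
  for (i in seq_len(nrow(res$pairs))) {
    key1 <- paste0(res$pairs$group2[i], "-", res$pairs$group1[i])
    key2 <- paste0(res$pairs$group1[i], "-", res$pairs$group2[i])
    ref_p <- tk[rownames(tk) %in% c(key1, key2), "p adj"]
    expect_equal(res$pairs$p[i], ref_p, tolerance = 1e-8)
  }
})

test_that("SNK p-values are never larger than Tukey for the extreme pair", {
  set.seed(11)
  vals <- list(a = rnorm(10, 0), b = rnorm(10, 0.6), c = rnorm(10, 1.8))
  snk <- compare_groups(vals, "anova_snk")$pairs
  tuk <- compare_groups(vals, "anova_tukey")$pairs
  # the widest-span pair uses the same critical value in both procedures
  w_snk <- snk[snk$span == 3, ]
  w_tuk <- tuk[tuk$group1 == w_snk$group1 & tuk$group2 == w_snk$group2, ]
  expect_equal(w_snk$p, w_tuk$p, tolerance = 1e-10)
  # narrower spans are tested at a smaller critical range under SNK
  expect_true(all(snk$p <= tuk$p + 1e-12))
})

test_that("group power and type-I behaviour match the printed design", {
  # wt vs Ts65Dn QT at the printed means/sems (n = 30). At this effect size
  # (noncentrality ~2.5) the two-sided test detects the difference at 0.05
  # in about two thirds of replicates.
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    wt <- rnorm(30, 67.5, 1.0 * sqrt(30))
    ts <- rnorm(30, 73.0, 2.0 * sqrt(30))
    hits <- hits + (compare_groups(list(wt = wt, ts = ts), "t")$p < 0.05)
  }
  expect_gte(hits / 20, 0.5)

  # three equal-mean groups: Tukey flags almost never at 0.05
  flags <- 0
  for (s in 1:30) {
    set.seed(500 + s)
    vals <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
    flags <- flags + any(compare_groups(vals, "anova_tukey")$pairs$p < 0.05)
  }
  expect_gte(1 - flags / 30, 0.93 - 2 * sqrt(0.05 * 0.95 / 30))
})

test_that("null p-values are stochastically not anti-conservative", {
  set.seed(12)
  pf <- replicate(200, {
    tab <- matrix(stats::rmultinom(1, 40, rep(0.25, 4)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NA_real_
    else fisher_exact(tab)
  })
  pf <- pf[!is.na(pf)]
  # discreteness makes exact tests conservative: P(p <= a) <= a
  for (a in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(pf <= a), a + 3 * sqrt(a * (1 - a) / length(pf)))
  }
})
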