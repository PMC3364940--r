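# Exact and classical cohort statistics: Fisher exact tests with explicit
# tail conventions, transmission-ratio chi-square under Mendelian or
# line-adjusted expectations, angular-interval tests on the frontal axis,
# and group-mean comparisons (t / ANOVA + SNK / Tukey).

#' Construct a genotype-count table
#'
#' @param cross label of the originating cross.
#' @param counts named non-negative integer counts per genotype class.
#' @param expected_ratios named per-class expected probabilities
#'   (must sum to 1 within 1e-9).
#' @param source `"observed"` or `"simulated"`.
#' @return a `genotype_counts` object.
#' @export
genotype_counts <- function(cross, counts, expected_ratios,
                            source = "observed") {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (abs(sum(expected_ratios) - 1) > 1e-9) {
    stop("expected ratios must sum to 1 (tolerance 1e-9)")
  }
  if (is.null(names(counts))) stop("counts must be named by class")
  if (!identical(sort(names(counts)), sort(names(expected_ratios)))) {
    stop("counts and expected_ratios must cover the same classes")
  }
  structure(list(cross = cross,
                 counts = counts,
                 expected_ratios = expected_ratios[names(counts)],
                 source = match.arg(source, c("observed", "simulated"))),
            class = "genotype_counts")
}

#' Fisher exact test on a 2x2 table with an explicit tail
#'
#' Exact hypergeometric computation over the support with fixed margins.
#' `lower` / `upper` are the cumulative tails on the `[1,1]` cell; the
#' two-sided p-value is the sum of all point probabilities not exceeding the
#' observed one (relative slack 1e-7 for floating-point ties) - the dominant
#' software convention.
#'
#' @param table 2x2 non-negative integer matrix.
#' @param tail `"two_sided"` (default), `"lower"` or `"upper"`.
#' @return the exact p-value.
#' @examples
#' fisher_exact(matrix(c(4, 8, 27, 2), 2, byrow = TRUE))          # 1.85e-4
#' fisher_exact(matrix(c(8, 23, 4, 8), 2, byrow = TRUE), "lower") # 0.4446
#' @export
fisher_exact <- function(table, tail = c("two_sided", "lower", "upper")) {
  tail <- match.arg(tail)
  if (!is.matrix(table) || !all(dim(table) == 2)) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("table entries must be non-negative integers")
  }
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(table[, 2]) == 0) {
    stop("zero margin: the test is undefined")
  }
  a <- table[1, 1]
  support <- max(0, c1 - r2):min(r1, c1)
  pts <- stats::dhyper(support, r1, r2, c1)
  p_obs <- pts[support == a]
  switch(tail,
    lower = sum(pts[support <= a]),
    upper = sum(pts[support >= a]),
    two_sided = min(1, sum(pts[pts <= p_obs * (1 + 1e-7)]))
  )
}

#' Pearson chi-square goodness of fit for genotype transmission
#'
#' @param counts a [genotype_counts()] object.
#' @param yates apply the continuity correction (|O-E| - 0.5; default off).
#' @return list with `chi2`, `df`, `p` and the per-class `contributions`
#'   (which sum to the statistic).
#' @examples
#' gc <- genotype_counts("demo", c(wt = 407, carrier = 210),
#'                       c(wt = 0.5, carrier = 0.5))
#' chi_square_gof(gc)$chi2  # 62.90
#' @export
chi_square_gof <- function(counts, yates = FALSE) {
  stopifnot(inherits(counts, "genotype_counts"))
  o <- counts$counts
  e <- counts$expected_ratios * sum(o)
  if (any(e == 0)) stop("zero expected count")
  if (any(e < 1)) stop("expected counts must be >= 1 per class")
  if (any(e < 5)) warning("expected count below 5; chi-square approximation is weak")
  dev <- abs(o - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  contrib <- dev^2 / e
  chi2 <- sum(contrib)
  df <- length(o) - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       contributions = contrib)
}

#' Expected genotype ratios for a double-heterozygous cross
#'
#' Line-adjusted independence model: with marginal transmission fractions
#' `p_a` and `p_b` for the two alleles, the four class probabilities are the
#' products (1-p_a or p_a) x (1-p_b or p_b), normalized.
#'
#' @param p_a,p_b marginal transmission fractions in (0, 1).
#' @return named probabilities `c(wt, a_only, b_only, a_b)` summing to 1.
#' @examples
#' expected_compound_ratios(0.34, 0.167)  # 0.550 0.283 0.110 0.057
#' @export
expected_compound_ratios <- function(p_a, p_b) {
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    stop("transmission fractions must be in (0, 1)")
  }
  r <- c(wt = (1 - p_a) * (1 - p_b), a_only = p_a * (1 - p_b),
         b_only = (1 - p_a) * p_b, a_b = p_a * p_b)
  r / sum(r)
}

#' Observed transmission rate of a genotype class
#'
#' @param counts a [genotype_counts()] object.
#' @param class class label.
#' @return percentage, reported to one decimal.
#' @examples
#' gc <- genotype_counts("demo", c(wt = 407, carrier = 210),
#'                       c(wt = 0.5, carrier = 0.5))
#' transmission_rate(gc, "carrier")  # 34.0
#' @export
transmission_rate <- function(counts, class) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (!class %in% names(counts$counts)) stop("missing class: ", class)
  total <- sum(counts$counts)
  if (total <= 0) stop("total count must be positive")
  round(100 * counts$counts[[class]] / total, 1)
}

# membership of angle x (degrees) on the closed arc from e1 to e2 passing
# through -90 degrees
.axis_in_interval <- function(x, e1, e2) {
  ccw <- function(a, b, v) ((v - a) %% 360) <= ((b - a) %% 360) + 1e-9
  if (ccw(e1, e2, -90)) ccw(e1, e2, x) else ccw(e2, e1, x)
}

#' Test genotype association with an angular axis interval
#'
#' Membership is computed on the directed arc between the interval endpoints
#' that passes through -90 degrees (the inferior/leftward sector, handling
#' wrapped intervals such as -7 to -124 degrees), with closed endpoints.
#' The resulting inside/outside x genotype 2x2 table is tested with
#' [fisher_exact()].
#'
#' @param samples data.frame with columns `genotype` and `axis` (degrees in
#'   (-180, 180]).
#' @param interval numeric length-2 endpoints (degrees).
#' @param genotypes the two genotypes compared (row order of the table).
#' @param tail passed to [fisher_exact()].
#' @return list with the 2x2 `table` (columns inside/outside), `p`, and the
#'   per-sample membership flags.
#' @export
axis_interval_test <- function(samples, interval, genotypes,
                               tail = "two_sided") {
  stopifnot(is.data.frame(samples), all(c("genotype", "axis") %in% names(samples)))
  if (length(interval) != 2 || interval[1] == interval[2]) {
    stop("degenerate interval")
  }
  if (any(samples$axis <= -180 | samples$axis > 180)) {
    stop("axis values must lie in (-180, 180]")
  }
  inside <- vapply(samples$axis, .axis_in_interval,
                   logical(1), e1 = interval[1], e2 = interval[2])
  missing_g <- setdiff(genotypes, samples$genotype)
  if (length(missing_g)) stop("no samples for genotype: ",
                              paste(missing_g, collapse = ", "))
  tab <- t(vapply(genotypes, function(g) {
    s <- samples$genotype == g
    c(inside = sum(inside[s]), outside = sum(!inside[s]))
  }, integer(2)))
  storage.mode(tab) <- "integer"
  list(table = tab, p = fisher_exact(tab, tail), inside = inside)
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare group means (t-test, ANOVA with SNK or Tukey post hoc)
#'
#' `"t"`: pooled-variance two-sample Student t-test. `"anova_snk"` /
#' `"anova_tukey"`: one-way ANOVA followed by the Student-Newman-Keuls or
#' Tukey HSD multiple-comparison procedure on studentized-range critical
#' values. Significance flags use the star convention `*` < 0.05,
#' `**` < 0.01, `***` < 0.001.
#'
#' @param values named list of numeric vectors, one per group.
#' @param method `"t"`, `"anova_snk"` or `"anova_tukey"`.
#' @return list with the omnibus `statistic`, `df`, `p`, and a `pairs`
#'   data.frame (group1, group2, diff, p, stars).
#' @export
compare_groups <- function(values, method = c("t", "anova_snk", "anova_tukey")) {
  method <- match.arg(method)
  if (length(values) < 2) stop("need at least two groups")
  if (any(vapply(values, length, 0L) < 2)) stop("need >= 2 values per group")
  g <- names(values)
  if (is.null(g)) g <- paste0("group", seq_along(values))
  ns <- vapply(values, length, 0L)
  ms <- vapply(values, mean, 0)
  vs <- vapply(values, stats::var, 0)

  if (method == "t") {
    if (length(values) != 2) stop("t-test requires exactly two groups")
    df <- sum(ns) - 2L
    sp2 <- sum((ns - 1) * vs) / df
    d <- ms[1] - ms[2]
    if (sp2 == 0) {
      tstat <- if (d == 0) 0 else Inf * sign(d)
      p <- if (d == 0) 1 else 0
    } else {
      tstat <- unname(d / sqrt(sp2 * (1 / ns[1] + 1 / ns[2])))
      p <- unname(2 * stats::pt(-abs(tstat), df))
    }
    pairs <- data.frame(group1 = g[1], group2 = g[2], diff = unname(d),
                        p = p, stars = .stars(p))
    return(list(method = method, statistic = unname(tstat), df = df,
                p = p, pairs = pairs))
  }

  k <- length(values)
  N <- sum(ns)
  grand <- sum(ns * ms) / N
  ssb <- sum(ns * (ms - grand)^2)
  ssw <- sum((ns - 1) * vs)
  df1 <- k - 1L; df2 <- N - k
  mse <- ssw / df2
  fstat <- if (mse == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / df1) / mse
  p_f <- if (is.infinite(fstat)) 0 else stats::pf(fstat, df1, df2,
                                                  lower.tail = FALSE)

  ord <- order(ms)
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      a <- ord[i]; b <- ord[j]
      se <- sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b]))
      q_obs <- if (se == 0) {
        if (ms[b] == ms[a]) 0 else Inf
      } else abs(ms[b] - ms[a]) / se
      # SNK uses the number of means spanned; Tukey always uses k
      r_span <- if (method == "anova_snk") j - i + 1L else k
      pq <- if (is.infinite(q_obs)) 0 else
        stats::ptukey(q_obs, r_span, df2, lower.tail = FALSE)
      pairs[[length(pairs) + 1L]] <- data.frame(
        group1 = g[a], group2 = g[b], diff = unname(ms[b] - ms[a]),
        q = q_obs, span = r_span, p = pq, stars = .stars(pq))
    }
  }
  pairs <- do.call(rbind, pairs)
  if (method == "anova_snk") {
    # step-down protection: a pair is declared non-significant if any pair
    # spanning it (wider range) is non-significant at 0.05
    pos <- stats::setNames(seq_len(k), g[ord])
    for (ii in order(-pairs$span)) {
      lo <- pos[pairs$group1[ii]]; hi <- pos[pairs$group2[ii]]
      if (pairs$p[ii] >= 0.05) {
        inside <- pos[pairs$group1] >= min(lo, hi) &
          pos[pairs$group2] <= max(lo, hi)
        pairs$p[inside] <- pmax(pairs$p[inside], pairs$p[ii])
      }
    }
    pairs$stars <- .stars(pairs$p)
  }
  list(method = method, statistic = unname(fstat), df = c(df1, df2),
       p = p_f, pairs = pairs)
}
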