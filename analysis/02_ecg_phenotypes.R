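#!/usr/bin/env Rscript
# Stage 2: electrocardiographic phenotyping of the simulated cohorts.
#
# Reads the per-animal summaries produced by stage 1 and derives the
# cohort-level results: interval comparisons (RR, PR, QT, QTc, heart rate),
# the qualitative-feature 2x2 table with its exact test, and the
# frontal-axis interval test (wild-type axes concentrate in the leftward
# sector -7..-124 degrees; trisomic axes scatter).

suppressMessages(library(dscardio))
cohort <- read.delim("results/ecg_cohort.tsv")

num <- c("RR", "PR", "QT", "QTc", "heart_rate_mean")
summ <- aggregate(cohort[num], list(genotype = cohort$genotype),
                  function(x) sprintf("%.2f +/- %.2f", mean(x),
                                      sd(x) / sqrt(length(x))))
cat("interval summary (mean +/- sem):\n")
print(summ, row.names = FALSE)

tests <- do.call(rbind, lapply(num, function(v) {
  res <- compare_groups(split(cohort[[v]], cohort$genotype), "t")
  data.frame(measure = v, t = round(res$statistic, 2), df = res$df,
             p = signif(res$p, 3), stars = res$pairs$stars)
}))
cat("\ntwo-sample t-tests (pooled variance):\n")
print(tests, row.names = FALSE)
write.table(tests, "results/interval_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

ft <- feature_table(cohort, c("wt", "Ts65Dn"))
p_ft <- fisher_exact(ft, "two_sided")
cat("\nqualitative-feature table (>=2 of fragmented QRS / slurr / S absence):\n")
print(ft)
cat(sprintf("Fisher exact (two-sided): P = %.3g\n", p_ft))
write.table(data.frame(genotype = rownames(ft), ft,
                       fisher_two_sided_p = p_ft),
            "results/feature_table.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

ax <- data.frame(genotype = cohort$genotype, axis = cohort$frontal_axis)
ax <- ax[is.finite(ax$axis), ]
res_ax <- axis_interval_test(ax, c(-7, -124), c("wt", "Ts65Dn"))
cat("\nfrontal-axis membership of the -7..-124 degree sector:\n")
print(res_ax$table)
cat(sprintf("Fisher exact (two-sided): P = %.3g\n", res_ax$p))
cat(sprintf("wt inside: %.0f%%; Ts65Dn outside: %.0f%%\n",
            100 * res_ax$table["wt", "inside"] / sum(res_ax$table["wt", ]),
            100 * res_ax$table["Ts65Dn", "outside"] /
              sum(res_ax$table["Ts65Dn", ])))
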