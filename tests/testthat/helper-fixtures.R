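# Shared fixtures: small synthetic recordings and printed reference tables.

extdata <- function(file) {
  system.file("extdata", file, package = "dscardio", mustWork = TRUE)
}

# anomaly-free, noise-free recording (exact ground truth)
quiet_recording <- function(genotype = "wt", duration = 10, seed = 1,
                            fs = 5000) {
  simulate_ecg(make_genotype_preset(genotype), duration, fs, seed = seed,
               noise_sd = 0,
               anomaly_p = list(p_notch = 0, p_rsr = 0, p_slurr = 0,
                                p_s_absent = 0))
}

# recording with exactly one anomaly type injected on every beat
single_anomaly_recording <- function(genotype = "Ts65Dn", anomaly, p = 1,
                                     duration = 6, seed = 1, noise_sd = 0) {
  ap <- list(p_notch = 0, p_rsr = 0, p_slurr = 0, p_s_absent = 0)
  ap[[anomaly]] <- p
  simulate_ecg(make_genotype_preset(genotype), duration, 5000, seed = seed,
               noise_sd = noise_sd, anomaly_p = ap)
}

# delineate one mid-trace beat on one lead
mid_beat <- function(recording, lead, beat_index = 3) {
  r <- detect_beats(recording)
  measure_beat(recording, lead, r[beat_index],
               rr_ms = stats::median(diff(r)) * 1000,
               next_r = r[beat_index + 1])
}

# printed weaning transmission counts
weaning_counts <- function() read_genotype_counts(extdata("transmission_weaning.tsv"))

# printed qPCR ratios for the five Mmu16 genes (with significance stars)
qpcr_table <- function() {
  utils::read.delim(extdata("qpcr_mmu16_ratios.tsv"), stringsAsFactors = FALSE)
}

# printed deregulated-gene table (group assignments + ratios + stars)
deregulated_table <- function() {
  utils::read.delim(extdata("deregulated_gene_ratios.tsv"),
                    stringsAsFactors = FALSE)
}

# brute-force Fisher oracle via explicit binomial-coefficient enumeration
fisher_oracle <- function(tab, tail = "two_sided") {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  pts <- vapply(support, function(a) {
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1))
  }, 0)
  p_obs <- pts[support == tab[1, 1]]
  switch(tail,
         lower = sum(pts[support <= tab[1, 1]]),
         upper = sum(pts[support >= tab[1, 1]]),
         two_sided = min(1, sum(pts[pts <= p_obs * (1 + 1e-7)])))
}
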