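# Beat detection and wave delineation against analytic ground truth.

test_that("beat detection recovers every ground-truth beat", {
  rec <- quiet_recording("wt", duration = 10)
  b <- detect_beats(rec)
  gt <- rec$ground_truth$beats$r_time
  expect_length(b, length(gt))
  expect_lt(max(abs(b - gt)) * 1000, 0.5)
  expect_true(all(diff(b) > 0))
})

test_that("beat detection tolerates physiological noise", {
  rec <- simulate_ecg(make_genotype_preset("wt"), 10, 5000, seed = 2,
                      noise_sd = 0.05)
  b <- detect_beats(rec)
  gt <- rec$ground_truth$beats$r_time
  matched <- vapply(gt, function(g) any(abs(b - g) < 0.002), TRUE)
  expect_gte(mean(matched), 0.99)
})

test_that("beat detection errors on flat or missing signal", {
  rec <- quiet_recording("wt", duration = 4)
  rec$leads$Vms <- rep(0, length(rec$leads$Vms))
  expect_error(detect_beats(rec, "Vms"), "no beats")
  expect_error(detect_beats(rec, "nope"), "lead not present")
  short <- quiet_recording("wt", duration = 4)
  short$leads <- lapply(short$leads, function(x) x[1:1000])
  expect_error(detect_beats(short, "Vms"), "2 s")
})

test_that("noise-free amplitudes match the preset table", {
  rec <- quiet_recording("wt", duration = 10, seed = 3)
  p <- rec$ground_truth$preset
  s <- summarize_animal(rec)
  # P/R/S on the rendered leads; Vms carries the T wave whose slow tail
  # overlaps neighbouring waves, so its P (and J) tolerances are looser
  for (lead in c("DI", "aVF", "V1", "Vs", "V4")) {
    for (w in c("P", "R", "S", "J")) {
      tol <- if (w == "J") 0.05 else 0.01
      expect_equal(s$amplitudes[lead, w], p$amplitudes[w, lead],
                   tolerance = tol,
                   label = sprintf("%s %s wave", lead, w))
    }
  }
  expect_equal(s$amplitudes["Vms", "R"], p$amplitudes["R", "Vms"],
               tolerance = 0.02)
  expect_equal(s$amplitudes["Vms", "S"], p$amplitudes["S", "Vms"],
               tolerance = 0.02)
  expect_equal(s$amplitudes["Vms", "T"], p$amplitudes["T", "Vms"],
               tolerance = 0.1)
})

test_that("noise-free intervals match the preset to sub-sample accuracy", {
  rec <- quiet_recording("wt", duration = 10, seed = 4)
  p <- rec$ground_truth$preset
  s <- summarize_animal(rec)
  expect_lt(abs(s$PR - p$PR), 0.2)
  # edge smoothing widens the complex by about one sample period
  expect_lt(abs(s$durations[["QRS"]] - p$QRS_dur), 0.3)
  expect_lt(abs(s$durations[["P"]] - p$P_dur), 0.3)
  expect_lt(abs(s$RR - p$mean_RR), 3 * p$RR_jitter_sd / sqrt(15))
  # QT uses a model-extrapolated offset whose flank truncation depends on
  # the realized RR; accuracy bound 2%
  expect_equal(s$QT, p$QT, tolerance = 0.02)
})

test_that("measurements are invariant to a DC offset", {
  rec <- quiet_recording("wt", duration = 6, seed = 5)
  rec_dc <- rec
  rec_dc$leads <- lapply(rec$leads, function(x) x + 1)
  m0 <- mid_beat(rec, "V1")
  m1 <- mid_beat(rec_dc, "V1")
  expect_equal(m0$amplitudes, m1$amplitudes, tolerance = 1e-9)
  expect_equal(m1$isoelectric_level, m0$isoelectric_level + 1,
               tolerance = 1e-9)
})

test_that("a beat with the S lobe suppressed reports S as missing", {
  rec <- single_anomaly_recording(anomaly = "p_s_absent", noise_sd = 0)
  m <- mid_beat(rec, "Vms")
  expect_true(is.na(m$amplitudes[["S"]]))
  expect_gte(m$s_min, -1e-6)
})

test_that("out-of-bounds beats are skipped with a reason", {
  rec <- quiet_recording("wt", duration = 4)
  m <- measure_beat(rec, "Vms", r_time = 0.01)
  expect_false(m$ok)
  expect_match(m$skip_reason, "bounds")
})

test_that("the QT correction follows QTc = QT / sqrt(RR/100)", {
  expect_equal(compute_qtc(66.57, 94.00), 68.66, tolerance = 1e-4)
  expect_equal(compute_qtc(81.88, 111.88), 77.41, tolerance = 1e-4)
  expect_equal(compute_qtc(55, 100), 55)
  expect_error(compute_qtc(-1, 100), "positive")
  expect_error(compute_qtc(60, 0), "positive")
  # strictly increasing in QT, decreasing in RR
  qt <- seq(40, 90, by = 5)
  expect_true(all(diff(compute_qtc(qt, 95)) > 0))
  rr <- seq(80, 120, by = 5)
  expect_true(all(diff(compute_qtc(70, rr)) < 0))
})

test_that("the frontal axis follows the clinical convention", {
  expect_equal(compute_axis(0.147, -0.134), -42.35, tolerance = 1e-3)
  expect_equal(compute_axis(0.009, 0.016), 60.6, tolerance = 1e-2)
  expect_equal(compute_axis(1, 0), 0)
  expect_equal(compute_axis(0, 1), 90)
  expect_equal(compute_axis(-1, 0), 180)
  expect_true(is.na(compute_axis(0, 0)))
  # invariant to joint positive scaling
  expect_equal(compute_axis(0.3, -0.2), compute_axis(3, -2))
})

test_that("rotating the frontal dipole rotates the recovered axis", {
  p <- make_genotype_preset("wt")
  base <- summarize_animal(quiet_recording("wt", 6, seed = 6))$frontal_axis
  # rotate the QRS dipole by swapping in rotated DI/aVF net amplitudes
  theta <- 30 * pi / 180
  di_n <- sum(p$amplitudes[c("R", "S"), "DI"])
  avf_n <- sum(p$amplitudes[c("R", "S"), "aVF"])
  v <- complex(real = di_n, imaginary = avf_n) * exp(1i * theta)
  scale_di <- Re(v) / di_n
  scale_avf <- Im(v) / avf_n
  p$amplitudes[c("R", "S"), "DI"] <- p$amplitudes[c("R", "S"), "DI"] * scale_di
  p$amplitudes[c("R", "S"), "aVF"] <- p$amplitudes[c("R", "S"), "aVF"] * scale_avf
  rec <- simulate_ecg(p, 6, 5000, seed = 6, noise_sd = 0,
                      anomaly_p = list(p_notch = 0, p_rsr = 0, p_slurr = 0,
                                       p_s_absent = 0))
  rotated <- summarize_animal(rec)$frontal_axis
  expect_equal(((rotated - base - 30 + 180) %% 360) - 180, 0, tolerance = 2)
})

test_that("constant RR of 100 ms gives 600 bpm mean and mode", {
  p <- make_genotype_preset("wt")
  p$mean_RR <- 100
  p$RR_jitter_sd <- 1e-9
  rec <- simulate_ecg(p, 21, 5000, seed = 7, noise_sd = 0,
                      anomaly_p = list(p_notch = 0, p_rsr = 0, p_slurr = 0,
                                       p_s_absent = 0))
  s <- summarize_animal(rec)
  expect_equal(s$heart_rate_mean, 600, tolerance = 1e-3)
  expect_lt(abs(s$heart_rate_mode - 600), 5)  # inside the 5-bpm mode bin
})

test_that("summaries error when no checkpoint holds enough beats", {
  rec <- quiet_recording("wt", duration = 3)
  expect_error(summarize_animal(rec, beats_per_checkpoint = 100),
               "checkpoint")
})

test_that("preset intervals are recovered across seeded animals", {
  for (g in c("wt", "Ts65Dn")) {
    p <- make_genotype_preset(g)
    res <- vapply(1:6, function(i) {
      s <- summarize_animal(simulate_ecg(p, 20, 5000, seed = 900 + i,
                                         anomaly_p = list(p_notch = 0,
                                                          p_rsr = 0,
                                                          p_slurr = 0,
                                                          p_s_absent = 0)))
      c(s$RR, s$PR, s$durations[["QRS"]], s$QT)
    }, numeric(4))
    m <- rowMeans(res)
    expect_equal(m[1], p$mean_RR, tolerance = 0.05, label = paste(g, "RR"))
    expect_equal(m[2], p$PR, tolerance = 0.05, label = paste(g, "PR"))
    expect_equal(m[3], p$QRS_dur, tolerance = 0.05, label = paste(g, "QRS"))
    expect_equal(m[4], p$QT, tolerance = 0.05, label = paste(g, "QT"))
  }
})
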