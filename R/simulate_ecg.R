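# Synthetic multi-lead mouse ECG.
#
# Waveform model: each beat is a sum of asymmetric Gaussian lobes (independent
# left/right widths) for the P, R, S, J and T waves. Nominal wave onsets and
# offsets are defined as the 5%-of-peak crossing of the corresponding lobe,
# so the delineation ground truth is analytic. The frontal plane is a
# two-component dipole: DI and aVF are rendered from the preset amplitude
# table and DII, DIII, aVR, aVL follow from the Einthoven/Goldberger
# identities (DIII = aVF - DI/2, DII = DI + DIII, aVR = -(DI + DII)/2,
# aVL = (DI - DIII)/2), which therefore hold exactly before noise injection.
# Precordial leads are independent templates against the Wilson reference.

# Fraction of the QRS duration preceding the R peak; the S nadir sits at
# +0.35 QRS and the QRS offset at +0.65 QRS.
.QRS_ON_FRAC <- 0.35
.QRS_OFF_FRAC <- 0.65
.S_NADIR_FRAC <- 0.35
.EDGE_Z <- sqrt(2 * log(20))  # 5%-of-peak crossing sits at 2.448 sd

.asym_gauss <- function(tau, center, amp, sl, sr) {
  s <- ifelse(tau < center, sl, sr)
  amp * exp(-0.5 * ((tau - center) / s)^2)
}

# Nominal event times of one beat, ms relative to the R peak.
.beat_schedule <- function(preset) {
  qrs_on <- -.QRS_ON_FRAC * preset$QRS_dur
  qrs_off <- .QRS_OFF_FRAC * preset$QRS_dur
  p_on <- qrs_on - preset$PR
  list(
    qrs_on = qrs_on, qrs_off = qrs_off,
    p_on = p_on, p_off = p_on + preset$P_dur,
    p_peak = p_on + preset$P_dur / 2,
    s_nadir = .S_NADIR_FRAC * preset$QRS_dur,
    j_peak = qrs_off + 3,
    t_peak = qrs_off + 10,
    t_off = qrs_on + preset$QT
  )
}

# Lobe list for one channel (times ms relative to R peak, amplitudes mV).
# The T lobe's right width is set so that the steepest-descent tangent of
# its downslope meets the baseline exactly at the nominal T offset
# (t_peak + 2 sigma, matching the delineation's tangent-extrapolated
# T-offset convention); sharp waves use the 5%-crossing convention.
.channel_lobes <- function(preset, lead) {
  sc <- .beat_schedule(preset)
  a <- preset$amplitudes[, lead]
  q <- preset$QRS_dur
  lobes <- list()
  if (!is.na(a[["P"]]) && a[["P"]] != 0) {
    sp <- (preset$P_dur / 2) / .EDGE_Z
    lobes$P <- list(center = sc$p_peak, amp = a[["P"]], sl = sp, sr = sp)
  }
  if (!is.na(a[["R"]]) && a[["R"]] != 0) {
    lobes$R <- list(center = 0, amp = a[["R"]],
                    sl = .QRS_ON_FRAC * q / .EDGE_Z, sr = 0.09 * q)
  }
  if (!is.na(a[["S"]]) && a[["S"]] != 0) {
    lobes$S <- list(center = sc$s_nadir, amp = a[["S"]],
                    sl = 0.09 * q,
                    sr = (.QRS_OFF_FRAC - .S_NADIR_FRAC) * q / .EDGE_Z)
  }
  if (!is.na(a[["J"]]) && a[["J"]] != 0) {
    lobes$J <- list(center = sc$j_peak, amp = a[["J"]], sl = 1.2, sr = 1.2)
  }
  if (!is.na(a[["T"]]) && a[["T"]] != 0) {
    lobes$T <- list(center = sc$t_peak, amp = a[["T"]],
                    sl = 3, sr = (sc$t_off - sc$t_peak) / 2)
  }
  lobes
}

# Monotone time warp implementing the R-foot slurr: from 45% of the
# onset-to-peak span the upstroke advances at 20% of nominal speed for
# 2.5 ms, then catches up linearly by the S nadir (the R peak is rendered
# slightly late, as on a genuinely slurred complex).
.slurr_warp <- function(tau, qrs_on, s_nadir) {
  t0 <- 0.55 * qrs_on
  t1 <- t0 + 2.5
  w1 <- t0 + 0.2 * 2.5
  out <- tau
  mid <- tau >= t0 & tau < t1
  out[mid] <- t0 + 0.2 * (tau[mid] - t0)
  late <- tau >= t1 & tau < s_nadir
  out[late] <- w1 + (tau[late] - t1) * (s_nadir - w1) / (s_nadir - t1)
  out
}

.render_beat <- function(tau, lobes, slurr = FALSE, qrs_on = NULL,
                         s_nadir = NULL) {
  if (slurr) tau <- .slurr_warp(tau, qrs_on, s_nadir)
  v <- 0
  for (lb in lobes) v <- v + .asym_gauss(tau, lb$center, lb$amp, lb$sl, lb$sr)
  v
}

#' Simulate a multi-lead mouse ECG recording
#'
#' Generates a beat train with normally distributed RR intervals (truncated
#' positive) and renders P, QRS, J and T waves as asymmetric Gaussian lobes
#' on the six limb leads (via a two-component frontal dipole, so the
#' Einthoven/Goldberger identities hold exactly before noise) and the four
#' precordial leads (independent templates). Qualitative anomalies are
#' injected per beat and per lead as independent Bernoulli events:
#' \describe{
#'   \item{notch}{short opposite-polarity lobe splitting the S nadir
#'     (an S-wave notch), injected into the frontal dipole so it appears on
#'     the inferior leads (DII, DIII, aVF) without crossing the baseline;}
#'   \item{RSR'}{secondary positive lobe after the S nadir on V1, returning
#'     above baseline, with the S wave halved (low-voltage S);}
#'   \item{slurr}{lower-limb upstroke slope reduced to 20% of nominal for
#'     2.5 ms on V1 and Vms;}
#'   \item{S absence}{S lobe suppressed on V1, Vms or Vs so the post-R
#'     minimum is non-negative.}
#' }
#' Ground truth (exact event times and the per-beat anomaly ledger) is
#' attached to the returned recording.
#'
#' @param preset a [make_genotype_preset()] object.
#' @param duration recording length in seconds (must hold at least 2 beats).
#' @param sampling_rate sampling frequency in Hz (>= 1000; the reference
#'   protocols use 2000 and 5000).
#' @param seed integer seed; all randomness in the call derives from it.
#' @param noise_sd optional override of the preset additive Gaussian noise
#'   SD (mV).
#' @param anomaly_p optional named list overriding any of `p_notch`, `p_rsr`,
#'   `p_slurr`, `p_s_absent`.
#' @param band_limit if `TRUE`, apply a 1-500 Hz Butterworth band-pass
#'   mimicking the acquisition chain (default off).
#' @param animal_id label stored on the recording.
#' @return an `ecg_recording`: named list of lead traces (mV), sampling rate,
#'   duration, genotype, and a `ground_truth` list with the preset, per-beat
#'   event times (s) and the anomaly ledger.
#' @export
simulate_ecg <- function(preset, duration, sampling_rate = 5000, seed,
                         noise_sd = NULL, anomaly_p = NULL,
                         band_limit = FALSE, animal_id = "sim") {
  validate_genotype_preset(preset)
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  if (!is.numeric(sampling_rate) || sampling_rate < 1000) {
    stop("sampling_rate must be >= 1000 Hz")
  }
  if (duration * 1000 < 2 * preset$mean_RR) {
    stop("duration must cover at least 2 beats")
  }
  if (missing(seed)) stop("seed is required")
  if (!is.null(noise_sd)) preset$noise_sd <- noise_sd
  if (!is.null(anomaly_p)) {
    for (nm in names(anomaly_p)) {
      if (!nm %in% c("p_notch", "p_rsr", "p_slurr", "p_s_absent")) {
        stop("unknown anomaly probability: ", nm)
      }
      preset[[nm]] <- anomaly_p[[nm]]
    }
  }
  validate_genotype_preset(preset)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  dur_ms <- duration * 1000
  sc <- .beat_schedule(preset)

  # beat train: first R placed so the full PQ complex fits in the trace
  n_est <- ceiling(dur_ms / max(preset$mean_RR - 4 * preset$RR_jitter_sd, 1)) + 3
  rr <- stats::rnorm(n_est, preset$mean_RR, preset$RR_jitter_sd)
  rr <- pmax(rr, 0.5 * preset$mean_RR)  # truncate away non-physiological draws
  r_ms <- (-sc$p_on + 2) + cumsum(c(0, rr))
  r_ms <- r_ms[r_ms <= dur_ms]
  n_beats <- length(r_ms)
  if (n_beats < 2) stop("duration must cover at least 2 beats")

  anomalies <- data.frame(
    notch = stats::runif(n_beats) < preset$p_notch,
    rsr_V1 = stats::runif(n_beats) < preset$p_rsr,
    slurr_V1 = stats::runif(n_beats) < preset$p_slurr,
    slurr_Vms = stats::runif(n_beats) < preset$p_slurr,
    sab_V1 = stats::runif(n_beats) < preset$p_s_absent,
    sab_Vms = stats::runif(n_beats) < preset$p_s_absent,
    sab_Vs = stats::runif(n_beats) < preset$p_s_absent
  )

  n <- round(duration * sampling_rate)
  t_ms <- (seq_len(n) - 1) / sampling_rate * 1000
  base_channels <- c("DI", "aVF", PRECORDIAL_LEADS)
  ch <- lapply(stats::setNames(base_channels, base_channels),
               function(l) numeric(n))
  lobes <- lapply(stats::setNames(base_channels, base_channels),
                  function(l) .channel_lobes(preset, l))
  q <- preset$QRS_dur
  win_lo <- sc$p_on - 4
  win_hi <- max(sc$t_off + 6, sc$j_peak + 5)

  for (b in seq_len(n_beats)) {
    r <- r_ms[b]
    i0 <- max(1L, floor((r + win_lo) / 1000 * sampling_rate) + 1L)
    i1 <- min(n, ceiling((r + win_hi) / 1000 * sampling_rate) + 1L)
    if (i0 > i1) next
    tau <- t_ms[i0:i1] - r
    for (lead in base_channels) {
      lb <- lobes[[lead]]
      slurred <- (lead == "V1" && anomalies$slurr_V1[b]) ||
        (lead == "Vms" && anomalies$slurr_Vms[b])
      sab <- (lead == "V1" && anomalies$sab_V1[b]) ||
        (lead == "Vms" && anomalies$sab_Vms[b]) ||
        (lead == "Vs" && anomalies$sab_Vs[b])
      rsr <- lead == "V1" && anomalies$rsr_V1[b]
      notch <- lead == "aVF" && anomalies$notch[b]
      lb_b <- lb
      if (sab) lb_b$S <- NULL
      if (rsr && !is.null(lb_b$S)) lb_b$S$amp <- lb_b$S$amp * 0.5
      if (rsr && !is.null(lb$R)) {
        lb_b$RSR <- list(center = 0.50 * q, amp = 0.35 * lb$R$amp,
                         sl = 0.6, sr = 0.6)
      }
      if (notch && !is.null(lb$S)) {
        # S-wave notch: the S nadir splits into two narrow sub-lobes with a
        # prominent valley between them, staying below the baseline
        s_amp <- lb_b$S$amp
        s_sl <- lb_b$S$sl
        s_sr <- lb_b$S$sr
        lb_b$S <- list(center = sc$s_nadir - 1, amp = 0.9 * s_amp,
                       sl = s_sl * 0.6, sr = 0.6 * 0.09 * q)
        lb_b$S2 <- list(center = sc$s_nadir + 1, amp = 0.9 * s_amp,
                        sl = 0.6 * 0.09 * q, sr = s_sr)
      }
      ch[[lead]][i0:i1] <- ch[[lead]][i0:i1] +
        .render_beat(tau, lb_b, slurred, sc$qrs_on, sc$s_nadir)
    }
  }

  leads <- vector("list", length(ECG_LEADS))
  names(leads) <- ECG_LEADS
  leads$DI <- ch$DI
  leads$aVF <- ch$aVF
  leads$DIII <- ch$aVF - 0.5 * ch$DI
  leads$DII <- leads$DI + leads$DIII
  leads$aVR <- -(leads$DI + leads$DII) / 2
  leads$aVL <- (leads$DI - leads$DIII) / 2
  for (l in PRECORDIAL_LEADS) leads[[l]] <- ch[[l]]

  if (band_limit) {
    bf <- signal::butter(2, c(1, 500) / (sampling_rate / 2), type = "pass")
    leads <- lapply(leads, function(x) as.numeric(signal::filtfilt(bf, x)))
  }
  if (preset$noise_sd > 0) {
    for (l in ECG_LEADS) {
      leads[[l]] <- leads[[l]] + stats::rnorm(n, 0, preset$noise_sd)
    }
  }

  beats <- data.frame(
    beat = seq_len(n_beats),
    r_time = r_ms / 1000,
    p_on = (r_ms + sc$p_on) / 1000,
    p_peak = (r_ms + sc$p_peak) / 1000,
    p_off = (r_ms + sc$p_off) / 1000,
    qrs_on = (r_ms + sc$qrs_on) / 1000,
    qrs_off = (r_ms + sc$qrs_off) / 1000,
    j_peak = (r_ms + sc$j_peak) / 1000,
    t_peak = (r_ms + sc$t_peak) / 1000,
    t_off = (r_ms + sc$t_off) / 1000
  )

  led <- function(flag, lead, anomaly) {
    if (!any(flag)) return(NULL)
    data.frame(beat = which(flag), lead = lead, anomaly = anomaly)
  }
  ledger <- rbind(
    led(anomalies$notch, "DII", "notch"),
    led(anomalies$notch, "DIII", "notch"),
    led(anomalies$notch, "aVF", "notch"),
    led(anomalies$rsr_V1, "V1", "rsr"),
    led(anomalies$slurr_V1, "V1", "slurr"),
    led(anomalies$slurr_Vms, "Vms", "slurr"),
    led(anomalies$sab_V1, "V1", "s_absent"),
    led(anomalies$sab_Vms, "Vms", "s_absent"),
    led(anomalies$sab_Vs, "Vs", "s_absent")
  )
  if (is.null(ledger)) {
    ledger <- data.frame(beat = integer(), lead = character(),
                         anomaly = character())
  }

  structure(list(
    animal_id = animal_id,
    genotype = preset$name,
    sampling_rate = sampling_rate,
    duration = duration,
    leads = leads,
    ground_truth = list(preset = preset, beats = beats, anomalies = ledger)
  ), class = "ecg_recording")
}

#' Sample times of a recording, in seconds
#' @param recording an `ecg_recording`.
#' @return numeric vector of sample times.
#' @export
recording_time <- function(recording) {
  stopifnot(inherits(recording, "ecg_recording"))
  (seq_along(recording$leads[[1]]) - 1) / recording$sampling_rate
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %s (%s): %.1f s at %d Hz, %d leads",
              x$animal_id, x$genotype, x$duration,
              as.integer(x$sampling_rate), length(x$leads)))
  if (!is.null(x$ground_truth)) {
    cat(sprintf(", %d ground-truth beats", nrow(x$ground_truth$beats)))
  }
  cat("\n")
  invisible(x)
}
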