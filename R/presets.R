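#' Lead-set constants
#'
#' The canonical ten-lead set: the six limb leads (Einthoven/Goldberger)
#' plus the four precordial derivations (V1, Vms, Vs, V4) referenced to the
#' Wilson central terminal, with the precordial and inferior subsets used
#' for feature scoring.
#'
#' @name lead_sets
#' @export
ECG_LEADS <- c("DI", "DII", "DIII", "aVR", "aVL", "aVF", "V1", "Vms", "Vs", "V4")

#' @rdname lead_sets
#' @export
PRECORDIAL_LEADS <- c("V1", "Vms", "Vs", "V4")

#' @rdname lead_sets
#' @export
INFERIOR_LEADS <- c("DII", "DIII", "aVF")

PRESET_NAMES <- c("wt", "Ts65Dn", "Ts65Dn/Ms5Yah", "Ms5Yah", "flecainide-Ts65Dn")

# Group-mean amplitude tables (mV). Rows: waves P,R,S,J,T; columns: leads.
# aVR entries are recorded on the clinical -aVR display convention (so the
# R entry is positive); aVL is a derived lead with no reference group mean
# and carries NA. T is rendered on Vms only: the delayed T wave is elusive
# on other leads, where it is modelled as absent.
.amp_table <- function(P, R, S, J, T) {
  m <- rbind(P = P, R = R, S = S, J = J, T = T)
  colnames(m) <- ECG_LEADS
  m
}

.wt_amps <- .amp_table(
  P = c(0.081, 0.172, 0.093, 0.138, NA, 0.128, 0.107, 0.181, 0.117, 0.096),
  R = c(0.334, 0.670, 0.555, 0.446, NA, 0.622, 0.879, 1.574, 0.897, 1.178),
  S = c(-0.187, -0.662, -0.793, -0.331, NA, -0.756, -0.358, -0.723, -0.714, -1.137),
  J = c(0.100, 0.180, 0.150, 0.120, NA, 0.160, 0.200, 0.300, 0.250, 0.200),
  T = c(0, 0, 0, 0, NA, 0, 0, 0.120, 0, 0)
)

.ts65dn_amps <- .amp_table(
  P = c(0.085, 0.159, 0.090, 0.120, NA, 0.107, 0.073, 0.151, 0.097, 0.161),
  R = c(0.356, 0.545, 0.433, 0.332, NA, 0.468, 0.770, 1.466, 0.716, 1.290),
  S = c(-0.347, -0.527, -0.504, -0.401, NA, -0.452, -0.119, -0.291, -0.313, -0.832),
  J = c(0.090, 0.130, 0.110, 0.110, NA, 0.100, 0.120, 0.180, 0.150, 0.180),
  T = c(0, 0, 0, 0, NA, 0, 0, 0.080, 0, 0)
)

# Compound Ts65Dn/Ms5Yah: frontal-plane amplitudes follow Ts65Dn (not
# rescued), precordial amplitudes follow wt (rescued) except the V1 S wave.
.tsms_amps <- local({
  m <- .ts65dn_amps
  m[, PRECORDIAL_LEADS] <- .wt_amps[, PRECORDIAL_LEADS]
  m["S", "V1"] <- .ts65dn_amps["S", "V1"]
  m["T", "Vms"] <- 0.10
  m
})

.new_preset <- function(name, mean_RR, RR_jitter_sd, PR, P_dur, QRS_dur, QT,
                        amplitudes, p_notch, p_rsr, p_slurr, p_s_absent,
                        noise_sd) {
  di <- sum(amplitudes[c("R", "S"), "DI"])
  avf <- sum(amplitudes[c("R", "S"), "aVF"])
  x <- list(
    name = name, mean_RR = mean_RR, RR_jitter_sd = RR_jitter_sd,
    PR = PR, P_dur = P_dur, QRS_dur = QRS_dur, QT = QT,
    amplitudes = amplitudes,
    p_notch = p_notch, p_rsr = p_rsr, p_slurr = p_slurr,
    p_s_absent = p_s_absent,
    noise_sd = noise_sd,
    axis_target = compute_axis(di, avf)
  )
  class(x) <- "genotype_preset"
  validate_genotype_preset(x)
  x
}

#' Validate a genotype preset
#'
#' Checks the internal consistency of a [make_genotype_preset()] object:
#' positive durations, interval ordering (`PR > P_dur`, `QT > QRS_dur`,
#' `mean_RR > QT`), probabilities in `[0, 1]`, a complete ten-lead amplitude
#' table and the sign convention (R-wave amplitudes non-negative, S-wave
#' amplitudes non-positive, on every lead carrying a reference value).
#'
#' @param preset a `genotype_preset` object.
#' @return the preset, invisibly; errors describe the violated constraint.
#' @export
validate_genotype_preset <- function(preset) {
  stopifnot(inherits(preset, "genotype_preset"))
  dur <- c(mean_RR = preset$mean_RR, PR = preset$PR, P_dur = preset$P_dur,
           QRS_dur = preset$QRS_dur, QT = preset$QT)
  if (any(dur <= 0)) {
    stop("all durations must be positive; offending: ",
         paste(names(dur)[dur <= 0], collapse = ", "))
  }
  if (preset$PR <= preset$P_dur) stop("PR must exceed P duration")
  if (preset$QT <= preset$QRS_dur) stop("QT must exceed QRS duration")
  if (preset$mean_RR <= preset$QT) stop("mean RR must exceed QT")
  p <- c(preset$p_notch, preset$p_rsr, preset$p_slurr, preset$p_s_absent)
  if (any(p < 0 | p > 1)) stop("anomaly probabilities must be in [0, 1]")
  a <- preset$amplitudes
  if (!identical(colnames(a), ECG_LEADS) ||
      !all(c("P", "R", "S", "J", "T") %in% rownames(a))) {
    stop("amplitude table must cover all ten leads for waves P, R, S, J, T")
  }
  rs <- a["R", ]; ss <- a["S", ]
  if (any(rs < 0, na.rm = TRUE)) stop("R-wave amplitudes must be >= 0")
  if (any(ss > 0, na.rm = TRUE)) stop("S-wave amplitudes must be <= 0")
  if (preset$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(preset)
}

#' Built-in genotype presets for the synthetic ECG generator
#'
#' Returns the waveform/interval parameter set for one of the built-in mouse
#' genotypes. Interval means and the P/R/S amplitude tables are the reference
#' group means for each genotype under urethane anaesthesia: wild type
#' (heart rate 667 bpm, PR 35.3 ms, QRS 9.02 ms, QT 67.5 ms), the Ts65Dn
#' segmental trisomy (606 bpm, PR 44.6 ms, QRS 9.89 ms, QT 73.0 ms), the
#' compound Ts65Dn/Ms5Yah rescue (RR 97.8 ms, PR 39.3 ms, QT back towards
#' wild type), the Ms5Yah monosomy (no adult ECG phenotype; modelled as wild
#' type) and Ts65Dn under 20 mg/kg flecainide (all intervals prolonged).
#'
#' Anomaly injection probabilities are per beat and per lead:
#' `p_notch` (inferior limb leads), `p_rsr` (V1), `p_slurr` (V1, Vms) and
#' `p_s_absent` (V1, Vms, Vs). The trisomic presets default these high (0.9),
#' wild type low (0.03), the compound model intermediate (0.45).
#'
#' @param name one of `"wt"`, `"Ts65Dn"`, `"Ts65Dn/Ms5Yah"`, `"Ms5Yah"`,
#'   `"flecainide-Ts65Dn"`.
#' @return a `genotype_preset` list: intervals (ms), per-lead amplitude table
#'   (mV), anomaly probabilities, additive noise SD (mV) and the frontal-axis
#'   target (degrees) implied by the DI/aVF net QRS amplitudes.
#' @examples
#' make_genotype_preset("wt")$QT        # 67.5 ms
#' make_genotype_preset("Ts65Dn")$PR    # 44.6 ms
#' @export
make_genotype_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% PRESET_NAMES)) {
    stop("unknown genotype preset; valid labels: ",
         paste(PRESET_NAMES, collapse = ", "))
  }
  switch(name,
    "wt" = .new_preset("wt",
      mean_RR = 60000 / 667, RR_jitter_sd = 2,
      PR = 35.3, P_dur = 10, QRS_dur = 9.02, QT = 67.5,
      amplitudes = .wt_amps,
      p_notch = 0.03, p_rsr = 0.03, p_slurr = 0.03, p_s_absent = 0.03,
      noise_sd = 0.02),
    "Ts65Dn" = .new_preset("Ts65Dn",
      mean_RR = 60000 / 606, RR_jitter_sd = 2,
      PR = 44.6, P_dur = 11.75, QRS_dur = 9.89, QT = 73.0,
      amplitudes = .ts65dn_amps,
      p_notch = 0.9, p_rsr = 0.9, p_slurr = 0.9, p_s_absent = 0.9,
      noise_sd = 0.02),
    "Ts65Dn/Ms5Yah" = .new_preset("Ts65Dn/Ms5Yah",
      mean_RR = 97.8, RR_jitter_sd = 2,
      PR = 39.3, P_dur = 11, QRS_dur = 9.6,
      QT = 65.5 * sqrt(97.8 / 100),  # from the reported QTc and RR
      amplitudes = .tsms_amps,
      p_notch = 0.45, p_rsr = 0.45, p_slurr = 0.45, p_s_absent = 0.45,
      noise_sd = 0.02),
    "Ms5Yah" = .new_preset("Ms5Yah",
      mean_RR = 60000 / 667, RR_jitter_sd = 2,
      PR = 35.3, P_dur = 10, QRS_dur = 9.02, QT = 67.5,
      amplitudes = .wt_amps,
      p_notch = 0.03, p_rsr = 0.03, p_slurr = 0.03, p_s_absent = 0.03,
      noise_sd = 0.02),
    "flecainide-Ts65Dn" = .new_preset("flecainide-Ts65Dn",
      mean_RR = 111.88, RR_jitter_sd = 3,
      PR = 55.63, P_dur = 21.13, QRS_dur = 14.25, QT = 81.88,
      amplitudes = .ts65dn_amps,
      p_notch = 0.9, p_rsr = 0.9, p_slurr = 0.9, p_s_absent = 0.9,
      noise_sd = 0.02)
  )
}

#' Look up a wave amplitude in a preset
#'
#' @param preset a `genotype_preset`.
#' @param lead lead name (one of the ten-lead set).
#' @param wave one of `"P"`, `"R"`, `"S"`, `"J"`, `"T"`.
#' @return amplitude in mV (NA on the derived aVL lead).
#' @export
preset_amplitude <- function(preset, lead, wave) {
  stopifnot(inherits(preset, "genotype_preset"))
  if (!(lead %in% ECG_LEADS)) stop("unknown lead: ", lead)
  if (!(wave %in% rownames(preset$amplitudes))) stop("unknown wave: ", wave)
  unname(preset$amplitudes[wave, lead])
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat("<genotype_preset>", x$name, "\n")
  cat(sprintf("  RR %.2f ms (jitter sd %.2f)  PR %.2f  QRS %.2f  QT %.2f ms\n",
              x$mean_RR, x$RR_jitter_sd, x$PR, x$QRS_dur, x$QT))
  cat(sprintf("  axis target %.1f deg, noise sd %.3f mV\n",
              x$axis_target, x$noise_sd))
  cat(sprintf("  anomaly p: notch %.2f rsr %.2f slurr %.2f s_absent %.2f\n",
              x$p_notch, x$p_rsr, x$p_slurr, x$p_s_absent))
  invisible(x)
}
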