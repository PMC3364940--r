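# Beat detection and wave delineation.
#
# Measurement conventions: the isoelectric level of each beat is the mean of
# five consecutive samples taken between the end of the P wave and the QRS
# onset, in a window starting 15 ms before the QRS onset (mouse ECG has no
# true electrical zero). Wave onsets/offsets are 5%-of-own-peak threshold
# crossings, except the T-wave offset: the delayed mouse T is broad and
# shallow and its terminal portion fuses with the next beat's P wave, so
# the offset is extrapolated tangent-style - the T downslope is fitted with
# a Gaussian flank over the clean segment before the next P wave, and the
# offset taken where the steepest-descent tangent of the fitted flank
# meets the isoelectric line (t_peak + 2 sigma). QT is measured on Vms
# only, where the T wave is constantly identified.

#' Default delineation settings
#'
#' @param amp_smooth_ms moving-average width for amplitude measurement (ms).
#' @param edge_smooth_ms moving-average width for onset/offset detection (ms).
#' @param t_smooth_ms moving-average width for T-wave processing (ms).
#' @param edge_frac onset/offset threshold as a fraction of the wave's own
#'   peak (default 0.05).
#' @param refractory_ms beat-detection refractory period (ms).
#' @param p_search_ms how far before the QRS onset to search for the P wave.
#' @param wave_floor_mv minimum deviation for a wave to be called present.
#' @param pr_lead,qt_lead,rr_lead leads used for the PR interval, the QT
#'   interval and beat detection.
#' @return a named list of settings.
#' @export
delineation_config <- function(amp_smooth_ms = 0.6,
                               edge_smooth_ms = 1.2,
                               t_smooth_ms = 2.0,
                               edge_frac = 0.05,
                               refractory_ms = 30,
                               p_search_ms = 65,
                               wave_floor_mv = 0.02,
                               pr_lead = "DII",
                               qt_lead = "Vms",
                               rr_lead = "Vms") {
  as.list(environment())
}

# centered moving average; width in samples (made odd), edges padded
.ma <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(h + 1L):(h + length(x))]
}

.ms_to_n <- function(ms, fs) max(1L, round(ms / 1000 * fs))

# leftward 5%-crossing: walk left from `from` until z drops below `level`;
# returns interpolated time (s) or NA
.cross_left <- function(z, t, from, level, min_idx) {
  j <- from
  while (j > min_idx && z[j] >= level) j <- j - 1L
  if (z[j] >= level) return(NA_real_)
  # interpolate between j (below) and j+1 (above)
  t[j] + (t[j + 1L] - t[j]) * (level - z[j]) / (z[j + 1L] - z[j])
}

.cross_right <- function(z, t, from, level, max_idx) {
  j <- from
  while (j < max_idx && z[j] >= level) j <- j + 1L
  if (z[j] >= level) return(NA_real_)
  t[j] - (t[j] - t[j - 1L]) * (level - z[j]) / (z[j - 1L] - z[j])
}

#' Detect R peaks in one lead
#'
#' Band-passed-amplitude thresholding: the trace is smoothed, a slow moving
#' average is subtracted (baseline/large-wave suppression), samples above
#' 45% of the filtered maximum are grouped into candidate complexes, and the
#' local maximum of each group is kept subject to a refractory period.
#'
#' @param recording an `ecg_recording`.
#' @param lead lead name (default from `config`).
#' @param config a [delineation_config()].
#' @return monotone increasing vector of R-peak times (s).
#' @export
detect_beats <- function(recording, lead = NULL, config = delineation_config()) {
  stopifnot(inherits(recording, "ecg_recording"))
  if (is.null(lead)) lead <- config$rr_lead
  if (!lead %in% names(recording$leads)) stop("lead not present: ", lead)
  fs <- recording$sampling_rate
  x <- recording$leads[[lead]]
  if (length(x) < 2 * fs) stop("need at least 2 s of signal")
  y <- .ma(x, .ms_to_n(1, fs))
  hp <- y - .ma(y, .ms_to_n(25, fs))
  peak <- max(hp)
  if (!is.finite(peak) || peak < 0.15) {
    stop("no beats found: filtered signal never exceeds 0.15 mV")
  }
  thr <- 0.45 * peak
  above <- hp > thr
  if (!any(above)) stop("no beats found")
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  idx <- mapply(function(s, e) s + which.max(y[s:e]) - 1L, starts, ends)
  amp <- y[idx]
  # refractory: greedy by amplitude
  refr <- .ms_to_n(config$refractory_ms, fs)
  keep <- logical(length(idx))
  for (o in order(amp, decreasing = TRUE)) {
    if (!any(keep & abs(idx - idx[o]) < refr)) keep[o] <- TRUE
  }
  sort((idx[keep] - 1L) / fs)
}

#' Delineate one beat on one lead
#'
#' Locates the QRS onset/offset (5%-of-R threshold crossings), the
#' isoelectric level (five-sample mean starting 15 ms before QRS onset),
#' signed wave extrema in ordered search windows (P before the QRS; Q, R, S
#' within it; J immediately after; T delayed, on the QT lead only) and the
#' derived amplitudes (relative to the isoelectric level) and durations.
#'
#' @param recording an `ecg_recording`.
#' @param lead lead name.
#' @param r_time R-peak time (s), from [detect_beats()].
#' @param rr_ms running RR estimate (ms) used to bound search windows.
#' @param next_r time of the following R peak (s), if known; bounds the
#'   T-wave search.
#' @param config a [delineation_config()].
#' @return a `beat_measurement` list: `ok` flag (with `skip_reason`),
#'   isoelectric level, amplitudes (mV, NA when the wave is absent),
#'   `s_min` (post-R minimum relative to the isoelectric level), durations
#'   (ms), onset/offset times (s).
#' @export
measure_beat <- function(recording, lead, r_time, rr_ms = 90, next_r = NA,
                         config = delineation_config()) {
  stopifnot(inherits(recording, "ecg_recording"))
  if (!lead %in% names(recording$leads)) stop("lead not present: ", lead)
  fs <- recording$sampling_rate
  x <- recording$leads[[lead]]
  n <- length(x)
  t <- (seq_len(n) - 1L) / fs
  skip <- function(reason) {
    structure(list(ok = FALSE, skip_reason = reason, lead = lead,
                   r_time = r_time), class = "beat_measurement")
  }

  ya <- NULL; ye <- NULL  # lazily smoothed local segment
  i_r0 <- round(r_time * fs) + 1L
  lo <- i_r0 - .ms_to_n(config$p_search_ms + 25, fs)
  hi <- i_r0 + .ms_to_n(min(rr_ms * 0.85, 95), fs)
  if (lo < 1L || hi > n) return(skip("window out of trace bounds"))
  seg <- lo:hi
  xs <- x[seg]; ts <- t[seg]
  ya <- .ma(xs, .ms_to_n(config$amp_smooth_ms, fs))
  ye <- .ma(xs, .ms_to_n(config$edge_smooth_ms, fs))
  ir <- i_r0 - lo + 1L

  # refine R peak on the amplitude-smoothed trace
  w2 <- .ms_to_n(2, fs)
  rwin <- max(1L, ir - w2):min(length(ya), ir + w2)
  ir <- rwin[which.max(ya[rwin])]

  # rough baseline for the QRS-onset threshold
  b0win <- (ir - .ms_to_n(45, fs)):(ir - .ms_to_n(5, fs))
  if (b0win[1] < 1L) return(skip("window out of trace bounds"))
  b0 <- stats::median(ye[b0win])
  r_raw <- ya[ir] - b0
  if (r_raw < config$wave_floor_mv) return(skip("no R deflection"))

  lvl_on <- b0 + config$edge_frac * r_raw
  qrs_on <- .cross_left(ye, ts, ir, lvl_on, max(1L, ir - .ms_to_n(12, fs)))
  if (is.na(qrs_on)) return(skip("QRS onset not found"))

  # isoelectric level: five consecutive samples of the working (smoothed)
  # trace, starting 15 ms before the QRS onset
  i_iso <- round((qrs_on - 0.015 - ts[1]) * fs) + 1L
  if (i_iso < 1L || i_iso + 4L > length(ye)) {
    return(skip("isoelectric window out of bounds"))
  }
  iso <- mean(ye[i_iso:(i_iso + 4L)])

  r_amp <- xs[ir] - iso

  # S: signed minimum after R within the QRS search span. The absence call
  # uses the more heavily smoothed trace so a suppressed S is not pushed
  # below zero by noise.
  swin <- (ir + 1L):min(length(ya), ir + .ms_to_n(8, fs))
  is_ <- swin[which.min(ya[swin])]
  # absence metric: local mean around the post-R minimum of the smoothed
  # trace (a bare one-sample minimum is biased negative under noise)
  is2 <- swin[which.min(ye[swin])]
  k1 <- .ms_to_n(1, fs)
  s_min <- mean(ye[max(1L, is2 - k1):min(length(ye), is2 + k1)]) - iso
  s_amp <- if (s_min < 0) xs[is_] - iso else NA_real_

  # QRS offset: 5% decay of the S depth (or of R when S is absent)
  if (!is.na(s_amp)) {
    lvl_off <- iso - config$edge_frac * abs(s_min)
    qrs_off <- .cross_right(-ye + 2 * iso, ts, is_, 2 * iso - lvl_off,
                            min(length(ye), is_ + .ms_to_n(7, fs)))
  } else {
    lvl_off <- iso + config$edge_frac * r_amp
    qrs_off <- .cross_right(ye, ts, ir + 1L, lvl_off,
                            min(length(ye), ir + .ms_to_n(8, fs)))
  }
  if (is.na(qrs_off)) qrs_off <- ts[min(length(ts), is_ + .ms_to_n(2, fs))]

  # Q: signed minimum between QRS onset and R
  i_on <- max(1L, round((qrs_on - ts[1]) * fs) + 1L)
  qwin <- i_on:ir
  iq <- qwin[which.min(ya[qwin])]
  q_amp <- xs[iq] - iso
  if (q_amp > -config$wave_floor_mv) q_amp <- NA_real_

  # R duration: 5% crossings of the R lobe itself
  lvl_r <- iso + config$edge_frac * r_amp
  r_end <- .cross_right(ye, ts, ir, lvl_r,
                        min(length(ye), ir + .ms_to_n(8, fs)))
  r_dur <- if (!is.na(r_end)) (r_end - qrs_on) * 1000 else NA_real_

  # P wave: maximum in the window before the QRS onset
  pwin_lo <- max(1L, i_on - .ms_to_n(config$p_search_ms, fs))
  pwin <- pwin_lo:max(pwin_lo, i_on - .ms_to_n(2, fs))
  ip <- pwin[which.max(ya[pwin])]
  p_amp <- xs[ip] - iso
  p_on <- p_off <- NA_real_
  p_dur <- NA_real_
  if (p_amp >= config$wave_floor_mv && ip > pwin[1] && ip < pwin[length(pwin)]) {
    lvl_p <- iso + config$edge_frac * p_amp
    p_on <- .cross_left(ye, ts, ip, lvl_p, pwin[1])
    p_off <- .cross_right(ye, ts, ip, lvl_p, i_on)
    if (!is.na(p_on) && !is.na(p_off)) p_dur <- (p_off - p_on) * 1000
  } else {
    p_amp <- NA_real_
  }

  # J wave: first positive peak immediately after the QRS offset
  i_off <- min(length(ya), round((qrs_off - ts[1]) * fs) + 1L)
  jwin <- i_off:min(length(ya), i_off + .ms_to_n(6, fs))
  ij <- jwin[which.max(ya[jwin])]
  j_amp <- xs[ij] - iso
  if (j_amp < config$wave_floor_mv || ij == jwin[length(jwin)]) j_amp <- NA_real_

  # T wave: QT lead only. The delayed T is the LAST prominent positive lobe
  # within 30 ms of the R peak (the J wave, adjoining the QRS, comes
  # earlier); anchoring on the R peak keeps the search valid when
  # fragmented or S-absent morphologies corrupt the QRS offset. The offset
  # is extrapolated from a Gaussian-flank fit of the downslope restricted
  # to the clean segment before the next beat's P wave.
  t_amp <- NA_real_; t_peak <- NA_real_; t_off <- NA_real_
  if (lead == config$qt_lead) {
    yt <- .ma(xs, .ms_to_n(config$t_smooth_ms, fs))
    # extrema scanned out to +45 ms so the slow T decay accumulates enough
    # swing to register as prominence; the peak itself must lie within
    # 11-30 ms of R
    t_hi <- min(length(yt), ir + .ms_to_n(45, fs),
                if (!is.na(next_r)) round((next_r - 0.045 - ts[1]) * fs) + 1L
                else length(yt))
    twin <- (ir + .ms_to_n(4, fs)):t_hi
    if (length(twin) > 4) {
      ex <- .prominent_extrema(yt[twin] - iso, 0.012)
      cand <- twin[ex$i[ex$type == "max"]]
      cand <- cand[yt[cand] - iso >= max(config$wave_floor_mv, 0.02) &
                     ts[cand] - ts[ir] >= 0.011 &
                     ts[cand] - ts[ir] <= 0.030]
      if (length(cand) > 0) {
        it <- cand[length(cand)]
        t_amp_c <- yt[it] - iso
        cap <- min(length(yt),
                   it + .ms_to_n(60, fs),
                   if (!is.na(next_r)) round((next_r - 0.020 - ts[1]) * fs) + 1L
                   else length(yt))
        # the T tail fuses with the next beat's P wave: fit only down to
        # the T-P valley, i.e. the first point after the T peak from which
        # the trace rises again by a discernible amount
        dn_hi <- cap
        jseq <- (it + .ms_to_n(6, fs)):cap
        if (length(jseq) > 1) {
          look <- .ms_to_n(3, fs)
          for (j in jseq) {
            ahead <- yt[j:min(j + look, length(yt))]
            if (max(ahead) - yt[j] > 0.015) { dn_hi <- j; break }
          }
        }
        if (dn_hi > it + .ms_to_n(8, fs)) {
          # skip the flattened cap of the smoothed peak: fit the limb only
          flank <- (it + .ms_to_n(3, fs)):dn_hi
          u <- (ts[flank] - ts[it]) * 1000
          yv <- yt[flank] - iso
          # profile out the amplitude: for fixed sigma the best-fit A is
          # linear, leaving a 1-D minimisation in sigma
          obj <- function(sg) {
            g <- exp(-0.5 * (u / sg)^2)
            -(sum(yv * g))^2 / sum(g^2)
          }
          sg <- stats::optimize(obj, c(2, 60))$minimum
          t_amp <- t_amp_c
          t_peak <- ts[it]
          # steepest-descent tangent of the fitted flank meets the
          # baseline at 2 sigma past the peak
          t_off <- ts[it] + 2 * sg / 1000
        }
      }
    }
  }

  structure(list(
    ok = TRUE, skip_reason = NA_character_,
    lead = lead, r_time = ts[ir],
    isoelectric_level = iso,
    amplitudes = c(P = p_amp, Q = q_amp, R = r_amp, S = s_amp,
                   J = j_amp, T = t_amp),
    s_min = s_min,
    durations = c(P = p_dur, R = r_dur, QRS = (qrs_off - qrs_on) * 1000),
    p_on = p_on, p_off = p_off, qrs_on = qrs_on, qrs_off = qrs_off,
    t_peak = t_peak, t_off = t_off
  ), class = "beat_measurement")
}

#' Rate-corrected QT interval
#'
#' Applies the rodent correction `QTc = QT / sqrt(RR / 100)` with both
#' intervals in ms, so that QTc equals QT at RR = 100 ms.
#'
#' @param qt QT interval (ms).
#' @param rr RR interval (ms).
#' @return QTc in ms. Vectorized.
#' @examples
#' compute_qtc(66.57, 94.00)  # 68.66
#' @export
compute_qtc <- function(qt, rr) {
  if (any(!is.finite(qt)) || any(!is.finite(rr)) || any(qt <= 0) || any(rr <= 0)) {
    stop("qt and rr must be positive")
  }
  qt / sqrt(rr / 100)
}

#' Frontal electrical axis from DI and aVF net QRS amplitudes
#'
#' The net QRS amplitude per lead is the algebraic sum R + S (S carries its
#' negative sign; an absent S contributes 0). The axis is the direction of
#' the (DI, aVF) vector in the clinical hexaxial convention: DI+ at 0
#' degrees, aVF+ at +90 degrees, range (-180, 180], negative angles
#' superior/leftward.
#'
#' @param di_net net QRS amplitude on DI (mV).
#' @param avf_net net QRS amplitude on aVF (mV).
#' @return axis in degrees, or NA (undefined) when both nets are zero.
#' @examples
#' compute_axis(0.147, -0.134)  # -42.4 degrees (leftward)
#' @export
compute_axis <- function(di_net, avf_net) {
  stopifnot(length(di_net) == length(avf_net))
  out <- ifelse(di_net == 0 & avf_net == 0, NA_real_,
                atan2(avf_net, di_net) * 180 / pi)
  ifelse(!is.na(out) & out <= -180, 180, out)
}

# Signal-averaged beat for low-amplitude wave delineation: segments aligned
# on the R peaks are averaged into one beat, which is then delineated as a
# mini recording. Used for the QT interval: the delayed mouse T wave is a
# few tens of microvolts per millisecond in slope, far below per-beat noise.
.averaged_beat <- function(recording, lead, r_times, med_rr_ms,
                           config = delineation_config()) {
  fs <- recording$sampling_rate
  x <- recording$leads[[lead]]
  pre <- .ms_to_n(95, fs)
  post <- .ms_to_n(min(0.95 * med_rr_ms, 100), fs)
  segs <- lapply(r_times, function(r) {
    i <- round(r * fs) + 1L
    if (i - pre < 1L || i + post > length(x)) return(NULL)
    x[(i - pre):(i + post)]
  })
  segs <- segs[!vapply(segs, is.null, TRUE)]
  if (length(segs) == 0) return(NULL)
  avg <- Reduce(`+`, segs) / length(segs)
  mini <- structure(list(
    animal_id = recording$animal_id, genotype = recording$genotype,
    sampling_rate = fs, duration = length(avg) / fs,
    leads = stats::setNames(list(avg), lead), ground_truth = NULL
  ), class = "ecg_recording")
  measure_beat(mini, lead, r_time = pre / fs, rr_ms = med_rr_ms,
               next_r = (pre / fs) + med_rr_ms / 1000, config = config)
}

#' Summarize one animal's ECG
#'
#' Follows the study's measurement cadence: at every 20-s checkpoint five
#' consecutive beats are delineated and averaged; the reported summary is
#' the mean over checkpoints. Intervals: RR from successive R peaks, PR from
#' P onset to QRS onset (on `config$pr_lead`), QT from QRS onset to T offset
#' (on `config$qt_lead`); QTc by [compute_qtc()]. Heart-rate mode is the
#' mode of the 10-s-window mean heart rate binned at 5 bpm. The frontal
#' axis comes from the mean net QRS amplitudes on DI and aVF via
#' [compute_axis()].
#'
#' @param recording an `ecg_recording`.
#' @param leads leads to measure amplitudes on (default: all present).
#' @param checkpoint_s spacing of measurement checkpoints (s).
#' @param beats_per_checkpoint consecutive beats averaged per checkpoint.
#' @param hr_mode_window_s,hr_mode_bin_bpm heart-rate-mode parameters.
#' @param config a [delineation_config()].
#' @return an `animal_ecg_summary` list: per-lead mean amplitudes,
#'   mean durations, RR/PR/QT/QTc (ms), mean and mode heart rate (bpm),
#'   frontal axis (degrees), number of measured and skipped beats.
#' @export
summarize_animal <- function(recording, leads = NULL,
                             checkpoint_s = 20, beats_per_checkpoint = 5,
                             hr_mode_window_s = 10, hr_mode_bin_bpm = 5,
                             config = delineation_config()) {
  stopifnot(inherits(recording, "ecg_recording"))
  if (is.null(leads)) leads <- names(recording$leads)
  r <- detect_beats(recording, config$rr_lead, config)
  checkpoints <- seq(0, recording$duration - 1e-9, by = checkpoint_s)
  usable <- vapply(checkpoints, function(cp) {
    sum(r >= cp) >= beats_per_checkpoint + 1L
  }, logical(1))
  checkpoints <- checkpoints[usable]
  if (length(checkpoints) == 0) {
    stop("recording shorter than one checkpoint window")
  }
  med_rr <- stats::median(diff(r)) * 1000

  meas <- list(); rr_ms <- c(); skipped <- 0L
  for (cp in checkpoints) {
    sel <- which(r >= cp)[seq_len(beats_per_checkpoint)]
    rr_ms <- c(rr_ms, diff(r[c(sel, sel[length(sel)] + 1L)]) * 1000)
    for (b in sel) {
      nxt <- if (b < length(r)) r[b + 1L] else NA
      for (ld in leads) {
        m <- measure_beat(recording, ld, r[b], rr_ms = med_rr,
                          next_r = nxt, config = config)
        if (m$ok) meas[[length(meas) + 1L]] <- m else skipped <- skipped + 1L
      }
    }
  }
  if (length(meas) == 0) stop("no measurable beats")

  by_lead <- split(meas, vapply(meas, `[[`, "", "lead"))
  amp <- t(vapply(by_lead, function(ms) {
    a <- do.call(rbind, lapply(ms, `[[`, "amplitudes"))
    colMeans(a, na.rm = TRUE)
  }, numeric(6)))
  amp[is.nan(amp)] <- NA_real_

  prm <- by_lead[[config$pr_lead]]
  pr <- if (!is.null(prm)) {
    mean(vapply(prm, function(m) (m$qrs_on - m$p_on) * 1000, 0), na.rm = TRUE)
  } else NA_real_
  p_dur <- if (!is.null(prm)) {
    mean(vapply(prm, function(m) m$durations[["P"]], 0), na.rm = TRUE)
  } else NA_real_
  qrs_dur <- if (!is.null(prm)) {
    mean(vapply(prm, function(m) m$durations[["QRS"]], 0), na.rm = TRUE)
  } else NA_real_
  r_dur <- if (!is.null(prm)) {
    mean(vapply(prm, function(m) m$durations[["R"]], 0), na.rm = TRUE)
  } else NA_real_
  # QT from the signal-averaged beat of each checkpoint (T is too shallow
  # for reliable per-beat tangent estimation at physiological noise)
  qt_cp <- vapply(checkpoints, function(cp) {
    sel <- which(r >= cp)[seq_len(beats_per_checkpoint)]
    m <- .averaged_beat(recording, config$qt_lead, r[sel], med_rr, config)
    if (is.null(m) || !isTRUE(m$ok) || is.na(m$t_off)) return(NA_real_)
    (m$t_off - m$qrs_on) * 1000
  }, 0)
  qt <- if (all(is.na(qt_cp))) NA_real_ else mean(qt_cp, na.rm = TRUE)

  rr_mean <- mean(rr_ms)
  hr_mean <- 60000 / rr_mean
  qtc <- if (is.finite(qt) && qt > 0) compute_qtc(qt, rr_mean) else NA_real_

  # HR mode over 10-s windows, 5-bpm bins (a shorter recording contributes
  # a single truncated window)
  wins <- if (recording$duration > hr_mode_window_s) {
    seq(0, recording$duration - hr_mode_window_s, by = hr_mode_window_s)
  } else 0
  win_hr <- vapply(wins, function(w) {
    rw <- r[r >= w & r < w + hr_mode_window_s]
    if (length(rw) < 2) return(NA_real_)
    60000 / (mean(diff(rw)) * 1000)
  }, 0)
  win_hr <- win_hr[is.finite(win_hr)]
  hr_mode <- if (length(win_hr)) {
    bins <- floor(win_hr / hr_mode_bin_bpm)
    tab <- table(bins)
    (as.numeric(names(tab)[which.max(tab)]) + 0.5) * hr_mode_bin_bpm
  } else NA_real_

  nets <- function(lead) {
    if (!lead %in% rownames(amp)) return(NA_real_)
    rv <- amp[lead, "R"]; sv <- amp[lead, "S"]
    (if (is.na(rv)) 0 else rv) + (if (is.na(sv)) 0 else sv)
  }
  axis <- if (all(c("DI", "aVF") %in% rownames(amp))) {
    compute_axis(nets("DI"), nets("aVF"))
  } else NA_real_

  structure(list(
    animal_id = recording$animal_id,
    genotype = recording$genotype,
    amplitudes = amp,
    durations = c(P = p_dur, R = r_dur, QRS = qrs_dur),
    RR = rr_mean, PR = pr, QT = qt, QTc = qtc,
    heart_rate_mean = hr_mean, heart_rate_mode = hr_mode,
    frontal_axis = axis,
    n_beats_measured = length(meas), n_beats_skipped = skipped
  ), class = "animal_ecg_summary")
}

#' @export
print.animal_ecg_summary <- function(x, ...) {
  cat(sprintf("<animal_ecg_summary> %s (%s)\n", x$animal_id, x$genotype))
  cat(sprintf("  RR %.2f  PR %.2f  QT %.2f  QTc %.2f ms\n",
              x$RR, x$PR, x$QT, x$QTc))
  cat(sprintf("  HR mean %.0f bpm (mode %.0f), axis %.1f deg\n",
              x$heart_rate_mean, x$heart_rate_mode, x$frontal_axis))
  invisible(x)
}
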