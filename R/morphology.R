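# Qualitative QRS-morphology features: fragmented QRS (notch / RSR' /
# RSR'S'), R-foot slurring, and S-wave absence, scored per lead and
# aggregated per animal with the >=2-feature affected rule.

#' Morphology-detection settings
#'
#' @param prominence_floor_mv minimum extremum prominence (mV); the working
#'   threshold is `max(prominence_floor_mv, prominence_frac * R)`.
#' @param prominence_frac prominence threshold as a fraction of the R
#'   amplitude.
#' @param slurr_drop slope threshold: slurring requires the upstroke
#'   derivative to fall below this fraction of its running maximum.
#' @param slurr_dwell_ms minimum dwell time below the slope threshold (ms).
#' @param s_absent_tol_mv tolerance on the (smoothed) post-R minimum for
#'   S-wave absence: the call is `post-R minimum >= -tol`. The default 0.03
#'   mV absorbs residual noise on a suppressed S while staying far below
#'   genuine S amplitudes.
#' @param qrs_onset_fraction assumed fraction of the QRS duration preceding
#'   the R peak, used to bound the fragmented-QRS search window from the R
#'   upstroke width (robust when fragmentation corrupts the S-based QRS
#'   offset).
#' @param beat_vote fraction of measured beats on which a feature must be
#'   detected for the lead-level (animal) call.
#' @return a named list of settings.
#' @export
morphology_config <- function(prominence_floor_mv = 0.05,
                              prominence_frac = 0.05,
                              slurr_drop = 0.5,
                              slurr_dwell_ms = 1.0,
                              s_absent_tol_mv = 0.03,
                              qrs_onset_fraction = 0.35,
                              beat_vote = 0.5) {
  as.list(environment())
}

# alternating-extrema sequence of z with zigzag pruning at `thresh`
.prominent_extrema <- function(z, thresh) {
  d <- diff(z)
  sgn <- sign(d)
  sgn[sgn == 0] <- 1
  turns <- which(diff(sgn) != 0) + 1L
  idx <- c(1L, turns, length(z))
  val <- z[idx]
  # prune the smallest adjacent swing until all swings >= thresh; interior
  # swings drop both members (merging the flanks), edge swings drop the
  # interior member only
  while (length(idx) > 2L) {
    sw <- abs(diff(val))
    k <- which.min(sw)
    if (sw[k] >= thresh) break
    drop <- if (k == 1L) 2L else if (k == length(sw)) k else c(k, k + 1L)
    idx <- idx[-drop]; val <- val[-drop]
  }
  keep <- idx[c(-1L, -length(idx))]
  data.frame(i = keep, v = z[keep],
             type = ifelse(z[keep] >= z[pmax(keep - 1L, 1L)], "max", "min"))
}

#' Classify fragmented-QRS morphology of one beat
#'
#' Counts sign-consistent local extrema inside the delineated QRS window
#' with prominence at least `max(0.05 mV, 5% of R)`: an extra positive
#' deflection after the S wave returning above baseline is RSR'; a further
#' negative deflection after it crossing below baseline is RSR'S'; extra
#' deflections that do not cross the baseline are a notch.
#'
#' @param recording an `ecg_recording`.
#' @param lead lead name.
#' @param beat a successful [measure_beat()] result for that lead.
#' @param config a [morphology_config()].
#' @return one of `"none"`, `"notch"`, `"RSR'"`, `"RSR'S'"`.
#' @export
detect_fqrs <- function(recording, lead, beat,
                        config = morphology_config()) {
  stopifnot(inherits(beat, "beat_measurement"), isTRUE(beat$ok))
  fs <- recording$sampling_rate
  x <- recording$leads[[lead]]
  i0 <- max(1L, round(beat$qrs_on * fs) + 1L)
  # bound the window from the R upstroke width: fragmentation corrupts the
  # S-based offset but leaves the onset-to-peak limb intact
  span <- (beat$r_time - beat$qrs_on) / config$qrs_onset_fraction
  i1 <- min(length(x), round((beat$qrs_on + span) * fs) + 1L)
  if (i1 - i0 < 4L) return("none")
  z <- .ma(x[i0:i1], .ms_to_n(0.6, fs)) - beat$isoelectric_level
  thr <- max(config$prominence_floor_mv,
             config$prominence_frac * beat$amplitudes[["R"]])
  ex <- .prominent_extrema(z, thr)
  if (nrow(ex) == 0) return("none")
  i_r <- ex$i[which.max(ex$v)]
  after_r <- ex[ex$i > i_r, , drop = FALSE]
  rows <- seq_len(nrow(after_r))
  neg_min <- rows[after_r$type == "min" & after_r$v < 0]
  pos_max <- rows[after_r$type == "max" & after_r$v > 0]
  # RSR': a secondary positive deflection returning above baseline after a
  # true (below-baseline) S; a further negative deflection makes it RSR'S'
  if (length(neg_min) > 0 && length(pos_max) > 0 &&
      any(pos_max > neg_min[1])) {
    rp <- pos_max[pos_max > neg_min[1]][1]
    return(if (any(neg_min > rp)) "RSR'S'" else "RSR'")
  }
  # extra deflections beyond the canonical R and (possibly) S that do not
  # cross the baseline are a notch
  n_extra <- nrow(ex) - 1L - (if (length(neg_min) > 0) 1L else 0L)
  if (n_extra > 0) "notch" else "none"
}

#' Detect R-upstroke slurring in one beat
#'
#' True when the upstroke derivative (between the QRS onset and the point
#' where the signal reaches 60% of the R amplitude) falls below half of its
#' running maximum for at least 1 ms.
#'
#' @inheritParams detect_fqrs
#' @return logical.
#' @export
detect_slurr <- function(recording, lead, beat,
                         config = morphology_config()) {
  stopifnot(inherits(beat, "beat_measurement"), isTRUE(beat$ok))
  fs <- recording$sampling_rate
  x <- recording$leads[[lead]]
  i_on <- max(1L, round(beat$qrs_on * fs) + 1L)
  i_r <- round(beat$r_time * fs) + 1L
  if (i_r - i_on < 4L) return(FALSE)
  pad <- .ms_to_n(1.5, fs)
  seg <- max(1L, i_on - pad):min(length(x), i_r + pad)
  z <- .ma(x[seg], .ms_to_n(0.6, fs))
  ii <- (i_on:i_r) - seg[1] + 1L
  # scan the limb between 8% and 70% of R: on a clean upstroke the slope
  # maximum sits at ~61% of the amplitude, so the derivative stays within
  # a few percent of its running maximum over this span
  amp_rel <- z[ii] - beat$isoelectric_level
  ii <- ii[amp_rel >= 0.08 * beat$amplitudes[["R"]] &
             amp_rel <= 0.7 * beat$amplitudes[["R"]]]
  if (length(ii) < 4L) return(FALSE)
  k <- .ms_to_n(0.4, fs)
  ii <- ii[ii - k >= 1L & ii + k <= length(z)]
  d <- (z[ii + k] - z[ii - k]) / (2 * k / fs * 1000)  # mV/ms
  d <- .ma(d, .ms_to_n(0.6, fs))
  M <- cummax(d)
  flag <- d < config$slurr_drop * M
  if (!any(flag)) return(FALSE)
  # dwell: some window of the required length must be >= 80% below the
  # slope threshold (tolerates isolated noise flips)
  need <- .ms_to_n(config$slurr_dwell_ms, fs)
  if (length(flag) < need) return(FALSE)
  roll <- .ma(as.numeric(flag), need)
  max(roll) >= 0.8
}

#' Detect S-wave absence in one beat
#'
#' True when the post-R minimum within the QRS window is not below the
#' isoelectric level (minus an optional tolerance).
#'
#' @param beat a successful [measure_beat()] result.
#' @param config a [morphology_config()].
#' @return logical.
#' @export
detect_s_absence <- function(beat, config = morphology_config()) {
  stopifnot(inherits(beat, "beat_measurement"), isTRUE(beat$ok))
  beat$s_min >= -config$s_absent_tol_mv
}

#' Per-lead feature detection over a set of beats
#'
#' Runs the three morphology detectors on each delineated beat of each lead
#' and majority-votes them into lead-level calls.
#'
#' @param recording an `ecg_recording`.
#' @param r_times R-peak times; defaults to [detect_beats()].
#' @param lead_set leads to score (default precordial V1, Vms, Vs, V4).
#' @param max_beats cap on the number of beats scored per lead.
#' @param config a [morphology_config()].
#' @param dconfig a [delineation_config()].
#' @return data.frame with one row per lead: `fqrs` (modal non-none call, or
#'   `"none"`), `slurr`, `s_absent` (majority-vote logicals) and the
#'   per-beat detection fractions.
#' @export
detect_features <- function(recording, r_times = NULL,
                            lead_set = PRECORDIAL_LEADS,
                            max_beats = 20,
                            config = morphology_config(),
                            dconfig = delineation_config()) {
  stopifnot(inherits(recording, "ecg_recording"))
  if (length(lead_set) == 0) stop("empty lead set")
  if (is.null(r_times)) r_times <- detect_beats(recording, config = dconfig)
  med_rr <- stats::median(diff(r_times)) * 1000
  use <- r_times[seq_len(min(max_beats, length(r_times) - 1L)) + 1L]
  use <- use[!is.na(use)]
  rows <- lapply(lead_set, function(ld) {
    fq <- character(0); sl <- logical(0); sa <- logical(0)
    for (i in seq_along(use)) {
      nxt <- r_times[match(use[i], r_times) + 1L]
      m <- measure_beat(recording, ld, use[i], rr_ms = med_rr,
                        next_r = nxt, config = dconfig)
      if (!isTRUE(m$ok)) next
      fq <- c(fq, detect_fqrs(recording, ld, m, config))
      sl <- c(sl, detect_slurr(recording, ld, m, config))
      sa <- c(sa, detect_s_absence(m, config))
    }
    if (length(fq) == 0) {
      return(data.frame(lead = ld, fqrs = "none", slurr = FALSE,
                        s_absent = FALSE, frac_fqrs = NA_real_,
                        frac_slurr = NA_real_, frac_s_absent = NA_real_,
                        n_beats = 0L))
    }
    frac_fq <- mean(fq != "none")
    fq_call <- if (frac_fq >= config$beat_vote) {
      tt <- table(fq[fq != "none"])
      names(tt)[which.max(tt)]
    } else "none"
    data.frame(lead = ld, fqrs = fq_call,
               slurr = mean(sl) >= config$beat_vote,
               s_absent = mean(sa) >= config$beat_vote,
               frac_fqrs = frac_fq, frac_slurr = mean(sl),
               frac_s_absent = mean(sa), n_beats = length(fq))
  })
  do.call(rbind, rows)
}

#' Score an animal by the two-feature rule
#'
#' Counts the distinct feature *types* (fragmented QRS, slurring, S-wave
#' absence) present on at least one lead of the configured lead set; an
#' animal is affected when at least two types are present.
#'
#' @param calls per-lead calls as returned by [detect_features()] (columns
#'   `lead`, `fqrs`, `slurr`, `s_absent`).
#' @param lead_set leads counted (default precordial).
#' @param animal_id label carried into the result.
#' @return a `feature_call` list: per-lead flags, `anomaly_count` (0-3) and
#'   `affected`.
#' @export
score_animal <- function(calls, lead_set = PRECORDIAL_LEADS,
                         animal_id = NA_character_) {
  if (length(lead_set) == 0) stop("empty lead set")
  calls <- calls[calls$lead %in% lead_set, , drop = FALSE]
  if (nrow(calls) == 0) stop("no calls for the requested lead set")
  types <- c(
    fqrs = any(calls$fqrs != "none"),
    slurr = any(calls$slurr),
    s_absent = any(calls$s_absent)
  )
  n <- sum(types)
  structure(list(animal_id = animal_id, calls = calls,
                 features_present = names(types)[types],
                 anomaly_count = n, affected = n >= 2L),
            class = "feature_call")
}

#' Cohort 2x2 feature table
#'
#' Cross-tabulates affected (>= 2 feature types) against genotype for a
#' pair of genotypes.
#'
#' @param cohort data.frame with columns `genotype` and `affected` (or a
#'   list of `feature_call`s plus a genotype vector).
#' @param genotypes character vector of the two genotypes (row order).
#' @return a 2x2 integer matrix, rows = genotypes, columns =
#'   `c("affected", "not_affected")`.
#' @export
feature_table <- function(cohort, genotypes) {
  stopifnot(is.data.frame(cohort), all(c("genotype", "affected") %in% names(cohort)))
  if (length(genotypes) != 2) stop("need exactly two genotypes")
  missing_g <- setdiff(genotypes, cohort$genotype)
  if (length(missing_g)) stop("unknown genotype: ", paste(missing_g, collapse = ", "))
  m <- t(vapply(genotypes, function(g) {
    aff <- cohort$affected[cohort$genotype == g]
    c(affected = sum(aff), not_affected = sum(!aff))
  }, integer(2)))
  storage.mode(m) <- "integer"
  m
}
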