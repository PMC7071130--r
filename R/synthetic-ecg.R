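# Synthetic 12-lead ECG generator.
#
# Produces labelled records with controllable class structure so the whole
# pipeline (preprocessing, training, evaluation) is testable without any
# external database. Beats are sums of Gaussian bumps (P, QRS, T) plus a
# rectangular ST-segment offset; myocardial-infarction classes perturb the
# ST level and T-wave amplitude on anatomically plausible lead subsets.

# Fixed per-lead projection gains: the same cardiac cycle seen from the 12
# standard angles (aVR and V1 predominantly inverted, precordial leads
# progressively larger). Purely a plausibility device, not a dipole model.
.lead_gains <- c(
  I = 0.9, II = 1.0, III = 0.5, aVR = -0.7, aVL = 0.4, aVF = 0.8,
  V1 = -0.5, V2 = 0.7, V3 = 0.9, V4 = 1.1, V5 = 1.0, V6 = 0.9
)

#' Parametric single-beat template
#'
#' Describes one heartbeat as three Gaussian bumps (P, QRS, T) on a flat
#' baseline, plus a rectangular ST-segment offset. Each bump is given as
#' `c(center, width, amplitude)` with center/width in seconds (width is the
#' Gaussian standard deviation) and amplitude in mV. Centers are positions
#' within the beat window, so the default QRS center of 0.25 s puts the
#' R peak at sample 250 of a 651-sample beat at 1000 Hz.
#'
#' The ST window, where `st_offset` is added, runs from 0.06 s after the QRS
#' center to half a T-width before the T center — the interval where
#' ST-segment elevation lives clinically.
#'
#' @param p_wave,qrs,t_wave Numeric triples `c(center_s, width_s, amplitude_mV)`.
#' @param st_offset ST-segment offset in mV.
#' @param baseline Constant baseline level in mV.
#' @return An object of class `beat_template`.
#' @export
#' @examples
#' tpl <- beat_template()
#' w <- make_beat(tpl, fs = 1000, n_samples = 651)
#' which.max(abs(w))  # R peak at sample 251 (1-based), i.e. 0.25 s
beat_template <- function(p_wave = c(0.08, 0.025, 0.15),
                          qrs = c(0.25, 0.012, 1.0),
                          t_wave = c(0.50, 0.05, 0.30),
                          st_offset = 0,
                          baseline = 0) {
  for (bump in list(p_wave = p_wave, qrs = qrs, t_wave = t_wave)) {
    if (length(bump) != 3L || !all(is.finite(bump)) || bump[2] <= 0) {
      stop_invalid("each wave must be c(center, width > 0, amplitude), all finite")
    }
  }
  if (!(p_wave[1] < qrs[1] && qrs[1] < t_wave[1])) {
    stop_invalid("wave centers must be ordered P < QRS < T")
  }
  structure(
    list(p_wave = p_wave, qrs = qrs, t_wave = t_wave,
         st_offset = st_offset, baseline = baseline),
    class = "beat_template"
  )
}

#' Render one beat template to a sampled waveform
#'
#' Deterministic: the waveform is the sum of the three Gaussian bumps, the
#' baseline, and the rectangular ST offset applied between QRS end
#' (QRS center + 0.06 s) and T onset (T center - half T width).
#'
#' @param template A [beat_template()].
#' @param fs Sampling frequency in Hz.
#' @param n_samples Number of samples to render.
#' @return Numeric vector of length `n_samples` (mV).
#' @export
make_beat <- function(template, fs = 1000, n_samples = 651) {
  check_scalar_number(fs, "fs", positive = TRUE)
  check_scalar_number(n_samples, "n_samples", positive = TRUE)
  stopifnot(inherits(template, "beat_template"))
  t <- (seq_len(n_samples) - 1) / fs
  bump <- function(par) par[3] * exp(-0.5 * ((t - par[1]) / par[2])^2)
  w <- bump(template$p_wave) + bump(template$qrs) + bump(template$t_wave) +
    template$baseline
  st_lo <- template$qrs[1] + 0.06
  st_hi <- template$t_wave[1] - template$t_wave[2] / 2
  if (st_hi > st_lo && template$st_offset != 0) {
    w <- w + template$st_offset * (t >= st_lo & t <= st_hi)
  }
  w
}

# Anatomical lead-region correspondence used by the MI class profiles:
# anterior V3-V4; septal V1-V2; inferior II, III, aVF; lateral I, aVL, V5, V6.
.class_lead_map <- list(
  HC   = character(0),
  AMI  = c("V3", "V4"),
  ALMI = c("I", "aVL", "V3", "V4", "V5", "V6"),
  ASMI = c("V1", "V2", "V3", "V4"),
  IMI  = c("II", "III", "aVF"),
  ILMI = c("II", "III", "aVF", "V5", "V6")
)

#' Class profile: how a diagnostic class deforms the beat
#'
#' A class is defined by the subset of leads it affects and by the
#' deformation applied there: an ST-segment shift (mV) and a multiplicative
#' T-wave amplitude change. The healthy-control profile affects no leads.
#' Default affected-lead sets follow the standard lead-region map
#' (anterior V3--V4, septal V1--V2, inferior II/III/aVF,
#' lateral I/aVL/V5/V6).
#'
#' @param class_label One of `"HC"`, `"AMI"`, `"ALMI"`, `"ASMI"`, `"IMI"`,
#'   `"ILMI"`.
#' @param affected_leads Character vector of lead names; defaults to the
#'   lead-region map for `class_label`.
#' @param st_shift ST-segment shift in mV on affected leads (0 for HC).
#' @param t_scale T-wave amplitude multiplier on affected leads (1 for HC).
#' @return An object of class `class_profile`.
#' @export
#' @examples
#' class_profile("IMI")$affected_leads  # II, III, aVF
class_profile <- function(class_label,
                          affected_leads = NULL,
                          st_shift = if (class_label == "HC") 0 else 0.3,
                          t_scale = if (class_label == "HC") 1 else 0.6) {
  class_label <- match.arg(class_label, names(.class_lead_map))
  affected_leads <- affected_leads %||% .class_lead_map[[class_label]]
  if (!all(affected_leads %in% ecg_leads())) {
    stop_invalid("unknown lead name in `affected_leads`")
  }
  if (class_label == "HC" &&
      (length(affected_leads) > 0 || st_shift != 0 || t_scale != 1)) {
    stop_invalid("the HC profile must have no affected leads, st_shift = 0, t_scale = 1")
  }
  structure(
    list(class_label = class_label, affected_leads = affected_leads,
         st_shift = st_shift, t_scale = t_scale),
    class = "class_profile"
  )
}

#' Patient profile: per-subject variation
#'
#' @param patient_id Identifier string.
#' @param amplitude_gain Global multiplicative gain (> 0, dimensionless).
#' @param heart_rate Beats per minute, in \[40, 180\].
#' @param noise_sd Additive white-noise standard deviation (mV).
#' @param wander_amp Baseline-wander (sinusoid) amplitude (mV).
#' @param wander_freq Baseline-wander frequency (Hz).
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(patient_id = "P001",
                            amplitude_gain = 1,
                            heart_rate = 75,
                            noise_sd = 0.05,
                            wander_amp = 0.1,
                            wander_freq = 0.25) {
  if (amplitude_gain <= 0) stop_invalid("`amplitude_gain` must be > 0")
  if (heart_rate < 40 || heart_rate > 180) {
    stop_invalid("`heart_rate` must lie in [40, 180] bpm")
  }
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  structure(
    list(patient_id = patient_id, amplitude_gain = amplitude_gain,
         heart_rate = heart_rate, noise_sd = noise_sd,
         wander_amp = wander_amp, wander_freq = wander_freq),
    class = "patient_profile"
  )
}

#' Generate one synthetic 12-lead record
#'
#' Renders `n_beats` repeats of the template at the patient's heart rate on
#' all 12 leads (each lead scaled by its fixed projection gain and the
#' patient's amplitude gain), applies the class deformation on the affected
#' leads, then adds Gaussian noise and sinusoidal baseline wander. Identical
#' seeds give bitwise-identical output.
#'
#' @param patient A [patient_profile()].
#' @param cls A [class_profile()].
#' @param n_beats Number of beats (>= 3, so that first/last-beat removal
#'   after segmentation leaves at least one beat).
#' @param seed Integer seed for the noise and wander phase.
#' @param template Base [beat_template()].
#' @param fs Sampling frequency (Hz).
#' @param noise_leads Optional character vector of leads replaced by pure
#'   Gaussian noise (no cardiac signal at all) — a deliberately uninformative
#'   channel for lead-weight diagnostics.
#' @param noise_lead_sd Standard deviation (mV) of such pure-noise leads.
#' @param record_id Identifier; default derived from the patient ID.
#' @return An object of class `ecg_record` with fields `signals`
#'   (12 x T matrix, mV), `fs`, `lead_names`, `patient_id`, `record_id`,
#'   `label`, and `qrs_centers` (ground-truth R-peak sample indices,
#'   1-based; kept for testing detectors).
#' @export
generate_record <- function(patient, cls, n_beats = 10, seed = 1,
                            template = beat_template(), fs = 1000,
                            noise_leads = NULL, noise_lead_sd = 0.2,
                            record_id = NULL) {
  stopifnot(inherits(patient, "patient_profile"), inherits(cls, "class_profile"))
  if (!is.numeric(n_beats) || n_beats < 3) {
    stop_invalid("`n_beats` must be >= 3 so that first/last-beat removal leaves a beat")
  }
  if (!is.null(noise_leads) && !all(noise_leads %in% ecg_leads())) {
    stop_invalid("unknown lead name in `noise_leads`")
  }
  period <- 60 / patient$heart_rate
  lead_margin <- 0.35                     # head room before the first QRS
  tail_margin <- 0.55                     # room for the last T wave + window
  n_total <- ceiling((lead_margin + (n_beats - 1) * period + tail_margin) * fs)
  t <- (seq_len(n_total) - 1) / fs
  qrs_times <- lead_margin + (seq_len(n_beats) - 1) * period

  leads <- ecg_leads()
  signals <- matrix(0, nrow = 12L, ncol = n_total,
                    dimnames = list(leads, NULL))
  with_seed(seed, {
    for (li in seq_along(leads)) {
      lead <- leads[li]
      if (lead %in% noise_leads) {
        signals[li, ] <- rnorm(n_total, sd = noise_lead_sd)
        next
      }
      tpl <- template
      if (lead %in% cls$affected_leads) {
        tpl$st_offset <- tpl$st_offset + cls$st_shift
        tpl$t_wave[3] <- tpl$t_wave[3] * cls$t_scale
      }
      gain <- .lead_gains[[lead]] * patient$amplitude_gain
      one <- rep(0, n_total)
      for (qc in qrs_times) {
        shift <- tpl
        off <- qc - tpl$qrs[1]
        shift$p_wave[1] <- tpl$p_wave[1] + off
        shift$qrs[1] <- qc
        shift$t_wave[1] <- tpl$t_wave[1] + off
        one <- one + make_beat(shift, fs = fs, n_samples = n_total)
        one <- one - shift$baseline       # baseline added once, below
      }
      one <- one + tpl$baseline
      one <- one * gain
      if (patient$noise_sd > 0) one <- one + rnorm(n_total, sd = patient$noise_sd)
      if (patient$wander_amp > 0) {
        phase <- runif(1, 0, 2 * pi)
        one <- one + patient$wander_amp *
          sin(2 * pi * patient$wander_freq * t + phase)
      }
      signals[li, ] <- one
    }
  })
  structure(
    list(signals = signals, fs = fs, lead_names = leads,
         patient_id = patient$patient_id,
         record_id = record_id %||% paste0(patient$patient_id, "_r1"),
         label = cls$class_label,
         qrs_centers = round(qrs_times * fs) + 1L),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> patient %s, label %s, 12 x %d @ %g Hz\n",
              x$record_id, x$patient_id, x$label, ncol(x$signals), x$fs))
  invisible(x)
}

#' Generate a labelled multi-patient dataset
#'
#' Draws one patient profile per subject (amplitude gain ~ U(0.7, 1.3),
#' heart rate ~ U(55, 95) bpm) and one record per subject for each class
#' profile, with unique patient IDs across the dataset.
#'
#' @param n_patients_per_class Subjects per class (>= 1).
#' @param classes List of [class_profile()] objects.
#' @param n_beats Beats per record.
#' @param seed Integer seed; fixes patient profiles and record noise.
#' @param noise_sd,wander_amp Noise level and baseline-wander amplitude (mV)
#'   shared by all patients.
#' @param noise_leads,noise_lead_sd Passed to [generate_record()].
#' @param template Base [beat_template()].
#' @return List of `ecg_record` objects.
#' @export
#' @examples
#' recs <- generate_dataset(2, list(class_profile("HC"), class_profile("IMI")),
#'                          n_beats = 4, seed = 7)
#' length(recs)
generate_dataset <- function(n_patients_per_class,
                             classes,
                             n_beats = 10,
                             seed = 1,
                             noise_sd = 0.05,
                             wander_amp = 0.1,
                             noise_leads = NULL,
                             noise_lead_sd = 0.2,
                             template = beat_template()) {
  if (length(classes) == 0) stop_invalid("`classes` must be a non-empty list")
  if (n_patients_per_class < 1) stop_invalid("`n_patients_per_class` must be >= 1")
  stopifnot(all(vapply(classes, inherits, logical(1), "class_profile")))
  records <- list()
  idx <- 0L
  with_seed(seed, {
    for (cls in classes) {
      for (p in seq_len(n_patients_per_class)) {
        idx <- idx + 1L
        pid <- sprintf("P%03d", idx)
        prof <- patient_profile(
          patient_id = pid,
          amplitude_gain = runif(1, 0.7, 1.3),
          heart_rate = runif(1, 55, 95),
          noise_sd = noise_sd,
          wander_amp = wander_amp,
          wander_freq = runif(1, 0.15, 0.4)
        )
        rec_seed <- sample.int(.Machine$integer.max, 1)
        records[[idx]] <- generate_record(
          prof, cls, n_beats = n_beats, seed = rec_seed,
          template = template, noise_leads = noise_leads,
          noise_lead_sd = noise_lead_sd,
          record_id = sprintf("%s_%s", pid, cls$class_label)
        )
      }
    }
  })
  records
}
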