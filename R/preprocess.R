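# Signal conditioning and beat segmentation.
#
# Pipeline order: per-lead min-max standardization to [-1, 1], db6 wavelet
# denoising + baseline-drift removal (re-clipped to [-1, 1]), Pan-Tompkins
# QRS detection on a single detection lead, and extraction of 651-sample
# windows (250 before the R peak, 400 after) across all 12 leads, with the
# first and last surviving beats of every record dropped. Everything here
# is deterministic — no RNG.

#' Preprocessing configuration
#'
#' @param wavelet_name Only `"db6"` is implemented (the transform the
#'   pipeline is built around).
#' @param decomposition_level DWT depth; the default 9 puts the discarded
#'   approximation band below ~1 Hz at 1000 Hz, where baseline wander lives.
#' @param pre_samples,post_samples Samples kept before/after the R peak;
#'   `pre + post + 1` is the beat length (651 by default).
#' @param detection_lead Lead driving QRS detection (default `"II"`); the
#'   detected peak indices are applied to all 12 leads so beats stay
#'   time-aligned across leads.
#' @param threshold_rule `"soft"` or `"hard"` wavelet detail thresholding.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(wavelet_name = "db6",
                              decomposition_level = 9,
                              pre_samples = 250,
                              post_samples = 400,
                              detection_lead = "II",
                              threshold_rule = c("soft", "hard")) {
  if (!identical(wavelet_name, "db6")) {
    stop_invalid("only the db6 wavelet is supported")
  }
  if (decomposition_level < 1) stop_invalid("`decomposition_level` must be >= 1")
  if (!detection_lead %in% ecg_leads()) {
    stop_invalid("`detection_lead` must be one of the 12 canonical leads")
  }
  structure(
    list(wavelet_name = wavelet_name,
         decomposition_level = decomposition_level,
         pre_samples = as.integer(pre_samples),
         post_samples = as.integer(post_samples),
         detection_lead = detection_lead,
         threshold_rule = match.arg(threshold_rule)),
    class = "preprocess_config"
  )
}

#' Standardize a record to \[-1, 1\] per lead
#'
#' Affine min-max map per lead: the lead minimum goes to -1 and the maximum
#' to +1. A constant lead carries no waveform information and is mapped to
#' all zeros with a warning.
#'
#' @param record An `ecg_record`.
#' @return The record with standardized signals.
#' @export
standardize <- function(record) {
  s <- record$signals
  for (i in seq_len(nrow(s))) {
    lo <- min(s[i, ]); hi <- max(s[i, ])
    if (hi == lo) {
      warning(sprintf("lead %s is constant; mapped to zeros",
                      record$lead_names[i]), call. = FALSE)
      s[i, ] <- 0
    } else {
      s[i, ] <- 2 * (s[i, ] - lo) / (hi - lo) - 1
    }
  }
  record$signals <- s
  record
}

#' Wavelet denoising and baseline-drift removal
#'
#' Per lead: multilevel db6 decomposition, the coarsest approximation band
#' zeroed (drift removal), fine detail bands shrunk with the universal
#' threshold (noise removal), inverse transform. Output length equals input
#' length. With `rescale = TRUE` (the default, and what the standard
#' pipeline uses after standardization) each lead is affinely re-mapped to
#' \[-1, 1\] afterwards: detrending shifts the resting level, and an affine
#' re-map restores the standardized range without the waveform distortion a
#' hard clip would cause (a clipped R peak becomes a flat plateau). A lead
#' that comes out constant maps to zeros.
#'
#' @param record An `ecg_record`.
#' @param cfg A [preprocess_config()].
#' @param rescale Re-map each filtered lead to \[-1, 1\].
#' @return The record with filtered signals.
#' @export
denoise_and_detrend <- function(record, cfg = preprocess_config(),
                                rescale = TRUE) {
  n <- ncol(record$signals)
  if (floor(log2(n)) < 1) {
    stop_invalid("record too short for wavelet decomposition; lower `decomposition_level`")
  }
  s <- record$signals
  for (i in seq_len(nrow(s))) {
    y <- wave_denoise(s[i, ], level = cfg$decomposition_level,
                      rule = cfg$threshold_rule)
    if (rescale) {
      lo <- min(y); hi <- max(y)
      y <- if (hi > lo) 2 * (y - lo) / (hi - lo) - 1 else rep(0, n)
    }
    s[i, ] <- y
  }
  record$signals <- s
  record
}

#' Pan-Tompkins QRS detection
#'
#' Classic stages on the configured detection lead: 5--15 Hz band-pass
#' (zero-phase Butterworth), five-point derivative, squaring, 150 ms
#' moving-window integration, adaptive dual signal/noise thresholds with
#' search-back, and a 200 ms refractory period. Accepted peaks are refined
#' to the local maximum of the raw detection lead within +-40 ms.
#'
#' @param record An `ecg_record` sampled at 1000 Hz (resample beforehand
#'   otherwise).
#' @param cfg A [preprocess_config()].
#' @return An object of class `qrs_annotations`: list with sorted 1-based
#'   `peak_indices` and `detection_lead`. Empty when nothing is found.
#' @export
detect_qrs <- function(record, cfg = preprocess_config()) {
  fs <- record$fs
  x <- record$signals[match(cfg$detection_lead, record$lead_names), ]
  n <- length(x)
  empty <- structure(list(peak_indices = integer(0),
                          detection_lead = cfg$detection_lead),
                     class = "qrs_annotations")
  if (n < fs || max(x) - min(x) < 1e-9) return(empty)

  # band-pass 5-15 Hz, zero phase so peak locations are not delayed
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  # five-point derivative emphasises QRS slopes
  der <- stats::filter(xf, c(1, 2, 0, -2, -1) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  # 150 ms moving-window integration
  win <- round(0.15 * fs)
  mwi <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate peaks: local maxima of the integrated signal
  is_peak <- c(FALSE, diff(mwi) > 0) & c(mwi[-n] >= mwi[-1], FALSE)
  cand <- which(is_peak)
  if (length(cand) == 0) return(empty)

  refractory <- as.integer(round(0.2 * fs))
  spki <- max(mwi[seq_len(min(2 * fs, n))]) / 3   # init from the first 2 s
  npki <- mean(mwi[seq_len(min(2 * fs, n))]) / 2
  thr1 <- npki + 0.25 * (spki - npki)
  accepted <- integer(0)
  for (p in cand) {
    last <- if (length(accepted) > 0) accepted[length(accepted)] else -Inf
    if (p - last < refractory) {
      # integrator ripple inside one QRS: keep the strongest local maximum
      if (mwi[p] > mwi[last]) accepted[length(accepted)] <- p
      next
    }
    if (mwi[p] > thr1) {
      accepted <- c(accepted, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  # search-back: if a long gap (> 1.66 x median RR) holds a sub-threshold
  # candidate above half the threshold, accept the strongest one
  if (length(accepted) >= 3) {
    rr <- stats::median(diff(accepted))
    gaps <- which(diff(accepted) > 1.66 * rr)
    for (g in gaps) {
      lo <- accepted[g] + refractory
      hi <- accepted[g + 1] - refractory
      inside <- cand[cand >= lo & cand <= hi]
      inside <- inside[mwi[inside] > 0.5 * thr1]
      if (length(inside) > 0) {
        accepted <- sort(c(accepted, inside[which.max(mwi[inside])]))
      }
    }
  }
  if (length(accepted) == 0) return(empty)

  # refine to the raw-lead local maximum within +-40 ms
  half <- as.integer(round(0.04 * fs))
  peaks <- vapply(accepted, function(p) {
    lo <- max(1L, as.integer(p) - half); hi <- min(n, as.integer(p) + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refinement can merge neighbours; enforce the refractory period again
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) >= refractory)
    peaks <- peaks[keep]
  }
  structure(list(peak_indices = peaks, detection_lead = cfg$detection_lead),
            class = "qrs_annotations")
}

#' Segment a record into 651-sample beats
#'
#' For each detected R peak `p` the inclusive window
#' `[p - pre_samples, p + post_samples]` is cut across all 12 leads. Peaks
#' whose window would leave the record are skipped (no padding), and the
#' first and last surviving beats are dropped. Fewer than three surviving
#' peaks therefore yield an empty result (`NULL`), not an error.
#'
#' @param record An `ecg_record` (standardized and filtered).
#' @param ann [detect_qrs()] annotations for the same record.
#' @param cfg A [preprocess_config()].
#' @return A [beat_dataset()] with the record's label and patient ID on
#'   every beat, or `NULL` when no beat survives.
#' @export
segment_beats <- function(record, ann, cfg = preprocess_config()) {
  stopifnot(inherits(ann, "qrs_annotations"))
  n <- ncol(record$signals)
  pre <- cfg$pre_samples; post <- cfg$post_samples
  peaks <- ann$peak_indices
  peaks <- peaks[peaks - pre >= 1 & peaks + post <= n]
  if (length(peaks) < 3) return(NULL)
  peaks <- peaks[-c(1, length(peaks))]
  beats <- array(NA_real_, dim = c(12L, pre + post + 1L, length(peaks)))
  for (i in seq_along(peaks)) {
    beats[, , i] <- record$signals[, (peaks[i] - pre):(peaks[i] + post)]
  }
  beat_dataset(beats,
               labels = rep(record$label, length(peaks)),
               patient_ids = rep(record$patient_id, length(peaks)))
}

#' Run the full preprocessing pipeline over records
#'
#' standardize -> denoise/detrend -> detect QRS -> segment, per record, then
#' concatenate all surviving beats into one [beat_dataset()].
#'
#' @param records List of `ecg_record` objects.
#' @param cfg A [preprocess_config()].
#' @param verbose Print per-record beat counts.
#' @return A [beat_dataset()].
#' @export
#' @examples
#' recs <- generate_dataset(1, list(class_profile("HC")), n_beats = 6, seed = 1)
#' ds <- preprocess_records(recs)
#' dim(ds$beats)
preprocess_records <- function(records, cfg = preprocess_config(),
                               verbose = FALSE) {
  parts <- list()
  for (rec in records) {
    r <- standardize(rec)
    r <- denoise_and_detrend(r, cfg)
    ann <- detect_qrs(r, cfg)
    ds <- segment_beats(r, ann, cfg)
    if (verbose) {
      message(sprintf("%s: %d peaks detected, %d beats emitted",
                      rec$record_id, length(ann$peak_indices),
                      if (is.null(ds)) 0L else n_beats(ds)))
    }
    if (!is.null(ds)) parts[[length(parts) + 1L]] <- ds
  }
  if (length(parts) == 0) stop_invalid("no beats survived preprocessing")
  ds <- bind_beats(parts)
  ds$class_names <- sort(unique(ds$labels))
  ds
}
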