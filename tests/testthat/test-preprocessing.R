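# Standardization, wavelet denoising / detrending, Pan-Tompkins detection
# and beat segmentation.

test_that("standardize min-max maps each lead onto [-1, 1]", {
  rec <- generate_record(clean_patient(), class_profile("HC"),
                         n_beats = 3, seed = 1)
  rec$signals[1, 1:3] <- c(0, 5, 10)       # known extremes on lead I
  rec$signals[1, -(1:3)] <- 5
  std <- suppressWarnings(standardize(rec))
  expect_equal(std$signals[1, 1:3], c(-1, 0, 1))
  for (i in 2:12) {
    expect_equal(range(std$signals[i, ]), c(-1, 1))
  }
  # a lead already spanning [-1, 1] is unchanged
  rec$signals[2, ] <- seq(-1, 1, length.out = ncol(rec$signals))
  std2 <- standardize(rec)
  expect_equal(std2$signals[2, ], rec$signals[2, ])
})

test_that("a constant lead standardizes to zeros with a warning, not an error", {
  rec <- generate_record(clean_patient(), class_profile("HC"),
                         n_beats = 3, seed = 1)
  rec$signals[5, ] <- 3.3
  expect_warning(std <- standardize(rec), "aVL")
  expect_equal(std$signals[5, ], rep(0, ncol(rec$signals)))
})

test_that("the wavelet transform reconstructs perfectly and denoising fixes zero", {
  set.seed(2)
  for (n in c(256, 1280)) {
    x <- rnorm(n)
    dec <- mlaecg:::wave_dec(x, 5)
    expect_equal(mlaecg:::wave_rec(dec), x, tolerance = 1e-10)
  }
  expect_equal(mlaecg:::wave_denoise(rep(0, 1000), 9), rep(0, 1000))
})

test_that("detrending removes at least 90% of a linear ramp (LS slope)", {
  rec <- generate_record(clean_patient(), class_profile("HC"),
                         n_beats = 5, seed = 3)
  n <- ncol(rec$signals)
  t <- (seq_len(n) - 1) / 1000
  ramp <- seq(0, 0.5, length.out = n)
  rec$signals[2, ] <- rec$signals[2, ] + ramp
  out <- denoise_and_detrend(rec, rescale = FALSE)
  slope_in <- coef(lm(rec$signals[2, ] ~ t))[2]
  slope_out <- coef(lm(out$signals[2, ] ~ t))[2]
  expect_lt(abs(slope_out), 0.1 * abs(slope_in))
})

test_that("denoising lowers the RMSE of a noisy beat train", {
  clean <- generate_record(clean_patient(), class_profile("HC"),
                           n_beats = 5, seed = 4)
  noisy <- clean
  set.seed(11)
  noisy$signals[2, ] <- clean$signals[2, ] + rnorm(ncol(clean$signals),
                                                   sd = 0.05)
  out <- denoise_and_detrend(noisy, rescale = FALSE)
  # compare against the detrended clean reference (the transform removes
  # the approximation band from any input)
  ref <- denoise_and_detrend(clean, rescale = FALSE)
  rmse_in <- sqrt(mean((noisy$signals[2, ] - clean$signals[2, ])^2))
  rmse_out <- sqrt(mean((out$signals[2, ] - ref$signals[2, ])^2))
  expect_lt(rmse_out, rmse_in)
})

test_that("Pan-Tompkins finds every beat of a clean record within 10 ms", {
  rec <- generate_record(clean_patient(hr = 60), class_profile("HC"),
                         n_beats = 10, seed = 7)
  r <- denoise_and_detrend(standardize(rec))
  ann <- detect_qrs(r)
  expect_length(ann$peak_indices, 10)
  expect_lte(max(abs(ann$peak_indices - rec$qrs_centers)), 10)
  expect_identical(ann$detection_lead, "II")
})

test_that("Pan-Tompkins handles noise, flat records and the refractory period", {
  # realistic noise + wander: all beats still found within 10 ms
  rec <- generate_record(
    patient_profile(heart_rate = 75, noise_sd = 0.05, wander_amp = 0.1),
    class_profile("IMI"), n_beats = 10, seed = 5
  )
  ann <- detect_qrs(denoise_and_detrend(standardize(rec)))
  expect_length(ann$peak_indices, 10)
  expect_lte(max(abs(ann$peak_indices - rec$qrs_centers)), 10)

  # flat zero record -> no peaks
  flat <- rec
  flat$signals[] <- 0
  expect_length(detect_qrs(flat)$peak_indices, 0)

  # two beats 150 ms apart: the second falls inside the 200 ms refractory
  tpl <- beat_template()
  t2 <- tpl; t2$p_wave[3] <- 0; t2$t_wave[3] <- 0
  n <- 3000
  one <- make_beat(t2, 1000, n)                       # QRS at 250 ms
  t3 <- t2; t3$p_wave[1] <- 0.23; t3$qrs[1] <- 0.40; t3$t_wave[1] <- 0.65
  two <- one + make_beat(t3, 1000, n)                 # second QRS at 400 ms
  close_rec <- structure(
    list(signals = matrix(rep(two, each = 12), nrow = 12,
                          dimnames = list(ecg_leads(), NULL)),
         fs = 1000, lead_names = ecg_leads(), patient_id = "P1",
         record_id = "r", label = "HC"),
    class = "ecg_record"
  )
  expect_length(detect_qrs(close_rec)$peak_indices, 1)
})

test_that("segmentation emits exact 12 x 651 windows and drops first/last beats", {
  rec <- generate_record(clean_patient(hr = 60), class_profile("HC"),
                         n_beats = 10, seed = 7)
  r <- denoise_and_detrend(standardize(rec))
  ann <- detect_qrs(r)
  ds <- segment_beats(r, ann)
  eligible <- sum(ann$peak_indices - 250 >= 1 &
                  ann$peak_indices + 400 <= ncol(r$signals))
  expect_equal(n_beats(ds), eligible - 2L)
  expect_equal(dim(ds$beats)[1:2], c(12L, 651L))
  expect_true(all(ds$beats >= -1 & ds$beats <= 1))
  expect_true(all(ds$labels == "HC"))
  expect_true(all(ds$patient_ids == rec$patient_id))
})

test_that("margin-violating peaks are skipped and tiny annotations yield NULL", {
  rec <- generate_record(clean_patient(hr = 60), class_profile("HC"),
                         n_beats = 10, seed = 7)
  r <- denoise_and_detrend(standardize(rec))
  ann <- detect_qrs(r)
  # inject a peak too close to the record start: skipped before the
  # first/last-removal step, so the output count drops by exactly one
  # (the early peak would otherwise have been the removed "first" beat)
  ann_bad <- ann
  ann_bad$peak_indices <- sort(c(100L, ann$peak_indices))
  expect_equal(n_beats(segment_beats(r, ann_bad)),
               n_beats(segment_beats(r, ann)))
  ann2 <- ann
  ann2$peak_indices <- ann$peak_indices[1:2]
  expect_null(segment_beats(r, ann2))
})

test_that("the full pipeline is deterministic and concatenates records", {
  recs <- generate_dataset(2, list(class_profile("HC"), class_profile("IMI")),
                           n_beats = 5, seed = 10)
  ds1 <- preprocess_records(recs)
  ds2 <- preprocess_records(recs)
  expect_identical(ds1$beats, ds2$beats)
  expect_setequal(unique(ds1$labels), c("HC", "IMI"))
  expect_equal(dim(ds1$beats)[1:2], c(12L, 651L))
})
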