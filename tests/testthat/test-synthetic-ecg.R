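# Synthetic 12-lead generator: waveform composition, class structure,
# determinism.

test_that("make_beat composes bumps, ST offset and baseline as documented", {
  # zero template -> zero waveform
  tpl0 <- beat_template(p_wave = c(0.08, 0.025, 0),
                        qrs = c(0.25, 0.012, 0),
                        t_wave = c(0.50, 0.05, 0))
  expect_equal(make_beat(tpl0, 1000, 651), rep(0, 651))

  # pure ST offset -> rectangular window [qrs + 0.06, t_center - t_width/2]
  tpl_st <- beat_template(p_wave = c(0.08, 0.025, 0),
                          qrs = c(0.25, 0.012, 0),
                          t_wave = c(0.50, 0.05, 0), st_offset = 0.2)
  w <- make_beat(tpl_st, 1000, 651)
  t <- (0:650) / 1000
  inside <- t >= 0.31 & t <= 0.475
  expect_equal(w[inside], rep(0.2, sum(inside)))
  expect_equal(w[!inside], rep(0, sum(!inside)))

  # default template: |waveform| peaks at the QRS center sample
  w <- make_beat(beat_template(), 1000, 651)
  expect_equal(which.max(abs(w)), 251)    # 0.25 s at 1000 Hz, 1-based
  expect_true(all(is.finite(w)))
})

test_that("make_beat and template constructors validate their inputs", {
  expect_error(make_beat(beat_template(), fs = 0, n_samples = 651), "fs")
  expect_error(make_beat(beat_template(), fs = 1000, n_samples = -1),
               "n_samples")
  expect_error(beat_template(qrs = c(0.25, -1, 1)), "width")
  expect_error(beat_template(p_wave = c(0.5, 0.02, 1)), "ordered")
  expect_error(class_profile("HC", st_shift = 0.1), "HC")
  expect_error(patient_profile(heart_rate = 300), "heart_rate")
})

test_that("generate_record is deterministic and class effects stay on affected leads", {
  p <- clean_patient()
  hc <- generate_record(p, class_profile("HC"), n_beats = 5, seed = 3)
  hc2 <- generate_record(p, class_profile("HC"), n_beats = 5, seed = 3)
  expect_identical(hc$signals, hc2$signals)

  # noiseless record is periodic: beats 1 s apart at 60 bpm repeat exactly
  period <- 1000
  seg1 <- hc$signals[, 101:(100 + period)]
  seg2 <- hc$signals[, (101 + period):(100 + 2 * period)]
  expect_equal(seg1, seg2, tolerance = 1e-12)

  # IMI with ST shift: exactly II, III, aVF differ from the HC record
  imi <- generate_record(p, class_profile("IMI", st_shift = 0.3),
                         n_beats = 5, seed = 3)
  differs <- vapply(seq_len(12), function(i) {
    any(abs(imi$signals[i, ] - hc$signals[i, ]) > 1e-12)
  }, logical(1))
  expect_equal(ecg_leads()[differs], c("II", "III", "aVF"))
  expect_error(generate_record(p, class_profile("HC"), n_beats = 2), "n_beats")
})

test_that("pure-noise leads carry noise only and no cardiac signal", {
  p <- clean_patient()
  rec <- generate_record(p, class_profile("HC"), n_beats = 5, seed = 9,
                         noise_leads = "V1", noise_lead_sd = 0.2)
  v1 <- rec$signals[match("V1", rec$lead_names), ]
  # no periodic structure: autocorrelation at one beat lag is tiny
  ac <- cor(v1[1:3000], v1[1001:4000])
  expect_lt(abs(ac), 0.1)
  # other leads untouched relative to a no-noise-lead run
  ref <- generate_record(p, class_profile("HC"), n_beats = 5, seed = 9)
  expect_identical(rec$signals[2, ], ref$signals[2, ])
})

test_that("generate_dataset yields unique patients, all labels, deterministically", {
  classes <- list(class_profile("HC"), class_profile("IMI"))
  recs <- generate_dataset(2, classes, n_beats = 4, seed = 7)
  expect_length(recs, 4)
  expect_length(unique(vapply(recs, `[[`, character(1), "patient_id")), 4)

  recs2 <- generate_dataset(2, classes, n_beats = 4, seed = 7)
  expect_identical(lapply(recs, `[[`, "signals"),
                   lapply(recs2, `[[`, "signals"))

  all6 <- generate_dataset(1, lapply(
    c("HC", "AMI", "ALMI", "ASMI", "IMI", "ILMI"), class_profile
  ), n_beats = 4, seed = 1)
  expect_setequal(vapply(all6, `[[`, character(1), "label"),
                  c("HC", "AMI", "ALMI", "ASMI", "IMI", "ILMI"))
  expect_error(generate_dataset(1, list(), n_beats = 4), "non-empty")
  expect_error(generate_dataset(0, classes, n_beats = 4), "n_patients")
})

test_that("leads outside every affected set carry no class signal at zero noise", {
  p <- clean_patient()
  by_class <- lapply(c("HC", "IMI"), function(cl) {
    generate_record(p, class_profile(cl), n_beats = 4, seed = 5)$signals
  })
  unaffected <- setdiff(ecg_leads(), class_profile("IMI")$affected_leads)
  for (lead in unaffected) {
    i <- match(lead, ecg_leads())
    expect_equal(by_class[[1]][i, ], by_class[[2]][i, ],
                 info = paste("lead", lead))
  }
})
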