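# Metrics, fold construction and the cross-validation plumbing.

test_that("confusion counts match hand tallies", {
  expect_equal(confusion(c(1, 1, 0), c(1, 0, 0), positive_class = 1),
               c(TP = 1L, FP = 0L, TN = 1L, FN = 1L))
  y <- c("MI", "HC", "MI", "HC")
  expect_equal(confusion(y, y, "MI"), c(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  allpos <- confusion(y, rep("MI", 4), "MI")
  expect_equal(allpos[["TN"]], 0L)
  expect_equal(allpos[["FP"]], 2L)
  expect_error(confusion(1:3, 1:2, 1), "equal length")
})

test_that("acc/sen/spe reproduce hand-computed percentages", {
  m <- acc_sen_spe(c(TP = 3, FP = 1, TN = 2, FN = 0))
  expect_equal(m[["acc"]], 100 * 5 / 6, tolerance = 1e-12)
  expect_equal(m[["sen"]], 100)
  expect_equal(m[["spe"]], 100 * 2 / 3, tolerance = 1e-12)

  expect_warning(m2 <- acc_sen_spe(c(TP = 0, FP = 0, TN = 8, FN = 0)),
                 "sensitivity")
  expect_equal(m2[["acc"]], 100)
  expect_equal(m2[["spe"]], 100)
  expect_true(is.nan(m2[["sen"]]))
  expect_error(acc_sen_spe(c(-1, 0, 0, 0)), "non-negative")
})

test_that("accuracy equals the prevalence-weighted mean of sen and spe", {
  set.seed(1)
  for (rep in 1:20) {
    cm <- c(TP = sample(0:30, 1), FP = sample(0:30, 1),
            TN = sample(0:30, 1), FN = sample(0:30, 1))
    if (cm[["TP"]] + cm[["FN"]] == 0 || cm[["TN"]] + cm[["FP"]] == 0) next
    m <- acc_sen_spe(cm)
    n_pos <- cm[["TP"]] + cm[["FN"]]
    n_neg <- cm[["TN"]] + cm[["FP"]]
    expect_equal(m[["acc"]],
                 (n_pos * m[["sen"]] + n_neg * m[["spe"]]) / (n_pos + n_neg),
                 tolerance = 1e-9)
  }
})

test_that("per-class one-vs-rest metrics match hand counting", {
  y_true <- c("A", "A", "B", "B", "C", "C")
  y_pred <- c("A", "B", "B", "B", "C", "A")
  pc <- per_class_metrics(y_true, y_pred, c("A", "B", "C"))
  a <- pc[pc$class == "A", ]
  expect_equal(c(a$TP, a$FP, a$TN, a$FN), c(1, 1, 3, 1))
  b <- pc[pc$class == "B", ]
  expect_equal(c(b$TP, b$FP, b$TN, b$FN), c(2, 1, 3, 0))
  # every class row carries the same overall accuracy
  expect_equal(unique(pc$acc), 100 * 4 / 6, tolerance = 1e-12)
  # perfect prediction: all sensitivities and specificities 100
  pc2 <- per_class_metrics(y_true, y_true, c("A", "B", "C"))
  expect_true(all(pc2$sen[pc2$class != "macro"] == 100))
  expect_true(all(pc2$spe[pc2$class != "macro"] == 100))
  # a class absent from the truth warns and yields NaN sensitivity
  expect_warning(pc3 <- per_class_metrics(c("A", "A"), c("A", "B"),
                                          c("A", "B")), "absent")
  expect_true(is.nan(pc3$sen[pc3$class == "B"]))
})

test_that("intra-patient folds partition the beats 3:1:1 with rotation", {
  ds <- random_beats(100, len = 16, n_patients = 10, seed = 2)
  folds <- make_folds(ds, "intra", k = 5, seed = 3)
  expect_length(folds, 5)
  all_tests <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(all_tests), 1:100)     # disjoint and exhaustive
  for (f in folds) {
    expect_equal(sort(c(f$train, f$val, f$test)), 1:100)
    expect_equal(length(f$test), 20)
    expect_equal(length(f$val), 20)
    expect_equal(length(f$train), 60)
  }
  # determinism
  folds2 <- make_folds(ds, "intra", k = 5, seed = 3)
  expect_identical(folds, folds2)
})

test_that("inter-patient folds are patient-disjoint and follow patients", {
  ds <- random_beats(120, len = 16, n_patients = 12, seed = 4)
  folds <- make_folds(ds, "inter", k = 5, seed = 5)
  for (f in folds) {
    expect_length(intersect(ds$patient_ids[f$train], ds$patient_ids[f$test]), 0)
    expect_length(intersect(ds$patient_ids[f$train], ds$patient_ids[f$val]), 0)
    expect_length(intersect(ds$patient_ids[f$val], ds$patient_ids[f$test]), 0)
    expect_equal(sort(c(f$train, f$val, f$test)), seq_len(n_beats(ds)))
  }
  # too few patients per class is an error
  ds_small <- random_beats(40, len = 16, n_patients = 4, seed = 6)
  expect_error(make_folds(ds_small, "inter"), "patients per class")
})

test_that("cross_validate wires training, metrics and lead weights together", {
  # tiny but real run: short beats, small model, one epoch
  ds <- random_beats(60, len = 64, n_patients = 10, seed = 7)
  cfg <- train_config(batch_size = 12, epochs = 1, hidden = 4, attn_dim = 3,
                      n_kernels = 2, seed = 5, task = "detection")
  cv <- cross_validate(ds, cfg, scheme = "intra", k = 5, seed = 8)
  expect_s3_class(cv, "mla_cv")
  expect_equal(nrow(cv$folds), 5L)
  expect_true(all(cv$folds$acc >= 0 & cv$folds$acc <= 100))
  expect_length(cv$mean_lead_weights, 12)
  expect_true(all(cv$lead_weights >= 0 & cv$lead_weights <= 1))
  # population std of identical values is zero
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(pop_sd(rep(cv$folds$acc[1], 5)), 0)

  dir <- file.path(tempdir(), "cvreport")
  write_cv_report(cv, dir)
  lwcsv <- read.csv(file.path(dir, "lead_weights.csv"))
  expect_equal(nrow(lwcsv), 12L)
  expect_true(file.exists(file.path(dir, "metrics.json")))
  expect_true(file.exists(file.path(dir, "metrics.csv")))
})
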