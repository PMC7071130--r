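# Evaluation: confusion counts, accuracy/sensitivity/specificity,
# per-class (one-vs-rest) reporting, five-fold intra-/inter-patient
# splitting, and cross-validation with lead-weight aggregation.

#' Binary confusion counts
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param positive_class The class counted as positive (conventionally the
#'   MI class); everything else is negative.
#' @return Named vector `c(TP, FP, TN, FN)`.
#' @export
#' @examples
#' confusion(c(1, 1, 0), c(1, 0, 0), positive_class = 1)  # TP 1, FN 1, TN 1
confusion <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred)) {
    stop_invalid("`y_true` and `y_pred` must have equal length")
  }
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Accuracy, sensitivity and specificity (percent)
#'
#' Acc = (TP+TN)/(TP+FP+TN+FN), Sen = TP/(TP+FN), Spe = TN/(FP+TN), all
#' times 100. A zero denominator yields `NaN` with a warning, not an error.
#'
#' @param counts Named vector from [confusion()] (or four counts in
#'   TP, FP, TN, FN order).
#' @return Named vector `c(acc, sen, spe)` in percent.
#' @export
#' @examples
#' acc_sen_spe(c(TP = 3, FP = 1, TN = 2, FN = 0))  # 83.33, 100, 66.67
acc_sen_spe <- function(counts) {
  tp <- counts[[1]]; fp <- counts[[2]]; tn <- counts[[3]]; fn <- counts[[4]]
  if (any(c(tp, fp, tn, fn) < 0)) stop_invalid("counts must be non-negative")
  total <- tp + fp + tn + fn
  acc <- if (total > 0) 100 * (tp + tn) / total else NaN
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else NaN
  spe <- if (fp + tn > 0) 100 * tn / (fp + tn) else NaN
  if (is.nan(sen)) warning("no positive cases: sensitivity undefined", call. = FALSE)
  if (is.nan(spe)) warning("no negative cases: specificity undefined", call. = FALSE)
  c(acc = acc, sen = sen, spe = spe)
}

#' Per-class one-vs-rest metrics
#'
#' For each class, the one-vs-rest confusion yields its sensitivity and
#' specificity. The per-class `acc` column reports the overall multi-class
#' fraction-correct (every class of one evaluation shares it — the
#' convention used in per-class MI-location tables); the one-vs-rest
#' accuracy is exposed separately as `acc_ovr`. A macro (unweighted) mean
#' row is appended.
#'
#' @param y_true,y_pred Label vectors.
#' @param class_names Class universe.
#' @return Data frame: one row per class plus a `"macro"` row, columns
#'   `class`, `TP`, `FP`, `TN`, `FN`, `acc`, `acc_ovr`, `sen`, `spe`.
#' @export
per_class_metrics <- function(y_true, y_pred, class_names = NULL) {
  class_names <- class_names %||% sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% class_names)) {
    stop_invalid("labels outside `class_names`")
  }
  overall <- 100 * mean(y_true == y_pred)
  rows <- lapply(class_names, function(cl) {
    cm <- confusion(y_true, y_pred, cl)
    if (!cl %in% y_true) {
      warning("class ", cl, " absent from y_true: its sensitivity is undefined",
              call. = FALSE)
    }
    m <- suppressWarnings(acc_sen_spe(cm))
    data.frame(class = cl, TP = cm[["TP"]], FP = cm[["FP"]], TN = cm[["TN"]],
               FN = cm[["FN"]], acc = overall, acc_ovr = m[["acc"]],
               sen = m[["sen"]], spe = m[["spe"]])
  })
  out <- do.call(rbind, rows)
  macro <- data.frame(class = "macro", TP = NA, FP = NA, TN = NA, FN = NA,
                      acc = overall, acc_ovr = mean(out$acc_ovr),
                      sen = mean(out$sen, na.rm = TRUE),
                      spe = mean(out$spe, na.rm = TRUE))
  rbind(out, macro)
}

#' Five-fold intra-/inter-patient splits
#'
#' Partitions the data into `k` near-equal parts and builds `k` rotating
#' folds, each using 3 parts for training, 1 for validation and 1 for
#' testing (the 3:1:1 proportion). Under the intra-patient scheme the
#' partition is at beat level, so one patient's beats can appear on both
#' sides; under the inter-patient scheme the partition is at patient level
#' (stratified by each patient's class so every part keeps all classes) and
#' beats follow their patients — the clinically realistic protocol.
#'
#' @param dataset A [beat_dataset()].
#' @param scheme `"intra"` or `"inter"`.
#' @param k Number of folds (5).
#' @param seed Integer seed for the partition.
#' @return List of `k` fold objects: `fold_index`, beat-index vectors
#'   `train`, `val`, `test`, and (inter) the patient partition.
#' @export
make_folds <- function(dataset, scheme = c("intra", "inter"), k = 5,
                       seed = 1) {
  scheme <- match.arg(scheme)
  n <- n_beats(dataset)
  parts <- with_seed(seed, {
    if (scheme == "intra") {
      split(sample.int(n), rep_len(seq_len(k), n))
    } else {
      pts <- unique(dataset$patient_ids)
      pt_class <- dataset$labels[match(pts, dataset$patient_ids)]
      if (any(table(pt_class) < k)) {
        stop_invalid(sprintf(
          "the inter-patient scheme needs at least %d patients per class", k))
      }
      assign_part <- integer(length(pts))
      for (cl in unique(pt_class)) {
        members <- sample(which(pt_class == cl))
        assign_part[members] <- rep_len(seq_len(k), length(members))
      }
      lapply(seq_len(k), function(p) {
        which(dataset$patient_ids %in% pts[assign_part == p])
      })
    }
  })
  lapply(seq_len(k), function(f) {
    test_p <- f
    val_p <- f %% k + 1L
    train_p <- setdiff(seq_len(k), c(test_p, val_p))
    list(fold_index = f,
         train = sort(unlist(parts[train_p], use.names = FALSE)),
         val = sort(parts[[val_p]]),
         test = sort(parts[[test_p]]),
         scheme = scheme)
  })
}

#' Five-fold cross-validation of the full model
#'
#' Trains one model per fold on the training parts and evaluates on the
#' test part, reporting accuracy/sensitivity/specificity per fold with mean
#' and (population) standard deviation, plus the mean MLA lead weight over
#' each fold's test beats — the lead-ranking diagnostic.
#'
#' @param dataset A [beat_dataset()].
#' @param cfg A [train_config()].
#' @param scheme `"intra"` or `"inter"`.
#' @param k Number of folds.
#' @param seed Seed for the fold partition (training seeds derive from
#'   `cfg$seed` plus the fold index).
#' @param verbose Print per-fold progress.
#' @return An object of class `mla_cv`: `folds` (data frame fold x metric),
#'   `mean`, `std`, `lead_weights` (k x 12 matrix plus a `mean` attribute),
#'   `per_class` (location only), `scheme`.
#' @export
cross_validate <- function(dataset, cfg = train_config(),
                           scheme = c("intra", "inter"), k = 5, seed = 1,
                           verbose = FALSE) {
  scheme <- match.arg(scheme)
  folds <- make_folds(dataset, scheme, k = k, seed = seed)
  class_names <- dataset$class_names
  positive <- if (cfg$task == "detection") class_names[2] else NULL
  fold_rows <- list()
  lw <- matrix(NA_real_, k, 12,
               dimnames = list(paste0("fold", seq_len(k)), ecg_leads()))
  per_class <- list()
  for (f in seq_len(k)) {
    fold <- folds[[f]]
    cfg_f <- cfg
    cfg_f$seed <- cfg$seed + f
    fit <- train(subset_beats(dataset, fold$train),
                 subset_beats(dataset, fold$val), cfg_f,
                 class_names = class_names, validate = FALSE)
    test <- subset_beats(dataset, fold$test)
    pr <- predict(fit, test)
    if (cfg$task == "detection") {
      cm <- confusion(test$labels, pr$class, positive)
      m <- suppressWarnings(acc_sen_spe(cm))
    } else {
      pc <- per_class_metrics(test$labels, pr$class, class_names)
      per_class[[f]] <- pc
      macro <- pc[pc$class == "macro", ]
      m <- c(acc = macro$acc, sen = macro$sen, spe = macro$spe)
    }
    lw[f, ] <- lead_weights(fit, test)
    fold_rows[[f]] <- data.frame(fold = f, acc = m[["acc"]],
                                 sen = m[["sen"]], spe = m[["spe"]])
    if (verbose) {
      message(sprintf("fold %d: acc %.2f%% sen %.2f%% spe %.2f%%",
                      f, m[["acc"]], m[["sen"]], m[["spe"]]))
    }
  }
  tab <- do.call(rbind, fold_rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(
    list(folds = tab,
         mean = colMeans(tab[, c("acc", "sen", "spe")]),
         std = vapply(tab[, c("acc", "sen", "spe")], pop_sd, numeric(1)),
         lead_weights = lw,
         mean_lead_weights = colMeans(lw),
         per_class = if (length(per_class) > 0) per_class else NULL,
         scheme = scheme, task = cfg$task),
    class = "mla_cv"
  )
}

#' @export
print.mla_cv <- function(x, ...) {
  cat(sprintf("<mla_cv> %s task, %s-patient scheme, %d folds\n",
              x$task, x$scheme, nrow(x$folds)))
  print(round(x$folds, 2), row.names = FALSE)
  cat(sprintf("mean: acc %.2f%% sen %.2f%% spe %.2f%% | std: %.2f / %.2f / %.2f\n",
              x$mean[["acc"]], x$mean[["sen"]], x$mean[["spe"]],
              x$std[["acc"]], x$std[["sen"]], x$std[["spe"]]))
  cat("mean lead weights:\n")
  print(round(x$mean_lead_weights, 3))
  invisible(x)
}

#' Write a cross-validation report to disk
#'
#' Emits `metrics.json` (raw values), `metrics.csv` (fold x metric, 2
#' decimals), `lead_weights.csv` (12 rows: lead, mean weight) and, for
#' location tasks, `per_class.csv`.
#'
#' @param cv An `mla_cv` object.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cv_report <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(scheme = cv$scheme, task = cv$task, folds = cv$folds,
         mean = as.list(cv$mean), std = as.list(cv$std),
         mean_lead_weights = as.list(cv$mean_lead_weights)),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA
  )
  tab <- cv$folds
  tab[, c("acc", "sen", "spe")] <- round(tab[, c("acc", "sen", "spe")], 2)
  write.csv(tab, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(data.frame(lead = colnames(cv$lead_weights),
                       mean_weight = cv$mean_lead_weights),
            file.path(dir, "lead_weights.csv"), row.names = FALSE)
  if (!is.null(cv$per_class)) {
    pc <- do.call(rbind, Map(function(p, f) cbind(fold = f, p),
                             cv$per_class, seq_along(cv$per_class)))
    write.csv(pc, file.path(dir, "per_class.csv"), row.names = FALSE)
  }
  invisible(dir)
}
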