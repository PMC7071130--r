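# Reading and writing ECG records, beat tensors and label tables.
#
# Records travel either as per-record CSV matrices (columns = leads, rows =
# samples) or as minimal WFDB pairs (text header + 16-bit binary signal
# file). Channels are always reordered into the canonical lead order on
# read; extra channels (e.g. Frank leads vx/vy/vz) are dropped.

#' Construct a beat dataset
#'
#' The container holding segmented heartbeats: a `12 x 651 x n` array of
#' standardized beats plus per-beat labels and patient IDs (the latter are
#' what makes patient-disjoint, inter-patient splitting possible).
#'
#' @param beats Numeric array `12 x T x n` (or a single `12 x T` matrix).
#' @param labels Character vector of per-beat class labels, length `n`.
#' @param patient_ids Character vector of per-beat patient IDs, length `n`.
#' @param class_names Ordered class universe; defaults to the sorted unique
#'   labels.
#' @return An object of class `beat_dataset`.
#' @export
beat_dataset <- function(beats, labels, patient_ids, class_names = NULL) {
  if (is.matrix(beats)) beats <- array(beats, dim = c(dim(beats), 1L))
  stopifnot(is.array(beats), length(dim(beats)) == 3L)
  n <- dim(beats)[3]
  if (n == 0L) stop_invalid("a beat dataset must contain at least one beat")
  if (length(labels) != n || length(patient_ids) != n) {
    stop_invalid("`labels` and `patient_ids` must have one entry per beat")
  }
  if (!all(is.finite(beats))) stop_invalid("beats must be finite everywhere")
  class_names <- class_names %||% sort(unique(as.character(labels)))
  if (!all(labels %in% class_names)) {
    stop_invalid("every label must belong to `class_names`")
  }
  structure(
    list(beats = beats, labels = as.character(labels),
         patient_ids = as.character(patient_ids),
         class_names = class_names),
    class = "beat_dataset"
  )
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats (%d x %d), %d patients, classes: %s\n",
              dim(x$beats)[3], dim(x$beats)[1], dim(x$beats)[2],
              length(unique(x$patient_ids)),
              paste(x$class_names, collapse = ", ")))
  print(table(x$labels))
  invisible(x)
}

#' Number of beats in a dataset
#' @param ds A [beat_dataset()].
#' @return Integer count.
#' @export
n_beats <- function(ds) dim(ds$beats)[3]

#' Subset a beat dataset by beat index
#' @param ds A [beat_dataset()].
#' @param idx Integer indices of the beats to keep.
#' @return A [beat_dataset()].
#' @export
subset_beats <- function(ds, idx) {
  beat_dataset(ds$beats[, , idx, drop = FALSE], ds$labels[idx],
               ds$patient_ids[idx], ds$class_names)
}

#' Concatenate beat datasets
#' @param ... [beat_dataset()] objects sharing beat dimensions.
#' @return A single [beat_dataset()].
#' @export
bind_beats <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "beat_dataset")) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) > 0)
  d <- dim(parts[[1]]$beats)[1:2]
  arrs <- lapply(parts, function(p) p$beats)
  beat_dataset(
    array(unlist(arrs, use.names = FALSE),
          dim = c(d, sum(vapply(parts, n_beats, integer(1))))),
    unlist(lapply(parts, `[[`, "labels")),
    unlist(lapply(parts, `[[`, "patient_ids")),
    sort(unique(unlist(lapply(parts, `[[`, "class_names"))))
  )
}

.as_record <- function(signals, fs, patient_id, record_id, label) {
  structure(
    list(signals = signals, fs = fs, lead_names = ecg_leads(),
         patient_id = patient_id, record_id = record_id, label = label),
    class = "ecg_record"
  )
}

# Reorder a channels x samples matrix with named rows into canonical order,
# dropping extra channels. Errors name the missing lead.
.canonicalize <- function(signals, channel_names) {
  if (length(channel_names) < 12L) {
    stop_invalid(sprintf("record has %d channels; 12 leads are required",
                         length(channel_names)))
  }
  idx <- match_leads(channel_names)
  if (anyNA(idx)) {
    stop_invalid("missing lead(s): ",
                 paste(ecg_leads()[is.na(idx)], collapse = ", "))
  }
  out <- signals[idx, , drop = FALSE]
  rownames(out) <- ecg_leads()
  out
}

#' Write / read a record as CSV
#'
#' CSV layout: one column per lead (header = lead name), one row per sample,
#' values in mV. Metadata (fs, IDs, label) travels in the sidecar label table
#' written by [write_dataset()], or is supplied by the caller on read.
#'
#' @param record An `ecg_record`.
#' @param path Output file.
#' @return `write_record_csv()` returns `path` invisibly.
#' @export
write_record_csv <- function(record, path) {
  df <- as.data.frame(t(record$signals))
  names(df) <- record$lead_names
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_record_csv
#' @param fs Sampling frequency in Hz.
#' @param patient_id,record_id,label Metadata attached to the returned record.
#' @return `read_record_csv()` returns an `ecg_record`.
#' @export
read_record_csv <- function(path, fs = 1000, patient_id = NA_character_,
                            record_id = NA_character_, label = NA_character_) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  signals <- .canonicalize(t(as.matrix(df)), names(df))
  .as_record(signals, fs, patient_id, record_id, label)
}

#' Write / read a minimal WFDB record (format 16)
#'
#' Writes a PhysioNet-style pair: a text header (`<record>.hea`) and an
#' interleaved little-endian 16-bit signal file (`<record>.dat`). The header
#' carries one signal line per channel with gain `1000/mV` and the lead name
#' in the description field; reading reorders channels by that name and
#' drops non-standard channels (e.g. Frank leads vx/vy/vz).
#'
#' @param record An `ecg_record`.
#' @param dir Output directory.
#' @param extra_channels Optional named matrix (channels x samples) of
#'   additional channels appended after the 12 leads (used to emulate
#'   15-channel recordings).
#' @return `write_record_wfdb()` invisibly returns the header path.
#' @export
write_record_wfdb <- function(record, dir, extra_channels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  signals <- record$signals
  ch_names <- record$lead_names
  if (!is.null(extra_channels)) {
    stopifnot(ncol(extra_channels) == ncol(signals),
              !is.null(rownames(extra_channels)))
    signals <- rbind(signals, extra_channels)
    ch_names <- c(ch_names, rownames(extra_channels))
  }
  n_sig <- nrow(signals)
  n_samp <- ncol(signals)
  gain <- 1000                              # ADC units per mV
  name <- record$record_id
  if (is.na(name) || !nzchar(name)) name <- "record"
  hea <- file.path(dir, paste0(name, ".hea"))
  dat <- paste0(name, ".dat")
  lines <- c(
    sprintf("%s %d %g %d", name, n_sig, record$fs, n_samp),
    sprintf("%s 16 %d(0)/mV 16 0 0 0 0 %s", dat, gain, ch_names)
  )
  writeLines(lines, hea)
  adc <- round(signals * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc), con, size = 2L, endian = "little")
  invisible(hea)
}

#' @rdname write_record_wfdb
#' @param path Path to the `.hea` header file.
#' @param fs Ignored (taken from the header); present for symmetry.
#' @param patient_id,record_id,label Metadata attached to the result.
#' @return `read_record_wfdb()` returns an `ecg_record` (12 canonical leads).
#' @export
read_record_wfdb <- function(path, fs = NULL, patient_id = NA_character_,
                             record_id = NA_character_, label = NA_character_) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(head_tok[2])
  fs_hdr <- as.numeric(head_tok[3])
  n_samp <- as.integer(head_tok[4])
  sig_lines <- lines[1 + seq_len(n_sig)]
  parse_sig <- function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    fmt <- tok[2]
    if (fmt != "16") stop_invalid("unsupported WFDB signal format: ", fmt)
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", tok[3])))
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ") else ""
    list(file = tok[1], gain = gain, desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  dat_path <- file.path(dirname(path), sigs[[1]]$file)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what = "integer", n = n_sig * n_samp,
                      size = 2L, signed = TRUE, endian = "little")
  mat <- matrix(as.numeric(raw_vals), nrow = n_sig)   # interleaved samples
  gains <- vapply(sigs, `[[`, numeric(1), "gain")
  gains[!is.finite(gains) | gains == 0] <- 200        # WFDB default gain
  mat <- mat / gains
  ch_names <- vapply(sigs, `[[`, character(1), "desc")
  signals <- .canonicalize(mat, ch_names)
  if (is.na(record_id)) record_id <- head_tok[1]
  .as_record(signals, fs_hdr, patient_id, record_id, label)
}

#' Read a record in either supported format
#'
#' @param path File path (`.csv`, or a WFDB `.hea` header).
#' @param format `"csv"` or `"wfdb"`; inferred from the extension by default.
#' @param ... Passed to the format-specific reader (metadata, fs).
#' @return An `ecg_record` with the 12 leads in canonical order.
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.hea$", path, ignore.case = TRUE)) "wfdb" else "csv"
  }
  switch(format,
         csv = read_record_csv(path, ...),
         wfdb = read_record_wfdb(path, ...))
}

#' Write / read a dataset of records with its label table
#'
#' Writes one file per record plus a sidecar `labels.csv`
#' (record_id, patient_id, label) — the label table is always explicit.
#'
#' @param records List of `ecg_record` objects.
#' @param dir Output directory.
#' @param format `"csv"` or `"wfdb"`.
#' @return `write_dataset()` invisibly returns `dir`; `read_dataset()`
#'   returns a list of `ecg_record` objects.
#' @export
write_dataset <- function(records, dir, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    record_id = vapply(records, `[[`, character(1), "record_id"),
    patient_id = vapply(records, `[[`, character(1), "patient_id"),
    label = vapply(records, `[[`, character(1), "label"),
    fs = vapply(records, `[[`, numeric(1), "fs")
  )
  for (rec in records) {
    if (format == "csv") {
      write_record_csv(rec, file.path(dir, paste0(rec$record_id, ".csv")))
    } else {
      write_record_wfdb(rec, dir)
    }
  }
  write.csv(meta, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  meta <- read.csv(file.path(dir, "labels.csv"),
                   colClasses = c(record_id = "character",
                                  patient_id = "character",
                                  label = "character"))
  lapply(seq_len(nrow(meta)), function(i) {
    path <- file.path(dir, paste0(meta$record_id[i],
                                  if (format == "csv") ".csv" else ".hea"))
    read_record(path, format,
                fs = meta$fs[i], patient_id = meta$patient_id[i],
                record_id = meta$record_id[i], label = meta$label[i])
  })
}

#' Write / read a beat dataset
#'
#' The beat tensor is serialized to a compressed array file (`.rds`), and a
#' plain-CSV manifest (`beat_index`, `patient_id`, `label`) is written next
#' to it so labels stay human-readable and diff-able. The round trip is
#' lossless.
#'
#' @param dataset A [beat_dataset()].
#' @param path Output `.rds` path; the manifest lands at
#'   `sub("\\.rds$", "_manifest.csv", path)`.
#' @return `write_beats()` invisibly returns `path`; `read_beats()` returns
#'   the [beat_dataset()].
#' @export
write_beats <- function(dataset, path) {
  stopifnot(inherits(dataset, "beat_dataset"))
  manifest <- data.frame(
    beat_index = seq_len(n_beats(dataset)),
    patient_id = dataset$patient_ids,
    label = dataset$labels
  )
  saveRDS(list(beats = dataset$beats, class_names = dataset$class_names),
          path, compress = "gzip")
  write.csv(manifest, sub("\\.rds$", "_manifest.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  blob <- readRDS(path)
  manifest <- read.csv(sub("\\.rds$", "_manifest.csv", path),
                       colClasses = c(patient_id = "character",
                                      label = "character"))
  if (nrow(manifest) != dim(blob$beats)[3]) {
    stop_invalid("manifest row count does not match the stored beat count")
  }
  beat_dataset(blob$beats, manifest$label, manifest$patient_id,
               blob$class_names)
}
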