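#' Annotated multi-channel EEG record
#'
#' The raw study object: a channels-by-timepoints matrix of amplitudes
#' (microvolts), its sampling rate, channel names, and expert seizure
#' annotations as `(start_s, end_s)` intervals measured from record start.
#'
#' @param signal Numeric matrix, channels x timepoints, or a numeric vector
#'   for a single-channel record.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Optional character vector, one name per channel.
#' @param annotations Data frame with columns `start_s`, `end_s`
#'   (may have zero rows).
#' @param record_id Identifier string.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(signal, fs, channel_names = NULL,
                       annotations = NULL, record_id = "record") {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("signal must be a numeric matrix (channels x timepoints)")
  }
  stop_if_not_scalar_number(fs, "fs")
  if (fs <= 0) stop("fs must be positive")
  if (nrow(signal) < 1) stop("at least one channel is required")
  if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal)) {
    stop("channel_names length must equal the channel count")
  }
  if (is.null(annotations)) {
    annotations <- data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  stopifnot(all(c("start_s", "end_s") %in% names(annotations)))
  dur <- ncol(signal) / fs
  if (nrow(annotations) > 0) {
    bad <- annotations$start_s < 0 | annotations$end_s > dur + 1e-9 |
      annotations$start_s >= annotations$end_s
    if (any(bad)) stop("annotations must satisfy 0 <= start_s < end_s <= duration")
  }
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 annotations = annotations, record_id = record_id),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record '%s'>: %d channel(s), %.2f s @ %g Hz, %d seizure annotation(s)\n",
              x$record_id, nrow(x$signal), ncol(x$signal) / x$fs, x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' Record duration in seconds
#' @param record An [eeg_record()].
#' @return Duration in seconds.
#' @export
record_duration <- function(record) ncol(record$signal) / record$fs

#' Read a single-column ASCII EEG record
#'
#' Reads the plain one-sample-per-line format used by the Bonn epilepsy
#' corpus subsets A-E (e.g. 4097 lines at 173.61 Hz, about 23.6 s).
#'
#' @param path Path to the ASCII file.
#' @param fs Sampling rate in Hz (the format does not carry one).
#' @param record_id Identifier; defaults to the file name.
#' @return A single-channel [eeg_record()] with empty annotations.
#' @export
read_ascii_record <- function(path, fs, record_id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]  # drop trailing blanks
  if (length(lines) == 0) stop(sprintf("empty record file: %s", path))
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x)) {
    bad <- which(is.na(x))[1]
    stop(sprintf("non-numeric value on line %d of %s: '%s'",
                 bad, path, lines[bad]))
  }
  eeg_record(x, fs = fs, record_id = record_id)
}

#' Read a directory of single-column ASCII records into EEG records
#'
#' Files named `<record_id>_ch<k>.txt` (the layout written by
#' [write_dataset_ascii()]) are grouped by record id into multi-channel
#' records; an `annotations.tsv` sidecar in the directory, when present,
#' populates the seizure annotations.
#'
#' @param dir Directory containing the ASCII files.
#' @param fs Sampling rate in Hz.
#' @return List of [eeg_record()] objects, ordered by record id.
#' @export
read_ascii_dataset <- function(dir, fs) {
  files <- list.files(dir, pattern = "_ch[0-9]+\\.txt$", full.names = TRUE)
  if (length(files) == 0) stop(sprintf("no '*_ch<k>.txt' record files in %s", dir))
  rid <- sub("_ch[0-9]+\\.txt$", "", basename(files))
  chan <- as.integer(sub("^.*_ch([0-9]+)\\.txt$", "\\1", basename(files)))
  ann_path <- file.path(dir, "annotations.tsv")
  ann <- if (file.exists(ann_path)) read_annotations(ann_path) else NULL
  lapply(sort(unique(rid)), function(r) {
    sel <- order(chan[rid == r])
    fset <- files[rid == r][sel]
    sig <- do.call(rbind, lapply(fset, function(f) {
      read_ascii_record(f, fs)$signal[1, ]
    }))
    ra <- if (!is.null(ann)) ann[ann$record_id == r, c("start_s", "end_s")] else NULL
    eeg_record(sig, fs = fs, record_id = r, annotations = ra)
  })
}

#' Read a seizure-interval annotation sidecar
#'
#' Tab-separated file with header columns `record_id`, `start_s`, `end_s`,
#' one seizure interval per line.
#'
#' @param path Path to the TSV sidecar.
#' @return Data frame with those three columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("record_id", "start_s", "end_s")
  if (!all(need %in% names(ann))) {
    stop("annotation sidecar must have columns record_id, start_s, end_s")
  }
  ann[need]
}

# ---------------------------------------------------------------------------
# EDF input/output. The reader supports the plain continuous EDF dialect:
# 16-bit samples, all signals at one common rate. CHB-MIT-style recordings
# fit this dialect; seizure marks are supplied separately via the TSV sidecar.

edf_pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' Write an EEG record to an EDF file
#'
#' Minimal EDF writer used both as a fixture generator for the reader's
#' tests and by the CLI. One data record per second; samples are quantized
#' to 16 bits over the per-channel physical range.
#'
#' @param record An [eeg_record()]; `fs` must be a positive integer and the
#'   duration a whole number of seconds (the signal is zero-padded to the
#'   next full second otherwise).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edf_record <- function(record, path) {
  fs <- record$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(fs)
  sig <- record$signal
  nc <- nrow(sig)
  n_rec <- ceiling(ncol(sig) / fs)
  if (ncol(sig) < n_rec * fs) {
    sig <- cbind(sig, matrix(0, nc, n_rec * fs - ncol(sig)))
  }
  pmin_ <- apply(sig, 1, min)
  pmax_ <- apply(sig, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X", 80), edf_pad(record$record_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * nc, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(nc, 4),
    paste(edf_pad(substr(record$channel_names, 1, 16), 16), collapse = ""),
    paste(rep(edf_pad("", 80), nc), collapse = ""),
    paste(rep(edf_pad("uV", 8), nc), collapse = ""),
    paste(edf_pad(formatC(pmin_, format = "g", digits = 6), 8), collapse = ""),
    paste(edf_pad(formatC(pmax_, format = "g", digits = 6), 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), nc), collapse = ""),
    paste(rep(edf_pad(dmax, 8), nc), collapse = ""),
    paste(rep(edf_pad("", 80), nc), collapse = ""),
    paste(rep(edf_pad(fs, 8), nc), collapse = ""),
    paste(rep(edf_pad("", 32), nc), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (c in seq_len(nc)) {
      dig <- round((sig[c, cols] - pmin_[c]) * scale[c]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an EEG record
#'
#' Supports continuous 16-bit EDF with every signal sampled at the same
#' rate. Annotations are not read from the file; supply them through the
#' TSV sidecar (see [read_annotations()]).
#'
#' @param path Path to the EDF file.
#' @return An [eeg_record()] with empty annotations.
#' @export
read_edf_record <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256) stop("malformed EDF header: file too short")
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  record_id <- fld(fixed, 89, 80)
  n_rec <- suppressWarnings(as.integer(fld(fixed, 237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(fixed, 245, 8)))
  nc <- suppressWarnings(as.integer(fld(fixed, 253, 4)))
  if (anyNA(c(n_rec, rec_dur, nc)) || nc < 1 || n_rec < 1 || rec_dur <= 0) {
    stop("malformed EDF header: bad record/signal counts")
  }
  sig_hdr <- readChar(con, 256 * nc, useBytes = TRUE)
  if (nchar(sig_hdr, type = "bytes") < 256 * nc) stop("malformed EDF header: truncated signal block")
  take <- function(width, offset, as = "character") {
    out <- vapply(seq_len(nc), function(i) {
      trimws(substr(sig_hdr, offset + (i - 1) * width + 1, offset + i * width))
    }, character(1))
    if (as == "numeric") suppressWarnings(as.numeric(out)) else out
  }
  labels <- take(16, 0)
  pmin_ <- take(8, nc * (16 + 80 + 8), "numeric")
  pmax_ <- take(8, nc * (16 + 80 + 8 + 8), "numeric")
  dmin <- take(8, nc * (16 + 80 + 8 + 8 + 8), "numeric")
  dmax <- take(8, nc * (16 + 80 + 8 + 8 + 8 + 8), "numeric")
  nsamp <- take(8, nc * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), "numeric")
  if (anyNA(c(pmin_, pmax_, dmin, dmax, nsamp))) {
    stop("malformed EDF header: non-numeric signal fields")
  }
  if (length(unique(nsamp)) != 1) {
    stop("unsupported EDF dialect: channels with differing sampling rates")
  }
  ns <- as.integer(nsamp[1])
  fs <- ns / rec_dur
  total <- n_rec * nc * ns
  raw <- readBin(con, integer(), n = total, size = 2, endian = "little")
  if (length(raw) < total) stop("malformed EDF file: truncated data section")
  # data records: per record, channels consecutive
  arr <- array(raw, dim = c(ns, nc, n_rec))
  sig <- matrix(0, nc, ns * n_rec)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (c in seq_len(nc)) {
    sig[c, ] <- (as.vector(arr[, c, ]) - dmin[c]) * gain[c] + pmin_[c]
  }
  eeg_record(sig, fs = fs, channel_names = labels,
             record_id = if (nzchar(record_id)) record_id else basename(path))
}

# ---------------------------------------------------------------------------
# Segmentation and labelling

#' One fixed-length EEG fragment
#' @keywords internal
new_fragment <- function(samples, start_s, record_id, index_in_record,
                         label = "unlabeled") {
  structure(list(samples = samples, start_s = start_s, label = label,
                 record_id = record_id, index_in_record = index_in_record),
            class = "eeg_fragment")
}

#' Segment an EEG record into overlapping fixed-length fragments
#'
#' Slides a window of `window_s` seconds in steps of `step_s` seconds over
#' the record (defaults 3 s / 1 s). Window and step lengths are converted to
#' samples with `floor`, so 173.61 Hz x 3 s gives a 520-sample window,
#' reproducibly. Fragments are returned unlabeled, in temporal order.
#'
#' @param record An [eeg_record()].
#' @param window_s Window length in seconds.
#' @param step_s Step between consecutive window starts, in seconds.
#' @return A `fragment_seq`: list of fragments with attributes `window_s`,
#'   `step_s`, `fs`, `record_id`. A record shorter than the window yields an
#'   empty sequence with a warning.
#' @export
segment_record <- function(record, window_s = 3, step_s = 1) {
  stopifnot(inherits(record, "eeg_record"))
  w <- floor_samples(record$fs * window_s)
  s <- floor_samples(record$fs * step_s)
  if (w < 1 || s < 1) stop("window_s and step_s must cover at least one sample")
  n <- ncol(record$signal)
  mk <- function(frags) {
    structure(frags, class = "fragment_seq", window_s = window_s,
              step_s = step_s, fs = record$fs, record_id = record$record_id)
  }
  if (n < w) {
    warning(sprintf("record '%s' (%d samples) is shorter than the window (%d samples); no fragments",
                    record$record_id, n, w))
    return(mk(list()))
  }
  n_frag <- (n - w) %/% s + 1L
  frags <- vector("list", n_frag)
  for (i in seq_len(n_frag)) {
    from <- (i - 1L) * s + 1L
    frags[[i]] <- new_fragment(
      samples = record$signal[, from:(from + w - 1L), drop = FALSE],
      start_s = (i - 1L) * step_s,
      record_id = record$record_id,
      index_in_record = i
    )
  }
  mk(frags)
}

merge_intervals <- function(ann) {
  if (nrow(ann) <= 1) return(ann)
  ann <- ann[order(ann$start_s), , drop = FALSE]
  out <- ann[1, , drop = FALSE]
  for (i in 2:nrow(ann)) {
    j <- nrow(out)
    if (ann$start_s[i] <= out$end_s[j]) {
      out$end_s[j] <- max(out$end_s[j], ann$end_s[i])
    } else {
      out <- rbind(out, ann[i, , drop = FALSE])
    }
  }
  out
}

#' Label fragments as ictal or non-ictal from seizure intervals
#'
#' A fragment covering `[start_s, start_s + window_s)` is labelled `ictal`
#' when its overlap with any (merged) seizure interval exceeds
#' `min_overlap_fraction` of the window (default 0: any positive overlap),
#' else `non_ictal`. Labelling is invariant to the order of intervals and to
#' splitting an interval into touching pieces, because intervals are merged
#' first.
#'
#' @param seq A `fragment_seq` from [segment_record()].
#' @param annotations Data frame with `start_s`, `end_s` columns (seconds
#'   from record start); rows outside the record cause an error.
#' @param record_duration_s Duration of the source record in seconds, used
#'   to validate the annotations. `NULL` skips the upper-bound check.
#' @param min_overlap_fraction Minimum ictal overlap, as a fraction of the
#'   window, required to label a fragment ictal.
#' @return The sequence with every fragment labelled.
#' @export
label_fragments <- function(seq, annotations, record_duration_s = NULL,
                            min_overlap_fraction = 0) {
  stopifnot(inherits(seq, "fragment_seq"))
  stopifnot(all(c("start_s", "end_s") %in% names(annotations)))
  if (nrow(annotations) > 0) {
    if (any(annotations$start_s >= annotations$end_s) ||
        any(annotations$start_s < 0)) {
      stop("annotation intervals must satisfy 0 <= start_s < end_s")
    }
    if (!is.null(record_duration_s) &&
        any(annotations$end_s > record_duration_s + 1e-9)) {
      stop("annotation interval extends beyond the record duration")
    }
    annotations <- merge_intervals(annotations)
  }
  window_s <- attr(seq, "window_s")
  out <- lapply(seq, function(f) {
    a <- f$start_s
    b <- f$start_s + window_s
    ov <- 0
    if (nrow(annotations) > 0) {
      ov <- max(pmin(b, annotations$end_s) - pmax(a, annotations$start_s), 0)
    }
    f$label <- if (ov > min_overlap_fraction * window_s && ov > 0) "ictal" else "non_ictal"
    f
  })
  attributes(out) <- attributes(seq)
  out
}

#' Labels of a fragment collection
#' @param fragments List of fragments.
#' @return Character vector of labels.
#' @export
fragment_labels <- function(fragments) {
  vapply(fragments, function(f) f$label, character(1))
}

#' Balance classes and split into train/test folds
#'
#' Emulates the study protocol for scarce ictal events: the majority class
#' is randomly down-sampled to the minority count (optionally capped at
#' `n_per_class` per class), then the balanced set is split 4:1 (by default)
#' into train and test folds, stratified by class so both folds stay
#' balanced. All randomness is governed by `seed`.
#'
#' @param fragments List of labelled fragments (labels `ictal`/`non_ictal`).
#' @param ratio Train share of the balanced data (default 0.8, i.e. 4:1).
#' @param seed Integer seed.
#' @param n_per_class Optional cap on retained fragments per class; `NULL`
#'   keeps the full minority count.
#' @return A `split_dataset`: list with `train`, `test` (fragment lists) and
#'   `seed`.
#' @export
balance_and_split <- function(fragments, ratio = 0.8, seed = 1,
                              n_per_class = NULL) {
  labs <- fragment_labels(fragments)
  if (any(labs == "unlabeled")) stop("fragments must be labelled before splitting")
  idx_pos <- which(labs == "ictal")
  idx_neg <- which(labs == "non_ictal")
  if (length(idx_pos) == 0) stop("no fragments of class 'ictal'")
  if (length(idx_neg) == 0) stop("no fragments of class 'non_ictal'")
  n_keep <- min(length(idx_pos), length(idx_neg))
  if (!is.null(n_per_class)) n_keep <- min(n_keep, n_per_class)
  with_seed(seed, {
    pos <- if (length(idx_pos) > n_keep) sample(idx_pos, n_keep) else idx_pos
    neg <- if (length(idx_neg) > n_keep) sample(idx_neg, n_keep) else idx_neg
    n_train <- round(ratio * n_keep)
    tr_pos <- sample(pos, n_train)
    tr_neg <- sample(neg, n_train)
    train_idx <- c(tr_pos, tr_neg)
    test_idx <- c(setdiff(pos, tr_pos), setdiff(neg, tr_neg))
    structure(list(train = fragments[train_idx],
                   test = fragments[test_idx],
                   seed = as.integer(seed)),
              class = "split_dataset")
  })
}

#' @export
print.split_dataset <- function(x, ...) {
  lt <- table(fragment_labels(x$train))
  le <- table(fragment_labels(x$test))
  cat(sprintf("<split_dataset> train: %d (%s), test: %d (%s), seed %d\n",
              length(x$train), paste(names(lt), lt, sep = "=", collapse = ", "),
              length(x$test), paste(names(le), le, sep = "=", collapse = ", "),
              x$seed))
  invisible(x)
}
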