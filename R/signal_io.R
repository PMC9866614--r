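#' Labelled skin-conductance signal
#'
#' Container for one subject's electrodermal activity (EDA) recording:
#' conductance samples in microsiemens at a fixed sampling rate, with one
#' affective-state label per sample.
#'
#' @param samples Numeric vector of conductance values, microsiemens.
#' @param labels Character vector of state codes, one per sample, each one
#'   of [eda_states()].
#' @param subject_id Opaque subject identifier.
#' @param fs Sampling rate in Hz (WESAD wrist EDA: 4).
#'
#' @return An object of class `labeled_signal`: a list with elements
#'   `subject_id`, `fs`, `samples`, `labels`.
#' @examples
#' sig <- labeled_signal(rnorm(96, 5), rep(c("baseline", "stress"), each = 48))
#' print(sig)
#' @export
labeled_signal <- function(samples, labels, subject_id = "S1", fs = 4) {
  samples <- as.numeric(samples)
  labels <- as.character(labels)
  if (length(samples) != length(labels)) {
    stop("length(samples) must equal length(labels)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite real numbers")
  }
  bad <- setdiff(unique(labels), eda_states())
  if (length(bad)) {
    stop("unknown state code(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(subject_id = as.character(subject_id), fs = fs,
         samples = samples, labels = labels),
    class = "labeled_signal"
  )
}

#' @export
print.labeled_signal <- function(x, ...) {
  cat(sprintf("<labeled_signal> subject %s: %d samples at %g Hz (%.1f s)\n",
              x$subject_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  tab <- table(factor(x$labels, levels = eda_states()))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
length.labeled_signal <- function(x) length(x$samples)

#' Downsample a high-rate label stream to the EDA rate
#'
#' WESAD labels are recorded at 700 Hz while the wrist EDA runs at 4 Hz, an
#' integer ratio of 175 label samples per EDA sample. Each block of `ratio`
#' consecutive labels is reduced to a single code: the block's label when it
#' is uniform, otherwise `"other"` — so a mixed block (a state transition
#' inside one EDA sample) can never produce a pure-looking label and is
#' excluded downstream.
#'
#' @param labels_hi Character vector of high-rate state codes.
#' @param ratio Integer number of high-rate samples per output sample.
#'
#' @return Character vector of length `floor(length(labels_hi) / ratio)`.
#' @examples
#' resample_labels(rep("stress", 350), 175)        # "stress" "stress"
#' resample_labels(c(rep("baseline", 275), rep("stress", 75)), 175)
#' @export
resample_labels <- function(labels_hi, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 1 ||
      ratio != round(ratio)) {
    stop("ratio must be a single integer >= 1")
  }
  ratio <- as.integer(ratio)
  labels_hi <- as.character(labels_hi)
  n_out <- length(labels_hi) %/% ratio
  if (n_out == 0L) return(character(0))
  m <- matrix(labels_hi[seq_len(n_out * ratio)], nrow = ratio)
  uniform <- colSums(m != m[rep(1L, ratio), , drop = FALSE]) == 0L
  out <- rep("other", n_out)
  out[uniform] <- m[1L, uniform]
  out
}

#' Map raw WESAD label codes to state names
#'
#' Codes 1/2/3 are the protocol's baseline/stress/amusement conditions;
#' everything else (0 transient, 4 meditation, 5-7 auxiliary) maps to
#' `"other"` and is excluded from all experiments.
#'
#' @param codes Integer vector of raw label codes.
#' @return Character vector of state names.
#' @export
map_wesad_codes <- function(codes) {
  out <- rep("other", length(codes))
  out[codes == 1] <- "baseline"
  out[codes == 2] <- "stress"
  out[codes == 3] <- "amusement"
  out
}

#' Read one WESAD per-subject record
#'
#' Adapter for the WESAD dataset's serialized per-subject files (Python
#' pickle as distributed by the dataset authors). Extracts the wrist EDA
#' channel (4 Hz) and the label channel (700 Hz), deserializing through the
#' `python` interpreter on `PATH`, then aligns labels to the EDA rate with
#' [resample_labels()] and maps raw codes via [map_wesad_codes()].
#'
#' The adapter is optional plumbing: every other function in the package
#' consumes [labeled_signal()] objects and never touches this reader.
#'
#' @param path Path to the subject record (e.g. `S2.pkl`).
#' @param fs_eda Wrist EDA sampling rate, Hz.
#' @param fs_label Label channel sampling rate, Hz.
#' @param python Python interpreter used for deserialization.
#'
#' @return A [labeled_signal()] at `fs_eda` Hz.
#' @export
read_wesad_subject <- function(path, fs_eda = 4, fs_label = 700,
                               python = Sys.which("python")) {
  if (!file.exists(path)) {
    stop_edafreq("io", sprintf("cannot read WESAD record: '%s'", path))
  }
  if (!nzchar(python)) {
    stop_edafreq("io", "no python interpreter found for pickle deserialization")
  }
  ratio <- fs_label / fs_eda
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("fs_label must be an integer multiple of fs_eda")
  }
  eda_file <- tempfile(fileext = ".txt")
  lab_file <- tempfile(fileext = ".txt")
  on.exit(unlink(c(eda_file, lab_file)), add = TRUE)
  script <- paste(
    "import pickle, sys",
    "path, eda_out, lab_out = sys.argv[1:4]",
    "with open(path, 'rb') as fh:",
    "    rec = pickle.load(fh, encoding='latin1')",
    "try:",
    "    eda = rec['signal']['wrist']['EDA']",
    "except (KeyError, TypeError):",
    "    sys.stderr.write('MISSING_CHANNEL signal/wrist/EDA')",
    "    sys.exit(3)",
    "try:",
    "    lab = rec['label']",
    "except (KeyError, TypeError):",
    "    sys.stderr.write('MISSING_CHANNEL label')",
    "    sys.exit(3)",
    "subject = rec.get('subject', '')",
    "with open(eda_out, 'w') as fh:",
    "    fh.write(str(subject) + '\\n')",
    "    for v in list(eda):",
    "        try:",
    "            fh.write(repr(float(v[0] if hasattr(v, '__len__') else v)) + '\\n')",
    "        except (TypeError, ValueError):",
    "            sys.stderr.write('MALFORMED signal/wrist/EDA')",
    "            sys.exit(4)",
    "with open(lab_out, 'w') as fh:",
    "    for v in list(lab):",
    "        fh.write(str(int(v)) + '\\n')",
    sep = "\n"
  )
  res <- suppressWarnings(system2(python, c("-c", shQuote(script),
                                            shQuote(path), shQuote(eda_file),
                                            shQuote(lab_file)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    msg <- paste(res, collapse = " ")
    if (grepl("MISSING_CHANNEL", msg)) {
      channel <- sub(".*MISSING_CHANNEL\\s+(\\S+).*", "\\1", msg)
      stop_edafreq("malformed_record",
                   sprintf("malformed WESAD record '%s': missing channel '%s'",
                           path, channel),
                   channel = channel)
    }
    stop_edafreq("io", sprintf("failed to deserialize '%s': %s", path, msg))
  }
  eda_lines <- readLines(eda_file)
  subject_id <- eda_lines[1L]
  if (!nzchar(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  samples <- as.numeric(eda_lines[-1L])
  codes <- as.integer(readLines(lab_file))
  labels <- resample_labels(map_wesad_codes(codes), as.integer(round(ratio)))
  n <- min(length(samples), length(labels))
  labeled_signal(samples[seq_len(n)], labels[seq_len(n)],
                 subject_id = subject_id, fs = fs_eda)
}

#' Read/write a labelled EDA signal as CSV
#'
#' Plain-text interchange format: columns `t_seconds`, `eda_uS`, `label`.
#'
#' @param signal A [labeled_signal()].
#' @param path File path.
#' @param subject_id Subject identifier to attach on read (default: file
#'   base name).
#' @param fs Sampling rate to attach on read, Hz.
#' @return `write_signal_csv` returns `path` invisibly; `read_signal_csv`
#'   returns a [labeled_signal()].
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "labeled_signal"))
  df <- data.frame(
    t_seconds = format((seq_along(signal$samples) - 1L) / signal$fs,
                       digits = 10, trim = TRUE, scientific = FALSE),
    eda_uS = format(signal$samples, digits = 17, trim = TRUE),
    label = signal$labels
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path, subject_id = NULL, fs = NULL) {
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric",
                                             "character"))
  if (is.null(fs)) {
    fs <- if (nrow(df) >= 2) 1 / (df$t_seconds[2] - df$t_seconds[1]) else 4
    fs <- round(fs, 6)
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  labeled_signal(df$eda_uS, df$label, subject_id = subject_id, fs = fs)
}

.meta_cols <- c("subject_id", "label", "segment_start")

#' Write/read a feature table as CSV
#'
#' Feature tables carry three metadata columns (`subject_id`, `label`,
#' `segment_start`) followed by one column per feature. Values round-trip
#' losslessly (full double precision is written).
#'
#' @param table Data frame of feature rows, or a list of identically named
#'   row records.
#' @param path File path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a data frame.
#' @export
write_feature_table <- function(table, path) {
  if (is.list(table) && !is.data.frame(table)) {
    if (length(table)) {
      nm <- names(table[[1L]])
      same <- vapply(table, function(r) identical(names(r), nm), logical(1))
      if (!all(same)) {
        stop_edafreq("schema",
                     "inconsistent feature names across feature records")
      }
    }
    table <- do.call(rbind, lapply(table, function(r) as.data.frame(r)))
  }
  missing_meta <- setdiff(.meta_cols, names(table))
  if (!is.null(table) && nrow(table) > 0 && length(missing_meta)) {
    stop_edafreq("schema", paste("feature table lacks metadata column(s):",
                                 paste(missing_meta, collapse = ", ")))
  }
  out <- table
  if (!is.null(out)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) {
      format(x, digits = 17, trim = TRUE)
    })
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character",
                                       label = "character"))
  for (col in setdiff(names(df), c("subject_id", "label"))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
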