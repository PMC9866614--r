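# Independent brute-force oracles, kept deliberately naive so they never
# share code with the implementation paths they check.

# Direct O(N^2) one-sided DFT magnitude sum.
brute_dft_onesided <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(0:(n %/% 2), function(b) {
    Mod(sum(x * exp(-1i * 2 * pi * b * k / n)))
  }, numeric(1))
}

# Loop-based block reduction of a high-rate label stream.
brute_resample_labels <- function(labels_hi, ratio) {
  n_out <- length(labels_hi) %/% ratio
  out <- character(n_out)
  for (t in seq_len(n_out)) {
    block <- labels_hi[((t - 1) * ratio + 1):(t * ratio)]
    out[t] <- if (length(unique(block)) == 1L) block[1L] else "other"
  }
  out
}

# Exhaustive window scan: 0-based starts of pure, non-"other" windows.
brute_pure_starts <- function(labels, t_length, t_step) {
  n <- length(labels)
  if (n < t_length) return(integer(0))
  starts <- seq.int(0L, n - t_length, by = t_step)
  ok <- vapply(starts, function(s) {
    win <- labels[(s + 1):(s + t_length)]
    length(unique(win)) == 1L && win[1L] != "other"
  }, logical(1))
  starts[ok]
}

# Re-slicing oracles for the sequence statistics.
brute_windowed_mean <- function(values, w) {
  vapply(w:length(values), function(k) mean(values[(k - w + 1):k]),
         numeric(1))
}
brute_windowed_variance <- function(values, w) {
  vapply(w:length(values), function(k) {
    win <- values[(k - w + 1):k]
    sum((win - mean(win))^2) / w
  }, numeric(1))
}

# Random label layout with geometric-ish run lengths, for segmentation
# property tests.
random_label_layout <- function(n, seed) {
  set.seed(seed)
  labs <- character(0)
  while (length(labs) < n) {
    labs <- c(labs, rep(sample(eda_states(), 1),
                        sample(c(5:30, 60, 120), 1)))
  }
  labs[seq_len(n)]
}

# A segment object for direct feature-level tests.
make_segment <- function(values, label = "baseline", fs = 4,
                         subject_id = "T1", start = 0L) {
  sig <- labeled_signal(values, rep(label, length(values)),
                        subject_id = subject_id, fs = fs)
  segment_signal(sig, segmentation_config(length(values),
                                          length(values) - 1L))[[1L]]
}

# Unit cosine sampled at an exact bin frequency.
cosine_segment <- function(f_hz = 1.0, n = 48L, fs = 4) {
  make_segment(cos(2 * pi * f_hz * (0:(n - 1)) / fs), fs = fs)
}

# Tiny per-segment feature table for sequence-assembly tests.
toy_feature_table <- function(n_rows, label = "stress", subject = "S1",
                              n_feats = 7L, seed = 42) {
  set.seed(seed)
  df <- data.frame(subject_id = subject, label = label,
                   segment_start = seq_len(n_rows) * 28L - 28L)
  for (i in seq_len(n_feats)) {
    df[[paste0("f", i)]] <- rnorm(n_rows)
  }
  df
}

# WESAD-style pickle fixture, written by the python interpreter (the
# fixture writer is the oracle for the reader round-trip).
write_wesad_pickle <- function(path, eda, codes, subject = "SX") {
  eda_txt <- tempfile(fileext = ".txt")
  lab_txt <- tempfile(fileext = ".txt")
  writeLines(format(eda, digits = 17, trim = TRUE), eda_txt)
  writeLines(as.character(as.integer(codes)), lab_txt)
  script <- paste(
    "import pickle, sys",
    "eda = [float(l) for l in open(sys.argv[1])]",
    "lab = [int(l) for l in open(sys.argv[2])]",
    "rec = {'subject': sys.argv[4],",
    "       'signal': {'wrist': {'EDA': [[v] for v in eda]},",
    "                  'chest': {}},",
    "       'label': lab}",
    "with open(sys.argv[3], 'wb') as fh:",
    "    pickle.dump(rec, fh)",
    sep = "\n")
  status <- system2(Sys.which("python"),
                    c("-c", shQuote(script), shQuote(eda_txt),
                      shQuote(lab_txt), shQuote(path), shQuote(subject)))
  unlink(c(eda_txt, lab_txt))
  stopifnot(status == 0)
  invisible(path)
}

# As above but with a channel removed, to exercise the structured error.
write_wesad_pickle_missing_eda <- function(path) {
  script <- paste(
    "import pickle, sys",
    "rec = {'subject': 'SX', 'signal': {'wrist': {}}, 'label': [1, 1]}",
    "with open(sys.argv[1], 'wb') as fh:",
    "    pickle.dump(rec, fh)",
    sep = "\n")
  status <- system2(Sys.which("python"), c("-c", shQuote(script),
                                           shQuote(path)))
  stopifnot(status == 0)
  invisible(path)
}
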