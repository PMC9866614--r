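#' Per-segment feature table for one or more signals
#'
#' Runs segmentation, preprocessing and frequency-domain feature
#' extraction over a signal or a cohort, returning one row per emitted
#' segment. Zero-energy segments (possible only for degenerate, constant
#' windows) are dropped with a warning rather than producing NaN features.
#'
#' @param signals A [labeled_signal()] or a list of them.
#' @param config A [segmentation_config()].
#' @param bands List of [frequency_band()] objects.
#' @param preprocess Per-segment preprocessing mode, see
#'   [preprocess_segment()].
#' @param normalize,include_dc Passed to [extract_segment_features()].
#' @return Data frame: `subject_id`, `label`, `segment_start`, then the
#'   `3m + 1` base features.
#' @export
segment_feature_table <- function(signals, config = segmentation_config(),
                                  bands = default_bands(),
                                  preprocess = c("mean-removal", "none"),
                                  normalize = c("none", "energy"),
                                  include_dc = FALSE) {
  preprocess <- match.arg(preprocess)
  normalize <- match.arg(normalize)
  if (inherits(signals, "labeled_signal")) signals <- list(signals)
  fnames <- feature_names(bands)
  rows <- list()
  n_dropped <- 0L
  for (sig in signals) {
    for (seg in segment_signal(sig, config)) {
      seg <- preprocess_segment(seg, preprocess)
      feats <- tryCatch(
        extract_segment_features(seg, bands, normalize, include_dc),
        edafreq_zero_energy = function(e) NULL
      )
      if (is.null(feats)) {
        n_dropped <- n_dropped + 1L
        next
      }
      row <- data.frame(subject_id = seg$subject_id, label = seg$label,
                        segment_start = seg$start)
      row[fnames] <- as.list(feats)
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d zero-energy segment(s)", n_dropped))
  }
  if (!length(rows)) {
    empty <- data.frame(subject_id = character(0), label = character(0),
                        segment_start = integer(0))
    empty[fnames] <- replicate(length(fnames), numeric(0), simplify = FALSE)
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full feature pipeline: segments to sequence features
#'
#' Convenience wrapper chaining [segment_feature_table()] and
#' [assemble_sequence_features()]: the table a classifier consumes, with
#' `3 (3m + 1)` feature columns (21 for the default two bands).
#'
#' @inheritParams segment_feature_table
#' @param w Sequence window size in segments.
#' @return Data frame of sequence feature rows.
#' @examples
#' cohort <- simulate_cohort(generator_params(n_subjects = 2, seed = 1))
#' feats <- build_feature_table(cohort, w = 7)
#' dim(feats)
#' @export
build_feature_table <- function(signals, config = segmentation_config(),
                                bands = default_bands(), w = 7L,
                                preprocess = c("mean-removal", "none"),
                                normalize = c("none", "energy"),
                                include_dc = FALSE) {
  base <- segment_feature_table(signals, config, bands,
                                match.arg(preprocess), match.arg(normalize),
                                include_dc)
  assemble_sequence_features(base, w)
}
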