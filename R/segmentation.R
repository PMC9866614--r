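#' Sliding-window segmentation configuration
#'
#' Window geometry in samples, as used throughout: window length
#' `t_length`, overlap `t_overlap`, derived step
#' `t_step = t_length - t_overlap`. The defaults (48-sample window,
#' 20-sample overlap; 12 s and 5 s at 4 Hz) are the headline configuration.
#'
#' @param t_length Window length, samples.
#' @param t_overlap Overlap between consecutive windows, samples. Must
#'   satisfy `0 <= t_overlap < t_length`.
#'
#' @return An object of class `segmentation_config` with elements
#'   `t_length`, `t_overlap`, `t_step`.
#' @export
segmentation_config <- function(t_length = 48L, t_overlap = 20L) {
  t_length <- as.integer(t_length)
  t_overlap <- as.integer(t_overlap)
  if (is.na(t_length) || t_length < 1L) stop("t_length must be >= 1 sample")
  if (is.na(t_overlap) || t_overlap < 0L || t_overlap >= t_length) {
    stop("t_overlap must satisfy 0 <= t_overlap < t_length")
  }
  structure(
    list(t_length = t_length, t_overlap = t_overlap,
         t_step = t_length - t_overlap),
    class = "segmentation_config"
  )
}

#' @export
print.segmentation_config <- function(x, ...) {
  cat(sprintf(
    "<segmentation_config> length %d, overlap %d, step %d samples\n",
    x$t_length, x$t_overlap, x$t_step))
  invisible(x)
}

#' Cut a labelled signal into single-state segments
#'
#' Slides a window of `t_length` samples over the signal in steps of
#' `t_step`, starting at sample 0. A window is emitted only when all of its
#' labels are identical and none is `"other"` — every segment belongs to
#' exactly one affective state; windows spanning a state transition are
#' rejected, never emitted. A signal shorter than the window yields an
#' empty list.
#'
#' @param signal A [labeled_signal()].
#' @param config A [segmentation_config()].
#'
#' @return List of `eda_segment` objects in temporal order. Each segment
#'   holds `subject_id`, `label`, `start` (0-based sample index into the
#'   source), `values` (`t_length` samples), `fs`.
#' @examples
#' sig <- labeled_signal(rnorm(200, 5),
#'                       rep(c("baseline", "stress"), each = 100))
#' length(segment_signal(sig, segmentation_config(48, 20)))
#' @export
segment_signal <- function(signal, config = segmentation_config()) {
  stopifnot(inherits(signal, "labeled_signal"),
            inherits(config, "segmentation_config"))
  n <- length(signal$samples)
  if (n < config$t_length) return(list())
  starts <- seq.int(0L, n - config$t_length, by = config$t_step)
  segs <- vector("list", length(starts))
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):(starts[i] + config$t_length)
    lab <- signal$labels[idx]
    if (lab[1L] != "other" && all(lab == lab[1L])) {
      keep[i] <- TRUE
      segs[[i]] <- structure(
        list(subject_id = signal$subject_id, label = lab[1L],
             start = starts[i], values = signal$samples[idx],
             fs = signal$fs),
        class = "eda_segment"
      )
    }
  }
  segs[keep]
}

#' @export
print.eda_segment <- function(x, ...) {
  cat(sprintf("<eda_segment> %s/%s: %d samples from index %d at %g Hz\n",
              x$subject_id, x$label, length(x$values), x$start, x$fs))
  invisible(x)
}

#' Per-segment preprocessing
#'
#' `"mean-removal"` (the default elsewhere in the pipeline) subtracts the
#' segment's own sample mean, zeroing the DC bin of its spectrum: raw skin
#' conductance sits on a large positive tonic offset that would otherwise
#' dominate every energy-based feature. `"none"` returns the segment
#' unchanged.
#'
#' @param seg An `eda_segment`.
#' @param mode `"mean-removal"` or `"none"`.
#' @return An `eda_segment`.
#' @export
preprocess_segment <- function(seg, mode = c("mean-removal", "none")) {
  stopifnot(inherits(seg, "eda_segment"))
  mode <- match.arg(mode)
  if (mode == "mean-removal") {
    seg$values <- seg$values - mean(seg$values)
  }
  seg
}
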