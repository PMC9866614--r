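#' Sliding-window mean and variance of a feature series
#'
#' `windowed_mean` returns, for every position `k = w .. n`, the mean of
#' the `w` most recent values; `windowed_variance` the population variance
#' (divisor `w`) over the same window. Output length is `n - w + 1`; the
#' first `w - 1` positions produce no output.
#'
#' @param values Ordered numeric vector (one feature over consecutive
#'   segments).
#' @param w Window size in segments, `>= 1`; `length(values)` must be at
#'   least `w`.
#' @return Numeric vector of length `length(values) - w + 1`.
#' @examples
#' windowed_mean(1:7, 7)      # 4
#' windowed_variance(1:7, 7)  # 28 / 7 = 4
#' @export
windowed_mean <- function(values, w) {
  .check_window(values, w)
  if (w == 1L) return(as.numeric(values))
  rowMeans(.windows(values, w))
}

#' @rdname windowed_mean
#' @export
windowed_variance <- function(values, w) {
  .check_window(values, w)
  if (w == 1L) return(numeric(length(values)))
  m <- .windows(values, w)
  mu <- rowMeans(m)
  rowMeans((m - mu)^2)
}

.check_window <- function(values, w) {
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w != round(w)) {
    stop("w must be a single integer >= 1")
  }
  if (length(values) < w) {
    stop("need at least w values to form one window")
  }
}

# row t = values[t .. t+w-1]; stats::embed reverses columns, which the
# mean/variance do not care about
.windows <- function(values, w) {
  stats::embed(as.numeric(values), w)
}

#' Sequence features over runs of consecutive segments
#'
#' Augments a per-segment feature table with the windowed mean and
#' variance of every base feature over `w` consecutive segments. Windows
#' are formed only within runs of segments that share one subject and one
#' label — no window ever crosses a subject or class boundary, since a
#' mixed window would have no defined class. The first `w - 1` segments of
#' each run produce no row (no padding); runs shorter than `w` contribute
#' nothing. Each output row keeps the current segment's metadata
#' (`segment_start` is the last segment in the window) and carries, per
#' base feature `a`: the current value `a`, the windowed mean `mw_a` and
#' the windowed variance `vw_a` — tripling the feature count to
#' `3 (3m + 1)` for `m` bands.
#'
#' @param table Data frame of per-segment features in temporal order,
#'   grouped by subject: columns `subject_id`, `label`, `segment_start`,
#'   then one column per base feature.
#' @param w Window size in segments (default 7, the headline
#'   configuration).
#' @return Data frame with the same metadata columns and `3x` the feature
#'   columns.
#' @export
assemble_sequence_features <- function(table, w = 7L) {
  stopifnot(is.data.frame(table))
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w != round(w)) {
    stop("w must be a single integer >= 1")
  }
  w <- as.integer(w)
  feat_cols <- setdiff(names(table), .meta_cols)
  out_cols <- as.vector(rbind(feat_cols, paste0("mw_", feat_cols),
                              paste0("vw_", feat_cols)))
  pieces <- list()
  for (sid in unique(table$subject_id)) {
    sub <- table[table$subject_id == sid, , drop = FALSE]
    runs <- rle(sub$label)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in seq_along(runs$lengths)) {
      if (runs$lengths[r] < w) next
      run <- sub[starts[r]:ends[r], , drop = FALSE]
      keep <- seq.int(w, nrow(run))
      block <- run[keep, .meta_cols, drop = FALSE]
      for (col in feat_cols) {
        block[[col]] <- run[[col]][keep]
        block[[paste0("mw_", col)]] <- windowed_mean(run[[col]], w)
        block[[paste0("vw_", col)]] <- windowed_variance(run[[col]], w)
      }
      pieces[[length(pieces) + 1L]] <- block
    }
  }
  if (!length(pieces)) {
    empty <- table[integer(0), .meta_cols, drop = FALSE]
    for (col in out_cols) empty[[col]] <- numeric(0)
    return(empty)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c(.meta_cols, out_cols)]
}
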