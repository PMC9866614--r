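#' One-sided amplitude spectrum of a segment
#'
#' Unnormalized forward DFT, `X(b) = sum_k x(k) exp(-i 2 pi b k / N)`,
#' retaining the one-sided bins `b = 0 .. N/2`. Bin `b` corresponds to
#' frequency `b * fs / N`; the frequency resolution is `fs / N = 1/(ts N)`.
#'
#' @param x An `eda_segment` or a numeric vector.
#' @param fs Sampling rate in Hz (ignored when `x` is a segment).
#'
#' @return An object of class `amplitude_spectrum`: list with `magnitudes`
#'   (length `floor(N/2) + 1`), `frequencies`, `resolution` (Hz), `fs`, `n`.
#' @examples
#' ts <- 0.25
#' x <- cos(2 * pi * 1.0 * (0:47) * ts)
#' sp <- amplitude_spectrum(x, fs = 4)
#' sp$magnitudes[13]  # bin at 1.0 Hz: N/2 = 24
#' @export
amplitude_spectrum <- function(x, fs = NULL) {
  if (inherits(x, "eda_segment")) {
    fs <- x$fs
    x <- x$values
  }
  if (is.null(fs)) stop("fs must be supplied for a bare numeric vector")
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("segment must contain at least 2 samples")
  mags <- Mod(stats::fft(x))[seq_len(n %/% 2L + 1L)]
  resolution <- fs / n
  structure(
    list(magnitudes = mags,
         frequencies = (seq_len(n %/% 2L + 1L) - 1L) * resolution,
         resolution = resolution, fs = fs, n = n),
    class = "amplitude_spectrum"
  )
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf(
    "<amplitude_spectrum> %d one-sided bins, resolution %.4g Hz (N=%d, fs=%g)\n",
    length(x$magnitudes), x$resolution, x$n, x$fs))
  invisible(x)
}

#' Normalize an amplitude spectrum to unit energy
#'
#' `mode = "energy"` divides all magnitudes by `sqrt(sum(|X|^2))` so the
#' total one-sided spectral energy is 1; an all-zero spectrum is returned
#' unchanged with a warning. `mode = "none"` is the identity. The band
#' features are scale-covariant, so normalization is optional and off by
#' default in [extract_segment_features()].
#'
#' @param spec An [amplitude_spectrum()].
#' @param mode `"energy"` or `"none"`.
#' @return An [amplitude_spectrum()].
#' @export
normalize_spectrum <- function(spec, mode = c("energy", "none")) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  mode <- match.arg(mode)
  if (mode == "none") return(spec)
  energy <- sum(spec$magnitudes^2)
  if (energy == 0) {
    warning("all-zero spectrum: energy normalization skipped")
    return(spec)
  }
  spec$magnitudes <- spec$magnitudes / sqrt(energy)
  spec
}

#' Frequency band
#'
#' A contiguous interval of the spectrum over which band features are
#' computed. With the default half-open edge rule a bin at frequency `f`
#' is in-band when `f_low <= f < f_high`, so adjacent bands partition the
#' axis and a shared edge bin (e.g. 1.0 Hz for the default 0-1 / 1-2 Hz
#' pair) belongs to exactly one band. The `"closed"` rule keeps both
#' edges in-band.
#'
#' @param f_low,f_high Band edges, Hz; `0 <= f_low < f_high`.
#' @param edge_rule `"half-open"` or `"closed"`.
#' @return An object of class `frequency_band`.
#' @export
frequency_band <- function(f_low, f_high,
                           edge_rule = c("half-open", "closed")) {
  edge_rule <- match.arg(edge_rule)
  if (!is.finite(f_low) || !is.finite(f_high) || f_low < 0 ||
      f_low >= f_high) {
    stop("band edges must satisfy 0 <= f_low < f_high")
  }
  structure(list(f_low = f_low, f_high = f_high, edge_rule = edge_rule),
            class = "frequency_band")
}

#' Default analysis bands for 4 Hz wrist EDA
#'
#' Two bands splitting the usable spectrum: 0.0-1.0 Hz (low frequencies,
#' where skin-conductance responses concentrate their energy) and
#' 1.0-2.0 Hz (up to the Nyquist frequency).
#'
#' @param edge_rule Passed to [frequency_band()].
#' @return List of two [frequency_band()] objects.
#' @export
default_bands <- function(edge_rule = "half-open") {
  list(frequency_band(0, 1, edge_rule), frequency_band(1, 2, edge_rule))
}

#' Bin indices of a frequency band
#'
#' @param spec An [amplitude_spectrum()].
#' @param band A [frequency_band()] within `[0, fs/2]`.
#' @return Integer vector of 1-based positions into `spec$magnitudes`; its
#'   length is the in-band bin count `N_b`.
#' @export
band_bins <- function(spec, band) {
  stopifnot(inherits(spec, "amplitude_spectrum"),
            inherits(band, "frequency_band"))
  if (band$f_high > spec$fs / 2 + 1e-9) {
    stop("band exceeds the Nyquist frequency fs/2")
  }
  f <- spec$frequencies
  eps <- 1e-9 * spec$resolution
  idx <- if (band$edge_rule == "half-open") {
    which(f >= band$f_low - eps & f < band$f_high - eps)
  } else {
    which(f >= band$f_low - eps & f <= band$f_high + eps)
  }
  if (!length(idx)) {
    stop_edafreq("empty_band",
                 sprintf("band [%g, %g] Hz contains no spectral bin",
                         band$f_low, band$f_high))
  }
  idx
}

#' Band features: mean, standard deviation, maximum
#'
#' Summaries of the in-band amplitude magnitudes: `band_mean` is the
#' arithmetic mean over the `N_b` in-band bins, `band_std` the sample
#' standard deviation (divisor `N_b - 1`), `band_max` the largest
#' magnitude.
#'
#' @param spec An [amplitude_spectrum()].
#' @param band A [frequency_band()].
#' @return A single numeric value.
#' @export
band_mean <- function(spec, band) {
  mean(spec$magnitudes[band_bins(spec, band)])
}

#' @rdname band_mean
#' @export
band_std <- function(spec, band) {
  m <- spec$magnitudes[band_bins(spec, band)]
  if (length(m) < 2L) {
    stop_edafreq("empty_band",
                 "band standard deviation requires at least 2 bins")
  }
  stats::sd(m)
}

#' @rdname band_mean
#' @export
band_max <- function(spec, band) {
  max(spec$magnitudes[band_bins(spec, band)])
}

#' Spectral energy profile
#'
#' Per-bin energy density `psi(f) = |X(f)|^2` and its normalized cumulative
#' sum `psi_cum(f)`, a non-decreasing curve rising to 1. By default the DC
#' bin is excluded so that the tonic offset of an unprocessed segment does
#' not swamp the profile; with per-segment mean removal the choice is
#' immaterial.
#'
#' @param spec An [amplitude_spectrum()].
#' @param include_dc Keep bin 0 in both sums?
#' @return Object of class `energy_profile`: `psi`, `psi_cum`,
#'   `frequencies` (one per retained bin), `include_dc`.
#' @export
energy_profile <- function(spec, include_dc = FALSE) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  keep <- if (include_dc) seq_along(spec$magnitudes) else
    seq_along(spec$magnitudes)[-1L]
  psi <- spec$magnitudes[keep]^2
  total <- sum(psi)
  if (total == 0) {
    stop_edafreq("zero_energy",
                 "segment has zero spectral energy; no energy profile")
  }
  structure(
    list(psi = psi, psi_cum = cumsum(psi) / total,
         frequencies = spec$frequencies[keep], include_dc = include_dc),
    class = "energy_profile"
  )
}

#' Half-energy frequency
#'
#' The smallest bin frequency at which the normalized cumulative energy
#' reaches one half: the frequency below which half the segment's spectral
#' energy lies. Computed on the discrete bin grid with no interpolation,
#' so the result is always an exact bin frequency; it is invariant under
#' positive rescaling of the signal.
#'
#' @param profile An [energy_profile()].
#' @return Frequency in Hz.
#' @export
half_energy_frequency <- function(profile) {
  stopifnot(inherits(profile, "energy_profile"))
  hit <- which(profile$psi_cum >= 0.5 - 1e-12)
  profile$frequencies[hit[1L]]
}

.fmt_hz <- function(x) {
  if (abs(x * 10 - round(x * 10)) < 1e-9) sprintf("%.1f", x)
  else format(x, trim = TRUE)
}

#' Feature names for a band set
#'
#' @param bands List of [frequency_band()] objects.
#' @return Character vector of the `3m + 1` base feature names, e.g.
#'   `"mean_0.0_1.0"`, ..., `"fhalf"`.
#' @export
feature_names <- function(bands = default_bands()) {
  per_band <- unlist(lapply(bands, function(b) {
    suffix <- paste0(.fmt_hz(b$f_low), "_", .fmt_hz(b$f_high))
    paste0(c("mean_", "sd_", "max_"), suffix)
  }))
  c(per_band, "fhalf")
}

#' Frequency-domain features of one segment
#'
#' The package's base feature vector: for each of the `m` frequency bands
#' the band mean, sample standard deviation and maximum of the amplitude
#' magnitudes, plus the band-independent half-energy frequency —
#' `3m + 1` features in total (7 for the default two bands).
#'
#' @param seg An `eda_segment` (preprocess first; see
#'   [preprocess_segment()]).
#' @param bands List of [frequency_band()] objects.
#' @param normalize Spectrum normalization before feature computation,
#'   `"none"` (default; the features are scale-covariant) or `"energy"`.
#' @param include_dc Passed to [energy_profile()].
#' @return Named numeric vector of length `3 * length(bands) + 1`.
#' @examples
#' sig <- labeled_signal(5 + cos(2 * pi * (0:47) * 0.25), rep("stress", 48))
#' seg <- segment_signal(sig, segmentation_config(48, 20))[[1]]
#' extract_segment_features(preprocess_segment(seg))
#' @export
extract_segment_features <- function(seg, bands = default_bands(),
                                     normalize = c("none", "energy"),
                                     include_dc = FALSE) {
  stopifnot(inherits(seg, "eda_segment"))
  normalize <- match.arg(normalize)
  spec <- amplitude_spectrum(seg)
  if (normalize == "energy") spec <- normalize_spectrum(spec, "energy")
  # fails first on zero-energy segments so callers can drop them
  fhalf <- half_energy_frequency(energy_profile(spec, include_dc))
  vals <- unlist(lapply(bands, function(b) {
    c(band_mean(spec, b), band_std(spec, b), band_max(spec, b))
  }))
  stats::setNames(c(vals, fhalf), feature_names(bands))
}
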