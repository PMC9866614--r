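#' Parameters for the synthetic EDA cohort generator
#'
#' The generator emulates the statistical structure that the frequency
#' features exploit, using the minimal standard electrodermal model: a
#' slowly drifting tonic level, a Poisson train of skin-conductance
#' responses (SCRs) with a bi-exponential pulse shape, and broadband
#' measurement noise. The class contrasts are built in by construction:
#' stress has frequent, large SCRs at a stationary rate and the least
#' noise (concentrating low-frequency energy and stabilising features
#' between segments); amusement has a bursty, minute-by-minute resampled
#' SCR rate (creating between-segment feature variance); baseline has
#' sparse SCRs and the most noise (flattening its spectrum).
#'
#' @param fs Sampling rate, Hz.
#' @param n_subjects Number of subjects in a cohort.
#' @param block_plan Data frame with columns `state`, `duration_s`: the
#'   per-subject session protocol, in order.
#' @param scr_rate Named vector, SCR events per minute per state.
#' @param amp_median Named vector, median SCR amplitude per state, uS
#'   (log-normal; stress largest).
#' @param amp_sdlog Named vector, log-scale SD of SCR amplitudes per
#'   state: stress responses are homogeneous (small dispersion), while
#'   amusement responses are heterogeneous — together with the bursty
#'   amusement rate this makes amusement features vary more between
#'   consecutive segments than stress features.
#' @param tau_r,tau_d SCR rise and decay time constants, seconds.
#' @param tonic_range Subject-specific tonic offset drawn uniformly from
#'   this interval, uS.
#' @param drift_sd Per-sample SD of the tonic random-walk drift, uS.
#' @param noise_sd Named vector, broadband noise SD per state, uS
#'   (baseline highest, stress lowest).
#' @param amusement_resample_s Seconds between redraws of the amusement
#'   SCR rate (burstiness); stress and baseline rates are constant.
#' @param amusement_rate_sdlog Log-scale SD of the redrawn amusement rate
#'   around its median.
#' @param seed Integer seed; subject `i` derives its own stream from
#'   `seed + i`.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(
    fs = 4,
    n_subjects = 6,
    block_plan = data.frame(
      state = c("baseline", "amusement", "stress"),
      duration_s = c(600, 300, 600)),
    scr_rate = c(baseline = 2, amusement = 4, stress = 8),
    amp_median = c(baseline = 0.3, amusement = 0.4, stress = 0.6),
    amp_sdlog = c(baseline = 0.5, amusement = 0.9, stress = 0.15),
    tau_r = 0.75,
    tau_d = 3.0,
    tonic_range = c(2, 20),
    drift_sd = 0.003,
    noise_sd = c(baseline = 0.08, amusement = 0.05, stress = 0.02),
    amusement_resample_s = 60,
    amusement_rate_sdlog = 0.7,
    seed = 1) {
  stopifnot(fs > 0, n_subjects >= 1,
            all(block_plan$duration_s > 0),
            all(block_plan$state %in% eda_states()),
            all(scr_rate > 0), all(amp_median > 0), all(amp_sdlog > 0),
            tau_r > 0, tau_d > 0,
            tonic_range[1] > 0, tonic_range[2] >= tonic_range[1],
            drift_sd >= 0, all(noise_sd >= 0),
            amusement_resample_s > 0, amusement_rate_sdlog >= 0)
  structure(
    list(fs = fs, n_subjects = as.integer(n_subjects),
         block_plan = block_plan, scr_rate = scr_rate,
         amp_median = amp_median, amp_sdlog = amp_sdlog,
         tau_r = tau_r, tau_d = tau_d, tonic_range = tonic_range,
         drift_sd = drift_sd, noise_sd = noise_sd,
         amusement_resample_s = amusement_resample_s,
         amusement_rate_sdlog = amusement_rate_sdlog,
         seed = as.integer(seed)),
    class = "generator_params"
  )
}

#' Bi-exponential skin-conductance-response pulse
#'
#' The standard SCR kernel `h(t) = A (exp(-t/tau_d) - exp(-t/tau_r))`,
#' scaled so its sampled peak equals `amplitude`: zero at `t = 0`, a fast
#' rise governed by `tau_r`, a slow decay governed by `tau_d`. The
#' continuous-time peak sits at `t = tau_r tau_d / (tau_d - tau_r) *
#' log(tau_d / tau_r)`. In the degenerate limit `tau_r == tau_d` the shape
#' collapses; a zero waveform is returned with a warning.
#'
#' @param amplitude Peak conductance increment, uS.
#' @param tau_r,tau_d Rise and decay time constants, seconds.
#' @param fs Sampling rate, Hz.
#' @param duration Kernel duration, seconds.
#' @return Numeric waveform of `round(duration * fs) + 1` samples.
#' @export
scr_pulse <- function(amplitude, tau_r = 0.75, tau_d = 3.0, fs = 4,
                      duration = 30) {
  stopifnot(amplitude >= 0, tau_r > 0, tau_d > 0, fs > 0, duration > 0)
  t <- seq(0, duration, by = 1 / fs)
  h <- exp(-t / tau_d) - exp(-t / tau_r)
  peak <- max(h)
  if (peak <= 1e-12) {
    warning("degenerate SCR shape (tau_r ~ tau_d): returning zeros")
    return(numeric(length(t)))
  }
  amplitude * h / peak
}

# Poisson event times at `rate_per_min` over [t0, t0 + duration_s)
.poisson_events <- function(rate_per_min, duration_s, t0 = 0) {
  lambda <- rate_per_min / 60 * duration_s
  n <- stats::rpois(1L, lambda)
  if (n == 0L) return(numeric(0))
  t0 + sort(stats::runif(n, 0, duration_s))
}

#' Simulate one subject's labelled EDA recording
#'
#' Follows the block plan exactly: within each block, SCR event times are
#' drawn as a Poisson process at the state's rate (the amusement rate is
#' redrawn every `amusement_resample_s` seconds), bi-exponential pulses
#' with log-normal amplitudes are superposed on the subject's drifting
#' tonic level, state-dependent Gaussian noise is added, and the result is
#' clipped to stay above 0.05 uS. Deterministic given
#' `(params$seed, subject_index)`.
#'
#' @param params A [generator_params()].
#' @param subject_index 1-based subject number within the cohort.
#' @return A [labeled_signal()]; the SCR event times (seconds) are
#'   attached as attribute `"event_times"` for diagnostics.
#' @export
simulate_subject <- function(params, subject_index = 1L) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed + as.integer(subject_index))
  fs <- params$fs
  plan <- params$block_plan
  block_n <- as.integer(round(plan$duration_s * fs))
  n_total <- sum(block_n)
  labels <- rep(plan$state, times = block_n)

  tonic0 <- stats::runif(1, params$tonic_range[1], params$tonic_range[2])
  drift <- cumsum(stats::rnorm(n_total, 0, params$drift_sd))
  noise <- stats::rnorm(n_total, 0, params$noise_sd[labels])

  kernel_s <- 30
  phasic <- numeric(n_total + as.integer(kernel_s * fs) + 1L)
  all_events <- numeric(0)
  block_t0 <- c(0, cumsum(plan$duration_s))
  for (b in seq_len(nrow(plan))) {
    state <- plan$state[b]
    dur <- plan$duration_s[b]
    if (state == "amusement" && params$amusement_rate_sdlog > 0) {
      # bursty: redraw the rate for every chunk
      chunk <- params$amusement_resample_s
      offs <- seq(0, dur - 1e-9, by = chunk)
      events <- unlist(lapply(offs, function(o) {
        rate <- stats::rlnorm(1, log(params$scr_rate[[state]]),
                              params$amusement_rate_sdlog)
        .poisson_events(rate, min(chunk, dur - o), block_t0[b] + o)
      }))
    } else {
      events <- .poisson_events(params$scr_rate[[state]], dur, block_t0[b])
    }
    if (!length(events)) next
    amps <- stats::rlnorm(length(events), log(params$amp_median[[state]]),
                          if (length(params$amp_sdlog) > 1L)
                            params$amp_sdlog[[state]] else params$amp_sdlog)
    kernel <- scr_pulse(1, params$tau_r, params$tau_d, fs, kernel_s)
    for (e in seq_along(events)) {
      i0 <- as.integer(floor(events[e] * fs)) + 1L
      idx <- i0:(i0 + length(kernel) - 1L)
      phasic[idx] <- phasic[idx] + amps[e] * kernel
    }
    all_events <- c(all_events, events)
  }

  x <- pmax(tonic0 + drift + phasic[seq_len(n_total)] + noise, 0.05)
  sig <- labeled_signal(x, labels,
                        subject_id = sprintf("synth%02d", subject_index),
                        fs = fs)
  attr(sig, "event_times") <- all_events
  sig
}

#' Simulate a multi-subject cohort
#'
#' `n_subjects` independent subjects, each with its own tonic offset and
#' a random stream derived deterministically from `seed + subject_index`.
#'
#' @param params A [generator_params()].
#' @return List of [labeled_signal()] objects with distinct subject ids.
#' @examples
#' cohort <- simulate_cohort(generator_params(n_subjects = 3, seed = 1))
#' vapply(cohort, function(s) s$subject_id, "")
#' @export
simulate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  lapply(seq_len(params$n_subjects),
         function(i) simulate_subject(params, i))
}
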