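#' Synthetic postsynaptic-current trace specification
#'
#' Ground-truth generator for spontaneous EPSC-like recordings: events at
#' Poisson times, biexponential kernels with log-normally distributed peak
#' amplitudes, inward (negative) polarity, plus white Gaussian baseline
#' noise at the sampling rate.
#'
#' @param rate Poisson event rate (Hz), >= 0.
#' @param amp_median median peak amplitude (pA).
#' @param amp_sigma log-scale SD of the amplitude distribution.
#' @param amp_min optional truncation floor for amplitudes (pA).
#' @param tau_rise,tau_decay kernel time constants (ms), rise < decay.
#' @param noise_sd baseline noise SD (pA).
#' @param duration trace length (s).
#' @param sample_rate sampling rate (Hz).
#' @param seed integer seed.
#' @return an object of class `psc_trace_spec`.
#' @export
psc_trace_spec <- function(rate = 2, amp_median = 15, amp_sigma = 0.25,
                           amp_min = 0, tau_rise = 0.5, tau_decay = 5,
                           noise_sd = 1.5, duration = 60,
                           sample_rate = 20000, seed = 1L) {
  if (rate < 0) ephys_error("rate must be >= 0", "psc_error")
  if (tau_rise >= tau_decay)
    ephys_error("tau_rise must be < tau_decay", "psc_error")
  if (duration <= 0) ephys_error("duration must be > 0", "psc_error")
  structure(list(rate = rate, amp_median = amp_median,
                 amp_sigma = amp_sigma, amp_min = amp_min,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 noise_sd = noise_sd, duration = duration,
                 sample_rate = sample_rate, seed = seed),
            class = "psc_trace_spec")
}

# peak-normalized biexponential kernel on the sample grid; t in ms
biexp_kernel <- function(tau_rise, tau_decay, length_ms, sample_rate) {
  t <- seq(0, length_ms, by = 1000 / sample_rate)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / max(k)
}

#' Simulate a PSC current trace with known events
#'
#' @param spec a [psc_trace_spec()].
#' @return list with `trace` (pA; events are negative deflections),
#'   `events` (data frame `onset_time_s`, `amplitude_pA` of every ground
#'   truth event) and `sample_rate`.
#' @export
simulate_psc_trace <- function(spec) {
  stopifnot(inherits(spec, "psc_trace_spec"))
  set.seed(spec$seed)
  n <- round(spec$duration * spec$sample_rate)
  trace <- stats::rnorm(n, 0, spec$noise_sd)
  n_ev <- stats::rpois(1, spec$rate * spec$duration)
  events <- data.frame(onset_time_s = numeric(0), amplitude_pA = numeric(0))
  if (n_ev > 0) {
    onset <- sort(stats::runif(n_ev, 0, spec$duration))
    amp <- stats::rlnorm(n_ev, log(spec$amp_median), spec$amp_sigma)
    if (spec$amp_min > 0) amp <- pmax(amp, spec$amp_min)
    kern <- biexp_kernel(spec$tau_rise, spec$tau_decay,
                         length_ms = 8 * spec$tau_decay,
                         sample_rate = spec$sample_rate)
    for (i in seq_len(n_ev)) {
      j0 <- floor(onset[i] * spec$sample_rate) + 1L
      j1 <- min(n, j0 + length(kern) - 1L)
      idx <- seq_len(j1 - j0 + 1L)
      trace[j0:j1] <- trace[j0:j1] - amp[i] * kern[idx]
    }
    events <- data.frame(onset_time_s = (floor(onset * spec$sample_rate)) /
                           spec$sample_rate,
                         amplitude_pA = amp)
  }
  list(trace = trace, events = events, sample_rate = spec$sample_rate)
}

#' Detection template
#'
#' Peak-normalized biexponential template for the scaled-template event
#' search. The study's manually fitted templates are not recoverable, so
#' the default is a generic fast EPSC shape (0.5 ms rise, 5 ms decay,
#' 30 ms long); all parameters are configurable.
#'
#' @inheritParams psc_trace_spec
#' @param length_ms template length (ms).
#' @return object of class `psc_template` with `samples` (peak 1),
#'   `tau_rise`, `tau_decay`, `sample_rate`.
#' @export
psc_template <- function(tau_rise = 0.5, tau_decay = 5, length_ms = 30,
                         sample_rate = 20000) {
  if (tau_rise >= tau_decay)
    ephys_error("tau_rise must be < tau_decay", "template_error")
  structure(list(samples = biexp_kernel(tau_rise, tau_decay, length_ms,
                                        sample_rate),
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 length_ms = length_ms, sample_rate = sample_rate),
            class = "psc_template")
}

#' Scaled-template detection of postsynaptic currents
#'
#' Slides the template across the (negated, so events are positive)
#' current trace; in every window the template is optimally scaled and
#' offset by least squares, and the detection score is the fitted scale
#' divided by its standard error (the Clements-Bekkers statistic). Events
#' are accepted where the score is a local maximum at or above
#' `criterion` AND the fitted amplitude reaches `amp_cutoff`; accepted
#' events are separated by at least the template rise time. Fitting an
#' offset per window makes detection invariant to DC shifts of the trace.
#'
#' @param trace current trace (pA), events as inward (negative)
#'   deflections.
#' @param sample_rate sampling rate (Hz).
#' @param template a [psc_template()].
#' @param criterion detection-score threshold (default 3.5, standard for
#'   the scaled-template method).
#' @param amp_cutoff minimum fitted amplitude (pA, default 5).
#' @return data frame with `onset_time_s`, `amplitude_pA`,
#'   `detection_score`, one row per accepted event, ordered in time.
#' @export
detect_pscs <- function(trace, sample_rate, template = psc_template(
                          sample_rate = sample_rate),
                        criterion = 3.5, amp_cutoff = 5) {
  w <- template$samples
  m <- length(w)
  n <- length(trace)
  if (m > n)
    ephys_error("template longer than trace", "template_error")
  x <- -trace  # inward events become positive
  sw <- sum(w); sww <- sum(w^2)
  Sww <- sww - sw^2 / m
  # rolling window sums; window starting at i covers x[i .. i+m-1]
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  nw <- n - m + 1L
  S_x <- cs[(m + 1L):(n + 1L)] - cs[1L:nw]
  S_x2 <- cs2[(m + 1L):(n + 1L)] - cs2[1L:nw]
  # cross-correlation sum_j x[i+j-1] w[j] via FFT convolution
  S_xw <- stats::convolve(x, w, conj = TRUE, type = "open")[m:n]
  s <- (S_xw - sw * S_x / m) / Sww
  o <- (S_x - s * sw) / m
  sse <- S_x2 + s^2 * sww + m * o^2 - 2 * s * S_xw - 2 * o * S_x +
    2 * s * o * sw
  sse[sse < 0] <- 0
  se <- sqrt(sse / (m - 2) / Sww)
  score <- ifelse(se > 0, s / se, 0)
  # candidate onsets: one per contiguous run of supra-criterion windows,
  # at the run's score maximum
  ok <- score >= criterion & s >= amp_cutoff
  loc <- integer(0)
  if (any(ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    loc <- vapply(runs, function(k) {
      i0 <- starts[k]
      i0 - 1L + which.max(score[i0:ends[k]])
    }, integer(1))
  }
  if (!length(loc))
    return(data.frame(onset_time_s = numeric(0),
                      amplitude_pA = numeric(0),
                      detection_score = numeric(0)))
  # enforce minimum separation (template rise time), keeping higher scores
  min_sep <- max(1L, round(template$tau_rise * sample_rate / 1000))
  ord <- loc[order(-score[loc])]
  keep <- logical(n)
  accepted <- integer(0)
  for (i in ord) {
    if (!any(keep[max(1L, i - min_sep):min(n, i + min_sep)])) {
      keep[i] <- TRUE
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)
  data.frame(onset_time_s = (accepted - 1L) / sample_rate,
             amplitude_pA = s[accepted],
             detection_score = score[accepted])
}

#' Detect spontaneous action potentials in a gap-free voltage trace
#'
#' Uses the overshoot criterion of [detect_spikes()]; the frequency is
#' the total event count divided by the trace duration.
#'
#' @param trace voltage trace (mV).
#' @param sample_rate sampling rate (Hz).
#' @return list with `times_s` (spike peak times) and `frequency_hz`.
#' @export
detect_saps <- function(trace, sample_rate) {
  peaks <- detect_spikes(trace, sample_rate)
  list(times_s = (peaks - 1L) / sample_rate,
       frequency_hz = length(peaks) / (length(trace) / sample_rate))
}

#' Event-rate and amplitude summary
#'
#' @param events data frame with an `amplitude_pA` column (as from
#'   [detect_pscs()]).
#' @param duration recording duration (s), > 0.
#' @return list with `frequency_hz` = N/duration and `mean_amplitude_pA`
#'   (`NA` when there are no events).
#' @export
event_stats <- function(events, duration) {
  if (duration <= 0) ephys_error("duration must be > 0", "event_error")
  n <- if (is.data.frame(events)) nrow(events) else length(events)
  list(frequency_hz = n / duration,
       mean_amplitude_pA = if (n == 0) NA_real_
                           else mean(events$amplitude_pA))
}
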