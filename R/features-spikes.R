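#' Detect action potentials in a voltage trace
#'
#' Spikes are counted by the overshoot criterion: one event per upward
#' 0 mV crossing followed by a local maximum, with a 1 ms refractory
#' period between accepted peaks. The peak is the largest sample between
#' the upward crossing and the next downward 0 mV crossing (or trace end).
#'
#' @param v voltage trace (mV).
#' @param sample_rate sampling rate (Hz).
#' @param window optional `c(from, to)` in samples restricting the search.
#' @param refractory_ms minimum separation between accepted peaks (ms).
#' @return integer vector of peak sample indices (possibly empty), ordered
#'   in time.
#' @export
detect_spikes <- function(v, sample_rate, window = NULL,
                          refractory_ms = 1) {
  if (is.null(window)) window <- c(1L, length(v))
  lo <- max(1L, window[1]); hi <- min(length(v), window[2])
  x <- v[lo:hi]
  n <- length(x)
  if (n < 2L) return(integer(0))
  up <- which(x[-n] < 0 & x[-1] >= 0) + 1L
  down <- which(x[-n] >= 0 & x[-1] < 0)
  peaks <- integer(0)
  for (u in up) {
    d <- down[down >= u]
    seg_end <- if (length(d)) d[1] else n
    pk <- u - 1L + which.max(x[u:seg_end])
    peaks <- c(peaks, pk)
  }
  if (length(peaks) > 1L) {
    ref <- refractory_ms * sample_rate / 1000
    keep <- peaks[1]
    for (p in peaks[-1]) if (p - keep[length(keep)] >= ref) keep <- c(keep, p)
    peaks <- keep
  }
  peaks + (lo - 1L)
}

#' Spike threshold by the dV/dt acceleration criterion
#'
#' The threshold is the voltage at the first sample before the peak where
#' the two-point forward-difference dV/dt reaches `dvdt_crit` (default
#' 5 mV/ms) and stays at or above it up to the rising flank, searching
#' backward no more than `max_back_ms`.
#'
#' @param v voltage trace (mV).
#' @param peak_idx spike peak sample index.
#' @param sample_rate sampling rate (Hz).
#' @param dvdt_crit acceleration criterion (mV/ms).
#' @param max_back_ms maximum backward search (ms).
#' @return list with `idx` (threshold sample) and `V` (threshold voltage,
#'   mV).
#' @export
spike_threshold <- function(v, peak_idx, sample_rate, dvdt_crit = 5,
                            max_back_ms = 10) {
  dt_ms <- 1000 / sample_rate
  lo <- max(1L, peak_idx - as.integer(round(max_back_ms / dt_ms)))
  if (peak_idx - lo < 1L)
    ephys_error("peak too close to trace start for threshold search",
                "threshold_error")
  dvdt <- (v[(lo + 1L):peak_idx] - v[lo:(peak_idx - 1L)]) / dt_ms
  j <- length(dvdt)
  while (j >= 1L && dvdt[j] < dvdt_crit) j <- j - 1L  # skip a flat top
  if (j < 1L)
    ephys_error(sprintf(
      "dV/dt never reached %.3g mV/ms within %.3g ms before the peak",
      dvdt_crit, max_back_ms), "threshold_error")
  while (j >= 1L && dvdt[j] >= dvdt_crit) j <- j - 1L
  idx <- lo + j  # first sample of the contiguous super-criterion run
  list(idx = idx, V = v[idx])
}

#' Spike shape: amplitude, half-width and AHP depths
#'
#' Amplitude is peak minus threshold voltage. Half-width is the time
#' between the rising and decaying crossings of the half-amplitude level,
#' both located by linear interpolation between samples. fAHP and mAHP are
#' the threshold voltage minus the minimum voltage within 4 and 6 ms after
#' the spike peak, reported as positive depths (no clamping: a decay that
#' never dips below threshold gives a non-positive value).
#'
#' @param v voltage trace (mV).
#' @param peak_idx spike peak sample index.
#' @param thr threshold as returned by [spike_threshold()].
#' @param sample_rate sampling rate (Hz).
#' @return list with `amplitude` (mV), `half_width` (ms), `fAHP` (mV),
#'   `mAHP` (mV). Components whose measurement window is truncated by the
#'   sweep end are `NA` with a warning.
#' @export
spike_shape <- function(v, peak_idx, thr, sample_rate) {
  dt_ms <- 1000 / sample_rate
  amp <- v[peak_idx] - thr$V
  half <- thr$V + amp / 2
  # rising crossing between threshold and peak
  ris <- NA_real_
  for (i in thr$idx:(peak_idx - 1L)) {
    if (v[i] <= half && v[i + 1L] > half) {
      ris <- i + (half - v[i]) / (v[i + 1L] - v[i])
      break
    }
  }
  # decaying crossing after the peak
  fall <- NA_real_
  i <- peak_idx
  while (i < length(v)) {
    if (v[i] >= half && v[i + 1L] < half) {
      fall <- i + (v[i] - half) / (v[i] - v[i + 1L])
      break
    }
    i <- i + 1L
  }
  hw <- if (is.na(ris) || is.na(fall)) {
    warning("half-width window truncated by sweep end")
    NA_real_
  } else (fall - ris) * dt_ms
  ahp_depth <- function(win_ms) {
    j1 <- peak_idx + 1L
    j2 <- peak_idx + as.integer(round(win_ms / dt_ms))
    if (j2 > length(v)) {
      warning(sprintf("%g ms AHP window truncated by sweep end", win_ms))
      return(NA_real_)
    }
    thr$V - min(v[j1:j2])
  }
  list(amplitude = amp, half_width = hw,
       fAHP = ahp_depth(4), mAHP = ahp_depth(6))
}

#' Full per-sweep spike table
#'
#' Runs [detect_spikes()], [spike_threshold()] and [spike_shape()] on one
#' voltage sweep and returns one row per spike.
#'
#' @inheritParams detect_spikes
#' @param dvdt_crit threshold criterion (mV/ms).
#' @return data frame with columns `peak_idx`, `peak_time_ms`, `peak_V`,
#'   `threshold_V`, `threshold_time_ms`, `amplitude`, `half_width`,
#'   `fAHP`, `mAHP`. Spikes whose threshold search fails are dropped.
#' @export
sweep_spikes <- function(v, sample_rate, window = NULL, dvdt_crit = 5) {
  peaks <- detect_spikes(v, sample_rate, window)
  out <- data.frame(peak_idx = integer(0), peak_time_ms = numeric(0),
                    peak_V = numeric(0), threshold_V = numeric(0),
                    threshold_time_ms = numeric(0), amplitude = numeric(0),
                    half_width = numeric(0), fAHP = numeric(0),
                    mAHP = numeric(0))
  dt_ms <- 1000 / sample_rate
  for (pk in peaks) {
    thr <- tryCatch(spike_threshold(v, pk, sample_rate, dvdt_crit),
                    ephystype_error = function(e) NULL)
    if (is.null(thr)) next
    shp <- suppressWarnings(spike_shape(v, pk, thr, sample_rate))
    out <- rbind(out, data.frame(
      peak_idx = pk, peak_time_ms = (pk - 1L) * dt_ms, peak_V = v[pk],
      threshold_V = thr$V, threshold_time_ms = (thr$idx - 1L) * dt_ms,
      amplitude = shp$amplitude, half_width = shp$half_width,
      fAHP = shp$fAHP, mAHP = shp$mAHP))
  }
  out
}
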