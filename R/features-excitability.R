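#' Excitability scalars from a current-step family
#'
#' Analyses a depolarizing step family (500 ms square pulses): counts
#' spikes per step with the 5 mV amplitude cutoff (peak-to-threshold
#' amplitude below the cutoff excludes spikelets from the counts), and
#' derives rheobase, maximum and mean firing frequency, and the AP-train
#' statistics measured at the step evoking about 50% of the maximum
#' firing.
#'
#' Definitions: rheobase is the lowest step amplitude with at least one
#' accepted spike; frequencies are spike count divided by the step
#' duration; mean frequency averages across all depolarizing steps; mean
#' ISI is the mean time between AP peaks at the 50%-of-maximum step;
#' amplitude change is (A2 - A1)/A1 for the first two spikes at that step.
#' The 50%-of-maximum step is the one whose count is nearest to half the
#' maximum count (ties towards the lower current, at least two spikes
#' required).
#'
#' Firing category at the 50%-max step (needs >= 3 spikes for the burst
#' test): `"burst"` if the first ISI is shorter than half the median of
#' the remaining ISIs; otherwise `"adaptive"` if the last ISI exceeds the
#' first by more than 30%; otherwise `"neither"`.
#'
#' @param stepset a voltage [sweep_set()] from a step-family protocol.
#' @param amp_cutoff spike amplitude cutoff (mV), default 5.
#' @param dvdt_crit threshold criterion passed to [spike_threshold()].
#' @return list with `rheobase` (pA, `NA` if no step fires), `max_freq`,
#'   `mean_freq` (Hz), `mean_ISI` (ms), `amp_change`,
#'   `burst_or_adaptive`, per-step `counts` and `currents`, the selected
#'   `shape_step` index, and `shape_spikes` (the spike table at that
#'   step).
#' @export
excitability_scalars <- function(stepset, amp_cutoff = 5, dvdt_crit = 5) {
  stopifnot(inherits(stepset, "sweep_set"),
            stepset$channel_kind == "voltage_mV")
  dep <- which(stepset$step_amplitudes > 0)
  if (length(dep) < 2L)
    ephys_error("need >= 2 depolarizing steps", "feature_error")
  proto <- stepset$protocol
  step_dur_s <- if (!is.null(proto)) proto$step_dur else 0.5
  win <- if (!is.null(proto)) {
    fs <- stepset$sample_rate
    c(round(proto$step_start * fs) + 1L,
      round((proto$step_start + proto$step_dur) * fs) +
        as.integer(round(0.002 * fs)))  # 2 ms grace for the last peak
  } else NULL
  tabs <- vector("list", length(dep))
  counts <- integer(length(dep))
  for (k in seq_along(dep)) {
    tab <- sweep_spikes(stepset$sweeps[[dep[k]]], stepset$sample_rate,
                        window = win, dvdt_crit = dvdt_crit)
    tab <- tab[!is.na(tab$amplitude) & tab$amplitude >= amp_cutoff, ,
               drop = FALSE]
    tabs[[k]] <- tab
    counts[k] <- nrow(tab)
  }
  currents <- stepset$step_amplitudes[dep]
  rheo <- if (any(counts > 0)) currents[which(counts > 0)[1]] else NA_real_
  max_freq <- max(counts) / step_dur_s
  mean_freq <- mean(counts / step_dur_s)
  mean_ISI <- amp_change <- NA_real_
  category <- NA_character_
  shape_step <- NA_integer_
  eligible <- which(counts >= 2L)
  if (length(eligible)) {
    target <- max(counts) / 2
    shape_step <- eligible[which.min(abs(counts[eligible] - target))]
    tab <- tabs[[shape_step]]
    isi <- diff(tab$peak_time_ms)
    mean_ISI <- mean(isi)
    amp_change <- (tab$amplitude[2] - tab$amplitude[1]) / tab$amplitude[1]
    category <- "neither"
    if (nrow(tab) >= 3L && isi[1] < 0.5 * stats::median(isi[-1])) {
      category <- "burst"
    } else if (isi[length(isi)] / isi[1] > 1.3) {
      category <- "adaptive"
    }
  }
  list(rheobase = rheo, max_freq = max_freq, mean_freq = mean_freq,
       mean_ISI = mean_ISI, amp_change = amp_change,
       burst_or_adaptive = category, counts = counts, currents = currents,
       shape_step = shape_step,
       shape_spikes = if (!is.na(shape_step)) tabs[[shape_step]] else NULL)
}
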