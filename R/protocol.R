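#' Stimulation protocols
#'
#' Constructors for the four stimulation protocols the analysis expects:
#' a family of 500 ms square current steps in +10 pA increments
#' (intrinsic excitability), a -200 pA sag/rebound pulse, a -10 pA / 100 ms
#' test pulse (passive properties) and a gap-free recording (spontaneous
#' activity). Times are seconds, currents pA, sampling in Hz.
#'
#' @param step_start pulse onset from sweep start (s).
#' @param step_dur pulse duration (s).
#' @param step_increment step family increment (pA).
#' @param step_min,step_max first and last step amplitude (pA); the
#'   increment must divide their difference.
#' @param tail recording time after pulse offset (s).
#' @param sample_rate sampling rate (Hz).
#' @return an object of class `protocol`.
#' @export
protocol_step_family <- function(step_start = 0.1, step_dur = 0.5,
                                 step_increment = 10, step_min = 10,
                                 step_max = 250, tail = 0.1,
                                 sample_rate = 20000) {
  stopifnot(step_dur > 0, sample_rate > 0, step_increment > 0)
  if (abs((step_max - step_min) %% step_increment) > 1e-9)
    ephys_error("step_increment must divide step_max - step_min",
                "protocol_error")
  structure(list(kind = "step_family", step_start = step_start,
                 step_dur = step_dur, step_increment = step_increment,
                 step_min = step_min, step_max = step_max, tail = tail,
                 sample_rate = sample_rate),
            class = "protocol")
}

#' @rdname protocol_step_family
#' @param sag_amp hyperpolarizing pulse amplitude (pA).
#' @param n_repeats repeated identical sweeps; passive measurements
#'   average them (noise suppression for the small test pulse), the
#'   rebound flag is per-sweep.
#' @export
protocol_sag_pulse <- function(sag_amp = -200, step_start = 0.1,
                               step_dur = 0.5, tail = 0.2,
                               n_repeats = 4, sample_rate = 20000) {
  stopifnot(step_dur > 0, sample_rate > 0, n_repeats >= 1)
  structure(list(kind = "sag_pulse", step_start = step_start,
                 step_dur = step_dur, sag_amp = sag_amp, tail = tail,
                 n_repeats = n_repeats, sample_rate = sample_rate),
            class = "protocol")
}

#' @rdname protocol_step_family
#' @param test_amp test pulse amplitude (pA).
#' @param test_dur test pulse duration (s).
#' @export
protocol_test_pulse <- function(test_amp = -10, step_start = 0.1,
                                test_dur = 0.1, tail = 0.1,
                                n_repeats = 32, sample_rate = 20000) {
  stopifnot(test_dur > 0, sample_rate > 0, n_repeats >= 1)
  structure(list(kind = "test_pulse", step_start = step_start,
                 step_dur = test_dur, test_amp = test_amp, tail = tail,
                 n_repeats = n_repeats, sample_rate = sample_rate),
            class = "protocol")
}

#' @rdname protocol_step_family
#' @param duration gap-free recording length (s).
#' @export
protocol_gap_free <- function(duration = 30, sample_rate = 20000) {
  stopifnot(duration > 0, sample_rate > 0)
  structure(list(kind = "gap_free", duration = duration,
                 sample_rate = sample_rate),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol>", x$kind, "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

# per-sweep injected current amplitudes (pA) for a protocol
protocol_amplitudes <- function(protocol) {
  switch(protocol$kind,
         step_family = seq(protocol$step_min, protocol$step_max,
                           by = protocol$step_increment),
         sag_pulse = rep(protocol$sag_amp, protocol$n_repeats),
         test_pulse = rep(protocol$test_amp, protocol$n_repeats),
         gap_free = 0)
}

# total sweep duration in seconds
protocol_duration <- function(protocol) {
  if (protocol$kind == "gap_free") return(protocol$duration)
  protocol$step_start + protocol$step_dur + protocol$tail
}

# injected-current vector (pA) for one sweep at amplitude `amp`
protocol_current <- function(protocol, amp) {
  n <- round(protocol_duration(protocol) * protocol$sample_rate)
  I <- numeric(n)
  if (protocol$kind != "gap_free") {
    i0 <- round(protocol$step_start * protocol$sample_rate) + 1L
    i1 <- round((protocol$step_start + protocol$step_dur) *
                  protocol$sample_rate)
    I[i0:i1] <- amp
  }
  I
}
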