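ID_CLAMP_MS_PER_S <- 1000

#' Derive a per-sweep RNG seed from a master seed
#'
#' All stochastic operations in the package take an explicit integer master
#' seed and expand it deterministically, so that a whole run is reproducible
#' from a single integer while individual sweeps still get independent
#' streams.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index (e.g. sweep number).
#' @return a positive integer seed strictly below 2^31.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # multiplicative hash mod the Mersenne prime 2^31 - 1; keeps seeds
  # representable as R integers
  s <- (abs(as.numeric(master)) %% 2147483647) + 1
  s <- (s * 48271 + as.numeric(index) * 104729 + 12345) %% 2147483647
  as.integer(s + 1)
}

#' Ornstein-Uhlenbeck current noise
#'
#' Exact-update OU process used as the simulator's stochastic current drive:
#' x[n+1] = x[n] exp(-dt/tau) + sigma sqrt(1 - exp(-2 dt/tau)) z, z ~ N(0,1),
#' so the stationary standard deviation is exactly `sigma` at any dt.
#'
#' @param n number of samples.
#' @param sigma stationary standard deviation (pA).
#' @param tau correlation time constant (ms).
#' @param dt time step (ms).
#' @param seed integer seed.
#' @return numeric vector of length n (pA), starting from the stationary
#'   distribution.
#' @export
ou_noise <- function(n, sigma, tau, dt, seed) {
  if (sigma <= 0) return(numeric(n))
  stopifnot(tau > 0, dt > 0, n >= 1)
  set.seed(seed)
  rho <- exp(-dt / tau)
  innov_sd <- sigma * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  z <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in seq_len(n - 1L)) x[i + 1L] <- x[i] * rho + z[i]
  x
}

# internal: stop with a consistent error class so callers can test on it
ephys_error <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "ephystype_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
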