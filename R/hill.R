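#' Firing-frequency versus injected-current (F-I) curve
#'
#' One point per depolarizing step: frequency is the accepted spike count
#' divided by the step duration (Hz, count/0.5 s for the standard 500 ms
#' pulse). Zero-frequency points are kept - they constrain the fitted
#' midpoint.
#'
#' @param currents injected step amplitudes (pA), strictly increasing.
#' @param freqs firing frequencies (Hz), same length.
#' @return an object of class `fi_curve` (data frame with columns
#'   `current`, `freq`).
#' @export
fi_curve <- function(currents, freqs) {
  if (length(currents) != length(freqs))
    ephys_error("currents and freqs must have equal length", "fi_error")
  if (any(diff(currents) <= 0))
    ephys_error("currents must be strictly increasing", "fi_error")
  structure(data.frame(current = currents, freq = freqs),
            class = c("fi_curve", "data.frame"))
}

#' @rdname fi_curve
#' @param stepset a voltage [sweep_set()] from a step-family protocol.
#' @param scalars optional precomputed [excitability_scalars()] output for
#'   `stepset`; computed if missing.
#' @export
build_fi <- function(stepset, scalars = NULL) {
  if (is.null(scalars)) scalars <- excitability_scalars(stepset)
  step_dur_s <- if (!is.null(stepset$protocol))
    stepset$protocol$step_dur else 0.5
  fi_curve(scalars$currents, scalars$counts / step_dur_s)
}

#' Fit the sigmoidal Hill function to an F-I curve
#'
#' Fits y = a x^b / (c^b + x^b) by bounded nonlinear least squares
#' (Levenberg-Marquardt). The three parameters characterize intrinsic
#' excitability: `a` is the curve maximum (maximum frequency, Hz), `b` the
#' dimensionless Hill exponent, and `c` the midpoint (pA), the current at
#' which the fitted frequency is exactly a/2. The reported steepness
#' (neuronal gain) is the derivative of the fitted curve at the midpoint,
#' a b / (4 c), in Hz/pA; the raw exponent `b` is kept alongside.
#'
#' Initialization: a0 = max observed frequency, c0 = current at the first
#' point reaching a0/2, b0 = 2. Bounds: a in (0, 3 a0], b in (0, 100],
#' c in (0, 3 max current].
#'
#' @param curve an [fi_curve()] (or anything with `current`/`freq`
#'   columns).
#' @param ... passed to [minpack.lm::nls.lm.control()]; defaults `ftol =
#'   1e-10`, `maxfev = 10000`.
#' @return an object of class `hill_fit` with components `a`, `b`, `c`,
#'   `steepness`, `rmse`, `converged`, `n_points`, `extrapolated_max`
#'   (fitted maximum above the largest observed frequency), `data` and the
#'   raw optimizer report.
#' @examples
#' x <- seq(10, 300, by = 10)
#' y <- 50 * x^4 / (100^4 + x^4)
#' fit <- fit_hill(fi_curve(x, y))
#' coef(fit)                 # recovers a = 50, b = 4, c = 100
#' predict(fit, newdata = 100)  # 25 Hz: f(c) = a/2
#' @export
fit_hill <- function(curve, ...) {
  x <- curve$current
  y <- curve$freq
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L)
    ephys_error("need >= 4 F-I points to fit", "fit_error")
  if (all(y == 0))
    ephys_error("flat all-zero F-I curve; fit refused", "fit_error")
  if (length(unique(y[y > 0])) <= 1L && sum(y > 0) <= 1L)
    ephys_error("degenerate F-I data (<= 1 distinct nonzero frequency)",
                "fit_error")
  a0 <- max(y)
  c0 <- x[which(y >= a0 / 2)[1]]
  if (!is.finite(c0) || c0 <= 0) c0 <- stats::median(x)
  start <- c(a = a0, b = 2, c = c0)
  lower <- c(a = 1e-6, b = 1e-6, c = 1e-6)
  upper <- c(a = 3 * a0, b = 100, c = 3 * max(x))
  resid_fn <- function(p) y - p[1] * x^p[2] / (p[3]^p[2] + x^p[2])
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxfev = 10000, ...)
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn, control = ctrl)
  p <- fit$par
  on_bound <- any(abs(p - upper) < 1e-8) || any(abs(p - lower) < 1e-8)
  converged <- fit$info %in% 1:4 && !on_bound
  rmse <- sqrt(mean(fit$fvec^2))
  out <- list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
              steepness = unname(p["a"] * p["b"] / (4 * p["c"])),
              rmse = rmse, converged = converged, n_points = length(x),
              extrapolated_max = unname(p["a"]) >= max(y),
              data = data.frame(current = x, freq = y),
              optim = fit)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  cat("Hill F-I fit: y = a x^b / (c^b + x^b)\n")
  cat(sprintf("  a (max frequency): %.*g Hz\n", digits, x$a))
  cat(sprintf("  b (Hill exponent): %.*g\n", digits, x$b))
  cat(sprintf("  c (midpoint):      %.*g pA\n", digits, x$c))
  cat(sprintf("  steepness a*b/(4c): %.*g Hz/pA\n", digits, x$steepness))
  cat(sprintf("  rmse %.3g Hz on %d points; converged: %s%s\n",
              x$rmse, x$n_points, x$converged,
              if (x$extrapolated_max) " (extrapolated maximum)" else ""))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c,
    steepness = object$steepness)
}

#' @export
summary.hill_fit <- function(object, ...) {
  cat(sprintf("Hill fit on %d F-I points (%g-%g pA)\n", object$n_points,
              min(object$data$current), max(object$data$current)))
  print(object)
  cat(sprintf("  f(c) = %.6g Hz (= a/2 under the model)\n",
              predict(object, newdata = object$c)))
  invisible(object)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$current
       else if (is.data.frame(newdata)) newdata$current
       else newdata
  object$a * x^object$b / (object$c^object$b + x^object$b)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$freq - predict(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$data$current, x$data$freq, pch = 19,
                 xlab = "injected current (pA)",
                 ylab = "firing frequency (Hz)", ...)
  xx <- seq(0, max(x$data$current), length.out = 200)
  graphics::lines(xx, predict(x, newdata = xx), col = "firebrick")
  graphics::abline(v = x$c, lty = 3)
  graphics::abline(h = x$a / 2, lty = 3)
  invisible(x)
}
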