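#' Assemble the 18-feature vector for one cell
#'
#' Combines [excitability_scalars()], [passive_properties()] and the Hill
#' fit of the F-I curve into the fixed 18-feature row used for clustering
#' (see [feature_names()] for the order and units). AP-shape features
#' (threshold, half-width, fast/medium AHP) are averaged over the spikes
#' of the 50%-of-maximum step. Missing values stay explicit (`NA`); a cell
#' with more than four missing features is flagged for exclusion.
#'
#' @param cell list with sweep sets `steps`, `sag`, `test`, as from
#'   [simulate_cell()].
#' @param hill optional precomputed [fit_hill()] result; fitted from the
#'   cell's F-I curve when `NULL` (midpoint/steepness become `NA` when the
#'   fit is refused).
#' @param cell_id,condition identifiers copied into the row.
#' @return one-row data frame with `cell_id`, `condition`, the 18
#'   features, and attributes `n_missing` and `excluded` (more than 4
#'   missing features).
#' @export
assemble_features <- function(cell, hill = NULL, cell_id = "cell",
                              condition = "control") {
  ex <- excitability_scalars(cell$steps)
  pp <- suppressWarnings(passive_properties(cell$test, cell$sag))
  if (is.null(hill)) {
    hill <- tryCatch(fit_hill(build_fi(cell$steps, ex)),
                     ephystype_error = function(e) NULL)
  }
  shape <- ex$shape_spikes
  mean_or_na <- function(x) if (is.null(x) || !length(x) ||
                                all(is.na(x))) NA_real_
                            else mean(x, na.rm = TRUE)
  row <- data.frame(
    cell_id = cell_id, condition = condition,
    rheobase = ex$rheobase,
    Cp = pp$Cp,
    V_m = pp$V_m,
    R_in = pp$R_in,
    max_freq = ex$max_freq,
    sag_amp = pp$sag_amp,
    rebound = as.logical(pp$rebound),
    burst_or_adaptive = ex$burst_or_adaptive,
    mean_freq = ex$mean_freq,
    mAHP = mean_or_na(shape$mAHP),
    fAHP = mean_or_na(shape$fAHP),
    midpoint = if (is.null(hill)) NA_real_ else hill$c,
    steepness = if (is.null(hill)) NA_real_ else hill$steepness,
    tau = pp$tau,
    threshold = mean_or_na(shape$threshold_V),
    amp_change = ex$amp_change,
    half_width = mean_or_na(shape$half_width),
    mean_ISI = ex$mean_ISI,
    stringsAsFactors = FALSE)
  n_missing <- sum(is.na(row[feature_names()]))
  attr(row, "n_missing") <- n_missing
  attr(row, "excluded") <- n_missing > 4L
  attr(row, "hill") <- hill
  row
}

#' Simulate and featurize a cohort of synthetic cells
#'
#' Draws `n_per_type` cells per preset, jittering the passive and
#' adaptation parameters log-normally (`jitter_sd` on the log scale) so
#' cells of a type vary realistically, simulates each cell under
#' `condition`, and assembles the feature matrix. Excluded cells (more
#' than 4 missing features) are dropped with a message.
#'
#' @param n_per_type named or unnamed integer vector, one count per
#'   preset, e.g. `c(type1 = 17, type2 = 3, type3 = 5)`.
#' @param seed integer master seed.
#' @param condition condition name(s) or [drug_condition()].
#' @param jitter_sd log-scale SD of the parameter jitter.
#' @param protocol step-family protocol for all cells.
#' @param presets preset list to draw from (default [make_presets()]);
#'   override e.g. to change `ca_scale` study-wide.
#' @return data frame of feature rows with extra columns `true_type` and
#'   `cell_id`; attribute `"cells"` keeps the per-cell jittered specs and
#'   seeds so the same cohort can be re-simulated under another condition.
#' @export
make_cohort <- function(n_per_type = c(type1 = 17, type2 = 3, type3 = 5),
                        seed = 1L, condition = "control",
                        jitter_sd = 0.08,
                        protocol = protocol_step_family(),
                        presets = make_presets()) {
  if (is.null(names(n_per_type))) names(n_per_type) <-
      names(presets)[seq_along(n_per_type)]
  cells <- list()
  idx <- 0L
  for (ty in names(n_per_type)) {
    for (j in seq_len(n_per_type[[ty]])) {
      idx <- idx + 1L
      cells[[idx]] <- list(
        spec = jitter_spec(presets[[ty]], derive_seed(seed, 1000L + idx),
                           jitter_sd),
        true_type = ty,
        cell_id = sprintf("%s_%02d", ty, j),
        seed = derive_seed(seed, idx))
    }
  }
  cohort_features(cells, condition, protocol)
}

#' @rdname make_cohort
#' @param cells per-cell list as stored in the `"cells"` attribute.
#' @export
cohort_features <- function(cells, condition = "control",
                            protocol = protocol_step_family()) {
  rows <- list()
  for (cl in cells) {
    rec <- simulate_cell(cl$spec, cl$seed, condition, protocol)
    row <- assemble_features(rec, cell_id = cl$cell_id,
                             condition = if (is.character(condition))
                               paste(condition, collapse = "+")
                             else paste(condition$name, collapse = "+"))
    row$true_type <- cl$true_type
    if (isTRUE(attr(row, "excluded"))) {
      message("cell ", cl$cell_id, " excluded (",
              attr(row, "n_missing"), " missing features)")
      next
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "cells") <- cells
  out
}

# log-normal multiplicative jitter of the kinetic/passive parameters
jitter_spec <- function(spec, seed, sd = 0.08) {
  set.seed(seed)
  mul <- function(x) x * exp(stats::rnorm(1, 0, sd))
  for (f in c("C_m", "g_L", "a_w", "b_w", "tau_w", "g_h", "g_BK",
              "g_tonic_inh"))
    spec[[f]] <- mul(spec[[f]])
  spec$E_L <- spec$E_L + stats::rnorm(1, 0, 1.2)
  spec$V_T <- spec$V_T + stats::rnorm(1, 0, 0.8)
  validate_neuron_spec(spec)
  spec
}
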