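# shared fixtures, memoized so expensive simulations run once per suite

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a fast step protocol for unit tests (fewer, shorter steps)
quick_steps <- function(step_max = 250)
  protocol_step_family(step_max = step_max, tail = 0.05)

# reference cohort at the study's per-type sample proportions
fixture_cohort <- function() memo("cohort", {
  make_cohort(c(type1 = 17, type2 = 3, type3 = 5), seed = 11)
})

# type1 excitability under the four contract conditions
fixture_contracts <- function() memo("contracts", {
  t1 <- make_presets()$type1
  t1_ca0 <- t1
  t1_ca0$ca_scale <- 0
  run <- function(spec, cond) {
    excitability_scalars(simulate_sweeps(spec, quick_steps(),
                                         condition = cond, seed = 7))
  }
  list(ctrl = run(t1, "control"), pax = run(t1, "paxilline"),
       bac = run(t1, "baclofen"),
       ctrl0 = run(t1_ca0, "control"), pax0 = run(t1_ca0, "paxilline"),
       bac0 = run(t1_ca0, "baclofen"))
})

# independent oracle: upward 0 mV crossing count with 1 ms refractory
oracle_spike_count <- function(v, sample_rate, refractory_ms = 1) {
  n <- length(v)
  up <- which(v[-n] < 0 & v[-1] >= 0) + 1L
  if (length(up) < 2L) return(length(up))
  ref <- refractory_ms * sample_rate / 1000
  kept <- up[1]; count <- 1L
  for (u in up[-1]) if (u - kept >= ref) { kept <- u; count <- count + 1L }
  count
}

# exhaustive greedy minimum-variance-increase (Ward) merge oracle
ward_oracle_merges <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  merges <- list()
  ess <- function(idx) {
    m <- x[idx, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  while (length(clusters) > 1L) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      cost <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (cost < best_cost) { best_cost <- cost; best <- c(j, i) }
    }
    merges[[length(merges) + 1L]] <-
      list(members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
           cost = best_cost)
    clusters[[best[2]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[1]]] <- NULL
  }
  merges
}

# membership sets of each hclust merge step
hclust_merge_sets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    members <- integer(0)
    for (side in hc$merge[k, ]) {
      members <- c(members,
                   if (side < 0) -side else sets[[side]])
    }
    sets[[k]] <- sort(members)
  }
  sets
}

match_events <- function(detected_s, truth_s, tol_s = 0.003) {
  vapply(truth_s, function(t) any(abs(detected_s - t) < tol_s), logical(1))
}
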