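#' Normality-gated paired comparison
#'
#' Two-stage procedure used for all within-cell drug comparisons: a
#' Shapiro-Wilk test on the paired differences at `alpha_gate`; if the
#' differences look normal a paired Student t test is used, otherwise the
#' Wilcoxon signed-rank test (exact distribution for n <= 25, normal
#' approximation with continuity correction above). The result records
#' which branch fired.
#'
#' @param pre,post equal-length paired value vectors, n >= 3.
#' @param alpha_gate gate level for the Shapiro-Wilk test (default 0.05).
#' @return object of class `comparison_result`: `test_name`, `statistic`,
#'   `p_value`, `shapiro_p`, `n`, `mean_pre`, `mean_post`, `sd_pre`,
#'   `sd_post`, `percent_change` (rounded) and
#'   `percent_change_exact`, plus a `degenerate` flag when all
#'   differences are zero (p reported as 1).
#' @export
paired_compare <- function(pre, post, alpha_gate = 0.05) {
  if (length(pre) != length(post))
    ephys_error("pre and post must be paired (equal length)",
                "stats_error")
  if (length(pre) < 3L) ephys_error("need n >= 3", "stats_error")
  d <- post - pre
  degenerate <- all(d == 0)
  if (degenerate) {
    res <- list(test_name = "degenerate (all differences zero)",
                statistic = NA_real_, p_value = 1, shapiro_p = NA_real_)
  } else if (length(unique(d)) == 1L) {
    # constant nonzero shift: Shapiro undefined; t test is exact here
    tt <- stats::t.test(post, pre, paired = TRUE)
    res <- list(test_name = "paired t test", statistic = unname(tt$statistic),
                p_value = tt$p.value, shapiro_p = NA_real_)
  } else {
    sw <- stats::shapiro.test(d)
    if (sw$p.value >= alpha_gate) {
      tt <- stats::t.test(post, pre, paired = TRUE)
      res <- list(test_name = "paired t test",
                  statistic = unname(tt$statistic),
                  p_value = tt$p.value, shapiro_p = sw$p.value)
    } else {
      # exact distribution for small n, unless ties/zeros force the
      # normal approximation anyway
      use_exact <- length(d) <= 25 && !any(d == 0) &&
        !anyDuplicated(abs(d[d != 0]))
      wt <- stats::wilcox.test(post, pre, paired = TRUE,
                               exact = use_exact, correct = TRUE)
      res <- list(test_name = "Wilcoxon signed-rank test",
                  statistic = unname(wt$statistic),
                  p_value = wt$p.value, shapiro_p = sw$p.value)
    }
  }
  pc <- if (mean(pre) != 0) percent_change(mean(pre), mean(post))
        else list(rounded = NA_real_, exact = NA_real_)
  structure(c(res, list(n = length(pre), mean_pre = mean(pre),
                        mean_post = mean(post), sd_pre = stats::sd(pre),
                        sd_post = stats::sd(post),
                        percent_change = pc$rounded,
                        percent_change_exact = pc$exact,
                        degenerate = degenerate)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (n = %d)\n", x$test_name, x$p_value, x$n))
  cat(sprintf("  %.4g +/- %.4g  ->  %.4g +/- %.4g  (%+d%%)\n",
              x$mean_pre, x$sd_pre, x$mean_post, x$sd_post,
              if (is.na(x$percent_change)) NA else x$percent_change))
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Normality-gated omnibus group comparison with post hoc tests
#'
#' Shapiro-Wilk on every group: if all groups pass at `alpha_gate`,
#' one-way ANOVA with Holm-Sidak-adjusted pairwise t tests; otherwise
#' Kruskal-Wallis with Dunn's pairwise test (Holm-adjusted). Groups with
#' n < 3 are excluded with a warning.
#'
#' @param groups named list of numeric vectors.
#' @param alpha_gate gate level per group (default 0.05).
#' @return a `comparison_result` with the omnibus test and a `posthoc`
#'   data frame (`pair`, `statistic`, `p_raw`, `p_adjusted`).
#' @export
group_compare <- function(groups, alpha_gate = 0.05) {
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  small <- vapply(groups, length, integer(1)) < 3L
  if (any(small)) {
    warning("excluding group(s) with n < 3: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) < 2L)
    ephys_error("need >= 2 groups with n >= 3", "stats_error")
  sw_p <- vapply(groups, function(g) {
    if (length(unique(g)) == 1L) return(0)  # constant: not normal
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  if (all(sw_p >= alpha_gate)) {
    fit <- stats::aov(values ~ fac)
    an <- summary(fit)[[1]]
    res <- list(test_name = "one-way ANOVA",
                statistic = an[["F value"]][1],
                p_value = an[["Pr(>F)"]][1])
    ph <- pairwise_t_holm_sidak(values, fac)
  } else {
    kw <- stats::kruskal.test(values, fac)
    res <- list(test_name = "Kruskal-Wallis test",
                statistic = unname(kw$statistic),
                p_value = kw$p.value)
    ph <- dunn_posthoc(values, fac)
  }
  structure(c(res, list(shapiro_p = sw_p, n = length(values),
                        mean_pre = NA_real_, mean_post = NA_real_,
                        percent_change = NA_real_, posthoc = ph)),
            class = "comparison_result")
}

# pairwise Welch t tests with Holm-Sidak step-down adjustment
pairwise_t_holm_sidak <- function(values, fac) {
  lv <- levels(fac)
  pairs <- utils::combn(lv, 2)
  stat <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    tt <- stats::t.test(values[fac == pairs[1, j]],
                        values[fac == pairs[2, j]])
    stat[j] <- unname(tt$statistic); p_raw[j] <- tt$p.value
  }
  data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
             statistic = stat, p_raw = p_raw,
             p_adjusted = holm_sidak_adjust(p_raw))
}

#' Holm-Sidak step-down p-value adjustment
#'
#' Sorted ascending, the i-th smallest of m p values is adjusted to
#' 1 - (1 - p)^(m - i + 1), with the running maximum enforcing
#' monotonicity; adjusted values are capped at 1 and never smaller than
#' the raw ones.
#'
#' @param p vector of raw p values.
#' @return adjusted p values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Dunn's rank-sum pairwise test after Kruskal-Wallis, tie-corrected,
# Holm-adjusted
dunn_posthoc <- function(values, fac) {
  r <- rank(values)
  n <- length(values)
  lv <- levels(fac)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_r <- tapply(r, fac, mean)
  n_g <- tapply(r, fac, length)
  pairs <- utils::combn(lv, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[a] + 1 / n_g[b]))
    z[j] <- (mean_r[a] - mean_r[b]) / se
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
             statistic = z, p_raw = p_raw,
             p_adjusted = stats::p.adjust(p_raw, "holm"))
}

#' Percent change between two group means
#'
#' 100 (post - pre)/pre, reported both at full precision and rounded to
#' the nearest integer (the convention used for the reported drug
#' effects).
#'
#' @param mean_pre,mean_post group means; `mean_pre` must be nonzero.
#' @return list with `exact` and `rounded` percent change.
#' @export
percent_change <- function(mean_pre, mean_post) {
  if (mean_pre == 0)
    ephys_error("percent change undefined for zero pre-mean",
                "stats_error")
  exact <- 100 * (mean_post - mean_pre) / mean_pre
  list(exact = exact, rounded = round(exact))
}
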