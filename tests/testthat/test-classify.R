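make_feature_df <- function(m, burst = NULL, rebound = NULL) {
  # wrap a numeric matrix as a feature data frame for prepare_matrix
  nm <- setdiff(feature_names(), c("rebound", "burst_or_adaptive"))
  df <- as.data.frame(matrix(m, nrow = nrow(m)))
  names(df) <- nm[seq_len(ncol(df))]
  for (missing in setdiff(nm, names(df))) df[[missing]] <- rnorm(nrow(m))
  df$rebound <- if (is.null(rebound)) rep(FALSE, nrow(m)) else rebound
  df$burst_or_adaptive <- if (is.null(burst)) rep("neither", nrow(m))
                          else burst
  df
}

test_that("prepared matrices are z-scored with encodings and imputation", {
  set.seed(5)
  df <- make_feature_df(matrix(rnorm(160, 50, 20), nrow = 10),
                        burst = sample(c("burst", "adaptive", "neither"),
                                       10, TRUE),
                        rebound = sample(c(TRUE, FALSE), 10, TRUE))
  df$tau[3] <- NA
  m <- prepare_matrix(df)
  expect_true(all(abs(colMeans(m)) < 1e-9))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-9))
  expect_true(all(c("burst", "adaptive") %in% colnames(m)))
  expect_equal(ncol(m), 19)
  expect_true(attr(m, "imputed")[3, "tau"])
  m18 <- prepare_matrix(df, encoding = "ordinal")
  expect_equal(ncol(m18), 18)
  # constant column dropped with a warning
  df$sag_amp <- 1
  expect_warning(m2 <- prepare_matrix(df), "constant")
  expect_false("sag_amp" %in% colnames(m2))
  # identical cells stay identical after scaling
  df2 <- make_feature_df(matrix(rnorm(64), nrow = 4),
                         burst = c("burst", "burst", "adaptive",
                                   "neither"),
                         rebound = c(TRUE, TRUE, FALSE, FALSE))
  df2[2, ] <- df2[1, ]
  m3 <- prepare_matrix(df2)
  expect_equal(m3[1, ], m3[2, ])
})

test_that("Ward clustering recovers well-separated blobs exactly", {
  set.seed(17)
  centers <- matrix(c(0, 0, 6, 0, 0, 6), ncol = 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:3, function(g)
    sweep(matrix(rnorm(40), ncol = 2), 2, centers[g, ], `+`)))
  truth <- rep(1:3, each = 20)
  cl <- ward_cluster(scale(x), k = 3)
  expect_equal(adjusted_rand_index(cl$labels, truth), 1.0)
  expect_true(all(diff(cl$hclust$height) >= -1e-9))
  expect_error(ward_cluster(scale(x), k = 100), class = "classify_error")
})

test_that("Ward merges equal the exhaustive minimum-variance oracle", {
  set.seed(23)
  for (n in c(6, 8)) {
    x <- matrix(rnorm(n * 3), ncol = 3)
    hc <- ward_cluster(x, k = 2)$hclust
    got <- hclust_merge_sets(hc)
    want <- ward_oracle_merges(x)
    for (k in seq_along(want))
      expect_equal(got[[k]], want[[k]]$members,
                   label = sprintf("n=%d merge %d", n, k))
    # ward.D2 heights are sqrt(2 x ESS increase)
    expect_equal(hc$height,
                 sqrt(2 * vapply(want, `[[`, numeric(1), "cost")),
                 tolerance = 1e-8)
  }
})

test_that("duplicated points merge at height zero", {
  x <- matrix(rnorm(12), ncol = 3)
  x <- rbind(x, x[1, ])
  hc <- ward_cluster(x, k = 2)$hclust
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
})

test_that("cluster labels are ordered by descending size", {
  coh <- fixture_cohort()
  m <- suppressWarnings(prepare_matrix(coh))
  cl <- ward_cluster(m, k = 3)
  expect_true(all(diff(cl$sizes) <= 0))
  expect_setequal(unique(cl$labels), 1:3)
})

test_that("row order does not change the Ward partition", {
  coh <- fixture_cohort()
  m <- suppressWarnings(prepare_matrix(coh))
  cl <- ward_cluster(m, k = 3)
  set.seed(2)
  perm <- sample(nrow(m))
  cl2 <- ward_cluster(m[perm, ], k = 3)
  expect_equal(adjusted_rand_index(cl2$labels, cl$labels[perm]), 1.0)
})

test_that("random-forest importance singles out the label-defining feature", {
  set.seed(9)
  x <- matrix(rnorm(600), ncol = 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  labels <- as.integer(x[, 1] > 0) + 1L
  rep1 <- rf_importance(x, labels, n_trees = 200, seed = 4)
  expect_equal(names(which.max(rep1$importance)), "f1")
  expect_equal(sum(rep1$importance), 1, tolerance = 1e-9)
  expect_true(all(rep1$importance >= 0))
  # determinism under the same seed
  rep2 <- rf_importance(x, labels, n_trees = 200, seed = 4)
  expect_identical(rep1, rep2)
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  set.seed(14)
  accs <- vapply(1:5, function(r) {
    x <- matrix(rnorm(400), ncol = 4)
    labels <- sample(rep(1:2, each = 50))
    rf_importance(x, labels, n_trees = 200, seed = r)$cv_accuracy
  }, numeric(1))
  # pooled over 5 x 100 held-out predictions: binomial 95% band around 1/2
  band <- qbinom(c(0.025, 0.975), 500, 0.5) / 500
  expect_gte(mean(accs), band[1] - 1e-9)
  expect_lte(mean(accs), band[2] + 1e-9)
  x <- matrix(rnorm(400), ncol = 4)
  rep1 <- rf_importance(x, sample(rep(1:2, each = 50)), n_trees = 100,
                        seed = 8)
  expect_equal(rep1$cv_method, "stratified 5-fold")
  # small classes flip to leave-one-out
  small <- rf_importance(x[1:12, ], rep(1:3, each = 4), n_trees = 100,
                         seed = 1)
  expect_equal(small$cv_method, "leave-one-out")
})

test_that("PCA loadings satisfy the closed-form correlated-pair axis", {
  set.seed(3)
  z <- rnorm(4000)
  x <- cbind(z + rnorm(4000, 0, sqrt((1 - 0.95) / 0.95)), z)
  x <- scale(cbind(x[, 1], x[, 2]))
  pc <- pca_map(x)
  expect_equal(sum(pc$explained_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$explained_fraction) <= 1e-12))
  angle <- acos(abs(sum(pc$loadings[, 1] * c(1, 1) / sqrt(2)))) * 180 / pi
  expect_lt(angle, 2)
  # sign convention: dominant loading positive
  expect_true(all(apply(pc$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("isotropic data spread variance evenly across components", {
  set.seed(8)
  x <- matrix(rnorm(6000), ncol = 3)
  pc <- pca_map(scale(x))
  expect_lt(diff(range(pc$explained_fraction)), 0.1)
})
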