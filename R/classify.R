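#' Standardize the feature matrix for clustering
#'
#' Encodes the two non-numeric features (rebound as 0/1;
#' burst-or-adaptive, by default, as two 0/1 dummy columns `burst` and
#' `adaptive`, or as a single ordinal column 0/0.5/1 for
#' neither/adaptive/burst under `encoding = "ordinal"`), imputes missing
#' values by the feature median (flagged in the `"imputed"` attribute),
#' z-scores every column over cells, and drops constant columns with a
#' warning. Features span four orders of magnitude (pA versus
#' dimensionless ratios), so Ward clustering is only meaningful on the
#' standardized matrix.
#'
#' @param features feature data frame (rows = cells) containing the
#'   columns of [feature_names()].
#' @param encoding `"dummy"` (default, 19 columns) or `"ordinal"` (strict
#'   18-column reading).
#' @return numeric matrix (cells x columns), each retained column with
#'   mean 0 and SD 1; attributes `"imputed"` (logical matrix) and
#'   `"dropped"` (names of constant columns).
#' @export
prepare_matrix <- function(features, encoding = c("dummy", "ordinal")) {
  encoding <- match.arg(encoding)
  if (nrow(features) < 2L)
    ephys_error("need >= 2 cells", "classify_error")
  num <- features[, setdiff(feature_names(),
                            c("rebound", "burst_or_adaptive")),
                  drop = FALSE]
  num$rebound <- as.numeric(features$rebound)
  cat_col <- features$burst_or_adaptive
  if (encoding == "dummy") {
    num$burst <- as.numeric(!is.na(cat_col) & cat_col == "burst")
    num$adaptive <- as.numeric(!is.na(cat_col) & cat_col == "adaptive")
  } else {
    num$burst_or_adaptive <- ifelse(is.na(cat_col), NA_real_,
                                    c(neither = 0, adaptive = 0.5,
                                      burst = 1)[cat_col])
  }
  m <- as.matrix(num)
  rownames(m) <- if ("cell_id" %in% names(features)) features$cell_id
                 else rownames(features)
  imputed <- is.na(m)
  for (j in seq_len(ncol(m)))
    if (any(imputed[, j]))
      m[imputed[, j], j] <- stats::median(m[, j], na.rm = TRUE)
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("dropping constant feature(s): ",
            paste(dropped, collapse = ", "))
    m <- m[, !(colnames(m) %in% dropped), drop = FALSE]
  }
  m <- scale(m)
  attr(m, "imputed") <- imputed
  attr(m, "dropped") <- dropped
  m
}

#' Ward hierarchical clustering of cells
#'
#' Agglomerative minimum-variance (Ward) clustering on Euclidean
#' distances; labels come from cutting the tree into `k` groups and are
#' renumbered by descending cluster size, so cluster 1 is always the
#' largest.
#'
#' @param m standardized matrix from [prepare_matrix()].
#' @param k number of clusters (default 3, per the three-type dendrogram
#'   cut).
#' @return object of class `cluster_result`: `hclust` tree, integer
#'   `labels` in 1..k, `k`, per-cluster `sizes` and `feature_means`.
#' @export
ward_cluster <- function(m, k = 3) {
  if (k > nrow(m))
    ephys_error("k exceeds the number of cells", "classify_error")
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  remap <- integer(k)
  remap[as.integer(names(sort(sizes, decreasing = TRUE)))] <- seq_len(k)
  labels <- remap[raw]
  fm <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(m[labels == g, , drop = FALSE])))
  rownames(fm) <- paste0("cluster", seq_len(k))
  structure(list(hclust = hc, labels = labels, k = k,
                 sizes = as.integer(table(labels)),
                 feature_means = fm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> Ward, k = %d; cluster sizes: %s\n",
              x$k, paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' @export
plot.cluster_result <- function(x, ...) {
  graphics::plot(x$hclust, labels = FALSE, hang = -1,
                 main = "Ward dendrogram", xlab = "", sub = "", ...)
  invisible(x)
}

#' Random-forest feature importance for cluster assignment
#'
#' Trains a random forest to predict the Ward cluster labels and reports
#' impurity (Gini) importances normalized to sum 1, plus a stratified
#' 5-fold cross-validated accuracy. When any class has fewer than 5
#' members the accuracy falls back to leave-one-out and the report is
#' flagged.
#'
#' @param m standardized matrix from [prepare_matrix()].
#' @param labels integer cluster labels.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed; the report is deterministic given it.
#' @return object of class `importance_report`: named `importance`
#'   (sums to 1), `cv_accuracy`, `cv_method`, `n_trees`, `seed`.
#' @export
rf_importance <- function(m, labels, n_trees = 500, seed = 1L) {
  labels <- as.factor(labels)
  set.seed(seed)
  rf <- randomForest::randomForest(x = m, y = labels, ntree = n_trees,
                                   importance = FALSE)
  imp <- rf$importance[, "MeanDecreaseGini"]
  imp <- imp / sum(imp)
  loo <- any(table(labels) < 5)
  folds <- if (loo) seq_len(nrow(m)) else stratified_folds(labels, 5, seed)
  pred <- factor(rep(NA_character_, nrow(m)), levels = levels(labels))
  for (f in unique(folds)) {
    tr <- folds != f
    set.seed(derive_seed(seed, f))
    fit <- randomForest::randomForest(x = m[tr, , drop = FALSE],
                                      y = labels[tr], ntree = n_trees)
    pred[!tr] <- stats::predict(fit, m[!tr, , drop = FALSE])
  }
  structure(list(importance = imp,
                 cv_accuracy = mean(pred == labels),
                 cv_method = if (loo) "leave-one-out" else
                   "stratified 5-fold",
                 n_trees = n_trees, seed = seed),
            class = "importance_report")
}

stratified_folds <- function(labels, k, seed) {
  set.seed(derive_seed(seed, 999L))
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' @export
print.importance_report <- function(x, digits = 3, ...) {
  cat(sprintf("<importance_report> %s accuracy %.1f%% (%d trees)\n",
              x$cv_method, 100 * x$cv_accuracy, x$n_trees))
  imp <- sort(x$importance, decreasing = TRUE)
  for (i in seq_len(min(6, length(imp))))
    cat(sprintf("  %-18s %.*f\n", names(imp)[i], digits, imp[i]))
  invisible(x)
}

#' PCA factor map of the feature matrix
#'
#' Principal axes of the standardized feature matrix. Loadings are signed
#' so that each component's largest-magnitude loading is positive; vector
#' direction and length in the loading (factor) map show how each
#' membrane property correlates with the components.
#'
#' @param m standardized matrix from [prepare_matrix()].
#' @return object of class `pca_result`: `loadings` (feature x
#'   component), `explained_fraction`, `scores` (cell x component).
#' @export
pca_map <- function(m) {
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  sco <- sweep(pc$x, 2, flip, `*`)
  structure(list(loadings = rot, explained_fraction = expl, scores = sco),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> explained variance:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained_fraction, 4)),
            collapse = ", "), "...\n")
  invisible(x)
}

#' @export
plot.pca_result <- function(x, comps = c(1, 2), ...) {
  ld <- x$loadings[, comps]
  graphics::plot(0, 0, type = "n", xlim = range(ld[, 1]) * 1.2,
                 ylim = range(ld[, 2]) * 1.2,
                 xlab = sprintf("PC%d (%.1f%%)", comps[1],
                                100 * x$explained_fraction[comps[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", comps[2],
                                100 * x$explained_fraction[comps[2]]),
                 main = "feature factor map", ...)
  graphics::arrows(0, 0, ld[, 1], ld[, 2], length = 0.06, col = "grey40")
  graphics::text(ld[, 1] * 1.08, ld[, 2] * 1.08, rownames(ld), cex = 0.7)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to label
#' renaming), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
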