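#' Coefficient-of-variation feature filter
#'
#' Removes low-variation features: a feature is kept when its coefficient
#' of variation, `100 * sd / |mean|`, is at least `cutoff_percent`. A zero
#' mean with positive SD is treated as infinite CV (kept); zero variance
#' gives CV 0 (removed at any positive cutoff). The filter is invariant
#' to positive rescaling of a feature.
#'
#' @param table a [feature_table()].
#' @param cutoff_percent minimum CV, in percent (default 30).
#' @return List with `table` (filtered [feature_table()]) and `report`
#'   (data.frame: feature, cv_percent, kept).
#' @export
cv_filter <- function(table, cutoff_percent = 30) {
  stopifnot(cutoff_percent >= 0)
  x <- unclass(table)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  cv <- ifelse(mu == 0, ifelse(s > 0, Inf, 0), 100 * s / abs(mu))
  keep <- cv >= cutoff_percent
  if (!any(keep)) warning("cv_filter removed every feature")
  report <- data.frame(feature = colnames(x), cv_percent = cv,
                       kept = keep, row.names = NULL)
  list(table = feature_table(x[, keep, drop = FALSE], rownames(x),
                             attr(table, "modality")),
       report = report)
}

#' Kruskal-Wallis differential-feature screen with FDR control
#'
#' Tests each feature for a location difference across groups with the
#' tie-corrected Kruskal-Wallis H statistic, adjusts p-values by
#' Benjamini-Hochberg, and keeps features with `q < fdr_level`. Features
#' constant across all samples get H = 0, p = 1.
#'
#' @param table a [feature_table()] (or numeric matrix).
#' @param labels group label per sample (>= 2 nonempty groups).
#' @param fdr_level BH false-discovery-rate threshold (default 0.05).
#' @return List with `selected` (feature names), and `report`
#'   (data.frame: feature, H, p, q, selected).
#' @export
kruskal_wallis_screen <- function(table, labels, fdr_level = 0.05) {
  x <- as.matrix(table)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) stop("need at least 2 groups")
  stats_per <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (max(v) == min(v)) return(c(0, 1))
    kt <- kruskal.test(v, labels)
    c(unname(kt$statistic), kt$p.value)
  }, numeric(2))
  h <- stats_per[1L, ]; p <- stats_per[2L, ]
  q <- p.adjust(p, method = "BH")
  sel <- q < fdr_level
  list(selected = colnames(x)[sel],
       report = data.frame(feature = colnames(x), H = h, p = p, q = q,
                           selected = sel, row.names = NULL))
}

#' Stability feature selection by penalized logistic regression
#'
#' Repeatedly splits the cohort (stratified by class), fits an
#' L1-penalized logistic regression on each training portion with the
#' penalty chosen by internal cross-validation, and records which
#' features receive nonzero coefficients. Features selected in at least
#' `freq_threshold` of the splits form the final candidate set.
#'
#' @param table a [feature_table()] or numeric matrix.
#' @param binary_labels two-class label vector.
#' @param n_splits number of random splits (default 100).
#' @param train_fraction training fraction per split (default 0.8).
#' @param freq_threshold minimum selection frequency (default 0.10).
#' @param seed RNG seed.
#' @param nfolds folds for the internal penalty cross-validation.
#' @return List with `selected` (feature names) and `frequency`
#'   (named numeric vector of per-feature selection frequencies).
#' @export
stability_select <- function(table, binary_labels, n_splits = 100L,
                             train_fraction = 0.8, freq_threshold = 0.10,
                             seed = 20240101L, nfolds = 5L) {
  x <- as.matrix(table)
  y <- as.factor(binary_labels)
  if (nlevels(droplevels(y)) != 2L) stop("labels must have exactly 2 classes")
  if (min(table(y)) < 5L) stop("each class needs at least 5 samples")
  set.seed(seed)
  counts <- setNames(numeric(ncol(x)), colnames(x))
  for (b in seq_len(n_splits)) {
    idx <- stratified_split(y, train_fraction)$train
    fit <- glmnet::cv.glmnet(x[idx, , drop = FALSE], y[idx],
                             family = "binomial", nfolds = nfolds,
                             standardize = TRUE)
    beta <- as.numeric(coef(fit, s = "lambda.min"))[-1L]
    counts[beta != 0] <- counts[beta != 0] + 1
  }
  freq <- counts / n_splits
  list(selected = names(freq)[freq >= freq_threshold & freq > 0],
       frequency = freq)
}
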