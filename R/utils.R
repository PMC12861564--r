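#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans p.adjust phyper qnorm pnorm pchisq pt quantile
#'   rnorm runif rbinom rexp rlnorm sd var cor aov anova coef predict
#'   complete.cases chisq.test kruskal.test t.test setNames dist
#' @importFrom utils read.csv write.csv head combn
#' @importFrom graphics image axis legend points par abline boxplot
NULL

# Euclidean projection of a vector onto the probability simplex
# (Duchi et al. 2008); used by the similarity-learning row updates.
project_simplex <- function(v) {
  n <- length(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_len(n) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# z-score columns; constant columns map to 0 rather than NaN
zscore <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, s, "/")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' used throughout the test-suite to score recovery of simulated subtypes.
#'
#' @param a,b label vectors of equal length.
#' @return Numeric scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

# stratified train/test split indices; returns list(train=, test=)
stratified_split <- function(y, train_fraction) {
  y <- as.factor(y)
  train <- unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    n_tr <- max(1L, round(length(idx) * train_fraction))
    if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
    sample(idx, n_tr)
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(seq_along(y), train)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
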