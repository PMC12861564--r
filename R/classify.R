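#' Fit a comparator classifier and score test samples
#'
#' The four benchmark learners used alongside the GA-tuned kernel PLS:
#' random forest (500 trees, sqrt(p) variables per split), L1-penalized
#' logistic regression (100-value penalty path, tenfold CV selection),
#' k-nearest neighbors (k = 1 by default), and Gaussian naive Bayes.
#' All return a continuous score for the positive class where the
#' method provides one (votes for kNN).
#'
#' @param method one of `"random_forest"`, `"l1_logistic"`, `"knn"`,
#'   `"naive_bayes"`.
#' @param train,test numeric feature matrices.
#' @param y binary 0/1 training labels (both classes present).
#' @param knn_k neighborhood size for kNN.
#' @return Numeric score vector, one per test row (higher = class 1).
#' @export
comparator_fit_predict <- function(method = c("random_forest", "l1_logistic",
                                              "knn", "naive_bayes"),
                                   train, y, test, knn_k = 1L) {
  method <- match.arg(method)
  train <- as.matrix(train); test <- as.matrix(test)
  if (length(unique(y)) < 2L) stop("a class is missing from training data")
  yf <- factor(y, levels = c(0, 1))
  switch(method,
    random_forest = {
      rf <- randomForest::randomForest(train, yf, ntree = 500L)
      unname(predict(rf, test, type = "prob")[, "1"])
    },
    l1_logistic = {
      if (ncol(train) == 1L) {   # glmnet requires >= 2 columns
        train <- cbind(train, 0); test <- cbind(test, 0)
      }
      cvfit <- glmnet::cv.glmnet(train, yf, family = "binomial",
                                 alpha = 1, nlambda = 100L, nfolds = 10L)
      as.numeric(predict(cvfit, test, s = "lambda.min", type = "response"))
    },
    knn = {
      pr <- class::knn(train, test, yf, k = knn_k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    naive_bayes = {
      nb <- e1071::naiveBayes(train, yf)
      unname(predict(nb, test, type = "raw")[, "1"])
    })
}

#' Binary classification metric battery
#'
#' From scores and true labels (threshold 0.5 by default) computes the
#' confusion counts and the eight metrics: AUC (rank formulation),
#' sensitivity, specificity, accuracy, Youden index (Se + Sp - 1),
#' F-measure, G-means (sqrt(Se * Sp)), and Matthews correlation
#' coefficient. Metrics with an undefined (zero) denominator are
#' reported as 0.
#'
#' @param y true 0/1 labels.
#' @param scores continuous scores (higher = class 1).
#' @param threshold classification threshold on the score.
#' @return One-row data.frame with `tp`, `fp`, `fn`, `tn` and the eight
#'   metrics.
#' @export
compute_metrics <- function(y, scores, threshold = 0.5) {
  stopifnot(length(y) == length(scores))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  safe <- function(num, den) if (den == 0) 0 else num / den
  se <- safe(tp, tp + fn); sp <- safe(tn, tn + fp)
  acc <- safe(tp + tn, tp + fp + fn + tn)
  prec <- safe(tp, tp + fp)
  fmeas <- if (prec + se == 0) 0 else 2 * prec * se / (prec + se)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             auc = rank_auc(y, scores), se = se, sp = sp, acc = acc,
             youden = se + sp - 1, f_measure = fmeas,
             g_means = sqrt(se * sp), mcc = mcc)
}

#' Repeated stratified-split evaluation of classifiers
#'
#' For each iteration the cohort is split (stratified, 80/20 by
#' default), every model is fit on the training part, scores the test
#' part, and the metric battery is recorded. Iterations on which a
#' model fails are redrawn.
#'
#' @param models named list of functions `f(train, y_train, test)`
#'   returning test scores (see [comparator_fit_predict()] and
#'   [gakpls_model()]).
#' @param x feature matrix; `y` binary 0/1 labels (both classes >= 5).
#' @param y labels.
#' @param n_iter iterations (the full study design uses 1000).
#' @param train_fraction training fraction per split.
#' @param seed RNG seed.
#' @return Named list of data.frames (`n_iter` rows of
#'   [compute_metrics()] output per model).
#' @export
resample_evaluate <- function(models, x, y, n_iter = 1000L,
                              train_fraction = 0.8, seed = 20240101L) {
  x <- as.matrix(x)
  if (min(table(y)) < 5L) stop("both classes need >= 5 samples")
  set.seed(seed)
  out <- lapply(models, function(m) vector("list", n_iter))
  it <- 0L; guard <- 0L
  while (it < n_iter) {
    guard <- guard + 1L
    if (guard > 10L * n_iter) stop("too many failed iterations")
    sp <- stratified_split(y, train_fraction)
    rows <- tryCatch(lapply(models, function(m) {
      sc <- m(x[sp$train, , drop = FALSE], y[sp$train],
              x[sp$test, , drop = FALSE])
      compute_metrics(y[sp$test], sc)
    }), error = function(e) NULL)
    if (is.null(rows)) next
    it <- it + 1L
    for (nm in names(models)) out[[nm]][[it]] <- rows[[nm]]
  }
  lapply(out, function(l) do.call(rbind, l))
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Compares each model's metric distribution against a reference model:
#' one-way ANOVA across models, then Dunnett's test with
#' multiplicity-adjusted p-values from the equal-correlation
#' multivariate t distribution (balanced design, correlation 1/2).
#'
#' @param metric_distributions named list of numeric vectors (equal
#'   length), or the output of [resample_evaluate()] plus `metric`.
#' @param reference name of the reference model (default `"GA-KPLS"`).
#' @param metric metric column to extract when data.frames are given.
#' @return List with `anova_f`, `anova_p`, and `comparisons`
#'   (data.frame: comparison, mean_diff, t, p_adj).
#' @export
dunnett_compare <- function(metric_distributions, reference = "GA-KPLS",
                            metric = "auc") {
  md <- metric_distributions
  if (is.data.frame(md[[1L]])) md <- lapply(md, function(d) d[[metric]])
  if (!reference %in% names(md)) stop("reference model not found")
  n_iter <- unique(lengths(md))
  if (length(n_iter) != 1L) stop("distributions must have equal length")
  k <- length(md)
  vals <- unlist(md, use.names = FALSE)
  grp <- factor(rep(names(md), each = n_iter), levels = names(md))
  av <- anova(aov(vals ~ grp))
  mse <- av["Residuals", "Mean Sq"]
  if (mse <= 0) stop("zero residual variance")
  dfree <- av["Residuals", "Df"]
  others <- setdiff(names(md), reference)
  m <- length(others)
  corr <- matrix(0.5, m, m); diag(corr) <- 1
  comp <- do.call(rbind, lapply(others, function(nm) {
    diff <- mean(md[[nm]]) - mean(md[[reference]])
    tstat <- diff / sqrt(2 * mse / n_iter)
    p_adj <- 1 - mvtnorm::pmvt(lower = rep(-abs(tstat), m),
                               upper = rep(abs(tstat), m),
                               corr = corr, df = as.integer(dfree))
    data.frame(comparison = paste(nm, "-", reference), mean_diff = diff,
               t = tstat, p_adj = as.numeric(p_adj))
  }))
  list(anova_f = av["grp", "F value"], anova_p = av["grp", "Pr(>F)"],
       comparisons = comp)
}

#' GA-tuned Gaussian-kernel PLS classifier
#'
#' The package's IDH-genotype model: the Gaussian kernel bandwidth (and
#' optionally the number of KPLS components) is tuned by a genetic
#' algorithm maximizing cross-validated AUC on the training data
#' ([ga_optimize()]); the final kernel PLS is then fit on all training
#' samples and its continuous output is calibrated to a probability by
#' logistic regression, with classification at 0.5.
#'
#' @param x training feature matrix.
#' @param y binary 0/1 labels.
#' @param sigma fixed bandwidth (skips GA tuning when given).
#' @param ncomp fixed component count (skips co-optimization when given
#'   together with `sigma`).
#' @param ... passed to [ga_optimize()] (population, generations, ...).
#' @param seed RNG seed.
#' @return Object of class `gakpls` with `kpls`, `sigma`, `ncomp`,
#'   `calibration` (glm), `ga` (tuning trace or NULL), `x_train`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(120), 60, 2)
#' y <- as.integer(rowSums(x^2) > 2)
#' fit <- gakpls(x, y, sigma = 1, ncomp = 3)
#' predict(fit, x)[1:3]
#' @export
gakpls <- function(x, y, sigma = NULL, ncomp = NULL, seed = 20240101L,
                   ...) {
  x <- as.matrix(x)
  ga <- NULL
  if (is.null(sigma) || is.null(ncomp)) {
    ga <- ga_optimize(x, y, seed = seed,
                      ncomp_range = if (is.null(ncomp)) 1:15 else ncomp,
                      ...)
    sigma <- sigma %||% ga$sigma
    ncomp <- ncomp %||% ga$ncomp
  }
  ncomp <- min(ncomp, nrow(x) - 1L)
  k <- gaussian_kernel(x, sigma = sigma)
  fit <- kpls_fit(k, y, ncomp)
  raw <- kpls_predict(fit, k)    # training scores, centered consistently
  # Platt-style calibration with smoothed targets; keeps the slope finite
  # (and the probability strictly monotone in the score) under perfect
  # separation of the training scores
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  target <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  calib <- suppressWarnings(
    stats::glm(target ~ raw, family = stats::quasibinomial()))
  structure(list(kpls = fit, sigma = sigma, ncomp = ncomp,
                 calibration = calib, ga = ga, x_train = x),
            class = "gakpls")
}

#' Predict method for GA-KPLS fits
#'
#' @param object a [gakpls()] fit.
#' @param newdata feature matrix.
#' @param type `"prob"` (calibrated probability), `"score"` (raw KPLS
#'   output) or `"class"` (0/1 at probability 0.5).
#' @param ... unused.
#' @return Numeric (or integer for `"class"`) vector.
#' @export
predict.gakpls <- function(object, newdata,
                           type = c("prob", "score", "class"), ...) {
  type <- match.arg(type)
  k <- gaussian_kernel(as.matrix(newdata), object$x_train, object$sigma)
  raw <- kpls_predict(object$kpls, k)
  if (type == "score") return(raw)
  pr <- as.numeric(predict(object$calibration,
                           data.frame(raw = raw), type = "response"))
  if (type == "class") as.integer(pr >= 0.5) else pr
}

#' @export
print.gakpls <- function(x, ...) {
  cat(sprintf("<gakpls> sigma = %.4g, %d components%s\n", x$sigma,
              x$ncomp,
              if (is.null(x$ga)) "" else
                sprintf(" (GA CV-AUC %.3f)", x$ga$fitness)))
  invisible(x)
}

#' @export
summary.gakpls <- function(object, ...) {
  print(object)
  if (!is.null(object$ga))
    cat("GA best-fitness trace:",
        paste(sprintf("%.3f", head(object$ga$history, 10)),
              collapse = " "), "...\n")
  invisible(object)
}

#' Model factory for resampling: GA-KPLS with fixed hyperparameters
#'
#' Returns a function `f(train, y, test)` suitable for
#' [resample_evaluate()], fitting a KPLS with the supplied bandwidth
#' and component count on each training split (the expensive GA tuning
#' is done once, up front, on the full training cohort).
#'
#' @param sigma,ncomp kernel bandwidth and component count.
#' @return A model function.
#' @export
gakpls_model <- function(sigma, ncomp) {
  force(sigma); force(ncomp)
  function(train, y, test) {
    fit <- gakpls(train, y, sigma = sigma, ncomp = ncomp)
    predict(fit, test, type = "prob")
  }
}

#' Model factories for the comparator classifiers
#'
#' @param method,knn_k see [comparator_fit_predict()].
#' @return A model function for [resample_evaluate()].
#' @export
comparator_model <- function(method, knn_k = 1L) {
  force(method); force(knn_k)
  function(train, y, test)
    comparator_fit_predict(method, train, y, test, knn_k = knn_k)
}
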