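test_that("gaussian_kernel matches direct formula evaluation", {
  x <- matrix(c(0, 0, 1, 2, 3, 1), 3, 2, byrow = TRUE)
  k <- gaussian_kernel(x, sigma = 1)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    oracle[i, j] <- exp(-sum((x[i, ] - x[j, ])^2) / 2)
  expect_equal(k, oracle, tolerance = 1e-12)
  expect_equal(diag(k), rep(1, 3))
  # sigma -> Inf limit: all-ones
  expect_equal(gaussian_kernel(x, sigma = 1e8),
               matrix(1, 3, 3), tolerance = 1e-10)
  expect_error(gaussian_kernel(x, sigma = 0), "positive")
  expect_error(gaussian_kernel(x, matrix(1, 2, 3)), "dimensions")
})

test_that("KPLS interpolates at saturation and extracts orthogonal scores", {
  set.seed(2)
  x <- matrix(rnorm(30 * 4), 30)
  y <- as.numeric(rowSums(x[, 1:2]) > 0)
  k <- gaussian_kernel(x, sigma = 2)
  f_full <- kpls_fit(k, y, 29)
  expect_lt(max(abs(kpls_predict(f_full, k) - y)), 1e-6)
  f5 <- kpls_fit(k, y, 5)
  gram <- crossprod(f5$scores)
  expect_lt(max(abs(gram - diag(5))), 1e-8)
  expect_error(kpls_fit(k, y, 30), "smaller than n")
  expect_error(kpls_fit(k, rep(1, 30), 3), "constant")
})

test_that("KPLS with a linear kernel reproduces linear NIPALS PLS", {
  set.seed(3)
  x <- matrix(rnorm(25 * 6), 25)
  y <- rnorm(25)
  f <- kpls_fit(tcrossprod(x), y, 4)
  # independent linear-PLS oracle on centered data
  xr <- scale(x, scale = FALSE); yr <- y - mean(y)
  t_oracle <- matrix(0, 25, 4)
  for (a in 1:4) {
    w <- crossprod(xr, yr)
    t_vec <- xr %*% w
    t_vec <- t_vec / sqrt(sum(t_vec^2))
    xr <- xr - t_vec %*% crossprod(t_vec, xr)
    yr <- yr - t_vec %*% crossprod(t_vec, yr)
    t_oracle[, a] <- t_vec
  }
  expect_lt(max(abs(abs(f$scores) - abs(t_oracle))), 1e-8)
})

test_that("rank-formula AUC equals trapezoidal ROC integration", {
  set.seed(4)
  for (i in 1:50) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    sc <- rnorm(40)
    a_rank <- gliotype:::rank_auc(y, sc)
    # trapezoidal oracle over the empirical ROC curve
    th <- c(Inf, sort(unique(sc), decreasing = TRUE), -Inf)
    tpr <- vapply(th, function(t) mean(sc[y == 1] >= t), 0)
    fpr <- vapply(th, function(t) mean(sc[y == 0] >= t), 0)
    a_trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(a_rank, a_trap, tolerance = 1e-10)
  }
  expect_equal(gliotype:::rank_auc(c(0, 1, 0, 1), rep(1, 4)), 0.5)
})

test_that("metric battery matches direct arithmetic", {
  y <- c(rep(1, 4), rep(0, 6))
  sc <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)  # TP=3 FP=1 FN=1 TN=5
  m <- compute_metrics(y, sc)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$se, 0.75)
  expect_equal(m$sp, 5 / 6, tolerance = 1e-4)
  expect_equal(m$acc, 0.8)
  expect_equal(m$youden, m$se + m$sp - 1, tolerance = 1e-12)
  expect_equal(m$f_measure, 0.75)
  expect_equal(m$mcc, 14 / 24, tolerance = 1e-12)
  expect_equal(m$g_means, sqrt(0.75 * 5 / 6), tolerance = 1e-12)
  # perfect classifier
  mp <- compute_metrics(y, y)
  expect_true(all(unlist(mp[c("auc", "se", "sp", "acc", "f_measure",
                              "g_means", "mcc")]) == 1))
  expect_equal(mp$youden, 1)
})

test_that("metric identities hold on random confusion configurations", {
  set.seed(6)
  for (i in 1:30) {
    y <- rbinom(30, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    sc <- runif(30)
    m <- compute_metrics(y, sc)
    expect_equal(m$youden, m$se + m$sp - 1, tolerance = 1e-12)
    expect_equal(m$g_means^2, m$se * m$sp, tolerance = 1e-12)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    expect_equal(m$tp + m$fn, sum(y))
  }
})

test_that("GA is deterministic and degenerates gracefully", {
  set.seed(7)
  x <- matrix(rnorm(60 * 3), 60)
  y <- as.integer(rowSums(x^2) > 3)
  g1 <- ga_optimize(x, y, population = 8, generations = 4, seed = 5)
  g2 <- ga_optimize(x, y, population = 8, generations = 4, seed = 5)
  expect_identical(g1[c("sigma", "ncomp")], g2[c("sigma", "ncomp")])
  # population 1, no crossover/mutation: the initial individual survives
  g3 <- ga_optimize(x, y, population = 1, generations = 3,
                    p_mutation = 0, p_crossover = 0, seed = 5)
  set.seed(5)
  invisible(as.matrix(dist(x))^2)
  expect_true(g3$sigma > 0 && g3$ncomp %in% 1:15)
  expect_error(ga_optimize(x, rep(1, 60)), "binary")
})

test_that("GA reaches at least 95% of the grid-search optimum", {
  set.seed(8)
  x <- matrix(rnorm(80 * 2), 80)
  y <- as.integer(rowSums(x^2) > qchisq(0.5, 2))
  med <- sqrt(median(as.matrix(dist(x))[upper.tri(diag(80))]^2))
  grid_best <- 0
  for (s in med * c(0.1, 0.25, 0.5, 1, 2, 5, 10)) for (nc in c(2L, 5L, 10L)) {
    set.seed(99)
    d2 <- as.matrix(dist(x))^2
    f <- gliotype:::.kpls_cv_auc(d2, y, s, nc, gliotype:::.make_folds(y, 5))
    grid_best <- max(grid_best, f)
  }
  ga <- ga_optimize(x, y, population = 12, generations = 10, seed = 99)
  expect_gte(ga$fitness, 0.95 * grid_best)
})

test_that("all comparators solve a perfectly separated problem", {
  set.seed(9)
  x <- matrix(c(rnorm(20, -5), rnorm(20, 5)), ncol = 1)
  y <- rep(0:1, each = 20)
  xt <- matrix(c(-4.5, 5.5, -6, 6), ncol = 1)
  yt <- c(0, 1, 0, 1)
  for (m in c("random_forest", "l1_logistic", "knn", "naive_bayes")) {
    sc <- comparator_fit_predict(m, x, y, xt)
    expect_equal(compute_metrics(yt, sc)$acc, 1)
  }
  expect_error(comparator_fit_predict("knn", x, rep(1, 40), xt), "missing")
})

test_that("resampling is reproducible and calibrated under label permutation", {
  set.seed(10)
  x <- matrix(rnorm(80 * 5), 80)
  y <- rbinom(80, 1, 0.5)   # labels independent of features
  models <- list(nb = comparator_model("naive_bayes"),
                 knn = comparator_model("knn"))
  r1 <- resample_evaluate(models, x, y, n_iter = 10, seed = 3)
  r2 <- resample_evaluate(models, x, y, n_iter = 10, seed = 3)
  expect_identical(r1, r2)
  mean_auc <- mean(r1$nb$auc)
  se_auc <- sd(r1$nb$auc) / sqrt(10)
  expect_lt(abs(mean_auc - 0.5), max(3 * se_auc, 0.12))
})

test_that("Dunnett comparison is conservative and matches a Monte-Carlo null", {
  set.seed(11)
  md <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30), d = rnorm(30, 1))
  res <- dunnett_compare(md, reference = "a", metric = NULL)
  # adjusted p >= unadjusted pairwise p
  for (i in seq_len(nrow(res$comparisons))) {
    t_i <- res$comparisons$t[i]
    p_raw <- 2 * pt(-abs(t_i), df = 4 * 30 - 4)
    expect_gte(res$comparisons$p_adj[i] + 1e-12, p_raw)
  }
  # identical distributions: all adjusted p near 1
  md0 <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  md0$b <- md0$a; md0$c <- md0$a
  res0 <- dunnett_compare(md0, reference = "a")
  expect_true(all(res0$comparisons$p_adj > 0.99))

  # Monte-Carlo max-|t| oracle for the shifted group's adjusted p
  t_obs <- res$comparisons$t[res$comparisons$comparison == "d - a"]
  mc <- vapply(1:4000, function(b) {
    g <- matrix(rnorm(4 * 30), 30)
    mse <- mean(apply(g, 2, var))
    max(abs(colMeans(g[, 2:4]) - mean(g[, 1])) / sqrt(2 * mse / 30))
  }, 0)
  p_mc <- mean(mc >= abs(t_obs))
  p_pkg <- res$comparisons$p_adj[res$comparisons$comparison == "d - a"]
  expect_lt(abs(p_pkg - p_mc), 0.03)
})

test_that("gakpls fits, predicts and beats a linear model on a radial signal", {
  set.seed(12)
  x <- matrix(rnorm(150 * 2), 150)
  y <- as.integer(rowSums(x^2) > qchisq(0.5, 2))
  fit <- gakpls(x[1:100, ], y[1:100], sigma = 1.5, ncomp = 4)
  pr <- predict(fit, x[101:150, ])
  expect_true(all(pr >= 0 & pr <= 1))
  auc_k <- gliotype:::rank_auc(y[101:150], pr)
  sc_l <- comparator_fit_predict("l1_logistic", x[1:100, ], y[1:100],
                                 x[101:150, ])
  auc_l <- gliotype:::rank_auc(y[101:150], sc_l)
  expect_gt(auc_k, auc_l + 0.1)
  cls <- predict(fit, x[101:150, ], type = "class")
  expect_true(all(cls %in% 0:1))
})
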