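test_that("chi-square handles homogeneous and degenerate tables", {
  res <- chi_square_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_warning(res2 <- chi_square_test(cbind(c(5, 3), c(10, 6), c(0, 0))),
                 "zero")
  expect_equal(res2$df, 1)
  expect_error(chi_square_test(matrix(0, 2, 2)), "invalid")
})

test_that("Mann-Whitney matches exhaustive enumeration", {
  res <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$U, 0)
  # exact two-sided p by enumerating all 20 rank arrangements
  combos <- combn(6, 3)
  u_all <- apply(combos, 2, function(ix) sum(ix) - 6)
  p_exact <- mean(abs(u_all - 4.5) >= abs(0 - 4.5)) # U symmetric about 4.5
  expect_equal(p_exact, 0.1)

  # same multiset in both samples: Z ~ 0
  res0 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_lt(abs(res0$Z), 0.5)
  # all values tied
  rest <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_identical(rest$Z, 0)
  expect_identical(rest$p, 1)
})

test_that("normal approximation tracks exact enumeration at n = m = 8", {
  # the exact null distribution of U is universal for untied data, so
  # compare across every achievable U with a non-extreme p-value
  u_all <- apply(combn(16, 8), 2, function(ix) sum(ix) - 36)
  for (u in 0:32) {
    p_exact <- mean(abs(u_all - 32) >= abs(u - 32) - 1e-9)
    if (p_exact < 0.05) next
    z <- (u - 32 - sign(u - 32) * 0.5) / sqrt(8 * 8 * 17 / 12)
    p_norm <- 2 * pnorm(-abs(z))
    expect_lt(abs(p_norm - p_exact) / p_exact, 0.05)
  }
  # and the package agrees with that formula on real data
  set.seed(19)
  xs <- rnorm(8); ys <- rnorm(8, 0.5)
  res <- mann_whitney(xs, ys)
  z <- (res$U - 32 - sign(res$U - 32) * 0.5) / sqrt(8 * 8 * 17 / 12)
  expect_equal(res$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("log-rank statistic matches a hand-computed six-subject example", {
  os <- c(1, 2, 3, 4, 5, 6); ev <- rep(1, 6)
  grp <- rep(c("A", "B"), each = 3)
  res <- km_logrank(os, ev, grp)
  # direct O-E / V computation over the six event times
  at_risk_a <- c(3, 2, 1, 0, 0, 0); at_risk <- 6:1
  o_a <- c(1, 1, 1, 0, 0, 0)
  e_a <- at_risk_a / at_risk
  v <- at_risk_a / at_risk * (1 - at_risk_a / at_risk) *
    (at_risk - 1) / pmax(at_risk - 1, 1)
  chisq_oracle <- sum(o_a - e_a)^2 / sum(v[at_risk > 1])
  expect_equal(res$chisq, chisq_oracle, tolerance = 1e-6)
  # identical groups: statistic ~ 0
  res0 <- km_logrank(c(os, os), c(ev, ev), rep(c("A", "B"), each = 6))
  expect_lt(res0$chisq, 1e-10)
})

test_that("subtype survival difference is detected at hazard ratio 2", {
  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(sim_cohort_spec(n_samples = 246, seed = 100 + s))
    km_logrank(co$clinical$os_days, co$clinical$event, co$labels)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("cox_fit recovers a known hazard ratio and rejects bad input", {
  set.seed(5)
  g <- rbinom(2000, 1, 0.5)
  os <- rexp(2000, ifelse(g == 1, 2, 1) / 1000)
  ev <- as.integer(os < 2000); os <- pmin(os, 2000)
  cf <- cox_fit(os, ev, data.frame(grp = g))
  expect_gt(cf$hr, 1.8); expect_lt(cf$hr, 2.2)
  expect_true(cf$hr_lo < cf$hr & cf$hr < cf$hr_hi)
  expect_error(cox_fit(os, ev, data.frame(c1 = rep(1, 2000))), "constant")
})

test_that("a survival-independent covariate has ~95% CI coverage", {
  cover <- vapply(1:60, function(s) {
    set.seed(s)
    x <- rbinom(150, 1, 0.5)
    os <- rexp(150, 1 / 500); ev <- as.integer(os < 1200)
    cf <- cox_fit(pmin(os, 1200), ev, data.frame(x = x))
    cf$hr_lo <= 1 && 1 <= cf$hr_hi
  }, TRUE)
  expect_gte(mean(cover), 0.85)
})

test_that("the cohort Cox table uses the canonical reference coding", {
  co <- shared_cohort()
  tab <- cox_subtype_table(co$clinical, co$labels, high_level = 1)
  expect_setequal(tab$term, c("subtype_high", "age_ge", "gender_male",
                              "grade3", "grade4", "volume_ge"))
  expect_gt(tab$hr[tab$term == "subtype_high"], 1)
})

test_that("point-biserial correlation reaches its closed-form extreme", {
  labels <- rep(0:1, each = 10)
  vol <- c(rep(1, 10), rep(2, 10))
  res <- subtype_volume_correlation(labels, vol)
  expect_equal(abs(res$r), 1, tolerance = 1e-12)
  # identical distributions: r = 0
  expect_equal(subtype_volume_correlation(labels, rep(c(1, 2), 10))$r, 0)
  expect_error(subtype_volume_correlation(labels, rep(1, 20)), "variance")
  # cohort sign convention: larger tumors in subtype 1 (high risk)
  co <- shared_cohort()
  r <- subtype_volume_correlation(co$labels, co$clinical$tumor_volume_cm3)$r
  expect_lt(r, 0)
  expect_true(res$ci[1] <= res$r && res$r <= res$ci[2])
})

test_that("mlm pathway scores equal a brute-force normal-equations fit", {
  set.seed(30)
  w <- matrix(rnorm(50 * 3), 50, 3,
              dimnames = list(paste0("g", 1:50), c("P1", "P2", "P3")))
  e <- matrix(rnorm(4 * 50), 4, 50, dimnames = list(NULL, paste0("g", 1:50)))
  sc <- pathway_scores_mlm(e, w)
  for (i in 1:4) {
    fit <- lm(e[i, ] ~ w)
    expect_equal(unname(sc[i, ]),
                 unname(summary(fit)$coefficients[-1, "t value"]),
                 tolerance = 1e-9)
  }
})

test_that("pathway scores are calibrated under the null and explode under exact fit", {
  set.seed(31)
  w <- matrix(rnorm(300 * 14), 300, 14,
              dimnames = list(paste0("g", 1:300), gliotype:::.pathways))
  e_null <- matrix(rnorm(40 * 300), 40, 300,
                   dimnames = list(NULL, rownames(w)))
  sc <- pathway_scores_mlm(e_null, w)
  expect_gt(mean(abs(sc) < 3), 0.97)
  # expression proportional to one weight column: that pathway dominates
  e_exact <- matrix(rep(w[, 5], 3), 3, byrow = TRUE,
                    dimnames = list(NULL, rownames(w)))
  e_exact <- e_exact + matrix(rnorm(length(e_exact), sd = 1e-8), 3)
  sc2 <- pathway_scores_mlm(e_exact, w)
  expect_true(all(sc2[, 5] > 100 * apply(abs(sc2[, -5]), 1, max)))
})

test_that("group comparison is antisymmetric in the group labeling", {
  set.seed(32)
  sc <- matrix(rnorm(40 * 14), 40, 14,
               dimnames = list(NULL, gliotype:::.pathways))
  class(sc) <- c("pathway_scores", class(sc))
  g <- rep(1:2, each = 20)
  c1 <- pathway_group_compare(sc, g, high = 1)
  c2 <- pathway_group_compare(sc, g, high = 2)
  expect_equal(c1$t, -c2$t, tolerance = 1e-12)
  expect_equal(c1$p, c2$p, tolerance = 1e-12)
})

test_that("hypergeometric p equals exhaustive enumeration on a small cohort", {
  # cohort of 12, cluster of 5, feature altered in 6, 4 of them in-cluster
  p_pkg <- phyper(4 - 1, 6, 6, 5, lower.tail = FALSE)
  combos <- combn(12, 5)
  altered <- 1:6
  k_in <- apply(combos, 2, function(ix) sum(ix %in% altered))
  expect_equal(p_pkg, mean(k_in >= 4), tolerance = 1e-12)

  # and the worked 30-sample case: 12 altered, 9 of 10 in-cluster
  p30 <- sum(vapply(9:10, function(x)
    choose(12, x) * choose(18, 10 - x), 0)) / choose(30, 10)
  expect_equal(phyper(8, 12, 18, 10, lower.tail = FALSE), p30,
               tolerance = 1e-12)
})

test_that("enrichment respects the fraction filters and count consistency", {
  set.seed(33)
  labels <- rep(1:2, c(10, 30))
  x <- matrix(rnorm(40 * 6), 40, 6)
  x[labels == 1, 1] <- x[labels == 1, 1] + 5    # planted in small cluster
  en <- radiomic_enrichment(x, labels)
  expect_true(all(en$k_in <= pmin(en$cluster_size, en$k_total)))
  hit <- en[en$feature == "f1" & en$cluster == 1 & en$direction == "over", ]
  expect_true(hit$significant)
  # uniform alteration passes nothing
  en0 <- radiomic_enrichment(matrix(rnorm(40 * 6), 40, 6), labels)
  expect_false(any(en0$significant[en0$feature != "f1"] &
                     !en0$passes_fraction_filter[en0$feature != "f1"]))
  expect_true(all(en0$q >= en0$p - 1e-12))
})

test_that("planted cluster-specific shifts are recovered with high sensitivity", {
  co <- simulate_cohort(sim_cohort_spec(n_samples = 150,
                                        proportions = c(0.25, 0.75),
                                        delta = 3 * sqrt(2), seed = 13))
  en <- radiomic_enrichment(co$tables$T1CE, co$labels)
  planted <- grep("_inf_", colnames(co$tables$T1CE), value = TRUE)
  detected <- unique(en$feature[en$significant])
  sens <- mean(planted %in% detected)
  fdr <- if (length(detected)) mean(!detected %in% planted) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("statistics are invariant to sample-order permutation", {
  co <- shared_cohort()
  set.seed(34)
  perm <- sample(nrow(co$clinical))
  r1 <- km_logrank(co$clinical$os_days, co$clinical$event, co$labels)
  r2 <- km_logrank(co$clinical$os_days[perm], co$clinical$event[perm],
                   co$labels[perm])
  expect_equal(r1$chisq, r2$chisq, tolerance = 1e-10)
  m1 <- mann_whitney(co$clinical$tumor_volume_cm3[co$labels == 1],
                     co$clinical$tumor_volume_cm3[co$labels == 2])
  x1 <- co$clinical$tumor_volume_cm3[co$labels == 1]
  m2 <- mann_whitney(sample(x1),
                     co$clinical$tumor_volume_cm3[co$labels == 2])
  expect_equal(m1$Z, m2$Z, tolerance = 1e-10)
})
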