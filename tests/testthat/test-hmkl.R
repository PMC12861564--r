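test_that("kernel bank entries match direct evaluation of the formula", {
  x <- matrix(c(0, 0, 1, 0, 0, 2, 3, 3), 4, 2, byrow = TRUE)
  rownames(x) <- paste0("p", 1:4)
  bank <- build_kernel_bank(x, sigma_grid = 1, k_grid = 1L,
                            standardize = FALSE)
  d <- as.matrix(dist(x))
  mu <- vapply(1:4, function(i) min(d[i, -i]), 0)   # k = 1 nearest neighbor
  k_oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    eps <- (mu[i] + mu[j]) / 2
    k_oracle[i, j] <- exp(-d[i, j]^2 / (2 * eps^2))
  }
  k_oracle <- (k_oracle + t(k_oracle)) / 2
  dimnames(k_oracle) <- dimnames(bank$kernels[[1]])
  expect_equal(bank$kernels[[1]], k_oracle, tolerance = 1e-12)
})

test_that("duplicate samples attain the maximal kernel value of 1", {
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 1), c(2, 7))
  rownames(x) <- paste0("p", 1:5)
  bank <- build_kernel_bank(x, sigma_grid = c(1, 2), k_grid = 2L,
                            standardize = FALSE)
  for (k in bank$kernels) {
    expect_equal(k[1, 2], 1)
    expect_equal(max(k), 1)
  }
})

test_that("default grids yield 35 kernels and k >= n errors", {
  co <- shared_cohort()
  bank <- build_kernel_bank(co$tables$T1CE)
  expect_length(bank$kernels, 35L)
  expect_true(all(vapply(bank$kernels,
                         function(k) max(abs(k - t(k))), 0) < 1e-10))
  expect_error(build_kernel_bank(matrix(rnorm(20), 5), k_grid = 5L),
               "smaller than n")
})

test_that("identical kernels force uniform kernel weights", {
  set.seed(1)
  x <- matrix(rnorm(40 * 5), 40)
  rownames(x) <- paste0("s", 1:40)
  bank <- build_kernel_bank(x, sigma_grid = c(1, 1), k_grid = 5L)
  st <- suppressWarnings(cimlr_stage1(bank, 2))
  expect_equal(unname(st$w), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("stage-1 objective is monotone non-increasing and S near block-diagonal on blobs", {
  bl <- two_blobs()
  bank <- build_kernel_bank(bl$x, k_grid = c(5L, 10L))
  st <- suppressWarnings(cimlr_stage1(bank, 2))
  expect_true(all(diff(st$objective) <= 1e-8))
  same <- outer(bl$labels, bl$labels, "==") & !diag(TRUE, 40)
  ratio <- mean(st$S[same]) / mean(st$S[!same & !diag(TRUE, 40)])
  expect_gt(ratio, 10)
  expect_lt(max(abs(st$S - t(st$S))), 1e-10)
})

test_that("fusion weights respect symmetry and informativeness", {
  bl <- two_blobs()
  bank <- build_kernel_bank(bl$x, k_grid = c(5L, 10L))
  st <- suppressWarnings(cimlr_stage1(bank, 2))
  # identical modalities share the weight equally
  fu <- umkl_fuse(list(a = st$S, b = st$S))
  expect_equal(unname(fu$beta), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(rv_coefficient(st$S, st$S), 1)
  # an uninformative (pure noise) modality gets strictly less weight
  set.seed(2)
  noise <- matrix(rnorm(40 * 4), 40)
  rownames(noise) <- rownames(bl$x)
  stn <- suppressWarnings(
    cimlr_stage1(build_kernel_bank(noise, k_grid = c(5L, 10L)), 2))
  fu2 <- umkl_fuse(list(inf = st$S, noise = stn$S))
  expect_gt(fu2$beta[["inf"]], fu2$beta[["noise"]])
  expect_equal(sum(fu2$beta), 1)
  # single modality passthrough
  fu1 <- umkl_fuse(list(st$S))
  expect_identical(fu1$beta, 1)
})

test_that("exact block-diagonal similarity is recovered perfectly", {
  s <- matrix(0.01, 30, 30)
  s[1:12, 1:12] <- 1
  s[13:30, 13:30] <- 1
  cl <- cluster_fused(s, 2, seed = 1)
  expect_equal(ari(cl$labels, rep(1:2, c(12, 18))), 1)
  # relabeling leaves ARI unchanged
  expect_equal(ari(3 - cl$labels, rep(1:2, c(12, 18))), 1)
})

test_that("the full pipeline is deterministic and fuses both modalities", {
  co <- shared_cohort()
  f1 <- shared_fit()
  f2 <- suppressWarnings(hmkl(co$tables, k = 2, seed = 42))
  expect_identical(f1$labels, f2$labels)
  expect_equal(f1$modality_weights, f2$modality_weights)
  expect_equal(sum(f1$modality_weights), 1)
  expect_lt(max(abs(f1$S_fused - t(f1$S_fused))), 1e-10)
  expect_true(all(table(f1$labels) > 0))
  expect_gt(ari(f1$labels, co$labels), 0.9)
})

test_that("fused clustering does not fall below the best single modality", {
  co <- shared_cohort()
  fused_ari <- ari(shared_fit()$labels, co$labels)
  singles <- vapply(co$tables, function(t) {
    f <- suppressWarnings(hmkl(list(t), k = 2, seed = 42))
    ari(f$labels, co$labels)
  }, 0)
  expect_gte(fused_ari, max(singles) - 0.02)
})

test_that("mismatched sample orders fail loudly", {
  co <- shared_cohort()
  t2 <- co$tables$T2FLAIR[rev(seq_len(nrow(co$tables$T2FLAIR))), ]
  expect_error(hmkl(list(co$tables$T1CE, t2), k = 2), "mismatched")
})
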