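# Out-of-sample extension: a new sample's spectral coordinates are the
# cross-similarity-weighted average of the training embedding rows
# (exact for an ideal block-constant embedding), re-scaled to unit norm
# to match the training embedding convention.
.embed_new <- function(fit, cross) {
  p <- cross / pmax(rowSums(cross), .Machine$double.eps)
  emb <- p %*% fit$embedding
  emb / pmax(sqrt(rowSums(emb^2)), .Machine$double.eps)
}

# fused cross-similarity of new samples against training samples, using
# the training fit's learned kernel weights and modality weights
.cross_similarity <- function(fit, train_tables, new_tables,
                              sigma_grid, k_grid) {
  m <- length(train_tables)
  cross <- NULL
  for (i in seq_len(m)) {
    tr <- as.matrix(train_tables[[i]]); te <- as.matrix(new_tables[[i]])
    joint <- zscore(rbind(tr, te))
    n_tr <- nrow(tr)
    bank <- build_kernel_bank(joint, sigma_grid, k_grid,
                              standardize = FALSE)
    w <- fit$stage1[[i]]$w
    kw <- Reduce(`+`, Map(`*`, lapply(bank$kernels, .normalize_kernel), w))
    block <- kw[(n_tr + 1L):nrow(joint), seq_len(n_tr), drop = FALSE]
    bm <- fit$modality_weights[i] * block
    cross <- if (is.null(cross)) bm else cross + bm
  }
  # keep each test row's nearest training neighborhood; the raw kernel
  # is weakly contrastive in high dimension, the neighbor set is not
  kk <- min(max(k_grid), ncol(cross) - 1L)
  t(apply(cross, 1L, function(r) {
    r[rank(-r, ties.method = "first") > kk] <- 0
    r
  }))
}

#' Clustering prediction index over a range of cluster counts
#'
#' For each candidate k, the cohort is repeatedly split; the hMKL
#' pipeline is fit on the training portion, held-out samples are
#' projected into the training spectral embedding (Nystrom extension of
#' the fused similarity) and assigned to the nearest training-cluster
#' centroid; the repeat's score is `1 - WSS_test / TSS_test`. CPI(k) is
#' the mean over repeats (higher is better).
#'
#' @param tables named list of aligned [feature_table()]s.
#' @param k_range candidate cluster counts.
#' @param n_repeats split repeats per k (default 20).
#' @param test_fraction held-out fraction (default 0.3).
#' @param seed RNG seed.
#' @param sigma_grid,k_grid kernel grids; the neighbor grid is capped
#'   below the training-set size automatically.
#' @param ... passed to [cimlr_stage1()].
#' @return Named numeric vector of CPI values, one per k.
#' @export
cpi <- function(tables, k_range = 2:8, n_repeats = 20L,
                test_fraction = 0.3, seed = 20240101L,
                sigma_grid = seq(1, 2.5, by = 0.25),
                k_grid = seq(10L, 30L, by = 5L), ...) {
  n <- nrow(tables[[1L]])
  if (any(k_range < 2L) || any(k_range > n / 3))
    stop("k_range must lie within [2, n/3]")
  set.seed(seed)
  splits <- lapply(seq_len(n_repeats), function(b)
    sample(n, round(n * test_fraction)))
  vals <- vapply(k_range, function(k) {
    scores <- vapply(splits, function(test_idx) {
      train_idx <- setdiff(seq_len(n), test_idx)
      kg <- k_grid[k_grid < length(train_idx)]
      tr <- lapply(tables, function(t) as.matrix(t)[train_idx, , drop = FALSE])
      te <- lapply(tables, function(t) as.matrix(t)[test_idx, , drop = FALSE])
      fit <- hmkl(tr, k, sigma_grid, kg, seed = seed, n_restarts = 20L, ...)
      cross <- .cross_similarity(fit, tr, te, sigma_grid, kg)
      emb <- .embed_new(fit, cross)
      dists <- outer(rowSums(emb^2), rowSums(fit$centers^2), "+") -
        2 * emb %*% t(fit$centers)
      assign <- max.col(-dists)
      wss <- sum((emb - fit$centers[assign, , drop = FALSE])^2)
      tss <- sum(sweep(emb, 2, colMeans(emb))^2)
      if (tss <= .Machine$double.eps) 1 else 1 - wss / tss
    }, 0)
    mean(scores)
  }, 0)
  setNames(vals, k_range)
}

#' Gap statistic over a range of cluster counts
#'
#' Tibshirani's gap: `Gap(k) = mean_b log(WSS_ref_b(k)) - log(WSS_obs(k))`
#' with reference datasets drawn uniformly over the feature-wise range
#' box of the concatenated standardized features, and the standard error
#' `sd_b(log WSS_ref) * sqrt(1 + 1/B)`.
#'
#' @param tables named list of aligned feature tables (concatenated and
#'   z-scored internally), or a single matrix.
#' @param k_range candidate cluster counts.
#' @param n_refs number of reference draws (default 50).
#' @param seed RNG seed.
#' @param nstart K-means restarts for each WSS evaluation.
#' @return data.frame with columns `k`, `gap`, `se`.
#' @export
gap_statistic <- function(tables, k_range = 2:8, n_refs = 50L,
                          seed = 20240101L, nstart = 10L) {
  x <- if (is.list(tables))
    do.call(cbind, lapply(tables, as.matrix)) else as.matrix(tables)
  x <- zscore(x)
  set.seed(seed)
  wss_of <- function(data, k)
    kmeans(data, k, nstart = nstart, iter.max = 50L)$tot.withinss
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  refs <- lapply(seq_len(n_refs), function(b) {
    r <- matrix(runif(length(x)), nrow(x), ncol(x))
    sweep(sweep(r, 2, hi - lo, "*"), 2, lo, "+")
  })
  res <- t(vapply(k_range, function(k) {
    log_obs <- log(wss_of(x, k))
    log_ref <- vapply(refs, wss_of, 0, k = k)
    log_ref <- log(log_ref)
    c(gap = mean(log_ref) - log_obs,
      se = sd(log_ref) * sqrt(1 + 1 / n_refs))
  }, c(gap = 0, se = 0)))
  data.frame(k = k_range, gap = res[, "gap"], se = res[, "se"])
}

#' Choose the cluster count maximizing CPI + Gap
#'
#' @param cpi_values named numeric vector from [cpi()].
#' @param gap_values data.frame from [gap_statistic()] (or a numeric
#'   vector over the same k range).
#' @return The selected k; ties break toward the smaller k.
#' @export
select_k <- function(cpi_values, gap_values) {
  gap <- if (is.data.frame(gap_values)) gap_values$gap else gap_values
  if (length(gap) != length(cpi_values))
    stop("CPI and Gap must cover the same k range")
  ks <- as.integer(names(cpi_values) %||% seq_along(cpi_values))
  total <- cpi_values + gap
  ks[order(-total, ks)][1L]
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio
#' `(S_i + S_j) / M_ij`, where `S_i` is the average distance of cluster
#' i's points to their centroid and `M_ij` the distance between
#' centroids. Lower is better.
#'
#' @param x numeric matrix (samples x dims), e.g. a spectral embedding.
#' @param labels cluster assignment.
#' @return Numeric scalar.
#' @export
dbi <- function(x, labels) {
  x <- as.matrix(x)
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop("need at least 2 clusters")
  if (all(tabulate(match(labels, cl)) == 1L))
    stop("all clusters are singletons")
  cent <- t(vapply(cl, function(g) colMeans(x[labels == g, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_along(cl), function(i) {
    pts <- x[labels == cl[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[i, ])^2)))
  }, 0)
  m <- as.matrix(dist(cent))
  r <- vapply(seq_along(cl), function(i) {
    max(vapply(setdiff(seq_along(cl), i),
               function(j) (s[i] + s[j]) / m[i, j], 0))
  }, 0)
  mean(r)
}

#' Calinski-Harabasz index
#'
#' `(B / (k - 1)) / (W / (n - k))` with between- and within-cluster
#' scatter B and W. Higher is better.
#'
#' @inheritParams dbi
#' @return Numeric scalar.
#' @export
ch_index <- function(x, labels) {
  x <- as.matrix(x)
  cl <- sort(unique(labels))
  k <- length(cl); n <- nrow(x)
  if (k < 2L) stop("need at least 2 clusters")
  gm <- colMeans(x)
  cent <- t(vapply(cl, function(g) colMeans(x[labels == g, , drop = FALSE]),
                   numeric(ncol(x))))
  sizes <- tabulate(match(labels, cl))
  b <- sum(sizes * rowSums(sweep(cent, 2, gm)^2))
  w <- sum(vapply(seq_along(cl), function(i)
    sum(sweep(x[labels == cl[i], , drop = FALSE], 2, cent[i, ])^2), 0))
  (b / (k - 1)) / (w / (n - k))
}

#' Select the number of subtypes for a multimodal cohort
#'
#' Runs [cpi()] and [gap_statistic()] over `k_range`, picks
#' `k* = argmax(CPI + Gap)` ([select_k()]), and reports the
#' Davies-Bouldin and Calinski-Harabasz indices of the full-cohort hMKL
#' clustering at each k as confirmatory diagnostics.
#'
#' @inheritParams cpi
#' @param n_refs gap-statistic reference draws.
#' @return Object of class `k_selection`: list with `table` (k, cpi,
#'   gap, total, dbi, ch), `k_star`, and the hmkl `fits` per k.
#' @export
choose_k <- function(tables, k_range = 2:8, n_repeats = 20L,
                     test_fraction = 0.3, n_refs = 50L,
                     seed = 20240101L,
                     sigma_grid = seq(1, 2.5, by = 0.25),
                     k_grid = seq(10L, 30L, by = 5L), ...) {
  cpi_v <- cpi(tables, k_range, n_repeats, test_fraction, seed,
               sigma_grid, k_grid, ...)
  gap_v <- gap_statistic(tables, k_range, n_refs, seed)
  fits <- lapply(k_range, function(k)
    hmkl(tables, k, sigma_grid, k_grid, seed = seed, ...))
  dbi_v <- vapply(fits, function(f) dbi(f$embedding, f$labels), 0)
  ch_v <- vapply(fits, function(f) ch_index(f$embedding, f$labels), 0)
  k_star <- select_k(cpi_v, gap_v)
  structure(list(table = data.frame(k = k_range, cpi = as.numeric(cpi_v),
                                    gap = gap_v$gap, gap_se = gap_v$se,
                                    total = as.numeric(cpi_v) + gap_v$gap,
                                    dbi = dbi_v, ch = ch_v),
                 k_star = k_star, fits = setNames(fits, k_range)),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> chosen k* =", x$k_star, "\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.k_selection <- function(x, ...) {
  with(x$table, {
    plot(k, total, type = "b", ylab = "CPI + Gap", xlab = "k", ...)
    abline(v = x$k_star, lty = 2)
  })
  invisible(x)
}
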