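#' Build a bank of neighborhood-adaptive Gaussian kernels
#'
#' For every pair (sigma multiplier, neighbor count k) on the grid, a
#' Gaussian kernel is computed with a locally adaptive bandwidth:
#' `K(i,j) = exp(-d(i,j)^2 / (2 * eps_ij^2))` with
#' `eps_ij = sigma * (mu_ik + mu_jk) / 2`, where `d` is Euclidean
#' distance on z-scored features and `mu_ik` is the mean distance from
#' sample i to its k nearest neighbors (excluding itself; distance ties
#' broken by sample order). Default grids are 7 sigma values (1.0 to 2.5
#' by 0.25) by 5 neighbor counts (10 to 30 by 5), i.e. 35 kernels.
#'
#' @param table a [feature_table()] or numeric matrix (samples x features).
#' @param sigma_grid bandwidth multipliers.
#' @param k_grid neighbor counts (each must be < n).
#' @param standardize z-score features before computing distances
#'   (default TRUE; bandwidth pooling across features assumes it).
#' @return An object of class `kernel_bank`: list with `kernels` (list of
#'   n x n symmetric matrices), `params` (data.frame sigma, k),
#'   `modality`, `sample_ids`.
#' @export
build_kernel_bank <- function(table, sigma_grid = seq(1, 2.5, by = 0.25),
                              k_grid = seq(10L, 30L, by = 5L),
                              standardize = TRUE) {
  x <- as.matrix(table)
  n <- nrow(x)
  if (!length(sigma_grid) || !length(k_grid)) stop("empty kernel grid")
  if (any(k_grid >= n)) stop("neighbor count k must be smaller than n")
  if (standardize) x <- zscore(x)
  d <- as.matrix(dist(x))
  # mean distance to the k nearest neighbors, per k in the grid
  ord <- apply(d, 1L, sort)                      # n x n, col i = sorted dists
  mu_k <- lapply(k_grid, function(k) colMeans(ord[2:(k + 1L), , drop = FALSE]))
  params <- expand.grid(sigma = sigma_grid, k = k_grid)
  kernels <- lapply(seq_len(nrow(params)), function(i) {
    mu <- mu_k[[match(params$k[i], k_grid)]]
    eps <- params$sigma[i] * outer(mu, mu, "+") / 2
    eps[eps == 0] <- .Machine$double.eps
    kk <- exp(-d^2 / (2 * eps^2))
    (kk + t(kk)) / 2
  })
  structure(list(kernels = kernels, params = params,
                 modality = attr(table, "modality") %||% "unknown",
                 sample_ids = rownames(x)),
            class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("<kernel_bank> %s: %d kernels on %d samples\n",
              x$modality, length(x$kernels), nrow(x$kernels[[1L]])))
  invisible(x)
}

# symmetrized row-stochastic normalization; puts every kernel on the
# same total-mass scale so the weight update rewards concentration
# (block structure) rather than a uniformly large bandwidth
.normalize_kernel <- function(k) {
  p <- k / rowSums(k)
  nrow(k) * (p + t(p)) / 2      # rescaled so the mean entry is ~1
}

#' Stage-1 similarity learning from a kernel bank
#'
#' Learns a row-stochastic sample-similarity matrix S from a bank of
#' Gaussian kernels by block-coordinate descent on the rank-constrained
#' multiple-kernel objective
#' \deqn{\min_{S,w,L} -\langle K_w, S\rangle + \beta \|S\|_F^2
#'   - \gamma\, tr(L^T S L) + \rho \sum_l w_l \log w_l}
#' subject to simplex rows of S, simplex kernel weights w, and
#' orthonormal L (n x k). The three block updates are each exact
#' minimizers (simplex projection for S rows, top-k eigenvectors of the
#' symmetrized S for L, softmax for w), so the objective is monotone
#' non-increasing. The rank term pulls S toward a k-block structure; k
#' is set to the candidate cluster count under evaluation.
#'
#' @param bank a [build_kernel_bank()] result.
#' @param k target cluster count (rank constraint), >= 2.
#' @param beta ridge penalty on S entries.
#' @param gamma weight of the rank (Laplacian) term; default `n / (50 k)`
#'   gives a gentle pull toward k blocks without hardening the graph.
#' @param rho0 entropy regularization per unit similarity mass; the
#'   effective weight-entropy penalty is `rho0 * n`.
#' @param max_iter,tol iteration cap and relative objective tolerance.
#' @return List with `S` (symmetrized learned similarity), `w` (kernel
#'   weights on the simplex), `objective` (per-iteration values),
#'   `converged` flag.
#' @export
cimlr_stage1 <- function(bank, k, beta = 2, gamma = NULL, rho0 = 0.05,
                         max_iter = 50L, tol = 1e-6) {
  stopifnot(inherits(bank, "kernel_bank"), k >= 2L)
  kernels <- lapply(bank$kernels, .normalize_kernel)
  n <- nrow(kernels[[1L]])
  if (k >= n) stop("k must be smaller than n")
  m <- length(kernels)
  gamma <- gamma %||% (n / (50 * k))
  rho <- rho0 * n
  w <- rep(1 / m, m)
  kw <- Reduce(`+`, Map(`*`, kernels, w))
  s <- kw / rowSums(kw)                      # feasible start: row-stochastic
  ll <- matrix(0, n, k)
  objective <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # L: top-k eigenvectors of symmetrized S (exact block minimizer)
    ss <- (s + t(s)) / 2
    ll <- eigen(ss, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
    lp <- tcrossprod(ll)
    # S rows: simplex projection of (K_w + gamma * LL^T) / (2 beta)
    v <- (kw + gamma * lp) / (2 * beta)
    s <- t(apply(v, 1L, project_simplex))
    # w: softmax of per-kernel alignment with S
    align <- vapply(kernels, function(kk) sum(kk * s), 0)
    a <- align / rho
    w <- exp(a - max(a)); w <- w / sum(w)
    kw <- Reduce(`+`, Map(`*`, kernels, w))
    obj <- -sum(kw * s) + beta * sum(s^2) - gamma * sum(lp * s) +
      rho * sum(ifelse(w > 0, w * log(w), 0))
    objective <- c(objective, obj)
    if (it > 1L) {
      rel <- abs(objective[it - 1L] - obj) /
        max(abs(objective[it - 1L]), .Machine$double.eps)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged && max_iter > 1L)
    warning("cimlr_stage1: no convergence after ", max_iter, " iterations")
  list(S = (s + t(s)) / 2, w = w, objective = objective,
       converged = converged)
}

#' Normalized Frobenius (RV) coefficient between two similarity matrices
#'
#' @param a,b symmetric matrices of identical dimension.
#' @return `sum(a*b) / sqrt(sum(a^2) * sum(b^2))`; 1 when `a == b`.
#' @export
rv_coefficient <- function(a, b) {
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

#' Stage-2 consensus fusion of per-modality similarities
#'
#' Combines the stage-1 similarities with nonnegative modality weights
#' beta that maximize agreement with the modalities' consensus
#' structure (STATIS-type): beta is the leading eigenvector, normalized
#' to the simplex, of the matrix of pairwise Frobenius inner products
#' between the similarities. Using raw (unnormalized) inner products
#' lets a modality with stronger, more concentrated structure receive
#' strictly larger weight; two identical modalities get weight 1/2 each.
#'
#' @param similarities list of n x n symmetric matrices, common sample
#'   order.
#' @return List with `S` (the fused matrix `sum(beta_m * S_m)`) and
#'   `beta` (modality weights, simplex).
#' @export
umkl_fuse <- function(similarities) {
  m <- length(similarities)
  if (m == 0L) stop("no similarities to fuse")
  if (m == 1L) return(list(S = similarities[[1L]], beta = 1))
  cmat <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m)
    cmat[i, j] <- cmat[j, i] <- sum(similarities[[i]] * similarities[[j]])
  v <- abs(eigen(cmat, symmetric = TRUE)$vectors[, 1L])
  beta <- v / sum(v)
  s <- Reduce(`+`, Map(`*`, similarities, beta))
  names(beta) <- names(similarities)
  list(S = s, beta = beta)
}

#' Spectral K-means clustering of a fused similarity
#'
#' Embeds samples with the top-k eigenvectors of the symmetrically
#' normalized similarity `D^{-1/2} S D^{-1/2}`, scales embedding rows to
#' unit norm, and runs K-means with multiple restarts, keeping the best
#' inertia. Deterministic given the seed.
#'
#' @param s n x n symmetric nonnegative similarity.
#' @param k number of clusters (>= 2).
#' @param seed RNG seed for the K-means restarts.
#' @param n_restarts K-means restarts (default 100).
#' @return List with `labels` (1..k), `embedding` (n x k, unit rows),
#'   `centers` (k x k K-means centroids), `eigenvectors`, `eigenvalues`,
#'   `degree` (row sums of S) for out-of-sample extension.
#' @export
cluster_fused <- function(s, k, seed = 20240101L, n_restarts = 100L) {
  stopifnot(k >= 2L, nrow(s) == ncol(s))
  deg <- rowSums(s)
  if (any(deg <= 0)) stop("degenerate similarity: zero-degree sample")
  dhalf <- 1 / sqrt(deg)
  sn <- s * tcrossprod(dhalf)
  es <- eigen((sn + t(sn)) / 2, symmetric = TRUE)
  vec <- es$vectors[, seq_len(k), drop = FALSE]
  emb <- vec / pmax(sqrt(rowSums(vec^2)), .Machine$double.eps)
  set.seed(seed)
  if (nrow(unique(emb)) < k) {
    # degenerate embedding (fewer distinct points than clusters): any
    # balanced assignment attains the same zero-variance optimum
    labels <- sort(rep_len(seq_len(k), nrow(emb)))
    centers <- t(vapply(seq_len(k), function(g)
      colMeans(emb[labels == g, , drop = FALSE]), numeric(ncol(emb))))
    km <- list(cluster = labels, centers = centers, size = tabulate(labels))
  } else {
    km <- kmeans(emb, centers = k, nstart = n_restarts, iter.max = 100L)
  }
  if (any(km$size == 0L)) stop("empty cluster in fused clustering")
  list(labels = km$cluster, embedding = emb, centers = km$centers,
       eigenvectors = vec, eigenvalues = es$values[seq_len(k)],
       degree = deg)
}

#' Hierarchical multi-kernel subtyping of a multimodal cohort
#'
#' The full two-stage pipeline: per modality, a bank of adaptive
#' Gaussian kernels is distilled into a learned similarity under the
#' rank-constrained multiple-kernel objective ([cimlr_stage1()]); the
#' per-modality similarities are then fused with consensus weights
#' ([umkl_fuse()]); finally spectral K-means on the fused similarity
#' yields the subtype assignment ([cluster_fused()]).
#'
#' @param tables named list of [feature_table()]s (or numeric matrices)
#'   over identical samples in identical order, one per modality.
#' @param k number of subtypes.
#' @param sigma_grid,k_grid kernel-bank grids (see [build_kernel_bank()]).
#' @param seed RNG seed (K-means restarts).
#' @param n_restarts K-means restarts.
#' @param ... further arguments passed to [cimlr_stage1()].
#' @return An object of class `hmkl`: list with `labels`, `k`,
#'   `S_fused`, `modality_weights` (beta), `stage1` (per-modality S, w,
#'   objective), `embedding`, `centers`, `sample_ids`, `seed`, `call`.
#' @examples
#' cohort <- simulate_cohort(sim_cohort_spec(n_samples = 60, seed = 7))
#' fit <- hmkl(cohort$tables, k = 2, k_grid = c(5, 10), seed = 7)
#' table(fit$labels, cohort$labels)
#' @export
hmkl <- function(tables, k, sigma_grid = seq(1, 2.5, by = 0.25),
                 k_grid = seq(10L, 30L, by = 5L), seed = 20240101L,
                 n_restarts = 100L, ...) {
  if (is.matrix(tables) || inherits(tables, "feature_table"))
    tables <- list(tables)
  ids <- lapply(tables, rownames)
  if (length(tables) > 1L &&
      !all(vapply(ids[-1L], identical, TRUE, ids[[1L]])))
    stop("modalities have mismatched sample orders; align_cohort() first")
  stage1 <- lapply(tables, function(t) {
    bank <- build_kernel_bank(t, sigma_grid, k_grid)
    cimlr_stage1(bank, k, ...)
  })
  fused <- umkl_fuse(lapply(stage1, `[[`, "S"))
  cl <- cluster_fused(fused$S, k, seed = seed, n_restarts = n_restarts)
  structure(list(labels = cl$labels, k = k, S_fused = fused$S,
                 modality_weights = fused$beta, stage1 = stage1,
                 embedding = cl$embedding, centers = cl$centers,
                 eigenvectors = cl$eigenvectors,
                 eigenvalues = cl$eigenvalues, degree = cl$degree,
                 sample_ids = ids[[1L]], seed = seed,
                 sigma_grid = sigma_grid, k_grid = k_grid,
                 call = match.call()),
            class = "hmkl")
}

#' @export
print.hmkl <- function(x, ...) {
  cat(sprintf("<hmkl> %d samples, k = %d subtypes\n",
              length(x$labels), x$k))
  cat("cluster sizes:", paste(table(x$labels), collapse = " / "), "\n")
  cat("modality weights:",
      paste(sprintf("%s=%.3f", names(x$modality_weights) %||%
                    seq_along(x$modality_weights), x$modality_weights),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hmkl <- function(object, ...) {
  cat("Hierarchical multi-kernel subtyping\n")
  print(object)
  for (m in seq_along(object$stage1)) {
    st <- object$stage1[[m]]
    cat(sprintf("  modality %d: %d stage-1 iterations, converged=%s, ",
                m, length(st$objective), st$converged))
    cat(sprintf("top kernel weight %.3f\n", max(st$w)))
  }
  invisible(object)
}

#' @export
plot.hmkl <- function(x, ...) {
  ord <- order(x$labels)
  image(x$S_fused[ord, ord], axes = FALSE, useRaster = TRUE,
        main = sprintf("Fused similarity (k = %d)", x$k), ...)
  invisible(x)
}
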