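# SNF full transition matrix: off-diagonal mass 1/2 spread proportionally,
# diagonal 1/2 (rows sum to 1)
.snf_full <- function(w) {
  diag(w) <- 0
  p <- w / (2 * pmax(rowSums(w), .Machine$double.eps))
  diag(p) <- 1 / 2
  p
}

# SNF sparse (k-NN) row-stochastic kernel
.snf_sparse <- function(w, k_neighbors) {
  n <- nrow(w)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(w[i, ], decreasing = TRUE)
    nb <- nb[nb != i][seq_len(k_neighbors)]
    s[i, nb] <- w[i, nb]
  }
  s / pmax(rowSums(s), .Machine$double.eps)
}

#' Similarity network fusion by cross-diffusion
#'
#' The published SNF iteration: per view, a full row-stochastic
#' transition matrix and a k-NN-sparsified local kernel are formed; each
#' view's transition matrix is then repeatedly updated by diffusing the
#' average of the other views through its own local kernel,
#' `P_v <- S_v %*% mean(P_-v) %*% t(S_v)`, for `t_iterations` rounds.
#' The output is the symmetrized average of the final transition
#' matrices.
#'
#' @param affinities list of >= 2 sample-affinity matrices (same order).
#' @param K_neighbors local-kernel neighborhood size (default 20).
#' @param t_iterations diffusion rounds (default 20).
#' @return Fused n x n symmetric matrix.
#' @export
snf_fuse <- function(affinities, K_neighbors = 20L, t_iterations = 20L) {
  m <- length(affinities)
  if (m < 2L) stop("need at least 2 affinity matrices")
  n <- nrow(affinities[[1L]])
  if (K_neighbors >= n) stop("K_neighbors must be smaller than n")
  p <- lapply(affinities, .snf_full)
  s <- lapply(affinities, .snf_sparse, k_neighbors = K_neighbors)
  for (it in seq_len(t_iterations)) {
    p_new <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, p[-v]) / (m - 1)
      pv <- s[[v]] %*% others %*% t(s[[v]])
      p_new[[v]] <- .snf_full((pv + t(pv)) / 2)
    }
    p <- p_new
  }
  fused <- Reduce(`+`, p) / m
  (fused + t(fused)) / 2
}

# adaptive Gaussian affinity used for transfer (single bandwidth pair)
.transfer_affinity <- function(x, sigma = 0.5, k_neighbors = 20L) {
  bank <- build_kernel_bank(x, sigma_grid = sigma,
                            k_grid = min(k_neighbors, nrow(x) - 1L),
                            standardize = FALSE)
  bank$kernels[[1L]]
}

#' Transfer subtype labels to an external cohort
#'
#' Builds joint (training + test) affinities per modality on per-cohort
#' z-scored features, fuses them with [snf_fuse()], and propagates the
#' training labels to the test rows by iterating `Y <- P Y` with the
#' training rows clamped, until the maximum change falls below `tol`.
#' Each test sample receives the label with the largest propagated
#' score.
#'
#' @param train_tables,test_tables per-modality feature tables; the two
#'   cohorts must share feature columns per modality (the intersection
#'   is used; empty intersection is an error).
#' @param train_labels subtype label per training sample.
#' @param K_neighbors,t_iterations SNF parameters.
#' @param sigma affinity bandwidth multiplier.
#' @param tol,max_iter propagation convergence control.
#' @return List with `labels` (predicted test labels), `scores` (test
#'   rows x classes propagated mass), `iterations`.
#' @export
group_predict <- function(train_tables, train_labels, test_tables,
                          K_neighbors = 20L, t_iterations = 20L,
                          sigma = 0.5, tol = 1e-8, max_iter = 1000L) {
  stopifnot(length(train_tables) == length(test_tables))
  n_tr <- nrow(train_tables[[1L]])
  if (length(train_labels) != n_tr)
    stop("one training label per training sample required")
  joint <- lapply(seq_along(train_tables), function(m) {
    tr <- as.matrix(train_tables[[m]]); te <- as.matrix(test_tables[[m]])
    common <- intersect(colnames(tr), colnames(te))
    if (length(common) == 0L) stop("empty feature intersection in modality ", m)
    rbind(zscore(tr[, common, drop = FALSE]),
          zscore(te[, common, drop = FALSE]))
  })
  n <- nrow(joint[[1L]])
  aff <- lapply(joint, .transfer_affinity, sigma = sigma,
                k_neighbors = K_neighbors)
  fused <- if (length(aff) >= 2L)
    snf_fuse(aff, K_neighbors, t_iterations) else aff[[1L]]
  p <- fused / pmax(rowSums(fused), .Machine$double.eps)
  classes <- sort(unique(train_labels))
  y <- matrix(0, n, length(classes))
  y[cbind(seq_len(n_tr), match(train_labels, classes))] <- 1
  y[(n_tr + 1L):n, ] <- 1 / length(classes)
  clamp <- y[seq_len(n_tr), , drop = FALSE]
  it <- 0L
  repeat {
    it <- it + 1L
    y_new <- p %*% y
    y_new[seq_len(n_tr), ] <- clamp
    delta <- max(abs(y_new - y))
    y <- y_new
    if (delta < tol || it >= max_iter) break
  }
  test_scores <- y[(n_tr + 1L):n, , drop = FALSE]
  rs <- rowSums(test_scores)
  test_scores <- test_scores / ifelse(rs > 0, rs, 1)
  colnames(test_scores) <- as.character(classes)
  list(labels = classes[max.col(test_scores, ties.method = "first")],
       scores = test_scores, iterations = it)
}
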