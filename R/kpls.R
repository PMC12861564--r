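#' Gaussian (RBF) kernel matrix
#'
#' `K(i,j) = exp(-||x_i - x'_j||^2 / (2 sigma^2))`.
#'
#' @param x numeric matrix (rows = samples).
#' @param x2 optional second matrix; defaults to `x`.
#' @param sigma bandwidth (> 0).
#' @return `nrow(x) x nrow(x2)` kernel matrix.
#' @export
gaussian_kernel <- function(x, x2 = NULL, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  x <- as.matrix(x); x2 <- if (is.null(x2)) x else as.matrix(x2)
  if (ncol(x) != ncol(x2)) stop("feature dimensions differ")
  d2 <- outer(rowSums(x^2), rowSums(x2^2), "+") - 2 * tcrossprod(x, x2)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Fit a kernel partial least squares regression
#'
#' NIPALS-style KPLS on a double-centered kernel: components are
#' extracted iteratively with kernel and response deflation
#' (score vectors come out mutually orthogonal), then the response is
#' regressed on the component scores through the dual coefficients
#' `B = U (T' K U)^{-1} T' y`. Mapping the data into the
#' kernel-induced feature space lets classes that are not linearly
#' separable in the input space become separable.
#'
#' @param k_train uncentered training kernel (n x n); centering is
#'   applied internally and reproduced for test kernels.
#' @param y numeric response (for classification, 0/1).
#' @param ncomp number of latent components (1 <= ncomp < n).
#' @return Object of class `kpls`: list with `alpha` (dual regression
#'   coefficients), `scores` (T), `y_mean`, `k_row_means`, `k_mean`,
#'   `ncomp`.
#' @export
kpls_fit <- function(k_train, y, ncomp) {
  k_train <- as.matrix(k_train)
  n <- nrow(k_train)
  if (ncomp >= n) stop("ncomp must be smaller than n")
  if (var(y) == 0) stop("constant response")
  k_row_means <- colMeans(k_train)
  k_mean <- mean(k_train)
  kc <- k_train - matrix(k_row_means, n, n, byrow = TRUE) -
    matrix(k_row_means, n, n) + k_mean
  y_mean <- mean(y)
  yr <- matrix(y - y_mean, n, 1L)
  kr <- kc
  tt <- matrix(0, n, ncomp); uu <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    u <- yr[, 1L, drop = FALSE]
    t_vec <- kr %*% u
    nt <- sqrt(sum(t_vec^2))
    if (nt < .Machine$double.eps) { ncomp <- a - 1L; break }
    t_vec <- t_vec / nt
    # single-response NIPALS converges in one pass
    c_load <- crossprod(yr, t_vec)
    u <- yr %*% c_load
    tt[, a] <- t_vec; uu[, a] <- u
    # deflate kernel and response by the extracted score
    kt <- kr %*% t_vec
    kr <- kr - t_vec %*% t(kt) - kt %*% t(t_vec) +
      t_vec %*% (crossprod(t_vec, kt)) %*% t(t_vec)
    yr <- yr - t_vec %*% crossprod(t_vec, yr)
  }
  if (ncomp == 0L) stop("no usable KPLS component")
  tt <- tt[, seq_len(ncomp), drop = FALSE]
  uu <- uu[, seq_len(ncomp), drop = FALSE]
  alpha <- uu %*% solve(crossprod(tt, kc %*% uu), crossprod(tt, y - y_mean))
  structure(list(alpha = alpha, scores = tt, y_mean = y_mean,
                 k_row_means = k_row_means, k_mean = k_mean,
                 ncomp = ncomp),
            class = "kpls")
}

#' Predict from a kernel PLS fit
#'
#' @param model a [kpls_fit()] object.
#' @param k_test_vs_train uncentered test-vs-train kernel
#'   (n_test x n_train); the training centering is applied to it.
#' @return Numeric vector of continuous scores.
#' @export
kpls_predict <- function(model, k_test_vs_train) {
  kt <- as.matrix(k_test_vs_train)
  n_tr <- length(model$k_row_means)
  if (ncol(kt) != n_tr) stop("test kernel must have one column per training sample")
  ktc <- kt - matrix(model$k_row_means, nrow(kt), n_tr, byrow = TRUE) -
    rowMeans(kt) + model$k_mean
  as.numeric(ktc %*% model$alpha + model$y_mean)
}

#' @export
print.kpls <- function(x, ...) {
  cat(sprintf("<kpls> %d components on %d training samples\n",
              x$ncomp, length(x$k_row_means)))
  invisible(x)
}
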