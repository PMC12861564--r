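# AUC by the rank (Mann-Whitney) formulation; ties get 0.5 credit
rank_auc <- function(y, scores) {
  pos <- y == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# mean stratified cross-validated AUC of a KPLS at (sigma, ncomp),
# reusing a precomputed squared-distance matrix
.kpls_cv_auc <- function(d2, y, sigma, ncomp, folds) {
  k_full <- exp(-d2 / (2 * sigma^2))
  aucs <- vapply(folds, function(test_idx) {
    tr <- setdiff(seq_along(y), test_idx)
    nc <- min(ncomp, length(tr) - 1L)
    fit <- tryCatch(kpls_fit(k_full[tr, tr], y[tr], nc),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    sc <- kpls_predict(fit, k_full[test_idx, tr, drop = FALSE])
    rank_auc(y[test_idx], sc)
  }, 0)
  m <- mean(aucs, na.rm = TRUE)
  if (is.nan(m)) 0 else m
}

.make_folds <- function(y, nfolds) {
  idx <- seq_along(y)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    members <- sample(idx[y == cl])
    fold[members] <- rep_len(seq_len(nfolds), length(members))
  }
  split(idx, fold)
}

#' Genetic-algorithm tuning of the Gaussian-kernel PLS classifier
#'
#' A generational GA over the kernel bandwidth (searched on the log
#' scale) and, optionally, the number of KPLS components: tournament
#' selection, uniform crossover, Gaussian mutation on log sigma and
#' unit-step integer mutation on the component count, with elitism.
#' Fitness is the mean stratified 5-fold cross-validated AUC on the
#' training data. Deterministic given the seed.
#'
#' @param x training feature matrix.
#' @param y binary 0/1 response.
#' @param sigma_range length-2 range for sigma (log-uniform init);
#'   default `median pairwise distance * c(0.1, 10)`.
#' @param ncomp_range integer range for the component count (set to a
#'   single value to fix it).
#' @param population,generations GA size (defaults 20 x 50).
#' @param mutation_sd Gaussian mutation SD on log sigma.
#' @param p_crossover,p_mutation per-gene crossover/mutation rates.
#' @param nfolds internal cross-validation folds.
#' @param seed RNG seed.
#' @return List with `sigma`, `ncomp`, `fitness` (best CV AUC), and
#'   `history` (best fitness per generation).
#' @export
ga_optimize <- function(x, y, sigma_range = NULL, ncomp_range = 1:15,
                        population = 20L, generations = 50L,
                        mutation_sd = 0.3, p_crossover = 0.9,
                        p_mutation = 0.3, nfolds = 5L,
                        seed = 20240101L) {
  x <- as.matrix(x)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("y must be binary 0/1 with both classes present")
  set.seed(seed)
  d2 <- as.matrix(dist(x))^2
  if (is.null(sigma_range)) {
    med <- sqrt(stats::median(d2[upper.tri(d2)]))
    sigma_range <- med * c(0.1, 10)
  }
  ls_range <- log(sigma_range)
  ncomp_range <- sort(unique(as.integer(ncomp_range)))
  folds <- .make_folds(y, nfolds)
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(ls, nc) {
    key <- paste(round(ls, 4), nc)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- tryCatch(.kpls_cv_auc(d2, y, exp(ls), nc, folds),
                  error = function(e) 0)
    cache[[key]] <- f
    f
  }
  pop <- data.frame(ls = runif(population, ls_range[1L], ls_range[2L]),
                    nc = sample(ncomp_range, population, replace = TRUE))
  fit <- mapply(fitness_of, pop$ls, pop$nc)
  history <- numeric(generations)
  for (g in seq_len(generations)) {
    if (population > 1L) {
      # tournament selection (size 2)
      pick <- function() {
        ij <- sample(population, 2L)
        ij[which.max(fit[ij])]
      }
      children <- pop
      for (i in seq_len(population)) {
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        ch <- p1
        if (runif(1) < p_crossover) {
          if (runif(1) < 0.5) ch$ls <- p2$ls
          if (runif(1) < 0.5) ch$nc <- p2$nc
        }
        if (runif(1) < p_mutation)
          ch$ls <- min(max(ch$ls + rnorm(1, sd = mutation_sd),
                           ls_range[1L]), ls_range[2L])
        if (runif(1) < p_mutation && length(ncomp_range) > 1L) {
          ch$nc <- ch$nc + sample(c(-1L, 1L), 1L)
          ch$nc <- min(max(ch$nc, min(ncomp_range)), max(ncomp_range))
        }
        children[i, ] <- ch
      }
      child_fit <- mapply(fitness_of, children$ls, children$nc)
      # elitism: keep the best parent
      worst <- which.min(child_fit)
      best <- which.max(fit)
      if (fit[best] > child_fit[worst]) {
        children[worst, ] <- pop[best, ]
        child_fit[worst] <- fit[best]
      }
      pop <- children; fit <- child_fit
    }
    history[g] <- max(fit)
  }
  best <- which.max(fit)
  list(sigma = exp(pop$ls[best]), ncomp = pop$nc[best],
       fitness = fit[best], history = history)
}
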