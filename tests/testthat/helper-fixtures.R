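# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- simulate_cohort(
      sim_cohort_spec(n_samples = 150, delta = 3, seed = 42))
  .fixtures$cohort
}

shared_fit <- function() {
  if (is.null(.fixtures$fit)) {
    co <- shared_cohort()
    .fixtures$fit <- suppressWarnings(hmkl(co$tables, k = 2, seed = 42))
  }
  .fixtures$fit
}

# tiny two-blob dataset for kernel/cluster unit tests
two_blobs <- function(n_per = 20L, sep = 8, p = 4L, seed = 7L) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = sep), n_per))
  rownames(x) <- sprintf("B%03d", seq_len(2L * n_per))
  list(x = x, labels = rep(1:2, each = n_per))
}
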