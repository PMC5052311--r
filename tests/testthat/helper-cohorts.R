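# Small cohorts and toy feature sets shared across test files.

tiny_params <- function(n_hnscc = 5, n_lung = 4, seed = 1, ...) {
  generator_params(n_hnscc = n_hnscc, n_lung = n_lung, seed = seed, ...)
}

tiny_cohort <- function(...) sample_cohort(tiny_params(...))

# linearly separable two-class 2-D point cloud with margin ~2
toy_separable <- function(n_per_class = 10, seed = 42, gap = 2) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(2 * n_per_class, gap / 2, 0.3), ncol = 2),
               matrix(rnorm(2 * n_per_class, -gap / 2, 0.3), ncol = 2))
    list(x = x, labels = rep(c("HNSCC", "LUNG"), each = n_per_class))
  })
}

# exact trilinear stack from known factors
trilinear_stack <- function(A, B, C) {
  X <- array(0, c(nrow(A), nrow(B), nrow(C)))
  for (r in seq_len(ncol(A))) {
    X <- X + outer(outer(A[, r], B[, r]), C[, r])
  }
  X
}

# maximal absolute column congruence (cosine) between estimated and true
# factors under the best column permutation
factor_congruence <- function(est, truth) {
  est <- sweep(est, 2, sqrt(colSums(est^2)), `/`)
  truth <- sweep(truth, 2, sqrt(colSums(truth^2)), `/`)
  cos <- abs(crossprod(truth, est))
  perms <- if (ncol(cos) == 1) list(1) else
    asplit(rbind(seq_len(ncol(cos)), rev(seq_len(ncol(cos)))), 1)
  best <- 0
  for (p in perms) {
    best <- max(best, min(cos[cbind(seq_len(ncol(cos)), p)]))
  }
  best
}
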