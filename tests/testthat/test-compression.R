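test_that("the default design grid has 21 stable, well-formed entries", {
  d1 <- enumerate_designs()
  d2 <- enumerate_designs()
  expect_length(d1, 21)
  expect_identical(d1, d2)
  expect_identical(vapply(d1, function(d) d$design_id, numeric(1)),
                   as.numeric(1:21))
  scalings <- vapply(d1, function(d) d$scaling, character(1))
  expect_length(unique(scalings), 7)
  kinds <- vapply(d1, function(d) d$decomposition, character(1))
  expect_identical(sort(unique(kinds)), c("parafac", "tucker3"))
  # every scaling is crossed with parafac ranks 2 and 4 and one tucker core
  expect_true(all(table(scalings) == 3))
})

test_that("a non-canonical override is accepted with a warning", {
  short <- list(list(scaling = "raw", decomposition = "parafac", rank = 2),
                list(scaling = "log_transform", decomposition = "tucker3",
                     rank = c(2, 2, 2)))
  expect_warning(d <- enumerate_designs(short), "2 designs, not the canonical 21")
  expect_length(d, 2)
})

test_that("scaling variants satisfy their defining identities", {
  t <- tiny_cohort(n_hnscc = 1, n_lung = 1, seed = 4)$records[[1]]$tensor
  expect_identical(apply_scaling(t, "raw"), array(as.numeric(t), dim(t)))
  cen <- apply_scaling(t, "center_temperature")
  expect_equal(max(abs(apply(cen, c(2, 3), mean))), 0, tolerance = 1e-12)
  aut <- apply_scaling(t, "autoscale_cycle")
  expect_equal(max(abs(apply(aut, c(1, 3), mean))), 0, tolerance = 1e-12)
  expect_equal(unname(apply(aut, c(1, 3), sd)),
               matrix(1, 32, 3), tolerance = 1e-9)
  expect_equal(max(apply_scaling(t, "unit_max")), 1)
  expect_equal(apply_scaling(t, "log_transform"), log(array(as.numeric(t), dim(t))))
  # constant-in-cycle tensor: sd floor engages, output is zeros not NaN
  const <- array(rep(as.numeric(t[, 1, ]), times = 36), c(32, 3, 36))
  const <- aperm(const, c(1, 3, 2))
  z <- apply_scaling(breath_tensor(const), "autoscale_cycle")
  expect_true(all(is.finite(z)))
  expect_equal(max(abs(z)), 0)
})

test_that("parafac recovers exact low-rank structure and generating factors", {
  withr::with_seed(31, {
    A <- matrix(rnorm(15 * 1), 15); B0 <- matrix(rnorm(32), 32)
    C0 <- matrix(rnorm(108), 108)
  })
  X1 <- trilinear_stack(A, B0, C0)
  m1 <- parafac_als(X1, 1, seed = 1)
  expect_gt(m1$fit, 1 - 1e-6)
  expect_gte(factor_congruence(m1$factors$B, B0), 0.999)
  expect_gte(factor_congruence(m1$factors$C, C0), 0.999)

  withr::with_seed(32, {
    A2 <- matrix(rnorm(15 * 2), 15); B2 <- matrix(rnorm(32 * 2), 32)
    C2 <- matrix(rnorm(108 * 2), 108)
  })
  X2 <- trilinear_stack(A2, B2, C2)
  fits <- vapply(1:20, function(s) parafac_als(X2, 2, seed = s)$fit, numeric(1))
  expect_gt(max(fits), 1 - 1e-6) # best of 20 random restarts hits the truth
  best <- parafac_als(X2, 2, seed = which.max(fits))
  expect_gte(factor_congruence(best$factors$B, B2), 0.99)
})

test_that("decompositions are deterministic given the seed", {
  X <- withr::with_seed(3, array(rnorm(10 * 32 * 108), c(10, 32, 108)))
  expect_identical(parafac_als(X, 2, seed = 5), parafac_als(X, 2, seed = 5))
  expect_identical(tucker3_hooi(X, c(3, 3, 2)), tucker3_hooi(X, c(3, 3, 2)))
})

test_that("parafac rejects excessive rank and non-finite input", {
  X <- array(1 + runif(4 * 5 * 6), c(4, 5, 6))
  expect_error(parafac_als(X, 5), "rank .5. exceeds")
  X[1] <- NA
  expect_error(parafac_als(X, 2), "non-finite")
  expect_error(tucker3_hooi(X, c(2, 2, 2)), "non-finite")
})

test_that("tucker3 fit is exact with a full core and on matching low rank", {
  X <- withr::with_seed(4, array(rnorm(6 * 7 * 8), c(6, 7, 8)))
  expect_equal(tucker3_hooi(X, c(6, 7, 8))$fit, 1, tolerance = 1e-9)
  r1 <- trilinear_stack(matrix(rnorm(6), 6), matrix(rnorm(7), 7),
                        matrix(rnorm(8), 8))
  expect_equal(tucker3_hooi(r1, c(1, 1, 1))$fit, 1, tolerance = 1e-6)
  expect_true(all(abs(crossprod(tucker3_hooi(X, c(2, 3, 2))$factors$A) -
                        diag(2)) < 1e-10)) # orthonormal factors
})

test_that("HOOI refines plain truncated HOSVD", {
  for (seed in 1:3) {
    X <- withr::with_seed(seed, array(rnorm(8 * 9 * 10), c(8, 9, 10)))
    hooi <- tucker3_hooi(X, c(2, 2, 2))
    # plain truncated HOSVD fit: project once onto leading singular vectors
    U <- lapply(1:3, function(m) {
      M <- apply(X, m, identity)
      e <- eigen(tcrossprod(t(M)), symmetric = TRUE)
      e$vectors[, 1:2]
    })
    Y <- X
    for (m in 1:3) {
      d <- dim(Y)
      perm <- c(m, setdiff(1:3, m))
      Ym <- matrix(aperm(Y, perm), d[m])
      Y <- aperm(array(crossprod(U[[m]], Ym), c(2, d[-m])), order(perm))
    }
    hosvd_fit <- sum(Y^2) / sum(X^2)
    expect_gte(hooi$fit + 1e-12, hosvd_fit)
  }
})

test_that("fit is non-decreasing in rank and core size on the same input", {
  for (seed in 1:3) {
    X <- withr::with_seed(seed + 10, array(rnorm(12 * 16 * 9), c(12, 16, 9)))
    pf <- vapply(1:4, function(r) {
      max(vapply(1:3, function(s) parafac_als(X, r, seed = s)$fit, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(pf) > -1e-8))
    tf <- vapply(1:4, function(r) tucker3_hooi(X, c(r, r, r))$fit, numeric(1))
    expect_true(all(diff(tf) > -1e-8))
  }
})

test_that("cohort compression is symmetric, permutation-stable and finite", {
  ds <- tiny_cohort(n_hnscc = 4, n_lung = 4, seed = 6)
  # duplicate tensors produce duplicate feature rows
  recs <- ds$records
  recs[["copy"]] <- recs[[1]]
  recs[["copy"]]$patient_id <- "copy"
  ds_dup <- breath_dataset(recs)
  for (design in enumerate_designs()[c(2, 21)]) {
    fs <- compress_dataset(ds_dup, design, seed = 1)
    expect_equal(unname(fs$x["P001", ]), unname(fs$x["copy", ]),
                 tolerance = 1e-6)
  }
  # permuting patient order leaves each patient's features unchanged
  design <- enumerate_designs()[[4]]
  fs1 <- compress_dataset(ds, design, seed = 2)
  perm <- withr::with_seed(1, sample(length(ds)))
  ds_p <- breath_dataset(ds$records[perm])
  fs2 <- compress_dataset(ds_p, design, seed = 2)
  expect_equal(fs2$x[rownames(fs1$x), ], fs1$x, tolerance = 1e-6)
  # every design yields finite features over fuzzed cohorts
  for (seed in 1:5) {
    dsf <- tiny_cohort(n_hnscc = 3, n_lung = 3, seed = seed, sigma_noise = 0.1)
    for (design in enumerate_designs()) {
      fs <- compress_dataset(dsf, design, seed = seed,
                             tol = 1e-6, max_iter = 60)
      expect_true(all(is.finite(fs$x)))
    }
  }
})

test_that("class separation in features grows with the latent separation", {
  sep <- vapply(c(0, 4), function(delta) {
    ds <- sample_cohort(generator_params(n_hnscc = 12, n_lung = 10,
                                         delta = delta, sigma_noise = 0.02,
                                         seed = 3))
    fs <- compress_dataset(ds, enumerate_designs()[[2]], seed = 1)
    labs <- dataset_labels(ds)
    x <- fs$x[, -ncol(fs$x), drop = FALSE] # drop the constant fit column
    mu1 <- colMeans(x[labs == "HNSCC", ]); mu0 <- colMeans(x[labs == "LUNG", ])
    S <- (stats::cov(x[labs == "HNSCC", ]) + stats::cov(x[labs == "LUNG", ])) / 2
    sqrt(mahalanobis(mu1, mu0, S))
  }, numeric(1))
  expect_gt(sep[2], sep[1])
})
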