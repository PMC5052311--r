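# --- small multilinear-algebra helpers -------------------------------------

# mode-n unfolding: rows = mode n, columns = remaining modes with the lower
# mode index running fastest (the layout matched by khatri_rao below)
unfold <- function(x, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(x, perm), d[mode])
}

# column-wise Khatri-Rao product: column r = kron(U[, r], V[, r])
khatri_rao <- function(U, V) {
  r <- ncol(U)
  out <- matrix(0, nrow(U) * nrow(V), r)
  for (j in seq_len(r)) out[, j] <- kronecker(U[, j], V[, j])
  out
}

# tensor times matrix along a mode
ttm <- function(x, M, mode) {
  d <- dim(x)
  perm <- c(mode, setdiff(seq_along(d), mode))
  y <- M %*% matrix(aperm(x, perm), d[mode])
  d2 <- d
  d2[mode] <- nrow(M)
  aperm(array(y, c(nrow(M), d2[-mode])), order(perm))
}

solve_gram <- function(G, B) {
  out <- tryCatch(solve(G, B), error = function(e) NULL)
  if (is.null(out)) {
    # near-singular Gram matrix (degenerate components); ridge fallback
    out <- solve(G + diag(1e-10 * max(diag(G), 1), nrow(G)), B)
  }
  out
}

# flip factor columns so the largest-magnitude entry is positive; returns
# the sign vector applied
fix_signs <- function(M) {
  s <- apply(M, 2, function(col) {
    v <- col[which.max(abs(col))]
    if (v < 0) -1 else 1
  })
  s
}

#' PARAFAC decomposition by alternating least squares
#'
#' Fits the trilinear model \eqn{x_{ijk} \approx \sum_r a_{ir} b_{jr} c_{kr}}
#' to a 3-way array, typically the cohort stack
#' (patient x temperature x cycle-sensor). Random seeded initialisation,
#' alternating least-squares updates, convergence when the relative change
#' in fit drops below `tol`. On return the non-patient factors `B`, `C`
#' have unit-norm columns with all magnitude absorbed into the first-mode
#' factor `A`, columns are ordered by decreasing explained variance, and
#' sign indeterminacy is resolved by making the largest-magnitude entry of
#' each `B`/`C` column positive.
#'
#' @param stack 3-way numeric array, first mode = patients.
#' @param rank Number of components (at most the first-mode size).
#' @param seed Seed for the random initialisation.
#' @param tol Relative fit-change convergence tolerance.
#' @param max_iter Maximum ALS sweeps.
#' @return A `factor_model`: `kind`, `factors` (list `A`, `B`, `C`),
#'   `core = NULL`, `fit` (fraction of variance explained), `n_iterations`,
#'   `converged`, `dims`.
#' @export
parafac_als <- function(stack, rank, seed = 1, tol = 1e-8, max_iter = 500) {
  d <- dim(stack)
  stopifnot(length(d) == 3L, rank >= 1)
  if (!all(is.finite(stack))) stop("non-finite values in input stack", call. = FALSE)
  if (rank > d[1]) {
    stop(sprintf("rank (%d) exceeds first-mode (patient) size (%d)", rank, d[1]),
         call. = FALSE)
  }
  X1 <- unfold(stack, 1)
  X2 <- unfold(stack, 2)
  X3 <- unfold(stack, 3)
  nrm2 <- sum(stack^2)
  BC <- withr::with_seed(seed, list(
    B = matrix(stats::rnorm(d[2] * rank), d[2]),
    C = matrix(stats::rnorm(d[3] * rank), d[3])))
  B <- BC$B; C <- BC$C
  A <- matrix(0, d[1], rank)
  fit <- 0
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    A <- t(solve_gram(crossprod(C) * crossprod(B),
                      t(X1 %*% khatri_rao(C, B))))
    B <- t(solve_gram(crossprod(C) * crossprod(A),
                      t(X2 %*% khatri_rao(C, A))))
    G3 <- X3 %*% khatri_rao(B, A)
    C <- t(solve_gram(crossprod(B) * crossprod(A), t(G3)))
    # ||X - Xhat||^2 = ||X||^2 - 2<X, Xhat> + ||Xhat||^2, all from Gram terms
    cross <- sum(C * G3)
    hat2 <- sum(crossprod(A) * crossprod(B) * crossprod(C))
    new_fit <- 1 - (nrm2 - 2 * cross + hat2) / nrm2
    if (it > 1 && abs(new_fit - fit) < tol) {
      fit <- new_fit
      converged <- TRUE
      break
    }
    fit <- new_fit
  }
  # normalise: unit-norm B, C columns, magnitude into A
  nb <- pmax(sqrt(colSums(B^2)), 1e-300)
  nc <- pmax(sqrt(colSums(C^2)), 1e-300)
  B <- sweep(B, 2, nb, `/`); C <- sweep(C, 2, nc, `/`)
  A <- sweep(A, 2, nb * nc, `*`)
  sb <- fix_signs(B); sc <- fix_signs(C)
  B <- sweep(B, 2, sb, `*`); C <- sweep(C, 2, sc, `*`)
  A <- sweep(A, 2, sb * sc, `*`)
  ord <- order(colSums(A^2), decreasing = TRUE)
  structure(list(kind = "parafac",
                 factors = list(A = A[, ord, drop = FALSE],
                                B = B[, ord, drop = FALSE],
                                C = C[, ord, drop = FALSE]),
                 core = NULL, fit = fit, n_iterations = it,
                 converged = converged, dims = d),
            class = "factor_model")
}

#' Tucker3 decomposition by higher-order orthogonal iteration
#'
#' Fits \eqn{X \approx G \times_1 U_1 \times_2 U_2 \times_3 U_3} with
#' orthonormal factor matrices, initialised by truncated higher-order SVD
#' and refined by HOOI. Convergence contract matches [parafac_als()]:
#' relative fit change below `tol` or `max_iter` sweeps. Column signs are
#' fixed (largest-magnitude entry positive) with the flips absorbed into
#' the core.
#'
#' @param stack 3-way numeric array, first mode = patients.
#' @param core Length-3 integer core size `(r1, r2, r3)`, elementwise at
#'   most the mode sizes.
#' @param seed Accepted for interface symmetry; the HOSVD initialisation is
#'   deterministic.
#' @param tol,max_iter As in [parafac_als()].
#' @return A `factor_model` with orthonormal `factors` (`A`, `B`, `C` for
#'   modes 1-3) and the `core` tensor; `fit` equals
#'   \eqn{\|G\|^2 / \|X\|^2}.
#' @export
tucker3_hooi <- function(stack, core, seed = 1, tol = 1e-8, max_iter = 500) {
  d <- dim(stack)
  stopifnot(length(d) == 3L, length(core) == 3L)
  if (!all(is.finite(stack))) stop("non-finite values in input stack", call. = FALSE)
  core <- as.integer(core)
  if (any(core < 1) || any(core > d)) {
    stop(sprintf("core (%s) must be between 1 and the mode sizes (%s)",
                 paste(core, collapse = ","), paste(d, collapse = ",")),
         call. = FALSE)
  }
  top_left <- function(M, r) {
    e <- eigen(tcrossprod(M), symmetric = TRUE)
    e$vectors[, seq_len(r), drop = FALSE]
  }
  U <- lapply(1:3, function(m) top_left(unfold(stack, m), core[m]))
  nrm2 <- sum(stack^2)
  fit <- 0
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    for (m in 1:3) {
      others <- setdiff(1:3, m)
      y <- stack
      for (o in others) y <- ttm(y, t(U[[o]]), o)
      U[[m]] <- top_left(unfold(y, m), core[m])
    }
    G <- ttm(ttm(ttm(stack, t(U[[1]]), 1), t(U[[2]]), 2), t(U[[3]]), 3)
    new_fit <- sum(G^2) / nrm2
    if (it > 1 && abs(new_fit - fit) < tol) {
      fit <- new_fit
      converged <- TRUE
      break
    }
    fit <- new_fit
  }
  signs <- lapply(U, fix_signs)
  U <- Map(function(M, s) sweep(M, 2, s, `*`), U, signs)
  G <- ttm(ttm(ttm(G, diag(signs[[1]], core[1]), 1),
               diag(signs[[2]], core[2]), 2), diag(signs[[3]], core[3]), 3)
  structure(list(kind = "tucker3",
                 factors = list(A = U[[1]], B = U[[2]], C = U[[3]]),
                 core = G, fit = fit, n_iterations = it,
                 converged = converged, dims = d),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %s, dims %s, fit %.4f (%d iterations%s)\n",
              x$kind, paste(x$dims, collapse = "x"), x$fit, x$n_iterations,
              if (x$converged) ", converged" else ""))
  invisible(x)
}
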