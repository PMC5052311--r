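# Build the cohort stack for one scaling: n_patients x 32 x 108, the
# cycle and sensor modes of each scaled measurement combined (cycle fastest).
cohort_stack <- function(ds, scaling) {
  n <- length(ds)
  stack <- array(0, c(n, 32L, 36L * 3L))
  for (i in seq_len(n)) {
    x <- apply_scaling(ds$records[[i]]$tensor, scaling)
    stack[i, , ] <- matrix(x, 32L, 36L * 3L)
  }
  dimnames(stack) <- list(names(ds$records), NULL, NULL)
  stack
}

fit_design <- function(stack, design, seed, tol = 1e-8, max_iter = 500) {
  if (design$decomposition == "parafac") {
    parafac_als(stack, design$rank, seed = seed, tol = tol,
                max_iter = max_iter)
  } else {
    core <- pmin(design$rank, dim(stack))
    tucker3_hooi(stack, core, seed = seed, tol = tol, max_iter = max_iter)
  }
}

# Least-squares projection of one scaled measurement (32 x 108 matrix, or a
# 32x36x3 array) onto the frozen non-patient factors of a cohort model;
# returns the patient-mode loading vector. This is how a held-out patient
# is coded without influencing the factor space.
project_patient <- function(model, x) {
  if (length(dim(x)) == 3L) x <- matrix(as.numeric(x), 32L, 36L * 3L)
  v <- as.numeric(x)
  if (model$kind == "parafac") {
    M <- khatri_rao(model$factors$C, model$factors$B) # (J*K) x R
    as.numeric(solve_gram(crossprod(M), crossprod(M, v)))
  } else {
    z <- as.numeric(crossprod(model$factors$B, x %*% model$factors$C)) # r2*r3
    G1 <- unfold(model$core, 1)
    as.numeric(solve_gram(tcrossprod(G1), G1 %*% z))
  }
}

#' Compress a cohort under one scaling design
#'
#' Applies the design's scaling to every measurement, stacks the cohort
#' along a patient mode, runs one cohort-level decomposition, and returns
#' each patient's patient-mode loadings (length = PARAFAC rank or Tucker3
#' r1) with the design's fraction of variance explained appended as a final
#' feature. A single shared factor space is what makes the loadings
#' comparable across patients.
#'
#' @param ds A [breath_dataset()] with at least 2 patients.
#' @param design A design from [enumerate_designs()].
#' @param seed Seed forwarded to the decomposition initialisation.
#' @param tol,max_iter Decomposition convergence controls.
#' @return A `feature_set`: list with `design_id`, `patient_id`, `x`
#'   (numeric matrix, one row per patient, rownames = patient ids), `fit`,
#'   and the fitted `model`.
#' @export
compress_dataset <- function(ds, design, seed = 1, tol = 1e-8,
                             max_iter = 500) {
  stopifnot(inherits(ds, "breath_dataset"), length(ds) >= 2)
  stack <- cohort_stack(ds, design$scaling)
  model <- fit_design(stack, design, seed, tol, max_iter)
  A <- model$factors$A
  x <- cbind(A, fit = model$fit)
  colnames(x) <- c(paste0("x", seq_len(ncol(A))), "fit")
  rownames(x) <- names(ds$records)
  structure(list(design_id = design$design_id,
                 patient_id = names(ds$records),
                 x = x, fit = model$fit, model = model,
                 scaling = design$scaling),
            class = "feature_set")
}

#' Export feature sets as a long data frame
#' @param fs A `feature_set` from [compress_dataset()] or a list of them.
#' @return data.frame with `patient_id`, `design_id`, `x1..xk`, `fit`.
#' @export
features_as_df <- function(fs) {
  if (inherits(fs, "feature_set")) fs <- list(fs)
  do.call(rbind, lapply(fs, function(f) {
    data.frame(patient_id = f$patient_id, design_id = f$design_id,
               as.data.frame(f$x), row.names = NULL)
  }))
}
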