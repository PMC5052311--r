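#' Configuration of the per-protocol analysis
#'
#' @param exclusion_fraction Fraction of designs that must misclassify a
#'   patient for exclusion (default 0.85; a patient is excluded when
#'   misclassified in at least 85 % of the ensemble's designs).
#' @param exclusion_threshold Score cut defining "falsely diagnosed" for
#'   the exclusion rule (default 0.5).
#' @param iterate_exclusion If `TRUE`, re-run the cross-validation on the
#'   reduced cohort and re-apply the rule until no further patient drops
#'   (default `FALSE`: one pass).
#' @param seed Seed for the protocol run.
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(exclusion_fraction = 0.85,
                            exclusion_threshold = 0.5,
                            iterate_exclusion = FALSE, seed = 1) {
  stopifnot(exclusion_fraction > 0, exclusion_fraction <= 1,
            exclusion_threshold >= 0, exclusion_threshold <= 1)
  structure(list(exclusion_fraction = exclusion_fraction,
                 exclusion_threshold = exclusion_threshold,
                 iterate_exclusion = isTRUE(iterate_exclusion),
                 seed = as.integer(seed)),
            class = "protocol_config")
}

design_fold_seed <- function(seed, design_id, fold) {
  derive_seed(seed, design_id * 1009L + fold)
}

#' Leave-one-out cross-validation over the design ensemble
#'
#' For every design and every patient: the scaling + cohort decomposition +
#' classifier chain is fitted on all other patients, the held-out patient
#' is projected onto the training fold's frozen factor space by least
#' squares, and scored. The held-out measurement influences nothing in its
#' own fold's training; the per-fold training ids are recorded so the
#' no-leakage property can be audited. A failed fold is recorded (score
#' `NA`) rather than fatal, but more than 10 % failed folds aborts the run.
#'
#' @param ds A [breath_dataset()] with at least 3 patients per class.
#' @param designs Designs from [enumerate_designs()].
#' @param ann_cfg An [ann_config()].
#' @param seed Master seed; decomposition initialisations are derived from
#'   it per (design, fold).
#' @param decomp_tol,decomp_max_iter Decomposition convergence controls for
#'   the cross-validation loop.
#' @return A `loocv_result`: `scores` (patients x designs matrix of
#'   held-out scores), `train_ids` (per-fold training ids), `failed`
#'   (logical matrix), `labels`.
#' @export
run_loocv <- function(ds, designs = enumerate_designs(),
                      ann_cfg = ann_config(), seed = 1,
                      decomp_tol = 1e-6, decomp_max_iter = 100) {
  labels <- dataset_labels(ds)
  stopifnot(sum(labels == "HNSCC") >= 3, sum(labels == "LUNG") >= 3)
  n <- length(ds)
  ids <- names(ds$records)
  did <- vapply(designs, function(d) d$design_id, numeric(1))
  scores <- matrix(NA_real_, n, length(designs),
                   dimnames = list(ids, as.character(did)))
  failed <- matrix(FALSE, n, length(designs),
                   dimnames = dimnames(scores))
  stacks <- list()
  for (sc in unique(vapply(designs, `[[`, character(1), "scaling"))) {
    stacks[[sc]] <- cohort_stack(ds, sc)
  }
  train_ids <- lapply(seq_len(n), function(i) ids[-i])
  for (j in seq_along(designs)) {
    d <- designs[[j]]
    stack <- stacks[[d$scaling]]
    for (i in seq_len(n)) {
      res <- tryCatch({
        tr <- stack[-i, , , drop = FALSE]
        model <- fit_design(tr, d, design_fold_seed(seed, d$design_id, i),
                            tol = decomp_tol, max_iter = decomp_max_iter)
        xtr <- cbind(model$factors$A, fit = model$fit)
        m <- train_ann(xtr, labels[-i], ann_cfg)
        xi <- c(project_patient(model, stack[i, , ]), model$fit)
        as.numeric(predict_score(m, xi))
      }, error = function(e) NA_real_)
      scores[i, j] <- res
      failed[i, j] <- is.na(res)
    }
  }
  if (mean(failed) > 0.10) {
    stop(sprintf("%.0f%% of LOOCV folds failed; aborting", 100 * mean(failed)),
         call. = FALSE)
  }
  structure(list(scores = scores, train_ids = train_ids, failed = failed,
                 labels = labels),
            class = "loocv_result")
}

#' Per-protocol exclusion of chronically misclassified patients
#'
#' A patient is excluded when the fraction of designs whose held-out score
#' falls on the wrong side of `exclusion_threshold` reaches
#' `exclusion_fraction` (e.g. misclassified by 18 of 21 designs, 0.857,
#' is excluded at the 0.85 rule; 17 of 21, 0.810, is retained).
#'
#' @param scores Patients x designs score matrix (rownames = patient ids),
#'   or a `loocv_result`.
#' @param labels Class labels aligned with the rows.
#' @param config A [protocol_config()].
#' @return List with `excluded` (character ids) and
#'   `misclassified_fraction` (named per-patient fractions).
#' @export
per_protocol_exclusion <- function(scores, labels,
                                   config = protocol_config()) {
  if (inherits(scores, "loocv_result")) {
    labels <- scores$labels
    scores <- scores$scores
  }
  y <- as_binary_labels(labels)
  pred <- scores > config$exclusion_threshold
  wrong <- sweep(pred, 1, y == 1, `!=`)
  frac <- rowMeans(wrong, na.rm = TRUE)
  list(excluded = rownames(scores)[frac >= config$exclusion_fraction],
       misclassified_fraction = frac)
}

#' Best-fit (in-sample) ensemble scoring
#'
#' Fits each design on all included patients and scores the same patients
#' in-sample — the optimistic "best fit of the data" companion to the
#' cross-validated scores. The consensus score is the unweighted mean over
#' designs.
#'
#' @inheritParams run_loocv
#' @return List with `scores` (patients x designs), `consensus` (named
#'   per-patient means), `fits` (per-design variance explained).
#' @export
best_fit <- function(ds, designs = enumerate_designs(),
                     ann_cfg = ann_config(), seed = 1,
                     decomp_tol = 1e-6, decomp_max_iter = 100) {
  labels <- dataset_labels(ds)
  ids <- names(ds$records)
  did <- vapply(designs, function(d) d$design_id, numeric(1))
  scores <- matrix(NA_real_, length(ds), length(designs),
                   dimnames = list(ids, as.character(did)))
  fits <- stats::setNames(numeric(length(designs)), as.character(did))
  for (j in seq_along(designs)) {
    d <- designs[[j]]
    fs <- compress_dataset(ds, d, seed = design_fold_seed(seed, d$design_id, 0L),
                           tol = decomp_tol, max_iter = decomp_max_iter)
    m <- train_ann(fs, labels, ann_cfg)
    scores[, j] <- predict_score(m, fs$x)
    fits[j] <- fs$fit
  }
  list(scores = scores, consensus = rowMeans(scores), fits = fits)
}

#' Run the full per-protocol ensemble analysis
#'
#' The complete inference procedure: leave-one-out cross-validation of
#' every design, per-protocol exclusion of patients misclassified in at
#' least `exclusion_fraction` of designs, and a best-fit (in-sample) model
#' of the included patients. Consensus scores are unweighted means over
#' designs.
#'
#' @inheritParams run_loocv
#' @param config A [protocol_config()].
#' @return An `ensemble_result`: `scores` (LOOCV, full cohort),
#'   `best_fit_scores` (included patients), `consensus_score` (LOOCV
#'   consensus, included patients), `consensus_best_fit`, `excluded`,
#'   `misclassified_fraction`, `labels`, `n_designs`, `loocv` (the raw
#'   `loocv_result`).
#' @export
run_protocol <- function(ds, designs = enumerate_designs(),
                         ann_cfg = ann_config(),
                         config = protocol_config(),
                         decomp_tol = 1e-6, decomp_max_iter = 100) {
  cv <- run_loocv(ds, designs, ann_cfg, seed = config$seed,
                  decomp_tol = decomp_tol, decomp_max_iter = decomp_max_iter)
  exc <- per_protocol_exclusion(cv, config = config)
  if (config$iterate_exclusion) {
    repeat {
      kept <- setdiff(names(ds$records), exc$excluded)
      ds_i <- subset_dataset(ds, kept)
      cv_i <- run_loocv(ds_i, designs, ann_cfg, seed = config$seed,
                        decomp_tol = decomp_tol,
                        decomp_max_iter = decomp_max_iter)
      exc_i <- per_protocol_exclusion(cv_i, config = config)
      if (!length(exc_i$excluded)) break
      exc$excluded <- c(exc$excluded, exc_i$excluded)
    }
  }
  included <- setdiff(names(ds$records), exc$excluded)
  ds_inc <- subset_dataset(ds, included)
  bf <- best_fit(ds_inc, designs, ann_cfg, seed = config$seed,
                 decomp_tol = decomp_tol, decomp_max_iter = decomp_max_iter)
  cons_cv <- rowMeans(cv$scores[included, , drop = FALSE], na.rm = TRUE)
  structure(list(scores = cv$scores, best_fit_scores = bf$scores,
                 consensus_score = cons_cv, consensus_best_fit = bf$consensus,
                 excluded = exc$excluded,
                 misclassified_fraction = exc$misclassified_fraction,
                 labels = cv$labels, n_designs = length(designs),
                 loocv = cv),
            class = "ensemble_result")
}

#' Diagnostic summary of an ensemble result
#'
#' Applies the metrics layer to the included patients' consensus scores:
#' accuracy-optimal thresholds, confusion matrices, sensitivity /
#' specificity / accuracy, MCC and ROC-AUC with DeLong intervals, for both
#' the best-fit and the cross-validated scores.
#'
#' @param res An `ensemble_result` from [run_protocol()].
#' @return List with elements `best_fit` and `cross_validation`, each
#'   holding `threshold`, `cm`, `sensitivity`, `specificity`, `accuracy`,
#'   `mcc`, `auc`, `ci95`; plus `excluded` and `n_included`.
#' @export
ensemble_metrics <- function(res) {
  stopifnot(inherits(res, "ensemble_result"))
  included <- names(res$consensus_score)
  labs <- res$labels[included]
  one <- function(scores) {
    th <- optimal_threshold(scores, labs, "accuracy")
    cm <- confusion_at_threshold(scores, labs, th)
    ssa <- sens_spec_acc(cm)
    roc <- roc_auc(scores, labs)
    list(threshold = th, cm = cm,
         sensitivity = unname(ssa["sensitivity"]),
         specificity = unname(ssa["specificity"]),
         accuracy = unname(ssa["accuracy"]),
         mcc = mcc(cm), auc = roc$auc, ci95 = roc$ci95)
  }
  list(best_fit = one(res$consensus_best_fit[included]),
       cross_validation = one(res$consensus_score),
       excluded = res$excluded, n_included = length(included))
}

#' Write an ensemble analysis to disk
#'
#' Emits `scores.csv` (patient, design, LOOCV and best-fit scores),
#' `excluded.csv`, `consensus.csv` (the per-patient scatter data:
#' consensus scores and label), `roc.csv` (curve points for both analyses)
#' and `metrics.json`.
#'
#' @param res An `ensemble_result`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- expand.grid(patient_id = rownames(res$scores),
                      design_id = colnames(res$scores),
                      stringsAsFactors = FALSE)
  long$loocv_score <- as.numeric(res$scores)
  bf_idx <- cbind(match(long$patient_id, rownames(res$best_fit_scores)),
                  match(long$design_id, colnames(res$best_fit_scores)))
  long$best_fit_score <- res$best_fit_scores[bf_idx]
  data.table::fwrite(long, file.path(dir, "scores.csv"))
  data.table::fwrite(
    data.frame(patient_id = res$excluded,
               misclassified_fraction =
                 res$misclassified_fraction[res$excluded]),
    file.path(dir, "excluded.csv"))
  data.table::fwrite(
    data.frame(patient_id = names(res$consensus_score),
               label = res$labels[names(res$consensus_score)],
               consensus_loocv = res$consensus_score,
               consensus_best_fit =
                 res$consensus_best_fit[names(res$consensus_score)]),
    file.path(dir, "consensus.csv"))
  met <- ensemble_metrics(res)
  jsonlite::write_json(met, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = I(10), force = TRUE)
  included <- names(res$consensus_score)
  labs <- res$labels[included]
  fields <- c(best_fit = "consensus_best_fit",
              cross_validation = "consensus_score")
  roc_rows <- do.call(rbind, lapply(names(fields), function(nm) {
    roc <- roc_auc(res[[fields[[nm]]]][included], labs)
    data.frame(analysis = nm, threshold = roc$thresholds,
               sensitivity = roc$sensitivity, specificity = roc$specificity)
  }))
  data.table::fwrite(roc_rows, file.path(dir, "roc.csv"))
  invisible(dir)
}
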