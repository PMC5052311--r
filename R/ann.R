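#' Configuration of the feed-forward classifier
#'
#' A deliberately small, fully deterministic multilayer perceptron: one
#' hidden layer of `hidden_units` tanh units and a logistic output, trained
#' by full-batch gradient descent on the cross-entropy loss with an L2
#' weight penalty. Inputs are standardised internally using training-set
#' statistics stored in the model, so affine rescalings of the features are
#' absorbed.
#'
#' @param hidden_units Hidden-layer width (default 4).
#' @param max_epochs Maximum gradient-descent epochs (default 500).
#' @param learning_rate Initial step size (default 0.01); the step adapts
#'   monotonically (halved when a step would increase the loss, gently
#'   grown otherwise), so training is a descent method regardless of scale.
#' @param l2_penalty L2 penalty on weights, biases excluded (default 1e-3).
#' @param seed Seed for the weight initialisation.
#' @param early_stop_tol Stop when the loss improves by less than this
#'   (default 1e-6).
#' @return An `ann_config` list.
#' @export
ann_config <- function(hidden_units = 4, max_epochs = 500,
                       learning_rate = 0.01, l2_penalty = 1e-3, seed = 1,
                       early_stop_tol = 1e-6) {
  stopifnot(hidden_units >= 1, max_epochs >= 1, learning_rate > 0,
            l2_penalty >= 0, early_stop_tol >= 0)
  structure(list(hidden_units = as.integer(hidden_units),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, l2_penalty = l2_penalty,
                 seed = as.integer(seed), early_stop_tol = early_stop_tol),
            class = "ann_config")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.numeric(labels))
  labels <- as.character(labels)
  if (!all(labels %in% c("HNSCC", "LUNG"))) {
    stop("labels must be \"HNSCC\"/\"LUNG\" (or logical with TRUE = positive)",
         call. = FALSE)
  }
  as.numeric(labels == "HNSCC") # HNSCC is the positive class
}

ann_forward <- function(w, Z) {
  H <- tanh(sweep(Z %*% w$W1, 2, w$b1, `+`))
  p <- stats::plogis(as.numeric(H %*% w$W2) + w$b2)
  list(H = H, p = p)
}

ann_loss <- function(w, Z, y, l2) {
  p <- pmin(pmax(ann_forward(w, Z)$p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p)) +
    0.5 * l2 * (sum(w$W1^2) + sum(w$W2^2))
}

#' Train the classifier on a feature matrix
#'
#' @param features Numeric matrix (rows = patients) or a `feature_set`
#'   from [compress_dataset()].
#' @param labels `"HNSCC"`/`"LUNG"` labels (HNSCC positive) or logical with
#'   `TRUE` positive; both classes must be present.
#' @param config An [ann_config()].
#' @return A `trained_model` holding the weights, the standardisation
#'   statistics, the config and the final training loss (`train_fit`).
#' @export
train_ann <- function(features, labels, config = ann_config()) {
  if (inherits(features, "feature_set")) features <- features$x
  X <- as.matrix(features)
  y <- as_binary_labels(labels)
  if (length(y) != nrow(X)) stop("labels/features length mismatch", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training requires both classes present", call. = FALSE)
  }
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), 1e-8)
  Z <- sweep(sweep(X, 2, ctr, `-`), 2, scl, `/`)
  d <- ncol(Z); h <- config$hidden_units
  w <- withr::with_seed(config$seed, list(
    W1 = matrix(stats::rnorm(d * h, 0, 1 / sqrt(d)), d, h),
    b1 = rep(0, h),
    W2 = stats::rnorm(h, 0, 1 / sqrt(h)),
    b2 = 0))
  l2 <- config$l2_penalty
  lr <- config$learning_rate
  n <- nrow(Z)
  loss <- ann_loss(w, Z, y, l2)
  for (epoch in seq_len(config$max_epochs)) {
    fw <- ann_forward(w, Z)
    dout <- (fw$p - y) / n
    gW2 <- as.numeric(crossprod(fw$H, dout)) + l2 * w$W2
    gb2 <- sum(dout)
    dH <- (dout %o% w$W2) * (1 - fw$H^2)
    gW1 <- crossprod(Z, dH) + l2 * w$W1
    gb1 <- colSums(dH)
    accepted <- FALSE
    for (try in 1:30) {
      cand <- list(W1 = w$W1 - lr * gW1, b1 = w$b1 - lr * gb1,
                   W2 = w$W2 - lr * gW2, b2 = w$b2 - lr * gb2)
      new_loss <- ann_loss(cand, Z, y, l2)
      if (new_loss <= loss) {
        accepted <- TRUE
        break
      }
      lr <- lr / 2
    }
    if (!accepted) break
    improvement <- loss - new_loss
    w <- cand
    loss <- new_loss
    lr <- min(lr * 1.05, 10 * config$learning_rate)
    if (improvement < config$early_stop_tol) break
  }
  structure(list(weights = w, center = ctr, scale = scl, dim = d,
                 config = config, train_fit = loss),
            class = "trained_model")
}

#' Score patients with a trained classifier
#'
#' @param m A `trained_model` from [train_ann()].
#' @param x Numeric vector (one patient) or matrix (rows = patients) of the
#'   training feature dimension.
#' @return Scores in `[0, 1]`; values near 1 favour HNSCC.
#' @export
predict_score <- function(m, x) {
  stopifnot(inherits(m, "trained_model"))
  if (is.null(dim(x))) x <- matrix(x, 1)
  x <- as.matrix(x)
  if (ncol(x) != m$dim) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 m$dim, ncol(x)), call. = FALSE)
  }
  Z <- sweep(sweep(x, 2, m$center, `-`), 2, m$scale, `/`)
  ann_forward(m$weights, Z)$p
}

#' Save / load a trained classifier as JSON
#'
#' Versioned plain-text weights file so models can be archived alongside
#' results.
#' @param m A `trained_model`.
#' @param path Output path.
#' @return `save_model`: invisibly, `path`. `load_model`: the model.
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "trained_model"))
  doc <- list(schema = "breathvoc-ann-1",
              weights = lapply(m$weights, function(v) {
                if (is.matrix(v)) list(dim = dim(v), data = as.numeric(v))
                else list(dim = NULL, data = as.numeric(v))
              }),
              center = m$center, scale = m$scale, dim = m$dim,
              config = unclass(m$config), train_fit = m$train_fit)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "breathvoc-ann-1")) {
    stop("unrecognised model schema: ", doc$schema, call. = FALSE)
  }
  w <- lapply(doc$weights, function(e) {
    if (length(e$dim) == 2) matrix(e$data, e$dim[[1]], e$dim[[2]]) else
      as.numeric(e$data)
  })
  w$b2 <- as.numeric(w$b2)
  cfg <- do.call(ann_config, doc$config)
  structure(list(weights = w[c("W1", "b1", "W2", "b2")],
                 center = as.numeric(doc$center),
                 scale = as.numeric(doc$scale),
                 dim = as.integer(doc$dim), config = cfg,
                 train_fit = doc$train_fit),
            class = "trained_model")
}
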