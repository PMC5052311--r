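scaling_levels <- c("raw", "center_temperature", "center_cycle",
                    "autoscale_temperature", "autoscale_cycle",
                    "log_transform", "unit_max")

#' Enumerate the ensemble of scaling designs
#'
#' The classification protocol runs the same compress-then-classify chain
#' under an ensemble of preprocessing/decomposition recipes and aggregates
#' across them. The default grid crosses 7 scaling variants with 3
#' decompositions (PARAFAC rank 2, PARAFAC rank 4, Tucker3 core (3,3,2)),
#' giving exactly 21 designs in a stable order with stable `design_id`s.
#'
#' @param config Optional override: a list of designs, each a list with
#'   `scaling`, `decomposition` (`"parafac"` or `"tucker3"`) and `rank`
#'   (scalar rank for PARAFAC, length-3 core for Tucker3). An override whose
#'   length is not 21 is accepted with a warning.
#' @return List of `scaling_design` objects, each with `design_id`,
#'   `scaling`, `decomposition`, `rank`.
#' @export
enumerate_designs <- function(config = NULL) {
  if (is.null(config)) {
    decomps <- list(list(decomposition = "parafac", rank = 2L),
                    list(decomposition = "parafac", rank = 4L),
                    list(decomposition = "tucker3", rank = c(3L, 3L, 2L)))
    config <- list()
    for (sc in scaling_levels) {
      for (d in decomps) {
        config[[length(config) + 1L]] <- c(list(scaling = sc), d)
      }
    }
  } else if (length(config) != 21L) {
    warning(sprintf("design grid has %d designs, not the canonical 21",
                    length(config)), call. = FALSE)
  }
  lapply(seq_along(config), function(i) {
    d <- config[[i]]
    d$scaling <- match.arg(d$scaling, scaling_levels)
    d$decomposition <- match.arg(d$decomposition, c("parafac", "tucker3"))
    if (d$decomposition == "parafac") {
      stopifnot(length(d$rank) == 1L, d$rank >= 1, d$rank <= 32)
    } else {
      # core is additionally bounded by the stacked cohort dims at fit time
      stopifnot(length(d$rank) == 3L, all(d$rank >= 1))
    }
    structure(c(list(design_id = i), d), class = "scaling_design")
  })
}

#' Apply a scaling variant to a breath tensor
#'
#' Preprocessing applied per patient before cohort-level decomposition.
#' `center_*` subtracts the mean over the named mode for every pair of
#' remaining indices; `autoscale_*` additionally divides by that mode's
#' standard deviation (floored at 1e-12, so a constant fibre scales to
#' zeros rather than NaN); `log_transform` takes natural logs (valid since
#' conductivities are positive); `unit_max` divides the whole tensor by its
#' maximum; `raw` is the identity.
#'
#' @param t A [breath_tensor()] (or plain 32x36x3 array).
#' @param scaling One of `r paste0('"', scaling_levels, '"', collapse = ", ")`.
#' @return Numeric array of the same shape (no longer constrained positive).
#' @export
apply_scaling <- function(t, scaling = scaling_levels) {
  scaling <- match.arg(scaling)
  x <- array(as.numeric(t), dim(t))
  mode_center <- function(x, mode) {
    m <- apply(x, setdiff(1:3, mode), mean)
    sweep(x, setdiff(1:3, mode), m, `-`)
  }
  mode_autoscale <- function(x, mode) {
    m <- apply(x, setdiff(1:3, mode), mean)
    s <- pmax(apply(x, setdiff(1:3, mode), stats::sd), 1e-12)
    sweep(sweep(x, setdiff(1:3, mode), m, `-`), setdiff(1:3, mode), s, `/`)
  }
  switch(scaling,
         raw = x,
         center_temperature = mode_center(x, 1),
         center_cycle = mode_center(x, 2),
         autoscale_temperature = mode_autoscale(x, 1),
         autoscale_cycle = mode_autoscale(x, 2),
         log_transform = log(x),
         unit_max = x / max(x))
}

#' Reduced six-design grid for desk-scale runs
#'
#' A fixed subset of the canonical 21-design ensemble covering six of the
#' seven scaling variants and all three decomposition settings. Intended
#' for quick analyses and continuous testing where the full ensemble's
#' runtime is not warranted; design ids are inherited from the full grid.
#'
#' @return List of 6 `scaling_design` objects.
#' @export
reduced_design_grid <- function() {
  enumerate_designs()[c(1L, 5L, 9L, 12L, 16L, 20L)]
}
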