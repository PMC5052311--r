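#' Construct a breath conductivity tensor
#'
#' One e-nose measurement: conductivity of three metal-oxide sensors recorded
#' over 32 temperature steps of a periodic heating/cooling ladder, repeated
#' for 36 measurement cycles. Values are in arbitrary instrument units; only
#' their relative structure carries information.
#'
#' @param values Numeric array of dimension 32 x 36 x 3, indexed
#'   `[temperature_step, cycle, sensor]`. All values must be finite and
#'   strictly positive (they are conductivities).
#' @param temperature_range Ordered pair of degrees Celsius spanned by the
#'   temperature ladder (default `c(260, 340)`).
#' @return A `breath_tensor`: the numeric array with the temperature range
#'   attached as an attribute.
#' @seealso [validate_tensor()]
#' @export
breath_tensor <- function(values, temperature_range = c(260, 340)) {
  values <- as.array(values)
  dimnames(values) <- NULL
  names(dim(values)) <- NULL
  t <- structure(values, temperature_range = as.numeric(temperature_range),
                 class = "breath_tensor")
  bad <- validate_tensor(t)
  if (length(bad)) {
    stop("invalid breath tensor: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  t
}

#' Tensor dimensions fixed by the measurement protocol
#' @return Integer vector `c(temperature = 32, cycle = 36, sensor = 3)`.
#' @export
tensor_dims <- function() c(temperature = 32L, cycle = 36L, sensor = 3L)

#' Validate a breath tensor
#'
#' Checks the measurement-protocol invariants: shape exactly 32 x 36 x 3, all
#' values finite and strictly positive, temperature range increasing. Never
#' throws; returns a description of every violation found.
#'
#' @param t Object to check (typically a [breath_tensor()]).
#' @return Character vector of violation descriptions, each naming the
#'   offending axis or index; `character(0)` if the tensor conforms.
#' @export
validate_tensor <- function(t) {
  bad <- character(0)
  dm <- dim(t)
  want <- tensor_dims()
  if (is.null(dm) || length(dm) != 3L) {
    return(sprintf("not a 3-way array (got %s dimensions)",
                   if (is.null(dm)) "no" else length(dm)))
  }
  if (!all(dm == want)) {
    bad <- c(bad, sprintf("shape is %s, expected 32x36x3",
                          paste(dm, collapse = "x")))
  } else {
    v <- as.numeric(t)
    nf <- which(!is.finite(v))
    np <- which(is.finite(v) & v <= 0)
    if (length(nf)) {
      ix <- arrayInd(nf[1L], dm)
      bad <- c(bad, sprintf(
        "%d non-finite value(s), first at (temperature=%d, cycle=%d, sensor=%d)",
        length(nf), ix[1], ix[2], ix[3]))
    }
    if (length(np)) {
      ix <- arrayInd(np[1L], dm)
      bad <- c(bad, sprintf(
        "%d non-positive conductivity value(s), first at (temperature=%d, cycle=%d, sensor=%d)",
        length(np), ix[1], ix[2], ix[3]))
    }
  }
  tr <- attr(t, "temperature_range")
  if (!is.null(tr) && (length(tr) != 2L || !all(is.finite(tr)) || tr[1] >= tr[2])) {
    bad <- c(bad, "temperature_range must be an increasing pair of degrees C")
  }
  bad
}

#' @export
print.breath_tensor <- function(x, ...) {
  tr <- attr(x, "temperature_range")
  cat(sprintf("<breath_tensor> 32x36x3 conductivities, %g-%g degC, range [%.3g, %.3g]\n",
              tr[1], tr[2], min(x), max(x)))
  invisible(x)
}
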