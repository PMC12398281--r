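#' Numerically stable sigmoid
#'
#' Overflow-free logistic function \eqn{S(x) = 1/(1+e^{-x})}.
#'
#' @param x numeric vector.
#' @return numeric vector in (0, 1).
#' @export
sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Numerically stable log-sigmoid
#'
#' Computes \eqn{\log S(x)} without overflow for large |x|.
#'
#' @param x numeric vector.
#' @return numeric vector, nonpositive.
#' @export
log_sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- -log1p(exp(-x[pos]))
  out[!pos] <- x[!pos] - log1p(exp(x[!pos]))
  out
}

# internal argument checks -------------------------------------------------

stop_shape <- function(...) stop(..., call. = FALSE)

check_numeric_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_shape(name, " must be a numeric matrix")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_shape(name, " contains missing or non-finite values")
  }
  invisible(x)
}

as_binary <- function(x, name) {
  x <- as.numeric(x)
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop_shape(name, " must be coded in {0, 1}")
  }
  x
}
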