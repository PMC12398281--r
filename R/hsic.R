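#' Kernel specification
#'
#' Describes a positive semi-definite kernel for use in [hsic()].
#'
#' @param name one of `"linear"`, `"rbf"`, `"polynomial"`.
#' @param bandwidth positive bandwidth for the RBF kernel
#'   \eqn{k(x,x') = \exp(-\|x-x'\|^2 / (2\,bandwidth^2))}.
#' @param degree integer degree (>= 1) for the polynomial kernel.
#' @param offset nonnegative offset for the polynomial kernel
#'   \eqn{k(x,x') = (x^\top x' + offset)^{degree}}.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(name = c("linear", "rbf", "polynomial"),
                        bandwidth = 1, degree = 2L, offset = 1) {
  name <- match.arg(name)
  if (name == "rbf" && (!is.numeric(bandwidth) || bandwidth <= 0)) {
    stop("bandwidth must be > 0 for the rbf kernel", call. = FALSE)
  }
  if (name == "polynomial") {
    if (degree < 1 || degree != as.integer(degree)) {
      stop("degree must be an integer >= 1 for the polynomial kernel",
           call. = FALSE)
    }
    if (offset < 0) stop("offset must be >= 0", call. = FALSE)
  }
  structure(list(name = name, bandwidth = bandwidth,
                 degree = as.integer(degree), offset = offset),
            class = "kernel_spec")
}

#' Gram matrix under a kernel specification
#'
#' @param x m x p numeric matrix (samples in rows).
#' @param kernel a [kernel_spec()].
#' @return m x m symmetric PSD matrix.
#' @export
gram_matrix <- function(x, kernel = kernel_spec("linear")) {
  x <- as.matrix(x)
  check_numeric_matrix(x, "x")
  inner <- tcrossprod(x)
  K <- switch(kernel$name,
    linear = inner,
    polynomial = (inner + kernel$offset)^kernel$degree,
    rbf = {
      sq <- diag(inner)
      d2 <- outer(sq, sq, "+") - 2 * inner
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * kernel$bandwidth^2))
    }
  )
  (K + t(K)) / 2
}

#' Centering matrix H
#'
#' \eqn{H = I - (1/m) 1 1^\top}; annihilates constants: `H %*% rep(1, m)` is 0.
#'
#' @param m number of samples (>= 1).
#' @return m x m centering matrix.
#' @export
centering_matrix <- function(m) {
  diag(m) - matrix(1 / m, m, m)
}

#' Hilbert-Schmidt independence criterion (biased empirical estimator)
#'
#' Measures statistical dependence between two multivariate samples as
#' \deqn{\rho_h(X, Y) = \frac{1}{(m-1)^2}\mathrm{tr}(K H L H),}
#' where K and L are the Gram matrices of the rows of `samples_x` and
#' `samples_y` and H is the centering matrix.  The value is nonnegative for
#' PSD kernels and zero iff the empirical kernel dependence vanishes.
#'
#' @param samples_x m x p numeric matrix.
#' @param samples_y m x q numeric matrix (same number of rows).
#' @param kernel_x,kernel_y [kernel_spec()] objects.
#' @return a nonnegative scalar.
#' @export
hsic <- function(samples_x, samples_y,
                 kernel_x = kernel_spec("linear"),
                 kernel_y = kernel_spec("linear")) {
  samples_x <- as.matrix(samples_x)
  samples_y <- as.matrix(samples_y)
  m <- nrow(samples_x)
  if (m < 2) stop("hsic requires at least 2 samples", call. = FALSE)
  if (nrow(samples_y) != m) {
    stop_shape("samples_x and samples_y must have the same number of rows")
  }
  K <- gram_matrix(samples_x, kernel_x)
  L <- gram_matrix(samples_y, kernel_y)
  H <- centering_matrix(m)
  KH <- K %*% H
  LH <- L %*% H
  val <- sum(t(KH) * LH) / (m - 1)^2  # tr(KH %*% LH)
  max(val, 0)
}

#' Simplified HSIC between a linear projection and a grouping vector
#'
#' For a linear projection \eqn{w^\top X} of the (augmented) design and a
#' binary grouping vector g with rank-one Gram matrix \eqn{L = g g^\top},
#' the HSIC trace collapses to a quadratic form
#' \deqn{\rho_{sh}(w^\top X, g) = w^\top X H L H X^\top w
#'       = (w^\top X (g - \bar g))^2,}
#' computed here without ever materializing the m x m matrices (cost O(mp)).
#'
#' `X` is supplied samples-by-features (m rows); the features-by-samples
#' orientation of the formula above is an internal convention.
#'
#' @param w weight vector of length `ncol(X)`.
#' @param X m x (p+1) numeric design matrix, samples in rows (include the
#'   constant column yourself if the bias participates).
#' @param g length-m grouping vector; any numeric coding (the centering
#'   absorbs affine re-coding up to a scalar).
#' @param normalize if `TRUE`, divide by \eqn{(m-1)^2} so the value matches
#'   the general [hsic()] scale and is stable across sample sizes.  The
#'   default `FALSE` returns the raw quadratic form.
#' @return a nonnegative scalar.
#' @export
simplified_hsic <- function(w, X, g, normalize = FALSE) {
  X <- as.matrix(X)
  if (length(w) != ncol(X)) {
    stop_shape("length(w) must equal ncol(X)")
  }
  if (length(g) != nrow(X)) {
    stop_shape("length(g) must equal nrow(X)")
  }
  gc <- g - mean(g)
  s <- sum((X %*% w) * gc)^2
  if (normalize) s <- s / (nrow(X) - 1)^2
  s
}
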