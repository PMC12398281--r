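# Independent oracles used across the suite.  These deliberately re-derive
# quantities through different routes (dense algebra, finite differences,
# IRLS) than the package's implementations.

# dense-algebra simplified HSIC: materializes H and L = g g^T explicitly
dense_simplified_hsic <- function(w, X, g, normalize = FALSE) {
  m <- nrow(X)
  H <- diag(m) - matrix(1 / m, m, m)
  L <- outer(g, g)
  Xt <- t(X)  # features x samples, as in the printed form
  val <- drop(t(w) %*% Xt %*% H %*% L %*% H %*% t(Xt) %*% w)
  if (normalize) val <- val / (m - 1)^2
  val
}

# central finite differences of a scalar function
fd_gradient <- function(fn, w, eps = 1e-6) {
  vapply(seq_along(w), function(k) {
    wp <- w; wm <- w
    wp[k] <- wp[k] + eps
    wm[k] <- wm[k] - eps
    (fn(wp) - fn(wm)) / (2 * eps)
  }, numeric(1))
}

# l2-penalized logistic regression by IRLS/Newton; the whole weight vector
# (bias included) is penalized, matching the GSDA convention alpha/2 * w'w.
irls_ridge_logistic <- function(X, y, alpha, max_iter = 100, tol = 1e-12) {
  Xa <- cbind(1, X)
  w <- numeric(ncol(Xa))
  for (k in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-drop(Xa %*% w)))
    grad <- drop(crossprod(Xa, p - y)) + alpha * w
    S <- p * (1 - p)
    Hm <- crossprod(Xa, Xa * S) + alpha * diag(ncol(Xa))
    step <- solve(Hm, grad)
    w <- w - step
    if (max(abs(step)) < tol) break
  }
  w
}

# small random grouped design with both groups and balanced labels
random_design <- function(m = 20, p = 3, seed = 1) {
  set.seed(seed)
  feats <- matrix(rnorm(m * p), m, p)
  labels <- rep(c(0, 1), length.out = m)
  groups <- rep(c(0, 0, 1, 1), length.out = m)
  grouped_design(feats, labels, groups, paste0("s", seq_len(m)))
}

# scaled-down synthetic world for unit tests (same structure as the
# defaults, fewer subjects / smaller h to keep the suite fast)
tiny_config <- function(seed = 1, n = 40, h = 12, ...) {
  synthetic_config(
    n_subjects_per_group = n, h = h,
    lobes = stats::setNames(c(h %/% 2, h - h %/% 2), c("frontal", "parietal")),
    shared_lateralized = data.frame(i = c(0, 2), j = c(1, 5),
                                    offset = 1.2, scale0 = c(1, 0.4),
                                    scale1 = c(1, 1.6)),
    exclusive_lateralized = data.frame(i = c(3, 4), j = c(8, 9),
                                       offset = 1.2, group = c(0, 1)),
    group_mean = data.frame(i = 6, j = 10, delta = 0.8),
    seed = seed, ...)
}
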