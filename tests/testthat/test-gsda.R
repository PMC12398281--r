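test_that("negative log-likelihood matches closed forms at w = 0", {
  d <- random_design(m = 20, p = 3, seed = 4)
  nt <- sum(d$groups == 0)
  w0 <- numeric(4)

  # lambda = 0, alpha = 0, balanced labels: n_t * log 2
  p00 <- gsda_hyperparams(alpha = 0, lam = 0)
  expect_equal(gsda_negloglik(w0, d, 0, p00), nt * log(2))

  # any lambda at w = 0 adds exactly lambda * log 2 (rho_sh(0) = 0)
  p05 <- gsda_hyperparams(alpha = 0, lam = 5)
  expect_equal(gsda_negloglik(w0, d, 0, p05), nt * log(2) + 5 * log(2))
})

test_that("negative log-likelihood matches a dense brute-force oracle", {
  d <- random_design(m = 20, p = 3, seed = 9)
  params <- gsda_hyperparams(alpha = 0.1, lam = 5)
  set.seed(2)
  w <- rnorm(4) * 0.5

  Xa <- cbind(1, d$features)
  t_idx <- d$groups == 0
  s <- drop(Xa[t_idx, ] %*% w)
  S <- 1 / (1 + exp(-s))
  ll <- -sum(d$labels[t_idx] * log(S) + (1 - d$labels[t_idx]) * log(1 - S))
  rho <- dense_simplified_hsic(w, Xa, d$groups, normalize = TRUE)
  expected <- ll + 0.1 / 2 * sum(w^2) - 5 * log(1 / (1 + exp(-rho)))
  expect_equal(gsda_negloglik(w, d, 0, params), expected, tolerance = 1e-10)
})

test_that("analytic gradient agrees with central finite differences", {
  d <- random_design(m = 20, p = 3, seed = 21)
  lam <- 5
  set.seed(22)
  for (rep in 1:10) {
    w <- rnorm(4) * 0.8
    # printed-form gradient == gradient of the objective with the
    # dependence term at lam/2 (the matched pairing used by the optimizer)
    fd_v <- fd_gradient(function(v) gsda_negloglik(
      v, d, 0, gsda_hyperparams(alpha = 0.1, lam = lam / 2)), w)
    an_v <- gsda_gradient(w, d, 0,
                          gsda_hyperparams(alpha = 0.1, lam = lam,
                                           grad_variant = "verbatim"))
    expect_lt(max(abs(fd_v - an_v)) / max(1, max(abs(fd_v))), 1e-5)

    # analytically exact variant == gradient of the full-lam objective
    fd_e <- fd_gradient(function(v) gsda_negloglik(
      v, d, 0, gsda_hyperparams(alpha = 0.1, lam = lam)), w)
    an_e <- gsda_gradient(w, d, 0,
                          gsda_hyperparams(alpha = 0.1, lam = lam,
                                           grad_variant = "exact"))
    expect_lt(max(abs(fd_e - an_e)) / max(1, max(abs(fd_e))), 1e-5)
  }
})

test_that("gradient degenerates correctly", {
  d <- random_design(m = 16, p = 4, seed = 31)
  w0 <- numeric(5)
  # at w = 0 the dependence term vanishes: grad = X_t (0.5 - y_t)
  g <- gsda_gradient(w0, d, 0, gsda_hyperparams(alpha = 0, lam = 7))
  Xa <- cbind(1, d$features)
  t_idx <- d$groups == 0
  expect_equal(g, drop(crossprod(Xa[t_idx, ],
                                 0.5 - d$labels[t_idx])),
               tolerance = 1e-12)

  # lambda = 0, alpha = 0: standard logistic gradient on target samples
  set.seed(32)
  w <- rnorm(5)
  g0 <- gsda_gradient(w, d, 1, gsda_hyperparams(alpha = 0, lam = 0))
  s <- drop(Xa[d$groups == 1, ] %*% w)
  expect_equal(g0, drop(crossprod(Xa[d$groups == 1, ],
                                  1 / (1 + exp(-s)) - d$labels[d$groups == 1])),
               tolerance = 1e-12)
})

test_that("lambda = 0 fit matches an independent IRLS ridge-logistic", {
  for (seed in 1:20) {
    d <- random_design(m = 40, p = 5, seed = 100 + seed)
    params <- gsda_hyperparams(alpha = 0.1, lam = 0, tol = 1e-8)
    for (tg in c(0, 1)) {
      fit <- gsda_fit(d, tg, params)
      t_idx <- d$groups == tg
      ref <- irls_ridge_logistic(d$features[t_idx, , drop = FALSE],
                                 d$labels[t_idx], alpha = 0.1)
      expect_lt(max(abs(fit$weights - ref)), 1e-4)
    }
  }
})

test_that("fits are deterministic and converge on toy problems", {
  d <- random_design(m = 30, p = 4, seed = 55)
  params <- gsda_hyperparams(alpha = 0.1, lam = 5)
  f1 <- gsda_fit(d, 0, params, seed = 3)
  f2 <- gsda_fit(d, 0, params, seed = 3)
  expect_identical(f1$weights, f2$weights)
  expect_true(f1$converged)
  expect_true(all(is.finite(f1$weights)))
})

test_that("gradient descent decreases its matched objective monotonically", {
  d <- random_design(m = 24, p = 3, seed = 77)
  lam <- 4
  grad_params <- gsda_hyperparams(alpha = 0.1, lam = lam)
  obj_params <- gsda_hyperparams(alpha = 0.1, lam = lam / 2)
  w <- numeric(4)
  prev <- gsda_negloglik(w, d, 0, obj_params)
  for (k in 1:100) {
    w <- w - 0.01 * gsda_gradient(w, d, 0, grad_params)
    cur <- gsda_negloglik(w, d, 0, obj_params)
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("fit rejects degenerate designs", {
  d <- random_design(m = 12, p = 2, seed = 8)
  # single-class target labels
  bad <- grouped_design(d$features, rep(1, 12), d$groups, d$subject_ids)
  expect_error(gsda_fit(bad, 0, gsda_hyperparams()), "single class")
  # lam > 0 with one group only
  solo <- grouped_design(d$features, d$labels, rep(0, 12), d$subject_ids)
  expect_error(gsda_fit(solo, 0, gsda_hyperparams(lam = 5)), "both groups")
  # absent target group
  expect_error(gsda_fit(solo, 1, gsda_hyperparams(lam = 0)), "target group")
})

test_that("prediction rule and probabilities", {
  w <- c(0, 1, 0, 0)
  model <- structure(list(weights = w, target_group = 0,
                          hyperparams = gsda_hyperparams(),
                          center = NULL, scale = NULL),
                     class = "gsda_model")
  # score exactly 0 -> label 1 (ties to 1)
  expect_identical(predict(model, matrix(0, 1, 3)), 1L)
  # first feature -3 -> S(-3) < 0.5 -> 0
  expect_identical(predict(model, matrix(c(-3, 5, 5), 1, 3)), 0L)
  expect_equal(predict_proba(model, matrix(0, 1, 3)), 0.5)
  # stable for huge scores
  expect_gte(predict_proba(model, matrix(c(1e3, 0, 0), 1, 3)), 1 - 1e-12)

  # elementwise agreement with a scalar sigmoid loop
  set.seed(91)
  X <- matrix(rnorm(30), 10, 3)
  wr <- rnorm(4)
  mr <- structure(list(weights = wr, target_group = 0,
                       hyperparams = gsda_hyperparams(),
                       center = NULL, scale = NULL), class = "gsda_model")
  manual <- vapply(seq_len(10), function(i) {
    s <- wr[1] + sum(wr[-1] * X[i, ])
    as.integer(1 / (1 + exp(-s)) >= 0.5)
  }, integer(1))
  expect_identical(predict(mr, X), manual)
  expect_error(predict(mr, matrix(0, 2, 5)), "columns")
})

test_that("model serialization round-trips through JSON", {
  d <- random_design(m = 20, p = 3, seed = 13)
  fit <- gsda_fit(d, 1, gsda_hyperparams(alpha = 0.1, lam = 2), seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_gsda_model(fit, path)
  back <- read_gsda_model(path)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$hyperparams$lam, 2)
  expect_equal(back$target_group, 1)
  X <- matrix(rnorm(15), 5, 3)
  expect_identical(predict(back, X), predict(fit, X))
})
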