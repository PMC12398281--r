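# helper: minimal first-order ensemble objects with prescribed weights
fake_ensemble <- function(W, target_group, lam = 5, alpha = 0.1) {
  n <- nrow(W)
  structure(list(
    records = data.frame(rep = seq_len(n), seed = seq_len(n), lam = lam,
                         alpha = alpha, target_group = target_group),
    weights = W,
    meta = list(alpha = alpha, lam_grid = lam, n_repetitions = n)),
    class = "first_order_ensemble")
}

test_that("second-order design assembly stacks weights and labels", {
  p <- 6
  Wm <- matrix(rnorm(3 * (p + 1)), 3)
  Wf <- matrix(rnorm(4 * (p + 1)), 4)
  d <- assemble_second_order_design(fake_ensemble(Wm, 0),
                                    fake_ensemble(Wf, 1), lam = 5)
  expect_equal(dim(d$features), c(7, p))        # bias excluded
  expect_equal(d$labels, c(0L, 0L, 0L, 1L, 1L, 1L, 1L))
  expect_equal(d$features[1, ], Wm[1, -1])      # column alignment
  # single model per side -> 2-row design
  d2 <- assemble_second_order_design(fake_ensemble(Wm[1, , drop = FALSE], 0),
                                     fake_ensemble(Wf[1, , drop = FALSE], 1))
  expect_equal(dim(d2$features), c(2, p))
  expect_error(assemble_second_order_design(fake_ensemble(Wm, 0),
                                            fake_ensemble(Wf, 1), lam = 3),
               "lam = 3")
})

test_that("second-order classification separates separable classes", {
  set.seed(10)
  p <- 8
  Wm <- cbind(0, matrix(rnorm(30 * p, 0, 0.1), 30)); Wm[, 2] <- Wm[, 2] + 2
  Wf <- cbind(0, matrix(rnorm(30 * p, 0, 0.1), 30)); Wf[, 2] <- Wf[, 2] - 2
  d <- assemble_second_order_design(fake_ensemble(Wm, 0),
                                    fake_ensemble(Wf, 1))
  res <- run_second_order(d, n_splits = 10, base_seed = 4)
  expect_equal(res$accuracy, rep(1, 10))
  expect_length(run_second_order(d, n_splits = 3, base_seed = 1)$accuracy, 3)
})

test_that("second-order accuracy is at chance for same-distribution classes", {
  set.seed(20)
  p <- 10
  W <- cbind(0, matrix(rnorm(80 * p), 80))  # one common distribution
  d <- assemble_second_order_design(fake_ensemble(W[1:40, ], 0),
                                    fake_ensemble(W[41:80, ], 1))
  res <- run_second_order(d, n_splits = 40, base_seed = 7)
  n_test <- 80 - 2 * round(0.8 * 40)
  half_width <- 1.96 * sqrt(0.25 / n_test)
  expect_lt(abs(mean(res$accuracy) - 0.5), half_width)
})

test_that("derive_mask implements floor(top_fraction * p) with tie-breaks", {
  # identical vectors at full scale: mask size floor(0.05 * 7503) = 375
  set.seed(30)
  v <- rnorm(7503)
  mask <- derive_mask(v, v, 0.05)
  expect_length(mask$indices, 375)

  # disjoint top sets -> empty mask
  expect_length(derive_mask(20:1, 1:20, 0.20)$indices, 0)

  # p = 20 toy vs brute-force sort-and-intersect
  set.seed(31)
  wa <- rnorm(20); wb <- rnorm(20)
  k <- floor(0.25 * 20)
  brute <- intersect(order(-abs(wa))[1:k], order(-abs(wb))[1:k]) - 1
  expect_setequal(derive_mask(wa, wb, 0.25)$indices, brute)

  # ties at the k-th magnitude broken by lower index
  tie <- c(5, 3, 3, 1)
  expect_equal(derive_mask(tie, tie, 0.5)$indices, c(0L, 1L))
  expect_error(derive_mask(wa, wb[1:10]), "length")
})

test_that("apply_mask_to_model intersects with the model's own top set", {
  w <- c(10, -9, 8, 0.1, 0.2, -0.3, 7, 0.4, 0.5, 0.6)
  mask <- structure(list(indices = c(0L, 1L, 3L)),
                    class = "lateralization_mask")
  sel <- apply_mask_to_model(w, mask, top_fraction = 0.4)
  # model top-4 by |w|: indices 0,1,2,6; intersection with mask: 0,1
  expect_equal(sel$index, c(0L, 1L))
  expect_equal(sel$weight, c(10, -9))
  empty <- structure(list(indices = integer(0)),
                     class = "lateralization_mask")
  expect_equal(nrow(apply_mask_to_model(w, empty, 0.4)), 0)
})

test_that("shared/exclusive partition matches hand enumeration", {
  sel <- list(
    hcp = list(male = data.frame(index = c(1, 2, 3), weight = 1),
               female = data.frame(index = c(2, 3, 4), weight = 1)),
    gsp = list(male = data.frame(index = c(1, 5), weight = 1),
               female = data.frame(index = c(6, 7), weight = 1)))
  out <- shared_exclusive_partition(sel)
  expect_equal(out$hcp$shared, c(2, 3))
  expect_equal(out$hcp$male_exclusive, 1)
  expect_equal(out$hcp$female_exclusive, 4)
  expect_length(out$gsp$shared, 0)
  expect_setequal(out$unique_connections, c(1, 2, 3, 4, 5, 6, 7))
  expect_equal(out$n_with_repetition, 10)

  # identical lists: all shared; disjoint: all exclusive
  same <- shared_exclusive_partition(list(d = list(male = 1:3, female = 1:3)))
  expect_equal(same$d$shared, 1:3)
  expect_length(same$d$male_exclusive, 0)
})

test_that("lobe average degree counts chord endpoints per lobe", {
  atlas <- default_atlas(35, c(A = 10, B = 5, C = 20))
  h <- 35
  # single chord inside lobe A (ROIs 0-9): 2 endpoints / 10 ROIs
  m1 <- structure(list(indices = pair_to_linear_index(0, 9, h)),
                  class = "lateralization_mask")
  d1 <- lobe_average_degree(m1, atlas)
  expect_equal(unname(d1["A"]), 0.2)
  expect_equal(unname(d1["B"]), 0)

  # chord spanning B (size 5) and C (size 20)
  m2 <- structure(list(indices = pair_to_linear_index(10, 20, h)),
                  class = "lateralization_mask")
  d2 <- lobe_average_degree(m2, atlas)
  expect_equal(unname(d2["B"]), 1 / 5)
  expect_equal(unname(d2["C"]), 1 / 20)

  # 6 chords, hand count: A-A, A-B, A-C, B-C, C-C, C-C
  idx <- c(pair_to_linear_index(c(0, 1, 2, 11, 21, 23),
                                c(5, 12, 30, 25, 22, 24), h))
  m3 <- structure(list(indices = idx), class = "lateralization_mask")
  d3 <- lobe_average_degree(m3, atlas)
  expect_equal(unname(d3["A"]), 4 / 10)   # endpoints: 0,5,1,2
  expect_equal(unname(d3["B"]), 2 / 5)    # endpoints: 12,11
  expect_equal(unname(d3["C"]), 6 / 20)   # endpoints: 30,25,21,22,23,24
})

test_that("interaction sign counts classify lobe relation and sign", {
  atlas <- default_atlas(10, c(A = 5, B = 5))
  h <- 10
  sel <- list(
    male = data.frame(index = pair_to_linear_index(c(0, 1), c(1, 7), h),
                      weight = c(0.5, -0.2)),     # intra+, inter-
    female = data.frame(index = pair_to_linear_index(c(5, 2), c(8, 3), h),
                        weight = c(0.3, 0)))      # intra+, intra+ (0 -> +)
  counts <- interaction_sign_counts(sel, atlas)
  get <- function(g, r, s) counts$count[counts$group == g &
                                          counts$relation == r &
                                          counts$sign == s]
  expect_equal(get("male", "intra", "positive"), 1)
  expect_equal(get("male", "inter", "negative"), 1)
  expect_equal(get("female", "intra", "positive"), 2)
  expect_equal(get("female", "inter", "positive"), 0)
  expect_equal(sum(counts$count), 4)

  # empty selection: all zeros
  empty <- interaction_sign_counts(
    list(male = data.frame(index = integer(0), weight = numeric(0))), atlas)
  expect_true(all(empty$count == 0))
})

test_that("mask edge list exports ROI pairs with lobes and signs", {
  atlas <- default_atlas(10, c(A = 5, B = 5))
  mask <- structure(list(indices = pair_to_linear_index(c(0, 4), c(2, 7), 10)),
                    class = "lateralization_mask")
  w <- seq(-1, 1, length.out = 45)
  edges <- mask_edge_list(mask, atlas, weights = w)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$roi_i, c(0, 4))
  expect_equal(edges$roi_j, c(2, 7))
  expect_equal(edges$lobe_i, c("A", "A"))
  expect_equal(edges$lobe_j, c("A", "B"))
  expect_equal(edges$weight, w[mask$indices + 1])
})
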