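# The MKL trainer against independent oracles: libsvm (e1071) for the
# single-kernel case, hand KKT analysis for a tiny toy problem, and its
# own contracts (dual feasibility, objective monotonicity, permutation
# invariance, the missing-group rescaling path).

test_that("single-kernel training equals a standalone SVM (libsvm oracle)", {
  for (seed in 1:3) {
    prob <- separable_problem(n_per_class = 15, q = 3, shift = 2,
                              seed = seed)
    ks <- compute_base_kernels(prob$features)
    m <- train_mkl(ks, prob$labels, C = 1)
    expect_equal(unname(m$weights), 1)           # simplex of dimension 1
    set.seed(seed + 100)
    x_new <- matrix(rnorm(8 * 3), 8, 3)
    phi <- predict(m, feature_group_set(list(A = x_new)))
    # oracle operates on the same standardized-normalized feature space
    sc <- ks$scalers$A
    z_tr <- ks$train_features$A / sqrt(rowSums(ks$train_features$A^2))
    z_new <- scale(x_new, sc$center, sc$scale)
    z_new <- z_new / sqrt(rowSums(z_new^2))
    phi_ref <- libsvm_phi(z_tr, prob$labels, z_new, C = 1)
    expect_equal(phi, phi_ref, tolerance = 1e-6)
  }
})

test_that("duplicated base kernels leave the decision function unchanged", {
  prob <- separable_problem(n_per_class = 12, q = 4, shift = 1.5, seed = 7)
  x <- prob$x
  ks1 <- compute_base_kernels(feature_group_set(list(A = x)))
  ks2 <- compute_base_kernels(feature_group_set(list(A = x, B = x)))
  m1 <- train_mkl(ks1, prob$labels, C = 1)
  m2 <- train_mkl(ks2, prob$labels, C = 1)
  set.seed(8)
  x_new <- matrix(rnorm(6 * 4), 6, 4)
  phi1 <- predict(m1, feature_group_set(list(A = x_new)))
  phi2 <- predict(m2, feature_group_set(list(A = x_new, B = x_new)))
  expect_equal(phi1, phi2, tolerance = 1e-6)
  expect_equal(sum(m2$weights), 1, tolerance = 1e-9)
})

test_that("hand-solved toy problem: decision values match the KKT analysis", {
  # one feature, three training points; after standardization and
  # unit-diagonal normalization a 1-d linear kernel becomes the sign
  # kernel s_i s_j with s_i = sign(x_i - mean(x)). Points: x = (-1, -0.5, 1),
  # y = (-1, -1, +1) -> s = (-1, -1, +1), classes sit at -1/+1 in the
  # s-space, maximal margin w = 1, b = 0, phi(x) = sign(x - mean(x)).
  fs <- feature_group_set(list(G = matrix(c(-1, -0.5, 1), 3, 1)))
  ks <- compute_base_kernels(fs)
  m <- train_mkl(ks, c(-1, -1, 1), C = 10)
  expect_equal(m$bias, 0, tolerance = 1e-6)
  phi <- predict(m, feature_group_set(list(G = matrix(c(0.5, -2), 2, 1))))
  expect_equal(phi, c(1, -1), tolerance = 1e-6)
  # dual invariants: sum alpha_i y_i = 0, 0 <= |alpha_i y_i| <= C
  expect_lt(abs(sum(m$dual_coef)), 1e-6 * m$C * 3)
  expect_true(all(abs(m$dual_coef) <= m$C + 1e-8))
})

test_that("the dual solve satisfies the KKT conditions to near machine precision", {
  # oracle-free optimality certificate across C regimes
  for (C in c(0.1, 1, 10)) {
    prob <- separable_problem(n_per_class = 20, q = 3, shift = 2,
                              seed = 50 + round(10 * C))
    ks <- compute_base_kernels(prob$features)
    m <- train_mkl(ks, prob$labels, C = C)
    alpha <- abs(m$dual_coef)
    marg <- prob$labels *
      (as.vector(ks$matrices$A %*% m$dual_coef) + m$bias)
    free <- alpha > 1e-8 * C & alpha < C * (1 - 1e-8)
    if (any(free)) expect_lt(max(abs(marg[free] - 1)), 1e-8 * max(1, C))
    expect_lt(max(1 - marg[alpha <= 1e-8 * C], 0), 1e-8 * max(1, C))
    expect_lt(max(marg[alpha >= C * (1 - 1e-8)] - 1, 0), 1e-8 * max(1, C))
  }
})

test_that("dual feasibility and objective monotonicity hold during training", {
  sim <- generate_synthetic(synthetic_config(n_pos = 60, n_neg = 60,
                                             seed = 21))
  ks <- compute_base_kernels(sim$features)
  m <- train_mkl(ks, sim$dataset$label, C = 1)
  n <- length(m$dual_coef)
  expect_true(all(abs(m$dual_coef) <= m$C + 1e-8))
  expect_lt(abs(sum(m$dual_coef)), 1e-6 * m$C * n)
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
  expect_true(all(m$weights >= 0))
  # outer objective trace is non-increasing
  expect_true(all(diff(m$objective) <= 1e-8 * abs(m$objective[1])))
})

test_that("permuting training order leaves test decision values unchanged", {
  sim <- generate_synthetic(synthetic_config(n_pos = 40, n_neg = 40,
                                             seed = 31))
  test <- generate_synthetic(synthetic_config(n_pos = 10, n_neg = 10,
                                              seed = 32))
  ks <- compute_base_kernels(sim$features)
  m <- train_mkl(ks, sim$dataset$label, C = 1)
  phi <- predict(m, test$features)
  set.seed(33)
  perm <- sample(nrow(sim$dataset))
  ks_p <- compute_base_kernels(features_subset(sim$features, perm))
  m_p <- train_mkl(ks_p, sim$dataset$label[perm], C = 1)
  phi_p <- predict(m_p, test$features)
  expect_equal(phi, phi_p, tolerance = 1e-6)
})

test_that("errors: single-class labels and misaligned kernels", {
  prob <- separable_problem(n_per_class = 5, seed = 2)
  ks <- compute_base_kernels(prob$features)
  expect_error(train_mkl(ks, rep(1, 10)), "single class")
  expect_error(train_mkl(ks, prob$labels[c(1, 2, 6, 7)]), "misaligned")
  expect_error(train_mkl(ks, c(rep(2, 5), rep(0, 5))), "-1/\\+1")
})

test_that("decision_function applies per-row weight rescaling for missing groups", {
  # hand-constructed model: known dual coefficients, bias and weights
  model <- structure(list(
    weights = c(A = 0.70, B = 0.26, C = 0.01, D = 0.03),
    dual_coef = c(0.5, -0.5), bias = 0.1, support_index = 1:2, C = 1,
    labels = c(1, -1)), class = "mkl_model")
  set.seed(41)
  blocks <- lapply(setNames(nm = c("A", "B", "C", "D")),
                   function(g) matrix(rnorm(3 * 2), 3, 2))
  # fully available row equals the plain composite decision value
  phi_full <- decision_function(model, blocks)
  comp <- compose_kernel(blocks, model$weights)
  expect_equal(phi_full, as.vector(comp %*% model$dual_coef) + 0.1)
  # row 2 missing group D: recompute with hand-renormalized weights
  avail <- matrix(TRUE, 3, 4)
  avail[2, 4] <- FALSE
  phi <- decision_function(model, blocks, avail)
  w_resc <- c(0.70, 0.26, 0.01, 0) / 0.97
  by_hand <- sum(vapply(1:4, function(g)
    w_resc[g] * sum(blocks[[g]][2, ] * model$dual_coef), numeric(1))) + 0.1
  expect_equal(phi[2], by_hand, tolerance = 1e-12)
  expect_equal(phi[-2], phi_full[-2])
  # no available group -> NA decision, NA prediction
  avail[3, ] <- FALSE
  phi2 <- decision_function(model, blocks, avail)
  expect_true(is.na(phi2[3]))
  pred <- predict_labels(model, blocks, avail)
  expect_true(is.na(pred[3]))
  # all dual coefficients zero -> phi = bias everywhere
  model0 <- model
  model0$dual_coef <- c(0, 0)
  expect_equal(decision_function(model0, blocks), rep(0.1, 3))
})

test_that("prediction tie at phi = 0 goes to the positive class", {
  model <- structure(list(weights = c(A = 1), dual_coef = c(1, -1),
                          bias = 0, support_index = 1:2, C = 1,
                          labels = c(1, -1)), class = "mkl_model")
  blocks <- list(A = matrix(c(0.5, 0.5, 0.2, 0.7), 2, 2, byrow = TRUE))
  phi <- decision_function(model, blocks)
  expect_equal(phi, c(0, -0.5))
  expect_equal(predict_labels(model, blocks), c(1L, -1L))
})

test_that("C selection by inner cross-validation favors the regularized end on noisy kernels", {
  sim <- generate_synthetic(synthetic_config(n_pos = 80, n_neg = 80,
                                             seed = 55))
  ks <- compute_base_kernels(sim$features)
  tc <- tune_C(ks, sim$dataset$label, grid = c(0.01, 1, 100), seed = 5)
  expect_true(tc$C %in% c(0.01, 1, 100))
  expect_equal(names(tc$auc), c("0.01", "1", "100"))
  # noise groups reward regularization: the inner-CV AUC at the small-C
  # end should not lose to the unregularized end
  expect_gte(tc$auc[["0.01"]], tc$auc[["100"]] - 0.02)
})
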