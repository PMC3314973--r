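test_that("softmax probabilities are row-stochastic, shift-invariant, and match the scalar oracle", {
  toy <- toy_classification()
  W <- matrix(rnorm(ncol(toy$X) * 3, sd = 0.3), ncol(toy$X), 3)
  P <- softmax_probabilities(toy$X, W)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
  expect_true(all(P > 0 & P < 1))

  # zero weights give the uniform distribution
  P0 <- softmax_probabilities(toy$X, 0 * W)
  expect_equal(P0, matrix(1 / 3, nrow(toy$X), 3), ignore_attr = TRUE)

  # adding one vector to every class column changes nothing
  v <- rnorm(ncol(toy$X))
  expect_equal(softmax_probabilities(toy$X, W + v), P, tolerance = 1e-12)

  # scores (1, 0, -1): exp(1)/(exp(1)+1+exp(-1)) etc., evaluated by hand
  P1 <- softmax_probabilities(matrix(1, 1, 1), matrix(c(1, 0, -1), 1, 3))
  expect_equal(as.numeric(P1),
               c(0.6652409557748219, 0.24472847105479767, 0.09003057317038046),
               tolerance = 1e-15)
})

test_that("log-likelihood matches its algebraic identities and a term-by-term oracle", {
  toy <- toy_classification(n_per_class = 5, d = 4)
  n <- nrow(toy$X)
  # W = 0 -> -n log m
  W0 <- matrix(0, 4, 3)
  expect_equal(log_likelihood(toy$X, toy$Y, W0), -n * log(3), tolerance = 1e-12)
  # equals sum of log predicted-class probabilities
  W <- matrix(rnorm(12, sd = 0.4), 4, 3)
  P <- softmax_probabilities(toy$X, W)
  expect_equal(log_likelihood(toy$X, toy$Y, W),
               sum(log(P[cbind(seq_len(n), max.col(toy$Y))])),
               tolerance = 1e-10)
  # 2-sample, 2-class toy against direct per-term evaluation
  X2 <- rbind(c(0.5, -1), c(2, 0.25))
  Y2 <- rbind(c(1, 0), c(0, 1))
  W2 <- rbind(c(0.2, -0.3), c(0.1, 0.4))
  s <- X2 %*% W2
  manual <- sum(Y2 * s) -
    (log(exp(s[1, 1]) + exp(s[1, 2])) + log(exp(s[2, 1]) + exp(s[2, 2])))
  expect_equal(log_likelihood(X2, Y2, W2), manual, tolerance = 1e-12)
  # malformed labels are rejected
  expect_error(log_likelihood(X2, rbind(c(1, 1), c(0, 1)), W2), "one-of-m")
})

test_that("objective combines likelihood and penalties correctly", {
  toy <- toy_classification(n_per_class = 5, d = 4)
  W <- matrix(c(1, -2, 0, 0.5, 0, 0, 3, -1, 0, 0, 0, 2), 4, 3)
  expect_equal(smlr_objective(toy$X, toy$Y, W, 0, 0),
               log_likelihood(toy$X, toy$Y, W), tolerance = 1e-12)
  # W = 0 -> -n log m for any penalties
  expect_equal(smlr_objective(toy$X, toy$Y, 0 * W, 5, 7),
               -nrow(toy$X) * log(3), tolerance = 1e-12)
  # hand arithmetic: L - 1 * sum|W| - 2 * sum(W^2)
  expect_equal(smlr_objective(toy$X, toy$Y, W, 1, 2),
               log_likelihood(toy$X, toy$Y, W) - 1 * 9.5 - 2 * 19.25,
               tolerance = 1e-12)
})

test_that("a lambda1 above the zero-gradient threshold yields the all-zero fit", {
  toy <- toy_classification()
  # the soft threshold keeps W = 0 iff lambda1 >= max |dL/dw| at W = 0
  G0 <- t(toy$X) %*% (toy$Y - 1 / 3)
  thr <- max(abs(G0))
  fit <- fit_smlr(toy$X, toy$Y, lambda1 = thr * 1.01, lambda2 = 0)
  expect_true(all(fit$weights == 0))
  fit2 <- fit_smlr(toy$X, toy$Y, lambda1 = thr * 0.9, lambda2 = 0)
  expect_gt(sum(fit2$weights != 0), 0)
})

test_that("component-wise fit agrees with an independent full-gradient optimizer", {
  toy <- toy_classification(n_per_class = 20, d = 20)
  lambda2 <- 1e-3
  fit <- fit_smlr(toy$X, toy$Y, lambda1 = 0, lambda2 = lambda2, tol = 1e-9,
                  max_sweeps = 5000)
  W_ref <- optim_smlr_oracle(toy$X, toy$Y, lambda2)
  obj_cd <- smlr_objective(toy$X, toy$Y, fit$weights, 0, lambda2)
  obj_ref <- smlr_objective(toy$X, toy$Y, W_ref, 0, lambda2)
  expect_lt(abs(obj_cd - obj_ref), 1e-4)
  ref_pred <- c("A", "B", "C")[apply(softmax_probabilities(toy$X, W_ref), 1,
                                     which.max)]
  expect_identical(predict(fit, toy$X)$.pred, ref_pred)
})

test_that("objective trace is non-decreasing and strictly concave fits are initialization-independent", {
  toy <- toy_classification()
  for (l1 in c(0, 0.5, 5)) {
    fit <- fit_smlr(toy$X, toy$Y, lambda1 = l1, lambda2 = 0.01)
    expect_true(all(diff(fit$objective_trace) >= -1e-9))
  }
  # lambda1 = 0, lambda2 > 0: strictly concave, two starts agree
  set.seed(1)
  f1 <- fit_smlr(toy$X, toy$Y, 0, 0.05, tol = 1e-9, max_sweeps = 3000)
  f2 <- fit_smlr(toy$X, toy$Y, 0, 0.05, tol = 1e-9, max_sweeps = 3000,
                 W0 = matrix(rnorm(60, sd = 0.5), 20, 3))
  o1 <- smlr_objective(toy$X, toy$Y, f1$weights, 0, 0.05)
  o2 <- smlr_objective(toy$X, toy$Y, f2$weights, 0, 0.05)
  expect_lt(abs(o1 - o2), 1e-6)
})

test_that("sparsity is monotone in lambda1 and duplicated columns are grouped by lambda2", {
  ladder <- c(0.05, 0.5, 2, 8, 30)
  nnz <- numeric(length(ladder))
  avg_over <- 0
  for (s in 1:3) {
    toy <- toy_classification(seed = 100 + s)
    nnz <- nnz + vapply(ladder, function(l1) {
      sum(fit_smlr(toy$X, toy$Y, l1, 1e-3)$weights != 0)
    }, numeric(1))
  }
  expect_true(all(diff(nnz) <= 0))

  # elastic-net grouping: a duplicated informative column gets shared weight
  toy <- toy_classification(n_per_class = 15, d = 6, shift = 3)
  Xd <- cbind(toy$X, toy$X[, 1])  # column 7 duplicates column 1
  fit <- fit_smlr(Xd, toy$Y, lambda1 = 0.5, lambda2 = 1)
  expect_gt(abs(fit$weights[1, 1]), 0)
  expect_gt(abs(fit$weights[7, 1]), 0)
})

test_that("predictions take the highest-probability class with ties to the lowest index", {
  toy <- toy_classification()
  # W = 0: all classes tie -> first class
  fit0 <- fit_smlr(toy$X, toy$Y, lambda1 = 1e6, lambda2 = 0)
  expect_true(all(predict(fit0, toy$X)$.pred == "A"))
  # explicit probability ordering
  fit <- fit_smlr(toy$X, toy$Y, 0.1, 1e-2)
  pr <- predict(fit, toy$X)
  probs <- as.matrix(pr[, fit$classes])
  expect_identical(pr$.pred, fit$classes[apply(probs, 1, which.max)])
  # strong planted effects are recovered
  expect_gt(mean(pr$.pred == toy$y), 0.95)
})

test_that("degenerate inputs are handled", {
  toy <- toy_classification(n_per_class = 5, d = 4)
  # an all-zero column keeps zero weight
  X0 <- toy$X; X0[, 2] <- 0
  fit <- fit_smlr(X0, toy$Y, 0.1, 0.1)
  expect_true(all(fit$weights[2, ] == 0))
  # non-convergence warns and flags
  expect_warning(
    f <- fit_smlr(toy$X, toy$Y, 0, 1e-6, tol = 1e-14, max_sweeps = 3L),
    "converge"
  )
  expect_false(f$converged)
  expect_equal(f$n_sweeps, 3L)
})

test_that("fitted models round-trip through JSON serialization", {
  toy <- toy_classification(n_per_class = 5, d = 4)
  fit <- fit_smlr(toy$X, toy$Y, 0.3, 1e-2)
  path <- withr::local_tempfile(fileext = ".json")
  write_smlr_fit(fit, path)
  back <- read_smlr_fit(path)
  expect_equal(unname(back$weights), unname(fit$weights), tolerance = 1e-12)
  expect_identical(back$classes, fit$classes)
  expect_identical(predict(back, toy$X)$.pred, predict(fit, toy$X)$.pred)
})
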