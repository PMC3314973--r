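test_that("the default regularization grid has 121 increasing pairs", {
  g <- lambda_grid()
  expect_equal(length(g$values), 11)
  expect_equal(nrow(g$pairs), 121)
  expect_true(all(diff(g$values) > 0))
  expect_equal(min(g$values), 1e-5)
  expect_equal(max(g$values), 1e5)
  expect_error(lambda_grid(from = -1), "from")
})

test_that("fold plans are subject-level leave-one-out, nested correctly", {
  subj15 <- sprintf("S%02d", 1:15)
  plan <- make_fold_plan(subj15)
  expect_equal(nrow(plan), 15)
  expect_true(all(vapply(plan$inner, nrow, integer(1)) == 14))
  # inner training sets have 13 subjects and never the test subject
  for (t in seq_len(nrow(plan))) {
    inner <- plan$inner[[t]]
    expect_false(plan$test_subject[t] %in% inner$validation_subject)
    for (tr in inner$train_subjects) {
      expect_equal(length(tr), 13)
      expect_false(plan$test_subject[t] %in% tr)
    }
    # inner folds cover the remaining subjects exactly once
    expect_setequal(inner$validation_subject,
                    setdiff(subj15, plan$test_subject[t]))
  }
  # every subject is outer test exactly once
  expect_setequal(plan$test_subject, subj15)
  # minimal case
  p3 <- make_fold_plan(c("a", "b", "c"))
  expect_equal(nrow(p3), 3)
  expect_true(all(vapply(p3$inner, nrow, integer(1)) == 2))
  expect_error(make_fold_plan(c("a", "a", "b")), "Duplicate")
  expect_error(make_fold_plan(c("a", "b")), "at least 3")
})

test_that("lambda selection prefers the sparsest model among tied maxima", {
  pairs <- tidyr::expand_grid(lambda1 = c(0.1, 1, 10), lambda2 = c(0.1, 1))
  acc <- c(0.5, 0.9, 0.9, 0.9, 0.2, 0.1)
  sel <- aslpattern:::select_lambda(pairs, acc)
  # ties at rows 2, 3, 4: largest lambda1 (1) wins, then smallest lambda2
  expect_equal(pairs$lambda1[sel], 1)
  expect_equal(pairs$lambda2[sel], 0.1)
})

small_cv <- function(noise_sd = 2, seed = 42L, ...) {
  ds <- generate_phantom_dataset(tiny_phantom_spec(noise_sd = noise_sd,
                                                   seed = seed))
  suppressWarnings(run_nested_cv(ds$scans, grid = lambda_grid(1e-3, 1e3, 100), ...))
}

test_that("nested cross-validation is deterministic and accounts accuracies per class", {
  cv1 <- small_cv()
  cv2 <- small_cv()
  expect_equal(cv1$folds$lambda1, cv2$folds$lambda1)
  expect_identical(cv1$predictions, cv2$predictions)
  # one prediction per subject-condition
  expect_equal(nrow(cv1$predictions), 4 * 3)
  expect_equal(sum(cv1$confusion), 12)
  # overall accuracy is the unweighted mean of per-class accuracies
  expect_equal(cv1$overall_accuracy, mean(cv1$class_accuracy$accuracy),
               tolerance = 1e-12)
  acc <- class_accuracies(cv1$confusion)
  expect_equal(cv1$overall_accuracy, acc$overall, tolerance = 1e-12)
  # tidiers
  td <- tidy(cv1)
  expect_true(all(c("subject", "condition", "predicted", "correct") %in% names(td)))
  gl <- glance(cv1)
  expect_equal(gl$n_predictions, 12L)
})

test_that("the held-out subject cannot influence its own fold's model selection", {
  spec <- tiny_phantom_spec(noise_sd = 2, seed = 5L)
  ds <- generate_phantom_dataset(spec)
  grid <- lambda_grid(1e-2, 1e2, 100)
  cv_a <- suppressWarnings(run_nested_cv(ds$scans, grid = grid))
  # replace subject S03's maps with pure noise and rerun
  mutated <- ds$scans
  set.seed(999)
  idx <- which(mutated$subject == "S03")
  mutated$map[idx] <- lapply(mutated$map[idx], function(mp) {
    cbf_map(array(rnorm(length(mp$flow), 50, 5), dim(mp$flow)),
            mp$voxel_size_mm)
  })
  cv_b <- suppressWarnings(run_nested_cv(mutated, grid = grid))
  # the fold testing S03 trained without S03: identical selected lambdas
  fa <- cv_a$folds[cv_a$folds$test_subject == "S03", ]
  fb <- cv_b$folds[cv_b$folds$test_subject == "S03", ]
  expect_equal(fa$lambda1, fb$lambda1)
  expect_equal(fa$lambda2, fb$lambda2)
  expect_equal(fa$inner_accuracy, fb$inner_accuracy)
})

test_that("strong planted effects are recovered well above chance on a small phantom", {
  cv <- small_cv(noise_sd = 1)
  expect_gte(cv$overall_accuracy, 0.75)
  # final model concentrates nonzero weight in discriminative voxels
  expect_false(is.null(cv$final_fit))
  expect_gt(sum(cv$final_fit$weights != 0), 0)
})

test_that("learning curves report per-class and overall accuracy per scan count", {
  ds <- generate_phantom_dataset(tiny_phantom_spec(noise_sd = 2))
  lc <- suppressWarnings(learning_curve(ds$scans, grid = lambda_grid(1e-2, 1e2, 100),
                                        k_values = c(1, 2)))
  expect_s3_class(lc, "asl_learning_curve")
  expect_equal(sort(unique(lc$k)), c(1, 2))
  expect_setequal(unique(lc$class), c("MPH", "ATX", "PLC", "overall"))
  expect_true(all(lc$accuracy >= 0 & lc$accuracy <= 1))
  # k = "all scans" equals the plain nested CV
  cv <- suppressWarnings(run_nested_cv(ds$scans, grid = lambda_grid(1e-2, 1e2, 100),
                                       k_scans = 2, final_model = FALSE))
  expect_equal(lc$accuracy[lc$k == 2 & lc$class == "overall"],
               cv$overall_accuracy)
})

test_that("the learning curve is flat on a noiseless phantom", {
  ds <- generate_phantom_dataset(tiny_phantom_spec(noise_sd = 0,
                                                   subject_offset_sd = 4))
  lc <- suppressWarnings(learning_curve(ds$scans,
                                        grid = lambda_grid(1e-2, 1e2, 100),
                                        k_values = c(1, 2)))
  ov <- lc[lc$class == "overall", ]
  expect_equal(ov$accuracy[ov$k == 1], ov$accuracy[ov$k == 2])
})
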