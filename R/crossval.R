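#' Logarithmic regularization grid
#'
#' Geometric ladder of candidate penalty values shared by `lambda1` and
#' `lambda2`, crossed into all pairs. The default spans 1e-5 to 1e5 in steps
#' of a factor 10: 11 values, 121 pairs.
#'
#' @param from,to Smallest and largest value (positive).
#' @param factor Multiplicative step (> 1).
#' @return An object of class `lambda_grid` with `values` (increasing) and
#'   `pairs` (tibble of `lambda1`, `lambda2`).
#' @export
lambda_grid <- function(from = 1e-5, to = 1e5, factor = 10) {
  if (from <= 0 || to < from || factor <= 1) {
    abort("Need 0 < from <= to and factor > 1.")
  }
  n_steps <- floor(log(to / from) / log(factor) + 1e-9)
  values <- from * factor^(0:n_steps)
  pairs <- tidyr::expand_grid(lambda1 = values, lambda2 = values)
  structure(list(values = values, pairs = pairs), class = "lambda_grid")
}

#' @export
print.lambda_grid <- function(x, ...) {
  cat(sprintf("<lambda_grid> %d values in [%g, %g], %d (lambda1, lambda2) pairs\n",
              length(x$values), min(x$values), max(x$values), nrow(x$pairs)))
  invisible(x)
}

#' Nested leave-one-subject-out fold plan
#'
#' Outer loop: each subject once held out as the test set. Inner loop, per
#' outer fold: each remaining subject once held out as the validation set,
#' the rest forming the inner training set. The test subject never appears
#' in any of its inner folds.
#'
#' @param subjects Character vector of unique subject IDs (>= 3).
#' @return A tibble with columns `test_subject`, `train_subjects`
#'   (list-column) and `inner` (list-column of tibbles with
#'   `validation_subject`, `train_subjects`).
#' @export
make_fold_plan <- function(subjects) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) abort("Duplicate subject IDs in fold plan.")
  if (length(subjects) < 3L) abort("Need at least 3 subjects for nested LOO-CV.")
  tibble::tibble(
    test_subject = subjects,
    train_subjects = lapply(subjects, function(s) setdiff(subjects, s)),
    inner = lapply(subjects, function(s) {
      tr <- setdiff(subjects, s)
      tibble::tibble(
        validation_subject = tr,
        train_subjects = lapply(tr, function(v) setdiff(tr, v))
      )
    })
  )
}

# order grid pairs for warm-started path fitting: lambda2 blocks, lambda1
# descending within each block (the all-zero solution at large lambda1 is the
# natural path start)
path_order <- function(pairs) {
  order(pairs$lambda2, -pairs$lambda1)
}

# tie-break: highest overall accuracy, then largest lambda1, then smallest
# lambda2. Among tied maxima the largest L1 penalty gives the sparsest
# model; at fixed lambda1 a heavier ridge penalty under-shrinks toward many
# small nonzero weights, so the smaller lambda2 is the sparser, better
# localized choice.
select_lambda <- function(pairs, overall) {
  stopifnot(nrow(pairs) == length(overall))
  best <- which(overall >= max(overall) - 1e-12)
  best <- best[order(-pairs$lambda1[best], pairs$lambda2[best])]
  best[1]
}

# warm-started path over the grid for one inner training set; accumulates
# per-pair, per-class correct counts on the validation rows
grid_search_fold <- function(X, Y, train_rows, val_rows, pairs, classes,
                             tol, max_sweeps) {
  ord <- path_order(pairs)
  m <- length(classes)
  d <- ncol(X)
  correct <- matrix(0, nrow(pairs), m)
  n_fail <- 0L
  Xtr <- X[train_rows, , drop = FALSE]
  Ytr <- Y[train_rows, , drop = FALSE]
  Xval <- X[val_rows, , drop = FALSE]
  true_val <- classes[max.col(Y[val_rows, , drop = FALSE], ties.method = "first")]
  W <- matrix(0, d, m)
  lam2_cur <- NA_real_
  for (p in ord) {
    l1 <- pairs$lambda1[p]; l2 <- pairs$lambda2[p]
    if (!identical(l2, lam2_cur)) {
      W <- matrix(0, d, m)  # new lambda2 block: restart path at zero
      lam2_cur <- l2
    }
    res <- .smlr_cd(Xtr, Ytr + 0.0, l1, l2, tol, as.integer(max_sweeps), W)
    W <- res$weights
    if (!res$converged) n_fail <- n_fail + 1L
    P <- softmax_probabilities(Xval, W)
    pred <- classes[apply(P, 1, which.max)]
    hits <- pred == true_val
    for (c in seq_len(m)) {
      correct[p, c] <- correct[p, c] + sum(hits[true_val == classes[c]])
    }
  }
  list(correct = correct, n_fail = n_fail)
}

#' Nested leave-one-subject-out cross-validation
#'
#' For each outer fold one subject is held out; the regularization pair
#' `(lambda1, lambda2)` is chosen by an inner leave-one-subject-out grid
#' search over the training subjects only, the classifier is refit on all
#' training subjects at the selected pair, and the held-out subject's rows
#' are predicted. Per-class accuracy is the fraction of that class's rows
#' predicted correctly across all outer folds; overall accuracy is the
#' unweighted mean of the per-class accuracies. The inner selection
#' criterion is the same overall accuracy computed on the aggregated
#' validation predictions; ties prefer the largest `lambda1` (the sparsest
#' model), then the smallest `lambda2`.
#'
#' Within-subject mean-centering is computed per subject, so test-subject
#' rows are centered with the subject's own mean over the selected
#' conditions; no quantity derived from the test subject enters training or
#' model selection.
#'
#' @param scans Scan tibble (see [build_feature_matrix()]).
#' @param conditions Condition labels to discriminate (default: all).
#' @param grid A [lambda_grid()].
#' @param k_scans Number of leading scans averaged per subject-condition
#'   (default: all).
#' @param fwhm_mm Smoothing FWHM in mm.
#' @param tol,max_sweeps Optimizer control for the cross-validation fits.
#'   Defaults are looser than [fit_smlr()]'s since accuracy-based selection
#'   does not require tightly converged weights.
#' @param final_model Also fit a model on all subjects at the modal selected
#'   pair, for discrimination mapping.
#' @return An object of class `asl_cv`: `folds` (per-outer-fold selections
#'   and inner accuracy surfaces), `predictions`, `confusion`,
#'   `class_accuracy`, `overall_accuracy`, plus `final_fit` and `features`
#'   when `final_model = TRUE`.
#' @export
run_nested_cv <- function(scans, conditions = NULL, grid = lambda_grid(),
                          k_scans = NULL, fwhm_mm = 8, tol = 1e-3,
                          max_sweeps = 25L, final_model = TRUE) {
  stopifnot(inherits(grid, "lambda_grid"))
  features <- build_feature_matrix(scans, conditions, k_scans, fwhm_mm)
  classes <- if (is.null(conditions)) unique(features$row_meta$condition) else conditions
  X <- features$X
  Y <- one_of_m(features$row_meta$condition, classes)
  subj <- features$row_meta$subject
  plan <- make_fold_plan(unique(subj))
  pairs <- grid$pairs
  m <- length(classes)

  fold_rows <- vector("list", nrow(plan))
  pred_rows <- vector("list", nrow(plan))
  n_fail_total <- 0L
  for (t in seq_len(nrow(plan))) {
    test_s <- plan$test_subject[t]
    inner <- plan$inner[[t]]
    correct <- matrix(0, nrow(pairs), m)
    totals <- integer(m)
    n_fail <- 0L
    for (v in seq_len(nrow(inner))) {
      val_s <- inner$validation_subject[v]
      tr_rows <- which(subj %in% inner$train_subjects[[v]])
      val_rows <- which(subj == val_s)
      gs <- grid_search_fold(X, Y, tr_rows, val_rows, pairs, classes,
                             tol, max_sweeps)
      correct <- correct + gs$correct
      n_fail <- n_fail + gs$n_fail
      true_val <- classes[max.col(Y[val_rows, , drop = FALSE], "first")]
      totals <- totals + as.integer(table(factor(true_val, classes)))
    }
    acc <- sweep(correct, 2, pmax(totals, 1L), `/`)
    overall <- rowMeans(acc)
    sel <- select_lambda(pairs, overall)
    l1 <- pairs$lambda1[sel]; l2 <- pairs$lambda2[sel]

    train_rows <- which(subj %in% plan$train_subjects[[t]])
    refit <- .smlr_cd(X[train_rows, , drop = FALSE],
                      Y[train_rows, , drop = FALSE] + 0.0,
                      l1, l2, tol, as.integer(max_sweeps),
                      matrix(0, ncol(X), m))
    if (!refit$converged) n_fail <- n_fail + 1L
    test_rows <- which(subj == test_s)
    P <- softmax_probabilities(X[test_rows, , drop = FALSE], refit$weights)
    pred <- classes[apply(P, 1, which.max)]

    fold_rows[[t]] <- tibble::tibble(
      test_subject = test_s, lambda1 = l1, lambda2 = l2,
      inner_accuracy = overall[sel],
      n_not_converged = n_fail,
      surface = list(dplyr::bind_cols(pairs, tibble::tibble(overall = overall)))
    )
    pred_rows[[t]] <- tibble::tibble(
      subject = test_s,
      condition = features$row_meta$condition[test_rows],
      predicted = pred
    )
    n_fail_total <- n_fail_total + n_fail
  }
  if (n_fail_total > 0L) {
    warn(sprintf("%d cross-validation fit(s) hit the sweep budget before convergence.",
                 n_fail_total))
  }

  folds <- dplyr::bind_rows(fold_rows)
  predictions <- dplyr::bind_rows(pred_rows)
  cm <- confusion_matrix(predictions$condition, predictions$predicted, classes)
  accs <- class_accuracies(cm)

  final_fit <- NULL
  if (final_model) {
    sel_tab <- folds |> dplyr::count(.data$lambda1, .data$lambda2) |>
      dplyr::arrange(dplyr::desc(.data$n), dplyr::desc(.data$lambda1),
                     dplyr::desc(.data$lambda2))
    final_fit <- fit_smlr(X, Y, lambda1 = sel_tab$lambda1[1],
                          lambda2 = sel_tab$lambda2[1],
                          tol = tol, max_sweeps = max_sweeps)
  }

  structure(
    list(folds = folds, predictions = predictions, confusion = cm,
         class_accuracy = tibble::tibble(class = classes,
                                         accuracy = unname(accs$per_class)),
         overall_accuracy = accs$overall, classes = classes,
         k_scans = k_scans, grid = grid, final_fit = final_fit,
         features = if (final_model) features else NULL),
    class = "asl_cv"
  )
}

#' @export
print.asl_cv <- function(x, ...) {
  cat(sprintf("<asl_cv> %d outer folds, classes: %s\n",
              nrow(x$folds), paste(x$classes, collapse = ", ")))
  cat(sprintf("  per-class accuracy: %s\n",
              paste(sprintf("%s %.1f%%", x$class_accuracy$class,
                            100 * x$class_accuracy$accuracy),
                    collapse = ", ")))
  cat(sprintf("  overall accuracy: %.2f%%\n", 100 * x$overall_accuracy))
  invisible(x)
}

#' Classification accuracy as a function of scans averaged
#'
#' Re-runs the nested cross-validation using only the first `k` scans per
#' subject-condition, for each `k` in `k_values`. Averaging more scans
#' suppresses per-scan noise, so accuracy is expected to rise with `k` on
#' noisy data and stay flat on noiseless data.
#'
#' @inheritParams run_nested_cv
#' @param k_values Integer vector of scan counts to evaluate.
#' @return A tibble of class `asl_learning_curve` with columns `k`, `class`
#'   (per-condition rows plus `"overall"`), and `accuracy`.
#' @export
learning_curve <- function(scans, conditions = NULL, grid = lambda_grid(),
                           k_values, fwhm_mm = 8, tol = 1e-3,
                           max_sweeps = 25L) {
  res <- lapply(k_values, function(k) {
    cv <- run_nested_cv(scans, conditions, grid, k_scans = k,
                        fwhm_mm = fwhm_mm, tol = tol,
                        max_sweeps = max_sweeps, final_model = FALSE)
    dplyr::bind_rows(
      cv$class_accuracy |> dplyr::mutate(k = k, .before = 1),
      tibble::tibble(k = k, class = "overall", accuracy = cv$overall_accuracy)
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("asl_learning_curve", class(out))
  out
}
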