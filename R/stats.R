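#' Confusion matrix of true versus predicted conditions
#'
#' Exact counts with a fixed, deterministic class ordering; rows are true
#' classes, columns predicted.
#'
#' @param true,predicted Equal-length label vectors.
#' @param classes Class ordering; defaults to unique true labels in order of
#'   first appearance. Labels outside `classes` are an error.
#' @return An `m x m` integer matrix with dimnames `true` x `predicted`.
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) == 0L) abort("Empty label sequences.")
  if (length(true) != length(predicted)) {
    abort("`true` and `predicted` must have the same length.")
  }
  if (is.null(classes)) classes <- unique(true)
  if (!all(c(true, predicted) %in% classes)) {
    abort("Labels outside the known class set.")
  }
  cm <- table(true = factor(true, classes), predicted = factor(predicted, classes))
  matrix(as.integer(cm), nrow = length(classes),
         dimnames = list(true = classes, predicted = classes))
}

#' Per-class and overall classification accuracy
#'
#' Per-class accuracy is the confusion-matrix diagonal divided by the row
#' sum; overall accuracy is the unweighted mean of the per-class accuracies
#' (so each condition counts equally regardless of row totals).
#'
#' @param cm Confusion matrix (true x predicted).
#' @return List with `per_class` (named vector) and `overall` (scalar).
#' @export
class_accuracies <- function(cm) {
  cm <- as.matrix(cm)
  totals <- rowSums(cm)
  if (any(totals == 0)) abort("Every true class must have at least one instance.")
  per_class <- diag(cm) / totals
  names(per_class) <- rownames(cm)
  list(per_class = per_class, overall = mean(per_class))
}

#' Chi-square test of per-class correct counts against chance
#'
#' Goodness-of-fit statistic on the per-class correct counts (the confusion
#' diagonal) against the expectation under chance-level accuracy:
#' `chi^2 = sum_c (O_c - E_c)^2 / E_c` with `E_c = row_total_c * chance` and
#' `df = m - 1`; upper-tail p-value from the chi-square distribution.
#'
#' @param cm Confusion matrix.
#' @param chance Chance accuracy; defaults to `1/m`.
#' @return A tibble with `statistic`, `df`, `p_value`, `chance`.
#' @export
chisq_vs_chance <- function(cm, chance = NULL) {
  cm <- as.matrix(cm)
  m <- nrow(cm)
  if (is.null(chance)) chance <- 1 / m
  O <- diag(cm)
  E <- rowSums(cm) * chance
  if (any(E <= 0)) abort("Expected counts must be positive.")
  stat <- sum((O - E)^2 / E)
  df <- m - 1L
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 chance = chance)
}

#' Exact binomial test of correct predictions against chance
#'
#' One-sided exact upper-tail probability `P(X >= k)` for
#' `X ~ Binomial(n, chance)`: the probability of at least the observed
#' number of correct predictions if the classifier were guessing at chance.
#'
#' @param k_correct Observed number of correct predictions.
#' @param n Total number of predictions.
#' @param chance Chance accuracy in (0, 1).
#' @return A tibble with `k`, `n`, `chance`, `p_value`.
#' @export
binomial_vs_chance <- function(k_correct, n, chance = 0.5) {
  if (n < 1L || k_correct < 0L || k_correct > n) {
    abort("Need 0 <= k_correct <= n with n >= 1.")
  }
  if (chance <= 0 || chance >= 1) abort("`chance` must be in (0, 1).")
  p <- pbinom(k_correct - 1, n, chance, lower.tail = FALSE)
  tibble::tibble(k = as.integer(k_correct), n = as.integer(n),
                 chance = chance, p_value = p)
}
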