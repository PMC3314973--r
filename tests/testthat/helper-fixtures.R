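# Shared in-code fixtures: small phantoms and toy classification problems.

# tiny fast phantom: 4 subjects, 3 conditions, 2 scans, one discriminative
# and one non-discriminative cluster on an 8x8x6 grid
tiny_phantom_spec <- function(noise_sd = 2, subject_offset_sd = 4, seed = 42L,
                              ...) {
  phantom_spec(
    grid_shape = c(8, 8, 6), n_subjects = 4, n_conditions = 3,
    scans_per_condition = 2,
    clusters = list(
      effect_cluster(c(3, 3, 3), 1.5, c(10, 0, -10)),
      effect_cluster(c(6, 6, 4), 1.2, c(5, 5, 5))   # common to all conditions
    ),
    baseline_cbf = 50, subject_offset_sd = subject_offset_sd,
    noise_sd = noise_sd, seed = seed, ...
  )
}

# linearly separable 3-class toy problem with planted mean shifts
toy_classification <- function(n_per_class = 20, d = 20, shift = 2,
                               seed = 7L) {
  set.seed(seed)
  m <- 3
  y <- rep(c("A", "B", "C"), each = n_per_class)
  X <- matrix(rnorm(length(y) * d), length(y), d)
  X[y == "A", 1] <- X[y == "A", 1] + shift
  X[y == "B", 2] <- X[y == "B", 2] + shift
  X[y == "C", 3] <- X[y == "C", 3] + shift
  list(X = X, y = y, Y = one_of_m(y, c("A", "B", "C")))
}

# independent full-gradient optimizer for the smooth (lambda1 = 0) elastic
# net objective, used as an oracle for the component-wise algorithm
optim_smlr_oracle <- function(X, Y, lambda2, maxit = 2000) {
  d <- ncol(X); m <- ncol(Y)
  obj <- function(w) {
    W <- matrix(w, d, m)
    -smlr_objective(X, Y, W, lambda1 = 0, lambda2 = lambda2)
  }
  grad <- function(w) {
    W <- matrix(w, d, m)
    P <- softmax_probabilities(X, W)
    G <- t(X) %*% (Y - P) - 2 * lambda2 * W
    -as.numeric(G)
  }
  fit <- optim(rep(0, d * m), obj, grad, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  matrix(fit$par, d, m, dimnames = list(NULL, colnames(Y)))
}
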