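test_that("reference-class reparameterization zeroes the reference and preserves predictions", {
  set.seed(21)
  W <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("MPH", "ATX", "PLC")))
  Wp <- reparameterize_weights(W, "PLC")
  expect_true(all(Wp[, "PLC"] == 0))
  expect_equal(Wp[, "MPH"], W[, "MPH"] - W[, "PLC"])
  # equal columns -> all-zero maps
  We <- matrix(rep(rnorm(5), 3), 5, 3, dimnames = dimnames(W))
  expect_true(all(reparameterize_weights(We, "PLC") == 0))
  # reference already zero -> identity
  W0 <- W; W0[, "PLC"] <- 0
  expect_equal(reparameterize_weights(W0, "PLC"), W0)
  expect_error(reparameterize_weights(W, "XXX"), "reference")
  # prediction invariance on 100 random inputs
  Xr <- matrix(rnorm(100 * 5), 100, 5)
  P1 <- softmax_probabilities(Xr, W)
  P2 <- softmax_probabilities(Xr, Wp)
  expect_equal(P1, P2, tolerance = 1e-12)
  expect_identical(apply(P1, 1, which.max), apply(P2, 1, which.max))
})

test_that("weights map onto the grid and back through the voxel index", {
  ds <- generate_phantom_dataset(tiny_phantom_spec())
  feats <- build_feature_matrix(ds$scans, k_scans = 2)
  d <- ncol(feats$X)
  W <- matrix(rnorm(d * 3), d, 3,
              dimnames = list(NULL, c("MPH", "ATX", "PLC")))
  maps <- discrimination_maps(W, feats, reference = "PLC")
  expect_named(maps, c("MPH", "ATX", "PLC"))
  expect_true(all(maps$PLC[feats$mask] == 0))
  expect_true(all(is.na(maps$MPH[!feats$mask])))
  # vectorize -> map -> vectorize is the identity on in-mask voxels
  expect_equal(maps$MPH[which(feats$mask)], W[, "MPH"] - W[, "PLC"],
               tolerance = 1e-12)
})

test_that("overlap maps partition the mask by exact-zero patterns", {
  # 3-voxel toy: A nonzero at {1,2}, B nonzero at {2,3} -> both = {2}
  a <- array(c(1, 2, 0, NA), c(4, 1, 1))
  b <- array(c(0, 5, -1, NA), c(4, 1, 1))
  ov <- compute_overlap_map(a, b)
  expect_identical(as.integer(ov$map[1:3, 1, 1]), c(1L, 3L, 2L))
  expect_true(is.na(ov$map[4, 1, 1]))
  # all-zero B -> only-A or neither
  ov2 <- compute_overlap_map(a, 0 * a)
  expect_true(all(ov2$map[1:3, 1, 1] %in% c(0L, 1L)))
  # identical nonzero patterns -> both everywhere nonzero
  ov3 <- compute_overlap_map(a, 2 * a)
  expect_identical(as.integer(ov3$map[1:3, 1, 1]), c(3L, 3L, 0L))
  # category counts sum to mask size
  expect_equal(sum(table(ov$map)), 3)
})

test_that("unpaired t-maps match the pooled-variance formula and are antisymmetric", {
  set.seed(31)
  dims <- c(4, 3, 2)
  A <- lapply(1:3, function(i) array(rnorm(prod(dims), 50, 5), dims))
  B <- lapply(1:3, function(i) array(rnorm(prod(dims), 55, 5), dims))
  tm <- unpaired_t_map(A, B)
  expect_equal(tm$df, 4L)
  # scalar textbook formula at an arbitrary voxel
  av <- vapply(A, function(v) v[2, 3, 1], numeric(1))
  bv <- vapply(B, function(v) v[2, 3, 1], numeric(1))
  sp <- sqrt(((2) * var(av) + (2) * var(bv)) / 4)
  t_manual <- (mean(av) - mean(bv)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(tm$t[2, 3, 1], t_manual, tolerance = 1e-12)
  # agrees with stats::t.test with pooled variance
  tt <- t.test(av, bv, var.equal = TRUE)
  expect_equal(tm$t[2, 3, 1], unname(tt$statistic), tolerance = 1e-12)
  # antisymmetry and the identical-groups zero map
  tm_swap <- unpaired_t_map(B, A)
  expect_equal(tm_swap$t, -tm$t, tolerance = 1e-12)
  tm0 <- unpaired_t_map(A, A)
  expect_true(all(tm0$t[is.finite(tm0$t)] == 0))
  # zero pooled variance -> NaN sentinel
  C <- lapply(1:2, function(i) array(1, dims))
  tmc <- unpaired_t_map(C, C)
  expect_true(all(is.nan(tmc$t)))
  expect_error(unpaired_t_map(A[1], B), "at least 2")
})

test_that("sign concordance counts matching directions among informative voxels", {
  mp <- array(c(1, -1, 0, 2), c(4, 1, 1))
  tp <- array(c(3, -2, 5, -1), c(4, 1, 1))
  # voxels 1, 2, 4 are nonzero; signs agree at 1 and 2
  expect_equal(sign_concordance(mp, tp), 2 / 3)
  expect_equal(sign_concordance(abs(mp), abs(tp)), 1)
  # undefined when no voxel qualifies
  expect_true(is.na(sign_concordance(0 * mp, tp)))
  expect_true(is.na(sign_concordance(mp, array(NaN, dim(mp)))))
})

test_that("planted effects give concordant weight and t-map directions", {
  spec <- tiny_phantom_spec(noise_sd = 1, subject_offset_sd = 4)
  ds <- generate_phantom_dataset(spec)
  feats <- build_feature_matrix(ds$scans, k_scans = 2)
  fit <- fit_smlr(feats$X, feats$row_meta$condition, lambda1 = 0.5,
                  lambda2 = 0.1, classes = c("MPH", "ATX", "PLC"))
  dm <- discrimination_maps(fit, feats, reference = "PLC")
  vol_of <- function(r) {
    v <- array(NA_real_, dim(feats$mask)); v[which(feats$mask)] <- feats$X[r, ]; v
  }
  rows_m <- which(feats$row_meta$condition == "MPH")
  rows_p <- which(feats$row_meta$condition == "PLC")
  tm <- unpaired_t_map(lapply(rows_m, vol_of), lapply(rows_p, vol_of))
  expect_gte(sign_concordance(dm$MPH, tm$t), 0.8)
})
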