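test_that("per-shell fits recover planted tensors on noise-free data", {
  coh <- clean_cohort()
  s <- coh$subjects[[1]]
  scale <- max(abs(s$tensors))
  for (b in c(1000, 2000, 3000)) {
    fit <- fit_tensor_shell(s$dwi, b)
    mask <- s$brain_mask
    for (j in 1:6) {
      planted <- s$tensors[, , , j][mask]
      got <- fit$tensor[, , , j][mask]
      expect_lt(max(abs(got - planted)) / scale, 1e-9)
    }
    expect_same_array(fit$s0_est[mask], rep(100, sum(mask)), 1e-6)
  }
  expect_error(fit_tensor_shell(s$dwi, 1500), "no shell")
})

test_that("constant signals give a zero tensor and nonpositive signals are flagged", {
  dm <- c(4, 4, 4)
  proto <- default_dwi_protocol(b_values = 1000)
  tens0 <- array(0, dim = c(dm, 6))
  dwi <- generate_dwi(tens0, proto, b0_value = 50, noise_sd = 0)
  fit <- fit_tensor_shell(dwi, 1000)
  expect_same_array(fit$tensor, tens0, 1e-12)
  # zero-signal voxels (outside the brain) are flagged with a zero tensor
  mask <- array(FALSE, dm); mask[2, 2, 2] <- TRUE
  dwi2 <- generate_dwi(tens0, proto, b0_value = 50, noise_sd = 0,
                       brain_mask = mask)
  fit2 <- fit_tensor_shell(dwi2, 1000)
  expect_true(all(fit2$flagged[!mask]))
  expect_false(fit2$flagged[2, 2, 2])
})

test_that("eigenvalues of a rotated prolate tensor are recovered to 1e-9", {
  pf <- prolate_tensor_field()
  proto <- default_dwi_protocol(b_values = 1000)
  dwi <- generate_dwi(pf$tensors, proto, b0_value = 100, noise_sd = 0)
  fit <- fit_tensor_shell(dwi, 1000)
  sm <- tensor_scalar_maps(fit)
  # independent oracle: dense eigen-decomposition of the planted matrix
  ev_oracle <- sort(eigen(pf$D, symmetric = TRUE)$values, decreasing = TRUE)
  tm <- matrix(fit$tensor, prod(dim(pf$tensors)[1:3]), 6)
  ev_fit <- structofunc:::tensor_eig_cpp(tm)$evals[1, ]
  expect_lt(max(abs(ev_fit - ev_oracle)) / max(ev_oracle), 1e-9)
  expect_equal(sm$md[1, 1, 1], mean(pf$lams), tolerance = 1e-9)
})

test_that("MD and FA match their closed forms", {
  mk_fit <- function(lams) {
    tens <- array(0, dim = c(2, 2, 2, 6))
    for (j in 1:3) tens[, , , j] <- lams[j]
    tens
  }
  sm_iso <- tensor_scalar_maps(mk_fit(c(1e-3, 1e-3, 1e-3)))
  expect_equal(sm_iso$fa[1, 1, 1], 0)
  expect_equal(sm_iso$md[1, 1, 1], 1e-3)
  sm_stick <- tensor_scalar_maps(mk_fit(c(1, 0, 0)))
  expect_equal(sm_stick$fa[1, 1, 1], 1)
  sm <- tensor_scalar_maps(mk_fit(c(1.7e-3, 2e-4, 2e-4)))
  expect_equal(sm$md[1, 1, 1], 0.7e-3, tolerance = 1e-12)
  lb <- mean(c(1.7, 0.2, 0.2))
  fa_expect <- sqrt(1.5 * sum((c(1.7, 0.2, 0.2) - lb)^2) /
                      sum(c(1.7, 0.2, 0.2)^2))
  expect_equal(sm$fa[1, 1, 1], fa_expect, tolerance = 1e-12)
  expect_equal(round(fa_expect, 4), 0.8704)
  # degenerate voxel: FA 0, direction (0,0,0)
  sm0 <- tensor_scalar_maps(mk_fit(c(0, 0, 0)))
  expect_equal(sm0$fa[1, 1, 1], 0)
  expect_equal(sm0$direction[1, 1, 1, ], c(0, 0, 0))
})

test_that("FA is scale-invariant and MD is linear in the eigenvalues", {
  set.seed(42)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3)
    D <- crossprod(A) * 1e-4
    tens <- array(0, dim = c(1, 2, 2, 6))
    comp <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    for (j in 1:6) tens[, , , j] <- comp[j]
    s1 <- tensor_scalar_maps(tens)
    s2 <- tensor_scalar_maps(tens * 3.7)
    expect_equal(s2$fa[1, 1, 1], s1$fa[1, 1, 1], tolerance = 1e-9)
    expect_equal(s2$md[1, 1, 1], 3.7 * s1$md[1, 1, 1], tolerance = 1e-12)
  }
})

test_that("directionally-encoded FA has norm FA and validates its inputs", {
  expect_equal(directional_fa(0, c(0.5, 0.5, 0.5)), c(0, 0, 0))
  expect_equal(directional_fa(1, c(1, 0, 0)), c(1, 0, 0))
  v <- c(1, 1, 0) / sqrt(2)
  out <- directional_fa(0.87, v)
  expect_equal(out, c(0.87 / sqrt(2), 0.87 / sqrt(2), 0), tolerance = 1e-9)
  expect_equal(sqrt(sum(out^2)), 0.87, tolerance = 1e-12)
  expect_error(directional_fa(0.5, c(1, 1, 0)), "unit-norm")
  expect_error(directional_fa(1.2, c(1, 0, 0)), "0, 1")
})

test_that("noise lifts the FA floor of isotropic tensors (directional check)", {
  dm <- c(8, 8, 8)
  tens <- array(0, dim = c(dm, 6))
  for (j in 1:3) tens[, , , j] <- 1e-3
  proto <- default_dwi_protocol(b_values = 1000, n_directions = 12)
  dwi <- structofunc:::with_seed(9, generate_dwi(tens, proto, 100, noise_sd = 1))
  sm <- tensor_scalar_maps(fit_tensor_shell(dwi, 1000))
  expect_gt(median(sm$fa), 0)
})

test_that("the feature stack transform is invertible and normalization is guarded", {
  coh <- clean_cohort()
  s <- coh$subjects[[1]]
  # crop box at native resolution: resampling is exact, so the round trip is too
  tr <- structofunc:::stack_transform(s$brain_mask, NULL)
  bb_shape <- tr$bb1 - tr$bb0 + 1L
  st <- build_feature_stack(s, target_shape = bb_shape, channels = "t1+t2",
                            normalize = FALSE)
  rec <- stack_to_volume(st$data[, , , 1], st$transform)
  inbox <- lapply(1:3, function(ax) tr$bb0[ax]:tr$bb1[ax])
  expect_lt(max(abs(rec[inbox[[1]], inbox[[2]], inbox[[3]]] -
                      s$structural$t1[inbox[[1]], inbox[[2]], inbox[[3]]])),
            1e-6)
  # full-volume mask at matching shape: identity transform
  s2 <- s
  s2$brain_mask <- array(TRUE, dim = s$grid_shape)
  st2 <- build_feature_stack(s2, channels = "t1", normalize = FALSE)
  expect_same_array(st2$data[, , , 1], s$structural$t1, 1e-12)
  # constant channel z-scores to all zeros rather than dividing by zero
  s3 <- s
  s3$structural$t1 <- array(5, dim = s$grid_shape)
  st3 <- build_feature_stack(s3, channels = "t1")
  expect_same_array(st3$data[, , , 1], array(0, dim = s$grid_shape))
  # empty mask is an error
  s4 <- s
  s4$brain_mask <- array(FALSE, dim = s$grid_shape)
  expect_error(build_feature_stack(s4), "empty brain mask")
  # 14 channels in the documented order
  st14 <- build_feature_stack(s)
  expect_identical(st14$channel_names,
                   c("t1", "t2",
                     "b1000_md", "b1000_fax", "b1000_fay", "b1000_faz",
                     "b2000_md", "b2000_fax", "b2000_fay", "b2000_faz",
                     "b3000_md", "b3000_fax", "b3000_fay", "b3000_faz"))
})
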