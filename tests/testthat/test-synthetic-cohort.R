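test_that("cohort_spec rejects invalid study conditions", {
  expect_error(cohort_spec(n_subjects = 1), "at least 2")
  expect_error(cohort_spec(grid_shape = c(15, 16, 16)), "even")
  expect_error(cohort_spec(noise_sd = -1), "nonnegative")
  bad_proto <- default_dwi_protocol()
  bad_proto$shells[[1]]$directions[1, ] <- c(1, 1, 0)
  expect_error(cohort_spec(dwi_protocol = bad_proto), "unit-norm")
  bad_b <- default_dwi_protocol()
  bad_b$shells[[1]]$b_value <- -100
  expect_error(cohort_spec(dwi_protocol = bad_b), "negative b-value")
})

test_that("with no individual component all subjects share the group template", {
  spec <- cohort_spec(n_subjects = 3, grid_shape = c(16, 16, 16),
                      effect_size = 0, noise_sd = 0, lateralization_sd = 0,
                      seed = 7, n_vertices_per_hemi = 40)
  coh <- generate_cohort(spec)
  a1 <- coh$subjects[[1]]$activations
  for (s in coh$subjects[-1])
    for (m in names(a1)) expect_same_array(s$activations[[m]], a1[[m]])
  # and the shared map is the group template restricted to the brain
  geom <- structofunc:::brain_geometry(spec)
  fields <- structofunc:::activation_fields(coh$atlas, geom)
  expect_same_array(a1[[3]], fields[[3]]$G * coh$subjects[[1]]$brain_mask)
})

test_that("cohorts are bit-identical when regenerated from the same spec", {
  spec <- cohort_spec(n_subjects = 3, grid_shape = c(16, 16, 16),
                      noise_sd = 0.4, dwi_noise_sd = 0.5, seed = 99,
                      n_vertices_per_hemi = 40)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
})

test_that("theta = 0 gives the undeformed population template", {
  spec <- cohort_spec(n_subjects = 2, grid_shape = c(16, 16, 16), seed = 1)
  s0 <- generate_subject(rep(0, spec$n_latent), 0, spec)
  # independent reconstruction of the template contrasts from the geometry
  geom <- structofunc:::brain_geometry(spec)
  rho <- geom$rho
  sub <- stats::plogis((0.45 - rho) / 0.04)
  mid <- stats::plogis((0.80 - rho) / 0.04)
  outer <- stats::plogis((1.00 - rho) / 0.04)
  wm <- pmax(mid - sub, 0)
  ctx <- pmax(outer - mid, 0)
  expect_same_array(s0$structural$t1, 0.70 * ctx + 0.85 * sub + 1.00 * wm, 1e-10)
  expect_same_array(s0$structural$t2, 0.95 * ctx + 0.70 * sub + 0.45 * wm, 1e-10)
})

test_that("identical latents, session and RNG state give identical records", {
  spec <- cohort_spec(n_subjects = 2, grid_shape = c(16, 16, 16),
                      noise_sd = 0.5, seed = 1)
  th <- c(0.3, -1, 0.2, 0.5, -0.4, 1.1)
  r1 <- structofunc:::with_seed(5, generate_subject(th, 0.2, spec))
  r2 <- structofunc:::with_seed(5, generate_subject(th, 0.2, spec))
  expect_identical(r1, r2)
  expect_error(generate_subject(c(1, 2), 0, spec), "n_latent")
})

test_that("retest sessions share structure and differ only by noise of the expected size", {
  coh <- tiny_cohort()
  s1 <- coh$subjects[[2]]
  s2 <- coh$retest[[2]]
  expect_identical(s1$structural, s2$structural)
  expect_identical(s1$tensors, s2$tensors)
  expect_identical(s1$dwi, s2$dwi)
  expect_identical(s2$session, 2L)
  # difference of two sessions is N(0, 2 sigma^2); E|d| = sigma * sqrt(2) * sqrt(2/pi)
  spec <- cohort_spec(n_subjects = 2, grid_shape = c(24, 24, 24),
                      noise_sd = 0.5, seed = 55, sessions = 2)
  coh24 <- generate_cohort(spec)
  d <- numeric(0)
  for (m in names(coh24$subjects[[1]]$activations)) {
    dd <- coh24$subjects[[1]]$activations[[m]] - coh24$retest[[1]]$activations[[m]]
    d <- c(d, abs(dd[coh24$subjects[[1]]$brain_mask]))
  }
  expected <- 0.5 * sqrt(2) * sqrt(2 / pi)
  expect_lt(abs(mean(d) - expected) / expected, 0.1)
})

test_that("activation differences reconstruct exactly from the stored latents", {
  coh <- clean_cohort()
  spec <- coh$spec
  geom <- structofunc:::brain_geometry(spec)
  fields <- structofunc:::activation_fields(coh$atlas, geom)
  a <- coh$subjects[[1]]; b <- coh$subjects[[3]]
  fa <- structofunc:::latent_readout(a$theta)
  fb <- structofunc:::latent_readout(b$theta)
  for (t in c(1, 6, 14)) {
    fl <- fields[[t]]
    diff_expect <- (spec$effect_size *
                      structofunc:::individual_component(fl, fa - fb) +
                      (a$lateralization - b$lateralization) * fl$h) *
      a$brain_mask
    expect_same_array(a$activations[[t]] - b$activations[[t]], diff_expect, 1e-10)
  }
})

test_that("lateralization term is antisymmetric at homologous vertices", {
  spec <- cohort_spec(n_subjects = 2, grid_shape = c(16, 16, 16),
                      effect_size = 0, noise_sd = 0, lateralization_sd = 0.8,
                      seed = 31, n_vertices_per_hemi = 40)
  coh <- generate_cohort(spec)
  s <- coh$subjects[[1]]
  geom <- structofunc:::brain_geometry(spec)
  fields <- structofunc:::activation_fields(coh$atlas, geom)
  tpl <- coh$template
  for (t in c(2, 9)) {
    av <- sample_to_surface(s$activations[[t]], tpl)
    hv <- sample_to_surface(fields[[t]]$h * s$brain_mask, tpl)
    left <- which(tpl$vertices$hemi == "L")
    hom <- tpl$homologue[left]
    expect_same_array(av[left] - av[hom],
                      2 * s$lateralization * hv[left], 1e-9)
  }
})

test_that("diffusion forward model matches the Stejskal-Tanner closed form", {
  dm <- c(4, 4, 4)
  proto <- default_dwi_protocol(b_values = 1000, n_directions = 6)
  # isotropic tensor: equal signal in all directions
  d <- 1.2e-3
  tens <- array(0, dim = c(dm, 6))
  for (j in 1:3) tens[, , , j] <- d
  dwi <- generate_dwi(tens, proto, b0_value = 100, noise_sd = 0)
  sig <- sapply(dwi$shells[[1]]$signals, function(s) s[1, 1, 1])
  expect_same_array(sig, rep(100 * exp(-1000 * d), 6), 1e-10)
  # b = 0 gives S0 everywhere
  dwi0 <- generate_dwi(tens, default_dwi_protocol(b_values = 0), 100, 0)
  expect_same_array(dwi0$shells[[1]]$signals[[1]], array(100, dm))
  # prolate tensor along its principal axis: S/S0 = exp(-b * lambda1)
  pf <- prolate_tensor_field()
  proto_axis <- list(shells = list(list(b_value = 1000,
                                        directions = matrix(pf$v1, 1))),
                     n_b0 = 1L)
  dwa <- generate_dwi(pf$tensors, proto_axis, 100, 0)
  expect_equal(dwa$shells[[1]]$signals[[1]][1, 1, 1] / 100, exp(-1.7),
               tolerance = 1e-9)
  expect_error(generate_dwi(tens, list(shells = list(list(b_value = -5,
                                                          directions = matrix(c(1, 0, 0), 1))),
                                       n_b0 = 1L), 100, 0), "negative b")
})

test_that("surface sampling is exact trilinear interpolation", {
  coh <- clean_cohort()
  tpl <- coh$template
  dm <- tpl$grid_shape
  expect_same_array(sample_to_surface(array(3.7, dm), tpl),
                    rep(3.7, nrow(tpl$vertices)), 1e-12)
  # locus exactly on a voxel center picks that voxel's value
  tpl2 <- tpl
  tpl2$vertices$lx[1] <- 5; tpl2$vertices$ly[1] <- 6; tpl2$vertices$lz[1] <- 7
  vol <- array(rnorm(prod(dm)), dim = dm)
  expect_equal(unname(sample_to_surface(vol, tpl2)[1]), vol[5, 6, 7])
  # midpoint between voxel centers differing along one axis averages them
  vol[5, 6, 7] <- 1; vol[6, 6, 7] <- 3
  tpl2$vertices$lx[1] <- 5.5
  expect_equal(unname(sample_to_surface(vol, tpl2)[1]), 2)
  # out-of-grid locus names the offending vertex
  tpl2$vertices$lx[2] <- 0.2
  expect_error(sample_to_surface(vol, tpl2), "vertex 2")
})

test_that("surface template has mirror-symmetric homologue pairs", {
  coh <- clean_cohort()
  tpl <- coh$template
  v <- tpl$vertices
  expect_equal(sum(v$hemi == "L"), sum(v$hemi == "R"))
  expect_identical(sort(tpl$homologue), seq_len(nrow(v)))
  hom <- tpl$homologue
  expect_same_array(v$x_mm, -v$x_mm[hom], 1e-9)
  expect_same_array(v$y_mm, v$y_mm[hom], 1e-9)
  expect_same_array(v$z_mm, v$z_mm[hom], 1e-9)
})

test_that("regenerated sessions keep structure and redraw only noise", {
  coh <- tiny_cohort()
  coh2 <- regenerate_session(coh, seed = 777)
  s1 <- coh$subjects[[1]]; s2 <- coh2$subjects[[1]]
  expect_identical(s1$structural, s2$structural)
  expect_false(identical(s1$activations, s2$activations))
  # noise-free cohorts are unchanged by regeneration
  cc <- clean_cohort()
  cc2 <- regenerate_session(cc, seed = 5)
  expect_equal(cc$subjects[[2]]$activations, cc2$subjects[[2]]$activations)
})
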