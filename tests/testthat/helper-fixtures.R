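# Shared fixtures, built once per test run (lazily) and cached.

.fixtures <- new.env(parent = emptyenv())

# small noisy cohort with a retest session
tiny_cohort <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- generate_cohort(cohort_spec(
      n_subjects = 4, grid_shape = c(16, 16, 16), noise_sd = 0.3,
      seed = 101, sessions = 2, n_vertices_per_hemi = 60))
  }
  .fixtures$tiny
}

# deterministic cohort: no activation noise
clean_cohort <- function() {
  if (is.null(.fixtures$clean)) {
    .fixtures$clean <- generate_cohort(cohort_spec(
      n_subjects = 4, grid_shape = c(16, 16, 16), noise_sd = 0,
      seed = 102, n_vertices_per_hemi = 60))
  }
  .fixtures$clean
}

# a prolate test tensor field (constant over a small grid), eigenvalues
# (1.7, 0.2, 0.2) x 1e-3 mm^2/s along a rotated axis
prolate_tensor_field <- function(dm = c(6, 6, 6),
                                 axis = c(1, 2, 2) / 3,
                                 lams = c(1.7e-3, 2e-4, 2e-4)) {
  v1 <- axis / sqrt(sum(axis^2))
  helper <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v2 <- helper - sum(helper * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  D <- lams[1] * outer(v1, v1) + lams[2] * outer(v2, v2) + lams[3] * outer(v3, v3)
  tens <- array(0, dim = c(dm, 6))
  comp <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  for (j in 1:6) tens[, , , j] <- comp[j]
  list(tensors = tens, D = D, lams = lams, v1 = v1)
}

expect_same_array <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
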