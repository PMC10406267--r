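test_that("pearson matches hand-computed values and guards degeneracy", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson(1:4, rep(2, 4)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(1:4, 1:5), "equal length")
})

test_that("correlation matrix equals the brute-force double loop", {
  set.seed(3)
  S <- 5; V <- 40
  pred <- matrix(rnorm(S * V), S, V, dimnames = list(paste0("s", 1:S), NULL))
  act <- matrix(rnorm(S * V), S, V, dimnames = list(paste0("s", 1:S), NULL))
  C <- correlation_matrix(pred, act)
  for (i in 1:S) for (j in 1:S)
    expect_equal(unclass(C)[i, j], pearson(pred[i, ], act[j, ]),
                 tolerance = 1e-12)
  expect_length(diag_values(C), S)
  expect_length(offdiag_values(C), S * (S - 1))
  # perfect predictions give a unit diagonal
  Cs <- correlation_matrix(act, act)
  expect_equal(unname(diag_values(Cs)), rep(1, S), tolerance = 1e-12)
  # subject-id ordering mismatches are rejected
  bad <- act
  rownames(bad) <- rev(rownames(bad))
  expect_error(correlation_matrix(pred, bad), "rownames")
})

test_that("double centering zeroes all row and column means", {
  expect_same_array(double_center(matrix(5, 3, 3)), matrix(0, 3, 3))
  expect_equal(double_center(diag(2)), matrix(c(.5, -.5, -.5, .5), 2))
  set.seed(1)
  M <- matrix(rnorm(36), 6)
  M2 <- double_center(M)
  expect_lt(max(abs(rowMeans(M2))), 1e-12)
  expect_lt(max(abs(colMeans(M2))), 1e-12)
  expect_same_array(double_center(M2), M2, 1e-12)
})

test_that("KS diagonal test matches stats::ks.test and hits its extremes", {
  set.seed(2)
  C <- matrix(rnorm(100), 10, 10)
  r <- ks_diag_test(C)
  ref <- suppressWarnings(stats::ks.test(diag(C), C[row(C) != col(C)]))
  expect_equal(r$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 0.1)
  # identical multisets on diagonal and off-diagonal give D = 0
  C0 <- matrix(1:9 / 10, 3, 3)
  C0[] <- 0.5
  diag(C0) <- c(0.1, 0.5, 0.9)
  C0[1, 2] <- 0.1; C0[2, 1] <- 0.5; C0[1, 3] <- 0.9
  C0[2, 3] <- 0.1; C0[3, 1] <- 0.5; C0[3, 2] <- 0.9
  expect_equal(ks_diag_test(C0)$D, 0)
  # fully separated diagonal gives D = 1 and a significant test
  C1 <- matrix(runif(64, 0, 0.2), 8, 8)
  diag(C1) <- runif(8, 0.8, 1)
  r1 <- ks_diag_test(C1)
  expect_equal(r1$D, 1)
  expect_true(r1$significant)
  expect_error(ks_diag_test(matrix(1, 4, 4)), "degenerate")
})

test_that("Bonferroni thresholds and printed forms match the reported conventions", {
  expect_equal(bonferroni(0.05, 1), 0.05)
  b47 <- bonferroni(0.05, 47)
  expect_equal(b47, 0.05 / 47)
  expect_identical(unname(threshold_print(b47)["rounded"]), "0.001")
  expect_identical(unname(threshold_print(b47)["truncated"]), "0.001")
  b20 <- bonferroni(0.05, 20)
  expect_equal(b20, 0.0025)
  expect_identical(unname(threshold_print(b20)["truncated"]), "0.002")
})

test_that("partial correlation residualizes on the covariate", {
  set.seed(9)
  n <- 60
  x0 <- rnorm(n); y0 <- rnorm(n); c0 <- rnorm(n)
  # make the covariate exactly orthogonal (and zero-mean) to x and y
  c_orth <- residuals(lm(c0 ~ x0 + y0))
  expect_equal(partial_correlation(x0, y0, c_orth), pearson(x0, y0),
               tolerance = 1e-12)
  # closed-form check: r_xy.c = (r_xy - r_xc r_yc) / sqrt((1-r_xc^2)(1-r_yc^2))
  x <- rnorm(n); cc <- rnorm(n)
  y <- 0.8 * cc + 0.4 * x + rnorm(n, sd = 0.3)
  rxy <- pearson(x, y); rxc <- pearson(x, cc); ryc <- pearson(y, cc)
  expect_equal(partial_correlation(x, y, cc),
               (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2)),
               tolerance = 1e-12)
  # y identical to the covariate leaves no residual variance
  expect_error(partial_correlation(x, cc, cc), "zero variance")
  # constant covariate falls back to the plain correlation, flagged
  r <- partial_correlation(x, y, rep(1, n))
  expect_equal(as.numeric(r), pearson(x, y))
  expect_true(attr(r, "constant_covariate"))
})

test_that("lateralization index behaves on symmetric and one-sided maps", {
  coh <- clean_cohort()
  tpl <- coh$template
  nv <- nrow(tpl$vertices)
  # mirror-symmetric map: LI = 0
  sym <- abs(tpl$vertices$x_mm) + tpl$vertices$y_mm^2 / 100
  r <- lateralization_index(sym, sym, tpl)
  expect_equal(r$li_pred, 0, tolerance = 1e-9)
  # map supported only on the left hemisphere, constant c near the peak
  left_only <- ifelse(tpl$vertices$hemi == "L", 2.5, 0)
  r2 <- lateralization_index(left_only, left_only, tpl)
  expect_equal(r2$li_pred, 2.5, tolerance = 1e-9)
  expect_error(lateralization_index(sym, sym, tpl, radius_mm = 1e-9), NA)
  # radius smaller than any inter-vertex distance still contains the peak
  expect_gte(r2$n_neighborhood, 2)
})

test_that("ICC(3,1) matches the ANOVA oracle and its invariances", {
  s1 <- c(1, 2, 3, 4)
  s2 <- c(1.1, 2.0, 3.2, 3.9)
  got <- icc31(s1, s2)
  # independent oracle: mean squares from aov on the long-format table
  long <- data.frame(y = c(s1, s2),
                     subj = factor(rep(1:4, 2)),
                     sess = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ subj + sess, data = long))[[1]]$`Mean Sq`
  bms <- ms[1]; ems <- ms[3]
  expect_equal(got, (bms - ems) / (bms + ems), tolerance = 1e-12)
  expect_equal(icc31(s1, s1), 1)
  expect_equal(icc31(s1, s1 + 10), 1)
  expect_error(icc31(rep(1, 4), rep(1, 4)), "zero total variance")
  expect_error(icc31(1:2, 1:2), "at least 3")
})

test_that("self-vs-other delta is the diagonal minus off-diagonal mean", {
  expect_equal(self_vs_other(diag(4)), 1)
  expect_equal(self_vs_other(matrix(0.3, 3, 3)), 0)
  expect_equal(self_vs_other(matrix(c(0.9, 0.3, 0.1, 0.8), 2, 2)), 0.65)
})

test_that("mixture fit is symmetric on symmetric data with monotone loglik", {
  set.seed(21)
  half <- c(rnorm(3000), rgamma(600, shape = 4, scale = 1.5))
  z <- c(half, -half)
  fit <- fit_ggm_mixture(z)
  expect_false(fit$degenerate)
  expect_equal(fit$gamma_pos$shape, fit$gamma_neg$shape, tolerance = 1e-6)
  expect_equal(fit$gamma_pos$scale, fit$gamma_neg$scale, tolerance = 1e-6)
  expect_equal(unname(fit$weights[2]), unname(fit$weights[3]),
               tolerance = 1e-6)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$loglik_trace) > -1e-6 * abs(fit$loglik)))
  # symmetric fit gives thresholds symmetric about zero
  thr <- mixture_thresholds(fit)
  expect_equal(thr[["positive"]], -thr[["negative"]], tolerance = 1e-5)
})

test_that("a pure Gaussian sample is assigned almost entirely to the null", {
  set.seed(33)
  fit <- fit_ggm_mixture(rnorm(1e4))
  expect_gt(fit$weights[1], 0.95)
  expect_lt(abs(fit$mu), 0.05)
  expect_equal(fit$sigma, 1, tolerance = 0.1)
})

test_that("gamma medians give the thresholds, exponential case in closed form", {
  fit <- structure(list(gamma_pos = list(shape = 1, scale = 2.5),
                        gamma_neg = list(shape = 4, scale = 1.5)),
                   class = "mixture_fit")
  thr <- mixture_thresholds(fit)
  expect_equal(thr[["positive"]], 2.5 * log(2), tolerance = 1e-9)
  # independent route: root of the gamma CDF at one half
  med <- uniroot(function(x) pgamma(x, shape = 4, scale = 1.5) - 0.5,
                 c(0.1, 50), tol = 1e-10)$root
  expect_equal(thr[["negative"]], -med, tolerance = 1e-6)
  expect_equal(round(med, 4), 5.5081)
  # one-sided data degenerates to a flagged two-component fit
  set.seed(4)
  f1 <- fit_ggm_mixture(abs(rnorm(500)) + 0.01)
  expect_true(f1$degenerate)
  expect_true(is.na(mixture_thresholds(f1)[["negative"]]))
})
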