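test_that("task atlas weights give each domain equal influence", {
  atlas <- default_task_atlas()
  expect_equal(sum(atlas$maps$weight), 1)
  by_domain <- tapply(atlas$maps$weight, atlas$maps$domain, sum)
  expect_true(all(abs(by_domain - 1 / length(atlas$domains)) < 1e-12))
  expect_error(task_atlas(data.frame(map = c("a", "a"), domain = "d")),
               "unique")
})

test_that("domain-weighted MSE matches hand-computed sums", {
  atlas <- task_atlas(data.frame(map = c("a1", "b1", "b2", "b3"),
                                 domain = c("A", "B", "B", "B")))
  dm <- c(4, 4, 4)
  zero <- array(0, dim = dm)
  # per-map MSE of 1 for every map: weights 1/2 + 3 * 1/6 sum to 1
  pred <- list(a1 = zero + 1, b1 = zero + 1, b2 = zero - 1, b3 = zero + 1)
  act <- list(a1 = zero, b1 = zero, b2 = zero, b3 = zero)
  expect_equal(domain_weighted_mse(pred, act, atlas), 1)
  expect_equal(domain_weighted_mse(act, act, atlas), 0)
  # quadratic homogeneity: doubling residuals quadruples the loss
  pred2 <- lapply(pred, function(v) v * 2)
  expect_equal(domain_weighted_mse(pred2, act, atlas),
               4 * domain_weighted_mse(pred, act, atlas))
  expect_error(domain_weighted_mse(pred[c(1, 2, 3)], act, atlas), "map")
  bad <- pred; names(bad)[1] <- "zz"
  expect_error(domain_weighted_mse(bad, act, atlas), "map set")
})

test_that("augmentation is an identity at degenerate settings and seeded", {
  cfg <- train_config(scale_augment_range = c(1, 1), noise_augment_sd = 0)
  x <- array(rnorm(27 * 2), dim = c(3, 3, 3, 2))
  y <- array(rnorm(27), dim = c(3, 3, 3, 1))
  a <- augment_pair(x, y, cfg)
  expect_identical(a$x, x)
  expect_identical(a$y, y)
  cfg2 <- train_config(scale_augment_range = c(0.9, 1.1),
                       noise_augment_sd = 0.1)
  a1 <- structofunc:::with_seed(4, augment_pair(x, y, cfg2))
  a2 <- structofunc:::with_seed(4, augment_pair(x, y, cfg2))
  expect_identical(a1, a2)
  # the same factor scales inputs and targets
  expect_equal(a1$y, y * a1$factor)
  # uniform scale factors average to 1 over many draws
  fs <- structofunc:::with_seed(8, replicate(1e4, augment_pair(x, y, cfg2)$factor))
  se <- (0.2 / sqrt(12)) / sqrt(1e4)
  expect_lt(abs(mean(fs) - 1), 3 * se)
})

make_tiny_train <- function(n = 2, seed = 1, dm = c(8, 8, 8), n_maps = 2) {
  atlas <- task_atlas(data.frame(map = paste0("m", seq_len(n_maps)),
                                 domain = rep("D", n_maps)))
  data <- structofunc:::with_seed(seed, lapply(seq_len(n), function(i) {
    list(x = array(rnorm(prod(dm) * 2), dim = c(dm, 2)),
         y = array(rnorm(prod(dm) * n_maps), dim = c(dm, n_maps)),
         subject_id = sprintf("s%02d", i))
  }))
  cfg <- model_config(2, n_maps, base_channels = 4, depth = 2,
                      dropout_rate = 0, groupnorm_groups = 2)
  list(atlas = atlas, data = data, model = build_model(cfg, seed))
}

test_that("patience scheduling follows the validation curve exactly", {
  tt <- make_tiny_train()
  val <- tt$data[1]
  val[[1]]$subject_id <- "v01"
  cfg <- train_config(max_epochs = 10, lr_patience_epochs = 3,
                      stop_patience_epochs = 6, initial_lr = 1e-3,
                      scale_augment_range = c(1, 1), noise_augment_sd = 0,
                      seed = 5)
  # flat curve: first decay at epoch lr_patience + 1, stop at stop_patience + 1
  flat <- train_model(tt$model, tt$data, val, tt$atlas, cfg,
                      val_loss_override = function(e) 1)
  expect_equal(nrow(flat$history), 7)
  expect_equal(flat$history$lr, c(rep(1e-3, 4), rep(5e-4, 3)))
  expect_equal(flat$best_epoch, 1)
  # strictly improving curve: no decay, runs to max_epochs
  imp <- train_model(tt$model, tt$data, val, tt$atlas, cfg,
                     val_loss_override = function(e) 1 / e)
  expect_equal(nrow(imp$history), 10)
  expect_true(all(imp$history$lr == 1e-3))
  expect_equal(imp$best_epoch, 10)
  # one epoch: single history row, no decay, no stop
  one <- train_model(tt$model, tt$data, val, tt$atlas,
                     train_config(max_epochs = 1, seed = 5))
  expect_equal(nrow(one$history), 1)
})

test_that("training enforces id disjointness and a nonempty validation set", {
  tt <- make_tiny_train()
  cfg <- train_config(max_epochs = 1, seed = 1)
  expect_error(train_model(tt$model, tt$data, tt$data[1], tt$atlas, cfg),
               "overlap")
  expect_error(train_model(tt$model, tt$data, list(), tt$atlas, cfg),
               "empty")
})

test_that("training is reproducible and a small step descends", {
  tt <- make_tiny_train()
  val <- tt$data[2]
  val[[1]]$subject_id <- "v01"
  cfg <- train_config(max_epochs = 3, seed = 12)
  f1 <- train_model(tt$model, tt$data[1], val, tt$atlas, cfg)
  f2 <- train_model(tt$model, tt$data[1], val, tt$atlas, cfg)
  expect_equal(f1$history, f2$history)
  # descent sanity: one tiny-LR epoch on the training sample decreases its loss
  cfg2 <- train_config(max_epochs = 1, initial_lr = 1e-5, seed = 3,
                       scale_augment_range = c(1, 1), noise_augment_sd = 0)
  before <- domain_weighted_mse(
    unet_forward(tt$model, tt$data[[1]]$x)$y, tt$data[[1]]$y, tt$atlas)
  fit <- train_model(tt$model, tt$data[1], val, tt$atlas, cfg2)
  # best-val checkpointing returns epoch-1 weights; recompute with them
  after <- domain_weighted_mse(
    unet_forward(fit$model, tt$data[[1]]$x)$y, tt$data[[1]]$y, tt$atlas)
  expect_lt(after, before)
})

test_that("the permutation baseline trains on a derangement", {
  for (i in 1:25)
    expect_true(all(structofunc:::with_seed(i, structofunc:::draw_derangement(5)) != 1:5))
  expect_equal(structofunc:::with_seed(1, structofunc:::draw_derangement(2)),
               c(2L, 1L))
  tt <- make_tiny_train(n = 3)
  val <- tt$data[1]
  val[[1]]$subject_id <- "v01"
  cfg <- train_config(max_epochs = 1, seed = 4)
  fit <- train_permutation_baseline(tt$model, tt$data, val, tt$atlas, cfg)
  expect_true(all(fit$permutation != 1:3))
  expect_setequal(fit$permutation, 1:3)
})

test_that("per-vertex linear baseline is exact on linear targets", {
  set.seed(77)
  S <- 12; V <- 6; P = 3; M <- 2
  feats <- array(rnorm(S * V * P), dim = c(S, V, P))
  W <- array(rnorm((P + 1) * V * M), dim = c(P + 1, V, M))
  targ <- array(0, dim = c(S, V, M))
  for (v in seq_len(V))
    targ[, v, ] <- cbind(1, feats[, v, ]) %*% W[, v, ]
  fit <- fit_linear_baseline(feats, targ)
  expect_false(any(fit$flagged))
  expect_lt(max(abs(fit$weights - W)), 1e-8)
  pred <- predict_linear_baseline(fit, feats)
  expect_lt(max(abs(pred - targ)), 1e-8)
  # all-zero features: weights 0, intercept = subject mean
  fz <- fit_linear_baseline(array(0, dim = c(S, V, P)) , targ)
  expect_true(all(fz$flagged))
  expect_equal(fz$weights[1, 1, 1], mean(targ[, 1, 1]), tolerance = 1e-8)
  expect_lt(max(abs(fz$weights[-1, , ])), 1e-8)
  expect_error(fit_linear_baseline(feats[1:4, , ], targ[1:4, , ]),
               "more subjects")
})

test_that("planted single-vertex weights match the normal-equations oracle", {
  set.seed(5)
  S <- 50; P <- 3
  X <- matrix(rnorm(S * P), S, P)
  beta <- c(0.5, -1.2, 2, 0.3)
  y <- cbind(1, X) %*% beta
  feats <- array(X, dim = c(S, 1, P))
  targ <- array(y, dim = c(S, 1, 1))
  fit <- fit_linear_baseline(feats, targ)
  # independent oracle: solve the normal equations directly
  Xi <- cbind(1, X)
  oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_lt(max(abs(fit$weights[, 1, 1] - oracle)), 1e-8)
  expect_lt(max(abs(fit$weights[, 1, 1] - beta)), 1e-8)
})

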