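#' Training configuration
#'
#' Adam optimization with patience-based learning-rate decay and early
#' stopping: the learning rate is multiplied by `lr_decay_factor` whenever the
#' validation loss has not improved (relative decrease > 1e-6) for
#' `lr_patience_epochs` consecutive epochs, and training stops after
#' `stop_patience_epochs` epochs without improvement. Augmentation draws one
#' shared scale factor for inputs and targets and adds white noise to the
#' inputs only.
#'
#' @param initial_lr initial Adam learning rate.
#' @param lr_decay_factor multiplicative decay in (0, 1).
#' @param lr_patience_epochs epochs without improvement before a decay.
#' @param stop_patience_epochs epochs without improvement before stopping
#'   (>= `lr_patience_epochs`).
#' @param scale_augment_range `(lo, hi)` with `lo <= 1 <= hi`.
#' @param noise_augment_sd input white-noise sd.
#' @param batch_size gradient-accumulation batch size.
#' @param max_epochs epoch cap.
#' @param seed integer seed covering shuffling, augmentation and dropout.
#' @param checkpoint which weights to return: `"best"` (lowest validation
#'   loss) or `"final"` (last epoch). With very small validation sets the
#'   validation loss is noise-dominated and best-val selection can freeze on
#'   an early lucky dip; `"final"` trains for a fixed budget instead.
#' @return object of class `train_config`.
#' @export
train_config <- function(initial_lr = 1e-3, lr_decay_factor = 0.5,
                         lr_patience_epochs = 20L, stop_patience_epochs = 50L,
                         scale_augment_range = c(0.9, 1.1),
                         noise_augment_sd = 0.05, batch_size = 1L,
                         max_epochs = 100L, seed = 1L,
                         checkpoint = c("best", "final")) {
  checkpoint <- match.arg(checkpoint)
  stopifnot(initial_lr > 0, lr_decay_factor > 0, lr_decay_factor < 1,
            lr_patience_epochs >= 1, stop_patience_epochs >= lr_patience_epochs,
            length(scale_augment_range) == 2L,
            scale_augment_range[1] <= 1, scale_augment_range[2] >= 1,
            scale_augment_range[1] > 0,
            noise_augment_sd >= 0, batch_size >= 1, max_epochs >= 1)
  structure(list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
                 lr_patience_epochs = as.integer(lr_patience_epochs),
                 stop_patience_epochs = as.integer(stop_patience_epochs),
                 scale_augment_range = scale_augment_range,
                 noise_augment_sd = noise_augment_sd,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), checkpoint = checkpoint),
            class = "train_config")
}

#' Domain-weighted mean-squared-error loss
#'
#' `L = sum_m weight_m * mean_voxels((pred_m - actual_m)^2)` with the per-map
#' weights of the task atlas, which give every task domain — not every map —
#' equal influence.
#'
#' @param pred,actual named lists of volumes, or 4D arrays whose 4th dimension
#'   follows the atlas map order.
#' @param atlas a [task_atlas()].
#' @return nonnegative scalar loss.
#' @export
domain_weighted_mse <- function(pred, actual, atlas) {
  p4 <- as_map_array(pred, atlas)
  a4 <- as_map_array(actual, atlas)
  if (!identical(dim(p4), dim(a4))) stop("pred and actual shapes differ")
  w <- atlas$maps$weight
  nvox <- prod(dim(p4)[1:3])
  r2 <- (p4 - a4)^2
  sum(w * colSums(matrix(r2, nvox, atlas$n_maps)) / nvox)
}

as_map_array <- function(x, atlas) {
  if (is.array(x) && length(dim(x)) == 4L) {
    if (dim(x)[4] != atlas$n_maps) stop("map count does not match the atlas")
    return(x)
  }
  if (is.list(x)) {
    if (!setequal(names(x), atlas$maps$map))
      stop("map set does not match the atlas")
    x <- x[atlas$maps$map]
    return(array(unlist(x, use.names = FALSE),
                 dim = c(dim(x[[1]]), length(x))))
  }
  stop("expected a 4D array or a named list of volumes")
}

# loss and gradient wrt pred, both as 4D arrays in atlas order
loss_and_grad <- function(pred4, actual4, weights) {
  nvox <- prod(dim(pred4)[1:3])
  r <- pred4 - actual4
  per_map <- colSums(matrix(r^2, nvox, length(weights))) / nvox
  dy <- sweep(r, 4, 2 * weights / nvox, `*`)
  list(loss = sum(weights * per_map), dy = dy)
}

#' Augment one training pair
#'
#' One scale factor drawn from `Uniform(lo, hi)` multiplies all input channels
#' *and* all target maps (a shared factor preserves the structure-to-function
#' relationship under scaling); i.i.d. Gaussian noise is then added to the
#' input channels only. Deterministic given the RNG state.
#'
#' @param x input 4D array.
#' @param y target 4D array.
#' @param config a [train_config()].
#' @return list with augmented `x`, `y` and the drawn `factor`.
#' @export
augment_pair <- function(x, y, config) {
  f <- runif(1, config$scale_augment_range[1], config$scale_augment_range[2])
  x <- x * f
  y <- y * f
  if (config$noise_augment_sd > 0)
    x <- x + array(rnorm(length(x), sd = config$noise_augment_sd), dim = dim(x))
  list(x = x, y = y, factor = f)
}

#' Prepare a training dataset from subject records
#'
#' Builds the feature stack and the stack-space target array (activation maps
#' pushed through the same crop/resample transform) for every subject.
#'
#' @param subjects list of `subject_record`s.
#' @param atlas a [task_atlas()].
#' @param channels channel set (see [build_feature_stack()]).
#' @param target_shape stack spatial shape (default: subject grid).
#' @return list of `list(x, y, subject_id, stack)` samples.
#' @export
prepare_dataset <- function(subjects, atlas, channels = "t1+t2+dti12",
                            target_shape = NULL) {
  lapply(subjects, function(s) {
    stack <- build_feature_stack(s, target_shape = target_shape,
                                 channels = channels)
    ts <- stack$transform$target_shape
    y <- array(0, dim = c(ts, atlas$n_maps))
    for (m in seq_len(atlas$n_maps))
      y[, , , m] <- resample_volume(s$activations[[atlas$maps$map[m]]],
                                    stack$transform)
    list(x = stack$data, y = y, subject_id = s$subject_id, stack = stack)
  })
}

# --- nested parameter-tree helpers (params/grads share one nesting) --------

zeros_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) return(lapply(p, zeros_like))
  p * 0
}

nested_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (i in seq_along(a)) a[i] <- list(nested_add(a[[i]], b[[i]]))
    return(a)
  }
  a + b
}

nested_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, nested_scale, s = s))
  a * s
}

adam_update <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(p) || is.null(g)) return(list(p = p, m = m, v = v))
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- adam_update(p[[i]], g[[i]], m[[i]], v[[i]], lr, t, b1, b2, eps)
      p[i] <- list(r$p); m[i] <- list(r$m); v[i] <- list(r$v)
    }
    return(list(p = p, m = m, v = v))
  }
  m2 <- b1 * m + (1 - b1) * g
  v2 <- b2 * v + (1 - b2) * g^2
  mh <- m2 / (1 - b1^t)
  vh <- v2 / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
}

#' Train a U-Net on paired stacks and activation targets
#'
#' Adam with the domain-weighted MSE loss, shared-scale/noise augmentation,
#' patience-based learning-rate decay, early stopping, and best-validation
#' checkpointing. Train and validation subject ids must be disjoint. Fully
#' reproducible from `config$seed`.
#'
#' @param model a `unet_model` (initial weights).
#' @param train_data,val_data datasets from [prepare_dataset()].
#' @param atlas a [task_atlas()].
#' @param config a [train_config()].
#' @param val_loss_override optional `function(epoch)` replacing the computed
#'   validation loss (used to exercise the scheduling logic in isolation).
#' @param verbose print per-epoch losses.
#' @return list with `model` (best-validation weights), `history` (data.frame
#'   epoch/train_loss/val_loss/lr), `best_epoch`, `best_val`.
#' @export
train_model <- function(model, train_data, val_data, atlas, config,
                        val_loss_override = NULL, verbose = FALSE) {
  ids_tr <- vapply(train_data, `[[`, "", "subject_id")
  ids_va <- vapply(val_data, `[[`, "", "subject_id")
  if (length(val_data) == 0L) stop("validation set must not be empty")
  if (length(intersect(ids_tr, ids_va)) > 0L)
    stop(sprintf("train and validation subject ids overlap: %s",
                 paste(intersect(ids_tr, ids_va), collapse = ", ")))
  w <- atlas$maps$weight
  with_seed(config$seed, {
    mstate <- zeros_like(model$params)
    vstate <- zeros_like(model$params)
    t_step <- 0L
    lr <- config$initial_lr
    best_val <- Inf
    best_params <- model$params
    best_epoch <- 0L
    since_improve <- 0L
    hist <- list()
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(train_data))
      tr_losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        idx <- ord[i:min(i + config$batch_size - 1L, length(ord))]
        gsum <- NULL
        for (j in idx) {
          smp <- train_data[[j]]
          aug <- augment_pair(smp$x, smp$y, config)
          fw <- unet_forward(model, aug$x, training = TRUE)
          lg <- loss_and_grad(fw$y, aug$y, w)
          tr_losses <- c(tr_losses, lg$loss)
          g <- unet_backward(model, fw$cache, lg$dy)
          gsum <- if (is.null(gsum)) g else nested_add(gsum, g)
        }
        gsum <- nested_scale(gsum, 1 / length(idx))
        t_step <- t_step + 1L
        upd <- adam_update(model$params, gsum, mstate, vstate, lr, t_step)
        model$params <- upd$p
        mstate <- upd$m
        vstate <- upd$v
        i <- i + config$batch_size
      }
      val_loss <- if (!is.null(val_loss_override)) val_loss_override(epoch)
      else mean(vapply(val_data, function(smp) {
        fw <- unet_forward(model, smp$x, training = FALSE)
        loss_and_grad(fw$y, smp$y, w)$loss
      }, 0))
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = mean(tr_losses),
                                  val_loss = val_loss, lr = lr)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2g",
                        epoch, mean(tr_losses), val_loss, lr))
      if (val_loss < best_val * (1 - 1e-6)) {
        best_val <- val_loss
        best_params <- model$params
        best_epoch <- epoch
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve %% config$lr_patience_epochs == 0L)
          lr <- lr * config$lr_decay_factor
        if (since_improve >= config$stop_patience_epochs) break
      }
    }
    if ((config$checkpoint %||% "best") == "best") model$params <- best_params
    list(model = model, history = do.call(rbind, hist),
         best_epoch = best_epoch, best_val = best_val)
  })
}

# derangement (permutation with no fixed points) of 1..n, from the current RNG
draw_derangement <- function(n) {
  if (n < 2L) stop("a derangement needs at least 2 elements")
  repeat {
    p <- sample(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Train the permuted-pairing baseline
#'
#' Identical to [train_model()] except that every training subject's input
#' stack is paired with a different subject's activation targets (a uniformly
#' drawn derangement), breaking the within-subject structure-to-function link.
#' The permutation is recorded in the result.
#'
#' @inheritParams train_model
#' @return as [train_model()], plus `permutation`.
#' @export
train_permutation_baseline <- function(model, train_data, val_data, atlas,
                                       config, verbose = FALSE) {
  n <- length(train_data)
  perm <- with_seed(config$seed + 1L, draw_derangement(n))
  permuted <- lapply(seq_len(n), function(i) {
    s <- train_data[[i]]
    s$y <- train_data[[perm[i]]]$y
    s
  })
  out <- train_model(model, permuted, val_data, atlas, config,
                     verbose = verbose)
  out$permutation <- perm
  out
}

#' Per-vertex linear regression baseline
#'
#' Fits an independent ordinary-least-squares model (with intercept) at every
#' (vertex, map) pair across training subjects. Rank-deficient vertices fall
#' back to the minimum-norm (pseudoinverse) solution and are flagged.
#'
#' @param vertex_features subjects x vertices x features array.
#' @param vertex_targets subjects x vertices x maps array.
#' @return object of class `linear_baseline`: list with `weights`
#'   ((features+1) x vertices x maps; row 1 is the intercept), `flagged`
#'   (logical per vertex), dims.
#' @export
fit_linear_baseline <- function(vertex_features, vertex_targets) {
  ds <- dim(vertex_features)
  dt <- dim(vertex_targets)
  stopifnot(length(ds) == 3L, length(dt) == 3L, ds[1] == dt[1], ds[2] == dt[2])
  S <- ds[1]; V <- ds[2]; P <- ds[3]; M <- dt[3]
  if (S <= P + 1L)
    stop(sprintf("need more subjects (%d) than features + 1 (%d)", S, P + 1L))
  W <- array(0, dim = c(P + 1L, V, M))
  flagged <- logical(V)
  for (v in seq_len(V)) {
    X <- cbind(1, matrix(vertex_features[, v, ], S, P))
    Y <- matrix(vertex_targets[, v, ], S, M)
    qr_x <- qr(X)
    if (qr_x$rank < P + 1L) {
      flagged[v] <- TRUE
      sv <- svd(X)
      pos <- sv$d > max(sv$d) * 1e-10
      W[, v, ] <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) %*% Y / sv$d[pos])
    } else {
      W[, v, ] <- qr.coef(qr_x, Y)
    }
  }
  structure(list(weights = W, flagged = flagged, n_features = P, n_maps = M,
                 n_vertices = V), class = "linear_baseline")
}

#' Predict from a fitted per-vertex linear baseline
#'
#' @param fit a `linear_baseline`.
#' @param vertex_features subjects x vertices x features array.
#' @return subjects x vertices x maps array of predictions.
#' @export
predict_linear_baseline <- function(fit, vertex_features) {
  ds <- dim(vertex_features)
  stopifnot(ds[2] == fit$n_vertices, ds[3] == fit$n_features)
  S <- ds[1]; V <- ds[2]; P <- ds[3]; M <- fit$n_maps
  out <- array(0, dim = c(S, V, M))
  for (v in seq_len(V)) {
    X <- cbind(1, matrix(vertex_features[, v, ], S, P))
    out[, v, ] <- X %*% fit$weights[, v, ]
  }
  out
}

#' Sample feature channels at surface vertices for a set of subjects
#'
#' Builds the (z-scored) channel volumes for each subject on the original
#' grid and samples them at the template vertex loci — the feature matrix for
#' the per-vertex linear baseline.
#'
#' @param subjects list of `subject_record`s.
#' @param template a [surface_template()].
#' @param channels channel set (see [build_feature_stack()]).
#' @return subjects x vertices x features array (channel names in
#'   `dimnames[[3]]`).
#' @export
vertex_feature_matrix <- function(subjects, template, channels = "t1+t2+dti12") {
  mats <- lapply(subjects, function(s) {
    cv <- channel_volumes(s, channels)
    vapply(seq_along(cv$vols), function(j) {
      v <- cv$vols[[j]]
      if (cv$norm_flags[j]) {
        mv <- v[s$brain_mask]
        sdv <- sd(mv)
        if (sdv > 0) v <- (v - mean(mv)) / sdv
      }
      sample_to_surface(v, template)
    }, numeric(nrow(template$vertices)))
  })
  out <- array(0, dim = c(length(subjects), nrow(template$vertices),
                          ncol(mats[[1]])))
  for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
  dimnames(out) <- list(NULL, NULL,
                        names(channel_volumes(subjects[[1]], channels)$vols))
  out
}
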