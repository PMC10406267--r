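#' Configure the residual 3D U-Net
#'
#' The architecture regresses one output channel per activation map from a
#' multi-channel volumetric feature stack. Encoder: `depth` layers, layer i
#' carrying `base_channels * 2^(i-1)` channels, each layer two pre-activation
#' residual blocks (group norm, ReLU, 3x3x3 convolution, twice, with an
#' identity skip and a 1x1x1 projection where channel counts change);
#' whole-channel dropout between the two blocks of the first layer only;
#' stride-2 convolutions (which double the channel count) between layers.
#' Decoder: mirrored, each layer receiving the trilinearly upsampled previous
#' decoder output (1x1x1-convolved to halve its channels) concatenated with
#' the same-depth encoder output. A final group norm and 1x1x1 convolution
#' map to `out_maps` channels with no output nonlinearity (z-score
#' regression).
#'
#' @param in_channels input channel count (14 full stack, 2 t1+t2, 1 for
#'   single-channel ablations).
#' @param out_maps number of predicted activation maps.
#' @param base_channels channels in the first encoder layer.
#' @param depth number of encoder layers; input spatial shape must be
#'   divisible by `2^(depth-1)`.
#' @param dropout_rate channel dropout rate in the first encoder layer.
#' @param groupnorm_groups preferred group-norm group count (per-layer group
#'   counts are the largest divisor of the channel count not exceeding this).
#' @param channel_names optional expected input channel names, checked by
#'   [predict_activations()].
#' @return object of class `model_config`.
#' @export
model_config <- function(in_channels, out_maps, base_channels = 32L,
                         depth = 5L, dropout_rate = 0.2,
                         groupnorm_groups = 8L, channel_names = NULL) {
  stopifnot(in_channels >= 1, out_maps >= 1, base_channels >= 1, depth >= 1,
            dropout_rate >= 0, dropout_rate < 1, groupnorm_groups >= 1)
  if (base_channels %% gn_groups(base_channels, groupnorm_groups) != 0)
    stop("base_channels must be divisible by its group-norm group count")
  structure(list(in_channels = as.integer(in_channels),
                 out_maps = as.integer(out_maps),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), dropout_rate = dropout_rate,
                 groupnorm_groups = as.integer(groupnorm_groups),
                 channel_names = channel_names), class = "model_config")
}

init_resblock <- function(cin, cout, gpref) {
  list(gn1 = init_gn(cin), conv1 = init_conv(3, cin, cout),
       gn2 = init_gn(cout), conv2 = init_conv(3, cout, cout),
       proj = if (cin != cout) init_conv(1, cin, cout) else NULL)
}

#' Build (initialize) a U-Net model
#'
#' Weights use fan-in-scaled Gaussian initialization drawn under `seed`.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `unet_model`: list with `config` and `params`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  ch <- config$base_channels * 2^(seq_len(config$depth) - 1L)
  g <- config$groupnorm_groups
  with_seed(seed, {
    params <- list(enc = vector("list", config$depth),
                   down = vector("list", config$depth),
                   dec = vector("list", max(config$depth - 1L, 0L)),
                   head = NULL)
    for (i in seq_len(config$depth)) {
      cin <- if (i == 1L) config$in_channels else ch[i]
      if (i > 1L) params$down[[i]] <- init_conv(3, ch[i - 1L], ch[i])
      params$enc[[i]] <- list(b1 = init_resblock(cin, ch[i], g),
                              b2 = init_resblock(ch[i], ch[i], g))
    }
    for (i in seq_len(config$depth - 1L)) {
      params$dec[[i]] <- list(up = init_conv(1, ch[i + 1L], ch[i]),
                              b1 = init_resblock(2L * ch[i], ch[i], g),
                              b2 = init_resblock(ch[i], ch[i], g))
    }
    params$head <- list(gn = init_gn(ch[1]),
                        conv = init_conv(1, ch[1], config$out_maps))
    structure(list(config = config, params = params), class = "unet_model")
  })
}

#' Number of trainable parameters
#' @param model a `unet_model`.
#' @return integer parameter count.
#' @export
param_count <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) n <<- n + length(x)
    invisible(NULL)
  }
  walk(model$params)
  n
}

resblock_fw <- function(p, x, gpref) {
  g1 <- gn_fw(x, p$gn1, gn_groups(dim(x)[4], gpref))
  r1 <- relu_fw(g1$y)
  h1 <- conv_fw(r1, p$conv1, 3, 1, 1)
  g2 <- gn_fw(h1, p$gn2, gn_groups(dim(h1)[4], gpref))
  r2 <- relu_fw(g2$y)
  h2 <- conv_fw(r2, p$conv2, 3, 1, 1)
  skip <- if (!is.null(p$proj)) conv_fw(x, p$proj, 1, 1, 0) else x
  list(y = h2 + skip,
       cache = list(x = x, g1 = g1, r1 = r1, g2 = g2, r2 = r2))
}

resblock_bw <- function(p, cache, dy) {
  cv2 <- conv_bw(cache$r2, p$conv2, dy, 3, 1, 1)
  dg2y <- relu_bw(cache$g2$y, cv2$dx)
  b2 <- gn_bw(cache$g2$cache, p$gn2, dg2y)
  cv1 <- conv_bw(cache$r1, p$conv1, b2$dx, 3, 1, 1)
  dg1y <- relu_bw(cache$g1$y, cv1$dx)
  b1 <- gn_bw(cache$g1$cache, p$gn1, dg1y)
  grads <- list(gn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                conv1 = list(w = cv1$dw, b = cv1$db),
                gn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
                conv2 = list(w = cv2$dw, b = cv2$db),
                proj = NULL)
  if (!is.null(p$proj)) {
    pv <- conv_bw(cache$x, p$proj, dy, 1, 1, 0)
    grads$proj <- list(w = pv$dw, b = pv$db)
    dx <- b1$dx + pv$dx
  } else dx <- b1$dx + dy
  list(dx = dx, grads = grads)
}

#' Forward pass of the U-Net
#'
#' @param model a `unet_model`.
#' @param x 4D input array (spatial dims x in_channels); each spatial dim
#'   must be divisible by `2^(depth-1)`.
#' @param training enable channel dropout (draws from the current RNG).
#' @return list with `y` (spatial dims x out_maps) and `cache` (for
#'   [unet_backward()]).
#' @export
unet_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  p <- model$params
  dm <- dim(x)
  if (length(dm) != 4L || dm[4] != cfg$in_channels)
    stop(sprintf("input must have %d channels, got %s", cfg$in_channels,
                 paste(dm, collapse = "x")))
  div <- 2^(cfg$depth - 1L)
  for (ax in 1:3)
    if (dm[ax] %% div != 0)
      stop(sprintf("spatial axis %d (size %d) is not divisible by %d",
                   ax, dm[ax], div))
  g <- cfg$groupnorm_groups
  enc_out <- vector("list", cfg$depth)
  cache <- list(enc = vector("list", cfg$depth),
                down_in = vector("list", cfg$depth),
                drop_scale = NULL,
                dec = vector("list", max(cfg$depth - 1L, 0L)))
  h <- x
  for (i in seq_len(cfg$depth)) {
    if (i > 1L) {
      cache$down_in[[i]] <- h
      h <- conv_fw(h, p$down[[i]], 3, 2, 1)
    }
    b1 <- resblock_fw(p$enc[[i]]$b1, h, g)
    h <- b1$y
    dscale <- NULL
    if (i == 1L && training && cfg$dropout_rate > 0) {
      dr <- channel_dropout_fw(h, cfg$dropout_rate)
      h <- dr$y
      dscale <- dr$scale
      cache$drop_scale <- dscale
    }
    b2 <- resblock_fw(p$enc[[i]]$b2, h, g)
    h <- b2$y
    cache$enc[[i]] <- list(b1 = b1$cache, b2 = b2$cache)
    enc_out[[i]] <- h
  }
  for (i in rev(seq_len(cfg$depth - 1L))) {
    u0 <- upsample2_fw_cpp(h, dim(h))
    u <- conv_fw(u0, p$dec[[i]]$up, 1, 1, 0)
    cc <- array(c(u, enc_out[[i]]), dim = c(dim(u)[1:3], dim(u)[4] + dim(enc_out[[i]])[4]))
    b1 <- resblock_fw(p$dec[[i]]$b1, cc, g)
    b2 <- resblock_fw(p$dec[[i]]$b2, b1$y, g)
    cache$dec[[i]] <- list(u0 = u0, n_up = dim(u)[4], b1 = b1$cache, b2 = b2$cache)
    h <- b2$y
  }
  gh <- gn_fw(h, p$head$gn, gn_groups(dim(h)[4], g))
  y <- conv_fw(gh$y, p$head$conv, 1, 1, 0)
  cache$head <- list(gn = gh, h = h)
  list(y = y, cache = cache)
}

#' Backward pass of the U-Net
#'
#' @param model a `unet_model`.
#' @param cache the cache from [unet_forward()].
#' @param dy gradient of the loss with respect to the output.
#' @return gradient list with the same nesting as `model$params`.
#' @export
unet_backward <- function(model, cache, dy) {
  cfg <- model$config
  p <- model$params
  g <- cfg$groupnorm_groups
  grads <- list(enc = vector("list", cfg$depth),
                down = vector("list", cfg$depth),
                dec = vector("list", max(cfg$depth - 1L, 0L)),
                head = NULL)
  hc <- cache$head
  cvh <- conv_bw(hc$gn$y, p$head$conv, dy, 1, 1, 0)
  gb <- gn_bw(hc$gn$cache, p$head$gn, cvh$dx)
  grads$head <- list(gn = list(gamma = gb$dgamma, beta = gb$dbeta),
                     conv = list(w = cvh$dw, b = cvh$db))
  dh <- gb$dx
  denc <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth - 1L)) {
    dc <- cache$dec[[i]]
    b2 <- resblock_bw(p$dec[[i]]$b2, dc$b2, dh)
    b1 <- resblock_bw(p$dec[[i]]$b1, dc$b1, b2$dx)
    n_up <- dc$n_up
    dcc <- b1$dx
    du <- dcc[, , , seq_len(n_up), drop = FALSE]
    de <- dcc[, , , n_up + seq_len(dim(dcc)[4] - n_up), drop = FALSE]
    denc[[i]] <- if (is.null(denc[[i]])) de else denc[[i]] + de
    cvu <- conv_bw(dc$u0, p$dec[[i]]$up, du, 1, 1, 0)
    grads$dec[[i]] <- list(up = list(w = cvu$dw, b = cvu$db),
                           b1 = b1$grads, b2 = b2$grads)
    dh <- upsample2_bw_cpp(cvu$dx, dim(cvu$dx) / c(2, 2, 2, 1))
  }
  denc[[cfg$depth]] <- dh
  for (i in rev(seq_len(cfg$depth))) {
    d <- denc[[i]]
    ec <- cache$enc[[i]]
    b2 <- resblock_bw(p$enc[[i]]$b2, ec$b2, d)
    d <- b2$dx
    if (i == 1L && !is.null(cache$drop_scale))
      d <- channel_dropout_bw(cache$drop_scale, d)
    b1 <- resblock_bw(p$enc[[i]]$b1, ec$b1, d)
    grads$enc[[i]] <- list(b1 = b1$grads, b2 = b2$grads)
    if (i > 1L) {
      cvd <- conv_bw(cache$down_in[[i]], p$down[[i]], b1$dx, 3, 2, 1)
      grads$down[[i]] <- list(w = cvd$dw, b = cvd$db)
      denc[[i - 1L]] <- if (is.null(denc[[i - 1L]])) cvd$dx else denc[[i - 1L]] + cvd$dx
    }
  }
  grads
}

#' Predict activation maps for one subject
#'
#' Runs the model on a feature stack (eval mode, no dropout) and maps every
#' predicted volume back to the subject's original grid through the stack's
#' inverse crop/resample transform.
#'
#' @param model a `unet_model`.
#' @param stack a `feature_stack` from [build_feature_stack()].
#' @param atlas a [task_atlas()] providing map names (length `out_maps`).
#' @return named list of 3D volumes on the original grid.
#' @export
predict_activations <- function(model, stack, atlas) {
  cfg <- model$config
  if (dim(stack$data)[4] != cfg$in_channels)
    stop(sprintf("stack has channels [%s] but the model expects %d channels%s",
                 paste(stack$channel_names, collapse = ", "), cfg$in_channels,
                 if (!is.null(cfg$channel_names))
                   sprintf(" [%s]", paste(cfg$channel_names, collapse = ", "))
                 else ""))
  if (!is.null(cfg$channel_names) &&
      !identical(cfg$channel_names, stack$channel_names))
    stop(sprintf("stack channel names [%s] do not match the model's expected [%s]",
                 paste(stack$channel_names, collapse = ", "),
                 paste(cfg$channel_names, collapse = ", ")))
  stopifnot(atlas$n_maps == cfg$out_maps)
  y <- unet_forward(model, stack$data, training = FALSE)$y
  out <- lapply(seq_len(cfg$out_maps), function(m)
    stack_to_volume(y[, , , m], stack$transform))
  names(out) <- atlas$maps$map
  out
}
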