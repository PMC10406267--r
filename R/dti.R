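#' Fit diffusion tensors for one b-shell
#'
#' Per-voxel ordinary least squares on the log signal,
#' `log S(g) = log S0 - b * t(g) %*% D %*% g`, using all b=0 volumes plus the
#' signals of the named shell only (each shell is fitted separately, sharing
#' the b0 volumes). Voxels with any nonpositive signal are flagged and get a
#' zero tensor.
#'
#' @param dwi a `dwi_sample` (see [generate_dwi()]).
#' @param b_value shell to fit; must exist in `dwi`.
#' @return object of class `tensor_fit`: list with `tensor` (4D array
#'   nx,ny,nz,6: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), `s0_est`,
#'   `shell_b`, `flagged` (logical array of zeroed voxels).
#' @export
fit_tensor_shell <- function(dwi, b_value) {
  bs <- vapply(dwi$shells, function(s) s$b_value, 0)
  i <- which(abs(bs - b_value) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("no shell with b = %g in this sample (available: %s)",
                 b_value, paste(bs, collapse = ", ")))
  sh <- dwi$shells[[i]]
  G <- sh$directions
  if (nrow(G) < 6L) stop("at least 6 gradient directions are required")
  if (length(dwi$b0_volumes) < 1L) stop("at least one b0 volume is required")
  dm <- dim(dwi$b0_volumes[[1]])
  nvox <- prod(dm)

  # design: rows = measurements, columns = (log S0, -b * quadratic form terms)
  bmat <- cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
                2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3])
  X <- rbind(
    cbind(1, matrix(0, length(dwi$b0_volumes), 6)),
    cbind(1, -sh$b_value * bmat))
  S <- c(lapply(dwi$b0_volumes, as.vector), lapply(sh$signals, as.vector))
  S <- do.call(rbind, S)                  # n_meas x nvox
  ok <- colSums(S <= 0) == 0
  beta <- matrix(0, 7, nvox)
  if (any(ok)) {
    XtXinvXt <- solve(crossprod(X), t(X))
    beta[, ok] <- XtXinvXt %*% log(S[, ok, drop = FALSE])
  }
  tensor <- array(0, dim = c(dm, 6L))
  for (j in 1:6) tensor[, , , j] <- array(beta[j + 1, ], dim = dm)
  s0 <- array(0, dim = dm)
  s0[ok] <- exp(beta[1, ok])
  structure(list(tensor = tensor, s0_est = s0, shell_b = sh$b_value,
                 flagged = array(!ok, dim = dm)), class = "tensor_fit")
}

#' Scalar maps from a tensor fit
#'
#' Per voxel: eigenvalues sorted descending and clamped at zero (clamp count
#' recorded), `MD = (l1+l2+l3)/3`,
#' `FA = sqrt(3/2) * sqrt(sum((l - mean(l))^2)) / sqrt(sum(l^2))` (0 when all
#' eigenvalues are 0), and the unit principal eigenvector with sign convention
#' first-nonzero-component nonnegative; degenerate voxels get direction
#' (0,0,0).
#'
#' @param fit a `tensor_fit` (or a bare 4D tensor array).
#' @return list with `md` (3D array), `fa` (3D array), `direction` (4D array
#'   nx,ny,nz,3), `n_clamped` (number of negative eigenvalues clamped).
#' @export
tensor_scalar_maps <- function(fit) {
  tens <- if (inherits(fit, "tensor_fit")) fit$tensor else fit
  dm <- dim(tens)[1:3]
  nvox <- prod(dm)
  tm <- matrix(tens, nrow = nvox)
  eg <- tensor_eig_cpp(tm)
  ev <- eg$evals
  n_clamped <- sum(ev < 0)
  ev[ev < 0] <- 0
  md <- rowMeans(ev)
  ss <- rowSums(ev^2)
  dev2 <- rowSums((ev - md)^2)
  fa <- ifelse(ss > 0, sqrt(1.5 * dev2 / ss), 0)
  dir <- eg$evec1
  dir[ss == 0, ] <- 0
  list(md = array(md, dim = dm), fa = array(fa, dim = dm),
       direction = array(dir, dim = c(dm, 3L)), n_clamped = n_clamped)
}

#' Directionally-encoded (RGB) fractional anisotropy
#'
#' FA multiplied by the absolute components of the principal eigenvector —
#' the standard red-green-blue FA encoding. Componentwise in `[0, FA]` with
#' Euclidean norm equal to FA.
#'
#' @param fa FA scalar (or vector), in `[0, 1]`.
#' @param direction unit 3-vector (or n x 3 matrix).
#' @return 3-vector (or n x 3 matrix) of FA-weighted absolute components.
#' @export
directional_fa <- function(fa, direction) {
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3)
  if (any(fa < 0 | fa > 1)) stop("FA must lie in [0, 1]")
  nrm <- sqrt(rowSums(direction^2))
  bad <- abs(nrm - 1) > 1e-6 & fa != 0
  if (any(bad)) stop("direction must be unit-norm (tolerance 1e-6) when FA > 0")
  out <- abs(direction) * fa
  if (nrow(out) == 1L) out <- drop(out)
  out
}

#' Build the model input feature stack for one subject
#'
#' Channel sets: `"t1+t2+dti12"` (t1, t2, then per shell MD, FAx, FAy, FAz —
#' 14 channels), `"t1+t2"`, `"t1"`, or a single binary channel
#' `"cortex-mask"` / `"subcortical-mask"` / `"brain-mask"`. Volumes are
#' cropped to the brain-mask bounding box, trilinearly resampled to
#' `target_shape`, and (for image channels) z-scored over brain voxels;
#' binary mask channels are passed through unnormalized. The crop/resample
#' transform is recorded so predictions can be mapped back to the original
#' grid with [stack_to_volume()].
#'
#' @param subject a `subject_record`.
#' @param target_shape 3 integers; default: the subject grid.
#' @param channels channel-set name (see above).
#' @param normalize z-score image channels over brain voxels.
#' @return object of class `feature_stack`: list with `data` (4D array
#'   target_shape x n_channels), `channel_names`, `transform`, `mask`
#'   (resampled brain mask), `subject_id`.
#' @export
build_feature_stack <- function(subject, target_shape = NULL,
                                channels = "t1+t2+dti12", normalize = TRUE) {
  dm <- subject$grid_shape
  if (is.null(target_shape)) target_shape <- dm
  target_shape <- as.integer(target_shape)
  mask <- subject$brain_mask
  if (!any(mask)) stop("empty brain mask")

  cv <- channel_volumes(subject, channels)
  vols <- cv$vols
  norm_flags <- cv$norm_flags
  tr <- stack_transform(mask, target_shape)
  n_ch <- length(vols)
  data <- array(0, dim = c(target_shape, n_ch))
  rmask <- resample_volume(mask * 1, tr) > 0.5
  for (j in seq_len(n_ch)) {
    v <- resample_volume(vols[[j]], tr)
    if (normalize && norm_flags[j]) {
      mv <- v[rmask]
      s <- sd(mv)
      v <- if (s > 0) (v - mean(mv)) / s else v * 0
    }
    data[, , , j] <- v
  }
  structure(list(data = data, channel_names = names(vols), transform = tr,
                 mask = rmask, subject_id = subject$subject_id),
            class = "feature_stack")
}

# Build the named channel volumes (original grid) for a channel set.
channel_volumes <- function(subject, channels) {
  dm <- subject$grid_shape
  vols <- list()
  norm_flags <- logical(0)
  add <- function(vs, name, nrm) {
    vols[[name]] <<- vs
    norm_flags[name] <<- nrm
  }
  if (channels %in% c("t1+t2+dti12", "t1+t2", "t1")) {
    add(subject$structural$t1, "t1", TRUE)
    if (channels != "t1") add(subject$structural$t2, "t2", TRUE)
    if (channels == "t1+t2+dti12") {
      for (sh in subject$dwi$shells) {
        fit <- fit_tensor_shell(subject$dwi, sh$b_value)
        sm <- tensor_scalar_maps(fit)
        rgb <- abs(sm$direction) * array(sm$fa, dim = c(dm, 3L))
        pre <- sprintf("b%d", as.integer(sh$b_value))
        add(sm$md, paste0(pre, "_md"), TRUE)
        add(rgb[, , , 1], paste0(pre, "_fax"), TRUE)
        add(rgb[, , , 2], paste0(pre, "_fay"), TRUE)
        add(rgb[, , , 3], paste0(pre, "_faz"), TRUE)
      }
    }
  } else if (channels %in% c("cortex-mask", "subcortical-mask", "brain-mask")) {
    kind <- sub("-mask$", "", channels)
    add(masked_input_volumes(subject, kind), channels, FALSE)
  } else stop(sprintf("unknown channel set '%s'", channels))
  list(vols = vols, norm_flags = norm_flags)
}

# Crop-to-bounding-box + trilinear resample transform. Maps target voxel
# centers linearly onto the source bounding box (edge-to-edge), which reduces
# to the identity when the box covers the full grid and shapes match.
stack_transform <- function(mask, target_shape) {
  idx <- which(mask, arr.ind = TRUE)
  bb0 <- apply(idx, 2, min)
  bb1 <- apply(idx, 2, max)
  list(bb0 = bb0, bb1 = bb1, source_shape = dim(mask),
       target_shape = target_shape)
}

# target voxel i center -> source coordinate
target_to_source <- function(tr) {
  lapply(1:3, function(ax) {
    len <- tr$bb1[ax] - tr$bb0[ax] + 1
    (tr$bb0[ax] - 0.5) + (seq_len(tr$target_shape[ax]) - 0.5) *
      (len / tr$target_shape[ax])
  })
}

resample_volume <- function(vol, tr) {
  cs <- target_to_source(tr)
  ts <- tr$target_shape
  pts <- cbind(rep(cs[[1]], times = ts[2] * ts[3]),
               rep(rep(cs[[2]], each = ts[1]), times = ts[3]),
               rep(cs[[3]], each = ts[1] * ts[2]))
  array(trilinear_at(vol, pts), dim = ts)
}

#' Map a stack-space volume back to the original grid
#'
#' Inverse of the crop/resample transform recorded by
#' [build_feature_stack()]: trilinear resampling of the stack-space volume at
#' the source voxel centers; voxels outside the crop box get 0.
#'
#' @param vol 3D array in stack space (`transform$target_shape`).
#' @param transform the `transform` element of a `feature_stack`.
#' @return 3D array on the original source grid.
#' @export
stack_to_volume <- function(vol, transform) {
  sdm <- transform$source_shape
  ts <- transform$target_shape
  out <- array(0, dim = sdm)
  # source coordinate -> target coordinate (inverse of target_to_source)
  cs <- lapply(1:3, function(ax) {
    len <- transform$bb1[ax] - transform$bb0[ax] + 1
    (seq_len(sdm[ax]) - (transform$bb0[ax] - 0.5)) * (ts[ax] / len) + 0.5
  })
  inside <- lapply(1:3, function(ax)
    which(cs[[ax]] >= 0.5 & cs[[ax]] <= ts[ax] + 0.5))
  pts <- cbind(rep(cs[[1]][inside[[1]]], times = length(inside[[2]]) * length(inside[[3]])),
               rep(rep(cs[[2]][inside[[2]]], each = length(inside[[1]])),
                   times = length(inside[[3]])),
               rep(cs[[3]][inside[[3]]], each = length(inside[[1]]) * length(inside[[2]])))
  out[inside[[1]], inside[[2]], inside[[3]]] <-
    array(trilinear_at(vol, pts),
          dim = c(length(inside[[1]]), length(inside[[2]]), length(inside[[3]])))
  out
}

#' Binary tissue-mask input volumes
#'
#' Masks derived from the synthetic tissue labels: `"cortex"`,
#' `"subcortical"`, or `"brain"` (the whole-brain mask, a superset of both).
#'
#' @param subject a `subject_record`.
#' @param kind one of `"cortex"`, `"subcortical"`, `"brain"`.
#' @return 3D 0/1 numeric array.
#' @export
masked_input_volumes <- function(subject, kind = c("cortex", "subcortical", "brain")) {
  kind <- match.arg(kind)
  m <- switch(kind,
              cortex = subject$tissue == 1L,
              subcortical = subject$tissue == 2L,
              brain = subject$brain_mask)
  if (!any(m)) stop(sprintf("the %s mask is empty for this subject", kind))
  m * 1
}
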