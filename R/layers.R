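# Differentiable layer primitives. All activations are 4D arrays
# (nx, ny, nz, channels); batch size is always one volume.

conv_fw <- function(x, p, k, stride = 1L, pad = 1L) {
  conv3d_fw_cpp(x, p$w, p$b, dim(x), as.integer(k), as.integer(stride),
                as.integer(pad))
}

conv_bw <- function(x, p, dy, k, stride = 1L, pad = 1L) {
  conv3d_bw_cpp(x, p$w, dy, dim(x), as.integer(k), as.integer(stride),
                as.integer(pad))
}

# Largest divisor of n_channels not exceeding the preferred group count; used
# so group normalization stays well-defined for any channel count (e.g. the
# 14-channel input layer with a preferred group count of 8 uses 7 groups).
gn_groups <- function(n_channels, preferred) {
  d <- which(n_channels %% seq_len(min(n_channels, preferred)) == 0)
  max(d)
}

gn_fw <- function(x, p, groups, eps = 1e-5) {
  dm <- dim(x)
  nvox <- prod(dm[1:3])
  C <- dm[4]
  cg <- C %/% groups
  M2 <- matrix(x, nvox * cg, groups)
  mu <- colMeans(M2)
  va <- colMeans(M2^2) - mu^2
  inv <- 1 / sqrt(va + eps)
  xhat2 <- sweep(sweep(M2, 2, mu, `-`), 2, inv, `*`)
  xhat <- matrix(xhat2, nvox, C)
  y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  dim(y) <- dm
  list(y = y, cache = list(xhat = xhat, inv = inv, dm = dm, groups = groups))
}

gn_bw <- function(cache, p, dy) {
  dm <- cache$dm
  nvox <- prod(dm[1:3])
  C <- dm[4]
  groups <- cache$groups
  cg <- C %/% groups
  dym <- matrix(dy, nvox, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, p$gamma, `*`)
  dxhat2 <- matrix(dxhat, nvox * cg, groups)
  xhat2 <- matrix(cache$xhat, nvox * cg, groups)
  N <- nvox * cg
  s1 <- colSums(dxhat2)
  s2 <- colSums(dxhat2 * xhat2)
  dx2 <- sweep(dxhat2 - sweep(xhat2, 2, s2 / N, `*`), 2, s1 / N, `-`)
  dx2 <- sweep(dx2, 2, cache$inv, `*`)
  dx <- array(dx2, dim = dm)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) pmax(x, 0)
relu_bw <- function(x, dy) dy * (x > 0)

# Whole-channel (spatial) dropout: zeroes entire feature channels.
channel_dropout_fw <- function(x, rate) {
  C <- dim(x)[4]
  keep <- runif(C) >= rate
  scale <- keep / (1 - rate)
  y <- sweep(x, 4, scale, `*`)
  list(y = y, scale = scale)
}

channel_dropout_bw <- function(scale, dy) sweep(dy, 4, scale, `*`)

init_conv <- function(k, cin, cout) {
  fan_in <- k^3 * cin
  list(w = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
       b = rep(0, cout))
}

init_gn <- function(C) list(gamma = rep(1, C), beta = rep(0, C))
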