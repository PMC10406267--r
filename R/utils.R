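#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so that library functions are reproducible without
#' clobbering the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Voxel-center coordinate grids for a volume of shape `dm` (1-based centers).
grid_coords <- function(dm) {
  list(
    x = array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dim = dm),
    y = array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dim = dm),
    z = array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dim = dm)
  )
}

#' Trilinear interpolation of a 3D volume at arbitrary points
#'
#' Points are in voxel index space (voxel centers at 1..n along each axis).
#'
#' @param vol 3D numeric array.
#' @param pts n x 3 matrix of coordinates.
#' @return numeric vector of interpolated values.
#' @keywords internal
trilinear_at <- function(vol, pts) {
  dm <- dim(vol)
  stopifnot(length(dm) == 3L, ncol(pts) == 3L)
  p <- pmin(pmax(pts, 1), matrix(dm, nrow(pts), 3, byrow = TRUE))
  i0 <- pmin(floor(p), matrix(dm - 1L, nrow(pts), 3, byrow = TRUE))
  i0 <- pmax(i0, 1)
  w <- p - i0
  i1 <- i0 + 1L
  idx <- function(a, b, c) {
    vol[cbind(a, b, c)]
  }
  (1 - w[, 3]) * ((1 - w[, 2]) * ((1 - w[, 1]) * idx(i0[, 1], i0[, 2], i0[, 3]) +
                                    w[, 1] * idx(i1[, 1], i0[, 2], i0[, 3])) +
                    w[, 2] * ((1 - w[, 1]) * idx(i0[, 1], i1[, 2], i0[, 3]) +
                                w[, 1] * idx(i1[, 1], i1[, 2], i0[, 3]))) +
    w[, 3] * ((1 - w[, 2]) * ((1 - w[, 1]) * idx(i0[, 1], i0[, 2], i1[, 3]) +
                                w[, 1] * idx(i1[, 1], i0[, 2], i1[, 3])) +
                w[, 2] * ((1 - w[, 1]) * idx(i0[, 1], i1[, 2], i1[, 3]) +
                            w[, 1] * idx(i1[, 1], i1[, 2], i1[, 3])))
}

# Mirror a volume's x axis about the mid-sagittal plane (x -> nx + 1 - x).
mirror_x <- function(vol) {
  vol[rev(seq_len(dim(vol)[1])), , , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
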