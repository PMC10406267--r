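#' Default diffusion acquisition protocol
#'
#' Three b-shells (1000, 2000, 3000 s/mm^2), each with the six icosahedral
#' gradient directions — the minimum direction count for a tensor fit — plus
#' one b=0 volume. Direction counts and b-values are configurable; six
#' directions per shell keeps the synthetic cohorts small while leaving the
#' per-shell tensor inverse problem exactly determined.
#'
#' @param b_values numeric vector of shell b-values (s/mm^2).
#' @param n_directions directions per shell (>= 6).
#' @param n_b0 number of b=0 volumes.
#' @return list with `shells` (list of `list(b_value, directions)`), `n_b0`.
#' @export
default_dwi_protocol <- function(b_values = c(1000, 2000, 3000),
                                 n_directions = 6L, n_b0 = 1L) {
  if (any(b_values < 0)) stop("b-values must be nonnegative")
  if (n_directions < 6L) stop("at least 6 directions per shell are required")
  dirs <- icosahedral_directions(n_directions)
  list(shells = lapply(b_values, function(b) list(b_value = b, directions = dirs)),
       n_b0 = as.integer(n_b0))
}

# n quasi-uniform unit gradient directions; the first six are the classic
# icosahedral set, further directions come from a Fibonacci hemisphere.
icosahedral_directions <- function(n) {
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(c(1, phi, 0), c(-1, phi, 0), c(0, 1, phi),
                c(0, -1, phi), c(phi, 0, 1), c(phi, 0, -1))
  base <- base / sqrt(rowSums(base^2))
  if (n <= 6L) return(base[seq_len(n), , drop = FALSE])
  m <- n - 6L
  i <- seq_len(m)
  z <- (2 * i - 1) / (2 * m)          # upper hemisphere
  th <- 2 * pi * i * (2 / (1 + sqrt(5)))
  extra <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  rbind(base, extra)
}

#' Specify a synthetic cohort
#'
#' Defines the study conditions for [generate_cohort()]: cohort size, grid,
#' the dimension of the per-subject latent anatomy vector theta, the amplitude
#' `effect_size` of the individual activation component, per-session activation
#' noise, the spread of the per-subject lateralization coefficient, vertex
#' alignment jitter (emulating surface-registration imperfection), and the
#' diffusion protocol.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param grid_shape 3 even positive integers (voxels).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param n_latent dimension of theta (1..8).
#' @param effect_size amplitude beta of the individual activation component.
#' @param noise_sd per-session activation noise sd (z-score units).
#' @param lateralization_sd sd of the per-subject lateralization coefficient.
#' @param alignment_jitter_mm sd of per-subject vertex sampling jitter.
#' @param dwi_protocol see [default_dwi_protocol()].
#' @param dwi_noise_sd additive Gaussian noise sd on diffusion signals
#'   (signal units; b0 is 100).
#' @param seed integer seed; the full cohort is reproducible from it.
#' @param sessions 1 or 2 (2 adds a retest session with fresh activation noise).
#' @param n_vertices_per_hemi vertices per hemisphere in the surface template.
#' @param smooth_fwhm_mm optional Gaussian smoothing of activation maps (0 = off).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L, grid_shape = c(24L, 24L, 24L),
                        voxel_size_mm = 2, n_latent = 6L,
                        effect_size = 1, noise_sd = 0.5,
                        lateralization_sd = 0.5, alignment_jitter_mm = 0,
                        dwi_protocol = default_dwi_protocol(),
                        dwi_noise_sd = 0, seed = 1L, sessions = 1L,
                        n_vertices_per_hemi = 120L, smooth_fwhm_mm = 0) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0))
    stop("grid_shape must be 3 positive integers")
  if (any(grid_shape %% 2L != 0L))
    stop("grid_shape must be even in each axis")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  if (n_latent < 1L || n_latent > 8L)
    stop("n_latent must be between 1 and 8 (8 deformation basis functions)")
  for (nm in c("effect_size", "noise_sd", "lateralization_sd",
               "alignment_jitter_mm", "dwi_noise_sd", "smooth_fwhm_mm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop(sprintf("%s must be a nonnegative scalar", nm))
  }
  for (sh in dwi_protocol$shells) {
    if (sh$b_value < 0) stop("negative b-value in dwi_protocol")
    nrm <- sqrt(rowSums(sh$directions^2))
    if (any(abs(nrm - 1) > 1e-8))
      stop("gradient directions must be unit-norm (tolerance 1e-8)")
  }
  if (!sessions %in% c(1L, 2L)) stop("sessions must be 1 or 2")
  structure(list(
    n_subjects = as.integer(n_subjects), grid_shape = grid_shape,
    voxel_size_mm = voxel_size_mm, n_latent = as.integer(n_latent),
    effect_size = effect_size, noise_sd = noise_sd,
    lateralization_sd = lateralization_sd,
    alignment_jitter_mm = alignment_jitter_mm,
    dwi_protocol = dwi_protocol, dwi_noise_sd = dwi_noise_sd,
    seed = as.integer(seed), sessions = as.integer(sessions),
    n_vertices_per_hemi = as.integer(n_vertices_per_hemi),
    smooth_fwhm_mm = smooth_fwhm_mm), class = "cohort_spec")
}

# ---------------------------------------------------------------------------
# Template geometry. The brain is an ellipsoid; the per-subject latent vector
# theta modulates the *internal* tissue boundaries (a folding-like radial
# deformation), while the outer brain boundary is identical across subjects.
# Consequence: cortex and subcortical shapes carry individual information, the
# whole-brain mask does not.
# ---------------------------------------------------------------------------

brain_geometry <- function(spec) {
  dm <- spec$grid_shape
  ctr <- (dm + 1) / 2
  semi <- c(0.42, 0.45, 0.40) * dm
  g <- grid_coords(dm)
  dx <- (g$x - ctr[1]) / semi[1]
  dy <- (g$y - ctr[2]) / semi[2]
  dz <- (g$z - ctr[3]) / semi[3]
  rho <- sqrt(dx^2 + dy^2 + dz^2)
  safe <- pmax(rho, 1e-9)
  u1 <- dx / safe; u2 <- dy / safe; u3 <- dz / safe
  # white-matter tract direction: circumferential (radial x z-axis)
  rx <- g$x - ctr[1]; ry <- g$y - ctr[2]; rz <- g$z - ctr[3]
  rn <- pmax(sqrt(rx^2 + ry^2 + rz^2), 1e-9)
  rx <- rx / rn; ry <- ry / rn; rz <- rz / rn
  tx <- ry; ty <- -rx; tz <- rep(0, length(rx))       # cross(radial, ez)
  tn <- sqrt(tx^2 + ty^2 + tz^2)
  deg <- tn < 1e-6                                    # radial ~ parallel to z
  tx[deg] <- 0; ty[deg] <- rz[deg]; tz[deg] <- -ry[deg]  # cross(radial, ex)
  tn <- pmax(sqrt(tx^2 + ty^2 + tz^2), 1e-9)
  list(dm = dm, ctr = ctr, semi = semi, rho = rho,
       u1 = u1, u2 = u2, u3 = u3,
       tract = list(x = tx / tn, y = ty / tn, z = tz / tn),
       outer = stats::plogis((1.00 - rho) / 0.04),
       coords = g)
}

# Fixed angular basis for the folding deformation: 8 low-order real
# spherical-harmonic-like polynomials of the radial direction.
latent_basis <- function(geom, n_latent) {
  u1 <- geom$u1; u2 <- geom$u2; u3 <- geom$u3
  B <- list(
    u1^2 - u2^2,
    u2^2 - u3^2,
    sqrt(3) * u1 * u2,
    sqrt(3) * u2 * u3,
    sqrt(3) * u1 * u3,
    (3 * u3^2 - 1) / 2,
    u1 * (u1^2 - 3 * u2^2) / 2,
    u2 * (u2^2 - 3 * u3^2) / 2
  )
  B[seq_len(n_latent)]
}

# Tissue memberships for one subject. Soft (logistic) boundaries give
# sub-voxel sensitivity to the deformation at coarse grids.
tissue_fields <- function(theta, geom, spec) {
  m <- 1
  B <- latent_basis(geom, spec$n_latent)
  for (k in seq_along(theta)) m <- m + 0.12 * theta[k] * B[[k]]
  m <- pmax(m, 0.6)
  rho_eff <- geom$rho / m
  sub <- stats::plogis((0.45 - rho_eff) / 0.04)
  mid <- stats::plogis((0.80 - rho_eff) / 0.04)
  outer <- geom$outer
  wm <- pmax(mid - sub, 0)
  ctx <- pmax(outer - mid, 0)
  brain <- outer > 0.5
  lab <- array(0L, dim = geom$dm)
  stack <- cbind(as.vector(ctx), as.vector(sub), as.vector(wm))
  lab[brain] <- max.col(stack[as.vector(brain), , drop = FALSE], ties.method = "first")
  list(ctx = ctx, sub = sub, wm = wm, brain = brain, tissue = lab)
}

# Nonlinear latent readouts driving the individual activation component.
# K = min(3, n_latent) bounded, Lipschitz, nonlinear functions of the first
# three latents (the same latents that deform anatomy and modulate
# diffusivity), giving each subject a multi-dimensional functional
# fingerprint; nonlinear so that a per-vertex linear model cannot represent
# the structure-to-function mapping exactly.
latent_readout <- function(theta) {
  t1 <- tanh(theta[1])
  t2 <- if (length(theta) >= 2) tanh(theta[2]) else 0
  t3 <- if (length(theta) >= 3) tanh(theta[3]) else 0
  f <- c(t1 + 0.5 * t2 * t3,
         t2 - 0.5 * t1 * t3,
         t3 + 0.5 * t1 * t2)
  f[seq_len(min(3L, length(theta)))]
}

# ---------------------------------------------------------------------------
# Fixed activation field atlas: per map, a smooth group template G, a smooth
# nonnegative individual-effect weight field w, and an antisymmetric
# lateralization field h. Fields depend only on the grid and the map's index
# in the atlas (fixed internal seeds), never on the cohort seed: they play the
# role of a population atlas shared by all cohorts.
# ---------------------------------------------------------------------------

smooth_bumps <- function(geom, n, amp_lo, amp_hi, sig_lo, sig_hi,
                         primary_amp = NULL) {
  dm <- geom$dm
  out <- array(0, dim = dm)
  scale <- dm[1] / 24
  g <- geom$coords
  n_total <- n + !is.null(primary_amp)
  for (i in seq_len(n_total)) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    rr <- runif(1, 0.1, 0.8)
    cen <- geom$ctr + rr * geom$semi * dir
    amp <- if (i == 1L && !is.null(primary_amp)) primary_amp else runif(1, amp_lo, amp_hi)
    sig <- runif(1, sig_lo, sig_hi) * scale
    out <- out + amp * exp(-((g$x - cen[1])^2 + (g$y - cen[2])^2 +
                               (g$z - cen[3])^2) / (2 * sig^2))
  }
  out
}

activation_fields <- function(atlas, geom) {
  brain <- geom$outer > 0.5
  lr_sign <- sign(geom$ctr[1] - geom$coords$x)   # +1 left (x < center), -1 right
  lapply(seq_len(atlas$n_maps), function(t) {
    with_seed(20000L + t, {
      G <- smooth_bumps(geom, 4, -1, 1.5, 2, 3.5, primary_amp = 3)
      G <- (G + mirror_x(G)) / 2
      w <- lapply(1:3, function(k) {
        wk <- smooth_bumps(geom, 2, 0.5, 1.5, 2.5, 4)
        pmax((wk + mirror_x(wk)) / 2, 0) * brain
      })
      s <- smooth_bumps(geom, 2, 0.5, 1.5, 2.5, 4)
      s <- pmax((s + mirror_x(s)) / 2, 0)
      list(G = G * brain, w = w, h = s * lr_sign * brain)
    })
  })
}

# Sum of the K planted individual components for one map's fields.
individual_component <- function(fl, f_s) {
  out <- 0
  for (k in seq_along(f_s)) out <- out + f_s[k] * fl$w[[k]]
  out
}

# Separable Gaussian smoothing (zero-padded); used only when smooth_fwhm_mm > 0.
gaussian_smooth3d <- function(vol, fwhm_mm, voxel_size_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(2.5 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  sm_axis <- function(v, axis) {
    out <- array(0, dim = dim(v))
    n <- dim(v)[axis]
    for (j in seq(-r, r)) {
      idx_to <- seq_len(n)[(seq_len(n) + j) >= 1 & (seq_len(n) + j) <= n]
      idx_from <- idx_to + j
      w <- k[j + r + 1]
      if (axis == 1) out[idx_to, , ] <- out[idx_to, , ] + w * v[idx_from, , ]
      if (axis == 2) out[, idx_to, ] <- out[, idx_to, ] + w * v[, idx_from, ]
      if (axis == 3) out[, , idx_to] <- out[, , idx_to] + w * v[, , idx_from]
    }
    out
  }
  sm_axis(sm_axis(sm_axis(vol, 1), 2), 3)
}

#' Generate one synthetic subject
#'
#' Structural contrasts and the diffusion tensor field are deterministic
#' functions of `theta` (no randomness): theta radially deforms the internal
#' tissue boundaries and modulates white-matter axial diffusivity, t1/t2 are
#' distinct affine functions of the soft tissue memberships. Activation maps
#' add the group template, the planted individual component
#' `effect_size * w_t * f(theta)`, the lateralization term `L_s * h_t`, and
#' per-session Gaussian noise drawn from the current RNG stream (seed the RNG,
#' or use [generate_cohort()], for reproducibility).
#'
#' @param theta latent anatomy vector, length `spec$n_latent`.
#' @param lateralization per-subject lateralization coefficient L_s.
#' @param spec a [cohort_spec()].
#' @param session session number (1 or 2).
#' @param subject_id subject identifier string.
#' @param atlas a [task_atlas()] (defaults to [default_task_atlas()]).
#' @param geom,fields precomputed geometry/field caches (internal reuse).
#' @return object of class `subject_record`.
#' @export
generate_subject <- function(theta, lateralization, spec, session = 1L,
                             subject_id = "sub-001",
                             atlas = default_task_atlas(),
                             geom = NULL, fields = NULL) {
  if (length(theta) != spec$n_latent)
    stop(sprintf("theta has length %d, expected n_latent = %d",
                 length(theta), spec$n_latent))
  if (is.null(geom)) geom <- brain_geometry(spec)
  if (is.null(fields)) fields <- activation_fields(atlas, geom)
  tf <- tissue_fields(theta, geom, spec)
  t1 <- 0.70 * tf$ctx + 0.85 * tf$sub + 1.00 * tf$wm
  t2 <- 0.95 * tf$ctx + 0.70 * tf$sub + 0.45 * tf$wm

  # diffusion tensors: prolate in white matter along the template tract
  # direction, near-isotropic in gray matter, zero outside the brain.
  # Inter-individual microstructure: the first three latents modulate WM
  # axial, WM radial and gray-matter diffusivity respectively.
  lam1 <- (1.5 + 0.4 * tanh(theta[1])) * 1e-3
  lam_perp <- (0.25 + 0.05 * if (length(theta) >= 2) tanh(theta[2]) else 0) * 1e-3
  d_gm <- (0.8 + 0.1 * if (length(theta) >= 3) tanh(theta[3]) else 0) * 1e-3
  tr <- geom$tract
  dm <- spec$grid_shape
  tens <- array(0, dim = c(dm, 6L))
  iso <- (tf$ctx + tf$sub) * d_gm
  dl <- lam1 - lam_perp
  tens[, , , 1] <- tf$wm * (lam_perp + dl * tr$x^2) + iso
  tens[, , , 2] <- tf$wm * (lam_perp + dl * tr$y^2) + iso
  tens[, , , 3] <- tf$wm * (lam_perp + dl * tr$z^2) + iso
  tens[, , , 4] <- tf$wm * dl * tr$x * tr$y
  tens[, , , 5] <- tf$wm * dl * tr$x * tr$z
  tens[, , , 6] <- tf$wm * dl * tr$y * tr$z
  for (j in 1:6) tens[, , , j] <- tens[, , , j] * tf$brain

  f_s <- latent_readout(theta)
  acts <- vector("list", atlas$n_maps)
  names(acts) <- atlas$maps$map
  for (t in seq_len(atlas$n_maps)) {
    fl <- fields[[t]]
    A <- fl$G + spec$effect_size * individual_component(fl, f_s) +
      lateralization * fl$h
    if (spec$noise_sd > 0)
      A <- A + array(rnorm(prod(dm), sd = spec$noise_sd), dim = dm)
    if (spec$smooth_fwhm_mm > 0)
      A <- gaussian_smooth3d(A, spec$smooth_fwhm_mm, spec$voxel_size_mm)
    acts[[t]] <- A * tf$brain
  }

  dwi <- generate_dwi(tens, spec$dwi_protocol, b0_value = 100,
                      noise_sd = spec$dwi_noise_sd, brain_mask = tf$brain)

  structure(list(
    subject_id = subject_id, session = as.integer(session),
    theta = theta, lateralization = lateralization,
    structural = list(t1 = t1, t2 = t2),
    tensors = tens, dwi = dwi, activations = acts,
    tissue = tf$tissue, brain_mask = tf$brain,
    grid_shape = dm, voxel_size_mm = spec$voxel_size_mm),
    class = "subject_record")
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' Forward Stejskal-Tanner model: per voxel and gradient direction g,
#' `S = S0 * exp(-b * t(g) %*% D %*% g)`, with S0 = `b0_value` inside the
#' brain and 0 outside, plus additive zero-mean Gaussian noise (a documented
#' simplification of Rician noise; signals are clamped at 0).
#'
#' @param tensors 4D array (nx, ny, nz, 6): Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in
#'   mm^2/s.
#' @param protocol see [default_dwi_protocol()].
#' @param b0_value S0 value inside the brain.
#' @param noise_sd additive Gaussian noise sd.
#' @param brain_mask logical array; S0 is 0 outside it (default: all inside).
#' @return object of class `dwi_sample`: list with `b0_volumes` (list of 3D
#'   arrays), `shells` (list of `list(b_value, directions, signals)`).
#' @export
generate_dwi <- function(tensors, protocol, b0_value = 100, noise_sd = 0,
                         brain_mask = NULL) {
  if (length(protocol$shells) == 0) stop("protocol must contain at least one shell")
  if (any(vapply(protocol$shells, function(s) s$b_value, 0) < 0))
    stop("negative b-value rejected")
  dm <- dim(tensors)[1:3]
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = dm)
  S0 <- b0_value * brain_mask
  noisy <- function(S) {
    if (noise_sd > 0) S <- S + array(rnorm(prod(dm), sd = noise_sd), dim = dm)
    pmax(S, 0)
  }
  b0s <- lapply(seq_len(protocol$n_b0), function(i) noisy(S0))
  shells <- lapply(protocol$shells, function(sh) {
    sig <- lapply(seq_len(nrow(sh$directions)), function(i) {
      g <- sh$directions[i, ]
      q <- g[1]^2 * tensors[, , , 1] + g[2]^2 * tensors[, , , 2] +
        g[3]^2 * tensors[, , , 3] + 2 * g[1] * g[2] * tensors[, , , 4] +
        2 * g[1] * g[3] * tensors[, , , 5] + 2 * g[2] * g[3] * tensors[, , , 6]
      noisy(S0 * exp(-sh$b_value * q))
    })
    list(b_value = sh$b_value, directions = sh$directions, signals = sig)
  })
  structure(list(b0_volumes = b0s, shells = shells), class = "dwi_sample")
}

#' Build the shared surface template
#'
#' Vertices lie on the template mid-cortical shell (normalized radius 0.9 of
#' the undeformed brain ellipsoid), equal counts per hemisphere, with an exact
#' left-right homologue bijection obtained by mirroring across the
#' mid-sagittal plane. Coordinates are in mm relative to the volume center;
#' sampling loci are in voxel index space.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `surface_template`: list with `vertices`
#'   (data.frame: vertex_id, hemi, x_mm, y_mm, z_mm, lx, ly, lz), `homologue`
#'   (integer vector: homologue\[i\] is the mirrored partner of vertex i),
#'   `grid_shape`, `voxel_size_mm`.
#' @export
surface_template <- function(spec) {
  H <- spec$n_vertices_per_hemi
  geom <- brain_geometry(spec)
  # Fibonacci sphere, filtered to the left side with a midplane margin
  N <- 8L * H
  i <- seq_len(N)
  z <- 1 - (2 * i - 1) / N
  th <- 2 * pi * i * (2 / (1 + sqrt(5)))
  u <- cbind(sqrt(pmax(1 - z^2, 0)) * cos(th), sqrt(pmax(1 - z^2, 0)) * sin(th), z)
  left <- u[u[, 1] < -0.08, , drop = FALSE]
  if (nrow(left) < H) stop("not enough candidate vertices; increase grid or lower n_vertices_per_hemi")
  left <- left[seq_len(H), , drop = FALSE]
  right <- left; right[, 1] <- -right[, 1]
  udir <- rbind(left, right)
  loci <- sweep(0.9 * sweep(udir, 2, geom$semi, `*`), 2, geom$ctr, `+`)
  coords <- sweep(loci, 2, geom$ctr, `-`) * spec$voxel_size_mm
  vertices <- data.frame(
    vertex_id = seq_len(2L * H),
    hemi = rep(c("L", "R"), each = H),
    x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3],
    lx = loci[, 1], ly = loci[, 2], lz = loci[, 3])
  homologue <- c(seq_len(H) + H, seq_len(H))
  structure(list(vertices = vertices, homologue = homologue,
                 grid_shape = spec$grid_shape,
                 voxel_size_mm = spec$voxel_size_mm),
            class = "surface_template")
}

#' Per-subject jittered copy of a surface template
#'
#' Adds Gaussian jitter (sd `jitter_mm`) to each vertex sampling locus,
#' emulating imperfect vertex correspondence between subjects after surface
#' registration. Jitter 0 emulates perfect functional alignment. Draws from
#' the current RNG stream.
#'
#' @param template a [surface_template()].
#' @param jitter_mm jitter sd in mm.
#' @return a jittered `surface_template`.
#' @export
jitter_template <- function(template, jitter_mm) {
  if (jitter_mm <= 0) return(template)
  v <- template$vertices
  n <- nrow(v)
  sd_vox <- jitter_mm / template$voxel_size_mm
  for (cl in c("lx", "ly", "lz")) {
    ax <- match(cl, c("lx", "ly", "lz"))
    v[[cl]] <- pmin(pmax(v[[cl]] + rnorm(n, sd = sd_vox), 1),
                    template$grid_shape[ax])
  }
  template$vertices <- v
  template
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject latent anatomy vectors `theta ~ N(0, I)` and
#' lateralization coefficients `L_s ~ N(0, lateralization_sd^2)`, generates
#' every subject with [generate_subject()], and returns the shared surface
#' template and task atlas. Fully reproducible from `spec$seed`. When
#' `spec$sessions == 2`, a retest record (identical structure/diffusion data,
#' fresh activation noise) is generated for every subject.
#'
#' @param spec a [cohort_spec()].
#' @param atlas a [task_atlas()].
#' @return object of class `cohort`: list with `subjects` (session-1
#'   records), `retest` (session-2 records or NULL), `template`, `atlas`,
#'   `spec`.
#' @export
generate_cohort <- function(spec, atlas = default_task_atlas()) {
  stopifnot(inherits(spec, "cohort_spec"))
  geom <- brain_geometry(spec)
  fields <- activation_fields(atlas, geom)
  template <- surface_template(spec)
  with_seed(spec$seed, {
    thetas <- matrix(rnorm(spec$n_subjects * spec$n_latent),
                     nrow = spec$n_subjects)
    lats <- rnorm(spec$n_subjects, sd = spec$lateralization_sd)
    ids <- sprintf("sub-%03d", seq_len(spec$n_subjects))
    subjects <- vector("list", spec$n_subjects)
    retest <- if (spec$sessions == 2L) vector("list", spec$n_subjects) else NULL
    for (s in seq_len(spec$n_subjects)) {
      subjects[[s]] <- generate_subject(thetas[s, ], lats[s], spec,
                                        session = 1L, subject_id = ids[s],
                                        atlas = atlas, geom = geom,
                                        fields = fields)
      if (spec$sessions == 2L) {
        r <- subjects[[s]]
        r$session <- 2L
        # only the activation noise differs between sessions
        f_s <- latent_readout(thetas[s, ])
        for (t in seq_len(atlas$n_maps)) {
          fl <- fields[[t]]
          A <- fl$G + spec$effect_size * individual_component(fl, f_s) +
            lats[s] * fl$h
          if (spec$noise_sd > 0)
            A <- A + array(rnorm(prod(spec$grid_shape), sd = spec$noise_sd),
                           dim = spec$grid_shape)
          if (spec$smooth_fwhm_mm > 0)
            A <- gaussian_smooth3d(A, spec$smooth_fwhm_mm, spec$voxel_size_mm)
          r$activations[[t]] <- A * subjects[[s]]$brain_mask
        }
        retest[[s]] <- r
      }
    }
    names(subjects) <- ids
    if (!is.null(retest)) names(retest) <- ids
    structure(list(subjects = subjects, retest = retest, template = template,
                   atlas = atlas, spec = spec), class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects, grid %s, %d maps, %d sessions\n",
              x$spec$n_subjects, paste(x$spec$grid_shape, collapse = "x"),
              x$atlas$n_maps, x$spec$sessions))
  invisible(x)
}

#' Redraw activation noise for an existing cohort
#'
#' Returns a cohort with identical structure, diffusion data and latent
#' parameters, but activation maps regenerated with fresh per-session noise
#' under `seed` — i.e. a new acquisition session for every subject. Useful for
#' evaluation-only replications of a trained model.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param seed integer seed for the new noise draws.
#' @return a `cohort` with redrawn activations.
#' @export
regenerate_session <- function(cohort, seed) {
  spec <- cohort$spec
  atlas <- cohort$atlas
  geom <- brain_geometry(spec)
  fields <- activation_fields(atlas, geom)
  redraw <- function(rec) {
    f_s <- latent_readout(rec$theta)
    for (t in seq_len(atlas$n_maps)) {
      fl <- fields[[t]]
      A <- fl$G + spec$effect_size * individual_component(fl, f_s) +
        rec$lateralization * fl$h
      if (spec$noise_sd > 0)
        A <- A + array(rnorm(prod(spec$grid_shape), sd = spec$noise_sd),
                       dim = spec$grid_shape)
      if (spec$smooth_fwhm_mm > 0)
        A <- gaussian_smooth3d(A, spec$smooth_fwhm_mm, spec$voxel_size_mm)
      rec$activations[[t]] <- A * rec$brain_mask
    }
    rec
  }
  with_seed(as.integer(seed), {
    cohort$subjects <- lapply(cohort$subjects, redraw)
    if (!is.null(cohort$retest)) cohort$retest <- lapply(cohort$retest, redraw)
  })
  cohort
}

#' Sample a volume onto the surface template
#'
#' Trilinear interpolation of a 3D volume at each vertex sampling locus.
#' Output is ordered by vertex id and named by it.
#'
#' @param volume 3D numeric array matching the template grid.
#' @param template a [surface_template()].
#' @return named numeric vector, one value per vertex.
#' @export
sample_to_surface <- function(volume, template) {
  dm <- dim(volume)
  if (!identical(as.integer(dm), as.integer(template$grid_shape)))
    stop("volume grid does not match template grid")
  v <- template$vertices
  pts <- cbind(v$lx, v$ly, v$lz)
  bad <- which(pts[, 1] < 1 | pts[, 1] > dm[1] |
                 pts[, 2] < 1 | pts[, 2] > dm[2] |
                 pts[, 3] < 1 | pts[, 3] > dm[3])
  if (length(bad))
    stop(sprintf("vertex %d sampling locus lies outside the volume grid",
                 v$vertex_id[bad[1]]))
  out <- trilinear_at(volume, pts)
  names(out) <- v$vertex_id
  out
}
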