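#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

#' Predicted-vs-actual correlation matrix
#'
#' `C[i, j] = pearson(pred_i, actual_j)`: rows index the subject whose
#' *predicted* map is used, columns the subject whose *actual* map is used.
#' Diagonal dominance of this matrix is the signature of individual-level
#' prediction. Rows of `pred` and `actual` must carry identical subject ids
#' (rownames) in identical order.
#'
#' @param pred,actual subjects x vertices matrices with subject-id rownames.
#' @return object of class `correlation_matrix` (a plain matrix with
#'   accessors [diag_values()] / [offdiag_values()]).
#' @export
correlation_matrix <- function(pred, actual) {
  if (!identical(dim(pred), dim(actual)))
    stop("pred and actual must have identical dimensions")
  if (is.null(rownames(pred)) || is.null(rownames(actual)) ||
      !identical(rownames(pred), rownames(actual)))
    stop("pred and actual must carry identical subject-id rownames")
  C <- stats::cor(t(pred), t(actual))
  if (any(!is.finite(C))) stop("zero-variance subject vector in input")
  class(C) <- c("correlation_matrix", class(C))
  C
}

#' @rdname correlation_matrix
#' @param C a square matrix.
#' @export
diag_values <- function(C) diag(unclass(C))

#' @rdname correlation_matrix
#' @export
offdiag_values <- function(C) {
  C <- unclass(C)
  C[row(C) != col(C)]
}

#' Double-center a square matrix
#'
#' Removes row means, column means and adds back the grand mean, so that all
#' row and column means of the result are zero — the "row and column
#' normalization" that sharpens the diagonal of a correlation matrix by
#' removing mean correlation differences between subjects.
#'
#' @param C square numeric matrix.
#' @return matrix of the same shape with zero row/column means.
#' @export
double_center <- function(C) {
  C <- unclass(C)
  if (nrow(C) != ncol(C)) stop("C must be square")
  sweep(sweep(C, 1, rowMeans(C), `-`), 2, colMeans(C), `-`) + mean(C)
}

# asymptotic Kolmogorov distribution survival function, with Stephens'
# small-sample correction applied by the caller
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Kolmogorov-Smirnov test: diagonal vs extra-diagonal correlations
#'
#' Two-sample KS test between the diagonal elements of a
#' prediction-vs-actual correlation matrix and its extra-diagonal elements.
#' `D` is the supremum ECDF difference; the p-value uses the asymptotic
#' Kolmogorov distribution with effective sample size
#' `n1 * n2 / (n1 + n2)` and Stephens' correction.
#'
#' @param C square `correlation_matrix` (n >= 3).
#' @param alpha significance level recorded in the result.
#' @return list with `D`, `p`, `n_diag`, `n_offdiag`, `alpha`,
#'   `significant`.
#' @export
ks_diag_test <- function(C, alpha = 0.05) {
  C <- unclass(C)
  if (nrow(C) != ncol(C) || nrow(C) < 3L) stop("C must be square with n >= 3")
  d <- diag(C)
  o <- C[row(C) != col(C)]
  ks <- ks_two_sample(d, o)
  list(D = ks$D, p = ks$p, n_diag = length(d), n_offdiag = length(o),
       alpha = alpha, significant = ks$p < alpha)
}

ks_two_sample <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L || sd(c(x, y)) == 0) stop("degenerate samples")
  v <- c(x, y)
  step <- c(rep(1 / n1, n1), rep(-1 / n2, n2))
  o <- order(v)
  cum <- cumsum(step[o])
  # evaluate the ECDF difference only after the last of any tied values
  last_of_tie <- c(diff(v[o]) != 0, TRUE)
  D <- max(abs(cum[last_of_tie]))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  list(D = D, p = kolmogorov_sf(lambda))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha overall significance level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return corrected threshold `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Printed forms of a significance threshold
#'
#' Reports the 3-decimal rounded and truncated representations of a
#' threshold, as used in text (e.g. 0.05/47 prints as "0.001", 0.05/20
#' truncates to "0.002").
#'
#' @param threshold numeric threshold.
#' @param digits decimal places (default 3).
#' @return named character vector with elements `rounded` and `truncated`.
#' @export
threshold_print <- function(threshold, digits = 3L) {
  c(rounded = formatC(round(threshold, digits), format = "f", digits = digits),
    truncated = formatC(floor(threshold * 10^digits) / 10^digits,
                        format = "f", digits = digits))
}

#' Partial correlation given one covariate
#'
#' Residualizes `x` and `y` on (intercept, covariate) by OLS and returns the
#' Pearson correlation of the residuals. A constant covariate degenerates to
#' the plain correlation (flagged via the `"constant_covariate"` attribute).
#'
#' @param x,y,covariate numeric vectors of equal length >= 4.
#' @return partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) stop("equal lengths required")
  if (n < 4L) stop("need at least 4 observations")
  if (sd(covariate) == 0) {
    r <- pearson(x, y)
    attr(r, "constant_covariate") <- TRUE
    return(r)
  }
  rx <- residuals(lm(x ~ covariate))
  ry <- residuals(lm(y ~ covariate))
  if (sd(rx) < 1e-10 * sd(x) || sd(ry) < 1e-10 * sd(y))
    stop("zero variance after residualization")
  pearson(rx, ry)
}

#' Lateralization index near the predicted peak
#'
#' The peak is the vertex with the maximum *predicted* value over both
#' hemispheres; the neighborhood is all vertices within `radius_mm`
#' (Euclidean distance in template coordinates) of the peak on the peak's
#' hemisphere, plus their homologues on the other hemisphere. The
#' lateralization index is mean(left values) - mean(right values) over that
#' neighborhood, computed identically for predicted and actual maps using the
#' same predicted-map peak.
#'
#' @param map_pred,map_actual per-vertex value vectors (template order).
#' @param template a [surface_template()].
#' @param radius_mm neighborhood radius (default 10 mm).
#' @return list with `li_pred`, `li_actual`, `peak_vertex`, `n_neighborhood`.
#' @export
lateralization_index <- function(map_pred, map_actual, template,
                                 radius_mm = 10) {
  v <- template$vertices
  stopifnot(length(map_pred) == nrow(v), length(map_actual) == nrow(v))
  peak <- which.max(map_pred)
  coords <- cbind(v$x_mm, v$y_mm, v$z_mm)
  same_hemi <- v$hemi == v$hemi[peak]
  d <- sqrt(rowSums(sweep(coords, 2, coords[peak, ], `-`)^2))
  nb <- which(same_hemi & d <= radius_mm)
  if (length(nb) == 0L)
    stop("empty peak neighborhood; radius too small for the vertex density")
  nb_all <- union(nb, template$homologue[nb])
  left <- nb_all[v$hemi[nb_all] == "L"]
  right <- nb_all[v$hemi[nb_all] == "R"]
  li <- function(vals) mean(vals[left]) - mean(vals[right])
  list(li_pred = li(map_pred), li_actual = li(map_actual),
       peak_vertex = v$vertex_id[peak], n_neighborhood = length(nb_all))
}

#' ICC(3,1): two-way mixed, consistency, single measurement
#'
#' `ICC = (BMS - EMS) / (BMS + (k-1) * EMS)` with k = 2 sessions, where BMS
#' and EMS are the between-subject and residual mean squares of the
#' two-way (subject x session) ANOVA. Invariant to additive session shifts.
#'
#' @param session1,session2 paired per-subject values (n >= 3).
#' @return ICC estimate.
#' @export
icc31 <- function(session1, session2) {
  n <- length(session1)
  if (length(session2) != n) stop("sessions must be paired")
  if (n < 3L) stop("need at least 3 subjects")
  X <- cbind(session1, session2)
  k <- 2L
  grand <- mean(X)
  if (sum((X - grand)^2) == 0) stop("zero total variance")
  ms <- rowMeans(X)
  ss_subj <- k * sum((ms - grand)^2)
  ss_sess <- n * sum((colMeans(X) - grand)^2)
  ss_tot <- sum((X - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_sess
  bms <- ss_subj / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems)
}

#' Self-vs-other correlation difference
#'
#' Mean of the diagonal (self-correlations) minus mean of the extra-diagonal
#' elements (other-correlations) of a prediction-vs-actual correlation
#' matrix. Positive values indicate individual-level prediction.
#'
#' @param C square matrix (n >= 2).
#' @return scalar delta.
#' @export
self_vs_other <- function(C) {
  C <- unclass(C)
  if (nrow(C) != ncol(C) || nrow(C) < 2L) stop("C must be square with n >= 2")
  mean(diag(C)) - mean(C[row(C) != col(C)])
}

# weighted gamma MLE via Newton on the shape parameter; `min_mean`
# constrains the component mean (shape * scale) away from zero — the gamma
# components model genuine activation, not the tails of the null, and the
# constraint keeps the mixture identifiable when the data are close to pure
# noise. On the boundary the constrained optimum over the shape is found
# numerically, so the EM step never decreases the likelihood.
gamma_wmle <- function(x, w, min_mean = 0) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  mlog <- sum(w * log(x)) / sw
  s <- log(mx) - mlog
  s <- max(s, 1e-10)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-12 * a) { a <- a_new; break }
    a <- a_new
  }
  if (mx < min_mean) {
    ll_boundary <- function(alpha) {
      sc <- min_mean / alpha
      alpha * (mlog - log(sc)) - mlog - mx / sc - lgamma(alpha)
    }
    a <- stats::optimize(ll_boundary, c(0.05, 200), maximum = TRUE)$maximum
    return(list(shape = a, scale = min_mean / a))
  }
  list(shape = a, scale = mx / a)
}

#' Fit a Gaussian plus two-gamma mixture to z-values
#'
#' EM fit of `pi0 * N(mu, sigma^2) + pi_pos * Gamma(z; shape, scale) +
#' pi_neg * Gamma(-z; shape, scale)`: a central null Gaussian plus gamma
#' components supported on the positive and negative sides (responsibilities
#' are zero on the wrong-sign side). Used to derive activation thresholds
#' from the gamma medians ([mixture_thresholds()]). The gamma components are
#' constrained to mean at least 2.5 times the null sd — they model genuine
#' activation, not the null's tails, and the constraint keeps the mixture
#' identifiable on near-null data. Initialization: mu = 0,
#' sigma = sd of the central 80% of the data, gammas moment-matched to the
#' tails beyond one sd, weights (0.8, 0.1, 0.1). Converges when the relative
#' log-likelihood change is below `tol` or after `max_iter` iterations; the
#' log-likelihood is non-decreasing across iterations. If one sign has no
#' data the fit degenerates to a two-component model (flagged).
#'
#' @param z numeric vector (n >= 100 recommended).
#' @param max_iter,tol EM controls.
#' @return object of class `mixture_fit`: list with `weights` (pi0, pi_pos,
#'   pi_neg), `mu`, `sigma`, `gamma_pos`, `gamma_neg` (shape/scale or NULL),
#'   `loglik`, `loglik_trace`, `n_iter`, `degenerate`.
#' @export
fit_ggm_mixture <- function(z, max_iter = 500L, tol = 1e-8) {
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 10L) stop("too few observations")
  pos <- z > 0
  neg <- z < 0
  degenerate <- !any(pos) || !any(neg)

  qs <- stats::quantile(z, c(0.1, 0.9))
  central <- z[z >= qs[1] & z <= qs[2]]
  mu <- 0
  sigma <- max(sd(central), 1e-3)
  mm_gamma <- function(x) {
    if (length(x) < 5L || sd(x) == 0) return(list(shape = 2, scale = 1))
    m <- mean(x); v <- var(x)
    list(shape = max(m^2 / v, 0.1), scale = max(v / m, 1e-6))
  }
  gp <- if (any(pos)) mm_gamma(z[z > sigma]) else NULL
  gn <- if (any(neg)) mm_gamma(-z[z < -sigma]) else NULL
  w <- if (degenerate) {
    if (any(pos)) c(0.9, 0.1, 0) else c(0.9, 0, 0.1)
  } else c(0.8, 0.1, 0.1)

  dens <- function() {
    d0 <- w[1] * dnorm(z, mu, sigma)
    dp <- if (!is.null(gp)) w[2] * ifelse(pos, dgamma(z, shape = gp$shape, scale = gp$scale), 0) else 0
    dn <- if (!is.null(gn)) w[3] * ifelse(neg, dgamma(-z, shape = gn$shape, scale = gn$scale), 0) else 0
    cbind(d0, dp, dn)
  }
  ll_trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- dens()
    tot <- pmax(rowSums(D), 1e-300)
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    if (iter >= max_iter) break
    ll_old <- ll
    R <- D / tot
    w <- pmax(unname(colMeans(R)), 0)
    w <- w / sum(w)
    s0 <- sum(R[, 1])
    mu <- sum(R[, 1] * z) / s0
    sigma <- sqrt(max(sum(R[, 1] * (z - mu)^2) / s0, 1e-6))
    if (!is.null(gp) && sum(R[pos, 2]) > 1e-8)
      gp <- gamma_wmle(z[pos], R[pos, 2], min_mean = 2.5 * sigma)
    if (!is.null(gn) && sum(R[neg, 3]) > 1e-8)
      gn <- gamma_wmle(-z[neg], R[neg, 3], min_mean = 2.5 * sigma)
  }
  structure(list(weights = w, mu = mu, sigma = sigma,
                 gamma_pos = gp, gamma_neg = gn,
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, n_iter = iter,
                 degenerate = degenerate), class = "mixture_fit")
}

#' Activation thresholds from the mixture gamma medians
#'
#' Positive threshold = median of the positive gamma component; negative
#' threshold = minus the median of the negative gamma component. A side
#' absent from a degenerate fit yields NA on that side.
#'
#' @param fit a `mixture_fit`.
#' @return named numeric vector `c(negative, positive)`.
#' @export
mixture_thresholds <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  pos <- if (!is.null(fit$gamma_pos))
    qgamma(0.5, shape = fit$gamma_pos$shape, scale = fit$gamma_pos$scale)
  else NA_real_
  neg <- if (!is.null(fit$gamma_neg))
    -qgamma(0.5, shape = fit$gamma_neg$shape, scale = fit$gamma_neg$scale)
  else NA_real_
  c(negative = neg, positive = pos)
}
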