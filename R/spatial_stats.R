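#' Pearson correlation between two regional maps
#'
#' Correlation over regions of two per-region value vectors sharing the
#' same ordered region set. Regions where either value is not finite are
#' dropped pairwise; the number of complete pairs actually used is
#' reported.
#'
#' @param map_a,map_b Numeric vectors of per-region values (same length;
#'   if both are named the names must agree).
#' @return List with `r` and `n_used`.
#' @export
pearson_map_correlation <- function(map_a, map_b) {
  if (length(map_a) != length(map_b))
    stop("maps have different lengths (", length(map_a), " vs ",
         length(map_b), ")")
  if (!is.null(names(map_a)) && !is.null(names(map_b)) &&
      !identical(names(map_a), names(map_b)))
    stop("maps must share the same ordered region set")
  ok <- is.finite(map_a) & is.finite(map_b)
  if (sum(ok) < 3L)
    stop("need at least 3 regions with both values finite (got ",
         sum(ok), ")")
  a <- map_a[ok]; b <- map_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in one of the maps")
  list(r = stats::cor(a, b), n_used = sum(ok))
}

#' Draw a uniform random 3-D rotation
#'
#' Haar-uniform over SO(3): a Gaussian 3x3 matrix is orthonormalized by
#' QR, column signs are fixed by the sign of R's diagonal, and one
#' column is flipped if the determinant is -1. Uses the current RNG
#' state.
#'
#' @return A 3x3 rotation matrix Q with Q'Q = I and det Q = +1.
#' @export
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Spin permutation test for the correlation of two regional maps
#'
#' Builds a spatial null for the Pearson correlation between two
#' parcellated cortical maps by randomly rotating the parcel centroids
#' on the sphere. For each permutation a fresh Haar-uniform rotation is
#' applied to all centroids and each region is reassigned the value of
#' the region whose original centroid is nearest (Euclidean; equivalent
#' to the largest dot product on the unit sphere) to its rotated
#' centroid — sampling with replacement is allowed, as in parcel-level
#' spin nulls. Only `map_a` is permuted. The two-sided p-value is
#' \deqn{p = \frac{1 + \#\{|r_{perm}| \ge |r_{obs}|\}}{n_{perm} + 1},}
#' which is never 0 and never below 1/(n_perm + 1).
#'
#' @param map_a,map_b Per-region value vectors (same ordered regions).
#' @param centroids Numeric matrix, one unit 3-vector row per region
#'   (for bilateral maps, single-hemisphere centroids).
#' @param n_perm Number of spins (>= 99).
#' @param seed Integer seed.
#' @return A `map_correlation` object: list with `r`, `n_regions`,
#'   `p_spin`, `n_perm`, `null_distribution`, `seed`.
#' @export
spin_permutation_p <- function(map_a, map_b, centroids, n_perm = 999L,
                               seed = 1L) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 3L) stop("centroids must be an R x 3 matrix")
  if (length(map_a) != nrow(centroids) || length(map_b) != nrow(centroids))
    stop("maps and centroids must cover the same regions")
  if (n_perm < 99L) stop("n_perm must be >= 99")
  nrm <- sqrt(rowSums(centroids^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("centroids must have unit norm")
  if (anyDuplicated(round(centroids, 12L)))
    stop("duplicate centroids")
  ok <- is.finite(map_a) & is.finite(map_b)
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " region(s) with undefined values")
    map_a <- map_a[ok]; map_b <- map_b[ok]
    centroids <- centroids[ok, , drop = FALSE]
  }
  if (length(map_a) < 3L) stop("fewer than 3 usable regions")
  r_obs <- stats::cor(map_a, map_b)
  null_r <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      Q <- random_rotation()
      rot <- centroids %*% t(Q)
      assign <- max.col(tcrossprod(rot, centroids), ties.method = "first")
      ap <- map_a[assign]
      # a rotation can collapse the assignment onto one region; a
      # constant permuted map carries no correlation
      if (stats::var(ap) == 0) return(0)
      stats::cor(ap, map_b)
    }, numeric(1L))
  })
  p <- (1 + sum(abs(null_r) >= abs(r_obs))) / (n_perm + 1)
  structure(list(r = r_obs, n_regions = length(map_a), p_spin = p,
                 n_perm = as.integer(n_perm), null_distribution = null_r,
                 seed = as.integer(seed)),
            class = "map_correlation")
}

#' @export
print.map_correlation <- function(x, ...) {
  cat(sprintf("map correlation: r = %.3f over %d regions, p_spin = %.4g (%d spins)\n",
              x$r, x$n_regions, x$p_spin, x$n_perm))
  invisible(x)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' Tests whether two Pearson correlations, estimated on n1 and n2
#' observations (here, regions), differ:
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'   {\sqrt{1/(n_1 - 3) + 1/(n_2 - 3)}},}
#' with a two-sided standard normal p-value.
#'
#' @param r1,r2 Correlations with |r| < 1.
#' @param n1,n2 Observation counts (>= 4).
#' @return List with `z` and `p`.
#' @export
compare_correlations_fisher <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1 (the z-transform is infinite at |r| = 1)")
  if (n1 < 4L || n2 < 4L) stop("need n >= 4 in each sample")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
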