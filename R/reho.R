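#' 4-D volume time series
#'
#' A 4-D intensity grid (x, y, z, t) with a 3-D analysis mask. The time
#' dimension must have length >= 3 so that within-voxel ranks (and the
#' Kendall's W denominator T^3 - T) are meaningful; data must be finite
#' inside the mask.
#'
#' @param data 4-D numeric array.
#' @param mask 3-D logical array matching the spatial dimensions.
#' @param voxel_dims Voxel dimensions in mm (metadata only; all
#'   computation is in voxel space).
#' @return An object of class `volume_time_series`.
#' @export
volume_time_series <- function(data, mask = NULL, voxel_dims = c(1, 1, 1)) {
  if (!(is.array(data) && length(dim(data)) == 4L))
    stop("`data` must be a 4-D array (x, y, z, t)")
  d <- dim(data)
  if (d[4L] < 3L) stop("need at least 3 time points (got ", d[4L], ")")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mask <- array(as.logical(mask), d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("mask shape does not match data")
  if (!any(mask)) stop("mask must contain at least one voxel")
  if (any(voxel_dims <= 0)) stop("voxel_dims must be positive")
  flat <- matrix(data, prod(d[1:3]), d[4L])
  if (!all(is.finite(flat[which(mask), ])))
    stop("data must be finite inside the mask")
  structure(list(data = data, mask = mask, voxel_dims = as.numeric(voxel_dims)),
            class = "volume_time_series")
}

#' Kendall's coefficient of concordance (KCC)
#'
#' Agreement of K rank orderings over T time points, the statistic
#' underlying voxelwise regional homogeneity. Each series is converted
#' to midranks over time; with rank sums \eqn{R_t} across series,
#' \deqn{W = \frac{12 \sum_t (R_t - K(T+1)/2)^2}
#'            {K^2 (T^3 - T) - K \sum_k C_k},}
#' where \eqn{C_k = \sum_g (g^3 - g)} over tied groups of series k is
#' the standard tie correction. W lies in \[0, 1\]: 1 for identical
#' orderings, near 1/K under independence. Returns `NaN` when the
#' denominator is 0 (all series fully tied).
#'
#' @param x Numeric matrix, one row per series (K >= 2), one column per
#'   time point (T >= 3).
#' @return Kendall's W.
#' @export
kendalls_w <- function(x) {
  x <- as.matrix(x)
  K <- nrow(x); Tn <- ncol(x)
  if (K < 2L) stop("need at least 2 series (got ", K, ")")
  if (Tn < 3L) stop("need at least 3 time points (got ", Tn, ")")
  if (!all(is.finite(x))) stop("series must be finite")
  ranks <- t(apply(x, 1L, rank))
  Rt <- colSums(ranks)
  S <- sum((Rt - K * (Tn + 1) / 2)^2)
  C <- sum(apply(x, 1L, tie_correction))
  denom <- K^2 * (Tn^3 - Tn) - K * C
  if (denom <= 0) return(NaN)
  12 * S / denom
}

#' Regional homogeneity map
#'
#' Computes, for every in-mask voxel, Kendall's W over the in-mask voxel
#' time series of its 3x3x3 neighborhood (27 voxels including the
#' center; fewer at mask edges). Constant (fully tied) series carry no
#' rank information and make the tie-corrected denominator degenerate,
#' so they are excluded from the neighborhood count K before W is
#' computed. Voxels whose K falls below `min_neighbors` (floor 2) get
#' `NaN`, as do all out-of-mask voxels.
#'
#' The whole map is computed in one vectorized pass: per-voxel time
#' ranks and tie corrections are computed once, then neighborhood rank
#' sums, counts and tie-correction totals are accumulated by 27 shifted
#' array additions.
#'
#' @param vts A [volume_time_series].
#' @param min_neighbors Minimum number of contributing series per voxel
#'   (default 2).
#' @return An object of class `reho_map` with fields `values` (3-D grid
#'   of W in \[0, 1\], `NaN` where undefined) and `neighbor_counts`
#'   (3-D integer grid of K used per voxel).
#' @export
reho_map <- function(vts, min_neighbors = 2L) {
  stopifnot(inherits(vts, "volume_time_series"))
  d <- dim(vts$data)
  nx <- d[1L]; ny <- d[2L]; nz <- d[3L]; Tn <- d[4L]
  nvox <- nx * ny * nz
  mask <- vts$mask
  X <- matrix(vts$data, nvox, Tn)
  inmask <- which(mask)

  rng <- apply(X[inmask, , drop = FALSE], 1L, function(v) v[which.max(v)] - v[which.min(v)])
  keep <- inmask[rng > 0]          # drop constant series
  Xk <- X[keep, , drop = FALSE]
  ranks <- t(apply(Xk, 1L, rank))
  Cv <- apply(Xk, 1L, tie_correction)

  R4 <- array(0, c(nx, ny, nz, Tn))
  R4flat <- matrix(0, nvox, Tn)
  R4flat[keep, ] <- ranks
  R4 <- array(R4flat, c(nx, ny, nz, Tn))
  I3 <- array(0, c(nx, ny, nz)); I3[keep] <- 1
  C3 <- array(0, c(nx, ny, nz)); C3[keep] <- Cv

  SumR <- array(0, c(nx, ny, nz, Tn))
  K3 <- array(0, c(nx, ny, nz))
  Cs <- array(0, c(nx, ny, nz))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xt <- max(1L, 1L + dx):min(nx, nx + dx); xs <- xt - dx
    yt <- max(1L, 1L + dy):min(ny, ny + dy); ys <- yt - dy
    zt <- max(1L, 1L + dz):min(nz, nz + dz); zs <- zt - dz
    SumR[xt, yt, zt, ] <- SumR[xt, yt, zt, , drop = FALSE] +
      R4[xs, ys, zs, , drop = FALSE]
    K3[xt, yt, zt] <- K3[xt, yt, zt] + I3[xs, ys, zs]
    Cs[xt, yt, zt] <- Cs[xt, yt, zt] + C3[xs, ys, zs]
  }

  Kv <- as.vector(K3)
  M <- matrix(SumR, nvox, Tn) - Kv * ((Tn + 1) / 2)
  S <- rowSums(M * M)
  denom <- Kv^2 * (Tn^3 - Tn) - Kv * as.vector(Cs)
  W <- 12 * S / denom
  W[denom <= 0] <- NaN
  W[Kv < max(min_neighbors, 2L)] <- NaN
  W[!as.vector(mask)] <- NaN
  W <- pmin(pmax(W, 0), 1)

  counts <- as.integer(round(Kv))
  counts[!as.vector(mask)] <- NA_integer_
  structure(list(values = array(W, c(nx, ny, nz)),
                 neighbor_counts = array(counts, c(nx, ny, nz))),
            class = "reho_map")
}

#' @export
print.reho_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat("reho_map:", paste(dim(x$values), collapse = "x"), "grid,",
      length(v), "defined voxels, mean W =", signif(mean(v), 4), "\n")
  invisible(x)
}

#' Mean of a voxel map within each atlas region
#'
#' Per region, the arithmetic mean over its voxels with defined
#' (non-NaN) values; background (label 0) never contributes. A region
#' with no defined voxel yields `NaN` with a warning.
#'
#' @param map3d 3-D numeric array (e.g. `reho_map$values`).
#' @param atlas A [parcellation_atlas].
#' @return Named numeric vector, one mean per region, named
#'   `"<name>_<hemisphere>"`, in atlas region order.
#' @export
extract_regional_means <- function(map3d, atlas) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  if (inherits(map3d, "reho_map")) map3d <- map3d$values
  if (!identical(dim(map3d), dim(atlas$labels)))
    stop("map shape ", paste(dim(map3d), collapse = "x"),
         " does not match atlas shape ",
         paste(dim(atlas$labels), collapse = "x"))
  reg <- atlas$regions
  out <- vapply(seq_len(nrow(reg)), function(k) {
    v <- map3d[atlas$labels == reg$id[k]]
    v <- v[!is.na(v)]
    if (!length(v)) return(NaN)
    mean(v)
  }, numeric(1L))
  names(out) <- paste(reg$name, reg$hemisphere, sep = "_")
  und <- which(is.nan(out))
  if (length(und))
    warning("no defined voxels in region(s): ",
            paste(names(out)[und], collapse = ", "))
  out
}

#' Average left and right hemisphere measures
#'
#' Collapses a per-hemisphere regional table to bilateral regions:
#' each output column is (L + R) / 2 per subject, pairing columns
#' `"<name>_L"` / `"<name>_R"`. If either side is missing (NaN/NA) for a
#' subject the bilateral value is NaN.
#'
#' @param table A [regional_table] whose columns carry `_L` / `_R`
#'   hemisphere suffixes.
#' @return A [regional_table] over bilateral regions.
#' @export
average_hemispheres <- function(table) {
  stopifnot(inherits(table, "regional_table"))
  cols <- table$region_ids
  hemi <- sub("^.*_([LR])$", "\\1", cols)
  base <- sub("_[LR]$", "", cols)
  bad <- which(!grepl("_[LR]$", cols))
  if (length(bad))
    stop("columns without an _L/_R hemisphere suffix: ",
         paste(cols[bad], collapse = ", "))
  names_u <- unique(base)
  orphan <- names_u[vapply(names_u, function(nm)
    !all(c("L", "R") %in% hemi[base == nm]), logical(1L))]
  if (length(orphan))
    stop("unpaired region name(s): ", paste(orphan, collapse = ", "))
  m <- sapply(names_u, function(nm) {
    l <- table$measures[, which(base == nm & hemi == "L")[1L]]
    r <- table$measures[, which(base == nm & hemi == "R")[1L]]
    out <- (l + r) / 2
    out[!is.finite(l) | !is.finite(r)] <- NaN
    out
  })
  m <- matrix(m, nrow = nrow(table$measures),
              dimnames = list(NULL, names_u))
  regional_table(table$subjects, m, measure_name = table$measure_name)
}
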