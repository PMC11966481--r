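#' Parcellation atlas
#'
#' Couples a 3-D integer label volume (0 = background) with a region
#' table giving, per region: integer id, bilateral name, hemisphere
#' (`"L"`/`"R"`) and a unit-sphere centroid. The centroid is the mean
#' voxel coordinate relative to the volume center, projected to the unit
#' sphere; spin permutations rotate these centroids.
#'
#' @param labels 3-D integer array of region labels.
#' @param regions Data frame with columns `id`, `name`, `hemisphere`,
#'   `cx`, `cy`, `cz`.
#' @return An object of class `parcellation_atlas`.
#' @export
parcellation_atlas <- function(labels, regions) {
  if (!(is.array(labels) && length(dim(labels)) == 3L))
    stop("`labels` must be a 3-D array")
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  need <- c("id", "name", "hemisphere", "cx", "cy", "cz")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stop("region table is missing columns: ", paste(miss, collapse = ", "))
  present <- sort(unique(as.integer(labels[labels > 0])))
  if (!setequal(present, regions$id))
    stop("labels present in the grid and region ids disagree: ",
         "grid-only {", paste(setdiff(present, regions$id), collapse = ","),
         "}, table-only {", paste(setdiff(regions$id, present), collapse = ","), "}")
  nrm <- sqrt(regions$cx^2 + regions$cy^2 + regions$cz^2)
  if (any(abs(nrm - 1) > 1e-9))
    stop("region centroids must have unit norm")
  if (!all(regions$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  structure(list(labels = labels, regions = regions),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat("parcellation_atlas:", nrow(x$regions), "regions on a",
      paste(dim(x$labels), collapse = "x"), "grid\n")
  invisible(x)
}

#' Build a toy bilateral parcellation
#'
#' Lays out `n_region_pairs` rectangular blocks on a (y, z) grid in the
#' left half of the volume and mirrors them across the mid-sagittal
#' plane, yielding `2 * n_region_pairs` regions whose left/right
#' centroids are mirror images. Regions are separated from each other
#' and from the midline by one-voxel background gaps, so 3x3x3
#' neighborhoods never straddle two regions (as cortical parcels are
#' separated by white matter and CSF in masked real data); the (y, z)
#' layout spreads the unit-sphere centroids in two dimensions, which
#' spin permutations need. The seed shuffles which block gets which
#' region id.
#'
#' @param grid_shape Integer vector of length 3, the volume dimensions.
#' @param n_region_pairs Number of bilateral region pairs.
#' @param seed Integer seed.
#' @return A [parcellation_atlas].
#' @export
make_toy_atlas <- function(grid_shape, n_region_pairs, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  n_region_pairs <- as.integer(n_region_pairs)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            n_region_pairs >= 1L)
  if (prod(grid_shape) < 8L * n_region_pairs)
    stop("grid too small: ", prod(grid_shape), " voxels cannot hold ",
         n_region_pairs, " region pairs of >= 4 voxels each")
  nx <- grid_shape[1L]; ny <- grid_shape[2L]; nz <- grid_shape[3L]
  width <- nx %/% 2L - 1L                       # midline gap
  gz <- as.integer(ceiling(sqrt(n_region_pairs)))
  gy <- as.integer(ceiling(n_region_pairs / gz))
  ty <- (ny - (gy - 1L)) %/% gy                 # block extents incl. gaps
  tz <- (nz - (gz - 1L)) %/% gz
  if (width < 1L || ty < 1L || tz < 1L || width * ty * tz < 4L)
    stop("grid too small: cannot fit ", n_region_pairs,
         " separated region pairs of >= 4 voxels into a ",
         paste(grid_shape, collapse = "x"), " grid")
  order_map <- withr::with_seed(as.integer(seed), sample.int(n_region_pairs))

  labels <- array(0L, dim = grid_shape)
  for (block in seq_len(n_region_pairs)) {
    pair <- order_map[block]
    iy <- (block - 1L) %% gy
    iz <- (block - 1L) %/% gy
    yr <- (iy * (ty + 1L) + 1L):(iy * (ty + 1L) + ty)
    zr <- (iz * (tz + 1L) + 1L):(iz * (tz + 1L) + tz)
    labels[1:width, yr, zr] <- 2L * pair - 1L                # left
    labels[(nx + 1L - width):nx, yr, zr] <- 2L * pair        # right
  }

  ctr <- (grid_shape + 1) / 2
  regions <- do.call(rbind, lapply(seq_len(2L * n_region_pairs), function(id) {
    vox <- which(labels == id, arr.ind = TRUE)
    cen <- colMeans(vox) - ctr
    cen <- cen / sqrt(sum(cen^2))
    data.frame(id = id,
               name = sprintf("region_%02d", (id + 1L) %/% 2L),
               hemisphere = if (id %% 2L == 1L) "L" else "R",
               cx = cen[1L], cy = cen[2L], cz = cen[3L],
               stringsAsFactors = FALSE)
  }))
  # exact mirror symmetry of paired centroids (guard against float drift)
  for (p in seq_len(n_region_pairs)) {
    l <- 2L * p - 1L
    regions[regions$id == l + 1L, c("cx", "cy", "cz")] <-
      regions[regions$id == l, c("cx", "cy", "cz")] * c(-1, 1, 1)
  }
  parcellation_atlas(labels, regions)
}

#' Write / read an atlas as NIfTI + TSV
#'
#' The label grid is stored as NIfTI-1 and the region table as TSV with
#' columns `id`, `name` (named `region` on disk), `hemisphere`, `cx`,
#' `cy`, `cz`.
#'
#' @param atlas A [parcellation_atlas].
#' @param nifti_path Path for the label volume (`.nii` / `.nii.gz`).
#' @param regions_path Path for the region TSV.
#' @return `write_atlas` returns the paths invisibly; `read_atlas`
#'   returns a [parcellation_atlas].
#' @export
write_atlas <- function(atlas, nifti_path, regions_path) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  RNifti::writeNifti(atlas$labels, nifti_path, datatype = "int16")
  out <- atlas$regions
  names(out)[names(out) == "name"] <- "region"
  utils::write.table(out, regions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(nifti_path, regions_path))
}

#' @rdname write_atlas
#' @export
read_atlas <- function(nifti_path, regions_path) {
  img <- RNifti::readNifti(nifti_path)
  labels <- array(as.integer(round(as.array(img))), dim = dim(img))
  regions <- utils::read.delim(regions_path, stringsAsFactors = FALSE)
  names(regions)[names(regions) == "region"] <- "name"
  parcellation_atlas(labels, regions)
}
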