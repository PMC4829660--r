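#' Slice-wise mean filter
#'
#' Replaces every pixel of every z-slice by the mean over a disk of the given
#' radius (pixels whose centre offset satisfies dx^2 + dy^2 <= r^2; at the
#' default r = 1.5 the disk covers 9 pixels). Used to reduce noise before
#' local-maxima identification. Border pixels average over the in-bounds part
#' of the disk, so a constant stack is left unchanged.
#'
#' @param stack a \code{\link{voxel_stack}}.
#' @param radius disk radius in pixels (> 0), default 1.5.
#' @return A filtered \code{\link{voxel_stack}}.
#' @export
mean_filter_slices <- function(stack, radius = 1.5) {
  stopifnot(inherits(stack, "voxel_stack"))
  stop_if_not_positive(radius, "radius")
  d <- dim(stack$data)
  out <- cpp_mean_filter_disk(as.numeric(stack$data), as.integer(d), radius)
  as_stack_like(stack, array(out, dim = d))
}

#' Normalize a stack to the unit interval
#'
#' Affine rescaling of the whole stack so min maps to 0 and max to 1.
#'
#' @param stack a \code{\link{voxel_stack}}.
#' @return A normalized \code{\link{voxel_stack}}.
#' @export
normalize_stack <- function(stack) {
  stopifnot(inherits(stack, "voxel_stack"))
  rng <- range(stack$data)
  if (diff(rng) == 0)
    stop("stack has zero dynamic range; cannot normalize", call. = FALSE)
  as_stack_like(stack, (stack$data - rng[1]) / diff(rng))
}

#' Find slice-wise local maxima
#'
#' Identifies, independently in every z-slice, local intensity maxima whose
#' prominence over the surrounding region exceeds \code{noise_tolerance}, and
#' marks each with a single voxel (deterministic tie-break on plateaus).
#' Mirrors the ImageJ "Find (Stack) Maxima" behaviour used by focus-counting
#' macros: candidate maxima are processed in decreasing intensity and a
#' candidate whose surrounding region within the tolerance touches the
#' territory of a higher maximum is merged into it. Maxima must additionally
#' rise more than the tolerance above the stack minimum, so object-free
#' noise slices contribute no marks.
#'
#' @param stack a \code{\link{voxel_stack}}, ideally normalized to [0, 1].
#' @param noise_tolerance required prominence, on the intensity scale of the
#'   stack (default 0.1 of the normalized range).
#' @return A \code{\link{voxel_stack}} whose data is a 0/1 maxima map.
#' @export
find_stack_maxima <- function(stack, noise_tolerance = 0.1) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (noise_tolerance < 0)
    stop("`noise_tolerance` must be >= 0", call. = FALSE)
  d <- dim(stack$data)
  out <- cpp_find_maxima_2d(as.numeric(stack$data), as.integer(d),
                            noise_tolerance,
                            min(stack$data) + noise_tolerance)
  as_stack_like(stack, array(as.numeric(out), dim = d))
}

#' Reconstruct artificial focal objects around marked maxima
#'
#' Convolves a binary maxima map slice-wise with a normalized Gaussian kernel
#' so that every marked voxel becomes a small synthetic blob; blobs from the
#' same focus in adjacent slices merge into one 3D object at the counting
#' stage.
#'
#' @param maxima_map a binary \code{\link{voxel_stack}} from
#'   \code{\link{find_stack_maxima}}.
#' @param gaussian_radius Gaussian sigma in pixels (default 1.0).
#' @return A \code{\link{voxel_stack}} of blob intensities.
#' @export
reconstruct_focal_objects <- function(maxima_map, gaussian_radius = 1.0) {
  stopifnot(inherits(maxima_map, "voxel_stack"))
  vals <- unique(as.vector(maxima_map$data))
  if (!all(vals %in% c(0, 1)))
    stop("`maxima_map` must be binary", call. = FALSE)
  d <- dim(maxima_map$data)
  out <- cpp_gaussian_blur(as.numeric(maxima_map$data), as.integer(d),
                           gaussian_radius, gaussian_radius, 0)
  as_stack_like(maxima_map, array(out, dim = d))
}

# peak response of a single interior marked voxel after the slice-wise
# normalized Gaussian reconstruction
single_marker_peak <- function(sigma) {
  hw <- max(1, ceiling(3 * sigma))
  w <- exp(-0.5 * (-hw:hw)^2 / sigma^2)
  1 / sum(w)^2
}

#' Count 3D objects above an intensity threshold
#'
#' Labels 26-connected components of voxels strictly above
#' \code{intensity_threshold}, discards components smaller than
#' \code{min_voxels}, and returns the count with the label map.
#'
#' @param stack a \code{\link{voxel_stack}}.
#' @param intensity_threshold scalar threshold (within the stack range).
#' @param min_voxels minimum object size in voxels (>= 1), default 4.
#' @param protocol tag recorded in the result.
#' @return An object of class \code{foci_count}: list with \code{count},
#'   \code{labels} (3D integer array), \code{voxel_volumes},
#'   \code{protocol}, \code{parameters}.
#' @export
count_objects_3d <- function(stack, intensity_threshold, min_voxels = 4,
                             protocol = "generic") {
  stopifnot(inherits(stack, "voxel_stack"))
  if (min_voxels < 1) stop("`min_voxels` must be >= 1", call. = FALSE)
  d <- dim(stack$data)
  mask <- as.integer(stack$data > intensity_threshold)
  lab <- cpp_label_components(mask, as.integer(d), 26L)
  lab <- prune_small_objects(lab, min_voxels)
  new_foci_count(array(lab, dim = d), protocol,
                 list(intensity_threshold = intensity_threshold,
                      min_voxels = min_voxels))
}

prune_small_objects <- function(lab, min_voxels) {
  if (!any(lab > 0)) return(as.integer(lab))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- integer(length(lab))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

new_foci_count <- function(labels, protocol, parameters) {
  n <- max(labels)
  structure(
    list(count = as.integer(n),
         labels = labels,
         voxel_volumes = if (n > 0) as.integer(tabulate(labels, nbins = n))
                         else integer(0),
         protocol = protocol,
         parameters = parameters),
    class = "foci_count")
}

#' @export
print.foci_count <- function(x, ...) {
  cat(sprintf("<foci_count> %d objects (%s protocol)\n", x$count, x$protocol))
  invisible(x)
}

#' Triangle (Zack) threshold of an intensity histogram
#'
#' Geometric construction for automatic background removal: a line is drawn
#' from the histogram peak to the far end of the longer tail, and the
#' threshold is placed at the bin whose perpendicular distance to that line
#' is maximal. Deterministic: ties resolve to the bin closest to the peak.
#'
#' @param counts histogram bin counts (>= 2 nonempty bins).
#' @param mids bin midpoints on the intensity scale (default bin indices).
#' @return The threshold intensity (a bin midpoint).
#' @export
triangle_threshold <- function(counts, mids = seq_along(counts)) {
  stopifnot(length(counts) == length(mids), !is.unsorted(mids))
  nonempty <- which(counts > 0)
  if (length(nonempty) < 2)
    stop("histogram needs at least 2 nonempty bins", call. = FALSE)
  p <- which.max(counts)
  lo <- nonempty[1]
  hi <- nonempty[length(nonempty)]
  e <- if ((hi - p) >= (p - lo)) hi else lo  # longer-tail side
  if (e == p) e <- if (hi > p) hi else lo
  idx <- if (e > p) p:e else e:p
  # perpendicular distance from (i, counts[i]) to the peak--tail line
  x1 <- p; y1 <- counts[p]; x2 <- e; y2 <- counts[e]
  dist <- abs((y2 - y1) * idx - (x2 - x1) * counts[idx] +
                x2 * y1 - y2 * x1) / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  best <- idx[which.max(dist)]
  mids[best]
}

#' Triangle threshold of a stack's voxel intensities
#' @param stack a \code{\link{voxel_stack}}.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold intensity.
#' @export
stack_threshold_triangle <- function(stack, n_bins = 256) {
  stopifnot(inherits(stack, "voxel_stack"))
  rng <- range(stack$data)
  if (diff(rng) == 0)
    stop("stack has zero dynamic range", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(as.vector(stack$data), breaks,
                      rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  triangle_threshold(counts, mids)
}

#' Separate touching objects by marker-controlled watershed
#'
#' Re-splits every labelled component using a 3D marker-controlled watershed
#' on the inverted smoothed intensity. Markers are h-maxima of the smoothed
#' intensity inside the component (domes of relative height at least
#' \code{h_rel} of the smoothed dynamic range), so a single convex blob is
#' never split while fused blobs with distinct summits are. The operation
#' never merges objects: flooding is confined to each input component, and
#' components without detectable internal structure are kept unchanged.
#'
#' @param labels 3D integer label array (e.g. from
#'   \code{\link{count_objects_3d}}).
#' @param stack the intensity \code{\link{voxel_stack}} the labels came from.
#' @param smooth_sigma Gaussian sigma (pixels) of the pre-watershed
#'   smoothing; default 1 lateral, half that axially.
#' @param h_rel h-maxima depth as a fraction of the smoothed intensity range
#'   (default 0.1).
#' @return A relabelled 3D integer array with count >= the input count.
#' @export
separate_touching_objects <- function(labels, stack, smooth_sigma = 1,
                                      h_rel = 0.1) {
  stopifnot(inherits(stack, "voxel_stack"),
            all(dim(labels) == dim(stack$data)))
  d <- dim(labels)
  mask <- as.integer(labels > 0)
  if (!any(mask == 1L)) return(array(0L, dim = d))
  sm <- cpp_gaussian_blur(as.numeric(stack$data), as.integer(d),
                          smooth_sigma, smooth_sigma, smooth_sigma / 2)
  rng <- range(sm)
  h <- h_rel * diff(rng)
  # h-maxima: reconstruct (f - h) under f, then take regional maxima
  rec <- cpp_reconstruct_dilation(sm - h, sm, as.integer(d), 26L)
  markers <- cpp_regional_maxima(rec, mask, as.integer(d), 26L)
  ws <- cpp_watershed(-sm, markers, mask, as.integer(d), 26L)
  # keep any component the watershed failed to mark (no internal maxima)
  ws <- array(ws, dim = d)
  unmarked <- mask == 1L & ws == 0L
  out <- integer(length(ws))
  out[ws > 0] <- ws[ws > 0]
  if (any(unmarked)) {
    shift <- max(ws)
    out[unmarked] <- shift + labels[unmarked]
  }
  array(prune_small_objects(out, 1L), dim = d)
}

#' Confocal / wide-field focus counting protocol
#'
#' Deterministic composition of the conventional-resolution counting chain:
#' slice-wise mean filter, global normalization, slice-wise local maxima,
#' Gaussian reconstruction of artificial focal objects and 3D
#' connected-component counting. The stack is assumed to be cropped to a
#' single nucleus.
#'
#' @param stack a \code{\link{voxel_stack}}.
#' @param mean_radius mean-filter disk radius (default 1.5).
#' @param noise_tolerance maxima prominence on the normalized scale
#'   (default 0.1).
#' @param recon_sigma reconstruction Gaussian sigma in pixels (default 1.0).
#' @param threshold object threshold; default half the reconstructed peak of
#'   an isolated maximum.
#' @param min_voxels minimum object size (default 4).
#' @return A \code{\link{count_objects_3d}} result (class \code{foci_count})
#'   with protocol \code{"confocal"}.
#' @export
count_confocal_rfi <- function(stack, mean_radius = 1.5,
                               noise_tolerance = 0.1, recon_sigma = 1.0,
                               threshold = NULL, min_voxels = 4) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (diff(range(stack$data)) == 0) {
    # empty nucleus: nothing to normalize, nothing to count
    return(new_foci_count(array(0L, dim = dim(stack$data)), "confocal",
                          list(empty = TRUE)))
  }
  sm <- mean_filter_slices(stack, mean_radius)
  nm <- normalize_stack(sm)
  mx <- find_stack_maxima(nm, noise_tolerance)
  rec <- reconstruct_focal_objects(mx, recon_sigma)
  thr <- threshold %||% (0.5 * single_marker_peak(recon_sigma))
  res <- count_objects_3d(rec, thr, min_voxels, protocol = "confocal")
  res$parameters <- c(res$parameters,
                      list(mean_radius = mean_radius,
                           noise_tolerance = noise_tolerance,
                           recon_sigma = recon_sigma))
  res
}

#' Super-resolution (3D-SIM) focus counting protocol
#'
#' Deterministic composition of the super-resolution counting chain for a
#' single-nucleus stack: automatic background removal by the triangle
#' method, 26-connected 3D labelling, watershed separation of touching
#' foci and counting.
#'
#' @param stack a \code{\link{voxel_stack}}.
#' @param min_voxels minimum object size (default 4).
#' @param smooth_sigma,h_rel watershed parameters, see
#'   \code{\link{separate_touching_objects}}.
#' @param separate run the touching-object separation step (default TRUE).
#' @return A \code{foci_count} with protocol \code{"sim"}.
#' @export
count_sim_rfi <- function(stack, min_voxels = 4, smooth_sigma = 1,
                          h_rel = 0.1, separate = TRUE) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (diff(range(stack$data)) == 0) {
    return(new_foci_count(array(0L, dim = dim(stack$data)), "sim",
                          list(empty = TRUE)))
  }
  thr <- stack_threshold_triangle(stack)
  d <- dim(stack$data)
  mask <- as.integer(stack$data > thr)
  lab <- cpp_label_components(mask, as.integer(d), 26L)
  lab <- array(prune_small_objects(lab, min_voxels), dim = d)
  if (separate && max(lab) > 0)
    lab <- separate_touching_objects(lab, stack, smooth_sigma, h_rel)
  lab <- array(prune_small_objects(lab, min_voxels), dim = d)
  new_foci_count(lab, "sim",
                 list(triangle_threshold = thr, min_voxels = min_voxels,
                      smooth_sigma = smooth_sigma, h_rel = h_rel))
}

#' Super-resolution to conventional focus-count ratios
#'
#' Computes the ratio of super-resolution to conventional focus counts per
#' cell and pooled over all cells (sum of SR counts over sum of conventional
#' counts), and combines both data sets.
#'
#' @param sr_counts,conventional_counts paired per-cell counts.
#' @return list of class \code{ratio_result}: \code{per_cell} ratios,
#'   \code{pooled}, \code{combined} (mean of per-cell ratios and the pooled
#'   ratio), \code{dispersion} (s.d. of that combined set), \code{n_cells}.
#' @export
resolution_ratio <- function(sr_counts, conventional_counts) {
  if (length(sr_counts) != length(conventional_counts))
    stop("count vectors must be paired", call. = FALSE)
  bad <- conventional_counts <= 0
  if (any(bad)) {
    warning(sprintf("%d cell(s) with zero conventional count excluded",
                    sum(bad)))
    sr_counts <- sr_counts[!bad]
    conventional_counts <- conventional_counts[!bad]
  }
  if (!length(sr_counts)) stop("no usable cells", call. = FALSE)
  per_cell <- sr_counts / conventional_counts
  pooled <- sum(sr_counts) / sum(conventional_counts)
  all_vals <- c(per_cell, pooled)
  structure(
    list(per_cell = per_cell, pooled = pooled,
         combined = mean(all_vals),
         dispersion = if (length(all_vals) > 1) sd(all_vals) else 0,
         n_cells = length(per_cell)),
    class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf(
    "<ratio_result> %d cells; per-cell mean %.2f, pooled %.2f, combined %.2f (s.d. %.2f)\n",
    x$n_cells, mean(x$per_cell), x$pooled, x$combined, x$dispersion))
  invisible(x)
}
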