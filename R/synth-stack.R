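#' Optical modality profile
#'
#' Bundles the point-spread-function widths, voxel sizes and camera noise
#' model of one imaging modality. The three built-in profiles emulate the
#' acquisition conditions of the study pipeline: spinning-disk/laser-scanning
#' confocal stacks (104 x 104 x 500 nm voxels), deconvolved wide-field stacks
#' and 3D structured-illumination (SIM) stacks on the unified
#' 40 x 40 x 125 nm grid. PSFs are modelled as anisotropic Gaussians; the
#' profiles preserve the resolution ordering sim < widefield_decon < confocal
#' (lateral sigma).
#'
#' @param name one of \code{"confocal"}, \code{"widefield_decon"},
#'   \code{"sim"}.
#' @param lateral_psf_sigma,axial_psf_sigma Gaussian PSF sigmas in nm.
#' @param voxel_xy,voxel_z voxel sizes in nm.
#' @param gain camera gain (counts per photon).
#' @param read_noise_sd additive Gaussian read noise s.d. (counts).
#' @param background mean background level (photons per voxel).
#' @return A list of class \code{modality_profile}.
#' @export
modality_profile <- function(name = c("confocal", "widefield_decon", "sim"),
                             lateral_psf_sigma = NULL,
                             axial_psf_sigma = NULL,
                             voxel_xy = NULL, voxel_z = NULL,
                             gain = 1, read_noise_sd = 2, background = 10) {
  name <- match.arg(name)
  defaults <- list(
    confocal        = c(110, 300, 104, 500),
    widefield_decon = c(90, 250, 40, 125),
    sim             = c(50, 140, 40, 125)
  )[[name]]
  p <- list(
    name = name,
    lateral_psf_sigma = lateral_psf_sigma %||% defaults[1],
    axial_psf_sigma = axial_psf_sigma %||% defaults[2],
    voxel_xy = voxel_xy %||% defaults[3],
    voxel_z = voxel_z %||% defaults[4],
    gain = gain, read_noise_sd = read_noise_sd, background = background
  )
  for (f in c("lateral_psf_sigma", "axial_psf_sigma", "voxel_xy", "voxel_z"))
    stop_if_not_positive(p[[f]], f)
  class(p) <- "modality_profile"
  p
}

# Lateral full width at half maximum of a profile's PSF, in nm.
#' @rdname modality_profile
#' @param profile a \code{modality_profile}.
#' @export
lateral_fwhm <- function(profile) 2 * sqrt(2 * log(2)) * profile$lateral_psf_sigma

# Sample focus centroids (nm) inside an axis-aligned ellipsoid centred at
# `centre`, optionally in compact clusters, with dart-throwing minimum
# separation. The exclusion zone is an ellipsoid (lateral radius
# `min_sep_nm`, axial radius `min_sep_axial_nm`) so that axial separations
# count for less, matching the anisotropic optical resolution. Called inside
# with_rng().
sample_centroids <- function(n_foci, semi_axes, centre, clustering,
                             min_sep_nm, min_sep_axial_nm = 3 * min_sep_nm) {
  unif_ellipsoid <- function(n, axes, ctr) {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n) {
      m <- matrix(runif(3 * 2 * (n - nrow(out) + 4), -1, 1), ncol = 3)
      keep <- rowSums(m^2) <= 1
      out <- rbind(out, m[keep, , drop = FALSE])
    }
    sweep(out[seq_len(n), , drop = FALSE] %*% diag(axes), 2, ctr, `+`)
  }
  place_min_sep <- function(n, axes, ctr, sep_lat, sep_ax = 3 * sep_lat) {
    pts <- matrix(NA_real_, n, 3)
    placed <- 0L
    tries <- 0L
    max_tries <- 4000L * max(n, 1L)
    while (placed < n) {
      cand <- unif_ellipsoid(1L, axes, ctr)
      ok <- placed == 0L || {
        dd <- sweep(pts[seq_len(placed), , drop = FALSE], 2, cand, `-`)
        min((dd[, 1]^2 + dd[, 2]^2) / sep_lat^2 + dd[, 3]^2 / sep_ax^2) >= 1
      }
      if (ok) {
        placed <- placed + 1L
        pts[placed, ] <- cand
      }
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place foci at the requested minimum separation",
             call. = FALSE)
    }
    pts
  }
  if (!isTRUE(clustering$enabled)) {
    cent <- if (min_sep_nm > 0)
      place_min_sep(n_foci, semi_axes, centre, min_sep_nm, min_sep_axial_nm)
    else unif_ellipsoid(n_foci, semi_axes, centre)
    return(list(centroids = cent, cluster = seq_len(n_foci)))
  }
  size <- max(1L, as.integer(round(clustering$mean_size %||% 5)))
  radius <- clustering$radius_nm %||% 250
  layout <- clustering$layout %||% "ring"
  n_clusters <- as.integer(ceiling(n_foci / size))
  parent_sep <- clustering$parent_min_sep_nm %||% (4 * radius)
  shrink <- pmax(semi_axes - radius, semi_axes * 0.5)
  parents <- place_min_sep(n_clusters, shrink, centre, parent_sep)
  sizes <- rep(size, n_clusters)
  extra <- n_clusters * size - n_foci
  if (extra > 0) sizes[n_clusters] <- size - extra
  cent <- matrix(NA_real_, 0, 3)
  clus <- integer(0)
  for (cl in seq_len(n_clusters)) {
    m <- sizes[cl]
    if (m == 0L) next
    offs <- if (identical(layout, "ring") && m > 1L) {
      phase <- runif(1, 0, 2 * pi)
      ang <- phase + 2 * pi * (seq_len(m) - 1L) / m
      cbind(radius * cos(ang), radius * sin(ang),
            rnorm(m, 0, radius / 4))
    } else {
      u <- matrix(rnorm(3 * m), ncol = 3)
      u <- u / sqrt(rowSums(u^2)) * radius * runif(m)^(1 / 3)
      u
    }
    cent <- rbind(cent, sweep(offs, 2, parents[cl, ], `+`))
    clus <- c(clus, rep(cl, m))
  }
  # clamp cluster members that jittered outside the nucleus back onto it
  rel <- sweep(cent, 2, centre, `-`)
  r <- sqrt(rowSums(sweep(rel, 2, semi_axes, `/`)^2))
  out <- which(r > 0.99)
  if (length(out)) cent[out, ] <- centre +
      rel[out, , drop = FALSE] * (0.99 / r[out])
  list(centroids = cent, cluster = clus)
}

#' Generate a synthetic 3D nuclear foci stack with known ground truth
#'
#' Places \code{n_foci} point sources (replication foci) inside an
#' ellipsoidal nucleus, renders each as an anisotropic-Gaussian PSF blob at
#' the requested modality, and adds background plus Poisson photon noise and
#' Gaussian read noise. Returns the rendered stack together with the exact
#' ground truth, so counting protocols can be validated against known focus
#' numbers.
#'
#' @param n_foci number of foci (>= 0).
#' @param profile a \code{\link{modality_profile}}.
#' @param clustering list: \code{enabled} (default FALSE), \code{mean_size}
#'   (foci per cluster, default 5), \code{radius_nm} (cluster radius, default
#'   250), \code{layout} (\code{"ring"} or \code{"sphere"}),
#'   \code{parent_min_sep_nm} (min distance between cluster centres).
#' @param nucleus list with \code{semi_axes_nm}, the ellipsoid semi-axes
#'   (default 8000 x 6000 x 3000 nm, i.e. a 16 x 12 x 6 um nucleus).
#' @param min_sep_nm minimum pairwise lateral centroid separation for
#'   unclustered placement (dart throwing; 0 disables).
#' @param min_sep_axial_nm axial radius of the pairwise exclusion ellipsoid
#'   (default 3 x \code{min_sep_nm}, reflecting the roughly threefold worse
#'   axial optical resolution).
#' @param intensity list with \code{mean_photons} (integrated photons per
#'   focus, default 5000) and \code{cv} (brightness heterogeneity, default
#'   0.2).
#' @param stack_dim optional integer dims \code{c(ny, nx, nz)}; errors if the
#'   nucleus does not fit. By default dims are derived from the nucleus plus
#'   a PSF margin.
#' @param seed RNG seed; identical arguments give identical output.
#' @return list with elements \code{stack} (a \code{\link{voxel_stack}}) and
#'   \code{truth} (class \code{foci_truth}: \code{centroids_nm} matrix,
#'   \code{intensity_photons}, \code{cluster}, \code{nuclear_mask} logical
#'   array, \code{count}, \code{semi_axes_nm}, \code{centre_nm}).
#' @export
generate_nucleus_stack <- function(n_foci, profile = modality_profile("sim"),
                                   clustering = list(enabled = FALSE),
                                   nucleus = list(semi_axes_nm = c(8000, 6000, 3000)),
                                   min_sep_nm = 0, min_sep_axial_nm = NULL,
                                   intensity = list(mean_photons = 5000, cv = 0.2),
                                   stack_dim = NULL, seed = 1) {
  min_sep_axial_nm <- min_sep_axial_nm %||% (3 * min_sep_nm)
  if (!is.numeric(n_foci) || length(n_foci) != 1L || n_foci < 0 ||
      n_foci != round(n_foci))
    stop("`n_foci` must be a non-negative integer", call. = FALSE)
  n_foci <- as.integer(n_foci)
  stopifnot(inherits(profile, "modality_profile"))
  axes <- nucleus$semi_axes_nm
  stopifnot(length(axes) == 3, all(axes > 0))
  margin_xy <- 4 * profile$lateral_psf_sigma + 2 * profile$voxel_xy
  margin_z <- 4 * profile$axial_psf_sigma + 2 * profile$voxel_z
  dims <- c(
    ceiling((2 * axes[2] + 2 * margin_xy) / profile$voxel_xy), # y
    ceiling((2 * axes[1] + 2 * margin_xy) / profile$voxel_xy), # x
    ceiling((2 * axes[3] + 2 * margin_z) / profile$voxel_z)    # z
  )
  if (!is.null(stack_dim)) {
    if (any(stack_dim < dims))
      stop("nucleus (plus PSF margin) does not fit in `stack_dim`",
           call. = FALSE)
    dims <- as.integer(stack_dim)
  }
  dims <- as.integer(dims)
  centre <- c(dims[2] * profile$voxel_xy / 2,  # x
              dims[1] * profile$voxel_xy / 2,  # y
              dims[3] * profile$voxel_z / 2)   # z
  with_rng(seed, {
    sampled <- sample_centroids(n_foci, axes, centre, clustering, min_sep_nm,
                                min_sep_axial_nm)
    photons <- rnorm_trunc(n_foci, intensity$mean_photons,
                           (intensity$cv %||% 0) * intensity$mean_photons,
                           lower = 0.1 * intensity$mean_photons)
    truth <- structure(
      list(centroids_nm = sampled$centroids,
           intensity_photons = photons,
           cluster = sampled$cluster,
           count = n_foci,
           semi_axes_nm = axes, centre_nm = centre,
           dims = dims),
      class = "foci_truth")
    truth$nuclear_mask <- nuclear_mask_grid(truth, profile)
    stack <- render_foci_stack(truth, profile, noise = TRUE, dims = dims)
    list(stack = stack, truth = truth)
  })
}

nuclear_mask_grid <- function(truth, profile) {
  dims <- truth$dims
  yc <- (seq_len(dims[1]) - 0.5) * profile$voxel_xy
  xc <- (seq_len(dims[2]) - 0.5) * profile$voxel_xy
  zc <- (seq_len(dims[3]) - 0.5) * profile$voxel_z
  ax <- truth$semi_axes_nm
  ct <- truth$centre_nm
  fy <- ((yc - ct[2]) / ax[2])^2
  fx <- ((xc - ct[1]) / ax[1])^2
  fz <- ((zc - ct[3]) / ax[3])^2
  outer(outer(fy, fx, `+`), fz, `+`) <= 1.000001
}

#' Render a foci ground truth at a given modality
#'
#' Re-renders the same geometric ground truth under a different optical
#' profile, the key step for comparing counting protocols across resolution
#' levels on identical geometry. Rendering is deterministic given the truth;
#' noise is drawn from \code{seed} when \code{noise = TRUE}.
#'
#' @param truth a \code{foci_truth} from \code{\link{generate_nucleus_stack}}.
#' @param profile a \code{\link{modality_profile}}.
#' @param noise add Poisson photon noise and Gaussian read noise.
#' @param seed RNG seed for the noise draw (ignored when called inside a
#'   seeded generator).
#' @param dims optional stack dims (used internally to keep the rendering
#'   grid identical to the one the ground truth was generated on).
#' @return A \code{\link{voxel_stack}}.
#' @export
render_foci_stack <- function(truth, profile, noise = TRUE, seed = NULL,
                              dims = NULL) {
  stopifnot(inherits(truth, "foci_truth"), inherits(profile, "modality_profile"))
  do_render <- function() {
    ax_nm <- truth$semi_axes_nm
    margin_xy <- 4 * profile$lateral_psf_sigma + 2 * profile$voxel_xy
    margin_z <- 4 * profile$axial_psf_sigma + 2 * profile$voxel_z
    if (is.null(dims)) dims <- as.integer(c(
      ceiling((2 * ax_nm[2] + 2 * margin_xy) / profile$voxel_xy),
      ceiling((2 * ax_nm[1] + 2 * margin_xy) / profile$voxel_xy),
      ceiling((2 * ax_nm[3] + 2 * margin_z) / profile$voxel_z)))
    centre <- c(dims[2] * profile$voxel_xy / 2,
                dims[1] * profile$voxel_xy / 2,
                dims[3] * profile$voxel_z / 2)
    # shift truth centroids into this grid's frame
    shift <- centre - truth$centre_nm
    s_xy <- profile$lateral_psf_sigma / profile$voxel_xy
    s_z <- profile$axial_psf_sigma / profile$voxel_z
    voxvol <- profile$voxel_xy^2 * profile$voxel_z
    sig_prod <- profile$lateral_psf_sigma^2 * profile$axial_psf_sigma
    n <- truth$count
    if (n > 0) {
      cen <- sweep(truth$centroids_nm, 2, shift, `+`)
      amp <- truth$intensity_photons * voxvol /
        ((2 * pi)^1.5 * sig_prod)
      sig <- cpp_add_gaussians(
        dims,
        cen[, 2] / profile$voxel_xy - 0.5,  # y in voxel units, 0-based
        cen[, 1] / profile$voxel_xy - 0.5,  # x
        cen[, 3] / profile$voxel_z - 0.5,   # z
        s_xy, s_xy, s_z, amp)
    } else {
      sig <- numeric(prod(dims))
    }
    lambda <- sig + profile$background
    if (noise) {
      obs <- rpois(length(lambda), lambda) * profile$gain +
        rnorm(length(lambda), 0, profile$read_noise_sd)
      obs[obs < 0] <- 0
    } else {
      obs <- lambda * profile$gain
    }
    voxel_stack(array(obs, dim = dims), profile$voxel_xy, profile$voxel_z,
                profile$name)
  }
  if (!is.null(seed)) with_rng(seed, do_render()) else do_render()
}

#' @export
print.foci_truth <- function(x, ...) {
  cat(sprintf("<foci_truth> %d foci in %.1f x %.1f x %.1f um nucleus\n",
              x$count, 2 * x$semi_axes_nm[1] / 1000,
              2 * x$semi_axes_nm[2] / 1000, 2 * x$semi_axes_nm[3] / 1000))
  invisible(x)
}
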