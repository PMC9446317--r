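#' Configuration for synthetic multi-component lesion masks
#'
#' Describes a synthetic stroke lesion: `n_components` disjoint spherical
#' blobs with radii drawn uniformly from `radius_range_mm`, placed around
#' the grid centre with per-axis Gaussian scatter of `dispersion_mm`.
#' Larger dispersion emulates the scattered, multi-territory infarct
#' pattern associated with cardioembolism, which inflates the oriented
#' bounding box while leaving per-component volume unchanged.
#'
#' @param grid_shape integer length-3, voxels per axis (each >= 16).
#' @param spacing_mm voxel size per axis (mm), positive.
#' @param n_components target number of disjoint blobs (>= 1).
#' @param radius_range_mm length-2, min/max blob radius (mm).
#' @param dispersion_mm standard deviation (mm) of blob-centre placement
#'   around the grid centre; 0 concentrates all blobs centrally.
#' @param seed integer RNG seed; the same config + seed is bit-reproducible.
#' @param max_tries bounded rejection-sampling budget for blob placement.
#' @return A `lesion_sim_config` list.
#' @export
lesion_sim_config <- function(grid_shape = c(64, 64, 64),
                              spacing_mm = c(1, 1, 1),
                              n_components = 1,
                              radius_range_mm = c(3, 6),
                              dispersion_mm = 15,
                              seed = 1,
                              max_tries = 1000) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L)) {
    stopf("grid_shape must be 3 integers >= 16")
  }
  spacing_mm <- check_spacing(spacing_mm)
  if (n_components < 1) stopf("n_components must be >= 1")
  if (length(radius_range_mm) != 2L || any(radius_range_mm <= 0) ||
      radius_range_mm[1] > radius_range_mm[2]) {
    stopf("radius_range_mm must be positive with min <= max")
  }
  if (dispersion_mm < 0) stopf("dispersion_mm must be >= 0")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 n_components = as.integer(n_components),
                 radius_range_mm = as.numeric(radius_range_mm),
                 dispersion_mm = dispersion_mm, seed = seed,
                 max_tries = max_tries),
            class = "lesion_sim_config")
}

# logical array of voxels whose centres fall inside the ellipsoid
rasterize_ellipsoid <- function(grid_shape, spacing_mm, center_mm, radii_mm) {
  lo <- pmax(1L, floor((center_mm - radii_mm) / spacing_mm) + 1L)
  hi <- pmin(grid_shape, ceiling((center_mm + radii_mm) / spacing_mm) + 1L)
  out <- array(FALSE, grid_shape)
  if (any(lo > hi)) return(out)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  # voxel centre of index i (1-based) is at (i - 0.5) * spacing
  dx2 <- (((ii - 0.5) * spacing_mm[1] - center_mm[1]) / radii_mm[1])^2
  dy2 <- (((jj - 0.5) * spacing_mm[2] - center_mm[2]) / radii_mm[2])^2
  dz2 <- (((kk - 0.5) * spacing_mm[3] - center_mm[3]) / radii_mm[3])^2
  sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  out[ii, jj, kk] <- sub
  out
}

#' Rasterize a sphere or ellipsoid into a lesion mask
#'
#' A voxel is foreground when its centre lies inside the ellipsoid. Useful
#' as an analytic fixture: the rasterized volume converges to
#' \eqn{4/3 \pi r^3} and the mesh surface area to \eqn{4 \pi r^2} as
#' spacing shrinks.
#'
#' @param grid_shape voxels per axis.
#' @param spacing_mm voxel size per axis (mm).
#' @param center_mm ellipsoid centre in mm (default: grid centre).
#' @param radii_mm length-1 (sphere) or length-3 radii in mm.
#' @return A [lesion_mask()].
#' @export
rasterize_ellipsoid_mask <- function(grid_shape, spacing_mm, radii_mm,
                                     center_mm = NULL) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- check_spacing(spacing_mm)
  if (length(radii_mm) == 1L) radii_mm <- rep(radii_mm, 3L)
  if (is.null(center_mm)) center_mm <- grid_shape * spacing_mm / 2
  lesion_mask(rasterize_ellipsoid(grid_shape, spacing_mm, center_mm, radii_mm),
              spacing_mm)
}

#' Rasterize an arbitrarily rotated solid cuboid
#'
#' A voxel is foreground when its centre, mapped into the cuboid's body
#' frame, lies within the half-extents. The rotation is Rx-Ry-Rz extrinsic
#' with angles in degrees. Used to exercise the oriented-bounding-box
#' estimator, whose volume for such a mask should approach
#' `prod(2 * half_extents_mm)`.
#'
#' @param grid_shape voxels per axis.
#' @param spacing_mm voxel size per axis (mm).
#' @param half_extents_mm length-3 cuboid half edge lengths (mm).
#' @param angles_deg length-3 rotation angles (degrees) about x, y, z.
#' @param center_mm cuboid centre in mm (default: grid centre).
#' @return A [lesion_mask()].
#' @export
rasterize_rotated_cuboid_mask <- function(grid_shape, spacing_mm,
                                          half_extents_mm,
                                          angles_deg = c(0, 0, 0),
                                          center_mm = NULL) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- check_spacing(spacing_mm)
  if (is.null(center_mm)) center_mm <- grid_shape * spacing_mm / 2
  R <- rotation_matrix_xyz(angles_deg)
  idx <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                               j = seq_len(grid_shape[2]),
                               k = seq_len(grid_shape[3])))
  ctr <- sweep(sweep(idx - 0.5, 2, spacing_mm, `*`), 2, center_mm, `-`)
  body <- ctr %*% R  # world -> body: columns of R are body axes in world
  inside <- abs(body[, 1]) <= half_extents_mm[1] &
    abs(body[, 2]) <= half_extents_mm[2] &
    abs(body[, 3]) <= half_extents_mm[3]
  lesion_mask(array(inside, grid_shape), spacing_mm)
}

rotation_matrix_xyz <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# all 26-neighbour index offsets (including face/edge/corner)
.offsets26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
.offsets26 <- .offsets26[rowSums(abs(.offsets26)) > 0, , drop = FALSE]

#' Generate a synthetic multi-component lesion mask with ground truth
#'
#' Places `n_components` disjoint spherical blobs by bounded rejection
#' sampling. Disjointness is enforced with a one-voxel dilation guard in
#' the 26-neighbourhood, so no two blobs touch even at a corner and the
#' realized component count is unambiguous under any labeling connectivity.
#'
#' @param config a [lesion_sim_config()].
#' @return A list with `mask` (a [lesion_mask()]) and `ground_truth`
#'   (realized `n_components`, per-component `component_volumes_mm3`,
#'   blob centres and radii).
#' @export
make_lesion_mask <- function(config) {
  stopifnot(inherits(config, "lesion_sim_config"))
  gs <- config$grid_shape; sp <- config$spacing_mm
  with_rng_seed(config$seed, {
    occupied <- array(FALSE, gs)
    centre0 <- gs * sp / 2
    vols <- numeric(0)
    centres <- matrix(NA_real_, config$n_components, 3)
    radii <- numeric(config$n_components)
    tries <- 0L
    for (ci in seq_len(config$n_components)) {
      placed <- FALSE
      while (!placed) {
        tries <- tries + 1L
        if (tries > config$max_tries) {
          stopf(paste0("could not place %d disjoint blobs in a %s grid ",
                       "after %d tries (radius %.1f-%.1f mm, dispersion ",
                       "%.1f mm)"),
                config$n_components, paste(gs, collapse = "x"),
                config$max_tries, config$radius_range_mm[1],
                config$radius_range_mm[2], config$dispersion_mm)
        }
        r <- runif(1, config$radius_range_mm[1], config$radius_range_mm[2])
        ctr <- centre0 + rnorm(3, 0, config$dispersion_mm)
        # blob must fit inside the grid with a one-voxel guard margin
        if (any(ctr - r < sp * 1.5) || any(ctr + r > (gs - 1.5) * sp)) next
        blob <- rasterize_ellipsoid(gs, sp, ctr, rep(r, 3))
        if (!any(blob)) next
        vox <- which(blob, arr.ind = TRUE)
        # one-voxel dilation guard (26-neighbourhood)
        guard <- vox[rep(seq_len(nrow(vox)), each = nrow(.offsets26)), ,
                     drop = FALSE] +
          .offsets26[rep(seq_len(nrow(.offsets26)), nrow(vox)), , drop = FALSE]
        keep <- guard[, 1] >= 1 & guard[, 1] <= gs[1] &
          guard[, 2] >= 1 & guard[, 2] <= gs[2] &
          guard[, 3] >= 1 & guard[, 3] <= gs[3]
        guard <- guard[keep, , drop = FALSE]
        if (any(occupied[vox]) || any(occupied[guard])) next
        occupied[vox] <- TRUE
        vols <- c(vols, nrow(vox) * prod(sp))
        centres[ci, ] <- ctr
        radii[ci] <- r
        placed <- TRUE
      }
    }
    list(mask = lesion_mask(occupied, sp),
         ground_truth = list(n_components = length(vols),
                             component_volumes_mm3 = vols,
                             centres_mm = centres, radii_mm = radii,
                             seed = config$seed))
  })
}

#' Generate a synthetic ADC volume from a lesion mask
#'
#' Voxels inside the mask take `lesion_adc`, voxels outside take
#' `background_adc`, and i.i.d. Gaussian noise of standard deviation
#' `noise_sd` is added everywhere. Acutely ischemic tissue has restricted
#' diffusion, so `lesion_adc` must lie below `background_adc` for threshold
#' segmentation to be well posed. Units are mm^2/s (typical parenchyma
#' ~800e-6, acute infarct core ~400e-6).
#'
#' @param mask a [lesion_mask()].
#' @param lesion_adc ADC value inside the lesion (mm^2/s).
#' @param background_adc ADC value outside the lesion (mm^2/s).
#' @param noise_sd Gaussian noise standard deviation (mm^2/s).
#' @param seed integer RNG seed for the noise.
#' @return An [image_volume()] with units "mm^2/s".
#' @export
make_adc_volume <- function(mask, lesion_adc = 400e-6,
                            background_adc = 800e-6,
                            noise_sd = 0, seed = 1) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (lesion_adc >= background_adc) {
    stopf("lesion_adc must be below background_adc (got %g >= %g)",
          lesion_adc, background_adc)
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  vals <- ifelse(mask$data == 1L, lesion_adc, background_adc)
  if (noise_sd > 0) {
    vals <- vals + with_rng_seed(seed, rnorm(length(vals), 0, noise_sd))
  }
  image_volume(array(vals, dim(mask$data)), mask$spacing_mm, units = "mm^2/s")
}

#' Build a toy brain atlas for location classification tests
#'
#' Partitions the grid into eight labels crossing hemisphere (left/right of
#' the mid-sagittal plane along the first axis), vascular territory
#' (anterior fraction of the second axis = internal carotid territory of
#' the respective side; posterior fraction = basilar), and a cortical shell
#' (voxels within `shell_voxels` of the outer grid boundary). It is a
#' deliberately schematic stand-in for a real parcellation + territory map:
#' the classification rules downstream only require conforming labels.
#'
#' @param grid_shape voxels per axis.
#' @param spacing_mm voxel size per axis (mm).
#' @param shell_voxels thickness of the cortical shell in voxels.
#' @param basilar_fraction posterior fraction of axis 2 assigned to the
#'   basilar territory.
#' @return An [atlas_volume()].
#' @export
make_toy_atlas <- function(grid_shape = c(64, 64, 64), spacing_mm = c(1, 1, 1),
                           shell_voxels = 2, basilar_fraction = 0.3) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- check_spacing(spacing_mm)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  i <- slice.index(array(0L, grid_shape), 1)
  j <- slice.index(array(0L, grid_shape), 2)
  k <- slice.index(array(0L, grid_shape), 3)
  right <- i > nx / 2
  basilar <- j > (1 - basilar_fraction) * ny
  shell <- i <= shell_voxels | i > nx - shell_voxels |
    j <= shell_voxels | j > ny - shell_voxels |
    k <= shell_voxels | k > nz - shell_voxels
  labels <- 1L + right + 2L * basilar + 4L * shell
  combos <- expand.grid(right = c(FALSE, TRUE), basilar = c(FALSE, TRUE),
                        shell = c(FALSE, TRUE))
  tab <- data.frame(
    label = 1L + combos$right + 2L * combos$basilar + 4L * combos$shell,
    name = paste0(ifelse(combos$right, "right ", "left "),
                  ifelse(combos$basilar, "basilar", "ICA"),
                  ifelse(combos$shell, " cortical", " deep")),
    hemisphere = ifelse(combos$right, "right", "left"),
    territory = ifelse(combos$basilar, "basilar",
                       ifelse(combos$right, "right ICA", "left ICA")),
    cortical = combos$shell,
    stringsAsFactors = FALSE
  )
  atlas_volume(labels, spacing_mm, tab[order(tab$label), ])
}
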