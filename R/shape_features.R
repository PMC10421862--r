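## 3D shape descriptors of a binary tumor mask, in physical units.
##
## Surface area uses the coarea estimator: the binary mask is smoothed with a
## small Gaussian (sigma_mm, physical units) and the integral of the gradient
## magnitude of the smoothed indicator equals the average perimeter of its
## level sets, which for a compact lesion approximates the surface area far
## more accurately than counting exposed voxel faces (which overestimates a
## sphere's area by ~50%).

shape_feature_names <- c(
  "shape_volume_ml", "shape_surface_area_mm2", "shape_surface_to_volume",
  "shape_sphericity", "shape_compactness1", "shape_compactness2",
  "shape_max_3d_diameter_mm", "shape_max_2d_diameter_axial_mm",
  "shape_max_2d_diameter_coronal_mm", "shape_max_2d_diameter_sagittal_mm",
  "shape_major_axis_mm", "shape_minor_axis_mm", "shape_least_axis_mm",
  "shape_elongation", "shape_flatness", "shape_equivalent_sphere_diameter_mm",
  "shape_bbox_extent_x_mm", "shape_bbox_extent_y_mm", "shape_bbox_extent_z_mm",
  "shape_extent_fraction", "shape_com_offset_mm", "shape_slice_count",
  "shape_mean_slice_area_mm2", "shape_largest_slice_perimeter_mm")

## 1D Gaussian convolution along an axis (zero padding; masks are assumed not
## to touch the volume border, which the phantom generator guarantees).
conv1_axis <- function(arr, kern, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  L <- da[1]; r <- (length(kern) - 1L) / 2L
  K <- matrix(0, L, L)
  for (o in -r:r) {
    i <- seq_len(L)
    j <- i + o
    ok <- j >= 1 & j <= L
    K[cbind(i[ok], j[ok])] <- kern[o + r + 1L]
  }
  a <- array(K %*% m, dim = da)
  aperm(a, order(perm))
}

smooth_mask <- function(mask, spacing, sigma_mm) {
  u <- array(as.numeric(mask), dim = dim(mask))
  for (ax in 1:3) {
    s <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    u <- conv1_axis(u, k / sum(k), ax)
  }
  u
}

surface_area_coarea <- function(mask, spacing, sigma_mm = 0.8) {
  u <- smooth_mask(mask, spacing, sigma_mm)
  d <- dim(u)
  g2 <- array(0, dim = d)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(u, perm)
    da <- dim(a)
    gr <- a
    gr[2:(da[1] - 1), , ] <- (a[3:da[1], , ] - a[1:(da[1] - 2), , ]) /
      (2 * spacing[ax])
    gr[c(1, da[1]), , ] <- 0
    g2 <- g2 + aperm(gr, order(perm))^2
  }
  sum(sqrt(g2)) * prod(spacing)
}

max_pairwise_dist <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  if (nrow(coords) > 4000L) {  # cap memory; boundary sets this large are rare
    keep <- round(seq(1, nrow(coords), length.out = 4000L))
    coords <- coords[keep, , drop = FALSE]
  }
  sq <- rowSums(coords^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
  sqrt(max(0, max(d2)))
}

boundary_voxels <- function(mask) {
  d <- dim(mask)
  inner <- mask
  shift_and <- function(m, ax, o) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    src <- if (o > 0) 1:(n - o) else (1 - o):n
    dst <- src + o
    idx_src[[ax]] <- src; idx_dst[[ax]] <- dst
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (o in c(-1L, 1L)) inner <- inner & shift_and(mask, ax, o)
  mask & !inner
}

slice_perimeter <- function(sl, spacing) {
  n1 <- nrow(sl); n2 <- ncol(sl)
  pad <- matrix(FALSE, n1 + 2L, n2 + 2L)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- sl
  exposed_x <- sum(pad[2:(n1 + 1), ] & !pad[1:n1, ]) +
    sum(pad[2:(n1 + 1), ] & !pad[3:(n1 + 2), ])   # edges of length spacing[2]
  exposed_y <- sum(pad[, 2:(n2 + 1)] & !pad[, 1:n2]) +
    sum(pad[, 2:(n2 + 1)] & !pad[, 3:(n2 + 2)])   # edges of length spacing[1]
  exposed_x * spacing[2] + exposed_y * spacing[1]
}

#' 3D shape descriptors of a tumor mask
#'
#' Computes the frozen set of 24 shape features in physical units: voxel
#' volume (mL), surface area (coarea estimate from a smoothed indicator),
#' surface-to-volume ratio, sphericity (clamped to (0, 1\]), two compactness
#' variants, maximum 3D diameter, per-plane maximum 2D diameters, principal
#' axis lengths (4 sqrt of the coordinate-covariance eigenvalues), elongation
#' and flatness, equivalent-sphere diameter, bounding-box extents, fill
#' fraction, centre-of-mass offset from the bounding-box centre, axial slice
#' count, mean per-slice area, and the grid perimeter of the largest slice.
#'
#' @param mask a [segmentation_mask()] (or logical 3D array).
#' @param spacing voxel spacing in mm (taken from the mask if omitted).
#' @return Named numeric vector of 24 features.
#' @export
extract_shape_features <- function(mask, spacing = NULL) {
  if (inherits(mask, "seg_mask")) {
    spacing <- spacing %||% mask$spacing
    mask <- mask$voxels
  }
  if (is.null(spacing)) stop("spacing required")
  if (!any(mask)) stop("empty mask")
  vox_vol <- prod(spacing)
  n <- sum(mask)
  volume_mm3 <- n * vox_vol
  volume_ml <- volume_mm3 / 1000

  A <- surface_area_coarea(mask, spacing)
  sphericity <- min(1, pi^(1 / 3) * (6 * volume_mm3)^(2 / 3) / A)
  compactness1 <- volume_mm3 / (sqrt(pi) * A^1.5)
  compactness2 <- 36 * pi * volume_mm3^2 / A^3

  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep(idx, 2, spacing, "*")
  bnd <- which(boundary_voxels(mask), arr.ind = TRUE)
  bcoords <- sweep(bnd, 2, spacing, "*")
  max3d <- max_pairwise_dist(bcoords)

  max2d <- function(fix_axis) {
    planes <- unique(bnd[, fix_axis])
    m <- 0
    for (p in planes) {
      sel <- bnd[, fix_axis] == p
      m <- max(m, max_pairwise_dist(bcoords[sel, -fix_axis, drop = FALSE]))
    }
    m
  }
  max2d_axial <- max2d(3)     # in-plane (x, y)
  max2d_coronal <- max2d(2)   # (x, z)
  max2d_sagittal <- max2d(1)  # (y, z)

  if (n > 1) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  elongation <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flatness <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0

  eq_diam <- (6 * volume_mm3 / pi)^(1 / 3)
  bb_lo <- apply(idx, 2, min); bb_hi <- apply(idx, 2, max)
  bbox <- (bb_hi - bb_lo + 1) * spacing
  extent <- volume_mm3 / prod(bbox)
  com <- colMeans(coords)
  bb_center <- (bb_lo + bb_hi) / 2 * spacing
  com_offset <- sqrt(sum((com - bb_center)^2))

  zs <- sort(unique(idx[, 3]))
  areas <- vapply(zs, function(z) sum(mask[, , z]) * spacing[1] * spacing[2],
                  numeric(1))
  zbig <- zs[which.max(areas)]
  perim <- slice_perimeter(mask[, , zbig], spacing)

  stats::setNames(
    c(volume_ml, A, A / volume_mm3, sphericity, compactness1, compactness2,
      max3d, max2d_axial, max2d_coronal, max2d_sagittal,
      axes[1], axes[2], axes[3], elongation, flatness, eq_diam,
      bbox[1], bbox[2], bbox[3], extent, com_offset,
      length(zs), mean(areas), perim),
    shape_feature_names)
}
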