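## Exact squared Euclidean distance transform with anisotropic spacing, by
## separable min-convolution along each axis (distance to the nearest TRUE
## voxel, measured center-to-center in mm).

edt_pass <- function(M, s) {
  L <- nrow(M)
  out <- matrix(Inf, L, ncol(M))
  offs2 <- (s * (seq_len(L) - 1))^2
  for (i in seq_len(L)) {
    acc <- M[i, ]
    for (j in seq_len(L)) {
      if (j == i) next
      acc <- pmin(acc, M[j, ] + offs2[abs(i - j) + 1L])
    }
    out[i, ] <- acc
  }
  out
}

#' Squared distance transform of a binary 3D array
#'
#' @param mask logical 3D array (distance is measured to its `TRUE` voxels).
#' @param spacing voxel spacing in mm.
#' @return 3D array of squared distances (mm^2); 0 inside the mask, `Inf` if
#'   the mask is empty.
#' @export
distance_transform_sq <- function(mask, spacing) {
  dims <- dim(mask)
  d2 <- array(ifelse(mask, 0, Inf), dim = dims)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(d2, perm)
    da <- dim(a)
    m <- matrix(a, nrow = da[1])
    m <- edt_pass(m, spacing[ax])
    a <- array(m, dim = da)
    d2 <- aperm(a, order(perm))
  }
  d2
}

#' Construct the intratumoral region and the fat-excluded peritumoral rim
#'
#' The rim is the morphological dilation of the tumor by `rim_mm` in physical
#' space (anisotropic voxel spacing respected), minus the tumor itself, minus
#' any voxel with HU at or below `max(fat_hu)` -- this removes peri-hepatic fat
#' (roughly -100 to -10 HU) and anything of even lower attenuation such as
#' air -- clipped to the volume bounds.
#'
#' @param volume a [ct_volume()].
#' @param tumor the tumor [segmentation_mask()] on the same grid.
#' @param rim_mm rim width in mm (default 12).
#' @param fat_hu excluded HU interval; only its upper bound is used as the
#'   exclusion threshold (everything at or below it is removed).
#' @return A list of class `region_pair`: `tumor`, `rim` (masks), `rim_mm`,
#'   `excluded_voxel_count` (voxels removed by the HU rule), and `rim_empty`
#'   (flag; when `TRUE`, downstream rim features are reported missing).
#' @export
extract_peritumoral_rim <- function(volume, tumor, rim_mm = 12,
                                    fat_hu = c(-100, -10)) {
  stopifnot(inherits(volume, "ct_volume"), inherits(tumor, "seg_mask"))
  if (rim_mm <= 0) stop("rim_mm must be positive")
  if (!any(tumor$voxels)) stop("empty region: tumor mask has no voxels")
  if (!identical(dim(tumor$voxels), dim(volume$intensities)))
    stop("grid mismatch between tumor mask and volume")
  d2 <- distance_transform_sq(tumor$voxels, volume$spacing)
  dilated <- d2 <= rim_mm^2 + 1e-9
  candidate <- dilated & !tumor$voxels
  fat <- volume$intensities <= max(fat_hu)
  rim_vox <- candidate & !fat
  excluded <- sum(candidate & fat)
  rim_empty <- !any(rim_vox)
  if (rim_empty)
    warning("peritumoral rim is empty after exclusions; rim features will be missing")
  rim <- structure(list(voxels = rim_vox, grid = volume$id, dim = dim(rim_vox),
                        spacing = volume$spacing, label = "rim"),
                   class = "seg_mask")
  structure(list(tumor = tumor, rim = rim, rim_mm = rim_mm,
                 fat_hu = fat_hu, excluded_voxel_count = excluded,
                 rim_empty = rim_empty),
            class = "region_pair")
}

#' @export
print.region_pair <- function(x, ...) {
  cat(sprintf("<region_pair> tumor %d vox, rim %d vox (width %g mm, %d voxels HU-excluded)%s\n",
              sum(x$tumor$voxels), sum(x$rim$voxels), x$rim_mm,
              x$excluded_voxel_count, if (x$rim_empty) " [rim empty]" else ""))
  invisible(x)
}
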