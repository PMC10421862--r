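#' CT volume container
#'
#' Bundles a 3D grid of Hounsfield-unit intensities with its voxel spacing and
#' an optional voxel-to-world affine. HU values outside the plausible scanner
#' range \[-1024, 3071\] are clipped with a warning (they arise from
#' reconstruction artifacts, not tissue).
#'
#' @param intensities 3D numeric array of HU values.
#' @param spacing numeric length-3, mm per voxel along (x, y, z); must be
#'   strictly positive.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @param id scan identifier.
#' @param timepoint `"pre"` or `"post"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, spacing, affine = NULL, id = "scan",
                      timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("non-3D payload: intensities must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (any(!is.finite(intensities)))
    stop("intensities must be finite HU values")
  lo <- -1024; hi <- 3071
  if (any(intensities < lo) || any(intensities > hi)) {
    warning("HU values outside [-1024, 3071] clipped (scanner artifacts)")
    intensities[intensities < lo] <- lo
    intensities[intensities > hi] <- hi
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  structure(
    list(intensities = intensities, spacing = as.numeric(spacing),
         affine = affine, id = id, timepoint = timepoint),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<ct_volume '%s' (%s)> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU [%g, %g]\n",
              x$id, x$timepoint, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Binary segmentation mask on a CT grid
#'
#' @param voxels 3D array; any value > 0 becomes 1.
#' @param reference the `ct_volume` the mask lives on.
#' @param label `"tumor"` or `"rim"`. A tumor mask must be nonempty.
#' @return An object of class `seg_mask` with logical `voxels`.
#' @export
segmentation_mask <- function(voxels, reference, label = c("tumor", "rim")) {
  label <- match.arg(label)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("non-3D payload: mask must be a 3D array")
  if (!inherits(reference, "ct_volume")) stop("reference must be a ct_volume")
  if (!identical(dim(voxels), dim(reference$intensities)))
    stop("grid mismatch: mask shape differs from reference volume")
  vox <- voxels > 0
  if (label == "tumor" && !any(vox))
    stop("empty region: all-zero tumor mask")
  structure(list(voxels = vox, grid = reference$id,
                 dim = dim(vox), spacing = reference$spacing, label = label),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask '%s' on grid '%s'> %d voxels set of %d x %d x %d\n",
              x$label, x$grid, sum(x$voxels), x$dim[1], x$dim[2], x$dim[3]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Readers / writers

is_nrrd <- function(path) grepl("\\.nrrd$", path, ignore.case = TRUE)

#' Read a CT volume from NIfTI or NRRD
#'
#' Voxel spacing is taken from the file header; a file without spacing
#' metadata or with a non-3D payload is rejected rather than guessed at.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @param id,timepoint passed to [ct_volume()]; `id` defaults to the file name.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, id = NULL, timepoint = "pre") {
  if (!file.exists(path)) stop("missing file: ", path)
  id <- id %||% sub("\\.(nii(\\.gz)?|nrrd)$", "", basename(path))
  if (is_nrrd(path)) {
    x <- read_nrrd(path)
    return(ct_volume(x$data, x$spacing, id = id, timepoint = timepoint))
  }
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("non-3D payload in ", path)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("missing spacing metadata in ", path)
  ct_volume(arr, sp[1:3], affine = RNifti::xform(img), id = id,
            timepoint = timepoint)
}

#' Write a CT volume (or raw array) to NIfTI or NRRD
#'
#' @param volume a [ct_volume()] or a 3D array (then `spacing` is required).
#' @param path output path; format chosen from the extension.
#' @param spacing voxel spacing, only needed when `volume` is a bare array.
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "ct_volume")) {
    arr <- volume$intensities
    spacing <- volume$spacing
  } else {
    arr <- volume
    if (is.null(spacing)) stop("spacing required when writing a bare array")
  }
  if (is_nrrd(path)) {
    write_nrrd(arr, spacing, path)
  } else {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' Read a segmentation mask and bind it to a reference volume
#'
#' Any stored value greater than zero maps to 1. The mask grid (shape and
#' spacing) must match the reference volume exactly; no resampling is done.
#'
#' @param path mask file (NIfTI or NRRD).
#' @param reference the [ct_volume()] the mask annotates.
#' @param label `"tumor"` (must be nonempty) or `"rim"`.
#' @return A [segmentation_mask()].
#' @export
read_mask <- function(path, reference, label = "tumor") {
  if (!file.exists(path)) stop("missing file: ", path)
  if (is_nrrd(path)) {
    x <- read_nrrd(path)
    arr <- x$data; sp <- x$spacing
  } else {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    sp <- RNifti::pixdim(img)[1:3]
  }
  if (length(dim(arr)) != 3L) stop("non-3D payload in ", path)
  if (!identical(dim(arr), dim(reference$intensities)))
    stop("grid mismatch: mask shape differs from reference volume")
  if (max(abs(sp - reference$spacing)) > 1e-4)
    stop("grid mismatch: mask spacing differs from reference volume")
  segmentation_mask(arr, reference, label = label)
}

#' @rdname read_mask
#' @param mask a [segmentation_mask()] to write (as 0/1 integers).
#' @export
write_mask <- function(mask, path) {
  write_volume(array(as.integer(mask$voxels), dim = mask$dim), path,
               spacing = mask$spacing)
}

# Minimal NRRD support (3D, attached data, raw or gzip encoding, little
# endian). No installed R package reads NRRD, so this is local plumbing.
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    hdr[[trimws(kv[1])]] <- trimws(kv[2])
  }
  sizes <- as.integer(strsplit(hdr[["sizes"]], "\\s+")[[1]])
  if (as.integer(hdr[["dimension"]]) != 3L || length(sizes) != 3L)
    stop("non-3D payload in ", path)
  spacing <- if (!is.null(hdr[["spacings"]])) {
    as.numeric(strsplit(hdr[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(hdr[["space directions"]])) {
    vecs <- strsplit(gsub("[()]", "", strsplit(hdr[["space directions"]], "\\)\\s*\\(")[[1]]), ",")
    vapply(vecs, function(v) sqrt(sum(as.numeric(v)^2)), numeric(1))
  } else stop("missing spacing metadata in ", path)
  type <- hdr[["type"]]
  enc <- hdr[["encoding"]] %||% "raw"
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.size(path))
  if (enc == "gzip") payload <- memDecompress(payload, type = "gzip")
  what <- switch(type,
                 "double" = "double", "float" = "double",
                 "short" = "integer", "int" = "integer",
                 "unsigned char" = "integer", "uchar" = "integer",
                 stop("unsupported NRRD type: ", type))
  size <- switch(type, "double" = 8L, "float" = 4L, "short" = 2L,
                 "int" = 4L, "unsigned char" = 1L, "uchar" = 1L)
  vals <- readBin(payload, what, n = n, size = size, endian = "little",
                  signed = !(type %in% c("unsigned char", "uchar")))
  if (length(vals) < n) stop("truncated NRRD payload in ", path)
  list(data = array(as.numeric(vals), dim = sizes), spacing = spacing)
}

write_nrrd <- function(arr, spacing, path, type = "double") {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(arr), collapse = " ")),
           paste0("spacings: ", paste(format(spacing, digits = 12), collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  writeLines(hdr, con, sep = "\n")
  if (type == "double") {
    writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  } else if (type == "short") {
    writeBin(as.integer(arr), con, size = 2L, endian = "little")
  } else stop("unsupported NRRD type: ", type)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tables

clinical_columns <- c("patient_id", "os_months", "event", "response",
                      "age", "race", "baseline_tumor_volume_ml")

#' Read and validate a clinical table
#'
#' Expects the fixed columns `patient_id, os_months, event, response, age,
#' race, baseline_tumor_volume_ml`, with `os_months > 0`, `event` in `{0, 1}`
#' and `response` in `{responder, non-responder}`.
#'
#' @param path CSV file path.
#' @return A validated `data.frame`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(tab)
}

validate_clinical <- function(tab) {
  miss <- setdiff(clinical_columns, names(tab))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(tab$os_months)) || any(tab$os_months <= 0))
    stop("os_months must be positive")
  if (!all(tab$event %in% c(0, 1))) stop("event must be 0/1")
  if (!all(tab$response %in% c("responder", "non-responder")))
    stop("response must be 'responder' or 'non-responder'")
  if (anyDuplicated(tab$patient_id)) stop("duplicate patient_id")
  tab
}

#' Write / read a feature table
#'
#' One row per (lesion, timepoint); column order is preserved. Missing values
#' are serialized as empty cells and restored as `NA`.
#'
#' @param table data.frame with `patient_id` and `timepoint` leading columns.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
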