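## ---------------------------------------------------------------------------
## 2D filtering primitives

## Cross-correlation of `img` with `kern` (odd-sized), 'same' output, borders
## handled by symmetric reflection. FFT-based so large Gabor kernels stay cheap.
conv2_reflect <- function(img, kern, correlate = TRUE) {
  k1 <- nrow(kern); k2 <- ncol(kern)
  stopifnot(k1 %% 2 == 1, k2 %% 2 == 1)
  if (correlate) kern <- kern[k1:1, k2:1, drop = FALSE]
  p1 <- (k1 - 1L) / 2L; p2 <- (k2 - 1L) / 2L
  n1 <- nrow(img); n2 <- ncol(img)
  ## symmetric (edge-inclusive) reflection indices; the triangular wave handles
  ## padding wider than the image itself
  reflect_idx <- function(n, p) {
    if (n == 1L) return(rep(1L, n + 2L * p))
    wave <- c(seq_len(n), rev(seq_len(n)))        # period 2n, edge-inclusive
    wave[((seq(1L - p, n + p) - 1L) %% (2L * n)) + 1L]
  }
  P <- img[reflect_idx(n1, p1), reflect_idx(n2, p2), drop = FALSE]
  N1 <- nrow(P) + k1 - 1L; N2 <- ncol(P) + k2 - 1L
  A <- matrix(0, N1, N2); A[seq_len(nrow(P)), seq_len(ncol(P))] <- P
  B <- matrix(0 + 0i, N1, N2); B[seq_len(k1), seq_len(k2)] <- kern
  conv <- stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE) / (N1 * N2)
  out <- conv[k1:(k1 + n1 - 1L), k2:(k2 + n2 - 1L), drop = FALSE]
  if (is.complex(kern)) out else Re(out)
}

#' Laws 5x5 texture kernels
#'
#' The 25 kernels are outer products of the five classical 1D vectors
#' L5 (level), E5 (edge), S5 (spot), R5 (ripple) and W5 (wave).
#'
#' @return Named list of 25 matrices (`L5L5`, `L5E5`, ...).
#' @export
laws_kernels <- function() {
  v <- list(L5 = c(1, 4, 6, 4, 1),
            E5 = c(-1, -2, 0, 2, 1),
            S5 = c(-1, 0, 2, 0, -1),
            R5 = c(1, -4, 6, -4, 1),
            W5 = c(-1, 2, 0, -2, 1))
  out <- list()
  for (a in names(v)) for (b in names(v))
    out[[paste0(a, b)]] <- outer(v[[a]], v[[b]])
  out
}

## Laplacian-of-Gaussian kernel, zero-sum so a constant image maps to zero.
log_kernel <- function(sigma = 1) {
  r <- ceiling(4 * sigma)
  x <- -r:r
  g <- outer(x, x, function(a, b) {
    r2 <- a^2 + b^2
    (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  })
  g - mean(g)
}

#' Gabor filter bank
#'
#' Complex Gabor kernels for `orientations` evenly spaced angles in `[0, pi)`
#' and the given sinusoid wavelengths (pixels), with an isotropic Gaussian
#' envelope of `sigma = 0.56 * wavelength`. Kernels are DC-corrected
#' (envelope-weighted) so the response to a constant image is zero; feature
#' maps use the magnitude of the complex response.
#'
#' @param orientations number of orientations (default 8, steps of pi/8).
#' @param wavelengths sinusoid wavelengths in pixels.
#' @return Named list of complex matrices (`o1w2`, ..., `o8w12`).
#' @export
gabor_kernels <- function(orientations = 8, wavelengths = c(2, 4, 6, 8, 10, 12)) {
  out <- list()
  for (k in seq_len(orientations)) {
    th <- (k - 1) * pi / orientations
    for (wl in wavelengths) {
      sigma <- 0.56 * wl
      r <- max(3L, ceiling(2.5 * sigma))
      x <- -r:r
      X <- matrix(x, length(x), length(x))
      Y <- t(X)
      xr <- X * cos(th) + Y * sin(th)
      yr <- -X * sin(th) + Y * cos(th)
      env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
      g <- env * exp(2i * pi * xr / wl)
      g <- g - (sum(g) / sum(env)) * env
      out[[sprintf("o%dw%d", k, wl)]] <- g
    }
  }
  out
}

## ---------------------------------------------------------------------------
## GLCM and Haralick features

haralick_names <- c("asm", "contrast", "correlation", "variance", "idm",
                    "sum_average", "sum_variance", "sum_entropy", "entropy",
                    "difference_variance", "difference_entropy", "imc1", "imc2")

#' Quantize intensities to equal-width gray levels
#'
#' @param x numeric values; @param levels number of bins; @param range
#'   quantization range (defaults to `range(x)`); a degenerate range maps
#'   everything to level 1.
#' @return Integer levels in `1..levels`.
#' @export
quantize_levels <- function(x, levels, range = NULL) {
  rng <- range %||% range(x, finite = TRUE)
  if (!is.finite(rng[1]) || rng[2] <= rng[1]) return(rep(1L, length(x)))
  q <- floor((x - rng[1]) / (rng[2] - rng[1]) * levels) + 1L
  pmin.int(pmax.int(q, 1L), as.integer(levels))
}

#' Gray-level co-occurrence matrix of a 2D region
#'
#' Counts ordered pairs of quantized intensities at each offset for pixel
#' pairs lying entirely inside the region, optionally symmetrized, and
#' normalizes each offset's counts to probabilities. Intensities are quantized
#' to `levels` equal-width bins over the region's own intensity range.
#'
#' @param slice 2D numeric matrix (HU values).
#' @param region 2D logical matrix, same shape.
#' @param levels gray levels (>= 2).
#' @param offsets list of `(drow, dcol)` displacements.
#' @param symmetric also count each pair in reverse order.
#' @return Object of class `glcm`: `p` (list of probability matrices, one per
#'   offset), `levels`, `offsets`, `symmetric`, `missing` (no valid pair).
#' @export
compute_glcm <- function(slice, region, levels = 64,
                         offsets = list(c(0, 1), c(1, 1), c(1, 0), c(1, -1)),
                         symmetric = TRUE) {
  stopifnot(identical(dim(slice), dim(region)), levels >= 2)
  if (sum(region) < 2) stop("region must contain at least 2 pixels")
  Q <- matrix(NA_integer_, nrow(slice), ncol(slice))
  Q[region] <- quantize_levels(slice[region], levels)
  pmats <- vector("list", length(offsets))
  any_pairs <- FALSE
  n1 <- nrow(Q); n2 <- ncol(Q)
  for (k in seq_along(offsets)) {
    d <- offsets[[k]]
    r0 <- max(1L, 1L - d[1]):min(n1, n1 - d[1])
    c0 <- max(1L, 1L - d[2]):min(n2, n2 - d[2])
    a <- Q[r0, c0, drop = FALSE]
    b <- Q[r0 + d[1], c0 + d[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    cnt <- matrix(0, levels, levels)
    if (any(ok)) {
      tab <- tabulate((a[ok] - 1L) * levels + b[ok], nbins = levels * levels)
      cnt <- matrix(tab, levels, levels, byrow = TRUE)
      if (symmetric) cnt <- cnt + t(cnt)
      any_pairs <- TRUE
    }
    tot <- sum(cnt)
    pmats[[k]] <- if (tot > 0) cnt / tot else cnt
  }
  structure(list(p = pmats, levels = levels, offsets = offsets,
                 symmetric = symmetric, missing = !any_pairs),
            class = "glcm")
}

## The 13 classical Haralick features of one normalized GLCM. Logs are base 2
## with 0*log(0) := 0; correlation and IMC1 fall back to 0 on degenerate
## marginals.
haralick_from_p <- function(iv, jv, pvec, Ng) {
  asm <- sum(pvec^2)
  entropy <- -sum(pvec * log2(pvec))
  px <- drop(rowsum(pvec, iv))
  py <- drop(rowsum(pvec, jv))
  xi <- as.numeric(rownames(rowsum(pvec, iv)))
  yj <- as.numeric(rownames(rowsum(pvec, jv)))
  mux <- sum(xi * px); muy <- sum(yj * py)
  sx <- sqrt(sum((xi - mux)^2 * px)); sy <- sqrt(sum((yj - muy)^2 * py))
  correlation <- if (sx > 0 && sy > 0)
    (sum(iv * jv * pvec) - mux * muy) / (sx * sy) else 0
  variance <- sum((iv - mux)^2 * pvec)
  idm <- sum(pvec / (1 + (iv - jv)^2))
  ps <- drop(rowsum(pvec, iv + jv)); ks <- as.numeric(rownames(rowsum(pvec, iv + jv)))
  sum_average <- sum(ks * ps)
  sum_variance <- sum((ks - sum_average)^2 * ps)
  sum_entropy <- -sum(ps * log2(ps))
  pd <- drop(rowsum(pvec, abs(iv - jv))); kd <- as.numeric(rownames(rowsum(pvec, abs(iv - jv))))
  contrast <- sum(kd^2 * pd)
  difference_variance <- sum((kd - sum(kd * pd))^2 * pd)
  difference_entropy <- -sum(pd * log2(pd))
  hx <- -sum(px * log2(px)); hy <- -sum(py * log2(py))
  lx <- log2(px); names(lx) <- xi
  ly <- log2(py); names(ly) <- yj
  hxy1 <- -sum(pvec * (lx[as.character(iv)] + ly[as.character(jv)]))
  pp <- outer(px, py)
  hxy2 <- -sum(pp * log2(pp))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy, entropy = entropy,
    difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2)
}

#' Haralick features of a GLCM
#'
#' Computes the 13 classical Haralick statistics (angular second moment,
#' contrast, correlation, sum-of-squares variance, inverse difference moment,
#' sum average/variance/entropy, entropy, difference variance/entropy, and the
#' two information measures of correlation) for each offset's probability
#' matrix and averages them over offsets. Logs use base 2 with `0*log 0 := 0`.
#'
#' @param glcm a [compute_glcm()] result.
#' @return Named numeric vector of 13 features (`NA` if the GLCM is flagged
#'   missing).
#' @export
haralick_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  if (glcm$missing)
    return(stats::setNames(rep(NA_real_, 13L), haralick_names))
  per <- lapply(glcm$p, function(P) {
    nz <- which(P > 0)
    if (!length(nz)) return(NULL)
    haralick_from_p(((nz - 1L) %% nrow(P)) + 1L, ((nz - 1L) %/% nrow(P)) + 1L,
                    P[nz], nrow(P))
  })
  per <- per[!vapply(per, is.null, logical(1))]
  stats::setNames(colMeans(do.call(rbind, per)), haralick_names)
}

## ---------------------------------------------------------------------------
## Response maps (one 2D map per filter, NA outside the region)

restrict_map <- function(m, region) {
  m[!region] <- NA_real_
  m
}

#' Laws, Laws-Laplacian and Gabor response maps of one slice
#'
#' `laws_response_maps()` correlates the slice with the 25 Laws 5x5 kernels;
#' `laws_laplacian_maps()` first smooths the slice with a Laplacian-of-Gaussian
#' (`sigma` = 1 pixel); `gabor_response_maps()` returns the magnitude of the
#' complex Gabor responses. Borders are handled by reflection; maps are
#' restricted to region pixels (NA elsewhere).
#'
#' @param slice 2D numeric matrix.
#' @param region 2D logical matrix.
#' @return Named list of response matrices.
#' @export
laws_response_maps <- function(slice, region) {
  stopifnot(any(region))
  lapply(laws_kernels(), function(k) restrict_map(conv2_reflect(slice, k), region))
}

#' @rdname laws_response_maps
#' @param sigma Gaussian scale (pixels) of the Laplacian-of-Gaussian prefilter.
#' @export
laws_laplacian_maps <- function(slice, region, sigma = 1) {
  stopifnot(any(region))
  sm <- conv2_reflect(slice, log_kernel(sigma))
  lapply(laws_kernels(), function(k) restrict_map(conv2_reflect(sm, k), region))
}

#' @rdname laws_response_maps
#' @param bank a [gabor_kernels()] list (built with defaults if omitted).
#' @export
gabor_response_maps <- function(slice, region, bank = gabor_kernels()) {
  stopifnot(any(region))
  lapply(bank, function(k) restrict_map(Mod(conv2_reflect(slice, k)), region))
}

#' Per-pixel Haralick response maps of one slice
#'
#' For every region pixel, a local GLCM is accumulated from the quantized
#' intensity pairs (all offsets pooled, symmetrized) whose first pixel falls
#' inside a `window` x `window` neighbourhood of that pixel and whose both
#' pixels lie in the region; the 13 Haralick statistics of that local GLCM
#' give the 13 map values. Quantization uses `levels` equal-width bins over
#' the region's intensity range.
#'
#' @inheritParams compute_glcm
#' @param window odd window side length in pixels.
#' @return Named list of 13 response matrices (NA outside the region).
#' @export
haralick_response_maps <- function(slice, region, levels = 64, window = 5,
                                   offsets = list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))) {
  stopifnot(identical(dim(slice), dim(region)), window %% 2 == 1)
  n1 <- nrow(slice); n2 <- ncol(slice)
  Q <- matrix(NA_integer_, n1, n2)
  if (any(region)) Q[region] <- quantize_levels(slice[region], levels)
  ## per-offset code matrices located at the pair's first pixel; the symmetric
  ## counterpart is a second code
  codes <- list()
  for (d in offsets) {
    a <- Q
    b <- matrix(NA_integer_, n1, n2)
    r0 <- max(1L, 1L - d[1]):min(n1, n1 - d[1])
    c0 <- max(1L, 1L - d[2]):min(n2, n2 - d[2])
    b[r0, c0] <- Q[r0 + d[1], c0 + d[2]]
    ok <- !is.na(a) & !is.na(b)
    cf <- matrix(NA_real_, n1, n2); cr <- matrix(NA_real_, n1, n2)
    cf[ok] <- (a[ok] - 1) * levels + b[ok]
    cr[ok] <- (b[ok] - 1) * levels + a[ok]
    codes <- c(codes, list(cf, cr))
  }
  centers <- which(region, arr.ind = TRUE)
  w <- (window - 1L) / 2L
  disp <- expand.grid(dr = -w:w, dc = -w:w)
  ## gather: one column per (displacement, code matrix)
  gather <- matrix(NA_real_, nrow(centers), nrow(disp) * length(codes))
  col <- 0L
  for (i in seq_len(nrow(disp))) {
    rr <- centers[, 1] + disp$dr[i]
    cc <- centers[, 2] + disp$dc[i]
    inb <- rr >= 1 & rr <= n1 & cc >= 1 & cc <= n2
    idx <- ifelse(inb, (cc - 1L) * n1 + rr, NA_integer_)
    for (cm in codes) {
      col <- col + 1L
      gather[inb, col] <- cm[idx[inb]]
    }
  }
  maps <- lapply(haralick_names, function(nm) matrix(NA_real_, n1, n2))
  names(maps) <- haralick_names
  vals <- matrix(NA_real_, nrow(centers), 13L)
  for (r in seq_len(nrow(centers))) {
    g <- gather[r, ]
    g <- g[!is.na(g)]
    if (!length(g)) next
    vals[r, ] <- haralick_from_pairs(g, levels)
  }
  cidx <- (centers[, 2] - 1L) * n1 + centers[, 1]
  for (k in 1:13) maps[[k]][cidx] <- vals[, k]
  maps
}

## Fast Haralick from the multiset of symmetrized pair codes of one local
## window (code = (a-1)*Ng + b, both directions present). Exploits symmetry:
## px == py, HXY2 = HX + HY. Agrees with haralick_from_p (tested).
haralick_from_pairs <- function(g, Ng) {
  N <- length(g)
  a <- ((g - 1) %/% Ng) + 1
  b <- ((g - 1) %% Ng) + 1
  cc <- rle(sort.int(g))$lengths
  q <- cc / N
  asm <- sum(q^2)
  entropy <- -sum(q * log2(q))
  px <- tabulate(a, Ng) / N
  ii <- seq_len(Ng)
  mux <- sum(ii * px)
  vx <- sum((ii - mux)^2 * px)
  sx <- sqrt(vx)
  correlation <- if (sx > 0) (sum(a * b) / N - mux^2) / vx else 0
  variance <- vx
  dif <- abs(a - b)
  pdiff <- tabulate(dif + 1L, Ng) / N        # index k+1 <-> |i-j| = k
  kd <- 0:(Ng - 1)
  contrast <- sum(kd^2 * pdiff)
  difference_variance <- sum((kd - sum(kd * pdiff))^2 * pdiff)
  nzd <- pdiff > 0
  difference_entropy <- -sum(pdiff[nzd] * log2(pdiff[nzd]))
  idm <- sum(pdiff / (1 + kd^2))
  psum <- tabulate(a + b - 1L, 2 * Ng - 1) / N  # index k-1 <-> i+j = k
  ks <- 2:(2 * Ng)
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  nzs <- psum > 0
  sum_entropy <- -sum(psum[nzs] * log2(psum[nzs]))
  nzp <- px > 0
  hx <- -sum(px[nzp] * log2(px[nzp]))
  lpx <- rep(0, Ng); lpx[nzp] <- log2(px[nzp])
  hxy1 <- -(sum(lpx[a]) + sum(lpx[b])) / N
  hxy2 <- 2 * hx
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm, contrast, correlation, variance, idm, sum_average, sum_variance,
    sum_entropy, entropy, difference_variance, difference_entropy, imc1, imc2)
}

## ---------------------------------------------------------------------------
## Region summaries and the full texture vector

texture_filter_names <- function(gabor_orientations = 8,
                                 gabor_wavelengths = c(2, 4, 6, 8, 10, 12)) {
  laws <- names(laws_kernels())
  gab <- names(gabor_kernels(gabor_orientations, gabor_wavelengths))
  c(paste0("haralick_", haralick_names),
    paste0("laws_", laws),
    paste0("lawslap_", laws),
    paste0("gabor_", gab))
}

#' Five first-order statistics of pooled response values
#'
#' Summarizes each response map's pooled per-pixel values (across all
#' annotated slices) by mean, median, SD (n-1), skewness and excess kurtosis;
#' a zero-variance map has skewness and kurtosis 0 by convention. An empty
#' pool yields `NA` entries.
#'
#' @param pooled named list of numeric vectors (one per filter).
#' @param region region label appended to the feature names.
#' @return Named numeric vector, `5 * length(pooled)` entries named
#'   `{filter}_{stat}_{region}`.
#' @export
summarize_region <- function(pooled, region) {
  out <- lapply(names(pooled), function(nm) {
    s <- first_order_stats(pooled[[nm]])
    stats::setNames(s, paste(nm, names(s), region, sep = "_"))
  })
  unlist(out)
}

## Pool per-pixel responses of all 111 filters across the annotated slices of
## one or more regions. Convolution maps (Laws, Laws-Laplacian, Gabor) depend
## only on the slice and are computed once and shared across regions; the
## local Haralick maps are region-specific (region-range quantization, pairs
## restricted to the region) and are computed per region.
pool_region_responses <- function(volume, masks, glcm_levels, window, bank) {
  filt <- c(paste0("haralick_", haralick_names),
            paste0("laws_", names(laws_kernels())),
            paste0("lawslap_", names(laws_kernels())),
            paste0("gabor_", names(bank)))
  if (inherits(masks, "seg_mask")) masks <- list(region = masks)
  pooled <- lapply(masks, function(m)
    stats::setNames(vector("list", length(filt)), filt))
  any_slice <- Reduce(`|`, lapply(masks, function(m) apply(m$voxels, 3, any)))
  lkern <- laws_kernels()
  logk <- log_kernel(1)
  for (z in which(any_slice)) {
    sl <- volume$intensities[, , z]
    sm <- conv2_reflect(sl, logk)
    conv_maps <- c(
      stats::setNames(lapply(lkern, function(k) conv2_reflect(sl, k)),
                      paste0("laws_", names(lkern))),
      stats::setNames(lapply(lkern, function(k) conv2_reflect(sm, k)),
                      paste0("lawslap_", names(lkern))),
      stats::setNames(lapply(bank, function(k) Mod(conv2_reflect(sl, k))),
                      paste0("gabor_", names(bank))))
    for (rn in names(masks)) {
      reg <- masks[[rn]]$voxels[, , z]
      if (!any(reg)) next
      sel <- which(reg)
      hm <- haralick_response_maps(sl, reg, levels = glcm_levels,
                                   window = window)
      for (nm in names(hm)) {
        key <- paste0("haralick_", nm)
        pooled[[rn]][[key]] <- c(pooled[[rn]][[key]], hm[[nm]][sel])
      }
      for (key in names(conv_maps))
        pooled[[rn]][[key]] <- c(pooled[[rn]][[key]], conv_maps[[key]][sel])
    }
  }
  pooled
}

#' Extract the full texture feature vector of one scan
#'
#' Runs all 111 texture filters (13 local Haralick, 25 Laws, 25
#' Laws-Laplacian, 48 Gabor) slice by slice over every annotated slice,
#' pools per-pixel responses within the tumor and within the peritumoral rim,
#' and summarizes each map by five first-order statistics: 555 named values
#' per region, 1110 in total. A flagged-empty rim yields `NA` rim entries.
#'
#' @param volume a [ct_volume()].
#' @param regions a [extract_peritumoral_rim()] region pair.
#' @param glcm_levels gray levels for the local Haralick maps.
#' @param window local GLCM window (pixels, odd).
#' @param gabor_orientations,gabor_wavelengths Gabor bank settings.
#' @return Named numeric vector of 1110 texture statistics with a
#'   `settings_hash` attribute recording the filter configuration.
#' @export
extract_texture_features <- function(volume, regions, glcm_levels = 64,
                                     window = 5, gabor_orientations = 8,
                                     gabor_wavelengths = c(2, 4, 6, 8, 10, 12)) {
  stopifnot(inherits(volume, "ct_volume"), inherits(regions, "region_pair"))
  bank <- gabor_kernels(gabor_orientations, gabor_wavelengths)
  masks <- list(tumor = regions$tumor)
  if (!regions$rim_empty) masks$rim <- regions$rim
  pooled <- pool_region_responses(volume, masks, glcm_levels, window, bank)
  tum <- summarize_region(pooled$tumor, "tumor")
  if (regions$rim_empty) {
    filt <- texture_filter_names(gabor_orientations, gabor_wavelengths)
    nms <- as.vector(t(outer(filt, c("mean", "median", "sd", "skewness", "kurtosis"),
                             paste, sep = "_")))
    rim <- stats::setNames(rep(NA_real_, length(nms)), paste(nms, "rim", sep = "_"))
  } else {
    rim <- summarize_region(pooled$rim, "rim")
  }
  out <- c(tum, rim)
  attr(out, "settings_hash") <- config_hash(list(
    glcm_levels = glcm_levels, window = window,
    gabor_orientations = gabor_orientations,
    gabor_wavelengths = gabor_wavelengths))
  out
}

#' Per-slice heatmap volume of one texture filter
#'
#' Computes one named filter's response map on every annotated slice and
#' returns it as a 3D array (NA outside the region), suitable for
#' [write_volume()] as an overlay.
#'
#' @param volume a [ct_volume()]; @param mask a [segmentation_mask()].
#' @param filter_name one of the 111 filter identifiers, e.g.
#'   `"haralick_entropy"`, `"laws_L5E5"`, `"gabor_o1w4"`.
#' @inheritParams extract_texture_features
#' @return 3D numeric array.
#' @export
texture_heatmap <- function(volume, mask, filter_name, glcm_levels = 64,
                            window = 5) {
  out <- array(NA_real_, dim = dim(volume$intensities))
  fam <- sub("_.*", "", filter_name)
  id <- sub("^[a-z]+_", "", filter_name)
  zs <- which(apply(mask$voxels, 3, any))
  for (z in zs) {
    sl <- volume$intensities[, , z]
    reg <- mask$voxels[, , z]
    m <- switch(fam,
      haralick = haralick_response_maps(sl, reg, levels = glcm_levels,
                                        window = window)[[id]],
      laws = laws_response_maps(sl, reg)[[id]],
      lawslap = laws_laplacian_maps(sl, reg)[[id]],
      gabor = gabor_response_maps(sl, reg)[[id]],
      stop("unknown filter family: ", fam))
    if (is.null(m)) stop("unknown filter: ", filter_name)
    out[, , z] <- m
  }
  out
}
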