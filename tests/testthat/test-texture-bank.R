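test_that("GLCM equals the brute-force pair-enumeration oracle", {
  set.seed(101)
  offsets <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (i in 1:100) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    sl <- matrix(sample(0:80, nr * nc, replace = TRUE), nr, nc)
    reg <- matrix(runif(nr * nc) < 0.8, nr, nc)
    if (sum(reg) < 2) reg[1:2] <- TRUE
    lev <- sample(2:8, 1)
    g <- compute_glcm(sl, reg, levels = lev, offsets = offsets)
    for (k in seq_along(offsets)) {
      expect_equal(g$p[[k]], glcm_oracle(sl, reg, lev, offsets[[k]]),
                   tolerance = 1e-12)
      if (sum(g$p[[k]]) > 0) expect_equal(sum(g$p[[k]]), 1)
      expect_equal(g$p[[k]], t(g$p[[k]]))  # symmetrized
    }
  }
})

test_that("GLCM worked examples match hand enumeration", {
  ## 2x2 region [[1,1],[1,2]], 2 levels, offset (0,1), symmetric
  sl <- matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE)
  g <- compute_glcm(sl, matrix(TRUE, 2, 2), levels = 2, offsets = list(c(0, 1)))
  expect_equal(g$p[[1]], matrix(c(0.5, 0.25, 0.25, 0), 2, 2))

  ## two-level vertical stripes, horizontal offset: all mass off-diagonal
  stripes <- matrix(c(10, 20), 4, 4, byrow = TRUE)  # columns alternate
  gs <- compute_glcm(stripes, matrix(TRUE, 4, 4), levels = 2,
                     offsets = list(c(0, 1)))
  expect_equal(sum(diag(gs$p[[1]])), 0)
  expect_equal(sum(gs$p[[1]]), 1)

  ## constant region: single nonzero entry with probability 1
  gc <- compute_glcm(matrix(7, 3, 3), matrix(TRUE, 3, 3), levels = 4,
                     offsets = list(c(0, 1)))
  expect_equal(gc$p[[1]][1, 1], 1)
  expect_equal(sum(gc$p[[1]] != 0), 1L)
})

test_that("Haralick closed forms hold", {
  ## single-entry GLCM: entropy 0, ASM 1; constant slice: contrast 0
  g <- compute_glcm(matrix(5, 4, 4), matrix(TRUE, 4, 4), levels = 8)
  h <- haralick_features(g)
  expect_equal(unname(h["entropy"]), 0)
  expect_equal(unname(h["asm"]), 1)
  expect_equal(unname(h["contrast"]), 0)

  ## uniform GLCM over Ng^2 entries: entropy = 2 log2(Ng), maximal
  for (ng in c(2, 4, 8)) {
    gu <- structure(list(p = list(matrix(1 / ng^2, ng, ng)), levels = ng,
                         offsets = list(c(0, 1)), symmetric = TRUE,
                         missing = FALSE), class = "glcm")
    hu <- haralick_features(gu)
    expect_equal(unname(hu["entropy"]), 2 * log2(ng))
  }

  ## entropy is non-negative and bounded by the uniform value
  set.seed(7)
  sl <- matrix(sample(0:50, 36, TRUE), 6, 6)
  hr <- haralick_features(compute_glcm(sl, matrix(TRUE, 6, 6), levels = 4))
  expect_gte(unname(hr["entropy"]), 0)
  expect_lte(unname(hr["entropy"]), 2 * log2(4))
})

test_that("fast per-pixel Haralick agrees with the reference on one GLCM", {
  set.seed(2)
  ng <- 8
  codes <- sample(ng * ng, 300, replace = TRUE)
  codes <- c(codes, (((codes - 1) %% ng)) * ng + ((codes - 1) %/% ng) + 1)
  fast <- deltarad:::haralick_from_pairs(codes, ng)
  cnt <- tabulate(codes, ng * ng)
  nz <- which(cnt > 0)
  ref <- deltarad:::haralick_from_p(((nz - 1) %/% ng) + 1,
                                    ((nz - 1) %% ng) + 1,
                                    cnt[nz] / sum(cnt), ng)
  expect_equal(unname(fast), unname(ref), tolerance = 1e-12)
})

test_that("Laws kernels: 25 distinct kernels with the stated structure", {
  lk <- laws_kernels()
  expect_length(lk, 25L)
  expect_false(any(duplicated(lapply(lk, as.vector))))
  expect_equal(sum(lk$L5L5), 256)   # (sum L5)^2 = 16^2
  ## all non-L5L5-rows/cols have a zero-sum factor -> zero response on constants
  const <- matrix(3, 16, 16)
  lm <- laws_response_maps(const, matrix(TRUE, 16, 16))
  expect_length(lm, 25L)
  for (nm in setdiff(names(lm), "L5L5"))
    expect_lt(max(abs(lm[[nm]])), 1e-9)
})

test_that("Laws-Laplacian maps vanish on constants and commute with Laws", {
  const <- matrix(42, 16, 16)
  ll <- laws_laplacian_maps(const, matrix(TRUE, 16, 16))
  expect_length(ll, 25L)
  expect_lt(max(vapply(ll, function(m) max(abs(m)), numeric(1))), 1e-9)

  ## LoG then Laws equals Laws then LoG on interior pixels
  set.seed(10)
  img <- matrix(rnorm(32 * 32, 50, 10), 32, 32)
  reg <- matrix(TRUE, 32, 32)
  a <- deltarad:::conv2_reflect(deltarad:::conv2_reflect(img, deltarad:::log_kernel(1)),
                                laws_kernels()$E5S5)
  b <- deltarad:::conv2_reflect(deltarad:::conv2_reflect(img, laws_kernels()$E5S5),
                                deltarad:::log_kernel(1))
  inner <- 8:25
  expect_equal(a[inner, inner], b[inner, inner], tolerance = 1e-8)
})

test_that("Gabor bank: 48 maps, zero on constants, orientations permute under rotation", {
  bank <- gabor_kernels()
  expect_length(bank, 48L)
  const <- matrix(-5, 24, 24)
  gm <- gabor_response_maps(const, matrix(TRUE, 24, 24), bank = bank)
  expect_length(gm, 48L)
  expect_lt(max(vapply(gm, max, numeric(1))), 1e-9)

  ## a grating rotated by 90 degrees excites the orientation 4 steps away
  n <- 33
  x <- matrix(seq_len(n), n, n)
  grating <- sin(2 * pi * x / 8)            # varies along rows
  rot <- t(grating)[, n:1]                  # 90-degree rotation
  reg <- matrix(TRUE, n, n)
  g1 <- gabor_response_maps(grating, reg, bank = bank)
  g2 <- gabor_response_maps(rot, reg, bank = bank)
  ctr <- 14:20
  for (k in c(1, 3, 6)) {
    k90 <- ((k - 1 + 4) %% 8) + 1
    m1 <- g1[[sprintf("o%dw8", k)]][ctr, ctr]
    m2 <- g2[[sprintf("o%dw8", k90)]][ctr, ctr]
    expect_equal(mean(m1), mean(m2), tolerance = 1e-6)
  }
})

test_that("filter responses are translation-equivariant on interior pixels", {
  set.seed(20)
  img <- matrix(rnorm(40 * 40, 50, 8), 40, 40)
  sh <- rbind(img[4:40, ], matrix(0, 3, 40))  # shift up by 3
  ## regions cover the same pixel multiset so quantization ranges match
  reg1 <- matrix(FALSE, 40, 40); reg1[4:40, ] <- TRUE
  reg2 <- matrix(FALSE, 40, 40); reg2[1:37, ] <- TRUE
  inner <- 12:26
  lm1 <- laws_response_maps(img, reg1)$E5E5
  lm2 <- laws_response_maps(sh, reg2)$E5E5
  expect_equal(lm1[inner + 3, inner], lm2[inner, inner], tolerance = 1e-8)
  gm1 <- gabor_response_maps(img, reg1)$o1w4
  gm2 <- gabor_response_maps(sh, reg2)$o1w4
  expect_equal(gm1[inner + 3, inner], gm2[inner, inner], tolerance = 1e-6)
  hm1 <- haralick_response_maps(img, reg1, levels = 8)$entropy
  hm2 <- haralick_response_maps(sh, reg2, levels = 8)$entropy
  expect_equal(hm1[inner + 3, inner], hm2[inner, inner], tolerance = 1e-10)
})

test_that("summary statistics follow the stated conventions", {
  s <- summarize_region(list(f = c(1, 2, 3)), "tumor")
  expect_equal(unname(s["f_mean_tumor"]), 2)
  expect_equal(unname(s["f_median_tumor"]), 2)
  expect_equal(unname(s["f_sd_tumor"]), 1)

  cs <- summarize_region(list(f = rep(4.5, 10)), "rim")
  expect_equal(unname(cs["f_mean_rim"]), 4.5)
  expect_equal(unname(cs["f_sd_rim"]), 0)
  expect_equal(unname(cs["f_skewness_rim"]), 0)
  expect_equal(unname(cs["f_kurtosis_rim"]), 0)

  es <- summarize_region(list(f = numeric(0)), "rim")
  expect_true(all(is.na(es)))
})

test_that("the full texture vector has the printed structure: 111 filters x 5 stats x 2 regions", {
  p <- small_phantom(seed = 13)
  rp <- extract_peritumoral_rim(p$volume, p$mask)
  fv <- extract_texture_features(p$volume, rp)
  expect_length(fv, 1110L)
  expect_equal(sum(grepl("_tumor$", names(fv))), 555L)
  expect_equal(sum(grepl("_rim$", names(fv))), 555L)
  expect_equal(sum(grepl("^haralick_", names(fv))), 13L * 5L * 2L)
  expect_equal(sum(grepl("^laws_", names(fv))), 25L * 5L * 2L)
  expect_equal(sum(grepl("^lawslap_", names(fv))), 25L * 5L * 2L)
  expect_equal(sum(grepl("^gabor_", names(fv))), 48L * 5L * 2L)
  expect_false(any(is.na(fv)))

  ## determinism: identical volumes give identical vectors
  fv2 <- extract_texture_features(p$volume, rp)
  expect_identical(fv, fv2)

  ## empty rim: rim entries flagged missing, never zero
  full <- array(TRUE, c(10, 10, 4))
  v <- ct_volume(array(50, c(10, 10, 4)), c(1, 1, 1))
  m <- segmentation_mask(full, v, label = "tumor")
  rp0 <- suppressWarnings(extract_peritumoral_rim(v, m))
  fv0 <- extract_texture_features(v, rp0)
  expect_length(fv0, 1110L)
  expect_true(all(is.na(fv0[grepl("_rim$", names(fv0))])))
})

test_that("higher planted heterogeneity raises tumor Haralick entropy", {
  cfg_lo <- small_cohort_config(seed = 17, amp_pre_range = c(2, 2))
  cfg_hi <- small_cohort_config(seed = 17, amp_pre_range = c(12, 12))
  ent <- vapply(list(cfg_lo, cfg_hi), function(cfg) {
    p <- generate_phantom(cfg, 1, "pre")
    rp <- extract_peritumoral_rim(p$volume, p$mask)
    pooled <- deltarad:::pool_region_responses(
      p$volume, list(tumor = rp$tumor), 64, 5, gabor_kernels(1, 4))
    mean(pooled$tumor$haralick_entropy)
  }, numeric(1))
  expect_gt(ent[2], ent[1])
})

test_that("texture heatmaps export one filter's map over annotated slices", {
  p <- small_phantom(seed = 23)
  hm <- texture_heatmap(p$volume, p$mask, "haralick_entropy")
  expect_equal(dim(hm), dim(p$volume$intensities))
  expect_true(all(is.na(hm[!p$mask$voxels])))
  expect_true(all(is.finite(hm[p$mask$voxels])))
  expect_true(all(hm[p$mask$voxels] >= 0))      # entropy is non-negative
  lw <- texture_heatmap(p$volume, p$mask, "laws_L5E5")
  expect_true(all(is.finite(lw[p$mask$voxels])))
  expect_error(texture_heatmap(p$volume, p$mask, "bogus_x"), "unknown filter")
  ## writable as a NIfTI overlay (NA outside the region becomes NaN on disk)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  hm0 <- hm; hm0[is.na(hm0)] <- 0
  write_volume(hm0, path, spacing = p$volume$spacing)
  expect_equal(read_volume(path)$intensities, hm0, ignore_attr = TRUE,
               tolerance = 1e-6)
})
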