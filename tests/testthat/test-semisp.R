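test_that("lesion_bbox is the tight inclusive box (0-based)", {
  m <- matrix(0, 128, 128)
  m[101, 41] <- 1  # 0-based (100, 40)
  expect_equal(unname(lesion_bbox(lesion_mask(m))), c(100, 40, 100, 40))

  m2 <- matrix(0, 64, 64)
  m2[11:20, 31:50] <- 1  # 0-based rows 10..19, cols 30..49
  expect_equal(unname(lesion_bbox(lesion_mask(m2))), c(10, 30, 19, 49))

  expect_error(lesion_bbox(lesion_mask(matrix(0, 8, 8))), "no foreground")
})

test_that("lesion_bbox equals the exhaustive foreground scan", {
  for (seed in 1:8) {
    m <- make_blob_mask(48, 56, seed)
    expect_equal(unname(lesion_bbox(m)), unname(oracle_bbox(m)))
  }
})

test_that("square ROI side follows the maximal extent and the scale factor", {
  m <- matrix(0, 100, 100)
  m[11:20, 31:50] <- 1  # 10 rows x 20 cols
  r1 <- square_roi(m, c(100, 100), 1)
  expect_equal(r1$side, 20)
  expect_equal(square_roi(m, c(100, 100), 2)$side, 40)
  expect_equal(square_roi(m, c(100, 100), 3)$side, 60)
  expect_equal(r1$center_row, (10 + 19) %/% 2)
  expect_equal(r1$center_col, (30 + 49) %/% 2)

  tiny <- matrix(0, 32, 32)
  tiny[5, 5] <- 1
  expect_equal(square_roi(tiny, c(32, 32), 1)$side, 8)  # floor clamp
})

test_that("square ROI is translation-equivariant with unchanged side", {
  base <- matrix(0, 80, 80)
  base[21:28, 31:42] <- 1
  r0 <- square_roi(base, c(80, 80), 1)
  for (shift in list(c(5, 3), c(-7, 11), c(14, -9))) {
    m <- matrix(0, 80, 80)
    m[21:28 + shift[1], 31:42 + shift[2]] <- 1
    r <- square_roi(m, c(80, 80), 1)
    expect_equal(r$side, r0$side)
    expect_equal(r$center_row, r0$center_row + shift[1])
    expect_equal(r$center_col, r0$center_col + shift[2])
  }
})

test_that("crop_resize matches the direct bilinear oracle on small inputs", {
  p <- matrix(c(0.1, 0.9, 0.4, 0.3, 0.7, 0.2, 0.8, 0.5, 0.6), 3, 3)
  expect_equal(sffnet:::cpp_resize_bilinear(p, 6, 6), oracle_bilinear(p, 6, 6),
               tolerance = 1e-12)
  set.seed(7)
  for (n in c(2, 4, 5, 8)) {
    img <- matrix(runif(n * n), n, n)
    for (out in c(3, 7, 16)) {
      expect_lt(max(abs(sffnet:::cpp_resize_bilinear(img, out, out) -
                        oracle_bilinear(img, out, out))), 1e-6)
    }
  }
})

test_that("crop_resize is the identity at native size and constant-preserving", {
  const <- image_slice(matrix(0.42, 300, 300))
  m <- matrix(0, 300, 300)
  m[40:80, 60:100] <- 1
  roi <- square_roi(m, c(300, 300))
  expect_lt(max(abs(crop_resize(const, roi) - 0.42)), 1e-12)

  set.seed(1)
  img <- matrix(runif(300 * 300), 300, 300)
  m224 <- matrix(0, 300, 300)
  m224[31:254, 41:264] <- 1  # extent exactly 224, interior
  roi224 <- square_roi(m224, c(300, 300))
  expect_equal(roi224$side, 224)
  got <- crop_resize(img, roi224)
  expect_equal(got, img[31:254, 41:264], tolerance = 1e-12)
})

test_that("out-of-bounds squares are zero-padded before resizing", {
  img <- matrix(1, 64, 64)
  m <- matrix(0, 64, 64)
  m[1:10, 1:10] <- 1
  roi <- square_roi(m, c(64, 64), 3)  # side 30 centered at (4,4): leaves image
  patch <- crop_resize(img, roi, 30)  # native side: no interpolation
  expect_equal(dim(patch), c(30, 30))
  expect_true(any(patch == 0))   # padded region
  expect_true(any(patch == 1))   # image region
})

test_that("CLAHE keeps range, boosts step contrast, and leaves flats alone", {
  const <- matrix(0.37, 224, 224)
  expect_identical(clahe_enhance(const), const)

  # a pure two-level step is a degenerate near-identity case for CLAHE;
  # its output spread is frozen as a regression value for the defaults
  step <- cbind(matrix(0.3, 224, 112), matrix(0.7, 224, 112))
  expect_equal(sd(clahe_enhance(step)), 0.199000, tolerance = 1e-4)
  # contrast genuinely increases on a low-contrast textured patch
  set.seed(5)
  tex <- matrix(runif(224 * 224, 0.4, 0.6), 224, 224)
  expect_gt(sd(clahe_enhance(tex)), sd(tex))
  expect_equal(sd(clahe_enhance(tex)), 0.112939, tolerance = 1e-4)

  set.seed(11)
  noisy <- matrix(runif(224 * 224), 224, 224)
  enh <- clahe_enhance(noisy)
  expect_gte(min(enh), 0)
  expect_lte(max(enh), 1)
  expect_identical(clahe_enhance(noisy), enh)  # deterministic

  expect_error(clahe_enhance(noisy, clip_limit = 0), "positive")
  expect_error(clahe_enhance(noisy, clip_limit = -1), "positive")
})

test_that("every strategy yields a 224x224 patch in [0, 1]", {
  ts <- toy_slice(300, 280)
  for (strat in c("semi_sp", "double", "triple", "whole_image", "lesion_only")) {
    p <- apply_strategy(ts$slice, ts$mask, strat)
    expect_equal(dim(p$pixels), c(224L, 224L))
    expect_gte(min(p$pixels), 0)
    expect_lte(max(p$pixels), 1)
    expect_equal(p$strategy, strat)
    expect_equal(p$provenance$lesion_id, "L1")
  }
})

test_that("whole_image resizes the full slice without CLAHE", {
  set.seed(3)
  img <- matrix(runif(512 * 448), 512, 448)
  sl <- image_slice(img, "P9", "L9", 2L, "MF-ICC")
  p <- apply_strategy(sl, NULL, "whole_image")
  expect_equal(dim(p$pixels), c(224L, 224L))
  expect_equal(p$provenance$strategy, "whole_image")
  expect_null(p$provenance$clahe)
  expect_equal(p$pixels, sffnet:::cpp_resize_bilinear(img, 224, 224))
})

test_that("lesion_only zeroes everything outside the mask before resizing", {
  ts <- toy_slice(300, 300, 40, 80, 60, 100)
  masked <- ts$slice$pixels * ts$mask$pixels
  roi <- square_roi(ts$mask, c(300, 300))
  crop <- crop_resize(masked, roi, roi$side)  # native side: no blending
  r0 <- roi$center_row - (roi$side - 1) %/% 2
  c0 <- roi$center_col - (roi$side - 1) %/% 2
  submask <- ts$mask$pixels[r0 + seq_len(roi$side), c0 + seq_len(roi$side)]
  expect_true(all(crop[submask == 0] == 0))
  # and the packaged strategy output agrees with the same pipeline + CLAHE
  p <- apply_strategy(ts$slice, ts$mask, "lesion_only")
  expect_equal(p$pixels, clahe_enhance(crop_resize(masked, roi)))
})

test_that("mask-requiring strategies refuse a missing mask", {
  ts <- toy_slice()
  expect_error(apply_strategy(ts$slice, NULL, "semi_sp"), "mask")
  expect_error(apply_strategy(ts$slice, NULL, "lesion_only"), "mask")
})

test_that("ROI geometry follows the lesion diameter in a phantom", {
  # a 41-pixel-diameter disc: bbox extent 41, so the Semi-SP side is 41
  m <- matrix(0, 128, 128)
  for (i in 1:128) for (j in 1:128)
    if ((i - 64)^2 + (j - 64)^2 <= 20^2) m[i, j] <- 1
  sl <- image_slice(matrix(0.5, 128, 128))
  p <- apply_strategy(sl, lesion_mask(m), "semi_sp")
  expect_equal(p$provenance$roi$side, 41)
})
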