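# Semi-segmented preprocessing (Semi-SP) and the alternative ROI strategies
# it is compared against: a square ROI sized by the maximal lesion extent
# (the lesion's maximum diameter, operationalized as the larger side of the
# tight bounding box), cropped with zero padding where the square leaves the
# image, rescaled to 224x224 by bilinear interpolation, and contrast-
# enhanced with CLAHE to sharpen lesion edges.
#
# Coordinate convention: row-major, 0-based, inclusive bounding-box bounds;
# recorded as such in every patch's provenance.

PATCH_SIZE <- 224L

#' Tight bounding box of a lesion mask
#'
#' @param mask A [lesion_mask()] or a binary matrix.
#' @return Integer vector `c(row_min, col_min, row_max, col_max)`, 0-based,
#'   inclusive.
#' @export
lesion_bbox <- function(mask) {
  m <- if (inherits(mask, "lesion_mask")) mask$pixels else mask
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("mask has no foreground pixels")
  c(row_min = min(idx[, 1]) - 1L, col_min = min(idx[, 2]) - 1L,
    row_max = max(idx[, 1]) - 1L, col_max = max(idx[, 2]) - 1L)
}

#' Square ROI from the lesion extent
#'
#' The square's side is `ceiling(scale_factor * lesion_extent)` where
#' `lesion_extent` is the larger of the bounding-box height and width (the
#' axis-aligned maximum diameter), clamped below at `min_side`; its center
#' is the integer midpoint of the bounding box. The square may extend beyond
#' the image; cropping handles the padding.
#'
#' @param mask A [lesion_mask()] or binary matrix.
#' @param image_shape `c(height, width)` of the parent image.
#' @param scale_factor Side multiplier (1 for Semi-SP, 2/3 for the enlarged
#'   comparison strategies).
#' @param min_side Smallest admissible side, pixels.
#' @return A list of class `square_roi` with `center_row`, `center_col`
#'   (0-based), `side`, and `scale_factor`.
#' @export
square_roi <- function(mask, image_shape, scale_factor = 1, min_side = 8L) {
  stopifnot(scale_factor >= 1, min_side >= 1)
  bb <- lesion_bbox(mask)
  extent <- max(bb["row_max"] - bb["row_min"] + 1,
                bb["col_max"] - bb["col_min"] + 1)
  side <- max(as.integer(ceiling(scale_factor * extent)), as.integer(min_side))
  structure(list(
    center_row = as.integer((bb["row_min"] + bb["row_max"]) %/% 2),
    center_col = as.integer((bb["col_min"] + bb["col_max"]) %/% 2),
    side = side,
    scale_factor = scale_factor,
    lesion_extent = as.integer(extent),
    image_shape = as.integer(image_shape)
  ), class = "square_roi")
}

#' Crop a square ROI and rescale it to a fixed size
#'
#' The square `[r0, r0 + side)` x `[c0, c0 + side)` with
#' `r0 = center_row - (side - 1) %/% 2` is extracted (zero-filled where it
#' leaves the image) and resampled to `out_size` by bilinear interpolation
#' (half-pixel centers, edge clamp). Resampling to the native side is the
#' identity.
#'
#' @param slice An [image_slice()] or a numeric matrix.
#' @param roi A [square_roi()].
#' @param out_size Output side in pixels.
#' @return `out_size` x `out_size` numeric matrix in `[0, 1]`.
#' @export
crop_resize <- function(slice, roi, out_size = PATCH_SIZE) {
  img <- if (inherits(slice, "image_slice")) slice$pixels else slice
  side <- roi$side
  r0 <- roi$center_row - (side - 1L) %/% 2L
  c0 <- roi$center_col - (side - 1L) %/% 2L
  crop <- matrix(0, side, side)
  rr <- intersect(seq(r0, r0 + side - 1L), seq(0L, nrow(img) - 1L))
  cc <- intersect(seq(c0, c0 + side - 1L), seq(0L, ncol(img) - 1L))
  if (length(rr) && length(cc))
    crop[rr - r0 + 1L, cc - c0 + 1L] <- img[rr + 1L, cc + 1L]
  cpp_resize_bilinear(crop, out_size, out_size)
}

#' Contrast-limited adaptive histogram equalization of a patch
#'
#' Quantizes the patch to 8 bits, applies CLAHE on a tile grid with the
#' given normalized clip limit, and clips the result back to `[0, 1]`.
#' A patch without contrast (constant) is returned unchanged.
#'
#' @param patch Numeric matrix in `[0, 1]`.
#' @param clip_limit Positive normalized clip limit.
#' @param tile_grid `c(rows, cols)` of the tile grid.
#' @param bins Number of histogram bins.
#' @return Matrix of the same shape in `[0, 1]`.
#' @export
clahe_enhance <- function(patch, clip_limit = 2, tile_grid = c(8, 8),
                          bins = 256) {
  if (!is.numeric(clip_limit) || length(clip_limit) != 1 || clip_limit <= 0)
    stopf("clip_limit must be a positive number, got %s",
          paste(clip_limit, collapse = ","))
  if (min(patch) < 0 || max(patch) > 1) stopf("patch must lie in [0, 1]")
  if (diff(range(patch)) == 0) return(patch)
  q <- round(patch * 255) / 255
  out <- EBImage::clahe(EBImage::Image(t(q)), nx = tile_grid[2],
                        ny = tile_grid[1], bins = bins, limit = clip_limit)
  out <- clamp01(t(as.matrix(out)))
  attributes(out) <- list(dim = dim(out))
  out
}

#' Apply one ROI preprocessing strategy to a slice
#'
#' Strategies: `semi_sp` (square ROI at the lesion's maximal extent, scale
#' 1), `double` / `triple` (the same square with side scaled 2x / 3x),
#' `whole_image` (the full slice resized, no CLAHE), and `lesion_only`
#' (pixels outside the mask zeroed before the Semi-SP geometry). CLAHE edge
#' enhancement is applied in all lesion-focused strategies; the whole-image
#' strategy bypasses the Semi-SP pipeline entirely.
#'
#' @param slice An [image_slice()].
#' @param mask A [lesion_mask()]; may be `NULL` only for `whole_image`.
#' @param strategy One of `"semi_sp"`, `"double"`, `"triple"`,
#'   `"whole_image"`, `"lesion_only"`.
#' @param clip_limit,tile_grid CLAHE parameters, see [clahe_enhance()].
#' @param out_size Output side in pixels.
#' @param min_side Smallest ROI side, see [square_roi()].
#' @return A list of class `roi_patch` with `pixels` (out_size^2 matrix in
#'   `[0, 1]`), `strategy`, and `provenance`.
#' @export
apply_strategy <- function(slice, mask, strategy = c("semi_sp", "double",
                                                     "triple", "whole_image",
                                                     "lesion_only"),
                           clip_limit = 2, tile_grid = c(8, 8),
                           out_size = PATCH_SIZE, min_side = 8L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(slice, "image_slice"))
  if (strategy != "whole_image" && is.null(mask))
    stopf("strategy '%s' requires a lesion mask", strategy)
  if (!is.null(mask)) stopifnot(inherits(mask, "lesion_mask"))

  roi <- NULL
  clahe_used <- strategy != "whole_image"
  if (strategy == "whole_image") {
    px <- cpp_resize_bilinear(slice$pixels, out_size, out_size)
  } else {
    scale <- switch(strategy, semi_sp = 1, double = 2, triple = 3,
                    lesion_only = 1)
    src <- slice$pixels
    if (strategy == "lesion_only") src <- src * mask$pixels
    roi <- square_roi(mask, dim(slice$pixels), scale, min_side)
    px <- crop_resize(src, roi, out_size)
    px <- clahe_enhance(px, clip_limit, tile_grid)
  }
  structure(list(
    pixels = px,
    strategy = strategy,
    provenance = list(
      patient_id = slice$patient_id,
      lesion_id = slice$lesion_id,
      slice_index = slice$slice_index,
      class_label = slice$class_label,
      strategy = strategy,
      roi = if (is.null(roi)) NULL else roi[c("center_row", "center_col",
                                              "side", "scale_factor")],
      coordinate_convention = "row-major, 0-based, inclusive bbox bounds",
      clahe = if (clahe_used) list(clip_limit = clip_limit,
                                   tile_grid = tile_grid) else NULL,
      augmented = FALSE,
      split = NA_character_
    )
  ), class = "roi_patch")
}

#' Preprocess every slice of a cohort manifest
#'
#' @param cohort Output of [make_cohort()], or a manifest data frame whose
#'   `image_path`/`mask_path` columns point to files on disk.
#' @param strategy,clip_limit,tile_grid,out_size See [apply_strategy()].
#' @return List of `roi_patch` objects aligned with the manifest rows.
#' @export
preprocess_cohort <- function(cohort, strategy = "semi_sp", clip_limit = 2,
                              tile_grid = c(8, 8), out_size = PATCH_SIZE) {
  manifest <- if (is.data.frame(cohort)) cohort else cohort$manifest
  in_memory <- !is.data.frame(cohort) && !is.null(cohort$slices)
  lapply(seq_len(nrow(manifest)), function(i) {
    if (in_memory) {
      sl <- cohort$slices[[i]]
      mk <- cohort$masks[[i]]
    } else {
      loaded <- load_slice(manifest$image_path[i], manifest$mask_path[i],
                           slice_index = 1L,
                           patient_id = manifest$patient_id[i],
                           lesion_id = manifest$lesion_id[i],
                           class_label = manifest$class_label[i])
      loaded$slice$slice_index <- manifest$slice_index[i]
      sl <- loaded$slice
      mk <- loaded$mask
    }
    apply_strategy(sl, mk, strategy, clip_limit, tile_grid, out_size)
  })
}
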