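# Seeded geometric augmentation: one random rotation, isotropic scaling and
# translation per copy, composed rotate -> scale -> translate about the
# patch center, resampled bilinearly with zero fill. Every draw is fully
# determined by (spec$seed, the patch's identifiers, draw_index), so an
# augmented dataset can be regenerated bit-identically.

#' Specification of the geometric augmentation
#'
#' @param max_translation Maximum |shift| as a fraction of the patch side.
#' @param scale_range Multiplicative scale range `c(lo, hi)`, both positive.
#' @param rotation_range Maximum |rotation| in degrees.
#' @param copies_per_image Augmented copies generated per input patch.
#' @param seed Base seed.
#' @return A list of class `augment_spec`.
#' @export
augment_spec <- function(max_translation = 0.1, scale_range = c(0.9, 1.1),
                         rotation_range = 15, copies_per_image = 4L,
                         seed = 0L) {
  stopifnot(length(scale_range) == 2, all(scale_range > 0),
            scale_range[1] <= scale_range[2], max_translation >= 0,
            rotation_range >= 0, is_count(copies_per_image))
  structure(list(max_translation = max_translation, scale_range = scale_range,
                 rotation_range = rotation_range,
                 copies_per_image = as.integer(copies_per_image),
                 seed = as.integer(seed)),
            class = "augment_spec")
}

#' One seeded geometric transform of a 224x224 patch
#'
#' @param patch A `roi_patch` (or plain matrix).
#' @param spec An [augment_spec()].
#' @param draw_index Integer distinguishing repeated draws for one patch.
#' @return An object of the same kind as `patch` with transformed pixels;
#'   `roi_patch` provenance gains `augmented = TRUE` and the draw record.
#' @export
random_geometric <- function(patch, spec, draw_index = 1L) {
  is_patch <- inherits(patch, "roi_patch")
  px <- if (is_patch) patch$pixels else patch
  stopifnot(nrow(px) == ncol(px))
  ids <- if (is_patch)
    c(patch$provenance$patient_id, patch$provenance$lesion_id,
      patch$provenance$slice_index) else "anonymous"
  n <- nrow(px)
  draws <- local_seed(mix_seed(spec$seed, ids, draw_index), {
    list(angle = runif(1, -spec$rotation_range, spec$rotation_range),
         scale = runif(1, spec$scale_range[1], spec$scale_range[2]),
         shift = runif(2, -spec$max_translation, spec$max_translation) * n)
  })
  th <- draws$angle * pi / 180
  s <- draws$scale
  ctr <- (n - 1) / 2
  # inverse map of translate(shift) o scale(s) o rotate(th) about the center
  ca <- cos(th) / s
  sa <- sin(th) / s
  m2 <- ctr - ca * (ctr + draws$shift[1]) - sa * (ctr + draws$shift[2])
  m5 <- ctr + sa * (ctr + draws$shift[1]) - ca * (ctr + draws$shift[2])
  out <- clamp01(cpp_warp_affine(px, c(ca, sa, m2, -sa, ca, m5), n, n))
  if (!is_patch) return(out)
  patch$pixels <- out
  patch$provenance$augmented <- TRUE
  patch$provenance$augment_draw <- list(draw_index = as.integer(draw_index),
                                        angle_deg = draws$angle,
                                        scale = s,
                                        shift_px = draws$shift,
                                        seed = spec$seed)
  patch
}

#' Expand a patch set with augmented copies
#'
#' Returns the originals followed by `copies_per_image` seeded copies of
#' each. Patches whose provenance marks them as test-split members are
#' refused: the held-out set is never augmented.
#'
#' @param patches List of `roi_patch` objects.
#' @param spec An [augment_spec()].
#' @return List of length `length(patches) * (1 + copies_per_image)`.
#' @export
expand_dataset <- function(patches, spec) {
  stopifnot(inherits(spec, "augment_spec"))
  if (length(patches) == 0) return(patches)
  splits <- vapply(patches, function(p)
    if (is.null(p$provenance$split)) NA_character_ else p$provenance$split,
    character(1))
  if (any(!is.na(splits) & splits == "test"))
    stopf("refusing to augment patches assigned to the test split")
  if (spec$copies_per_image == 0) return(patches)
  out <- vector("list", length(patches) * (1 + spec$copies_per_image))
  k <- 1
  for (p in patches) {
    out[[k]] <- p
    k <- k + 1
    for (d in seq_len(spec$copies_per_image)) {
      out[[k]] <- random_geometric(p, spec, d)
      k <- k + 1
    }
  }
  out
}
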