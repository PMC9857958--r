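# Synthetic lesion-phantom generator.
#
# Emulates the two T2WI lesion phenotypes the classifier has to separate:
# HCC-like lesions have a sharp boundary and a bright rim ("pseudocapsule"),
# MF-ICC-like lesions have a blurred, irregular margin and no rim. Lesions
# are star-convex blobs (radial harmonic perturbation of a base radius)
# embedded in a smooth noisy background; slices of one lesion share geometry
# up to a small per-slice radius jitter so lesion-grouped splitting is
# meaningful. Everything is deterministic in (spec$seed, lesion_seed,
# slice_index).

#' Specification of the synthetic lesion phantom
#'
#' Bundles every tunable of the phantom generator. Class-dependent entries
#' are named vectors over `c("HCC", "MF-ICC")`.
#'
#' @param image_size Side of the square slice, pixels.
#' @param lesion_radius_range Base lesion radius range in pixels; the draw is
#'   shrunk if the perturbed blob plus margin would not fit the image.
#' @param edge_sigma Gaussian blur (pixels) of the lesion boundary per class;
#'   small for the sharp HCC-like margin, large for the blurred MF-ICC-like
#'   margin.
#' @param rim_contrast Additive intensity of the bright boundary rim
#'   (pseudocapsule) per class.
#' @param shape_irregularity Amplitude of the radial harmonic perturbation
#'   per class (fraction of the base radius).
#' @param background_texture_scale Gaussian blur sigma (pixels) of the
#'   background texture field.
#' @param background_texture_amp Standard deviation of the background
#'   texture, intensity units.
#' @param lesion_contrast Additive intensity offset of the lesion over the
#'   background.
#' @param noise_sigma Standard deviation of the per-pixel Gaussian noise.
#' @param slices_per_lesion_range Integer range of slices per lesion.
#' @param margin Minimum distance (pixels) between the lesion support and
#'   the image border.
#' @param seed Base seed folded into every random draw.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256,
                         lesion_radius_range = c(12, 40),
                         edge_sigma = c("HCC" = 1.0, "MF-ICC" = 3.0),
                         rim_contrast = c("HCC" = 0.25, "MF-ICC" = 0),
                         shape_irregularity = c("HCC" = 0.08, "MF-ICC" = 0.25),
                         background_texture_scale = 8,
                         background_texture_amp = 0.15,
                         lesion_contrast = 0.30,
                         noise_sigma = 0.03,
                         slices_per_lesion_range = c(3, 6),
                         margin = 8,
                         seed = 0) {
  stopifnot(image_size >= 32, margin >= 0, noise_sigma >= 0,
            all(edge_sigma >= 0), length(lesion_radius_range) == 2,
            lesion_radius_range[1] <= lesion_radius_range[2])
  if (lesion_radius_range[2] + margin >= image_size / 2)
    stopf("lesion radius range [%g, %g] cannot fit a %dpx image with margin %d",
          lesion_radius_range[1], lesion_radius_range[2], image_size, margin)
  structure(list(
    image_size = image_size,
    lesion_radius_range = lesion_radius_range,
    edge_sigma = edge_sigma,
    rim_contrast = rim_contrast,
    shape_irregularity = shape_irregularity,
    background_texture_scale = background_texture_scale,
    background_texture_amp = background_texture_amp,
    lesion_contrast = lesion_contrast,
    noise_sigma = noise_sigma,
    slices_per_lesion_range = slices_per_lesion_range,
    margin = margin,
    seed = seed
  ), class = "phantom_spec")
}

# Lesion-level geometry draws shared by all slices of one lesion.
phantom_geometry <- function(spec, class_label, lesion_seed) {
  irr <- unname(spec$shape_irregularity[class_label])
  local_seed(mix_seed(spec$seed, lesion_seed, 0L), {
    r0 <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
    # harmonic perturbation s(theta) = sum_k (a_k / k) cos(k theta + phi_k)
    kk <- 2:5
    a <- runif(4, 0.5, 1)
    phi <- runif(4, 0, 2 * pi)
    smax <- sum(a / kk)  # upper bound of |s|
    rmax <- r0 * (1 + irr * smax) * 1.1  # head-room for per-slice jitter
    lo <- spec$margin + rmax + 1
    hi <- spec$image_size - spec$margin - rmax - 1
    if (lo >= hi)
      stopf("lesion of base radius %.1f cannot fit a %dpx image with margin %d",
            r0, spec$image_size, spec$margin)
    ctr <- runif(2, lo, hi)
    nsl <- sample(seq(spec$slices_per_lesion_range[1],
                      spec$slices_per_lesion_range[2]), 1)
    list(r0 = r0, a = a, phi = phi, k = kk, irr = irr,
         center = ctr, n_slices = nsl)
  })
}

#' Generate one synthetic phantom slice with its ground-truth mask
#'
#' @param spec A [phantom_spec()].
#' @param class_label `"HCC"` or `"MF-ICC"`.
#' @param lesion_seed Integer identifying the lesion; all slices with the
#'   same `(spec$seed, lesion_seed)` share geometry.
#' @param slice_index 1-based slice number within the lesion.
#' @return A list with elements `slice` (an `image_slice`) and `mask`
#'   (a `lesion_mask`).
#' @export
make_phantom <- function(spec, class_label, lesion_seed, slice_index = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  class_label <- match.arg(class_label, .classes)
  geo <- phantom_geometry(spec, class_label, lesion_seed)
  n <- spec$image_size
  rows <- matrix(seq_len(n) - 1, n, n)
  cols <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  dr <- rows - geo$center[1]
  dc <- cols - geo$center[2]
  dist <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  s <- 0
  for (i in seq_along(geo$k))
    s <- s + (geo$a[i] / geo$k[i]) * cos(geo$k[i] * theta + geo$phi[i])

  slice_draws <- local_seed(mix_seed(spec$seed, lesion_seed, slice_index), {
    list(jitter = runif(1, 0.92, 1.08),
         texture = matrix(rnorm(n * n), n, n),
         noise = matrix(rnorm(n * n, sd = spec$noise_sigma), n, n))
  })

  rtheta <- geo$r0 * slice_draws$jitter * (1 + geo$irr * s)
  mask <- (dist <= rtheta) * 1

  sig <- unname(spec$edge_sigma[class_label])
  soft <- if (sig > 0) gauss_blur(mask, sig) else mask

  bg_tex <- gauss_blur(slice_draws$texture, spec$background_texture_scale)
  bg_tex <- bg_tex / max(sd(bg_tex), 1e-12) * spec$background_texture_amp

  img <- 0.35 + bg_tex + spec$lesion_contrast * soft

  rimc <- unname(spec$rim_contrast[class_label])
  if (rimc > 0) {
    ring <- ((dist <= rtheta) & (dist >= rtheta - 2.5)) * 1
    img <- img + rimc * gauss_blur(ring, 0.8)
  }

  img <- clamp01(img + slice_draws$noise)

  slice <- image_slice(img,
                       patient_id = sprintf("P%04d", lesion_seed),
                       lesion_id = sprintf("L%04d", lesion_seed),
                       slice_index = slice_index,
                       class_label = class_label)
  list(slice = slice, mask = lesion_mask(mask))
}

# Gaussian blur via EBImage (transposed in/out: EBImage's first dim is x).
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  t(as.matrix(EBImage::gblur(EBImage::Image(t(m)), sigma = sigma)))
}

#' Generate a synthetic cohort of lesions with a manifest
#'
#' Draws `n_per_class` lesions per phenotype, each with its per-lesion
#' number of slices, and returns (and optionally writes) the cohort in the
#' manifest schema used throughout the package: columns `patient_id`,
#' `lesion_id`, `slice_index`, `class_label`, `image_path`, `mask_path`.
#'
#' @param n_per_class Either a single integer (both classes) or a named
#'   vector over `c("HCC", "MF-ICC")`.
#' @param spec A [phantom_spec()]. Its `seed` is combined with `seed`.
#' @param seed Cohort-level seed folded into every lesion.
#' @param out_dir If non-`NULL`, PNG images/masks and `manifest.csv` are
#'   written there.
#' @param slices_per_lesion Optional fixed number of slices per lesion,
#'   overriding the spec's per-lesion draw.
#' @return A list with `manifest` (data frame), and, when `out_dir` is
#'   `NULL`, `slices` and `masks` (lists aligned with manifest rows).
#' @export
make_cohort <- function(n_per_class, spec = phantom_spec(), seed = 0,
                        out_dir = NULL, slices_per_lesion = NULL) {
  if (length(n_per_class) == 1)
    n_per_class <- c("HCC" = unname(n_per_class), "MF-ICC" = unname(n_per_class))
  stopifnot(all(n_per_class >= 1))
  spec$seed <- mix_seed(spec$seed, seed)
  rows <- list()
  slices <- list()
  masks <- list()
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  }
  lesion_counter <- 0
  for (cls in .classes) {
    for (i in seq_len(n_per_class[[cls]])) {
      lesion_counter <- lesion_counter + 1
      geo <- phantom_geometry(spec, cls, lesion_counter)
      nsl <- if (is.null(slices_per_lesion)) geo$n_slices else slices_per_lesion
      for (si in seq_len(nsl)) {
        ph <- make_phantom(spec, cls, lesion_counter, si)
        img_path <- NA_character_
        msk_path <- NA_character_
        if (!is.null(out_dir)) {
          base <- sprintf("%s_L%04d_s%02d.png", gsub("-", "", cls),
                          lesion_counter, si)
          img_path <- file.path(out_dir, "images", base)
          msk_path <- file.path(out_dir, "masks", base)
          write_gray_png(ph$slice$pixels, img_path)
          write_gray_png(ph$mask$pixels, msk_path)
        } else {
          slices[[length(slices) + 1]] <- ph$slice
          masks[[length(masks) + 1]] <- ph$mask
        }
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = ph$slice$patient_id,
          lesion_id = ph$slice$lesion_id,
          slice_index = si,
          class_label = cls,
          image_path = img_path,
          mask_path = msk_path,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    return(list(manifest = manifest))
  }
  list(manifest = manifest, slices = slices, masks = masks)
}
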