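# Reading and writing of 2-D grayscale slices and binary lesion masks.
# PNG via the png package, NIfTI via RNifti; NRRD through a minimal reader
# for the plain-text header + raw/gzip raster layout (no NRRD reader exists
# in the R stack this package builds on).

#' Construct an image slice
#'
#' A 2-D grayscale slice with intensities normalized to `[0, 1]` plus the
#' identifiers used for lesion-grouped bookkeeping.
#'
#' @param pixels Numeric matrix in `[0, 1]`, at least 8x8.
#' @param patient_id,lesion_id Character identifiers.
#' @param slice_index 1-based index of the slice within its lesion.
#' @param class_label `"HCC"`, `"MF-ICC"` or `NA` when unknown.
#' @return A list of class `image_slice`.
#' @export
image_slice <- function(pixels, patient_id = NA_character_,
                        lesion_id = NA_character_, slice_index = 1L,
                        class_label = NA_character_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 8 || ncol(pixels) < 8)
    stopf("slice must be at least 8x8, got %dx%d", nrow(pixels), ncol(pixels))
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stopf("slice intensities must lie in [0, 1]")
  if (!is.na(class_label)) class_label <- match.arg(class_label, .classes)
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
                 patient_id = patient_id, lesion_id = lesion_id,
                 slice_index = as.integer(slice_index),
                 class_label = class_label),
            class = "image_slice")
}

#' Construct a binary lesion mask
#'
#' @param pixels Matrix with values in `{0, 1}`, same shape as its slice.
#' @return A list of class `lesion_mask`.
#' @export
lesion_mask <- function(pixels) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(pixels %in% c(0, 1)))
    stopf("mask values must be 0 or 1")
  structure(list(pixels = pixels), class = "lesion_mask")
}

# Minimal NRRD reader: text header (key: value / field:= value lines,
# terminated by a blank line) followed by the raster. Supports the subset
# produced by common exporters: types {uchar, ushort, short, int, float,
# double}, encodings {raw, gzip}, little endian, 2-D or 3-D.
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  header <- character()
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stopf("'%s' is not an NRRD file", path)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    if (!startsWith(ln, "#")) header <- c(header, ln)
  }
  kv <- list()
  for (ln in header) {
    parts <- regmatches(ln, regexpr(":=?", ln), invert = TRUE)[[1]]
    if (length(parts) == 2)
      kv[[trimws(tolower(parts[1]))]] <- trimws(parts[2])
  }
  sizes <- as.integer(strsplit(kv[["sizes"]], "\\s+")[[1]])
  type <- tolower(kv[["type"]])
  enc <- tolower(kv[["encoding"]])
  n <- prod(sizes)
  spec <- switch(type,
    "uchar" = , "unsigned char" = , "uint8" = list(what = "integer", size = 1, signed = FALSE),
    "short" = , "int16" = list(what = "integer", size = 2, signed = TRUE),
    "ushort" = , "unsigned short" = , "uint16" = list(what = "integer", size = 2, signed = FALSE),
    "int" = , "int32" = list(what = "integer", size = 4, signed = TRUE),
    "float" = list(what = "numeric", size = 4, signed = TRUE),
    "double" = list(what = "numeric", size = 8, signed = TRUE),
    stopf("unsupported NRRD type '%s'", type))
  payload <- readBin(con, "raw", n = file.size(path))
  if (enc == "gzip") payload <- memDecompress(payload, type = "gzip")
  else if (enc != "raw") stopf("unsupported NRRD encoding '%s'", enc)
  vals <- readBin(payload, spec$what, n = n, size = spec$size,
                  signed = if (spec$size >= 4) TRUE else spec$signed,
                  endian = "little")
  array(as.double(vals), dim = sizes)
}

read_gray_array <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- paste0(ext, ".gz")
  if (!file.exists(path)) stopf("file not found: %s", path)
  low <- tolower(path)
  if (endsWith(low, ".png")) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    a
  } else if (endsWith(low, ".nrrd")) {
    a <- read_nrrd(path)
    # NRRD axis order is fastest-first (x, y[, z]); transpose to (row, col)
    if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
  } else if (endsWith(low, ".nii") || endsWith(low, ".nii.gz")) {
    as.array(RNifti::readNifti(path))
  } else {
    stopf("unsupported image format: %s (supported: PNG, NRRD, NIfTI)", path)
  }
}

#' Load a grayscale slice and its aligned lesion mask
#'
#' Reads PNG (8/16-bit), NRRD, or NIfTI files; 3-D volumes are reduced to
#' one slice by `slice_index` (third axis). The image is min-max normalized
#' to `[0, 1]` (an intensity-constant image maps to all zeros); the mask is
#' binarized at `> 0`.
#'
#' @param path,mask_path Image and mask file paths.
#' @param slice_index Slice selector for 3-D inputs, also recorded in the
#'   returned object.
#' @param patient_id,lesion_id,class_label Identifiers stored on the slice.
#' @return A list with `slice` (an [image_slice()]) and `mask`
#'   (a [lesion_mask()]).
#' @export
load_slice <- function(path, mask_path, slice_index = 1L,
                       patient_id = NA_character_, lesion_id = NA_character_,
                       class_label = NA_character_) {
  img <- read_gray_array(path)
  msk <- read_gray_array(mask_path)
  pick <- function(a) {
    if (length(dim(a)) == 3) {
      if (slice_index < 1 || slice_index > dim(a)[3])
        stopf("slice_index %d out of range 1..%d", slice_index, dim(a)[3])
      a <- a[, , slice_index]
    }
    a
  }
  img <- pick(img)
  msk <- pick(msk)
  if (!identical(dim(img), dim(msk)))
    stopf("image and mask shapes differ: %s vs %s",
          paste(dim(img), collapse = "x"), paste(dim(msk), collapse = "x"))
  rng <- range(img)
  img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  list(slice = image_slice(img, patient_id, lesion_id, slice_index, class_label),
       mask = lesion_mask((msk > 0) * 1))
}

# 16-bit grayscale PNG writer (png::writePNG writes 16-bit from doubles when
# asked for; fall back is handled by readPNG's normalization on read).
write_gray_png <- function(pixels, path) {
  png::writePNG(clamp01(pixels), target = path)
  invisible(path)
}

#' Write a preprocessed ROI patch with a provenance sidecar
#'
#' The patch is written as a grayscale PNG, and its provenance (source
#' identifiers, ROI geometry, strategy, enhancement parameters) as a JSON
#' sidecar next to it.
#'
#' @param patch A `roi_patch` from [apply_strategy()].
#' @param path PNG output path; the sidecar replaces the extension by
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_patch <- function(patch, path) {
  stopifnot(inherits(patch, "roi_patch"))
  write_gray_png(patch$pixels, path)
  side <- sub("\\.png$", ".json", path, ignore.case = TRUE)
  jsonlite::write_json(patch$provenance, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
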