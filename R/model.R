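# SFFNet: a ResNet101-style backbone rebuilt from three ideas --
# pre-activation "stationary" residual bottlenecks (SRB), channel+spatial
# attention (CBAM) inserted after the stem's conv/norm/ReLU and before the
# max-pool, and multilayer feature fusion (MFF) that concatenates the stem
# output X0 (64@112x112 for 224 input) with the bilinearly upsampled
# shallow-stage output X3 (x2: 256@56 -> 112) and deep-stage output X6
# (x16: 2048@7 -> 112), giving the fused map Ffu (2368@112x112) that feeds
# a global-average-pooling + fully-connected 2-class head.

#' SFFNet architecture configuration
#'
#' @param preset `"full"` (stage block counts 3,4,23,3, the 101-layer
#'   backbone) or `"reduced"` (1,1,1,1; same widths and feature-map shapes,
#'   desk-scale depth).
#' @param stage_block_counts Optional explicit 4-vector of block counts,
#'   overriding the preset.
#' @param input_channels 1 (grayscale T2WI) or 3.
#' @param num_classes Number of output classes.
#' @param cbam_reduction Channel-attention bottleneck reduction; must divide
#'   the stem width (64).
#' @param cbam_spatial_kernel Odd spatial-attention kernel size.
#' @param pretrained_weights Optional checkpoint path loaded into new models.
#' @return A list of class `sffnet_config`.
#' @export
sffnet_config <- function(preset = c("reduced", "full"),
                          stage_block_counts = NULL,
                          input_channels = 1L, num_classes = 2L,
                          cbam_reduction = 16L, cbam_spatial_kernel = 7L,
                          pretrained_weights = NULL) {
  preset <- match.arg(preset)
  counts <- if (!is.null(stage_block_counts)) as.integer(stage_block_counts)
            else if (preset == "full") c(3L, 4L, 23L, 3L) else c(1L, 1L, 1L, 1L)
  stopifnot(length(counts) == 4, all(counts >= 1))
  if (!input_channels %in% c(1L, 3L))
    stopf("input_channels must be 1 or 3")
  if (64L %% cbam_reduction != 0)
    stopf("cbam_reduction (%d) must divide the stem width 64", cbam_reduction)
  if (cbam_spatial_kernel %% 2 != 1)
    stopf("cbam_spatial_kernel must be odd, got %d", cbam_spatial_kernel)
  structure(list(preset = preset,
                 stage_block_counts = counts,
                 stem_channels = 64L,
                 stage_out_channels = c(256L, 512L, 1024L, 2048L),
                 input_channels = as.integer(input_channels),
                 num_classes = as.integer(num_classes),
                 cbam_reduction = as.integer(cbam_reduction),
                 cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
                 pretrained_weights = pretrained_weights),
            class = "sffnet_config")
}

#' Instantiate an SFFNet model
#'
#' Weights are Kaiming-initialized from `seed` (batch-norm scale 1/shift 0,
#' zero head bias); if the config names a pretrained checkpoint it is loaded
#' non-strictly on top.
#'
#' @param config An [sffnet_config()].
#' @param seed Initialization seed.
#' @return An object of class `sffnet_model`.
#' @export
sffnet_model <- function(config = sffnet_config(), seed = 0L) {
  stopifnot(inherits(config, "sffnet_config"))
  m <- structure(list(ptr = sff_create(config, as.integer(seed)),
                      config = config, seed = as.integer(seed)),
                 class = "sffnet_model")
  if (!is.null(config$pretrained_weights))
    load_pretrained(m, config$pretrained_weights, strict = FALSE)
  m
}

#' @export
print.sffnet_model <- function(x, ...) {
  cat(sprintf("SFFNet (%s preset: blocks %s), %d input channel(s), %s parameters\n",
              x$config$preset,
              paste(x$config$stage_block_counts, collapse = ","),
              x$config$input_channels,
              format(param_count(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters (including batch-norm statistics' scale
#' and shift, excluding running moments)
#' @param model An `sffnet_model`.
#' @return Numeric count.
#' @export
param_count <- function(model) sff_param_count(model$ptr)

# Coerce a matrix / (H,W,C) / (H,W,C,B) input into a 4-D batch array.
as_batch <- function(x, channels = 1L) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 4) stopf("expected a matrix or 3-D/4-D array")
  x
}

# Stack a list of roi_patch objects (or matrices) into a (H,W,1,N) batch.
patches_to_batch <- function(patches) {
  mats <- lapply(patches, function(p) if (inherits(p, "roi_patch")) p$pixels else p)
  n <- length(mats)
  h <- nrow(mats[[1]])
  out <- array(0, dim = c(h, ncol(mats[[1]]), 1L, n))
  for (i in seq_len(n)) out[, , 1L, i] <- mats[[i]]
  out
}

#' Stem forward pass: conv7x7/2 -> batch norm -> ReLU -> CBAM
#'
#' Returns the attention-gated stem output X0 (`B x 64 @ 112x112` for
#' 224x224 input, returned as an `(112, 112, 64, B)` array). Max-pooling is
#' not part of X0; it feeds the first residual stage.
#'
#' @param model An `sffnet_model`.
#' @param x Input batch: matrix, `(H,W,C)` or `(H,W,C,B)` array, 224x224.
#' @return `(112, 112, 64, B)` array.
#' @export
stem_forward <- function(model, x) {
  sff_stem_forward(model$ptr, as_batch(x))
}

#' Convolutional block attention (CBAM) forward pass
#'
#' Channel attention first (sigmoid of a shared bias-free two-layer MLP
#' applied to per-channel average- and max-pooled descriptors, summed), then
#' spatial attention (sigmoid of a `spatial_kernel` convolution over the
#' channel-wise mean and max maps); the input is gated by both.
#'
#' @param x `(H,W,C)` or `(H,W,C,B)` array.
#' @param reduction Channel bottleneck reduction; must divide C.
#' @param spatial_kernel Odd kernel size of the spatial attention conv.
#' @param weights Optional list with `W1` (C/r x C), `W2` (C x C/r),
#'   `conv.W` (2*k^2 x 1), `conv.b` (1); freshly seeded when `NULL`.
#' @param seed Seed for fresh weights.
#' @param return_attention Also return the channel (C x B) and spatial
#'   (H*W x B) attention maps.
#' @return Gated array of the input's shape, or a list when
#'   `return_attention`.
#' @export
cbam_forward <- function(x, reduction = 16L, spatial_kernel = 7L,
                         weights = NULL, seed = 0L,
                         return_attention = FALSE) {
  x <- as_batch(x)
  C <- dim(x)[3]
  if (C %% reduction != 0)
    stopf("reduction (%d) must divide the channel count (%d)", reduction, C)
  if (spatial_kernel %% 2 != 1) stopf("spatial_kernel must be odd")
  if (is.null(weights)) {
    cr <- C %/% reduction
    weights <- local_seed(seed, list(
      W1 = matrix(rnorm(cr * C, sd = sqrt(2 / C)), cr, C),
      W2 = matrix(rnorm(C * cr, sd = sqrt(2 / cr)), C, cr),
      conv.W = matrix(rnorm(2 * spatial_kernel^2,
                            sd = sqrt(2 / (2 * spatial_kernel^2)))),
      conv.b = 0))
  }
  y <- cpp_cbam_forward(x, weights$W1, weights$W2,
                        matrix(weights$conv.W, ncol = 1),
                        weights$conv.b, spatial_kernel)
  if (!return_attention) return(y)
  att <- cpp_cbam_attention(x, weights$W1, weights$W2,
                            matrix(weights$conv.W, ncol = 1),
                            weights$conv.b, spatial_kernel)
  list(output = y, channel = att$channel, spatial = att$spatial)
}

#' Stationary residual block (SRB) forward pass
#'
#' Pre-activation bottleneck: norm -> ReLU -> 1x1 conv(mid) -> norm -> ReLU
#' -> 3x3 conv(mid, stride) -> norm -> ReLU -> 1x1 conv(out) with no
#' trailing normalization (the last conv carries a bias instead). The
#' shortcut is the identity when shapes match, else a strided 1x1
#' projection followed by a norm. Output = branch + shortcut.
#'
#' @param x `(H,W,C)` or `(H,W,C,B)` array with `in_ch` channels.
#' @param mid_ch,out_ch Bottleneck and output widths.
#' @param stride 1 or 2 (2 halves the spatial size).
#' @param weights Optional weight list as produced by [srb_init()].
#' @param seed Seed for fresh weights.
#' @return `(H', W', out_ch, B)` array.
#' @export
srb_block <- function(x, mid_ch, out_ch, stride = 1L, weights = NULL,
                      seed = 0L) {
  x <- as_batch(x)
  in_ch <- dim(x)[3]
  if (is.null(weights)) weights <- srb_init(in_ch, mid_ch, out_ch, stride, seed)
  if (nrow(weights$conv1.W) != in_ch)
    stopf("weights expect %d input channels but x has %d",
          nrow(weights$conv1.W), in_ch)
  cpp_srb_forward(x, weights, mid_ch, out_ch, as.integer(stride))
}

#' Freshly initialized SRB weights
#' @inheritParams srb_block
#' @param in_ch Input channel count.
#' @return Named weight list (batch-norm moments at their identity values).
#' @export
srb_init <- function(in_ch, mid_ch, out_ch, stride = 1L, seed = 0L) {
  cpp_srb_init(c(in_ch), mid_ch, out_ch, as.integer(stride), as.integer(seed))
}

#' Multilayer feature fusion (MFF)
#'
#' `FL = concat(X0, up2(X3))` and `Ffu = concat(FL, up16(X6))`, with both
#' upsamplings bilinear onto X0's grid. Channels add: with the standard
#' widths, `C(Ffu) = 64 + 256 + 2048 = 2368`.
#'
#' @param X0 `(H,W,C0,B)` stem output.
#' @param X3 `(H/2,W/2,C3,B)` shallow-stage output.
#' @param X6 `(H/16,W/16,C6,B)` deep-stage output.
#' @return List with arrays `FL` and `Ffu` on X0's grid.
#' @export
mff_fuse <- function(X0, X3, X6) {
  X0 <- as_batch(X0); X3 <- as_batch(X3); X6 <- as_batch(X6)
  d0 <- dim(X0); d3 <- dim(X3); d6 <- dim(X6)
  if (d0[4] != d3[4] || d0[4] != d6[4])
    stopf("batch sizes differ: %d, %d, %d", d0[4], d3[4], d6[4])
  if (any(d3[1:2] * 2L != d0[1:2]))
    stopf("X3 spatial size (%dx%d) must be half of X0's (%dx%d)",
          d3[1], d3[2], d0[1], d0[2])
  if (any(d6[1:2] * 16L != d0[1:2]))
    stopf("X6 spatial size (%dx%d) must be 1/16 of X0's (%dx%d)",
          d6[1], d6[2], d0[1], d0[2])
  up3 <- cpp_upsample4d(X3, d0[1], d0[2])
  up6 <- cpp_upsample4d(X6, d0[1], d0[2])
  FL <- array(0, dim = c(d0[1], d0[2], d0[3] + d3[3], d0[4]))
  FL[, , seq_len(d0[3]), ] <- X0
  FL[, , d0[3] + seq_len(d3[3]), ] <- up3
  Ffu <- array(0, dim = c(d0[1], d0[2], dim(FL)[3] + d6[3], d0[4]))
  Ffu[, , seq_len(dim(FL)[3]), ] <- FL
  Ffu[, , dim(FL)[3] + seq_len(d6[3]), ] <- up6
  list(FL = FL, Ffu = Ffu)
}

#' Full SFFNet forward pass
#'
#' Runs stem (+CBAM), max-pool, the four residual stages, fuses X0/X3/X6
#' and produces 2-class logits from global average pooling of the fused map
#' followed by a fully connected layer. (The head pools each fused branch
#' through exact bilinear-upsampling weights, which is algebraically equal
#' to pooling the materialized `Ffu`.)
#'
#' @param model An `sffnet_model`.
#' @param x Input batch (matrix or `(H,W,C[,B])` array), 224x224.
#' @param features When `TRUE`, also return the named feature maps
#'   `X0`, `X3`, `X6`, `FL`, `Ffu`.
#' @return List with `logits` (B x num_classes) and optionally `features`.
#' @export
sffnet_forward <- function(model, x, features = FALSE) {
  x <- as_batch(x)
  out <- sff_forward(model$ptr, x, train = FALSE, want_features = features)
  res <- list(logits = out$logits)
  if (features) {
    fu <- mff_fuse(out$X0, out$X3, out$X6)
    res$features <- list(X0 = out$X0, X3 = out$X3, X6 = out$X6,
                         FL = fu$FL, Ffu = fu$Ffu)
  }
  res
}

#' Class probabilities for a batch
#' @param model An `sffnet_model`.
#' @param x Input batch array or list of patches.
#' @param batch_size Forward-pass batch size.
#' @return N x num_classes matrix of softmax probabilities, columns named
#'   by class.
#' @export
predict_proba <- function(model, x, batch_size = 16L) {
  if (is.list(x)) x <- patches_to_batch(x)
  x <- as_batch(x)
  n <- dim(x)[4]
  probs <- matrix(NA_real_, n, model$config$num_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    lg <- sff_forward(model$ptr, x[, , , idx, drop = FALSE],
                      train = FALSE, want_features = FALSE)$logits
    e <- exp(lg - apply(lg, 1, max))
    probs[idx, ] <- e / rowSums(e)
  }
  colnames(probs) <- .classes[seq_len(ncol(probs))]
  probs
}

#' Save model weights to a checkpoint file
#' @param model An `sffnet_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(sff_get_weights(model$ptr), path)
  invisible(path)
}

#' Load matching tensors from a checkpoint
#'
#' Copies every tensor whose name and shape match the model's; the rest are
#' reported. With `strict = TRUE` any mismatch or absence is an error. An
#' empty checkpoint matches nothing and leaves the model unchanged.
#'
#' @param model An `sffnet_model` (modified in place).
#' @param weights_path RDS file holding a named weight list (see
#'   [save_checkpoint()]).
#' @param strict Error on any mismatch.
#' @return List with `matched`, `skipped_file` (in file, not matched) and
#'   `missing_model` (model tensors absent from the file), invisibly.
#' @export
load_pretrained <- function(model, weights_path, strict = FALSE) {
  if (!file.exists(weights_path)) stopf("weights file not found: %s", weights_path)
  file_w <- readRDS(weights_path)
  cur <- sff_get_weights(model$ptr)
  same_shape <- function(a, b) identical(dim(a), dim(b)) &&
    length(a) == length(b)
  matched <- character()
  skipped_file <- character()
  for (nm in names(file_w)) {
    if (nm %in% names(cur) && same_shape(cur[[nm]], file_w[[nm]])) {
      cur[[nm]] <- file_w[[nm]]
      matched <- c(matched, nm)
    } else {
      skipped_file <- c(skipped_file, nm)
    }
  }
  missing_model <- setdiff(names(cur), matched)
  if (strict && (length(skipped_file) > 0 || length(missing_model) > 0))
    stopf("strict loading failed; unmatched in file: [%s]; missing from file: [%s]",
          paste(skipped_file, collapse = ", "),
          paste(head(missing_model, 10), collapse = ", "))
  if (length(matched) > 0) sff_set_weights(model$ptr, cur)
  invisible(list(matched = matched, skipped_file = skipped_file,
                 missing_model = missing_model))
}
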