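# Independent oracles and tiny fixture builders shared across tests.
# The oracles are deliberately naive (direct per-pixel / per-pair
# computation) so they stay independent of the implementation paths they
# check.

# Direct bilinear interpolation with half-pixel centers and edge clamp,
# computed per output pixel.
oracle_bilinear <- function(img, out_h, out_w) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, out_h, out_w)
  for (u in seq_len(out_h) - 1) {
    for (v in seq_len(out_w) - 1) {
      sr <- min(max((u + 0.5) * H / out_h - 0.5, 0), H - 1)
      sc <- min(max((v + 0.5) * W / out_w - 0.5, 0), W - 1)
      i0 <- floor(sr); j0 <- floor(sc)
      i1 <- min(i0 + 1, H - 1); j1 <- min(j0 + 1, W - 1)
      fr <- sr - i0; fc <- sc - j0
      out[u + 1, v + 1] <-
        img[i0 + 1, j0 + 1] * (1 - fr) * (1 - fc) +
        img[i1 + 1, j0 + 1] * fr * (1 - fc) +
        img[i0 + 1, j1 + 1] * (1 - fr) * fc +
        img[i1 + 1, j1 + 1] * fr * fc
    }
  }
  out
}

# Mann-Whitney pairwise concordance with half credit for ties.
oracle_auc <- function(scores, labels, positive = "MF-ICC") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Exhaustive bounding-box scan over every foreground pixel (0-based).
oracle_bbox <- function(mask) {
  rs <- c(); cs <- c()
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j] > 0) { rs <- c(rs, i - 1); cs <- c(cs, j - 1) }
  c(row_min = min(rs), col_min = min(cs), row_max = max(rs), col_max = max(cs))
}

# Random blob mask: a filled disc plus seeded satellite pixels.
make_blob_mask <- function(h, w, seed = 1) {
  set.seed(seed)
  m <- matrix(0, h, w)
  cr <- sample(seq(10, h - 10), 1)
  cc <- sample(seq(10, w - 10), 1)
  rad <- sample(3:7, 1)
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((i - cr)^2 + (j - cc)^2 <= rad^2) m[i, j] <- 1
  extra <- sample(which(m == 0), 5)
  # keep satellites near the blob so the mask stays connected enough
  m[extra[abs((extra - 1) %% h - cr) < 9]] <- 1
  m
}

# A deterministic toy slice/mask pair with a rectangular lesion.
toy_slice <- function(h = 64, w = 64, r0 = 20, r1 = 29, c0 = 30, c1 = 49,
                      label = "HCC") {
  set.seed(42)
  img <- matrix(runif(h * w, 0.2, 0.8), h, w)
  msk <- matrix(0, h, w)
  msk[r0:r1, c0:c1] <- 1
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + 0.15
  list(slice = image_slice(pmin(img, 1), "P1", "L1", 1L, label),
       mask = lesion_mask(msk))
}

# Mean boundary-gradient feature used to check phantom learnability:
# average finite-difference gradient magnitude over the mask edge ring.
boundary_gradient <- function(img, mask) {
  gy <- img[-1, ] - img[-nrow(img), ]
  gx <- img[, -1] - img[, -ncol(img)]
  g <- sqrt(gy[, -ncol(gy)]^2 + gx[-nrow(gx), ]^2)
  er <- mask - (mask &
    rbind(mask[-1, ], 0) & rbind(0, mask[-nrow(mask), ]) &
    cbind(mask[, -1], 0) & cbind(0, mask[, -ncol(mask)]))
  ring <- which(er[-nrow(er), -ncol(er)] > 0)
  mean(g[ring])
}

# Published per-class results-table rows used as analytic inputs.
table1_semi_sp <- list(precision_1 = 0.9078, recall_1 = 0.9657, f1_1 = 0.9359,
                       precision_2 = 0.9470, recall_2 = 0.8621, f1_2 = 0.9025,
                       accuracy = 0.9226, auc = 0.9680)
table2_resnet101 <- list(accuracy = 0.8424, auc = 0.8847,
                         precision_mficc = 0.8358, f1_mficc = 0.8029)
table2_sffnet <- list(accuracy = 0.9226, auc = 0.9680,
                      precision_mficc = 0.9470, f1_mficc = 0.9025)
table2_mff_mficc <- list(precision = 0.9748, recall = 0.8000, f1 = 0.8788)
table3_inception_hcc <- list(precision = 0.8333, recall = 0.7843, f1 = 0.8081)
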