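# helpers: direct R reference implementations (double precision, naive
# loops) of the conv / batch-norm pieces, used as oracles for the C++ path.

conv_ref <- function(x, W, bias, k, stride, pad) {
  d <- dim(x)  # (H, W, Cin, B)
  cin <- d[3]; B <- d[4]
  oh <- (d[1] + 2 * pad - k) %/% stride + 1
  ow <- (d[2] + 2 * pad - k) %/% stride + 1
  cout <- ncol(W)
  y <- array(0, c(oh, ow, cout, B))
  for (b in 1:B) for (co in 1:cout) for (u in 1:oh) for (v in 1:ow) {
    acc <- if (length(bias)) bias[co] else 0
    for (c in 1:cin) for (ki in 1:k) for (kj in 1:k) {
      ih <- (u - 1) * stride - pad + ki - 1
      iw <- (v - 1) * stride - pad + kj - 1
      if (ih >= 0 && ih < d[1] && iw >= 0 && iw < d[2]) {
        q <- (c - 1) * k * k + (ki - 1) * k + (kj - 1) + 1
        acc <- acc + x[ih + 1, iw + 1, c, b] * W[q, co]
      }
    }
    y[u, v, co, b] <- acc
  }
  y
}

bn_ref <- function(x, bn, relu = TRUE, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in 1:d[3]) {
    t <- (x[, , c, , drop = FALSE] - bn$rm[c]) / sqrt(bn$rv[c] + eps) *
      bn$gamma[c] + bn$beta[c]
    if (relu) t[t < 0] <- 0
    y[, , c, ] <- t
  }
  y
}

srb_ref <- function(x, w, mid, out, stride) {
  a1 <- bn_ref(x, w$bn1)
  z1 <- conv_ref(a1, w$conv1.W, NULL, 1, 1, 0)
  a2 <- bn_ref(z1, w$bn2)
  z2 <- conv_ref(a2, w$conv2.W, NULL, 3, stride, 1)
  a3 <- bn_ref(z2, w$bn3)
  br <- conv_ref(a3, w$conv3.W, w$conv3.b, 1, 1, 0)
  if (!is.null(w$shortcut.conv.W)) {
    sc <- conv_ref(x, w$shortcut.conv.W, NULL, 1, stride, 0)
    sc <- bn_ref(sc, w$shortcut.bn, relu = FALSE)
    br + sc
  } else {
    br + x
  }
}

grid256 <- function(...) round(array(runif(prod(...)), dim = c(...)) * 256) / 256

test_that("stem output is B x 64 @ 112x112 with CBAM inside", {
  m <- sffnet_model(sffnet_config("reduced"), seed = 1)
  x2 <- grid256(224, 224, 1, 2)
  expect_equal(dim(stem_forward(m, x2)), c(112L, 112L, 64L, 2L))
  x16 <- grid256(224, 224, 1, 16)
  expect_equal(dim(stem_forward(m, x16)), c(112L, 112L, 64L, 16L))
  z <- array(0, c(224, 224, 1, 1))
  expect_true(all(is.finite(stem_forward(m, z))))
  bad <- array(0, c(128, 128, 1, 1))
  expect_error(stem_forward(m, bad), "224")
})

test_that("CBAM preserves shape and gates by sigmoid attention", {
  x <- grid256(14, 14, 32, 2)
  y <- cbam_forward(x, reduction = 8, seed = 3)
  expect_equal(dim(y), dim(x))
  # freezing all attention weights at zero makes both gates exactly 0.5
  zw <- list(W1 = matrix(0, 4, 32), W2 = matrix(0, 32, 4),
             conv.W = matrix(0, 2 * 49, 1), conv.b = 0)
  expect_equal(cbam_forward(x, reduction = 8, weights = zw), x / 4)
  att <- cbam_forward(x, reduction = 8, seed = 3, return_attention = TRUE)
  expect_true(all(att$channel > 0 & att$channel < 1))
  expect_true(all(att$spatial > 0 & att$spatial < 1))
  # gates in (0,1) shrink magnitudes
  expect_true(all(abs(att$output) <= abs(x) + 1e-12))
  expect_error(cbam_forward(x, reduction = 5), "divide")
})

test_that("SRB with a zeroed branch is exactly the identity", {
  w <- srb_init(16, 8, 16, 1, seed = 2)
  w$conv1.W[] <- 0; w$conv2.W[] <- 0; w$conv3.W[] <- 0; w$conv3.b[] <- 0
  x <- grid256(10, 10, 16, 2)  # float-representable values
  expect_identical(srb_block(x, 8, 16, 1, weights = w), x)
})

test_that("SRB matches a direct R composition oracle", {
  set.seed(5)
  for (stride in c(1, 2)) {
    w <- srb_init(6, 4, 10, stride, seed = stride)
    # non-trivial normalization statistics
    for (bnm in c("bn1", "bn2", "bn3", "shortcut.bn")) {
      if (is.null(w[[bnm]])) next
      nc <- length(w[[bnm]]$gamma)
      w[[bnm]]$rm <- rnorm(nc, 0, 0.3)
      w[[bnm]]$rv <- runif(nc, 0.5, 1.5)
      w[[bnm]]$gamma <- runif(nc, 0.5, 1.5)
      w[[bnm]]$beta <- rnorm(nc, 0, 0.2)
    }
    x <- grid256(8, 8, 6, 2)
    got <- srb_block(x, 4, 10, stride, weights = w)
    ref <- srb_ref(x, w, 4, 10, stride)
    expect_equal(dim(got), dim(ref))
    expect_lt(max(abs(got - ref)), 1e-4)
  }
})

test_that("SRB stride-2 halves the spatial size and projects channels", {
  x <- grid256(16, 16, 8, 1)
  y <- srb_block(x, 4, 12, 2, seed = 1)
  expect_equal(dim(y), c(8L, 8L, 12L, 1L))
  expect_error(srb_block(x, 4, 12, 1, weights = srb_init(6, 4, 12, 1)),
               "channels")
})

test_that("MFF fusion concatenates channels on the shallow grid", {
  X0 <- array(0.2, c(16, 16, 3, 2))
  X3 <- array(0.7, c(8, 8, 5, 2))
  X6 <- array(0.4, c(1, 1, 4, 2))
  fu <- mff_fuse(X0, X3, X6)
  expect_equal(dim(fu$FL), c(16L, 16L, 8L, 2L))
  expect_equal(dim(fu$Ffu), c(16L, 16L, 12L, 2L))
  # bilinear upsampling of constants is constant: blockwise constant output
  expect_lt(max(abs(fu$Ffu[, , 1:3, ] - 0.2)), 1e-6)
  expect_lt(max(abs(fu$Ffu[, , 4:8, ] - 0.7)), 1e-6)
  expect_lt(max(abs(fu$Ffu[, , 9:12, ] - 0.4)), 1e-6)
})

test_that("MFF commutes with batch slicing and checks spatial ratios", {
  set.seed(9)
  X0 <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  X3 <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  X6 <- array(runif(1 * 1 * 4 * 3), c(1, 1, 4, 3))
  all3 <- mff_fuse(X0, X3, X6)$Ffu
  one <- mff_fuse(X0[, , , 2, drop = FALSE], X3[, , , 2, drop = FALSE],
                  X6[, , , 2, drop = FALSE])$Ffu
  expect_equal(all3[, , , 2, drop = FALSE], one)
  expect_equal(dim(all3)[4], 3L)
  expect_error(mff_fuse(X0, array(0, c(5, 5, 2, 3)), X6), "half")
  expect_error(mff_fuse(X0, X3, array(0, c(2, 2, 4, 3))), "1/16")
})

test_that("feature map shapes hold for both depth presets", {
  configs <- list(reduced = sffnet_config("reduced"),
                  full = sffnet_config("full"))
  batch <- list(reduced = 2L, full = 1L)
  for (nm in names(configs)) {
    m <- sffnet_model(configs[[nm]], seed = 1)
    x <- grid256(224, 224, 1, batch[[nm]])
    out <- sffnet_forward(m, x, features = TRUE)
    B <- batch[[nm]]
    expect_equal(dim(out$features$X0), c(112L, 112L, 64L, B))
    expect_equal(dim(out$features$X3), c(56L, 56L, 256L, B))
    expect_equal(dim(out$features$X6), c(7L, 7L, 2048L, B))
    expect_equal(dim(out$features$FL), c(112L, 112L, 320L, B))
    expect_equal(dim(out$features$Ffu), c(112L, 112L, 2368L, B))
    expect_equal(dim(out$logits), c(B, 2L))
  }
})

test_that("the fused-weight head equals pooling the materialized Ffu", {
  m <- sffnet_model(sffnet_config("reduced"), seed = 4)
  x <- grid256(224, 224, 1, 2)
  out <- sffnet_forward(m, x, features = TRUE)
  w <- sffnet:::sff_get_weights(m$ptr)
  gap <- apply(out$features$Ffu, c(3, 4), mean)
  ref <- t(gap) %*% w[["fc.W"]] + matrix(w[["fc.b"]], 2, 2, byrow = TRUE)
  expect_lt(max(abs(ref - out$logits)), 1e-4)
})

test_that("softmax probabilities are normalized and deterministic", {
  m <- sffnet_model(sffnet_config("reduced"), seed = 1)
  x <- grid256(224, 224, 1, 3)
  p <- predict_proba(m, x)
  expect_equal(rowSums(p), rep(1, 3))
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict_proba(m, x))
  m2 <- sffnet_model(sffnet_config("reduced"), seed = 1)
  expect_identical(predict_proba(m2, x), p)
})

test_that("the 101-layer preset has more parameters than the reduced one", {
  full <- sffnet_model(sffnet_config("full"), seed = 1)
  red <- sffnet_model(sffnet_config("reduced"), seed = 1)
  expect_gt(param_count(full), param_count(red))
  expect_gt(param_count(full), 4e7)  # ResNet101-scale backbone
})

test_that("checkpoints round-trip and pretrained loading matches by name", {
  d <- withr::local_tempdir()
  m <- sffnet_model(sffnet_config("reduced"), seed = 1)
  x <- grid256(224, 224, 1, 1)
  base <- sffnet_forward(m, x)$logits
  ck <- file.path(d, "ck.rds")
  save_checkpoint(m, ck)
  m2 <- sffnet_model(sffnet_config("reduced"), seed = 99)
  expect_false(isTRUE(all.equal(sffnet_forward(m2, x)$logits, base)))
  rep <- load_pretrained(m2, ck)
  expect_length(rep$skipped_file, 0)
  expect_length(rep$missing_model, 0)
  expect_equal(sffnet_forward(m2, x)$logits, base)

  # an empty checkpoint matches nothing and changes nothing
  saveRDS(list(), file.path(d, "empty.rds"))
  rep0 <- load_pretrained(m2, file.path(d, "empty.rds"))
  expect_length(rep0$matched, 0)
  expect_equal(sffnet_forward(m2, x)$logits, base)
  expect_error(load_pretrained(m2, file.path(d, "empty.rds"), strict = TRUE),
               "strict")

  # a backbone-only checkpoint loads the backbone and reports the head
  w <- readRDS(ck)
  saveRDS(w[setdiff(names(w), c("fc.W", "fc.b"))], file.path(d, "bb.rds"))
  m3 <- sffnet_model(sffnet_config("reduced"), seed = 99)
  rep3 <- load_pretrained(m3, file.path(d, "bb.rds"))
  expect_setequal(rep3$missing_model, c("fc.W", "fc.b"))
  expect_error(load_pretrained(m3, file.path(d, "bb.rds"), strict = TRUE),
               "fc")
})

test_that("configuration invariants are enforced", {
  expect_error(sffnet_config(cbam_reduction = 7), "divide")
  expect_error(sffnet_config(cbam_spatial_kernel = 4), "odd")
  expect_error(sffnet_config(input_channels = 2), "1 or 3")
  expect_error(sffnet_config(stage_block_counts = c(1, 0, 1, 1)))
  cfg <- sffnet_config("full")
  expect_equal(cfg$stage_block_counts, c(3L, 4L, 23L, 3L))
})
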