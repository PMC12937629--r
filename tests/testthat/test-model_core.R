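# Architecture construction, shapes, forward contract, complexity.

test_that("analytic stage shapes follow the published progression", {
  sh <- intermediate_shapes(arch_config())
  expect_equal(sh[sh$stage == "stem", c("channels", "height", "width")],
               data.frame(channels = 64L, height = 224L, width = 224L),
               ignore_attr = TRUE)
  expect_equal(unlist(sh[sh$stage == "rdsb1", 2:4], use.names = FALSE),
               c(128L, 112L, 112L))
  expect_equal(unlist(sh[sh$stage == "rdsb2", 2:4], use.names = FALSE),
               c(256L, 56L, 56L))
  expect_equal(unlist(sh[sh$stage == "logits", 2:4], use.names = FALSE),
               c(9L, 1L, 1L))
  sh64 <- intermediate_shapes(arch_config(input_size = 64))
  expect_equal(unlist(sh64[sh64$stage == "rdsb2", 3:4], use.names = FALSE),
               c(16L, 16L))
})

test_that("analytic shapes agree with shapes observed during forward", {
  for (size in c(16L, 32L)) {
    cfg <- tiny_arch(input_size = size)
    set.seed(1)
    m <- build_bone_cnn(cfg)
    x <- array(rnorm(size * size * 2 * 2), dim = c(size, size, 2L, 2L))
    forward_logits(m, x, record_shapes = TRUE)
    sh <- intermediate_shapes(cfg)
    obs <- m$observed
    expect_equal(obs[["stem.conv2"]][1:3],
                 unlist(sh[sh$stage == "stem", c("height", "width", "channels")],
                        use.names = FALSE))
    expect_equal(obs[["rdsb1.pw"]][1:3],
                 unlist(sh[sh$stage == "rdsb1", c("height", "width", "channels")],
                        use.names = FALSE))
    expect_equal(obs[["msfa.fuse.conv"]][1:3],
                 unlist(sh[sh$stage == "msfa", c("height", "width", "channels")],
                        use.names = FALSE))
  }
})

test_that("invalid configurations are rejected with the offending field", {
  expect_error(arch_config(dropout_p = 1), "dropout_p")
  expect_error(arch_config(num_classes = 1), "num_classes")
  expect_error(arch_config(msfa_branch_kernels = c(1, 4)), "msfa_branch_kernels")
  expect_error(arch_config(stem_channels = c(0, 64)), "stem_channels")
})

test_that("forward yields a probability row per image, summing to one", {
  set.seed(2)
  m <- build_bone_cnn(tiny_arch())
  x <- array(rnorm(16 * 16 * 2 * 5), dim = c(16, 16, 2, 5))
  p <- predict(m, x, type = "prob")
  expect_equal(dim(p), c(5L, 3L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  # degenerate all-zero input stays finite
  p0 <- predict(m, array(0, dim = c(16, 16, 2, 2)), type = "prob")
  expect_true(all(is.finite(p0)))
  # shape mismatch is an input error
  expect_error(predict(m, array(0, dim = c(8, 8, 2, 1))), "spatial size")
  expect_error(predict(m, array(NaN, dim = c(16, 16, 2, 1))), "finite")
})

test_that("inference is deterministic and permutation-equivariant", {
  set.seed(3)
  m <- build_bone_cnn(tiny_arch())
  x <- array(rnorm(16 * 16 * 2 * 6), dim = c(16, 16, 2, 6))
  p1 <- predict(m, x, type = "prob")
  p2 <- predict(m, x, type = "prob")
  expect_identical(p1, p2)
  perm <- c(4, 1, 6, 2, 5, 3)
  pp <- predict(m, x[, , , perm, drop = FALSE], type = "prob")
  expect_equal(pp, p1[perm, ], tolerance = 1e-12)
})

test_that("parameter counts equal the closed-form per-layer sums", {
  set.seed(4)
  m <- build_bone_cnn(arch_config())
  rep <- count_parameters(m)
  # independent oracle: closed-form arithmetic on the default configuration
  conv <- function(k, cin, cout) k^2 * cin * cout
  bn <- function(c) 2 * c
  oracle <- conv(3, 3, 32) + bn(32) + conv(3, 32, 64) + bn(64) +         # stem
    (9 * 64 + bn(64) + conv(1, 64, 128) + bn(128) +                      # rdsb1
       conv(1, 64, 128) + bn(128)) +
    (9 * 128 + bn(128) + conv(1, 128, 256) + bn(256) +                   # rdsb2
       conv(1, 128, 256) + bn(256)) +
    conv(1, 256, 256) + bn(256) +                                        # rsb
    conv(1, 256, 128) + bn(128) + conv(3, 256, 128) + bn(128) +          # msfa
    conv(5, 256, 128) + bn(128) + conv(1, 384, 256) + bn(256) +
    (256 * 512 + 512) + (512 * 9 + 9)                                    # head
  expect_equal(rep$trainable_parameters, oracle)
  pl <- rep$per_layer
  expect_equal(pl$parameters[pl$layer == "stem.conv2"], 18432)
  expect_equal(pl$parameters[pl$layer == "head.fc2"], 4617)
  expect_equal(sum(pl$parameters), rep$trainable_parameters)
})

test_that("MAC counts match hand-derived values and the measured pass", {
  set.seed(5)
  m <- build_bone_cnn(arch_config())
  rep <- count_macs(m)
  pl <- rep$per_layer
  expect_equal(pl$macs[pl$layer == "stem.conv2"], 18432 * 224 * 224)
  expect_equal(pl$macs[pl$layer == "msfa.b5.conv"], 25 * 256 * 128 * 56 * 56)
  expect_equal(sum(pl$macs), rep$macs)
  # a 1x1 convolution with one in/out channel on a 1x1 input costs one MAC
  x1 <- array(2, dim = c(1, 1, 1, 1))
  w1 <- array(3, dim = c(1, 1, 1, 1))
  expect_equal(as.vector(boneCNN:::cpp_conv_fwd(x1, w1, 1L, 0L)), 6)
  # measured (hook) MACs at a smaller input size agree exactly
  set.seed(5)
  m64 <- build_bone_cnn(arch_config(input_size = 64))
  expect_identical(count_macs(m64)$macs, count_macs_measured(m64)$macs)
})

test_that("convolution kernels match a direct-summation oracle", {
  set.seed(6)
  x <- array(rnorm(6 * 6 * 2 * 1), dim = c(6, 6, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 3), dim = c(3, 3, 2, 3))
  for (stride in c(1L, 2L)) {
    y <- boneCNN:::cpp_conv_fwd(x, w, stride, 1L)
    ho <- dim(y)[1]
    # brute-force correlation with zero padding
    for (o in 1:3) for (oh in 1:ho) for (ow in 1:ho) {
      acc <- 0
      for (c in 1:2) for (kh in 1:3) for (kw in 1:3) {
        ih <- (oh - 1) * stride + kh - 1
        iw <- (ow - 1) * stride + kw - 1
        if (ih >= 1 && ih <= 6 && iw >= 1 && iw <= 6)
          acc <- acc + x[ih, iw, c, 1] * w[kh, kw, c, o]
      }
      expect_equal(y[oh, ow, o, 1], acc, tolerance = 1e-12)
    }
  }
})

test_that("backpropagation matches finite differences on a tiny model", {
  set.seed(7)
  cfg <- tiny_arch(input_size = 8L)
  m <- build_bone_cnn(cfg)
  x <- array(rnorm(8 * 8 * 2 * 3), dim = c(8, 8, 2, 3))
  y <- c(0L, 1L, 2L)
  loss_fn <- function() softmax_crossentropy(forward_logits(m, x, TRUE), y)$loss
  lo <- softmax_crossentropy(forward_logits(m, x, TRUE), y)
  boneCNN:::backward_bone_cnn(m, lo$dlogits)
  eps <- 1e-6
  for (lname in c("stem.conv1", "rdsb1.dw", "rdsb1.sc", "msfa.b3.conv",
                  "head.fc1", "stem.bn1")) {
    l <- m$layers[[lname]]
    for (f in boneCNN:::layer_param_fields(l)) {
      g <- l[[paste0("g", f)]]
      for (i in sample(length(l[[f]]), 2)) {
        v0 <- l[[f]][i]
        l[[f]][i] <- v0 + eps; lp <- loss_fn()
        l[[f]][i] <- v0 - eps; lm <- loss_fn()
        l[[f]][i] <- v0
        expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
      }
    }
  }
})

test_that("checkpoints round-trip the model exactly", {
  set.seed(8)
  m <- build_bone_cnn(tiny_arch())
  x <- array(rnorm(16 * 16 * 2 * 2), dim = c(16, 16, 2, 2))
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_identical(forward_logits(m, x), forward_logits(m2, x))
  expect_true(file.exists(sub("\\.rds$", ".json", ck)))
})
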