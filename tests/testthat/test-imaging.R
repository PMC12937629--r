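# Preprocessing: loading, resizing, normalisation, CLAHE, augmentation.

test_that("loading standardises size, channels and intensity scale", {
  td <- tempfile(); dir.create(td)
  # non-square 16-bit grayscale input
  img <- matrix(runif(128 * 256), 128, 256)
  f <- file.path(td, "a.png")
  png::writePNG(img, f, dpi = NULL)
  out <- load_and_standardize(f, size = 64L)
  expect_equal(dim(out), c(64L, 64L, 3L))
  expect_identical(out[, , 1], out[, , 2])
  expect_true(all(out >= 0 & out <= 1))
  # constant field resizes to the same constant
  png::writePNG(matrix(0.5, 100, 30), f)
  out <- load_and_standardize(f, size = 48L)
  expect_equal(as.vector(out), rep(out[1, 1, 1], length(out)), tolerance = 1e-6)
  # same-size input passes through up to 8-bit quantisation
  vals <- matrix((0:255)[1 + (seq_len(32 * 32) %% 256)] / 255, 32, 32)
  png::writePNG(vals, f)
  out <- load_and_standardize(f, size = 32L)
  expect_equal(out[, , 1], vals, tolerance = 1e-12)
  # unreadable file raises an I/O error naming the path
  expect_error(load_and_standardize(file.path(td, "missing.png")), "missing.png")
})

test_that("ImageNet normalisation centres and scales per channel", {
  img <- array(0, dim = c(2, 2, 3))
  img[, , 1] <- 0.485; img[, , 2] <- 0.456; img[, , 3] <- 0.406
  out <- normalize_image(img)
  expect_equal(as.vector(out), rep(0, 12))
  img[, , 1] <- 1
  out <- normalize_image(img)
  expect_equal(out[1, 1, 1], (1 - 0.485) / 0.229, tolerance = 1e-4)
  expect_error(normalize_image(matrix(0, 2, 2)), "\\(H, W, 3\\)")
})

test_that("CLAHE with one tile and no clipping equals global equalisation", {
  for (seed in 1:10) {
    set.seed(seed)
    img <- matrix(runif(256), 16, 16)
    expect_equal(clahe(img, Inf, c(1L, 1L)), global_equalize_oracle(img),
                 tolerance = 1e-12)
  }
})

test_that("CLAHE is a bounded mapping that preserves flat images", {
  cc <- clahe(matrix(0.37, 32, 32), 2.0, c(4L, 4L))
  expect_equal(as.vector(cc), rep(cc[1, 1], length(cc)))
  expect_lt(abs(cc[1, 1] - 0.37), 2 / 256)
  set.seed(1)
  out <- clahe(matrix(rbeta(64 * 64, 2, 5), 64, 64), 2.0, c(8L, 8L))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(clahe(matrix(0, 4, 4), 2.0, c(8L, 8L)), "tile grid")
})

test_that("augmentation draws are deterministic and identity-collapsible", {
  set.seed(2)
  img <- matrix(runif(64 * 64), 64, 64)
  id_pol <- augmentation_policy(rotation_degrees = 0, translation_fraction = 0,
                                hflip_probability = 0, gamma_range = c(1, 1),
                                apply_clahe = FALSE)
  expect_identical(random_augment(img, id_pol, seed = 5), img)
  pol <- augmentation_policy(seed = 9)
  a1 <- random_augment(img, pol, seed = 42)
  a2 <- random_augment(img, pol, seed = 42)
  expect_identical(a1, a2)
  expect_false(identical(a1, random_augment(img, pol, seed = 43)))
})

test_that("gamma correction and all transforms stay inside [0, 1]", {
  expect_equal(gamma_correct(matrix(0.5, 3, 3), 2), matrix(0.25, 3, 3))
  set.seed(3)
  for (i in 1:5) {
    img <- matrix(runif(32 * 32), 32, 32)
    pol <- augmentation_policy(rotation_degrees = runif(1, 0, 12),
                               translation_fraction = runif(1, 0, 0.049),
                               gamma_range = sort(runif(2, 0.8, 1.2)))
    out <- random_augment(img, pol, seed = i)
    expect_true(all(out >= 0 & out <= 1))
    expect_equal(dim(out), dim(img))
  }
})

test_that("invalid augmentation policies are configuration errors", {
  expect_error(augmentation_policy(rotation_degrees = 15), "rotation")
  expect_error(augmentation_policy(translation_fraction = 0.05), "translation")
  expect_error(augmentation_policy(hflip_probability = 1.5), "flip")
  expect_error(augmentation_policy(gamma_range = c(1.2, 0.8)), "gamma")
})

test_that("balancing plans spread copies evenly and respect targets", {
  plan <- plan_class_balancing(c(A = 100L, B = 100L),
                               c(A = 600L, B = 100L), seed = 1)
  expect_equal(plan$A$multiplicities, rep(5L, 100))
  expect_equal(plan$B$multiplicities, rep(0L, 100))
  expect_equal(planned_total(plan), 700)
  plan2 <- plan_class_balancing(c(A = 7L), c(A = 17L), seed = 2)
  expect_equal(sum(plan2$A$multiplicities), 10)
  expect_lte(diff(range(plan2$A$multiplicities)), 1)
  expect_error(plan_class_balancing(c(A = 10L), c(A = 5L)), "below")
})

test_that("published class targets reproduce the 6631-image working set", {
  dist <- bone_tumor_class_distribution()
  # original per-class counts must stay below the augmentation targets;
  # planning up to the published totals yields the published dataset size
  current <- stats::setNames(pmin(dist$total, 98L), dist$class_name)
  plan <- plan_class_balancing(current, stats::setNames(dist$total,
                                                        dist$class_name))
  expect_equal(planned_total(plan), 6631)
})
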