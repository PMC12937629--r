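# Manifests, stratified splitting, k-fold planning, CSV round-trips.

test_that("manifest construction walks class directories in sorted order", {
  td <- tempfile()
  sp <- phantom_spec(image_size = 32L, seed = 5)
  gen <- generate_dataset(4, sp, td)
  m <- build_manifest(td)
  expect_equal(nrow(m), 36L)
  expect_equal(attr(m, "class_names"), paste0("C", 0:8))
  expect_equal(unname(table(m$class_index)), rep(4L, 9), ignore_attr = TRUE)
  expect_true(all(m$split == "unassigned"))
  expect_equal(sort(m$path), sort(gen$path))
  expect_error(build_manifest(file.path(td, "nope")), "no such directory")
})

test_that("duplicate paths and unknown split tokens are format errors", {
  df <- data.frame(path = c("a.png", "a.png"), class_index = 0L,
                   class_name = "C0", split = "unassigned",
                   origin = "original", source_image = "", seed = 1L)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_manifest(f), "unique")
  df <- data.frame(path = c("a.png", "b.png"), class_index = 0L,
                   class_name = "C0", split = c("train", "training"),
                   origin = "original", source_image = "", seed = 1L)
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_manifest(f), "line 3.*training")
  utils::write.csv(df[0, ], f, row.names = FALSE)
  expect_equal(nrow(read_manifest(f)), 0L)
})

test_that("stratified split matches the published 600-record allocation", {
  m <- fake_manifest(c(C0 = 600L))
  m <- stratified_split(m, split_spec(c(0.7, 0.2, 0.1), seed = 4))
  expect_equal(unname(table(m$split)[c("train", "val", "test")]),
               c(420L, 120L, 60L), ignore_attr = TRUE)
})

test_that("split fractions of (1,0,0) put every record in train", {
  m <- stratified_split(fake_manifest(c(A = 13L, B = 7L)),
                        split_spec(c(1, 0, 0), seed = 1))
  expect_true(all(m$split == "train"))
})

test_that("per-class subset sizes stay within one of n * fraction", {
  set.seed(10)
  for (rep in 1:25) {
    counts <- sample(5:300, 4)
    names(counts) <- paste0("K", 1:4)
    m <- stratified_split(fake_manifest(counts),
                          split_spec(c(0.7, 0.2, 0.1), seed = rep))
    for (cl in names(counts)) {
      n <- counts[[cl]]
      got <- table(factor(m$split[m$class_name == cl],
                          levels = c("train", "val", "test")))
      expect_equal(sum(got), n)
      expect_true(all(abs(got - n * c(0.7, 0.2, 0.1)) <= 1))
    }
  }
})

test_that("published per-class table cells obey the same +/-1 stratification", {
  dist <- bone_tumor_class_distribution()
  expect_equal(sum(dist$total), 6631L)
  expect_true(all(abs(dist$train - dist$total * 0.7) <= 1))
  expect_true(all(abs(dist$validation - dist$total * 0.2) <= 1))
  expect_true(all(abs(dist$test - dist$total * 0.1) <= 1))
  expect_equal(dist$train + dist$validation + dist$test, dist$total)
})

test_that("split assignment is deterministic in the seed", {
  m1 <- stratified_split(fake_manifest(c(A = 57L, B = 91L)),
                         split_spec(seed = 7))
  m2 <- stratified_split(fake_manifest(c(A = 57L, B = 91L)),
                         split_spec(seed = 7))
  expect_identical(m1$split, m2$split)
  m3 <- stratified_split(fake_manifest(c(A = 57L, B = 91L)),
                         split_spec(seed = 8))
  expect_false(identical(m1$split, m3$split))
})

test_that("classes smaller than the subset count are rejected by name", {
  expect_error(stratified_split(fake_manifest(c(tiny = 2L)),
                                split_spec(c(0.7, 0.2, 0.1), seed = 1)),
               "tiny")
})

test_that("k-fold plans partition records with balanced strata", {
  m <- fake_manifest(stats::setNames(rep(10L, 9), paste0("C", 0:8)))
  plan <- kfold_plan(m, k = 5, seed = 2)
  expect_equal(unname(table(plan$assignment)), rep(18L, 5), ignore_attr = TRUE)
  for (f in 1:5)
    expect_equal(unname(table(m$class_index[plan$assignment == f])),
                 rep(2L, 9), ignore_attr = TRUE)
  # 93 records: fold sizes within one of 93/5
  m2 <- fake_manifest(c(A = 45L, B = 48L))
  p2 <- kfold_plan(m2, k = 5, seed = 3)
  expect_true(all(abs(table(p2$assignment) - 93 / 5) <= 1))
  expect_equal(sort(unlist(lapply(1:5, function(f) which(p2$assignment == f)))),
               seq_len(93))
  expect_error(kfold_plan(fake_manifest(c(A = 3L)), k = 5), "fewer than k")
})

test_that("manifest CSV round-trips exactly, including augmented records", {
  td <- tempfile()
  sp <- phantom_spec(image_size = 32L, seed = 6)
  m <- generate_dataset(5, sp, td)
  m <- stratified_split(m, split_spec(seed = 2))
  cur <- table(m$class_name[m$split == "train"])
  plan <- plan_class_balancing(stats::setNames(as.integer(cur), names(cur)),
                               stats::setNames(rep(5L, 9), names(cur)),
                               seed = 3)
  m <- materialize_augmented_set(m, plan, augmentation_policy(seed = 4))
  f <- tempfile(fileext = ".csv")
  write_manifest(m, f)
  m2 <- read_manifest(f)
  expect_identical(as.data.frame(m), as.data.frame(m2))
  expect_identical(attr(m, "class_names"), attr(m2, "class_names"))
})
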