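#' Published class distribution of the nine-class tumour benchmark
#'
#' The per-class image counts of the augmented nine-class primary bone
#' tumour radiograph benchmark, together with its published stratified
#' 70/20/10 train/validation/test allocation (6631 images in total, 4640
#' of them in the training split).  These counts serve as the default
#' class-balancing targets of the augmentation planner.
#'
#' @return A data frame with columns `class_name`, `total`, `train`,
#'   `validation`, `test`.
#' @export
bone_tumor_class_distribution <- function() {
  data.frame(
    class_name = paste0("C", 0:8),
    total = c(600L, 1403L, 984L, 626L, 600L, 672L, 482L, 600L, 664L),
    train = c(420L, 982L, 688L, 438L, 420L, 470L, 337L, 420L, 465L),
    validation = c(120L, 281L, 197L, 125L, 120L, 134L, 96L, 120L, 133L),
    test = c(60L, 140L, 99L, 63L, 60L, 68L, 49L, 60L, 66L),
    stringsAsFactors = FALSE
  )
}

manifest_columns <- c("path", "class_index", "class_name", "split", "origin",
                      "source_image")
split_tokens <- c("train", "val", "test", "unassigned")

new_manifest <- function(records, class_names, created_seed = NA_integer_) {
  stopifnot(identical(names(records), manifest_columns))
  structure(records,
            class_names = class_names,
            created_seed = created_seed,
            class = c("dataset_manifest", "data.frame"))
}

validate_manifest <- function(manifest) {
  if (anyDuplicated(manifest$path))
    stop("manifest paths must be unique", call. = FALSE)
  bad <- !manifest$split %in% split_tokens
  if (any(bad))
    stop(sprintf("unknown split token '%s'", manifest$split[which(bad)[1]]),
         call. = FALSE)
  k <- length(attr(manifest, "class_names"))
  if (nrow(manifest) > 0 &&
      (min(manifest$class_index) < 0L || max(manifest$class_index) >= k))
    stop("class indices must be dense in 0..K-1", call. = FALSE)
  aug <- manifest$origin == "augmented"
  if (any(aug & manifest$split != "train"))
    stop("augmented records must live in the train split", call. = FALSE)
  if (any(aug & is.na(manifest$source_image)))
    stop("augmented records must reference their source image", call. = FALSE)
  invisible(manifest)
}

#' Build a dataset manifest from a class-per-directory tree
#'
#' Scans `root/<class_name>/*.png`; class order is the sorted directory
#' names, class indices 0..K-1 in that order.  All records start with
#' split `"unassigned"` and origin `"original"`.
#'
#' @param root Dataset root directory.
#' @return A `dataset_manifest` (a data frame with one row per image).
#' @export
build_manifest <- function(root) {
  if (!dir.exists(root)) stop(sprintf("no such directory: %s", root), call. = FALSE)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L)
    stop(sprintf("no class directories under %s", root), call. = FALSE)
  recs <- lapply(seq_along(classes), function(i) {
    files <- sort(list.files(file.path(root, classes[i]), pattern = "\\.png$",
                             full.names = TRUE))
    if (length(files) == 0L)
      warning(sprintf("class directory '%s' contains no PNG files", classes[i]),
              call. = FALSE)
    if (length(files) == 0L) return(NULL)
    data.frame(path = files, class_index = i - 1L, class_name = classes[i],
               split = "unassigned", origin = "original",
               source_image = NA_character_, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  m <- new_manifest(records, classes)
  validate_manifest(m)
  m
}

#' Stratified split specification
#'
#' @param fractions Length-3 numeric `(train, val, test)`, non-negative,
#'   summing to 1.
#' @param seed Integer seed for the per-class shuffles.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.70, 0.20, 0.10), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three non-negative values summing to 1",
         call. = FALSE)
  structure(list(fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

# Allocate n records to (train, val, test): floor(n * f) to train and val,
# remainder to test, then move single records from over-full to under-full
# subsets (largest fractional remainder first) until every subset is within
# one record of its ideal size n * f.
split_counts <- function(n, fractions) {
  ideal <- n * fractions
  counts <- c(floor(ideal[1]), floor(ideal[2]), 0)
  counts[3] <- n - counts[1] - counts[2]
  frac <- ideal - floor(ideal)
  while (max(counts - ideal) > 1 + 1e-9) {
    from <- which.max(counts - ideal)
    under <- which(counts < ideal)
    to <- under[order(-frac[under], under)][1]
    counts[from] <- counts[from] - 1
    counts[to] <- counts[to] + 1
  }
  as.integer(counts)
}

#' Stratified 70/20/10 split at image level
#'
#' Assigns every record of each class to train/val/test so that each
#' subset's size is within one record of `n * fraction`, using a seeded
#' per-class shuffle.  Splitting is performed on original images before any
#' augmentation; see [materialize_augmented_set()].
#'
#' @param manifest A `dataset_manifest` whose records are all unassigned.
#' @param spec A [split_spec()].
#' @return The manifest with the `split` column filled in.
#' @export
stratified_split <- function(manifest, spec = split_spec()) {
  validate_manifest(manifest)
  if (any(manifest$split != "unassigned"))
    stop("manifest already has split assignments", call. = FALSE)
  n_subsets <- sum(spec$fractions > 0)
  set.seed(spec$seed)
  for (ci in sort(unique(manifest$class_index))) {
    rows <- which(manifest$class_index == ci)
    n <- length(rows)
    if (n < n_subsets)
      stop(sprintf("class '%s' has %d records, fewer than the %d subsets",
                   manifest$class_name[rows[1]], n, n_subsets), call. = FALSE)
    counts <- split_counts(n, spec$fractions)
    ord <- sample(rows)
    manifest$split[ord] <- rep(c("train", "val", "test"), counts)
  }
  attr(manifest, "created_seed") <- spec$seed
  validate_manifest(manifest)
  manifest
}

#' Stratified k-fold plan
#'
#' Partitions the records into `k` folds, stratified by class: within each
#' class a seeded shuffle is dealt round-robin, so per-class fold sizes
#' differ by at most one.  Fold `f`'s validation set is the records
#' assigned `f`.
#'
#' @param manifest A `dataset_manifest`.
#' @param k Number of folds.
#' @param seed Seed for the per-class shuffles.
#' @return List of class `fold_plan` with `k`, `seed` and `assignment`
#'   (an integer vector in `1..k`, aligned with the manifest rows).
#' @export
kfold_plan <- function(manifest, k = 5L, seed = 1L) {
  validate_manifest(manifest)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  set.seed(seed)
  assignment <- integer(nrow(manifest))
  for (ci in sort(unique(manifest$class_index))) {
    rows <- which(manifest$class_index == ci)
    if (length(rows) < k)
      stop(sprintf("class '%s' has fewer than k = %d records",
                   manifest$class_name[rows[1]], k), call. = FALSE)
    ord <- sample(rows)
    assignment[ord] <- rep_len(seq_len(k), length(ord))
  }
  structure(list(k = k, seed = as.integer(seed), assignment = assignment),
            class = "fold_plan")
}

#' Read / write dataset manifests as CSV
#'
#' The CSV carries the documented columns
#' `path,class_index,class_name,split,origin,source_image,seed` (UTF-8,
#' header required); `write_manifest()` followed by `read_manifest()` is
#' the identity on all fields.
#'
#' @param manifest A `dataset_manifest`.
#' @param path CSV file path.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  df$seed <- attr(manifest, "created_seed")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @return `read_manifest()` returns a `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(path = "character",
                                       class_name = "character",
                                       split = "character",
                                       origin = "character",
                                       source_image = "character"))
  missing <- setdiff(c(manifest_columns, "seed"), names(df))
  if (length(missing) > 0)
    stop(sprintf("manifest '%s' is missing columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad <- which(!df$split %in% split_tokens)
  if (length(bad) > 0)
    stop(sprintf("manifest '%s' line %d: unknown split token '%s'",
                 path, bad[1] + 1L, df$split[bad[1]]), call. = FALSE)
  df$source_image[!nzchar(df$source_image) | is.na(df$source_image)] <- NA_character_
  seed <- if (nrow(df) > 0) df$seed[1] else NA_integer_
  pairs <- unique(df[, c("class_index", "class_name")])
  class_names <- pairs$class_name[order(pairs$class_index)]
  recs <- df[, manifest_columns]
  rownames(recs) <- NULL
  m <- new_manifest(recs, class_names, as.integer(seed))
  validate_manifest(m)
  m
}

#' Summarise a manifest
#'
#' @param object A `dataset_manifest`.
#' @param ... Unused.
#' @export
summary.dataset_manifest <- function(object, ...) {
  tab <- table(class = object$class_name, split = object$split)
  cat(sprintf("dataset manifest: %d records, %d classes\n", nrow(object),
              length(attr(object, "class_names"))))
  print(tab)
  invisible(tab)
}
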