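#' Plan class-balancing augmentation
#'
#' Distributes `target - current` augmented copies per class as evenly as
#' possible over that class's original images: every image receives
#' `floor(extra / current)` copies and a seeded draw (without replacement)
#' assigns the remainder, so multiplicities differ by at most one within a
#' class.
#'
#' @param current_counts Named integer vector: images currently available
#'   per class.
#' @param target_counts Named integer vector with the same names: desired
#'   totals per class (defaults to the published nine-class distribution,
#'   see [bone_tumor_class_distribution()]).
#' @param seed Seed for the remainder assignment.
#' @return An `augmentation_plan`: per class, a list with `current`,
#'   `target` and `multiplicities` (copies per image, in the class's image
#'   order).
#' @export
plan_class_balancing <- function(current_counts,
                                 target_counts = NULL,
                                 seed = 1L) {
  if (is.null(target_counts)) {
    dist <- bone_tumor_class_distribution()
    target_counts <- stats::setNames(dist$total, dist$class_name)
    target_counts <- target_counts[names(current_counts)]
  }
  if (!identical(sort(names(current_counts)), sort(names(target_counts))))
    stop("current and target counts must cover the same classes", call. = FALSE)
  set.seed(seed)
  plan <- lapply(names(current_counts), function(cl) {
    cur <- as.integer(current_counts[[cl]])
    tgt <- as.integer(target_counts[[cl]])
    if (tgt < cur)
      stop(sprintf("target for class '%s' (%d) is below its current count (%d)",
                   cl, tgt, cur), call. = FALSE)
    extra <- tgt - cur
    mult <- rep(extra %/% cur, cur)
    r <- extra %% cur
    if (r > 0) {
      lucky <- sample.int(cur, r)
      mult[lucky] <- mult[lucky] + 1L
    }
    list(current = cur, target = tgt, multiplicities = mult)
  })
  names(plan) <- names(current_counts)
  structure(plan, seed = as.integer(seed), class = "augmentation_plan")
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat("augmentation plan:\n")
  for (cl in names(x)) {
    cat(sprintf("  %s: %d -> %d (+%d copies)\n", cl, x[[cl]]$current,
                x[[cl]]$target, sum(x[[cl]]$multiplicities)))
  }
  cat(sprintf("  planned total: %d images\n", planned_total(x)))
  invisible(x)
}

#' @rdname plan_class_balancing
#' @param plan An `augmentation_plan`.
#' @export
planned_total <- function(plan) {
  sum(vapply(plan, function(p) p$current + sum(p$multiplicities), 1))
}

#' Materialise an augmentation plan as PNG files
#'
#' Applies the plan to the training split only: for every original training
#' image of each class, writes the planned number of augmented copies
#' (named `<stem>_aug<k>.png` next to the source image, or under
#' `out_dir`), each produced by one seeded draw of the augmentation policy,
#' and appends the corresponding records with `origin = "augmented"`.
#' Validation and test records are never touched; a plan whose class has
#' more multiplicities than the class has training images is rejected.
#'
#' Per-copy seeds are derived deterministically from the policy seed, the
#' source image's position and the copy number, so a manifest, plan and
#' policy reproduce byte-identical files.
#'
#' @param manifest A split `dataset_manifest`.
#' @param plan An [plan_class_balancing()] result keyed by class name,
#'   multiplicities aligned with the class's training images in manifest
#'   order.
#' @param policy An [augmentation_policy()].
#' @param out_dir Optional directory for the augmented files (class
#'   subdirectories are created); defaults to each source image's directory.
#' @return The extended manifest.
#' @export
materialize_augmented_set <- function(manifest, plan,
                                      policy = augmentation_policy(),
                                      out_dir = NULL) {
  validate_manifest(manifest)
  new_rows <- list()
  for (cl in names(plan)) {
    rows <- which(manifest$class_name == cl & manifest$origin == "original")
    train_rows <- rows[manifest$split[rows] == "train"]
    mult <- plan[[cl]]$multiplicities
    if (length(mult) > length(train_rows))
      stop(sprintf(
        "plan for class '%s' covers %d images but only %d train records exist",
        cl, length(mult), length(train_rows)), call. = FALSE)
    if (plan[[cl]]$current != length(train_rows))
      stop(sprintf(
        "plan for class '%s' was built for %d images but the train split has %d",
        cl, plan[[cl]]$current, length(train_rows)), call. = FALSE)
    for (j in seq_along(mult)) {
      if (mult[j] == 0L) next
      src <- manifest$path[train_rows[j]]
      img <- png::readPNG(src)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      dir <- if (is.null(out_dir)) dirname(src) else {
        d <- file.path(out_dir, cl)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        d
      }
      stem <- tools::file_path_sans_ext(basename(src))
      for (copy in seq_len(mult[j])) {
        seed <- derive_seed(policy$seed, train_rows[j], copy)
        aug <- random_augment(img, policy, seed = seed)
        dest <- file.path(dir, sprintf("%s_aug%03d.png", stem, copy))
        png::writePNG(aug, dest)
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          path = dest, class_index = manifest$class_index[train_rows[j]],
          class_name = cl, split = "train", origin = "augmented",
          source_image = src, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(new_rows) == 0L) return(manifest)
  records <- rbind(as.data.frame(manifest),
                   do.call(rbind, c(new_rows, list(make.row.names = FALSE))))
  rownames(records) <- NULL
  m <- new_manifest(records, attr(manifest, "class_names"),
                    attr(manifest, "created_seed"))
  validate_manifest(m)
  m
}

# Deterministic 31-bit seed from a base seed and record/copy indices.
derive_seed <- function(base, record, copy) {
  as.integer((as.numeric(base) * 100003 + record * 1009 + copy) %% 2147483647)
}
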