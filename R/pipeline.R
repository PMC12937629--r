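#' Load one split of a manifest into memory
#'
#' Reads every record of the requested split with
#' [load_and_standardize()], optionally applies the ImageNet
#' normalisation, and stacks the result into an `(S, S, 3, N)` array with
#' 0-based integer labels.
#'
#' @param manifest A `dataset_manifest`.
#' @param split One of `"train"`, `"val"`, `"test"`, or `"all"`.
#' @param input_size Target image side length.
#' @param normalize Apply [normalize_image()] to every image.
#' @param spec A [normalization_spec()].
#' @return List with `x`, `y`, `paths` and `class_names`.
#' @export
load_split <- function(manifest, split = "train", input_size = 224L,
                       normalize = TRUE, spec = normalization_spec()) {
  rows <- if (split == "all") seq_len(nrow(manifest)) else
    which(manifest$split == split)
  if (length(rows) == 0L)
    stop(sprintf("no records with split '%s'", split), call. = FALSE)
  n <- length(rows)
  x <- array(0, dim = c(input_size, input_size, 3L, n))
  for (i in seq_len(n)) {
    img <- load_and_standardize(manifest$path[rows[i]], input_size)
    if (normalize) img <- normalize_image(img, spec)
    x[, , , i] <- img
  }
  list(x = x, y = as.integer(manifest$class_index[rows]),
       paths = manifest$path[rows],
       class_names = attr(manifest, "class_names"))
}

#' Stratified k-fold cross-validation
#'
#' Plans `k` stratified folds over the manifest's training records (or all
#' records when no split is assigned), trains a freshly initialised model
#' on `k - 1` folds and evaluates on the held-out fold, and aggregates the
#' per-fold cross-entropy, accuracy and macro-F1 as mean and standard
#' deviation.
#'
#' @param manifest A `dataset_manifest`.
#' @param arch An [arch_config()].
#' @param train_cfg A [train_config()].
#' @param k Number of folds.
#' @param seed Seed for the fold plan; fold `f` trains with seed
#'   `seed + f`.
#' @param verbose Print per-epoch progress.
#' @return List of class `cv_report` with `fold_metrics` (one row per
#'   fold) and `summary` (mean +/- sd per metric).
#' @export
run_cv <- function(manifest, arch, train_cfg = train_config(), k = 5L,
                   seed = 1L, verbose = FALSE) {
  rows <- if (any(manifest$split == "train"))
    which(manifest$split == "train") else seq_len(nrow(manifest))
  sub <- new_manifest(as.data.frame(manifest)[rows, manifest_columns],
                      attr(manifest, "class_names"),
                      attr(manifest, "created_seed"))
  rownames(sub) <- NULL
  plan <- kfold_plan(sub, k, seed)
  all_data <- load_split(sub, "all", arch$input_size)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- plan$assignment == f
    tr <- list(x = all_data$x[, , , !hold, drop = FALSE],
               y = all_data$y[!hold])
    va <- list(x = all_data$x[, , , hold, drop = FALSE],
               y = all_data$y[hold])
    cfg_f <- train_cfg
    cfg_f$seed <- train_cfg$seed + f
    set.seed(cfg_f$seed)
    model <- build_bone_cnn(arch)
    fit <- train_model(model, tr, va, cfg_f, verbose = verbose)
    rep <- evaluate_model(fit$model, va, all_data$class_names)
    folds[[f]] <- data.frame(fold = f, cross_entropy = rep$mean_loss,
                             accuracy = rep$accuracy,
                             macro_f1 = rep$macro_f1)
  }
  fold_metrics <- do.call(rbind, folds)
  out <- list(fold_metrics = fold_metrics,
              summary = cv_aggregate(fold_metrics[, -1]))
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation:\n", nrow(x$fold_metrics)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
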