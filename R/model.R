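#' Build the Bone-CNN model
#'
#' Constructs the full layer graph described by an [arch_config()]: stem
#' (two 3x3 conv->BN->ReLU layers at full resolution), RDSB-1 and RDSB-2
#' (depthwise 3x3 -> BN -> ReLU -> pointwise 1x1 -> BN plus a projection
#' shortcut, followed by ReLU), a 1x1 refinement block, the MSFA module
#' (parallel 1x1/3x3/5x5 branches concatenated and fused by a 1x1
#' convolution), global average pooling and the fully connected head.
#' Convolutions followed by batch normalisation carry no bias; the two
#' fully connected layers do.  Softmax is applied only at prediction time;
#' training consumes raw logits.
#'
#' Weight initialisation draws from the current RNG stream: call
#' `set.seed()` beforehand for reproducible models.
#'
#' @param config An [arch_config()].
#' @return An object of class `bone_cnn`.
#' @examples
#' set.seed(1)
#' model <- build_bone_cnn(arch_config(input_size = 64))
#' @export
build_bone_cnn <- function(config) {
  validate_arch_config(config)
  L <- list()
  sc <- config$stem_channels
  L$stem.conv1 <- new_conv("stem.conv1", 3L, config$input_channels, sc[1])
  L$stem.bn1 <- new_bn("stem.bn1", sc[1])
  L$stem.conv2 <- new_conv("stem.conv2", 3L, sc[1], sc[2])
  L$stem.bn2 <- new_bn("stem.bn2", sc[2])
  for (i in seq_along(config$rdsb_specs)) {
    sp <- config$rdsb_specs[[i]]
    p <- sprintf("rdsb%d", i)
    L[[paste0(p, ".dw")]] <- new_dwconv(paste0(p, ".dw"), sp[1], 3L, sp[3])
    L[[paste0(p, ".bn1")]] <- new_bn(paste0(p, ".bn1"), sp[1])
    L[[paste0(p, ".pw")]] <- new_conv(paste0(p, ".pw"), 1L, sp[1], sp[2])
    L[[paste0(p, ".bn2")]] <- new_bn(paste0(p, ".bn2"), sp[2])
    if (sp[1] != sp[2] || sp[3] != 1L) {
      L[[paste0(p, ".sc")]] <- new_conv(paste0(p, ".sc"), 1L, sp[1], sp[2], sp[3])
      L[[paste0(p, ".scbn")]] <- new_bn(paste0(p, ".scbn"), sp[2])
    }
  }
  last_c <- config$rdsb_specs[[length(config$rdsb_specs)]][2]
  L$rsb.conv <- new_conv("rsb.conv", 1L, last_c, config$refine_channels)
  L$rsb.bn <- new_bn("rsb.bn", config$refine_channels)
  for (k in config$msfa_branch_kernels) {
    nm <- sprintf("msfa.b%d", k)
    L[[paste0(nm, ".conv")]] <- new_conv(paste0(nm, ".conv"), k,
                                         config$refine_channels,
                                         config$msfa_branch_channels)
    L[[paste0(nm, ".bn")]] <- new_bn(paste0(nm, ".bn"),
                                     config$msfa_branch_channels)
  }
  cat_c <- config$msfa_branch_channels * length(config$msfa_branch_kernels)
  L$msfa.fuse.conv <- new_conv("msfa.fuse.conv", 1L, cat_c,
                               config$msfa_fused_channels)
  L$msfa.fuse.bn <- new_bn("msfa.fuse.bn", config$msfa_fused_channels)
  L$head.fc1 <- new_dense("head.fc1", config$msfa_fused_channels,
                          config$head_hidden_units)
  L$head.fc2 <- new_dense("head.fc2", config$head_hidden_units,
                          config$num_classes)

  model <- new.env(parent = emptyenv())
  model$config <- config
  model$layers <- L
  model$cache <- new.env(parent = emptyenv())
  class(model) <- "bone_cnn"
  model
}

#' @export
print.bone_cnn <- function(x, ...) {
  rep <- count_parameters(x)
  cat(sprintf("Bone-CNN model: %d layers, %s trainable parameters (%.3f M)\n",
              length(x$layers), format(rep$trainable_parameters, big.mark = ","),
              rep$parameters_millions))
  print(x$config)
  invisible(x)
}

as_batch <- function(x, config) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) != 4L)
    stop("input must be an (H, W, C) image or an (H, W, C, N) batch", call. = FALSE)
  if (d[1] != config$input_size || d[2] != config$input_size)
    stop(sprintf("input spatial size %dx%d does not match configured %d",
                 d[1], d[2], config$input_size), call. = FALSE)
  if (d[3] != config$input_channels)
    stop(sprintf("input has %d channels, expected %d", d[3],
                 config$input_channels), call. = FALSE)
  if (!all(is.finite(x))) stop("input contains non-finite values", call. = FALSE)
  x
}

# Run one 'conv -> BN -> ReLU' unit, caching what backward needs.
cbr_fwd <- function(model, conv_name, bn_name, x, training, record) {
  L <- model$layers
  fwd <- if (L[[conv_name]]$kind == "dwconv") dwconv_fwd else conv_fwd
  y <- bn_fwd(L[[bn_name]], fwd(L[[conv_name]], x, training), training,
              relu = TRUE)
  if (training) model$cache[[paste0("relu.", bn_name)]] <- y
  if (record) model$observed[[conv_name]] <- dim(y)
  y
}

cbr_bwd <- function(model, conv_name, bn_name, dy) {
  L <- model$layers
  dy <- relu_bwd(dy, model$cache[[paste0("relu.", bn_name)]])
  model$cache[[paste0("relu.", bn_name)]] <- NULL
  dy <- bn_bwd(L[[bn_name]], dy)
  bwd <- if (L[[conv_name]]$kind == "dwconv") dwconv_bwd else conv_bwd
  bwd(L[[conv_name]], dy)
}

#' Forward pass producing logits
#'
#' @param model A `bone_cnn` model.
#' @param x An `(H, W, C)` image or `(H, W, C, N)` batch matching the model's
#'   configured input size.
#' @param training Logical; use batch statistics and dropout (`TRUE`) or
#'   running statistics in inference mode (`FALSE`).
#' @param record_shapes Logical; record observed per-layer output shapes in
#'   `model$observed` (used by the complexity profiler's measurement pass).
#' @return A `num_classes x N` matrix of logits.
#' @export
forward_logits <- function(model, x, training = FALSE, record_shapes = FALSE) {
  cfg <- model$config
  x <- as_batch(x, cfg)
  L <- model$layers
  if (record_shapes) model$observed <- list()
  cache <- model$cache

  a <- cbr_fwd(model, "stem.conv1", "stem.bn1", x, training, record_shapes)
  a <- cbr_fwd(model, "stem.conv2", "stem.bn2", a, training, record_shapes)

  for (i in seq_along(cfg$rdsb_specs)) {
    p <- sprintf("rdsb%d", i)
    has_sc <- !is.null(L[[paste0(p, ".sc")]])
    if (training) cache[[paste0(p, ".in")]] <- a
    main <- cbr_fwd(model, paste0(p, ".dw"), paste0(p, ".bn1"), a, training,
                    record_shapes)
    main <- bn_fwd(L[[paste0(p, ".bn2")]],
                   conv_fwd(L[[paste0(p, ".pw")]], main, training), training)
    if (record_shapes) model$observed[[paste0(p, ".pw")]] <- dim(main)
    if (has_sc) {
      sc <- bn_fwd(L[[paste0(p, ".scbn")]],
                   conv_fwd(L[[paste0(p, ".sc")]], a, training), training)
      if (record_shapes) model$observed[[paste0(p, ".sc")]] <- dim(sc)
    } else {
      sc <- a
    }
    a <- cpp_add_relu(main, sc)
    if (training) cache[[paste0(p, ".out")]] <- a
  }

  a <- cbr_fwd(model, "rsb.conv", "rsb.bn", a, training, record_shapes)

  if (training) cache$msfa.in <- a
  branches <- lapply(cfg$msfa_branch_kernels, function(k) {
    nm <- sprintf("msfa.b%d", k)
    cbr_fwd(model, paste0(nm, ".conv"), paste0(nm, ".bn"), a, training,
            record_shapes)
  })
  cat_ <- do.call(abind4, branches)
  a <- cbr_fwd(model, "msfa.fuse.conv", "msfa.fuse.bn", cat_, training,
               record_shapes)

  if (training) cache$gap.in_dim <- dim(a)
  f <- gap_fwd(a)
  h <- relu_fwd(dense_fwd(L$head.fc1, f, training))
  if (training) cache$head.relu <- h
  dp <- dropout_fwd(h, cfg$dropout_p, training)
  if (training) cache$head.dropmask <- dp$mask
  logits <- dense_fwd(L$head.fc2, dp$y, training)
  if (record_shapes) {
    model$observed[["head.fc1"]] <- c(nrow(h), ncol(h))
    model$observed[["head.fc2"]] <- c(nrow(logits), ncol(logits))
  }
  logits
}

# Backward pass from dlogits; leaves gradients in each layer's g* slots.
backward_bone_cnn <- function(model, dlogits) {
  cfg <- model$config
  L <- model$layers
  cache <- model$cache

  dy <- dense_bwd(L$head.fc2, dlogits)
  if (!is.null(cache$head.dropmask)) dy <- dy * cache$head.dropmask
  dy <- relu_bwd(dy, cache$head.relu)
  dy <- dense_bwd(L$head.fc1, dy)
  dy <- gap_bwd(dy, cache$gap.in_dim)

  dy <- cbr_bwd(model, "msfa.fuse.conv", "msfa.fuse.bn", dy)
  bc <- cfg$msfa_branch_channels
  dmsfa_in <- 0
  for (j in seq_along(cfg$msfa_branch_kernels)) {
    k <- cfg$msfa_branch_kernels[j]
    nm <- sprintf("msfa.b%d", k)
    dslice <- slice4(dy, (j - 1L) * bc + seq_len(bc))
    dmsfa_in <- dmsfa_in + cbr_bwd(model, paste0(nm, ".conv"),
                                   paste0(nm, ".bn"), dslice)
  }
  dy <- cbr_bwd(model, "rsb.conv", "rsb.bn", dmsfa_in)

  for (i in rev(seq_along(cfg$rdsb_specs))) {
    p <- sprintf("rdsb%d", i)
    has_sc <- !is.null(L[[paste0(p, ".sc")]])
    dy <- relu_bwd(dy, cache[[paste0(p, ".out")]])
    dmain <- bn_bwd(L[[paste0(p, ".bn2")]], dy)
    dmain <- conv_bwd(L[[paste0(p, ".pw")]], dmain)
    dmain <- cbr_bwd(model, paste0(p, ".dw"), paste0(p, ".bn1"), dmain)
    if (has_sc) {
      dsc <- bn_bwd(L[[paste0(p, ".scbn")]], dy)
      dsc <- conv_bwd(L[[paste0(p, ".sc")]], dsc)
      dy <- dmain + dsc
    } else {
      dy <- dmain + dy
    }
    cache[[paste0(p, ".out")]] <- NULL
    cache[[paste0(p, ".in")]] <- NULL
  }

  dy <- cbr_bwd(model, "stem.conv2", "stem.bn2", dy)
  dy <- cbr_bwd(model, "stem.conv1", "stem.bn1", dy)
  invisible(dy)
}

# Concatenate (H, W, C, N) arrays along the channel axis.
abind4 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], 1L)
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    out[, , at + seq_len(dim(x)[3]), ] <- x
    at <- at + dim(x)[3]
  }
  out
}

slice4 <- function(x, channels) {
  y <- x[, , channels, , drop = FALSE]
  y
}

#' Predict from a Bone-CNN model
#'
#' Runs the network in inference mode (running batch-norm statistics, no
#' dropout) and applies softmax to the logits.  Hard class predictions take
#' the highest-probability class, breaking ties towards the lowest index.
#'
#' @param object A `bone_cnn` model.
#' @param x An image or batch (see [forward_logits()]).
#' @param type `"prob"` for an `N x K` matrix of class probabilities,
#'   `"class"` for 0-based hard labels, `"logits"` for raw logits.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.bone_cnn <- function(object, x, type = c("prob", "class", "logits"), ...) {
  type <- match.arg(type)
  logits <- forward_logits(object, x, training = FALSE)
  if (type == "logits") return(t(logits))
  probs <- t(softmax_cols(logits))
  if (type == "prob") return(probs)
  max.col(probs, ties.method = "first") - 1L
}

# Column-wise numerically stable softmax of a K x N matrix.
softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

#' Extract or restore model weights
#'
#' `get_weights()` returns all trainable parameters and batch-norm running
#' statistics as a named list of numeric arrays; `set_weights()` writes such
#' a list back into a model of identical architecture.
#'
#' @param model A `bone_cnn` model.
#' @return A named list of arrays.
#' @export
get_weights <- function(model) {
  out <- list()
  for (l in model$layers) {
    fields <- c(layer_param_fields(l),
                if (l$kind == "bn") c("running_mean", "running_var"))
    for (f in fields) out[[paste0(l$name, ".", f)]] <- l[[f]]
  }
  out
}

#' @rdname get_weights
#' @param weights A list produced by `get_weights()`.
#' @export
set_weights <- function(model, weights) {
  for (l in model$layers) {
    fields <- c(layer_param_fields(l),
                if (l$kind == "bn") c("running_mean", "running_var"))
    for (f in fields) {
      key <- paste0(l$name, ".", f)
      if (is.null(weights[[key]]))
        stop(sprintf("weights are missing entry '%s'", key), call. = FALSE)
      l[[f]] <- weights[[key]]
    }
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the weight list together with the architecture
#' configuration; a sidecar JSON file (same path with extension `.json`)
#' records the configuration in readable form.
#'
#' @param model A `bone_cnn` model.
#' @param path Checkpoint path (an `.rds` file).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), weights = get_weights(model)),
          path)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(unclass(model$config), sidecar, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a rebuilt `bone_cnn` model.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(arch_config, ck$config)
  model <- build_bone_cnn(cfg)
  set_weights(model, ck$weights)
  model
}
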