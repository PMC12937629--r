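#' Architecture configuration for Bone-CNN
#'
#' Declarative description of the Bone-CNN layer graph: a two-convolution
#' stem at full resolution, two strided residual depthwise separable blocks
#' (RDSB), a 1x1 refinement block (RSB), a multi-scale feature aggregation
#' (MSFA) module with parallel 1x1/3x3/5x5 branches, global average pooling
#' and a compact fully connected head.
#'
#' @param input_size Input image side length in pixels (images are square).
#' @param input_channels Number of input channels (radiographs are replicated
#'   to three channels for compatibility with ImageNet conventions).
#' @param stem_channels Integer pair: output channels of the two stem
#'   convolutions.
#' @param rdsb_specs List of `c(in, out, stride)` triples, one per residual
#'   depthwise separable block.
#' @param refine_channels Channels of the 1x1 refinement block (RSB-3).
#' @param msfa_branch_kernels Odd kernel sizes of the parallel MSFA branches.
#' @param msfa_branch_channels Output channels of every MSFA branch.
#' @param msfa_fused_channels Output channels of the 1x1 fusion convolution.
#' @param head_hidden_units Units of the hidden fully connected layer.
#' @param dropout_p Dropout probability applied before the final layer.
#' @param num_classes Number of output classes (9 for the multi-class tumour
#'   task, 2 for the binary external-validation variant).
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(input_size = 224L,
                        input_channels = 3L,
                        stem_channels = c(32L, 64L),
                        rdsb_specs = list(c(64L, 128L, 2L), c(128L, 256L, 2L)),
                        refine_channels = 256L,
                        msfa_branch_kernels = c(1L, 3L, 5L),
                        msfa_branch_channels = 128L,
                        msfa_fused_channels = 256L,
                        head_hidden_units = 512L,
                        dropout_p = 0.3,
                        num_classes = 9L) {
  cfg <- list(
    input_size = as.integer(input_size),
    input_channels = as.integer(input_channels),
    stem_channels = as.integer(stem_channels),
    rdsb_specs = lapply(rdsb_specs, as.integer),
    refine_channels = as.integer(refine_channels),
    msfa_branch_kernels = as.integer(msfa_branch_kernels),
    msfa_branch_channels = as.integer(msfa_branch_channels),
    msfa_fused_channels = as.integer(msfa_fused_channels),
    head_hidden_units = as.integer(head_hidden_units),
    dropout_p = as.numeric(dropout_p),
    num_classes = as.integer(num_classes)
  )
  class(cfg) <- "arch_config"
  validate_arch_config(cfg)
  cfg
}

#' @rdname arch_config
#' @param config An `arch_config` object.
#' @export
validate_arch_config <- function(config) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid architecture config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  counts <- c(
    input_size = config$input_size, input_channels = config$input_channels,
    refine_channels = config$refine_channels,
    msfa_branch_channels = config$msfa_branch_channels,
    msfa_fused_channels = config$msfa_fused_channels,
    head_hidden_units = config$head_hidden_units
  )
  for (f in names(counts)) {
    if (length(counts[[f]]) != 1L || is.na(counts[[f]]) || counts[[f]] < 1L)
      stop_cfg(f, "must be a single strictly positive integer")
  }
  if (length(config$stem_channels) != 2L || any(config$stem_channels < 1L))
    stop_cfg("stem_channels", "must be two strictly positive counts")
  for (s in config$rdsb_specs) {
    if (length(s) != 3L || any(s < 1L))
      stop_cfg("rdsb_specs", "entries must be (in, out, stride), all positive")
  }
  if (any(config$msfa_branch_kernels < 1L) ||
      any(config$msfa_branch_kernels %% 2L == 0L))
    stop_cfg("msfa_branch_kernels", "must be strictly positive odd kernel sizes")
  if (!is.finite(config$dropout_p) || config$dropout_p < 0 || config$dropout_p >= 1)
    stop_cfg("dropout_p", "must satisfy 0 <= p < 1")
  if (config$num_classes < 2L)
    stop_cfg("num_classes", "must be at least 2")
  invisible(config)
}

#' @export
print.arch_config <- function(x, ...) {
  cat("Bone-CNN architecture config\n")
  cat(sprintf("  input: %d x %d x %d\n", x$input_channels, x$input_size, x$input_size))
  cat(sprintf("  stem: %s channels\n", paste(x$stem_channels, collapse = " -> ")))
  for (i in seq_along(x$rdsb_specs)) {
    s <- x$rdsb_specs[[i]]
    cat(sprintf("  RDSB-%d: %d -> %d, stride %d\n", i, s[1], s[2], s[3]))
  }
  cat(sprintf("  RSB: 1x1, %d -> %d\n", x$rdsb_specs[[length(x$rdsb_specs)]][2],
              x$refine_channels))
  cat(sprintf("  MSFA: kernels {%s}, %d per branch -> fuse %d\n",
              paste(x$msfa_branch_kernels, collapse = ","),
              x$msfa_branch_channels, x$msfa_fused_channels))
  cat(sprintf("  head: %d -> %d -> %d (dropout %.2f)\n", x$msfa_fused_channels,
              x$head_hidden_units, x$num_classes, x$dropout_p))
  invisible(x)
}

#' Analytic per-stage output shapes
#'
#' Computes the output shape of every stage of the network from the
#' configuration alone, without running a forward pass.  For the default
#' configuration the spatial progression is 224x224 (stem) -> 112x112
#' (RDSB-1) -> 56x56 (RDSB-2, RSB-3, MSFA) -> global pooling.
#'
#' @param config An `arch_config`.
#' @return A data frame with columns `stage`, `channels`, `height`, `width`.
#' @export
intermediate_shapes <- function(config) {
  validate_arch_config(config)
  s <- config$input_size
  rows <- list(list("input", config$input_channels, s, s))
  rows <- c(rows, list(list("stem", config$stem_channels[2], s, s)))
  for (i in seq_along(config$rdsb_specs)) {
    sp <- config$rdsb_specs[[i]]
    s <- conv_out_dim(s, 3L, sp[3], 1L)
    rows <- c(rows, list(list(sprintf("rdsb%d", i), sp[2], s, s)))
  }
  rows <- c(rows, list(
    list("rsb", config$refine_channels, s, s),
    list("msfa", config$msfa_fused_channels, s, s),
    list("gap", config$msfa_fused_channels, 1L, 1L),
    list("head_hidden", config$head_hidden_units, 1L, 1L),
    list("logits", config$num_classes, 1L, 1L)
  ))
  data.frame(
    stage = vapply(rows, `[[`, "", 1L),
    channels = vapply(rows, function(r) as.integer(r[[2]]), 1L),
    height = vapply(rows, function(r) as.integer(r[[3]]), 1L),
    width = vapply(rows, function(r) as.integer(r[[4]]), 1L),
    stringsAsFactors = FALSE
  )
}

# Output side length of a convolution with square kernel k, stride s, pad p.
conv_out_dim <- function(n, k, stride, pad) {
  as.integer((n + 2L * pad - k) %/% stride + 1L)
}
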