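# Neural-network layer primitives.
#
# Each layer is a mutable environment holding its weights, its gradient
# slots and (while training) the forward cache needed for backpropagation.
# Heavy kernels (convolutions, batch-norm reductions) are compiled; glue
# stays in R.  Batches are arrays with dim = c(H, W, C, N).

new_layer <- function(.kind, .name, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$name <- .name
  fields <- list(...)
  for (f in names(fields)) assign(f, fields[[f]], envir = e)
  class(e) <- c(paste0("layer_", .kind), "bone_layer")
  e
}

# He-normal initialisation; draws come from the caller's RNG stream.
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

new_conv <- function(name, k, cin, cout, stride = 1L) {
  new_layer("conv", name,
            k = as.integer(k), cin = as.integer(cin), cout = as.integer(cout),
            stride = as.integer(stride), pad = as.integer((k - 1L) / 2L),
            W = he_init(c(k, k, cin, cout), k * k * cin))
}

new_dwconv <- function(name, c, k = 3L, stride = 1L) {
  new_layer("dwconv", name,
            k = as.integer(k), c = as.integer(c),
            stride = as.integer(stride), pad = as.integer((k - 1L) / 2L),
            W = he_init(c(k, k, c), k * k))
}

new_bn <- function(name, c, eps = 1e-5, momentum = 0.1) {
  new_layer("bn", name,
            c = as.integer(c), eps = eps, momentum = momentum,
            gamma = rep(1, c), beta = rep(0, c),
            running_mean = rep(0, c), running_var = rep(1, c))
}

new_dense <- function(name, nin, nout) {
  new_layer("dense", name,
            nin = as.integer(nin), nout = as.integer(nout),
            W = matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin),
            b = rep(0, nout))
}

conv_fwd <- function(l, x, training) {
  if (training) l$x <- x
  cpp_conv_fwd(x, l$W, l$stride, l$pad)
}

conv_bwd <- function(l, dy) {
  g <- cpp_conv_bwd(l$x, l$W, dy, l$stride, l$pad)
  l$gW <- g$dw
  l$x <- NULL
  g$dx
}

dwconv_fwd <- function(l, x, training) {
  if (training) l$x <- x
  cpp_dwconv_fwd(x, l$W, l$stride, l$pad)
}

dwconv_bwd <- function(l, dy) {
  g <- cpp_dwconv_bwd(l$x, l$W, dy, l$stride, l$pad)
  l$gW <- g$dw
  l$x <- NULL
  g$dx
}

bn_fwd <- function(l, x, training, relu = FALSE) {
  if (training) {
    st <- cpp_bn_stats(x)
    l$x <- x
    l$batch_mean <- st$mean
    l$batch_var <- st$var
    l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * st$mean
    l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * st$var
    cpp_bn_apply(x, l$gamma, l$beta, st$mean, st$var, l$eps, relu)
  } else {
    cpp_bn_apply(x, l$gamma, l$beta, l$running_mean, l$running_var, l$eps, relu)
  }
}

bn_bwd <- function(l, dy) {
  g <- cpp_bn_bwd(l$x, dy, l$gamma, l$batch_mean, l$batch_var, l$eps)
  l$ggamma <- g$dgamma
  l$gbeta <- g$dbeta
  l$x <- NULL
  g$dx
}

dense_fwd <- function(l, x, training) {
  if (training) l$x <- x
  sweep(l$W %*% x, 1L, l$b, "+")
}

dense_bwd <- function(l, dy) {
  l$gW <- dy %*% t(l$x)
  l$gb <- rowSums(dy)
  l$x <- NULL
  t(l$W) %*% dy
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

# `y` is the cached ReLU output; its positivity pattern equals the input's.
relu_bwd <- function(dy, y) {
  if (is.matrix(dy)) {
    dy[y <= 0] <- 0
    dy
  } else {
    cpp_relu_bwd(dy, y)
  }
}

gap_fwd <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

gap_bwd <- function(dy, in_dim) {
  hw <- in_dim[1] * in_dim[2]
  array(rep(as.vector(dy) / hw, each = hw), dim = in_dim)
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  list(y = x * mask, mask = mask)
}

# Trainable fields of a layer, in a fixed order (the optimiser relies on it).
layer_param_fields <- function(l) {
  switch(l$kind,
         conv = "W",
         dwconv = "W",
         bn = c("gamma", "beta"),
         dense = c("W", "b"),
         character(0))
}

layer_grad_field <- function(field) paste0("g", field)

layer_n_params <- function(l) {
  sum(vapply(layer_param_fields(l), function(f) length(l[[f]]), 1L))
}
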