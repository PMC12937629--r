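#' Synthetic radiograph phantom specification
#'
#' Parameters of the deterministic phantom generator used to exercise the
#' pipeline without clinical data.  Phantoms render a vertical long-bone
#' band (bright cortical stripes around a darker medullary cavity) on a
#' dark soft-tissue background, add one class-keyed lesion motif drawn
#' from the radiographic vocabulary that distinguishes bone tumours
#' (lytic discs, moth-eaten lucency clusters, ground-glass matrix,
#' exostoses, sunburst periosteal spicules, onion-skin laminations,
#' expansile remodelling, punctate calcifications, trabecular striation),
#' then blur with a Gaussian point-spread and add Gaussian noise.  The
#' phantoms validate code paths; they make no claim of radiological
#' realism.
#'
#' @param image_size Side length in pixels (at least 32).
#' @param num_classes Number of lesion classes (up to 9 motifs).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param contrast Lesion-to-bone intensity offset, in (0, 1].
#' @param blur_sigma Gaussian point-spread sigma in pixels (0 disables).
#' @param seed Base seed of the generator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 224L, num_classes = 9L, noise_sd = 0.03,
                         contrast = 0.35, blur_sigma = 1.0, seed = 1L) {
  sp <- list(image_size = as.integer(image_size),
             num_classes = as.integer(num_classes),
             noise_sd = noise_sd, contrast = contrast,
             blur_sigma = blur_sigma, seed = as.integer(seed))
  if (sp$image_size < 32L) stop("image_size must be at least 32", call. = FALSE)
  if (sp$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (sp$contrast <= 0 || sp$contrast > 1)
    stop("contrast must lie in (0, 1]", call. = FALSE)
  if (sp$num_classes < 2L || sp$num_classes > 9L)
    stop("num_classes must be between 2 and 9", call. = FALSE)
  class(sp) <- "phantom_spec"
  sp
}

# Separable Gaussian blur with edge replication.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(rep(1, r), seq_len(h), rep(h, r)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (t in seq_along(k)) out <- out + k[t] * pad[(t - 1) + seq_len(h), ]
  pad <- out[, c(rep(1, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (t in seq_along(k)) out <- out + k[t] * pad[, (t - 1) + seq_len(w)]
  out
}

#' Generate one phantom radiograph
#'
#' Deterministic given `(class_index, spec, seed)`: the lesion geometry is
#' drawn from an RNG seeded with `seed`, so identical calls give
#' bitwise-identical images.
#'
#' @param class_index 0-based lesion class.
#' @param spec A [phantom_spec()].
#' @param seed Seed for this image's random draws.
#' @return An `image_size x image_size` matrix in `[0, 1]`.
#' @export
generate_phantom <- function(class_index, spec = phantom_spec(), seed = 1L) {
  if (class_index < 0 || class_index >= spec$num_classes)
    stop(sprintf("class_index %d out of range 0..%d", class_index,
                 spec$num_classes - 1L), call. = FALSE)
  set.seed(seed)
  S <- spec$image_size
  bg <- 0.12; medulla <- 0.45; cortex <- 0.80
  ct <- spec$contrast

  yy <- matrix(seq_len(S), S, S) / S
  xx <- matrix(rep(seq_len(S), each = S), S, S) / S

  cx0 <- stats::runif(1, 0.45, 0.55)          # band centre (fraction of width)
  hw <- stats::runif(1, 0.17, 0.22)           # band half-width
  cth <- stats::runif(1, 0.035, 0.05)         # cortical thickness
  img <- matrix(bg, S, S) + 0.03 * xx          # mild detector gradient
  band <- abs(xx - cx0) < hw
  img[band] <- medulla
  cortical <- band & (abs(xx - cx0) > hw - cth)
  img[cortical] <- cortex

  ly <- stats::runif(1, 0.3, 0.7)              # lesion centre (fractions)
  lx <- cx0 + stats::runif(1, -0.4, 0.4) * (hw - cth)
  d <- sqrt((yy - ly)^2 + (xx - lx)^2)

  if (class_index == 0) {          # sharply marginated lytic disc + rim
    r <- stats::runif(1, 0.09, 0.13)
    img[d < r] <- medulla - ct
    img[d >= r & d < 1.22 * r] <- medulla + 0.6 * ct
  } else if (class_index == 1) {   # moth-eaten lucency cluster
    n <- sample(7:10, 1)
    for (i in seq_len(n)) {
      py <- ly + stats::runif(1, -0.13, 0.13)
      px <- lx + stats::runif(1, -0.6, 0.6) * (hw - cth)
      rr <- stats::runif(1, 0.018, 0.032)
      img[sqrt((yy - py)^2 + (xx - px)^2) < rr] <- medulla - ct
    }
  } else if (class_index == 2) {   # ground-glass matrix (hazy patch)
    r <- stats::runif(1, 0.12, 0.16)
    haze <- gaussian_blur(matrix(stats::runif(S * S, -1, 1), S, S),
                          max(2, S / 45))
    haze <- haze / max(abs(haze))
    inside <- d < r
    img[inside] <- medulla - 0.35 * ct + 0.45 * ct * haze[inside]
  } else if (class_index == 3) {   # exostotic protrusion off the cortex
    side <- sample(c(-1, 1), 1)
    ex <- cx0 + side * hw
    r <- stats::runif(1, 0.06, 0.09)
    bump <- sqrt((yy - ly)^2 + (xx - ex)^2) < r
    img[bump] <- cortex
  } else if (class_index == 4) {   # radiating sunburst spicules
    side <- sample(c(-1, 1), 1)
    ox <- cx0 + side * (hw - cth / 2)
    n <- sample(9:12, 1)
    th <- stats::runif(n, -pi / 2.2, pi / 2.2)
    len <- stats::runif(n, 0.14, 0.22)
    for (i in seq_len(n)) {
      t <- seq(0.02, len[i], length.out = ceiling(len[i] * S))
      py <- pmin(pmax(round((ly + t * sin(th[i])) * S), 1), S)
      px <- pmin(pmax(round((ox + side * t * cos(th[i])) * S), 1), S)
      img[cbind(py, px)] <- medulla + ct
      img[cbind(pmin(py + 1, S), px)] <- medulla + ct
    }
  } else if (class_index == 5) {   # concentric onion-skin laminations
    side <- sample(c(-1, 1), 1)
    ox <- cx0 + side * hw
    for (i in 1:4) {
      r <- 0.045 + 0.035 * i
      ring <- abs(sqrt((yy - ly)^2 + (xx - ox)^2) - r) < 0.011
      img[ring] <- medulla + 0.8 * ct
    }
  } else if (class_index == 6) {   # expansile band with thinned cortex
    eh <- stats::runif(1, 0.16, 0.2)
    ell <- ((yy - ly) / eh)^2 + ((xx - cx0) / (1.45 * hw))^2 < 1
    img[ell] <- medulla + 0.3 * ct
    img[ell & abs(xx - cx0) > 1.2 * hw] <- medulla + 0.55 * ct
  } else if (class_index == 7) {   # punctate calcifications in a lucency
    r <- stats::runif(1, 0.11, 0.15)
    img[d < r] <- medulla - 0.6 * ct
    n <- sample(6:10, 1)
    for (i in seq_len(n)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 0.75 * r)
      py <- ly + rad * sin(ang); px <- lx + rad * cos(ang)
      img[sqrt((yy - py)^2 + (xx - px)^2) < 0.013] <- 0.92
    }
  } else {                         # horizontal trabecular striations
    period <- stats::runif(1, 0.05, 0.08)
    stripes <- 0.5 * ct * sin(2 * pi * yy / period)
    inner <- band & !cortical
    img[inner] <- img[inner] + stripes[inner]
  }

  img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(S * S, sd = spec$noise_sd), S, S)
  pmin(pmax(img, 0), 1)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_per_class` phantoms per class as 8-bit PNGs under
#' `out_dir/C<k>/` and returns the matching manifest (all splits
#' unassigned).  Per-image seeds are derived from `spec$seed`, the class
#' and the image number, so two runs with the same spec produce identical
#' bytes.
#'
#' @param n_per_class Images per class.
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory.
#' @return A `dataset_manifest`.
#' @export
generate_dataset <- function(n_per_class, spec = phantom_spec(), out_dir) {
  stopifnot(n_per_class >= 1L)
  recs <- list()
  for (k in seq_len(spec$num_classes) - 1L) {
    cl <- paste0("C", k)
    dir <- file.path(out_dir, cl)
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop(sprintf("cannot create directory '%s'", dir), call. = FALSE)
    for (i in seq_len(n_per_class)) {
      seed <- derive_seed(spec$seed, k * 100000L + i, 0L)
      img <- generate_phantom(k, spec, seed = seed)
      path <- file.path(dir, sprintf("%s_%04d.png", cl, i))
      png::writePNG(img, path)
      recs[[length(recs) + 1L]] <- data.frame(
        path = path, class_index = k, class_name = cl, split = "unassigned",
        origin = "original", source_image = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  m <- new_manifest(records, paste0("C", seq_len(spec$num_classes) - 1L),
                    spec$seed)
  validate_manifest(m)
  m
}
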