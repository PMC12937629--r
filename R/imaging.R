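#' ImageNet normalisation constants
#'
#' Per-channel mean and standard deviation used to standardise the
#' three-channel images (mu = 0.485/0.456/0.406, sigma = 0.229/0.224/0.225).
#'
#' @param mean,std Numeric length-3 vectors.
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(mean = c(0.485, 0.456, 0.406),
                               std = c(0.229, 0.224, 0.225)) {
  if (length(mean) != 3L || length(std) != 3L)
    stop("normalisation spec requires three channels", call. = FALSE)
  if (any(std <= 0)) stop("std must be strictly positive", call. = FALSE)
  structure(list(mean = mean, std = std), class = "normalization_spec")
}

#' Augmentation policy
#'
#' The class-balancing augmentation family: CLAHE, random rotation within
#' +/-12 degrees, horizontal flipping with probability 0.5, slight random
#' translation (strictly below 5% of each dimension) and gamma correction.
#' Ranges are deliberately tight so that diagnostically relevant features
#' (mineralisation patterns, cortical disruption, periosteal reaction,
#' lesion borders) are not distorted.
#'
#' @param rotation_degrees Half-width of the symmetric rotation range.
#' @param translation_fraction Maximum translation as a fraction of each
#'   dimension (exclusive upper bound 0.05).
#' @param hflip_probability Probability of a horizontal flip.
#' @param gamma_range Interval for the gamma exponent.
#' @param clahe_clip_limit CLAHE clip limit as a multiple of the mean
#'   per-bin count (`Inf` disables clipping).
#' @param clahe_tile_grid Integer pair: CLAHE contextual tile grid.
#' @param apply_clahe Logical; apply CLAHE as the first transform.
#' @param seed Base seed identifying the policy's random stream.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(rotation_degrees = 12,
                                translation_fraction = 0.04,
                                hflip_probability = 0.5,
                                gamma_range = c(0.8, 1.2),
                                clahe_clip_limit = 2.0,
                                clahe_tile_grid = c(8L, 8L),
                                apply_clahe = TRUE,
                                seed = 1L) {
  pol <- list(rotation_degrees = rotation_degrees,
              translation_fraction = translation_fraction,
              hflip_probability = hflip_probability,
              gamma_range = as.numeric(gamma_range),
              clahe_clip_limit = clahe_clip_limit,
              clahe_tile_grid = as.integer(clahe_tile_grid),
              apply_clahe = isTRUE(apply_clahe),
              seed = as.integer(seed))
  if (pol$rotation_degrees < 0 || pol$rotation_degrees > 12)
    stop("invalid augmentation policy: rotation must lie within +/-12 degrees",
         call. = FALSE)
  if (pol$translation_fraction < 0 || pol$translation_fraction >= 0.05)
    stop("invalid augmentation policy: translation must be below 5%",
         call. = FALSE)
  if (pol$hflip_probability < 0 || pol$hflip_probability > 1)
    stop("invalid augmentation policy: flip probability outside [0,1]",
         call. = FALSE)
  if (length(pol$gamma_range) != 2L || any(pol$gamma_range <= 0) ||
      diff(pol$gamma_range) < 0)
    stop("invalid augmentation policy: gamma_range must be a positive interval",
         call. = FALSE)
  class(pol) <- "augmentation_policy"
  pol
}

#' Load a PNG radiograph and standardise it
#'
#' Reads an 8- or 16-bit grayscale (or RGB) PNG, converts RGB to luminance,
#' rescales intensities to `[0, 1]` (8-bit by 1/255, 16-bit by 1/65535, as
#' performed by the PNG reader), resizes anisotropically with bilinear
#' interpolation to a `size x size` square, and replicates the result
#' across three identical channels.
#'
#' @param path PNG file path.
#' @param size Target side length in pixels.
#' @return An `(size, size, 3)` array in `[0, 1]`.
#' @export
load_and_standardize <- function(path, size = 224L) {
  img <- tryCatch(png::readPNG(path), error = function(e) {
    stop(sprintf("cannot read PNG '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  if (any(dim(img) == 0L)) stop(sprintf("zero-area image '%s'", path),
                                call. = FALSE)
  out <- resize_bilinear(img, size, size)
  array(out, dim = c(size, size, 3L))
}

#' Bilinear resize of a single-channel image
#'
#' Anisotropic resize: each axis is scaled independently onto the target
#' grid (pixel-centre alignment), so non-square inputs are distorted to the
#' square target, which is the stated behaviour of the preprocessing
#' pipeline.
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Target dimensions.
#' @return A numeric `out_h x out_w` matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  yi <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xi <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  bilinear_sample(img, outer(yi, rep(1, out_w)), outer(rep(1, out_h), xi))
}

# Sample img at fractional (row, col) coordinate matrices (0-based), with
# coordinates clamped to the image (edge replication outside the frame).
bilinear_sample <- function(img, ry, cx) {
  h <- nrow(img); w <- ncol(img)
  ry <- pmin(pmax(ry, 0), h - 1)
  cx <- pmin(pmax(cx, 0), w - 1)
  y0 <- floor(ry); x0 <- floor(cx)
  fy <- ry - y0; fx <- cx - x0
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  at <- function(yy, xx) img[cbind(as.vector(yy) + 1, as.vector(xx) + 1)]
  i00 <- at(y0, x0)
  i01 <- at(y0, x1)
  i10 <- at(y1, x0)
  i11 <- at(y1, x1)
  v <- i00 * (1 - fy) * (1 - fx) + i01 * (1 - fy) * fx +
    i10 * fy * (1 - fx) + i11 * fy * fx
  matrix(v, nrow(ry), ncol(ry))
}

#' Standardise a three-channel image with a normalisation spec
#'
#' `out[c] = (in[c] - mean[c]) / std[c]` per channel.
#'
#' @param img An `(H, W, 3)` array in `[0, 1]`.
#' @param spec A [normalization_spec()].
#' @return The standardised array.
#' @export
normalize_image <- function(img, spec = normalization_spec()) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("normalize_image expects an (H, W, 3) array", call. = FALSE)
  sweep(sweep(img, 3L, spec$mean, "-"), 3L, spec$std, "/")
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Standard CLAHE on a single-channel image in `[0, 1]`: the image is
#' divided into a grid of contextual tiles; each tile's 256-bin histogram
#' is clipped at `clip_limit` times the mean bin count, the clipped mass is
#' redistributed uniformly, and the tile's cumulative mapping is rescaled
#' to `[0, 1]`; every pixel is finally mapped by bilinear interpolation
#' between the mappings of the four nearest tile centres.  With a single
#' tile and no clipping (`clip_limit = Inf`) this reduces to global
#' histogram equalisation.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param clip_limit Clip limit as a multiple of the mean per-bin count;
#'   `Inf` (or any non-finite value) disables clipping.
#' @param tile_grid Integer pair `(rows, cols)` of contextual tiles.
#' @param nbins Number of histogram bins.
#' @return The equalised matrix, values in `[0, 1]`.
#' @export
clahe <- function(img, clip_limit = 2.0, tile_grid = c(8L, 8L), nbins = 256L) {
  h <- nrow(img); w <- ncol(img)
  gr <- tile_grid[1]; gc <- tile_grid[2]
  if (gr > h || gc > w)
    stop("tile grid larger than image", call. = FALSE)
  bins <- pmin(pmax(floor(img * nbins), 0), nbins - 1) # 0-based bin index
  row_edges <- round(seq(0, h, length.out = gr + 1))
  col_edges <- round(seq(0, w, length.out = gc + 1))
  # mapping[, i, j]: bin -> [0,1] for tile (i, j)
  mapping <- array(0, dim = c(nbins, gr, gc))
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      tile <- bins[(row_edges[i] + 1):row_edges[i + 1],
                   (col_edges[j] + 1):col_edges[j + 1]]
      counts <- tabulate(tile + 1L, nbins)
      npix <- length(tile)
      if (is.finite(clip_limit)) {
        clip <- clip_limit * npix / nbins
        excess <- sum(pmax(counts - clip, 0))
        counts <- pmin(counts, clip) + excess / nbins
      }
      mapping[, i, j] <- cumsum(counts) / npix
    }
  }
  # tile centres (0-based pixel coordinates)
  rc <- (row_edges[-1] + row_edges[-(gr + 1)]) / 2 - 0.5
  cc <- (col_edges[-1] + col_edges[-(gc + 1)]) / 2 - 0.5
  py <- matrix(seq_len(h) - 1, h, w)
  px <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  # fractional tile coordinates, clamped so border pixels extend the edge tile
  ty <- tile_frac(py, rc)
  tx <- tile_frac(px, cc)
  i0 <- floor(ty); j0 <- floor(tx)
  fy <- ty - i0; fx <- tx - j0
  i1 <- pmin(i0 + 1, gr - 1); j1 <- pmin(j0 + 1, gc - 1)
  m <- function(ii, jj) mapping[cbind(as.vector(bins) + 1, as.vector(ii) + 1,
                                      as.vector(jj) + 1)]
  out <- m(i0, j0) * (1 - fy) * (1 - fx) + m(i0, j1) * (1 - fy) * fx +
    m(i1, j0) * fy * (1 - fx) + m(i1, j1) * fy * fx
  matrix(pmin(pmax(out, 0), 1), h, w)
}

# Continuous tile index of pixel coordinates p given tile centres ctr.
tile_frac <- function(p, ctr) {
  k <- length(ctr)
  if (k == 1L) return(p * 0)
  idx <- findInterval(as.vector(p), ctr)       # 0..k
  idx <- pmin(pmax(idx, 1L), k - 1L)           # clamp into bracketing pairs
  lo <- ctr[idx]; hi <- ctr[idx + 1L]
  f <- (as.vector(p) - lo) / (hi - lo)
  matrix(pmin(pmax(idx - 1 + f, 0), k - 1), nrow(p), ncol(p))
}

#' Geometric and photometric augmentation primitives
#'
#' `rotate_image()` rotates about the image centre by `degrees`
#' (counter-clockwise), `translate_image()` shifts by a fraction of each
#' dimension; both resample bilinearly and replicate edge values outside
#' the frame, so no synthetic black wedges are introduced.
#' `gamma_correct()` raises `[0, 1]` intensities to the exponent `g`.
#'
#' @param img Numeric matrix.
#' @param degrees Rotation angle in degrees.
#' @return The transformed matrix.
#' @export
rotate_image <- function(img, degrees) {
  if (degrees == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  th <- degrees * pi / 180
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  py <- matrix(seq_len(h) - 1, h, w) - cy
  px <- matrix(rep(seq_len(w) - 1, each = h), h, w) - cx
  # inverse map: source = R(-th) %*% target
  ry <- cos(th) * py + sin(th) * px + cy
  cx_ <- -sin(th) * py + cos(th) * px + cx
  bilinear_sample(img, ry, cx_)
}

#' @rdname rotate_image
#' @param dy,dx Shift as a fraction of height/width (positive moves content
#'   down/right).
#' @export
translate_image <- function(img, dy, dx) {
  if (dy == 0 && dx == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  py <- matrix(seq_len(h) - 1, h, w) - dy * h
  px <- matrix(rep(seq_len(w) - 1, each = h), h, w) - dx * w
  bilinear_sample(img, py, px)
}

#' @rdname rotate_image
#' @param g Gamma exponent.
#' @export
gamma_correct <- function(img, g) {
  pmin(pmax(img, 0), 1)^g
}

#' Apply one random draw of the augmentation family
#'
#' Applies, in fixed order: CLAHE, rotation (uniform within the policy
#' range), horizontal flip, translation (per-axis uniform), gamma
#' correction (exponent uniform in `gamma_range`).  All draws come from
#' the R RNG: seeding it (or passing `seed`) makes the output
#' deterministic.
#'
#' @param img A single-channel matrix or `(H, W, 3)` array in `[0, 1]`.
#' @param policy An [augmentation_policy()].
#' @param seed Optional seed applied before drawing.
#' @return The augmented image, same shape as the input.
#' @export
random_augment <- function(img, policy = augmentation_policy(), seed = NULL) {
  if (!inherits(policy, "augmentation_policy"))
    stop("policy must be an augmentation_policy", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  three <- length(dim(img)) == 3L
  ch <- if (three) img[, , 1] else img
  angle <- stats::runif(1, -policy$rotation_degrees, policy$rotation_degrees)
  flip <- stats::runif(1) < policy$hflip_probability
  dy <- stats::runif(1, -policy$translation_fraction, policy$translation_fraction)
  dx <- stats::runif(1, -policy$translation_fraction, policy$translation_fraction)
  g <- stats::runif(1, policy$gamma_range[1], policy$gamma_range[2])
  if (policy$apply_clahe)
    ch <- clahe(ch, policy$clahe_clip_limit, policy$clahe_tile_grid)
  ch <- rotate_image(ch, angle)
  if (flip) ch <- ch[, rev(seq_len(ncol(ch)))]
  ch <- translate_image(ch, dy, dx)
  ch <- gamma_correct(ch, g)
  if (three) array(ch, dim = dim(img)) else ch
}
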