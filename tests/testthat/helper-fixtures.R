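# Shared fixtures, all generated in code.

# A small architecture for fast model mechanics tests.
tiny_arch <- function(input_size = 16L, num_classes = 3L, dropout_p = 0,
                      input_channels = 2L) {
  arch_config(input_size = input_size, input_channels = input_channels,
              stem_channels = c(3L, 4L), rdsb_specs = list(c(4L, 6L, 2L)),
              refine_channels = 5L, msfa_branch_kernels = c(1L, 3L),
              msfa_branch_channels = 3L, msfa_fused_channels = 4L,
              head_hidden_units = 5L, dropout_p = dropout_p,
              num_classes = num_classes)
}

# Normalised phantom batch: n images cycling over the 9 classes.
phantom_batch <- function(n, size = 64L, seed = 11L) {
  sp <- phantom_spec(image_size = size, seed = seed)
  x <- array(0, dim = c(size, size, 3L, n))
  y <- integer(n)
  for (i in seq_len(n)) {
    k <- (i - 1L) %% 9L
    img <- generate_phantom(k, sp, seed = seed * 1000L + i)
    x[, , , i] <- normalize_image(array(img, dim = c(size, size, 3L)))
    y[i] <- k
  }
  list(x = x, y = y)
}

# Manifest with the given per-class record counts and fake paths, built
# through the CSV reader so no image files are needed.
fake_manifest <- function(counts, split = "unassigned") {
  rows <- do.call(rbind, lapply(seq_along(counts), function(i) {
    data.frame(path = sprintf("img/%s/%06d.png", names(counts)[i],
                              seq_len(counts[i])),
               class_index = i - 1L, class_name = names(counts)[i],
               split = split, origin = "original", source_image = "",
               seed = 1L, stringsAsFactors = FALSE)
  }))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rows, f, row.names = FALSE)
  on.exit(unlink(f))
  read_manifest(f)
}

# Count 4-connected components of a logical mask (tiny flood fill).
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    stack <- start
    while (length(stack) > 0) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- comp
      r <- (p - 1L) %% nrow(mask) + 1L
      c <- (p - 1L) %/% nrow(mask) + 1L
      nb <- c(if (r > 1) p - 1L, if (r < nrow(mask)) p + 1L,
              if (c > 1) p - nrow(mask), if (c < ncol(mask)) p + nrow(mask))
      stack <- c(stack, nb[mask[nb] & lab[nb] == 0L])
    }
  }
  comp
}

# Exhaustive pair-counting AUC oracle (ties count one half).
pair_count_auc <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

# Brute-force global histogram equalisation: each pixel maps to the
# fraction of pixels with a bin index at or below its own.
global_equalize_oracle <- function(img, nbins = 256L) {
  bins <- pmin(pmax(floor(img * nbins), 0), nbins - 1)
  out <- vapply(as.vector(bins), function(b) mean(bins <= b), 1)
  matrix(out, nrow(img), ncol(img))
}
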