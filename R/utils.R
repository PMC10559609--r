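# Internal helpers shared across modules.

# Derive a reproducible child seed from a base seed and integer offsets.
# Stays below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (k in c(...)) s <- (s * 69069 + as.numeric(k) * 1009 + 1) %% m
  as.integer(s)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Bilinear resize of an H x W (x C) array; wraps EBImage.
resize_bilinear <- function(img, height, width) {
  if (length(dim(img)) == 2L) {
    # EBImage images are x (columns) by y (rows): transpose in and out
    t(EBImage::resize(t(img), w = width, h = height))
  } else {
    out <- array(0, c(height, width, dim(img)[3]))
    for (ch in seq_len(dim(img)[3])) {
      out[, , ch] <- t(EBImage::resize(t(img[, , ch]), w = width, h = height))
    }
    out
  }
}

# Nearest-neighbour resize for label masks (no interpolation of classes).
resize_nearest <- function(mask, height, width) {
  h0 <- nrow(mask); w0 <- ncol(mask)
  ri <- pmin(h0, pmax(1L, as.integer(floor((seq_len(height) - 0.5) * h0 / height) + 1L)))
  ci <- pmin(w0, pmax(1L, as.integer(floor((seq_len(width) - 0.5) * w0 / width) + 1L)))
  mask[ri, ci, drop = FALSE]
}

stop_if_not_binary <- function(mask, what = "mask") {
  if (!is.matrix(mask)) stop(what, " must be a matrix", call. = FALSE)
  if (!all(mask %in% c(0, 1))) stop(what, " must be binary (0/1)", call. = FALSE)
  invisible(mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
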