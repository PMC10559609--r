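# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different algorithms from the package code paths.

# point-in-polygon by scalar crossing count + explicit on-edge test
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]; x2 <- poly[i, 1]; y2 <- poly[i, 2]
    # on-segment check
    d <- abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1))
    if (d <= 1e-9 * (abs(x2 - x1) + abs(y2 - y1) + 1) &&
        x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
        y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9) {
      return(TRUE)
    }
    if ((y1 > y) != (y2 > y)) {
      xs <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
      if (x < xs) inside <- !inside
    }
    j <- i
  }
  inside
}

# full-raster pixel-center scan
oracle_rasterize <- function(poly, height, width) {
  out <- matrix(0L, height, width)
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      if (oracle_point_in_polygon(c - 1, r - 1, poly)) out[r, c] <- 1L
    }
  }
  out
}

# queue-based flood fill, independent of the package's stack-based C++ code
oracle_label_flood <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offsets <- if (connectivity == 8L) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  current <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (mask[r, c] == 0 || lab[r, c] != 0L) next
    current <- current + 1L
    queue <- list(c(r, c))
    lab[r, c] <- current
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offsets))) {
        rr <- p[1] + offsets[k, 1]; cc <- p[2] + offsets[k, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] != 0 && lab[rr, cc] == 0L) {
          lab[rr, cc] <- current
          queue <- c(queue, list(c(rr, cc)))
        }
      }
    }
  }
  lab
}

# brute-force binary morphology with a square structuring element
oracle_dilate <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask); h <- (se - 1) %/% 2
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    rs <- max(1, r - h):min(H, r + h)
    cs <- max(1, c - h):min(W, c + h)
    out[r, c] <- as.integer(any(mask[rs, cs] == 1))
  }
  out
}

oracle_erode <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask); h <- (se - 1) %/% 2
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    rs <- max(1, r - h):min(H, r + h)
    cs <- max(1, c - h):min(W, c + h)
    out[r, c] <- as.integer(all(mask[rs, cs] == 1))
  }
  out
}

oracle_clean <- function(mask, se) {
  m <- oracle_erode(oracle_dilate(mask, se), se)   # closing
  oracle_dilate(oracle_erode(m, se), se)           # opening
}

# longest run of TRUE via the gap-position method (not run-length encoding)
oracle_longest_run <- function(x) {
  gaps <- c(0L, which(!x), length(x) + 1L)
  max(diff(gaps) - 1L)
}

# Clopper-Pearson by numeric inversion of the binomial tail probabilities
oracle_cp_ci <- function(successes, n, level = 0.95) {
  alpha <- 1 - level
  low <- if (successes == 0) 0 else {
    uniroot(function(p) 1 - pbinom(successes - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  high <- if (successes == n) 1 else {
    uniroot(function(p) pbinom(successes, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(low = low, high = high)
}

# AUC by trapezoidal integration of the empirical ROC curve
oracle_auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# exact two-sided McNemar by exhaustive enumeration of the 2^(b+c)
# equally likely discordant-outcome assignments under H0
oracle_mcnemar_enum <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  extreme <- 0
  for (bits in 0:(2^n - 1)) {
    x <- sum(bitwAnd(bitwShiftR(bits, 0:(n - 1)), 1L))
    if (abs(x - n / 2) >= abs(b - n / 2)) extreme <- extreme + 1
  }
  extreme / 2^n
}

# small in-memory synthetic sample sets for segmentation tests
make_sample_set <- function(cfg, n, id_offset = 0L) {
  lapply(seq_len(n), function(i) {
    cancer <- i %% 2 == 0
    mod <- if (i %% 4 < 2) "WLI" else "NBI"
    f <- generate_frame(cfg, cancer, mod, id = id_offset + i)
    list(image = f$image, mask = f$mask, modality = mod,
         patient_id = paste0("p", id_offset + i),
         label = if (cancer) "cancer" else "normal")
  })
}

random_polygon <- function(max_xy = 15) {
  n <- sample(3:8, 1)
  cx <- runif(1, 3, max_xy - 3); cy <- runif(1, 3, max_xy - 3)
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 1, min(cx, cy, max_xy - cx, max_xy - cy))
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}
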