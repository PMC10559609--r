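# Native U-Net implementation. Feature maps are (H*W) x C matrices in
# column-major pixel order; convolutions run through C++ im2col + BLAS gemm
# (src/primitives.cpp); the training loop is hand-written backprop + Adam.
#
# Architecture: 4 encoder blocks (two 3x3 conv + ReLU, then 2x2 max-pool,
# stride 2), a bottleneck, and 4 decoder blocks (2x nearest upsample + 3x3
# conv, concatenation with the encoder skip at the same resolution, two 3x3
# conv + ReLU), closed by a 1x1 convolution producing a per-pixel cancer
# logit. "Same" padding keeps every output at the input resolution, so skip
# concatenation needs no cropping and predicted masks align with full-size
# annotations.

UNET_DEPTH <- 4L

#' Specify a U-Net segmentation network
#'
#' @param input_size `(H, W)` of the network input; both must be divisible
#'   by 16 (four 2x pooling halvings).
#' @param base_channels channels of the first encoder block; doubled at each
#'   of the four depth levels.
#' @param in_channels input channels (3 for RGB).
#' @param modality_fusion `"pooled"` trains one network on all modalities
#'   (the default); `"embedding"` adds a learned per-modality embedding
#'   merged into the bottleneck through a linear layer.
#' @return a list of class `unet_spec`.
#' @export
unet_spec <- function(input_size = c(512L, 512L), base_channels = 16L,
                      in_channels = 3L,
                      modality_fusion = c("pooled", "embedding")) {
  input_size <- as.integer(input_size)
  if (any(input_size %% 16L != 0L)) {
    stop("input_size must be divisible by 16: the four 2x2 stride-2 ",
         "poolings halve the resolution four times", call. = FALSE)
  }
  structure(list(input_size = input_size,
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 depth = UNET_DEPTH,
                 modality_fusion = match.arg(modality_fusion)),
            class = "unet_spec")
}

# ---- index caches ---------------------------------------------------------

# 3x3 same-padding neighbour indices: HW x 9 matrix of 1-based pixel rows,
# with HW + 1 marking zero padding. Column-major pixel order.
neighbour_index <- function(H, W) {
  HW <- H * W
  r <- rep(seq_len(H), W); cc <- rep(seq_len(W), each = H)
  idx <- matrix(HW + 1L, HW, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    rr <- r + dr; c2 <- cc + dc
    ok <- rr >= 1L & rr <= H & c2 >= 1L & c2 <= W
    idx[ok, k] <- (c2[ok] - 1L) * H + rr[ok]
  }
  idx
}

# 2x2 pooling children: (HW/4) x 4 index matrix into the fine grid.
pool_index <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  r2 <- rep(seq_len(H2), W2); c2 <- rep(seq_len(W2), each = H2)
  cbind((2L * c2 - 2L) * H + 2L * r2 - 1L,
        (2L * c2 - 2L) * H + 2L * r2,
        (2L * c2 - 1L) * H + 2L * r2 - 1L,
        (2L * c2 - 1L) * H + 2L * r2)
}

# nearest-neighbour 2x upsampling: length-4HW map fine pixel -> coarse row.
upsample_index <- function(H2, W2) {
  H <- 2L * H2
  r <- rep(seq_len(H), W2 * 2L); cc <- rep(seq_len(W2 * 2L), each = H)
  (ceiling(cc / 2L) - 1L) * H2 + ceiling(r / 2L)
}

get_cached_index <- function(model, kind, H, W) {
  key <- paste0(kind, H, "x", W)
  if (is.null(model$cache[[key]])) {
    model$cache[[key]] <- switch(kind,
                                 nbr = neighbour_index(H, W),
                                 pool = pool_index(H, W),
                                 up = upsample_index(H, W))
  }
  model$cache[[key]]
}

# ---- model construction ---------------------------------------------------

he_init <- function(n_in, n_out, fan_in) {
  matrix(rnorm(n_in * n_out, 0, sqrt(2 / fan_in)), n_in, n_out)
}

unet_channel_plan <- function(spec) {
  C <- spec$base_channels
  enc <- lapply(1:4, function(l) {
    cin <- if (l == 1L) spec$in_channels else C * 2L^(l - 2L)
    c(cin = cin, cout = C * 2L^(l - 1L))
  })
  list(enc = enc, bottleneck = c(cin = C * 8L, cout = C * 16L))
}

#' Build a U-Net model from a specification
#'
#' Parameters are He-initialized from the given seed, so two builds with the
#' same spec and seed are identical.
#'
#' @param spec a [unet_spec()].
#' @param seed integer seed for parameter initialization.
#' @return an object of class `unet_model` (environment holding parameters,
#'   spec, and cached index tables).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  C <- spec$base_channels
  plan <- unet_channel_plan(spec)
  params <- withr::with_seed(as.integer(seed), {
    p <- list()
    conv <- function(cin, cout) list(W = he_init(9L * cin, cout, 9L * cin),
                                     b = rep(0, cout))
    for (l in 1:4) {
      ch <- plan$enc[[l]]
      p[[paste0("enc", l, "a")]] <- conv(ch["cin"], ch["cout"])
      p[[paste0("enc", l, "b")]] <- conv(ch["cout"], ch["cout"])
    }
    p$bott_a <- conv(plan$bottleneck["cin"], plan$bottleneck["cout"])
    p$bott_b <- conv(plan$bottleneck["cout"], plan$bottleneck["cout"])
    for (l in 4:1) {
      cskip <- C * 2L^(l - 1L)
      p[[paste0("up", l)]] <- conv(2L * cskip, cskip)
      p[[paste0("dec", l, "a")]] <- conv(2L * cskip, cskip)
      p[[paste0("dec", l, "b")]] <- conv(cskip, cskip)
    }
    p$head <- list(W = he_init(C, 1L, C), b = 0)
    if (spec$modality_fusion == "embedding") {
      p$emb <- list(W = matrix(0, 2L, 16L * C), b = NULL)
    }
    p
  })
  model <- new.env(parent = emptyenv())
  model$spec <- spec
  model$params <- params
  model$cache <- new.env(parent = emptyenv())
  model$train_config <- NULL
  class(model) <- "unet_model"
  model
}

n_parameters <- function(model) {
  sum(vapply(model$params,
             function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cat("U-Net segmentation model\n",
      "  input size: ", paste(x$spec$input_size, collapse = " x "), "\n",
      "  base channels: ", x$spec$base_channels,
      " | fusion: ", x$spec$modality_fusion, "\n",
      "  parameters: ", format(n_parameters(x), big.mark = ","), "\n",
      sep = "")
  invisible(x)
}

# ---- forward / backward ---------------------------------------------------

# x: (HW x in_channels) matrix. Returns logits plus (optionally) the
# activation tape needed for the backward pass.
unet_forward <- function(model, x, modality = NULL, keep_tape = FALSE) {
  p <- model$params
  H <- model$spec$input_size[1]; W <- model$spec$input_size[2]
  tape <- if (keep_tape) list() else NULL
  conv_relu <- function(x, name, H, W, relu = TRUE) {
    idx <- get_cached_index(model, "nbr", H, W)
    z <- conv3_forward(x, idx, p[[name]]$W, p[[name]]$b)
    a <- if (relu) z * (z > 0) else z
    if (keep_tape) tape[[name]] <<- list(x = x, z = z, H = H, W = W)
    a
  }
  skips <- vector("list", 4L)
  dims <- vector("list", 4L)
  a <- x
  for (l in 1:4) {
    a <- conv_relu(a, paste0("enc", l, "a"), H, W)
    a <- conv_relu(a, paste0("enc", l, "b"), H, W)
    skips[[l]] <- a; dims[[l]] <- c(H, W)
    pidx <- get_cached_index(model, "pool", H, W)
    pooled <- a[pidx[, 1L], , drop = FALSE]
    bestk <- matrix(1L, nrow(pidx), ncol(a))
    for (k in 2:4) {
      cand <- a[pidx[, k], , drop = FALSE]
      better <- cand > pooled
      bestk[better] <- k
      pooled[better] <- cand[better]
    }
    if (keep_tape) tape[[paste0("pool", l)]] <- list(bestk = bestk, H = H, W = W)
    a <- pooled
    H <- H %/% 2L; W <- W %/% 2L
  }
  a <- conv_relu(a, "bott_a", H, W)
  a <- conv_relu(a, "bott_b", H, W)
  if (model$spec$modality_fusion == "embedding") {
    m <- if (identical(modality, "NBI")) 2L else 1L
    a <- sweep(a, 2L, p$emb$W[m, ], "+")
    if (keep_tape) tape$emb <- list(m = m)
  }
  for (l in 4:1) {
    uidx <- get_cached_index(model, "up", H, W)
    a <- a[uidx, , drop = FALSE]
    H <- 2L * H; W <- 2L * W
    if (keep_tape) tape[[paste0("upix", l)]] <- list(uidx = uidx)
    a <- conv_relu(a, paste0("up", l), H, W)
    a <- cbind(skips[[l]], a)
    a <- conv_relu(a, paste0("dec", l, "a"), H, W)
    a <- conv_relu(a, paste0("dec", l, "b"), H, W)
  }
  logits <- a %*% p$head$W + p$head$b
  if (keep_tape) tape$head <- list(x = a)
  list(logits = logits, tape = tape)
}

# Backward pass; returns gradient list parallel to model$params.
unet_backward <- function(model, tape, dlogits) {
  p <- model$params
  g <- list()
  d <- dlogits
  g$head <- list(W = crossprod(tape$head$x, d), b = sum(d))
  d <- d %*% t(p$head$W)
  conv_bwd <- function(d, name, relu = TRUE) {
    t <- tape[[name]]
    if (relu) d <- d * (t$z > 0)
    idx <- get_cached_index(model, "nbr", t$H, t$W)
    bk <- conv3_backward(t$x, idx, p[[name]]$W, d)
    g[[name]] <<- list(W = bk$dw, b = as.numeric(bk$db))
    bk$dx
  }
  dskips <- vector("list", 4L)
  for (l in 1:4) {
    d <- conv_bwd(d, paste0("dec", l, "b"))
    d <- conv_bwd(d, paste0("dec", l, "a"))
    cskip <- ncol(d) %/% 2L
    dskips[[l]] <- d[, seq_len(cskip), drop = FALSE]
    d <- d[, cskip + seq_len(cskip), drop = FALSE]
    d <- conv_bwd(d, paste0("up", l))
    uidx <- tape[[paste0("upix", l)]]$uidx
    d <- rowsum(d, uidx)
  }
  if (model$spec$modality_fusion == "embedding") {
    m <- tape$emb$m
    dW <- matrix(0, 2L, ncol(d))
    dW[m, ] <- colSums(d)
    g$emb <- list(W = dW, b = NULL)
  }
  d <- conv_bwd(d, "bott_b")
  d <- conv_bwd(d, "bott_a")
  for (l in 4:1) {
    t <- tape[[paste0("pool", l)]]
    pidx <- get_cached_index(model, "pool", t$H, t$W)
    dfine <- matrix(0, t$H * t$W, ncol(d))
    for (k in 1:4) {
      sel <- t$bestk == k
      dk <- d
      dk[!sel] <- 0
      dfine[pidx[, k], ] <- dfine[pidx[, k], ] + dk
    }
    d <- dfine
    d <- d + dskips[[l]]
    d <- conv_bwd(d, paste0("enc", l, "b"))
    d <- conv_bwd(d, paste0("enc", l, "a"))
  }
  g
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable binary cross-entropy with logits
bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

# ---- training -------------------------------------------------------------

#' Training configuration for the U-Net
#'
#' Optimizer, loss, and augmentation ranges are configurable because the
#' clinical pipeline this mirrors fixes only the augmentation families
#' (horizontal flips, rotations, colour jitter, blur, noise).
#'
#' @param epochs,batch_size,learning_rate optimizer schedule; Adam is used.
#' @param loss `"bce"` (pixel-wise binary cross-entropy) or `"bce_dice"`.
#' @param augment named logical toggles: `hflip`, `rotation`, `color_jitter`,
#'   `blur`, `noise`.
#' @param jitter_strength colour-jitter half-range (multiplicative and
#'   additive, image units).
#' @param noise_sd augmentation noise standard deviation (image units).
#' @param modality_filter `"all"` (the pooled multimodal model), `"WLI"`
#'   (model W), or `"NBI"` (model N); selects which training frames are used.
#' @param early_stopping_patience epochs without verification improvement
#'   before stopping; model selection keeps the best verification-loss
#'   parameters.
#' @param seed RNG seed covering shuffling, augmentation draws and batching.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 8L, batch_size = 2L, learning_rate = 1e-3,
                         loss = c("bce", "bce_dice"),
                         augment = list(hflip = TRUE, rotation = TRUE,
                                        color_jitter = TRUE, blur = FALSE,
                                        noise = FALSE),
                         jitter_strength = 0.08, noise_sd = 0.02,
                         modality_filter = c("all", "WLI", "NBI"),
                         early_stopping_patience = 3L, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = "adam",
                 loss = match.arg(loss),
                 augment = modifyList(list(hflip = FALSE, rotation = FALSE,
                                           color_jitter = FALSE, blur = FALSE,
                                           noise = FALSE), augment),
                 jitter_strength = jitter_strength, noise_sd = noise_sd,
                 modality_filter = match.arg(modality_filter),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- augmentations (exported so the transforms are unit-testable) --------

#' Data augmentation transforms
#'
#' Each transform maps an image (H x W x 3) and its mask (H x W or `NULL`)
#' to the transformed pair. Geometric transforms are applied identically to
#' image and mask; photometric ones leave the mask untouched.
#'
#' @param image H x W x 3 array.
#' @param mask binary H x W matrix or `NULL`.
#' @return list with transformed `image` and `mask`.
#' @export
aug_hflip <- function(image, mask = NULL) {
  idx <- rev(seq_len(dim(image)[2]))
  list(image = image[, idx, , drop = FALSE],
       mask = if (is.null(mask)) NULL else mask[, idx, drop = FALSE])
}

#' @rdname aug_hflip
#' @param k number of 90-degree counter-clockwise rotations (0-3).
#' @export
aug_rot90 <- function(image, mask = NULL, k = 1L) {
  k <- k %% 4L
  rot_m <- function(m) {
    for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    m
  }
  if (k == 0L) return(list(image = image, mask = mask))
  out <- array(0, c(dim(rot_m(image[, , 1])), 3L))
  for (ch in 1:3) out[, , ch] <- rot_m(image[, , ch])
  list(image = out, mask = if (is.null(mask)) NULL else rot_m(mask))
}

#' @rdname aug_hflip
#' @param scale,shift per-channel multiplicative factors and additive
#'   offsets (length 3).
#' @export
aug_color_jitter <- function(image, mask = NULL, scale = c(1, 1, 1),
                             shift = c(0, 0, 0)) {
  for (ch in 1:3) image[, , ch] <- image[, , ch] * scale[ch] + shift[ch]
  list(image = clamp01(image), mask = mask)
}

#' @rdname aug_hflip
#' @export
aug_blur <- function(image, mask = NULL) {
  for (ch in 1:3) {
    image[, , ch] <- t(EBImage::filter2(t(image[, , ch]),
                                        matrix(1 / 9, 3, 3)))
  }
  list(image = image, mask = mask)
}

#' @rdname aug_hflip
#' @param sd Gaussian noise standard deviation.
#' @export
aug_noise <- function(image, mask = NULL, sd = 0.02) {
  list(image = clamp01(image + array(rnorm(length(image), 0, sd), dim(image))),
       mask = mask)
}

# random augmentation draw used inside the training loop (RNG already seeded)
apply_augmentations <- function(image, mask, cfg) {
  a <- cfg$augment
  if (isTRUE(a$hflip) && runif(1) < 0.5) {
    out <- aug_hflip(image, mask); image <- out$image; mask <- out$mask
  }
  if (isTRUE(a$rotation)) {
    out <- aug_rot90(image, mask, k = sample(0:3, 1))
    image <- out$image; mask <- out$mask
  }
  if (isTRUE(a$color_jitter)) {
    s <- cfg$jitter_strength
    out <- aug_color_jitter(image, mask, scale = runif(3, 1 - s, 1 + s),
                            shift = runif(3, -s / 2, s / 2))
    image <- out$image
  }
  if (isTRUE(a$blur) && runif(1) < 0.3) image <- aug_blur(image)$image
  if (isTRUE(a$noise)) image <- aug_noise(image, sd = cfg$noise_sd)$image
  list(image = image, mask = mask)
}

# ---- dataset loading ------------------------------------------------------

#' Load training samples from a manifest
#'
#' Reads every frame, resizes images bilinearly and masks nearest-neighbour
#' to the model input size, and rasterizes annotations where present. Frames
#' without an annotation get an all-background mask, which is correct for
#' benign/normal frames.
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @param input_size `(H, W)` target size.
#' @param splits which splits to load.
#' @return named list of per-split sample lists; each sample has `image`
#'   (H x W x 3), `mask` (H x W), `modality`, `patient_id`, `label`.
#' @export
load_samples <- function(manifest, input_size,
                         splits = c("train", "verification", "test")) {
  out <- list()
  for (sp in splits) {
    rows <- manifest[manifest$split == sp, , drop = FALSE]
    out[[sp]] <- lapply(seq_len(nrow(rows)), function(i) {
      img <- read_image(rows$frame_path[i])
      if (!identical(dim(img)[1:2], as.integer(input_size))) {
        img <- resize_bilinear(img, input_size[1], input_size[2])
      }
      mask <- matrix(0L, input_size[1], input_size[2])
      ap <- rows$annotation_path[i]
      if (!is.na(ap) && nzchar(ap)) {
        ann <- read_annotation(ap)
        h0 <- if (is.na(ann$image_height)) input_size[1] else ann$image_height
        w0 <- if (is.na(ann$image_width)) input_size[2] else ann$image_width
        mask <- resize_nearest(rasterize_annotation(ann, h0, w0),
                               input_size[1], input_size[2])
      }
      list(image = img, mask = mask, modality = rows$modality[i],
           patient_id = rows$patient_id[i], label = rows$label[i])
    })
  }
  out
}

image_to_input <- function(image) {
  d <- dim(image)
  matrix(image, d[1] * d[2], 3L)
}

#' Train a U-Net segmentation model
#'
#' Minimizes pixel-wise binary cross-entropy with Adam; the verification
#' split drives early stopping and model selection (the returned model holds
#' the parameters with the best verification loss). The modality filter
#' realizes the three variants: a WLI-only model, an NBI-only model, and the
#' pooled multimodal model trained on all frames.
#'
#' @param model a [build_model()] result (updated in place and returned).
#' @param data either a manifest data.frame or a list with `train` and
#'   optional `verification` sample lists as produced by [load_samples()].
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses?
#' @return the trained model, with `model$history` a data.frame of per-epoch
#'   training and verification losses.
#' @export
train <- function(model, data, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "train_config"))
  if (is.data.frame(data)) {
    data <- load_samples(data, model$spec$input_size,
                         splits = c("train", "verification"))
  }
  train_set <- data$train %||% list()
  verif_set <- data$verification %||% list()
  if (cfg$modality_filter != "all") {
    keep <- function(s) vapply(s, function(x) x$modality == cfg$modality_filter,
                               logical(1))
    train_set <- train_set[keep(train_set)]
    verif_set <- verif_set[keep(verif_set)]
  }
  if (!length(train_set)) stop("empty training split", call. = FALSE)

  adam <- list(m = rapply(model$params, function(x) x * 0, how = "replace"),
               v = rapply(model$params, function(x) x * 0, how = "replace"),
               t = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        verif_loss = numeric(0))
  best <- list(loss = Inf, params = model$params)
  stale <- 0L

  eval_loss <- function(set) {
    if (!length(set)) return(NA_real_)
    mean(vapply(set, function(s) {
      fw <- unet_forward(model, image_to_input(s$image), s$modality)
      bce_with_logits(fw$logits, as.numeric(s$mask))
    }, numeric(1)))
  }

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(length(train_set))
      batch_losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        ids <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
        grad_sum <- NULL
        loss_sum <- 0
        for (j in ids) {
          s <- train_set[[j]]
          augd <- apply_augmentations(s$image, s$mask, cfg)
          x <- image_to_input(augd$image)
          y <- as.numeric(augd$mask)
          fw <- unet_forward(model, x, s$modality, keep_tape = TRUE)
          loss <- bce_with_logits(fw$logits, y)
          if (!is.finite(loss)) {
            stop("non-finite training loss at epoch ", epoch,
                 "; lower the learning rate", call. = FALSE)
          }
          pr <- sigmoid(fw$logits)
          dz <- (pr - y) / length(y)
          if (cfg$loss == "bce_dice") {
            inter <- sum(pr * y)
            denom <- sum(pr) + sum(y) + 1
            loss <- loss + 1 - (2 * inter + 1) / denom
            ddice <- -(2 * y * denom - (2 * inter + 1)) / denom^2
            dz <- dz + ddice * pr * (1 - pr)
          }
          loss_sum <- loss_sum + loss
          g <- unet_backward(model, fw$tape, dz)
          grad_sum <- if (is.null(grad_sum)) g else {
            for (nm in names(g)) {
              grad_sum[[nm]]$W <- grad_sum[[nm]]$W + g[[nm]]$W
              if (!is.null(g[[nm]]$b)) {
                grad_sum[[nm]]$b <- grad_sum[[nm]]$b + g[[nm]]$b
              }
            }
            grad_sum
          }
        }
        nb <- length(ids)
        adam$t <- adam$t + 1
        corr1 <- 1 - beta1^adam$t; corr2 <- 1 - beta2^adam$t
        for (nm in names(grad_sum)) {
          for (part in c("W", "b")) {
            gr <- grad_sum[[nm]][[part]]
            if (is.null(gr)) next
            gr <- gr / nb
            adam$m[[nm]][[part]] <- beta1 * adam$m[[nm]][[part]] + (1 - beta1) * gr
            adam$v[[nm]][[part]] <- beta2 * adam$v[[nm]][[part]] + (1 - beta2) * gr^2
            step <- cfg$learning_rate * (adam$m[[nm]][[part]] / corr1) /
              (sqrt(adam$v[[nm]][[part]] / corr2) + eps)
            model$params[[nm]][[part]] <- model$params[[nm]][[part]] - step
          }
        }
        batch_losses <- c(batch_losses, loss_sum / nb)
        i <- i + cfg$batch_size
      }
      vloss <- eval_loss(verif_set)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = mean(batch_losses),
                                  verif_loss = vloss))
      if (verbose) {
        message(sprintf("epoch %d: train %.4f verif %s", epoch,
                        mean(batch_losses),
                        ifelse(is.na(vloss), "-", sprintf("%.4f", vloss))))
      }
      sel_loss <- if (is.na(vloss)) mean(batch_losses) else vloss
      if (sel_loss < best$loss) {
        best$loss <- sel_loss
        best$params <- model$params
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$early_stopping_patience) break
      }
    }
  })
  model$params <- best$params
  model$history <- history
  model$train_config <- cfg
  model
}

# ---- inference ------------------------------------------------------------

#' Segment a frame
#'
#' Resizes the frame bilinearly to the model input size, runs the network,
#' and thresholds the per-pixel cancer probability. The probability map and
#' binary mask are returned at model input resolution with the original
#' frame size recorded for later upsampling.
#'
#' @param model trained `unet_model`.
#' @param frame an `endo_frame` or a raw H x W x 3 array.
#' @param probability_threshold mask pixels where probability strictly
#'   exceeds this value (default 0.5).
#' @return list of class `segmentation_result`: `prob_map` (H x W in
#'   \[0,1\]), `binary_mask` (H x W in `{0,1}`), `source_size`,
#'   `probability_threshold`.
#' @export
predict_frame <- function(model, frame, probability_threshold = 0.5) {
  modality <- NULL
  if (inherits(frame, "endo_frame")) {
    modality <- frame$modality
    frame <- frame$image
  }
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L) {
    stop("predict_frame() requires an RGB (H x W x 3) input", call. = FALSE)
  }
  src <- dim(frame)[1:2]
  size <- model$spec$input_size
  if (!identical(as.integer(src), size)) {
    frame <- resize_bilinear(frame, size[1], size[2])
  }
  fw <- unet_forward(model, image_to_input(frame), modality)
  prob <- matrix(sigmoid(fw$logits), size[1], size[2])
  structure(list(prob_map = prob,
                 binary_mask = matrix(as.integer(prob > probability_threshold),
                                      size[1], size[2]),
                 source_size = as.integer(src),
                 probability_threshold = probability_threshold),
            class = "segmentation_result")
}

#' Render a probability heatmap over a frame
#'
#' Maps per-pixel cancer probability through a cool-to-warm colour ramp and
#' alpha-blends it over the original frame, at the frame's own resolution.
#'
#' @param result a `segmentation_result`.
#' @param frame the frame it was computed from (`endo_frame` or array).
#' @param alpha blend weight of the heatmap layer.
#' @return 8-bit integer H x W x 3 array (values 0-255) at frame resolution.
#' @export
render_heatmap <- function(result, frame, alpha = 0.45) {
  if (inherits(frame, "endo_frame")) frame <- frame$image
  H <- dim(frame)[1]; W <- dim(frame)[2]
  p <- result$prob_map
  if (!identical(dim(p), c(H, W))) p <- resize_bilinear(p, H, W)
  p <- clamp01(p)
  # piecewise-linear ramp; warmth (R - B) is strictly increasing in p
  stops <- rbind(c(0.10, 0.10, 0.60), c(0.70, 0.10, 0.50), c(1.00, 0.15, 0.10))
  seg2 <- p >= 0.5
  t1 <- pmin(p / 0.5, 1); t2 <- pmax((p - 0.5) / 0.5, 0)
  heat <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    lo <- stops[1, ch] + t1 * (stops[2, ch] - stops[1, ch])
    hi <- stops[2, ch] + t2 * (stops[3, ch] - stops[2, ch])
    heat[, , ch] <- ifelse(seg2, hi, lo)
  }
  blended <- (1 - alpha) * frame + alpha * heat
  out <- array(as.integer(round(255 * clamp01(blended))), c(H, W, 3L))
  out
}

# ---- checkpoints ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized weights file with a JSON sidecar
#' recording the architecture spec and training configuration.
#'
#' @param model a `unet_model`.
#' @param path checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @return `path` (save) or the restored `unet_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = model$spec, params = model$params,
               history = model$history %||% NULL,
               train_config = model$train_config), path)
  sidecar <- list(spec = unclass(model$spec),
                  train_config = if (!is.null(model$train_config)) {
                    unclass(model$train_config)
                  },
                  n_parameters = n_parameters(model),
                  package_version = as.character(packageVersion("laryngoscreen")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$spec, seed = 1L)
  model$params <- ck$params
  model$history <- ck$history
  model$train_config <- ck$train_config
  model
}
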