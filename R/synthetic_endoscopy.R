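# Seed-controlled synthetic laryngoscopy data: frames, labelme annotations,
# patient manifests, and videos. The generator emulates the statistical
# structure the pipeline assumes -- modality-dependent mucosa palettes, one
# irregular cancer lesion per positive frame, small benign distractor blobs,
# and lesion persistence across video frames -- without any photorealism.

#' Configuration for the synthetic endoscopy generator
#'
#' All generator outputs are pure functions of the configuration, its `seed`,
#' and the call arguments, so fixtures are reproducible bit-for-bit.
#'
#' @param seed base integer seed.
#' @param image_size `(H, W)` in pixels.
#' @param lesion_probability fraction of patients carrying cancer.
#' @param lesion_area_range `(min, max)` cancer-lesion mask area in pixels.
#' @param distractor_area_range `(min, max)` area of benign/noise blobs, which
#'   share the lesion palette but must stay below the frame-decision area
#'   threshold.
#' @param modality_mix fraction of frames imaged under WLI (the rest NBI).
#' @param noise_sd per-pixel Gaussian intensity noise (image units, \[0,1\]).
#' @param video_fps frame rate of generated videos.
#' @param video_duration_range `(min, max)` clip duration in seconds; the
#'   default 8--25 s matches one short endoscopy clip per lesion.
#' @param lesion_persistence fraction of a cancer video's frames in which the
#'   lesion is visible, as one contiguous run.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         image_size = c(128L, 128L),
                         lesion_probability = 0.4,
                         lesion_area_range = c(600, 1800),
                         distractor_area_range = c(8, 64),
                         modality_mix = 0.5,
                         noise_sd = 0.02,
                         video_fps = 25,
                         video_duration_range = c(8, 25),
                         lesion_persistence = 0.8) {
  cfg <- list(seed = as.integer(seed), image_size = as.integer(image_size),
              lesion_probability = lesion_probability,
              lesion_area_range = lesion_area_range,
              distractor_area_range = distractor_area_range,
              modality_mix = modality_mix, noise_sd = noise_sd,
              video_fps = video_fps,
              video_duration_range = video_duration_range,
              lesion_persistence = lesion_persistence)
  stopifnot(length(cfg$image_size) == 2L, all(cfg$image_size >= 32L),
            cfg$lesion_probability >= 0, cfg$lesion_probability <= 1,
            cfg$modality_mix >= 0, cfg$modality_mix <= 1,
            cfg$video_fps > 0, cfg$lesion_persistence > 0,
            cfg$lesion_persistence <= 1,
            diff(cfg$video_duration_range) >= 0)
  for (rng in list(cfg$lesion_area_range, cfg$distractor_area_range)) {
    if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2]) {
      stop("area ranges must be positive with min <= max", call. = FALSE)
    }
  }
  # the lesion (with its radial irregularity) must fit inside the frame
  rmax <- sqrt(cfg$lesion_area_range[2] / pi) * 1.6
  if (rmax > 0.36 * min(cfg$image_size)) {
    stop("lesion_area_range infeasible for image_size: maximum lesion radius ",
         round(rmax, 1), " px exceeds the placeable region", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

# Star-convex polygon with target rasterized pixel area inside [lo, hi].
# Returns an n x 2 (x, y) matrix in 0-based pixel coordinates.
make_star_polygon <- function(center, target_area, lo, hi, height, width,
                              n_vertices = 16L, irregularity = 0.25) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ang <- ang + runif(n_vertices, -0.5, 0.5) * (2 * pi / n_vertices) * 0.4
  ang <- sort(ang %% (2 * pi))
  raw <- exp(rnorm(n_vertices, 0, irregularity))
  # circular 3-point smoothing keeps the margin irregular but not spiky
  sm <- (raw + raw[c(n_vertices, seq_len(n_vertices - 1L))] +
           raw[c(seq_len(n_vertices - 1L) + 1L, 1L)]) / 3
  r0 <- sqrt(target_area / pi)
  poly_at <- function(scale) {
    cbind(x = center[1] + scale * r0 * sm * cos(ang),
          y = center[2] + scale * r0 * sm * sin(ang))
  }
  scale <- 1
  poly <- poly_at(scale)
  for (iter in 1:12) {
    area <- sum(rasterize_polygon(poly, height, width))
    if (area >= lo && area <= hi) break
    target <- (lo + hi) / 2
    scale <- scale * sqrt(target / max(area, 1))
    poly <- poly_at(scale)
  }
  poly
}

# Modality palettes: broad pink/red mucosa for WLI; darker green/brown with
# vessel-like curvilinear texture for NBI. Lesions share a palette across
# distractors so that only size separates the classes.
synth_palette <- function(modality) {
  if (modality == "WLI") {
    list(bg = c(0.78, 0.52, 0.50), bg_var = 0.06,
         lesion = c(0.93, 0.72, 0.64), lesion_var = 0.05, vessels = 0L)
  } else {
    list(bg = c(0.30, 0.46, 0.38), bg_var = 0.05,
         lesion = c(0.50, 0.27, 0.22), lesion_var = 0.05, vessels = 6L)
  }
}

synth_background <- function(H, W, pal, noise_sd) {
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    coarse <- matrix(pal$bg[ch] + rnorm(36, 0, pal$bg_var), 6, 6)
    img[, , ch] <- resize_bilinear(coarse, H, W)
  }
  if (pal$vessels > 0L) {
    for (v in seq_len(pal$vessels)) {
      t <- seq(0, 1, length.out = 4L * max(H, W))
      x <- runif(1, 1, W) + (W / 2) * (t - 0.5) * runif(1, -1, 1) +
        W * 0.15 * sin(2 * pi * runif(1, 1, 3) * t + runif(1, 0, 2 * pi))
      y <- runif(1, 1, H) + (H / 2) * (t - 0.5) * runif(1, -1, 1) +
        H * 0.15 * sin(2 * pi * runif(1, 1, 3) * t + runif(1, 0, 2 * pi))
      r <- pmin(H, pmax(1L, round(y))); c <- pmin(W, pmax(1L, round(x)))
      keep <- !duplicated(cbind(r, c))
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[cbind(r[keep], c[keep])] <- pl[cbind(r[keep], c[keep])] - 0.12
        img[, , ch] <- pl
      }
    }
  }
  img + array(rnorm(H * W * 3L, 0, noise_sd), c(H, W, 3L))
}

paint_blob <- function(img, mask01, color, var) {
  idx <- which(mask01 == 1L)
  if (!length(idx)) return(img)
  tex <- rnorm(length(idx), 0, var)
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[idx] <- color[ch] + tex
    img[, , ch] <- pl
  }
  img
}

#' Generate one synthetic endoscopy frame
#'
#' Draws a textured mucosa-like background in the requested modality's
#' palette, optionally one irregular cancer lesion whose mask area falls in
#' `cfg$lesion_area_range`, and zero or more small distractor blobs in the
#' lesion palette (present in either class). The returned frame's mask marks
#' exactly the cancer lesion; the generating lesion polygon is attached as
#' attribute `"lesion_polygon"` so it can be written as a labelme annotation.
#'
#' @param cfg a [synth_config()].
#' @param cancer logical; paint a cancer lesion?
#' @param modality `"WLI"` or `"NBI"`.
#' @param patient_id,frame_index metadata for the returned frame.
#' @param id integer stream offset; frames with different `id` are
#'   independent draws, frames with identical `(cfg, arguments)` are
#'   bit-identical.
#' @return an `endo_frame` with a (possibly empty) ground-truth mask.
#' @export
generate_frame <- function(cfg, cancer, modality = c("WLI", "NBI"),
                           patient_id = "synthetic", frame_index = 0L,
                           id = 0L) {
  modality <- match.arg(modality)
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  seed <- derive_seed(cfg$seed, id, as.integer(cancer),
                      match(modality, MODALITIES))
  withr::with_seed(seed, {
    pal <- synth_palette(modality)
    img <- synth_background(H, W, pal, cfg$noise_sd)
    mask <- matrix(0L, H, W)
    poly <- NULL
    if (isTRUE(cancer)) {
      center <- c(runif(1, 0.40, 0.60) * W, runif(1, 0.40, 0.60) * H)
      target <- runif(1, cfg$lesion_area_range[1], cfg$lesion_area_range[2])
      poly <- make_star_polygon(center, target, cfg$lesion_area_range[1],
                                cfg$lesion_area_range[2], H, W)
      mask <- rasterize_polygon(poly, H, W)
      img <- paint_blob(img, mask, pal$lesion, pal$lesion_var)
    }
    n_distract <- stats::rpois(1, 1)
    for (d in seq_len(n_distract)) {
      dc <- c(runif(1, 0.15, 0.85) * W, runif(1, 0.15, 0.85) * H)
      dt <- runif(1, cfg$distractor_area_range[1], cfg$distractor_area_range[2])
      dp <- make_star_polygon(dc, dt, 1, cfg$distractor_area_range[2], H, W,
                              n_vertices = 8L)
      dmask <- rasterize_polygon(dp, H, W)
      dmask[mask == 1L] <- 0L  # the cancer lesion has priority
      img <- paint_blob(img, dmask, pal$lesion, pal$lesion_var)
    }
    frame <- new_frame(clamp01(img), modality = modality,
                       patient_id = patient_id, frame_index = frame_index,
                       mask = mask)
    attr(frame, "lesion_polygon") <- poly
    frame
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes PNG frames, labelme-style polygon annotations for cancer frames
#' (traced from the generating lesion polygon), and a patient-level manifest
#' CSV with patient-disjoint train/verification/test splits. Cancer status is
#' assigned per patient (all of a cancer patient's frames show the lesion),
#' mirroring per-patient pathology labels.
#'
#' @param cfg a [synth_config()].
#' @param n_patients number of synthetic patients.
#' @param frames_per_patient frames per patient (at most 10).
#' @param dir output directory.
#' @param split_props named proportions for train/verification/test.
#' @return the manifest data.frame (also written to `dir/manifest.csv`),
#'   invisibly.
#' @export
generate_dataset <- function(cfg, n_patients, frames_per_patient, dir,
                             split_props = c(train = 0.6, verification = 0.2,
                                             test = 0.2)) {
  if (frames_per_patient > 10L) {
    stop("frames_per_patient must be at most 10", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  split_props <- split_props / sum(split_props)
  n_cancer <- round(n_patients * cfg$lesion_probability)
  patients <- withr::with_seed(derive_seed(cfg$seed, 7001L), {
    assign_split <- function(n) {
      # stratified, deterministic split assignment within a label group
      counts <- floor(split_props * n)
      rem <- n - sum(counts)
      if (rem > 0) {
        top <- order(split_props * n - counts, decreasing = TRUE)[seq_len(rem)]
        counts[top] <- counts[top] + 1L
      }
      sample(rep(SPLITS, counts))
    }
    labels <- c(rep("cancer", n_cancer),
                sample(c("benign", "normal"), n_patients - n_cancer,
                       replace = TRUE))
    splits <- character(n_patients)
    splits[labels == "cancer"] <- assign_split(n_cancer)
    splits[labels != "cancer"] <- assign_split(n_patients - n_cancer)
    data.frame(patient_id = sprintf("P%04d", seq_len(n_patients)),
               label = labels, split = splits, stringsAsFactors = FALSE)
  })
  rows <- vector("list", n_patients * frames_per_patient)
  k <- 0L
  for (p in seq_len(n_patients)) {
    cancer <- patients$label[p] == "cancer"
    for (f in seq_len(frames_per_patient)) {
      id <- derive_seed(cfg$seed, 100L + p, f)
      modality <- withr::with_seed(derive_seed(id, 3L), {
        if (runif(1) < cfg$modality_mix) "WLI" else "NBI"
      })
      frame <- generate_frame(cfg, cancer, modality,
                              patient_id = patients$patient_id[p],
                              frame_index = f - 1L, id = id)
      stem <- sprintf("%s_f%02d", patients$patient_id[p], f - 1L)
      frame_path <- file.path(dir, paste0(stem, ".png"))
      write_image(frame$image, frame_path)
      ann_path <- ""
      poly <- attr(frame, "lesion_polygon")
      if (cancer && !is.null(poly)) {
        ann <- structure(
          list(image_path = basename(frame_path),
               image_height = cfg$image_size[1],
               image_width = cfg$image_size[2],
               shapes = list(list(label = "cancer", points = poly))),
          class = "annotation")
        ann_path <- file.path(dir, paste0(stem, ".json"))
        write_annotation(ann, ann_path)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        patient_id = patients$patient_id[p], frame_path = frame_path,
        annotation_path = ann_path, modality = frame$modality,
        label = patients$label[p], split = patients$split[p],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Generate a synthetic endoscopy video
#'
#' Duration is drawn from `cfg$video_duration_range`. In a cancer video the
#' lesion is visible in one contiguous run of at least
#' `lesion_persistence * n_frames` frames, jittered in position and scale
#' frame to frame; per-frame truth labels follow lesion visibility. Negative
#' videos may contain a persistent small distractor blob (a benign-lesion
#' stand-in) but never a cancer-sized one.
#'
#' @param cfg a [synth_config()].
#' @param cancer logical video-level truth.
#' @param modality `"WLI"`, `"NBI"`, or `NULL` to draw from
#'   `cfg$modality_mix`.
#' @param id integer stream offset (see [generate_frame()]).
#' @param path optional directory; when given, the video is also written in
#'   the frame-directory container of [write_video_frames()].
#' @return an `endo_video` list: `frames`, `fps`, `n_frames`,
#'   `duration_seconds`, logical `truth` per frame, and `modality`.
#' @export
generate_video <- function(cfg, cancer, modality = NULL, id = 0L,
                           path = NULL) {
  seed <- derive_seed(cfg$seed, 50000L, id, as.integer(cancer))
  video <- withr::with_seed(seed, {
    H <- cfg$image_size[1]; W <- cfg$image_size[2]
    modality <- modality %||% (if (runif(1) < cfg$modality_mix) "WLI" else "NBI")
    pal <- synth_palette(modality)
    duration <- runif(1, cfg$video_duration_range[1], cfg$video_duration_range[2])
    n <- max(1L, as.integer(round(duration * cfg$video_fps)))
    truth <- rep(FALSE, n)
    base_poly <- NULL
    if (isTRUE(cancer)) {
      run_len <- max(1L, as.integer(round(cfg$lesion_persistence * n)))
      start <- sample.int(n - run_len + 1L, 1L)
      truth[start:(start + run_len - 1L)] <- TRUE
      center <- c(runif(1, 0.42, 0.58) * W, runif(1, 0.42, 0.58) * H)
      target <- runif(1, cfg$lesion_area_range[1], cfg$lesion_area_range[2])
      base_poly <- make_star_polygon(center, target, cfg$lesion_area_range[1],
                                     cfg$lesion_area_range[2], H, W)
    }
    background <- synth_background(H, W, pal, noise_sd = 0)
    # persistent benign distractor in some videos of either class
    dist_poly <- NULL
    if (runif(1) < 0.5) {
      dc <- c(runif(1, 0.2, 0.8) * W, runif(1, 0.2, 0.8) * H)
      dt <- runif(1, cfg$distractor_area_range[1], cfg$distractor_area_range[2])
      dist_poly <- make_star_polygon(dc, dt, 1, cfg$distractor_area_range[2],
                                     H, W, n_vertices = 8L)
    }
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      img <- background + array(rnorm(H * W * 3L, 0, cfg$noise_sd), c(H, W, 3L))
      mask <- matrix(0L, H, W)
      if (!is.null(dist_poly)) {
        jd <- dist_poly + matrix(rnorm(2, 0, 1), nrow(dist_poly), 2,
                                 byrow = TRUE)
        img <- paint_blob(img, rasterize_polygon(jd, H, W), pal$lesion,
                          pal$lesion_var)
      }
      if (truth[i]) {
        ctr <- colMeans(base_poly)
        jitter <- rnorm(2, 0, 1.5)
        scale <- runif(1, 0.96, 1.04)
        jp <- sweep(sweep(base_poly, 2, ctr) * scale, 2, ctr + jitter, "+")
        mask <- rasterize_polygon(jp, H, W)
        img <- paint_blob(img, mask, pal$lesion, pal$lesion_var)
      }
      frames[[i]] <- new_frame(clamp01(img), modality = modality,
                               frame_index = i - 1L, mask = mask)
    }
    structure(list(frames = frames, fps = cfg$video_fps, n_frames = n,
                   duration_seconds = n / cfg$video_fps, truth = truth,
                   modality = modality),
              class = "endo_video")
  })
  if (!is.null(path)) {
    write_video_frames(video$frames, video$fps, path, truth = video$truth,
                       modality = video$modality)
  }
  video
}
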