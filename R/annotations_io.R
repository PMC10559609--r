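# Frames, labelme-style polygon annotations, dataset manifests, and the
# frame-directory video container.

MODALITIES <- c("WLI", "NBI")
PATHOLOGY_LABELS <- c("cancer", "benign", "normal")
SPLITS <- c("train", "verification", "test")

#' Construct an endoscopy frame
#'
#' A frame couples an RGB raster with its imaging modality (white-light or
#' narrow-band), the patient it came from, its index within a video, and an
#' optional ground-truth cancer mask.
#'
#' @param image numeric H x W x 3 array with values in \[0, 1\].
#' @param modality `"WLI"` or `"NBI"`.
#' @param patient_id opaque patient identifier string.
#' @param frame_index non-negative integer position within the source video.
#' @param mask optional binary H x W matrix (1 = cancer pixel); must match
#'   the image height/width.
#' @return an object of class `endo_frame`.
#' @export
new_frame <- function(image, modality, patient_id = "unknown",
                      frame_index = 0L, mask = NULL) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an H x W x 3 RGB array", call. = FALSE)
  }
  modality <- match.arg(modality, MODALITIES)
  if (frame_index < 0) stop("frame_index must be non-negative", call. = FALSE)
  if (!is.null(mask)) {
    stop_if_not_binary(mask)
    if (!identical(dim(mask), dim(image)[1:2])) {
      stop("mask dimensions must equal image dimensions", call. = FALSE)
    }
  }
  structure(
    list(image = image, modality = modality, patient_id = as.character(patient_id),
         frame_index = as.integer(frame_index), mask = mask),
    class = "endo_frame"
  )
}

#' Read a labelme-style polygon annotation file
#'
#' Parses the labelme JSON dialect (keys `imagePath`, `imageHeight`,
#' `imageWidth`, `shapes` with per-shape `label` and `points`). Unknown keys
#' are ignored.
#'
#' @param path path to the JSON annotation file.
#' @return a list of class `annotation` with fields `image_path`,
#'   `image_height`, `image_width` and `shapes` (each shape a list with
#'   `label` and an n x 2 `points` matrix of (x, y) pixel coordinates).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed annotation JSON in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  shapes <- lapply(doc$shapes %||% list(), function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p)[1:2])))
    if (is.null(pts) || nrow(pts) < 3L) {
      stop("polygon with fewer than 3 vertices in ", path, call. = FALSE)
    }
    if (!all(is.finite(pts)) || any(pts < 0)) {
      stop("polygon vertices must be finite and non-negative in ", path, call. = FALSE)
    }
    colnames(pts) <- c("x", "y")
    list(label = as.character(s$label %||% ""), points = pts)
  })
  structure(
    list(image_path = as.character(doc$imagePath %||% ""),
         image_height = as.integer(doc$imageHeight %||% NA),
         image_width = as.integer(doc$imageWidth %||% NA),
         shapes = shapes),
    class = "annotation"
  )
}

#' Write a labelme-style polygon annotation file
#'
#' @param ann an `annotation` object (see [read_annotation()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  doc <- list(
    version = "5.0.1",
    flags = setNames(list(), character(0)),
    shapes = lapply(ann$shapes, function(s) {
      list(label = s$label,
           points = lapply(seq_len(nrow(s$points)),
                           function(i) as.numeric(s$points[i, ])),
           group_id = NULL, shape_type = "polygon",
           flags = setNames(list(), character(0)))
    }),
    imagePath = ann$image_path,
    imageHeight = ann$image_height,
    imageWidth = ann$image_width
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Rasterize polygon annotations to a binary mask
#'
#' The union of all polygons whose label matches `label` is painted onto a
#' `{0,1}` raster. A pixel is set when its center lies inside (or exactly on
#' the edge of) any polygon. Pixel centers use 0-based coordinates with
#' x = column and y = row, so pixel `(r, c)` (1-based R indexing) has center
#' `(x = c - 1, y = r - 1)`. Vertices outside the raster are clipped, not an
#' error; degenerate zero-area polygons contribute nothing (with a warning).
#'
#' @param ann an `annotation` object.
#' @param height,width raster dimensions (positive integers).
#' @param label label selecting which shapes to rasterize (default "cancer").
#' @return binary `height` x `width` matrix.
#' @export
rasterize_annotation <- function(ann, height, width, label = "cancer") {
  if (height <= 0 || width <= 0) stop("height and width must be positive", call. = FALSE)
  out <- matrix(0L, height, width)
  for (s in ann$shapes) {
    if (!identical(s$label, label)) next
    out <- out | rasterize_polygon(s$points, height, width)
  }
  mode(out) <- "integer"
  out
}

# Even-odd fill of one polygon at pixel centers; edge points count as inside.
rasterize_polygon <- function(points, height, width) {
  px <- points[, 1]; py <- points[, 2]
  # shoelace area; degenerate polygons contribute nothing
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  area2 <- abs(sum(px * py[j] - px[j] * py))
  out <- matrix(0L, height, width)
  if (area2 < .Machine$double.eps * 100) {
    warning("degenerate zero-area polygon ignored", call. = FALSE)
    return(out)
  }
  c0 <- max(0L, floor(min(px))); c1 <- min(width - 1L, ceiling(max(px)))
  r0 <- max(0L, floor(min(py))); r1 <- min(height - 1L, ceiling(max(py)))
  if (c0 > c1 || r0 > r1) return(out)
  cols <- seq(c0, c1); rows <- seq(r0, r1)
  X <- rep(cols, each = length(rows))
  Y <- rep(rows, times = length(cols))
  inside <- rep(FALSE, length(X))
  on_edge <- rep(FALSE, length(X))
  eps <- 1e-9
  for (i in seq_len(n)) {
    x1 <- px[j[i]]; y1 <- py[j[i]]; x2 <- px[i]; y2 <- py[i]
    crosses <- ((y1 > Y) != (y2 > Y))
    if (any(crosses)) {
      xs <- x1 + (Y[crosses] - y1) * (x2 - x1) / (y2 - y1)
      flip <- X[crosses] < xs
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    # point-on-segment test (edge-inclusive tie-break)
    d <- abs((x2 - x1) * (Y - y1) - (y2 - y1) * (X - x1))
    seg <- d <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      X >= pmin(x1, x2) - eps & X <= pmax(x1, x2) + eps &
      Y >= pmin(y1, y2) - eps & Y <= pmax(y1, y2) + eps
    on_edge <- on_edge | seg
  }
  hit <- inside | on_edge
  out[cbind(Y + 1L, X + 1L)[hit, , drop = FALSE]] <- 1L
  out
}

#' Read / write a patient-level dataset manifest
#'
#' The manifest is a CSV with header
#' `patient_id,frame_path,annotation_path,modality,label,split`; an empty
#' `annotation_path` means no annotation. Extra columns are preserved.
#'
#' @param path CSV path.
#' @return a data.frame of manifest records.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("patient_id", "frame_path", "annotation_path", "modality",
                "label", "split")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' @rdname read_manifest
#' @param manifest a manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a dataset manifest against the dataset-construction rules
#'
#' Checks the patient-independence of splits (no patient may appear in more
#' than one of train/verification/test), the cap of at most 10 frames per
#' patient, and that cancer-labeled training frames carry an annotation.
#' Violations are returned as data, not raised as errors.
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @return data.frame with columns `rule`, `patient_id`, `detail`; zero rows
#'   iff the manifest is valid.
#' @export
validate_manifest <- function(manifest) {
  v <- list()
  add <- function(rule, pid, detail) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, patient_id = pid,
                                       detail = detail, stringsAsFactors = FALSE)
  }
  bad_mod <- !manifest$modality %in% MODALITIES
  for (i in which(bad_mod)) {
    add("invalid modality", manifest$patient_id[i], manifest$modality[i])
  }
  bad_lab <- !manifest$label %in% PATHOLOGY_LABELS
  for (i in which(bad_lab)) {
    add("invalid label", manifest$patient_id[i], manifest$label[i])
  }
  bad_split <- !manifest$split %in% SPLITS
  for (i in which(bad_split)) {
    add("invalid split", manifest$patient_id[i], manifest$split[i])
  }
  for (pid in unique(manifest$patient_id)) {
    rows <- manifest[manifest$patient_id == pid, ]
    splits <- unique(rows$split)
    if (length(splits) > 1L) {
      add("split leakage", pid, paste(sort(splits), collapse = "+"))
    }
    if (nrow(rows) > 10L) {
      add("frame cap exceeded", pid, paste0(nrow(rows), " frames"))
    }
  }
  need_ann <- manifest$label == "cancer" & manifest$split == "train" &
    (is.na(manifest$annotation_path) | manifest$annotation_path == "")
  for (i in which(need_ann)) {
    add("missing training annotation", manifest$patient_id[i],
        manifest$frame_path[i])
  }
  if (length(v)) do.call(rbind, v) else {
    data.frame(rule = character(0), patient_id = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  }
}

#' Read / write an RGB image
#'
#' PNG is the native format; JPG is read through EBImage when its decoder is
#' available.
#'
#' @param path image path.
#' @return numeric H x W x 3 array in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else {
    img <- tryCatch(as.array(EBImage::readImage(path)),
                    error = function(e) stop("cannot read image ", path, ": ",
                                             conditionMessage(e), call. = FALSE))
    img <- aperm(img, c(2, 1, 3))  # EBImage stores x-major
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image
#' @param image numeric H x W x 3 array in \[0, 1\].
#' @export
write_image <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' Read a video stored as a frame directory
#'
#' Videos are stored as a directory of numbered PNG frames plus a
#' `video.json` sidecar recording the frame rate, frame order, and (for
#' synthetic videos) per-frame truth labels. The frame rate must be present
#' in the sidecar or supplied explicitly.
#'
#' @param path directory containing `video.json` and frame images.
#' @param fps optional frames-per-second override when the sidecar lacks it.
#' @param modality,patient_id metadata attached to the returned frames
#'   (defaults come from the sidecar when present).
#' @return a list of class `endo_video` with `frames` (list of
#'   [new_frame()] objects), `fps`, `n_frames`, `duration_seconds`, and
#'   `truth` (per-frame logical labels or `NULL`).
#' @export
read_video_frames <- function(path, fps = NULL, modality = NULL,
                              patient_id = NULL) {
  meta_path <- file.path(path, "video.json")
  if (!dir.exists(path) || !file.exists(meta_path)) {
    stop("unreadable video container (expected directory with video.json): ",
         path, call. = FALSE)
  }
  meta <- jsonlite::fromJSON(meta_path)
  fps <- fps %||% meta$fps
  if (is.null(fps) || !is.finite(fps) || fps <= 0) {
    stop("frame rate missing from video metadata; pass an explicit `fps` ",
         "override to read_video_frames()", call. = FALSE)
  }
  modality <- modality %||% (meta$modality %||% "WLI")
  patient_id <- patient_id %||% (meta$patient_id %||% "unknown")
  files <- file.path(path, meta$files)
  frames <- lapply(seq_along(files), function(i) {
    new_frame(read_image(files[i]), modality = modality,
              patient_id = patient_id, frame_index = i - 1L)
  })
  structure(
    list(frames = frames, fps = as.numeric(fps), n_frames = length(frames),
         duration_seconds = length(frames) / as.numeric(fps),
         truth = if (!is.null(meta$truth)) as.logical(meta$truth) else NULL),
    class = "endo_video"
  )
}

#' Write a video as a frame directory
#'
#' @param frames list of H x W x 3 arrays or `endo_frame` objects, in order.
#' @param fps frames per second (must be positive).
#' @param path output directory (created if needed).
#' @param truth optional per-frame logical truth labels.
#' @param modality,patient_id recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_video_frames <- function(frames, fps, path, truth = NULL,
                               modality = "WLI", patient_id = "unknown") {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("frame_%05d.png", seq_along(frames) - 1L)
  for (i in seq_along(frames)) {
    img <- if (inherits(frames[[i]], "endo_frame")) frames[[i]]$image else frames[[i]]
    write_image(img, file.path(path, files[i]))
  }
  meta <- list(fps = fps, n_frames = length(frames), files = files,
               modality = modality, patient_id = patient_id)
  if (!is.null(truth)) meta$truth <- as.logical(truth)
  jsonlite::write_json(meta, file.path(path, "video.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
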