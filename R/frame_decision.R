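# Frame-level decision layer: morphological cleanup, connected-component
# area measurement, the strict area-threshold cancer call, and grid-based
# threshold selection.

#' Default area-threshold candidate grid
#'
#' Candidate square side lengths 8, 16, 32, 64, 128 and 256 pixels at the
#' 512 x 512 working resolution, i.e. candidate areas 64 ... 65536 px.
#'
#' @return strictly increasing numeric vector of candidate areas (px).
#' @export
area_threshold_grid <- function() {
  c(8, 16, 32, 64, 128, 256)^2
}

#' Morphological cleanup of a predicted mask
#'
#' Closing (dilation then erosion: fills interior voids) followed by opening
#' (erosion then dilation: removes speckle noise), both with the same square
#' structuring element. Idempotent when applied twice.
#'
#' @param mask binary matrix.
#' @param structuring_element_size odd side length of the square structuring
#'   element (default 5).
#' @return cleaned binary matrix of the same shape.
#' @export
clean_mask <- function(mask, structuring_element_size = 5L) {
  stop_if_not_binary(mask)
  se <- as.integer(structuring_element_size)
  if (se < 1L || se %% 2L == 0L) {
    stop("structuring_element_size must be a positive odd integer", call. = FALSE)
  }
  if (se > min(dim(mask))) {
    stop("structuring element (", se, " px) larger than the mask (",
         paste(dim(mask), collapse = " x "), ")", call. = FALSE)
  }
  if (se == 1L) return(mask)
  brush <- EBImage::makeBrush(se, shape = "box")
  m <- t(mask)  # EBImage works x-major
  m <- EBImage::closing(m, brush)
  m <- EBImage::opening(m, brush)
  out <- t(m)
  mode(out) <- "integer"
  out
}

#' Label connected components of a binary mask
#'
#' @param mask binary matrix.
#' @param connectivity 8 (default: diagonally touching pixels are one
#'   region) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stop_if_not_binary(mask)
  if (!connectivity %in% c(4L, 8L)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  m <- mask
  mode(m) <- "integer"
  label_components_cpp(m, as.integer(connectivity))
}

#' Frame-level cancer call from a cleaned mask
#'
#' Labels the connected components of the (already cleaned) mask and calls
#' the frame cancer exactly when the largest component's area strictly
#' exceeds `area_threshold`. The threshold is defined at a 512 x 512 working
#' resolution; masks of other sizes have their areas rescaled by
#' `prod(reference_size) / prod(dim(mask))` before comparison (set
#' `reference_size = NULL` to compare raw pixel counts).
#'
#' @param mask cleaned binary matrix.
#' @param area_threshold area threshold in reference-resolution pixels
#'   (default 1024 = 32 x 32).
#' @param connectivity component connectivity, 8 (default) or 4.
#' @param reference_size resolution at which `area_threshold` is defined
#'   (default `c(512, 512)`), or `NULL` for no rescaling.
#' @param sum_areas if `TRUE`, use the summed area of all components instead
#'   of the largest single component.
#' @return list of class `frame_decision`: `is_cancer`,
#'   `largest_component_area` (raw pixels), `component_count`, and `score`
#'   (the reference-resolution area used for the call and for ROC sweeps).
#' @export
classify_frame <- function(mask, area_threshold = 1024,
                           connectivity = 8L,
                           reference_size = c(512L, 512L),
                           sum_areas = FALSE) {
  lab <- label_components(mask, connectivity)
  n_comp <- max(lab)
  areas <- if (n_comp > 0L) tabulate(lab[lab > 0L], n_comp) else integer(0)
  raw <- if (!length(areas)) 0L else if (sum_areas) sum(areas) else max(areas)
  factor <- if (is.null(reference_size)) 1 else {
    prod(as.numeric(reference_size)) / prod(dim(mask))
  }
  score <- raw * factor
  structure(list(is_cancer = score > area_threshold,
                 largest_component_area = as.integer(raw),
                 component_count = n_comp,
                 score = score,
                 area_threshold = area_threshold),
            class = "frame_decision")
}

# shared by both grid-selection operations
select_threshold_from_grid <- function(scores, truth, grid, metric) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2L) {
    stop("threshold selection requires both classes in the verification set",
         call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("candidate grid must be strictly increasing", call. = FALSE)
  }
  stats <- vapply(grid, function(th) {
    call <- scores > th
    c(metric = mean(call == truth),
      sensitivity = mean(call[truth]),
      specificity = mean(!call[!truth]),
      n_positive_calls = sum(call))
  }, numeric(4))
  tab <- data.frame(threshold = grid, t(stats))
  names(tab)[2] <- metric
  best <- which(tab[[metric]] == max(tab[[metric]]))[1]  # tie -> smaller
  list(selected_threshold = grid[best], table = tab, metric = metric)
}

#' Select the frame-level area threshold on a verification set
#'
#' Evaluates every candidate area on the verification frames and returns the
#' best according to the selection metric (accuracy), together with the full
#' metric-vs-threshold table. Ties are broken toward the smaller area,
#' favouring sensitivity in a screening setting.
#'
#' @param areas per-frame largest-component areas (reference-resolution
#'   pixels; the `score` field of [classify_frame()]).
#' @param truth per-frame logical cancer truth.
#' @param grid candidate areas, strictly increasing
#'   (default [area_threshold_grid()]).
#' @return list with `selected_threshold`, the evaluation `table`
#'   (threshold, accuracy, sensitivity, specificity, positive-call count),
#'   and `metric`.
#' @export
select_area_threshold <- function(areas, truth, grid = area_threshold_grid()) {
  select_threshold_from_grid(areas, truth, grid, "accuracy")
}
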