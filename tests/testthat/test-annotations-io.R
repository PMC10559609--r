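test_that("annotation write -> read round-trips shapes, labels and vertices", {
  tmp <- withr::local_tempfile(fileext = ".json")

  # empty annotation
  empty <- structure(list(image_path = "a.png", image_height = 10L,
                          image_width = 12L, shapes = list()),
                     class = "annotation")
  write_annotation(empty, tmp)
  got <- read_annotation(tmp)
  expect_length(got$shapes, 0)
  expect_equal(got$image_height, 10L)

  # one labeled square
  square <- matrix(c(1, 1, 5, 1, 5, 5, 1, 5), ncol = 2, byrow = TRUE,
                   dimnames = list(NULL, c("x", "y")))
  one <- structure(list(image_path = "b.png", image_height = 8L,
                        image_width = 8L,
                        shapes = list(list(label = "cancer", points = square))),
                   class = "annotation")
  write_annotation(one, tmp)
  got <- read_annotation(tmp)
  expect_length(got$shapes, 1)
  expect_equal(got$shapes[[1]]$label, "cancer")
  expect_equal(unname(got$shapes[[1]]$points), unname(square))

  # two overlapping polygons keep input order
  tri <- cbind(x = c(2, 6, 4), y = c(2, 2, 6))
  two <- one
  two$shapes <- list(list(label = "cancer", points = square),
                     list(label = "benign", points = tri))
  write_annotation(two, tmp)
  got <- read_annotation(tmp)
  expect_equal(vapply(got$shapes, `[[`, "", "label"), c("cancer", "benign"))
  expect_equal(unname(got$shapes[[2]]$points), unname(tri))
})

test_that("malformed annotations raise informative errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_annotation(bad), "malformed annotation JSON")
  expect_error(read_annotation(bad), basename(bad))

  twovert <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(imagePath = "x.png", imageHeight = 5, imageWidth = 5,
         shapes = list(list(label = "cancer",
                            points = list(c(1, 1), c(2, 2))))),
    twovert, auto_unbox = TRUE)
  expect_error(read_annotation(twovert), "fewer than 3 vertices")

  expect_error(read_annotation(file.path(tempdir(), "nope.json")), "not found")
})

test_that("rasterization fills pixel centers inside the polygon union", {
  empty <- structure(list(image_path = "", image_height = 12L,
                          image_width = 12L, shapes = list()),
                     class = "annotation")
  expect_equal(sum(rasterize_annotation(empty, 12, 12)), 0)

  # square whose edges pass exactly through centers (0,0) and (9,9):
  # edge-inclusive containment gives exactly 10 x 10 ones
  sq <- function(x0, y0, x1, y1) {
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  ann <- structure(list(image_path = "", image_height = 20L, image_width = 20L,
                        shapes = list(list(label = "cancer",
                                           points = sq(0, 0, 9, 9)))),
                   class = "annotation")
  expect_equal(sum(rasterize_annotation(ann, 20, 20)), 100)

  # two disjoint 100-px squares add up
  ann$shapes <- list(list(label = "cancer", points = sq(0, 0, 9, 9)),
                     list(label = "cancer", points = sq(12, 12, 21, 21)))
  expect_equal(sum(rasterize_annotation(ann, 25, 25)), 200)

  # non-cancer labels are not rasterized
  ann$shapes[[2]]$label <- "benign"
  expect_equal(sum(rasterize_annotation(ann, 25, 25)), 100)

  # vertices beyond the raster are clipped, not an error
  ann$shapes <- list(list(label = "cancer", points = sq(5, 5, 40, 40)))
  r <- rasterize_annotation(ann, 10, 10)
  expect_equal(sum(r), 25)

  # degenerate zero-area polygon contributes nothing, with a warning
  deg <- structure(list(image_path = "", image_height = 10L, image_width = 10L,
                        shapes = list(list(label = "cancer",
                                           points = cbind(x = c(1, 5, 9),
                                                          y = c(2, 2, 2))))),
                   class = "annotation")
  expect_warning(r <- rasterize_annotation(deg, 10, 10), "degenerate")
  expect_equal(sum(r), 0)
})

test_that("rasterization agrees with the pixel-center point-in-polygon oracle", {
  withr::local_seed(11)
  for (i in 1:100) {
    poly <- random_polygon(15)
    ann <- structure(list(image_path = "", image_height = 16L,
                          image_width = 16L,
                          shapes = list(list(label = "cancer", points = poly))),
                     class = "annotation")
    got <- rasterize_annotation(ann, 16, 16)
    expect_identical(got, oracle_rasterize(poly, 16, 16))
  }
})

test_that("manifest validation reports the dataset-construction violations", {
  m <- data.frame(
    patient_id = c("P1", "P1", "P1"),
    frame_path = paste0("f", 1:3, ".png"),
    annotation_path = c("a1.json", "a2.json", "a3.json"),
    modality = c("WLI", "NBI", "WLI"),
    label = "cancer", split = "train", stringsAsFactors = FALSE)
  expect_equal(nrow(validate_manifest(m)), 0)

  leak <- m
  leak$split <- c("train", "train", "test")
  v <- validate_manifest(leak)
  expect_equal(v$rule, "split leakage")
  expect_equal(v$patient_id, "P1")

  cap <- m[rep(1, 11), ]
  cap$frame_path <- paste0("f", 1:11, ".png")
  v <- validate_manifest(cap)
  expect_true("frame cap exceeded" %in% v$rule)

  noann <- m
  noann$annotation_path <- ""
  v <- validate_manifest(noann)
  expect_equal(unique(v$rule), "missing training annotation")
  expect_equal(nrow(v), 3)

  badmod <- m
  badmod$modality[2] <- "fluorescence"
  expect_true("invalid modality" %in% validate_manifest(badmod)$rule)
})

test_that("manifest CSV round-trips and enforces required columns", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  m <- data.frame(patient_id = c("P1", "P2"), frame_path = c("a.png", "b.png"),
                  annotation_path = c("a.json", ""), modality = c("WLI", "NBI"),
                  label = c("cancer", "normal"), split = c("train", "test"),
                  stringsAsFactors = FALSE)
  write_manifest(m, tmp)
  expect_equal(read_manifest(tmp), m)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(m[, 1:3], bad, row.names = FALSE)
  expect_error(read_manifest(bad), "missing columns")
})

test_that("frame-directory videos round-trip frames, fps and duration", {
  withr::local_seed(3)
  mk <- function(n) lapply(seq_len(n), function(i) array(runif(16 * 16 * 3),
                                                         c(16, 16, 3)))
  d1 <- withr::local_tempdir()
  write_video_frames(mk(50), fps = 25, d1, modality = "NBI")
  v <- read_video_frames(d1)
  expect_equal(v$n_frames, 50)
  expect_equal(v$fps, 25)
  expect_equal(v$duration_seconds, 2)
  expect_equal(v$frames[[1]]$frame_index, 0L)
  expect_equal(v$frames[[50]]$frame_index, 49L)
  expect_equal(v$frames[[1]]$modality, "NBI")

  d2 <- withr::local_tempdir()
  write_video_frames(mk(1), fps = 25, d2)
  expect_equal(read_video_frames(d2)$n_frames, 1)

  d3 <- withr::local_tempdir()
  write_video_frames(mk(75), fps = 30, d3)
  expect_equal(read_video_frames(d3)$duration_seconds, 2.5)
})

test_that("video containers without frame rate demand an explicit override", {
  d <- withr::local_tempdir()
  write_video_frames(list(array(0.5, c(16, 16, 3))), fps = 10, d)
  meta <- jsonlite::fromJSON(file.path(d, "video.json"))
  meta$fps <- NULL
  jsonlite::write_json(meta, file.path(d, "video.json"), auto_unbox = TRUE)
  expect_error(read_video_frames(d), "explicit `fps` override")
  expect_equal(read_video_frames(d, fps = 10)$fps, 10)
  expect_error(read_video_frames(file.path(d, "missing")), "unreadable")
})

test_that("frame constructor enforces mask and modality invariants", {
  img <- array(0.5, c(8, 8, 3))
  expect_error(new_frame(img, "XRAY"), "arg")
  expect_error(new_frame(img, "WLI", mask = matrix(0L, 4, 4)), "dimensions")
  expect_error(new_frame(img[, , 1], "WLI"), "RGB")
  f <- new_frame(img, "WLI", mask = matrix(0L, 8, 8))
  expect_s3_class(f, "endo_frame")
})
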