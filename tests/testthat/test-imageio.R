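test_that("channel_image enforces the 8-bit invariants", {
  expect_s3_class(channel_image(matrix(0:255, 16, 16)), "channel_image")
  expect_error(channel_image(matrix(-1, 2, 2)), "0, 255")
  expect_error(channel_image(matrix(256, 2, 2)), "0, 255")
  expect_error(channel_image(array(0, c(2, 2, 2))), "matrix")
  img <- channel_image(array(7L, c(4, 6, 3)))
  expect_true(im_is_rgb(img))
  expect_equal(c(im_height(img), im_width(img)), c(4, 6))
})

test_that("records enforce co-registration and promote grayscale channels", {
  bf <- channel_image(matrix(100L, 64, 64))
  rgb <- channel_image(array(10L, c(64, 64, 3)))
  rec <- ccc_record("r1", bf, rgb, rgb)
  expect_equal(im_height(rec$cd61), 64)
  # grayscale fluorescence promoted to 3 identical planes
  rec2 <- ccc_record("r2", bf, channel_image(matrix(5L, 64, 64)), rgb)
  expect_true(im_is_rgb(rec2$cd61))
  expect_equal(rec2$cd61$pixels[, , 1], rec2$cd61$pixels[, , 3])
  bad <- channel_image(array(0L, c(64, 32, 3)))
  expect_error(ccc_record("r3", bf, rgb, bad), "registration error.*cd45")
  expect_error(ccc_record("r4", bf, rgb, rgb,
                          truth_mask = binary_mask(matrix(FALSE, 2, 2))),
               "registration error")
})

test_that("image and mask files round-trip through PNG", {
  dir <- withr::local_tempdir()
  set.seed(9)
  img <- channel_image(matrix(sample(0:255, 48 * 32, TRUE), 48, 32))
  p <- file.path(dir, "g.png")
  write_image(img, p)
  expect_equal(read_image(p)$pixels, img$pixels)
  rgb <- channel_image(array(sample(0:255, 24 * 24 * 3, TRUE), c(24, 24, 3)))
  p2 <- file.path(dir, "c.png")
  write_image(rgb, p2)
  expect_equal(read_image(p2)$pixels, rgb$pixels)
  m <- binary_mask(matrix(sample(c(TRUE, FALSE), 30 * 20, TRUE), 30, 20))
  p3 <- file.path(dir, "m.png")
  write_mask(m, p3)
  expect_identical(read_mask(p3)$grid, m$grid)
  expect_error(read_image(file.path(dir, "absent.png")), "input error")
  expect_error(read_image(file.path(dir, "x.tif")), "input error")
})

test_that("read_record loads triplets and reports the offending channel", {
  dir <- withr::local_tempdir()
  bf <- channel_image(matrix(200L, 64, 64))
  fl <- channel_image(array(3L, c(64, 64, 3)))
  write_image(bf, file.path(dir, "bf.png"))
  write_image(fl, file.path(dir, "cd61.png"))
  write_image(fl, file.path(dir, "cd45.png"))
  rec <- read_record(file.path(dir, "bf.png"), file.path(dir, "cd61.png"),
                     file.path(dir, "cd45.png"))
  expect_equal(c(im_height(rec$brightfield), im_width(rec$brightfield)),
               c(64, 64))
  expect_equal(rec$record_id, "bf")
  # grayscale fluorescence file is promoted by replication
  write_image(channel_image(matrix(40L, 64, 64)), file.path(dir, "gray61.png"))
  rec2 <- read_record(file.path(dir, "bf.png"), file.path(dir, "gray61.png"),
                      file.path(dir, "cd45.png"))
  expect_equal(rec2$cd61$pixels[, , 1], rec2$cd61$pixels[, , 2])
  # mismatched dimensions name the channel
  write_image(channel_image(array(0L, c(64, 32, 3))), file.path(dir, "bad45.png"))
  expect_error(read_record(file.path(dir, "bf.png"), file.path(dir, "cd61.png"),
                           file.path(dir, "bad45.png")),
               "registration error.*cd45")
})

test_that("polygon labels serialize to text and back within 1e-6", {
  set.seed(4)
  labs <- lapply(1:3, function(i) {
    ang <- sort(runif(5, 0, 2 * pi))
    polygon_label(i - 1, cbind(0.5 + 0.3 * cos(ang), 0.5 + 0.3 * sin(ang)))
  })
  dir <- withr::local_tempdir()
  p <- file.path(dir, "labels.txt")
  write_polygon_labels(labs, p)
  back <- read_polygon_labels(p)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$class_id, labs[[i]]$class_id)
    expect_true(max(abs(back[[i]]$vertices - labs[[i]]$vertices)) <= 1e-6)
  }
  expect_error(polygon_label(0, rbind(c(0, 0), c(1, 1))), "format error")
  expect_error(polygon_label(-1, rbind(c(0, 0), c(1, 0), c(1, 1))),
               "non-negative")
})

test_that("mask_to_polygon_label traces the full frame to unit corners", {
  lab <- mask_to_polygon_label(binary_mask(matrix(TRUE, 10, 10)))
  v <- lab$vertices
  expect_equal(nrow(v), 4)
  corners <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  start <- which(v[, 1] == 0 & v[, 2] == 0)
  expect_length(start, 1)
  rot <- v[c(start:nrow(v), seq_len(start - 1)), , drop = FALSE]
  expect_equal(unname(rot), corners)
  expect_error(mask_to_polygon_label(binary_mask(matrix(FALSE, 5, 5))),
               "empty-region")
})

test_that("mask -> polygon -> mask round trip is tight on convex regions", {
  # centred disk, radius 20 in 100x100 (the flagship case) plus random
  # convex rectangles and disks with >= 100 px
  cases <- list(disk_mask(100, 100, 50, 50, 20),
                rect_mask(60, 80, 10, 40, 20, 70),
                disk_mask(50, 50, 25, 20, 9))
  set.seed(11)
  for (i in 1:4) {
    r <- sample(6:15, 1)
    cases[[length(cases) + 1]] <-
      disk_mask(64, 64, sample(20:44, 1), sample(20:44, 1), r)
  }
  for (m in cases) {
    lab <- mask_to_polygon_label(m)
    back <- polygon_to_mask(lab, nrow(m$grid), ncol(m$grid))
    expect_gte(iou(m, back), 0.98)
  }
})

test_that("polygon_to_mask handles full-frame and degenerate polygons", {
  full <- polygon_label(0, rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(mask_area(polygon_to_mask(full, 10, 10)), 100)
  degen <- polygon_label(0, rbind(c(0.1, 0.1), c(0.5, 0.5), c(0.9, 0.9)))
  expect_equal(mask_area(polygon_to_mask(degen, 20, 20)), 0)
  expect_error(polygon_to_mask(full, 0, 10), "parameter error")
})

test_that("polygon export uses the largest connected component only", {
  m <- matrix(FALSE, 40, 40)
  m[5:10, 5:10] <- TRUE      # 36 px
  m[20:35, 20:35] <- TRUE    # 256 px
  lab <- mask_to_polygon_label(binary_mask(m))
  back <- polygon_to_mask(lab, 40, 40)
  expect_identical(back$grid, rect_mask(40, 40, 20, 35, 20, 35)$grid)
})

test_that("manifests require the core columns", {
  dir <- withr::local_tempdir()
  df <- data.frame(record_id = "a", brightfield = "a.png",
                   cd61 = "b.png", cd45 = "c.png",
                   class = "cluster", phenotype = "")
  p <- file.path(dir, "manifest.csv")
  write_manifest(df, p)
  expect_equal(read_manifest(p)$record_id, "a")
  write.csv(df[, 1:2], p, row.names = FALSE)
  expect_error(read_manifest(p), "lacks columns")
})
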