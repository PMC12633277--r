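test_that("pad_to_square centres content in gray padding", {
  img <- channel_image(array(sample(0:255, 100 * 50 * 3, TRUE), c(100, 50, 3)))
  out <- pad_to_square(img)
  expect_equal(dim(out$pixels), c(100, 100, 3))
  expect_equal(out$pixels[, 26:75, ], img$pixels)      # content centred
  expect_true(all(out$pixels[, 1:25, ] == 173))        # left band
  expect_true(all(out$pixels[, 76:100, ] == 173))      # right band
  # square input returned unchanged
  sq <- channel_image(matrix(50L, 30, 30))
  expect_identical(pad_to_square(sq), sq)
})

test_that("odd padding puts the extra pixel on the right/bottom", {
  img <- channel_image(matrix(1L, 101, 50))
  out <- pad_to_square(img)
  expect_equal(dim(out$pixels), c(101, 101))
  expect_equal(out$pixels[, 26:75], img$pixels)  # 25 left, 26 right
  expect_true(all(out$pixels[, 1:25] == 173))
  expect_true(all(out$pixels[, 76:101] == 173))
})

test_that("padding never alters original pixels and has the forced area", {
  set.seed(21)
  for (i in 1:5) {
    h <- sample(10:60, 1); w <- sample(10:60, 1)
    img <- channel_image(matrix(sample(0:255, h * w, TRUE), h, w))
    out <- pad_to_square(img)
    side <- max(h, w)
    top <- (side - h) %/% 2; left <- (side - w) %/% 2
    expect_equal(out$pixels[top + seq_len(h), left + seq_len(w)], img$pixels)
    content <- matrix(FALSE, side, side)
    content[top + seq_len(h), left + seq_len(w)] <- TRUE
    expect_equal(sum(!content), side^2 - h * w)
    expect_true(all(out$pixels[!content] == 173))
  }
})

test_that("resize_to_standard is 224x224 RGB and preserves constants", {
  img <- channel_image(matrix(90L, 37, 111))
  out <- resize_to_standard(img)
  expect_equal(dim(out$pixels), c(224, 224, 3))
  expect_true(all(out$pixels == 90))
  # idempotence on a constant 224 input
  flat <- channel_image(array(42L, c(224, 224, 3)))
  expect_equal(resize_to_standard(flat)$pixels, flat$pixels)
  # exact identity when dimensions match (half-pixel-center mapping)
  set.seed(2)
  sq <- channel_image(array(sample(0:255, 224 * 224 * 3, TRUE), c(224, 224, 3)))
  expect_equal(resize_to_standard(sq)$pixels, sq$pixels)
  expect_error(resize_to_standard(img, side = 0), "parameter error")
})

test_that("augment obeys multiplicity, determinism and identity configs", {
  set.seed(3)
  img <- channel_image(array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)))
  cfg <- augmentation_config()
  out <- augment(img, cfg, rng_seed = 7)
  expect_length(out, 5)
  for (o in out) expect_equal(dim(o$pixels), dim(img$pixels))
  out2 <- augment(img, cfg, rng_seed = 7)
  for (i in 1:5) expect_identical(out[[i]]$pixels, out2[[i]]$pixels)
  out3 <- augment(img, cfg, rng_seed = 8)
  expect_false(all(vapply(1:5, function(i)
    identical(out[[i]]$pixels, out3[[i]]$pixels), logical(1))))
  # identity config
  idc <- augmentation_config(multiplicity = 1, crop_scale = c(1, 1),
                             rotation_degrees = c(0, 0),
                             hflip = FALSE, vflip = FALSE,
                             jitter_strength = list(brightness = 0,
                                                    contrast = 0,
                                                    saturation = 0, hue = 0),
                             blur_sigma = c(0, 0))
  expect_identical(augment(img, idc, 1)[[1]]$pixels, img$pixels)
  expect_error(augmentation_config(multiplicity = 0), ">= 1")
  expect_error(augmentation_config(crop_scale = c(0, 1)), "crop_scale")
})

test_that("augmentation multiplies fold counts exactly as printed", {
  tab <- ccc_fold_table()
  cfg <- augmentation_config()
  expect_equal(tab$train_cluster * cfg$multiplicity,
               c(3410, 3405, 3395, 3410, 3480))
  expect_equal(tab$train_non_cluster * cfg$multiplicity,
               c(2860, 2865, 2875, 2865, 2795))
  expect_equal(sum(tab$test_cluster) + sum(tab$test_non_cluster), 1568)
})

test_that("make_folds reproduces the stratified remainder arithmetic", {
  ids <- sprintf("r%04d", 1:1568)
  classes <- rep(c("cluster", "non_cluster"), c(855, 713))
  split <- make_folds(data.frame(record_id = ids, class = classes), k = 5,
                      seed = 1)
  totals <- as.integer(table(split$assignments))
  expect_equal(sort(totals, decreasing = TRUE), c(314, 314, 314, 313, 313))
  # partition: every record in exactly one fold
  expect_equal(sort(names(split$assignments)), sort(ids))
  # per-class fold sizes differ by <= 1
  for (cl in c("cluster", "non_cluster")) {
    cnt <- table(split$assignments[classes == cl])
    expect_lte(diff(range(cnt)), 1)
  }
  # determinism
  split2 <- make_folds(data.frame(record_id = ids, class = classes), k = 5,
                       seed = 1)
  expect_identical(split$assignments, split2$assignments)
})

test_that("make_folds handles the minimal balanced case and errors", {
  recs <- data.frame(record_id = letters[1:4],
                     class = c("a", "a", "b", "b"))
  split <- make_folds(recs, k = 2, seed = 0)
  expect_equal(unname(table(split$assignments)), array(c(2L, 2L)))
  for (f in 0:1) {
    members <- names(split$assignments)[split$assignments == f]
    expect_setequal(unique(recs$class[recs$record_id %in% members]),
                    c("a", "b"))
  }
  expect_error(make_folds(recs, k = 1), "k must be >= 2")
  expect_error(make_folds(recs, k = 3), "fewer than k")
})

test_that("fold splits round-trip through CSV", {
  recs <- data.frame(record_id = sprintf("r%02d", 1:20),
                     class = rep(c("x", "y"), 10))
  split <- make_folds(recs, k = 5, seed = 3)
  p <- file.path(withr::local_tempdir(), "folds.csv")
  write_fold_split(split, p)
  back <- read_fold_split(p)
  expect_equal(back$k, 5)
  expect_identical(back$assignments[names(split$assignments)],
                   split$assignments)
})
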