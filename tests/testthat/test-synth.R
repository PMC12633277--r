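test_that("scene kinds satisfy their construction contracts", {
  blank <- generate_scene(scene_spec("blank", seed = 1))
  expect_equal(mask_area(blank$truth_mask), 0)
  expect_equal(blank$truth_class, "non_cluster")

  clus <- generate_scene(scene_spec("cluster", n_cells = 3, seed = 2))
  expect_equal(clus$truth_class, "cluster")
  insts <- attr(clus, "truth_instances")
  expect_length(insts, 3)
  # at least one pair of cells touches/overlaps
  touching <- FALSE
  for (i in 1:2) for (j in (i + 1):3)
    if (sum(insts[[i]]$grid & mask_dilate(insts[[j]], 1)$grid) > 0)
      touching <- TRUE
  expect_true(touching)

  sep <- generate_scene(scene_spec("separated_cells", seed = 3))
  sep_insts <- attr(sep, "truth_instances")
  for (i in seq_along(sep_insts)) for (j in seq_along(sep_insts)) {
    if (i >= j) next
    expect_equal(sum(mask_dilate(sep_insts[[i]], 1)$grid &
                       sep_insts[[j]]$grid), 0)
  }
  expect_error(scene_spec("blank", n_cells = 2), "n_cells = 0")
  expect_error(scene_spec("cluster", n_cells = 1), ">= 2")
})

test_that("generation is deterministic given the spec seed", {
  a <- generate_scene(scene_spec("cluster", seed = 77))
  b <- generate_scene(scene_spec("cluster", seed = 77))
  expect_identical(a$brightfield$pixels, b$brightfield$pixels)
  expect_identical(a$truth_mask$grid, b$truth_mask$grid)
  c <- generate_scene(scene_spec("cluster", seed = 78))
  expect_false(identical(a$brightfield$pixels, c$brightfield$pixels))
})

test_that("staining paints the implied channels with requested coverage", {
  rec <- generate_scene(scene_spec("cluster", noise_sigma = 0, seed = 5))
  area <- mask_area(rec$truth_mask)
  green <- stain_channel("cd61_green")
  yellow <- stain_channel("cd45_yellow")

  # rbc: nothing painted, both extracted masks empty
  rbc <- apply_staining(rec, stain_spec("rbc_cluster", seed = 1))
  expect_equal(mask_area(extract_stain_mask(rbc$cd61, green)), 0)
  expect_equal(mask_area(extract_stain_mask(rbc$cd45, yellow)), 0)

  # platelet at full coverage: green overlap is exactly 100
  plt <- apply_staining(rec, stain_spec("platelet_cluster",
                                        coverage_frac = 1, seed = 2))
  gm <- extract_stain_mask(plt$cd61,
                           stain_channel("cd61_green", morph_open = FALSE))
  expect_equal(overlap_percentage(rec$truth_mask, gm), 100)
  expect_equal(mask_area(extract_stain_mask(plt$cd45, yellow)), 0)

  # wbc+platelet at 50%: both overlaps within 2 pp
  both <- apply_staining(rec, stain_spec("wbc_platelet_cluster",
                                         coverage_frac = 0.5, seed = 3))
  og <- overlap_percentage(rec$truth_mask,
                           extract_stain_mask(both$cd61, green))
  oy <- overlap_percentage(rec$truth_mask,
                           extract_stain_mask(both$cd45, yellow))
  expect_lt(abs(og - 50), 2)
  expect_lt(abs(oy - 50), 2)

  # oracle: painted-in-mask pixel count matches coverage to within 2 pp
  hsv <- rgb_to_hsv255(both$cd61)
  painted <- hsv$v >= 100
  expect_lt(abs(100 * sum(painted & rec$truth_mask$grid) / area - 50), 2)
})

test_that("painted stain re-extracts exactly in the noise-free case", {
  rec <- generate_scene(scene_spec("cluster", noise_sigma = 0, seed = 8))
  plt <- apply_staining(rec, stain_spec("platelet_cluster",
                                        coverage_frac = 0.6,
                                        intensity = 200, seed = 4))
  hsv <- rgb_to_hsv255(plt$cd61)
  painted <- binary_mask(hsv$v >= 100)
  for (v in c(100, 140, 190)) {  # any threshold <= intensity - 10
    ch <- stain_channel("cd61_green", v_lo = v, morph_open = FALSE)
    expect_equal(iou(extract_stain_mask(plt$cd61, ch), painted), 1)
  }
})

test_that("artifact stain lies wholly outside the mask", {
  rec <- generate_scene(scene_spec("cluster", noise_sigma = 0, seed = 9))
  art <- apply_staining(rec, stain_spec("excluded_artifact",
                                        coverage_frac = 0,
                                        artifact_area_px = 60, seed = 5))
  gm <- extract_stain_mask(art$cd61, stain_channel("cd61_green",
                                                   morph_open = FALSE))
  expect_equal(mask_area(gm), 60)
  expect_equal(sum(gm$grid & rec$truth_mask$grid), 0)
  # even a 2 px dilation of the truth mask misses the artifact
  expect_equal(sum(gm$grid & mask_dilate(rec$truth_mask, 2)$grid), 0)
})

test_that("staining without a truth mask is an input error", {
  blank <- generate_scene(scene_spec("blank", seed = 10))
  expect_error(apply_staining(blank, stain_spec("platelet_cluster",
                                                coverage_frac = 0.5)),
               "input error")
})

test_that("generate_dataset writes a deterministic, well-formed corpus", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- generate_dataset(dir1, n_records = 24, seed = 6, image_size = 64)
  m2 <- generate_dataset(dir2, n_records = 24, seed = 6, image_size = 64)
  expect_equal(nrow(m1), 24)
  expect_setequal(unique(m1$class), c("cluster", "non_cluster"))
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  # files exist and load as a record
  rec <- read_record(file.path(dir1, m1$brightfield[1]),
                     file.path(dir1, m1$cd61[1]),
                     file.path(dir1, m1$cd45[1]))
  expect_s3_class(rec, "ccc_record")
  # artifact_rate = 1: every cluster gets outside-only staining
  dir3 <- withr::local_tempdir()
  m3 <- generate_dataset(dir3, n_records = 12, artifact_rate = 1,
                         class_mix = c(cluster = 1, non_cluster = 0),
                         seed = 7, image_size = 64, noise_sigma = 0)
  expect_true(all(m3$phenotype == "excluded_artifact"))
  for (i in seq_len(nrow(m3))) {
    g <- read_mask(file.path(dir3, m3$mask[i]))
    cd61 <- read_image(file.path(dir3, m3$cd61[i]))
    stained <- rgb_to_hsv255(cd61)$v >= 100
    expect_gt(sum(stained), 0)
    expect_equal(sum(stained & g$grid), 0)
  }
})
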