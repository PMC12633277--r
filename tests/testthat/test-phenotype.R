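test_that("overlap_percentage is the forced arithmetic", {
  cluster <- rect_mask(20, 20, 1, 10, 1, 10)          # 100 px
  stain <- rect_mask(20, 20, 1, 2, 1, 10)             # overlaps 20
  expect_equal(overlap_percentage(cluster, stain), 20)
  disjoint <- rect_mask(20, 20, 15, 18, 15, 18)
  expect_equal(overlap_percentage(cluster, disjoint), 0)
  # stain superset of cluster scores 100 even though it extends beyond
  super <- rect_mask(20, 20, 1, 15, 1, 15)
  expect_equal(overlap_percentage(cluster, super), 100)
  expect_error(overlap_percentage(binary_mask(matrix(FALSE, 20, 20)), stain),
               "undefined-denominator")
  expect_error(overlap_percentage(cluster, rect_mask(10, 10, 1, 2, 1, 2)),
               "registration error")
})

test_that("channel_state covers its four outcomes with inclusive threshold", {
  cfg <- phenotype_config(overlap_threshold_pct = 15)
  cluster <- rect_mask(30, 30, 1, 10, 1, 10)  # 100 px
  empty <- binary_mask(matrix(FALSE, 30, 30))
  expect_equal(channel_state(cluster, empty, cfg), "no_stain")
  outside <- rect_mask(30, 30, 20, 25, 20, 25)
  expect_equal(channel_state(cluster, outside, cfg), "artifact")
  ov16 <- rect_mask(30, 30, 1, 2, 1, 8)   # 16 px -> 16%
  expect_equal(channel_state(cluster, ov16, cfg), "present")
  ov15 <- rect_mask(30, 30, 1, 3, 1, 5)   # 15 px -> exactly 15%: inclusive
  expect_equal(channel_state(cluster, ov15, cfg), "present")
  ov14 <- rect_mask(30, 30, 1, 2, 1, 7)   # 14 px -> 14%
  expect_equal(channel_state(cluster, ov14, cfg), "absent")
})

test_that("the decision table is total and matches the stated rules", {
  states <- c("present", "absent", "artifact", "no_stain")
  for (g in states) for (y in states) {
    lab <- cccpheno:::phenotype_from_states(g, y)
    expect_true(lab %in% ccc_phenotypes())
    if (g == "present" && y == "present")
      expect_equal(lab, "wbc_platelet_cluster")
    else if (g == "present") expect_equal(lab, "platelet_cluster")
    else if (y == "present") expect_equal(lab, "wbc_cluster")
    else if (any(c(g, y) == "artifact") && !any(c(g, y) == "absent"))
      expect_equal(lab, "excluded_artifact")
    else expect_equal(lab, "rbc_cluster")
  }
})

test_that("classify_phenotype applies the rules on constructed masks", {
  cluster <- rect_mask(40, 40, 5, 14, 5, 14)  # 100 px
  rec <- ccc_record("t", channel_image(matrix(200L, 40, 40)),
                    flat_rgb(40, 40, c(0, 0, 0)), flat_rgb(40, 40, c(0, 0, 0)),
                    truth_mask = cluster)
  masks <- function(gmask, ymask) list(green = gmask, yellow = ymask)
  empty <- binary_mask(matrix(FALSE, 40, 40))
  g40 <- rect_mask(40, 40, 5, 8, 5, 14)    # 40 px inside
  rep1 <- classify_phenotype(rec, cluster, stain_masks = masks(g40, empty))
  expect_equal(rep1$label, "platelet_cluster")
  expect_equal(rep1$overlap_pct_green, 40)
  expect_equal(rep1$yellow_state, "no_stain")
  y20 <- rect_mask(40, 40, 5, 6, 5, 14)    # 20 px inside
  rep2 <- classify_phenotype(rec, cluster, stain_masks = masks(g40, y20))
  expect_equal(rep2$label, "wbc_platelet_cluster")
  outside <- rect_mask(40, 40, 30, 35, 30, 35)
  rep3 <- classify_phenotype(rec, cluster, stain_masks = masks(outside, empty))
  expect_equal(rep3$label, "excluded_artifact")
  expect_equal(rep3$green_state, "artifact")
  rep4 <- classify_phenotype(rec, cluster, stain_masks = masks(empty, empty))
  expect_equal(rep4$label, "rbc_cluster")
  # mixed evidence (artifact on one channel, sub-threshold on the other)
  # is not excluded: the absent channel carries real overlap
  sub <- rect_mask(40, 40, 5, 5, 5, 9)     # 5 px -> 5%
  rep5 <- classify_phenotype(rec, cluster, stain_masks = masks(outside, sub))
  expect_equal(rep5$label, "rbc_cluster")
})

test_that("raising the threshold is monotone toward rbc_cluster", {
  rank <- c(rbc_cluster = 0, excluded_artifact = 0, platelet_cluster = 1,
            wbc_cluster = 1, wbc_platelet_cluster = 2)
  set.seed(17)
  for (i in 1:10) {
    rec <- generate_scene(scene_spec("cluster", noise_sigma = 0,
                                     seed = 800 + i))
    rec <- apply_staining(rec, stain_spec("wbc_platelet_cluster",
                                          coverage_frac = runif(1, 0.05, 0.6),
                                          seed = 900 + i))
    prev <- Inf
    for (thr in c(5, 15, 30, 60, 90)) {
      lab <- classify_phenotype(rec, rec$truth_mask,
                                phenotype_config(thr))$label
      expect_lte(rank[[lab]], prev)
      prev <- rank[[lab]]
    }
  }
})

test_that("overlap percentage is stable under 2x upsampling", {
  up <- function(m) binary_mask(m$grid[rep(seq_len(nrow(m$grid)), each = 2),
                                       rep(seq_len(ncol(m$grid)), each = 2)])
  set.seed(19)
  for (i in 1:5) {
    cl <- disk_mask(48, 48, sample(15:30, 1), sample(15:30, 1), sample(8:12, 1))
    st <- disk_mask(48, 48, sample(15:30, 1), sample(15:30, 1), sample(6:10, 1))
    if (mask_area(cl) == 0) next
    a <- overlap_percentage(cl, st)
    b <- overlap_percentage(up(cl), up(st))
    expect_lt(abs(a - b), 1)
  }
})
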