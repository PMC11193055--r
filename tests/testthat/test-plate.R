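test_that("serpentine reassembly follows the meandering acquisition order", {
  # acquisition index -> (row, col) for the 3 x 4 grid, enumerated by hand
  lookup <- rbind(
    c(0, 0, 0), c(1, 0, 1), c(2, 0, 2), c(3, 0, 3),
    c(4, 1, 3), c(5, 1, 2), c(6, 1, 1), c(7, 1, 0),
    c(8, 2, 0), c(9, 2, 1), c(10, 2, 2), c(11, 2, 3)
  )
  for (r in seq_len(nrow(lookup))) {
    pos <- wellcounter:::serpentine_position(lookup[r, 1], c(3L, 4L))
    expect_equal(unname(pos), lookup[r, 2:3])
  }

  # tiles filled with their acquisition index land on the expected block
  tiles <- lapply(0:11, function(k) {
    channel_image(matrix(k / 11, 10, 10), "hoechst", tile_index = k)
  })
  mosaic <- reassemble(tile_set(tiles, "A1"))
  for (r in seq_len(nrow(lookup))) {
    k <- lookup[r, 1]; row <- lookup[r, 2]; col <- lookup[r, 3]
    block <- mosaic$pixels[row * 10 + 1:10, col * 10 + 1:10]
    expect_equal(unique(as.vector(block)), k / 11)
  }
})

test_that("split and reassemble round-trip any divisible image", {
  set.seed(3)
  px <- matrix(runif(60 * 80), 60, 80)
  img <- channel_image(px, "pi", well_id = "C3")
  expect_equal(reassemble(split_tiles(img))$pixels, px)

  # degenerate 1 x 1 grid is the identity
  one <- split_tiles(img, grid_shape = c(1L, 1L))
  expect_equal(reassemble(one)$pixels, px)

  # shape errors
  expect_error(tile_set(list(img), "A1"), "expected 12 tiles")
  bad <- c(rep(list(channel_image(matrix(0.1, 5, 5), "hoechst")), 11),
           list(channel_image(matrix(0.1, 6, 5), "hoechst")))
  expect_error(tile_set(bad, "A1"), "identical dimensions")
  expect_error(split_tiles(channel_image(matrix(0.1, 7, 9), "hoechst")),
               "not divisible")
})

test_that("per-tile and reassembled counts agree away from tile seams", {
  # nuclei at tile centres: 6+ px from every seam of the 3 x 4 grid
  tile_h <- 60; tile_w <- 60
  centers <- expand.grid(x = tile_w * (0:3) + 30, y = tile_h * (0:2) + 30)
  sc <- make_scene(centers$x, centers$y, radius_px = 2.8,
                   field_size = c(3 * tile_h, 4 * tile_w), noise_sd = 0)
  img <- render_channels(sc)$hoechst
  whole <- count_image(img)
  tiles <- split_tiles(img)
  per_tile <- sum(vapply(tiles$tiles, count_image, numeric(1)))
  expect_equal(whole, nrow(centers))
  expect_equal(per_tile, whole)
})

test_that("count_well subtracts PI from Hoechst and clamps at zero", {
  sc <- generate_scene(60, dead_fraction = 0.25, field_size = c(300, 300),
                       noise_sd = 0, min_separation_px = 12, seed = 12)
  ch <- render_channels(sc)
  wc <- count_well(ch$hoechst, ch$pi,
                   well_center_xy = sc$well_center_xy,
                   well_radius_px = sc$well_radius_px)
  expect_equal(wc$hoechst, 60)
  expect_equal(wc$pi, 15)
  expect_equal(wc$viable, 45)

  # PI > Hoechst clamps to zero with a warning
  blank <- channel_image(matrix(0.05, 300, 300), "hoechst")
  expect_warning(wc2 <- count_well(blank, structure(ch$pi, class = "channel_image")),
                 "clamped")
  expect_equal(wc2$viable, 0)

  # channel mismatch is an error
  expect_error(count_well(ch$pi, ch$pi), "channel mismatch")
})

test_that("growth series computes fold changes against the 0 h reference", {
  layout <- validate_plate_layout(data.frame(
    well = c("A1", "A2", "B1", "B2", "C1"),
    cell_line = "HEp-2", treatment = "none", dose_uM = 0,
    timepoint_h = c(0, 0, 72, 72, 72),
    replicate = c(1, 2, 1, 2, 3),
    role = c("untreated_control", "untreated_control", "sample", "sample",
             "sample")
  ))
  counts <- data.frame(well = c("A1", "A2", "B1", "B2", "C1"),
                       hoechst = 0, pi = 0,
                       viable = c(5000, 5000, 35000, 35000, 35000))
  gs <- growth_series(counts, layout)
  expect_equal(gs$fold_change[gs$timepoint_h == 72], 7.0)
  expect_equal(gs$n[gs$timepoint_h == 72], 3L)

  # permuting well order leaves the series unchanged
  perm <- sample(nrow(counts))
  gs2 <- growth_series(counts[perm, ], layout)
  expect_equal(gs2, gs)

  # single replicate reports sd as NA, not zero
  gs1 <- growth_series(counts[c(1, 3), ], layout)
  expect_true(is.na(gs1$sd_viable[gs1$timepoint_h == 72]))

  # missing reference names the condition
  expect_error(growth_series(counts[3:5, ], layout), "reference")
})

test_that("survival and killing rates follow the group-mean convention", {
  s <- survival_rate(400, 1000)
  expect_equal(s$survival, 0.40)
  expect_equal(s$killing, 0.60)

  expect_equal(survival_rate(1000, 1000)$survival, 1.0)
  expect_equal(survival_rate(1000, 1000)$killing, 0.0)

  # ratio of group means, cross-checked against both conventions by hand
  tg <- c(200, 400); ug <- c(1000, 1000)
  expect_equal(survival_rate(tg, ug)$survival, mean(tg) / mean(ug))  # 0.30
  expect_equal(survival_rate(tg, ug)$survival, 0.30)
  expect_equal(survival_rate(tg, ug)$survival_paired, mean(tg / ug))

  # scale invariance
  expect_equal(survival_rate(3 * tg, 3 * ug)$survival, 0.30)

  # survival above 1 is reported as-is
  expect_gt(survival_rate(1200, 1000)$survival, 1)

  expect_error(survival_rate(400, numeric(0)), "untreated")
  expect_error(survival_rate(400, c(0, 0)), "untreated")
})

test_that("plate layout validation catches malformed inputs", {
  good <- data.frame(well = "A1", cell_line = "x", treatment = "none",
                     dose_uM = 0, timepoint_h = 0, replicate = 1,
                     role = "sample")
  expect_s3_class(validate_plate_layout(good), "plate_layout")
  bad_well <- good; bad_well$well <- "Z9"
  expect_error(validate_plate_layout(bad_well), "invalid well")
  bad_role <- good; bad_role$role <- "mystery"
  expect_error(validate_plate_layout(bad_role), "invalid roles")
  expect_error(validate_plate_layout(good[, -1]), "missing columns")
})
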