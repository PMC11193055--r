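test_that("grayscale conversion handles unit, colour and integer inputs", {
  m <- matrix(runif(30), 5, 6)
  expect_equal(to_grayscale(m)$pixels, m)

  rgb <- array(0.4, dim = c(5, 6, 3))
  expect_equal(to_grayscale(rgb)$pixels, matrix(0.4, 5, 6))

  m16 <- matrix(c(0, 32768, 65535), 1, 3)
  expect_equal(to_grayscale(m16)$pixels[1, 3], 1.0)
  expect_equal(to_grayscale(m16)$pixels[1, 1], 0.0)

  expect_error(to_grayscale(array(1, dim = c(4, 4, 2))), "channel count")
})

test_that("well masking replaces outside pixels with the original mean", {
  # uniform image is a fixed point
  u <- channel_image(matrix(0.3, 50, 50), "hoechst")
  expect_equal(mask_outside_well(u, c(25, 25), 10)$pixels, u$pixels)

  # binary disk image: outside becomes the full-image mean
  h <- 60; w <- 60
  out <- wellcounter:::outside_well_mask(h, w, c(30, 30), 15)
  px <- matrix(1, h, w); px[out] <- 0
  img <- channel_image(px, "hoechst")
  masked <- mask_outside_well(img, c(30, 30), 15)
  expect_equal(unique(masked$pixels[out]), mean(px))
  expect_equal(masked$pixels[!out], px[!out])

  # one-pass semantics: a second pass changes outside only via the new mean
  twice <- mask_outside_well(masked, c(30, 30), 15)
  expect_equal(unique(twice$pixels[out]), mean(masked$pixels))

  expect_error(mask_outside_well(u, c(25, 25), -1), "positive")
})

test_that("median smoothing matches a brute-force window scan", {
  # constant image unchanged
  cimg <- channel_image(matrix(0.7, 20, 20), "hoechst")
  expect_equal(median_smooth(cimg)$pixels, cimg$pixels)

  # isolated hot pixel removed
  hot <- matrix(0, 20, 20); hot[10, 10] <- 1
  expect_equal(max(median_smooth(channel_image(hot, "hoechst"))$pixels), 0)

  # checkerboard and random images equal the brute-force 4x4 median
  chk <- matrix(rep_len(c(0, 1), 15 * 14), 15, 14)
  expect_equal(median_smooth(channel_image(chk, "hoechst"))$pixels,
               brute_median_filter(chk, 4L, 4L))
  set.seed(8)
  rnd <- matrix(runif(13 * 17), 13, 17)
  expect_equal(median_smooth(channel_image(rnd, "hoechst"))$pixels,
               brute_median_filter(rnd, 4L, 4L))
  # odd window too
  expect_equal(median_smooth(channel_image(rnd, "hoechst"), c(3, 3))$pixels,
               brute_median_filter(rnd, 3L, 3L))
})

test_that("a single Gaussian spot is detected at the right place and scale", {
  px <- gaussian_spot_image(101, 101, x0 = 50, y0 = 50, sd = 2.5, peak = 0.5)
  img <- channel_image(px, "hoechst")
  params <- detection_params()
  blobs <- detect_blobs(img, params)
  expect_equal(nrow(blobs), 1)
  expect_lte(abs(blobs$y - 50), 1)
  expect_lte(abs(blobs$x - 50), 1)
  grid <- sigma_grid(params)
  expect_equal(blobs$sigma, grid[which.min(abs(grid - 2.5))])

  # exhaustive scan of the materialized response volume agrees
  vol <- log_scale_space(img, params)
  mx <- brute_scale_space_maxima(vol, params$threshold)
  expect_equal(nrow(mx), 1)
  expect_equal(unname(mx[1, 1:2]), c(blobs$y, blobs$x))

  # constant image yields no blobs
  expect_equal(nrow(detect_blobs(channel_image(matrix(0.4, 101, 101),
                                               "hoechst"))), 0)
})

test_that("a grid of well-separated identical spots is counted exactly", {
  centers <- expand.grid(x = seq(30, 110, by = 20), y = seq(30, 110, by = 20))
  px <- matrix(0, 141, 141)
  for (k in seq_len(nrow(centers))) {
    px <- px + gaussian_spot_image(141, 141, centers$x[k], centers$y[k],
                                   sd = 2, peak = 0.5)
  }
  blobs <- detect_blobs(channel_image(pmin(px, 1), "hoechst"))
  expect_equal(nrow(blobs), 25)
  m <- match_detections(centers, blobs, max_dist = 2)
  expect_equal(m$n_matched, 25)
})

test_that("pre-pruning detection equals the brute-force scale-space scan", {
  params <- detection_params()
  for (s in 1:4) {
    set.seed(100 + s)
    px <- matrix(runif(128 * 128, 0, 0.2), 128, 128)
    for (k in 1:6) {
      px <- px + gaussian_spot_image(128, 128, runif(1, 20, 108),
                                     runif(1, 20, 108), sd = runif(1, 1.5, 4),
                                     peak = runif(1, 0.3, 0.7))
    }
    img <- channel_image(pmin(px, 1), "hoechst")
    blobs <- detect_blobs(img, params, prune = FALSE)
    vol <- log_scale_space(img, params)
    mx <- brute_scale_space_maxima(vol, params$threshold)
    got <- blobs[order(blobs$sigma, blobs$x, blobs$y), c("y", "x")]
    want <- data.frame(y = mx[, 1], x = mx[, 2])
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("overlap pruning is idempotent and keeps the coarser blob", {
  blobs <- data.frame(y = c(50, 52, 90), x = c(50, 51, 90),
                      sigma = c(3, 2, 2.5), response = c(0.2, 0.3, 0.1))
  p1 <- prune_blobs(blobs, 0.35)
  expect_equal(nrow(p1), 2)           # the two close blobs collapse to one
  expect_true(3 %in% p1$sigma)        # larger sigma wins
  expect_equal(prune_blobs(p1, 0.35), p1)

  # far-apart blobs untouched
  far <- data.frame(y = c(10, 60), x = c(10, 60), sigma = c(2, 2),
                    response = c(0.1, 0.1))
  expect_equal(nrow(prune_blobs(far, 0.35)), 2)
})

test_that("raising the threshold never increases the blob count", {
  set.seed(11)
  px <- matrix(runif(150 * 150, 0, 0.15), 150, 150)
  for (k in 1:10) {
    px <- px + gaussian_spot_image(150, 150, runif(1, 15, 135),
                                   runif(1, 15, 135), sd = 2.2,
                                   peak = runif(1, 0.2, 0.8))
  }
  img <- median_smooth(channel_image(pmin(px, 1), "hoechst"))
  counts <- vapply(c(0.001, 0.005, 0.02, 0.05, 0.1), function(th) {
    nrow(detect_blobs(img, detection_params(threshold = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("blob centres shift with integer image translations", {
  base <- gaussian_spot_image(120, 120, 40, 45, sd = 2.5, peak = 0.6,
                              background = 0.05)
  b0 <- detect_blobs(channel_image(base, "hoechst"))
  shifted <- matrix(0.05, 120, 120)
  shifted[(1:120) > 7, (1:120) > 5] <- base[1:113, 1:115]
  b1 <- detect_blobs(channel_image(shifted, "hoechst"))
  expect_equal(nrow(b0), 1)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$y, b0$y + 7)
  expect_equal(b1$x, b0$x + 5)
  expect_equal(b1$sigma, b0$sigma)
})

test_that("detection error is explicit when the image is too small", {
  tiny <- channel_image(matrix(0.5, 16, 16), "hoechst")
  expect_error(detect_blobs(tiny), "filter support")
})

test_that("detection achieves its resolving envelope on synthetic scenes", {
  # separation 12 px, noise sd 0.005: the regime where the default threshold
  # separates spot responses from noise responses
  for (s in 1:2) {
    sc <- subarea_scene(600, seed = s, field_size = c(600, 600),
                        noise_sd = 0.005, min_separation_px = 12)
    img <- median_smooth(render_channels(sc)$hoechst)
    blobs <- detect_blobs(img)
    m <- match_detections(sc$nuclei, blobs, max_dist = 3)
    expect_gte(m$precision, 0.98)
    expect_gte(m$recall, 0.98)
  }
})

test_that("counting is invariant to bright artifacts outside the well", {
  sc <- generate_scene(60, field_size = c(300, 300), noise_sd = 0,
                       min_separation_px = 12, seed = 4)
  ch <- render_channels(sc)
  n0 <- count_image(ch$hoechst, well_center_xy = sc$well_center_xy,
                    well_radius_px = sc$well_radius_px)
  # paint bright artifacts outside the well disk
  px <- ch$hoechst$pixels
  out <- which(wellcounter:::outside_well_mask(300, 300, sc$well_center_xy,
                                               sc$well_radius_px))
  set.seed(2)
  px[sample(out, 40)] <- 1
  dirty <- channel_image(px, "hoechst")
  n1 <- count_image(dirty, well_center_xy = sc$well_center_xy,
                    well_radius_px = sc$well_radius_px)
  expect_equal(n1, n0)
})
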