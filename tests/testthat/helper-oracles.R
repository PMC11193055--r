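# Independent brute-force oracles used across tests.  These re-derive the
# quantities from first principles and must stay independent of the package's
# implementation paths.

# Brute-force strict scale-space maxima: same rule as the detector (>= all 26
# in-bounds neighbours, equal values resolved toward the lower (y, x, scale)
# lexicographic index), implemented by direct neighbour scan over candidate
# voxels of the materialized response volume.
brute_scale_space_maxima <- function(vol, threshold) {
  dd <- dim(vol)
  cand <- which(vol >= threshold, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]; s <- cand[r, 3]
    v <- vol[i, j, s]
    ok <- TRUE
    for (ds in -1:1) for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0 && ds == 0) next
      ii <- i + di; jj <- j + dj; ss <- s + ds
      if (ii < 1 || ii > dd[1] || jj < 1 || jj > dd[2] ||
          ss < 1 || ss > dd[3]) next
      u <- vol[ii, jj, ss]
      if (u > v) { ok <- FALSE; break }
      if (u == v) {
        precedes <- (i < ii) || (i == ii && (j < jj || (j == jj && s < ss)))
        if (!precedes) { ok <- FALSE; break }
      }
    }
    keep[r] <- ok
  }
  m <- cand[keep, , drop = FALSE]
  m[order(m[, 3], m[, 2], m[, 1]), , drop = FALSE]
}

# Brute-force median filter with the even-window anchor (extra row/col toward
# increasing index) and symmetric reflection, via direct window scans.
brute_median_filter <- function(px, kr = 4L, kc = 4L) {
  reflect <- function(i, n) {
    while (i < 1 || i > n) i <- if (i < 1) 1 - i else 2 * n + 1 - i
    as.integer(i)
  }
  nr <- nrow(px); nc <- ncol(px)
  br <- (kr - 1) %/% 2; ar <- kr - 1 - br
  bc <- (kc - 1) %/% 2; ac <- kc - 1 - bc
  out <- px
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- vapply((i - br):(i + ar), reflect, integer(1), n = nr)
      ci <- vapply((j - bc):(j + ac), reflect, integer(1), n = nc)
      out[i, j] <- median(px[ri, ci])
    }
  }
  out
}

# Profiled grid-search LL4 oracle: for fixed (b, e) the model is linear in
# (c, d); exhaustive search over a log grid, independent of the LM path.
grid_fit_ll4 <- function(dat, nb = 40L, ne = 80L) {
  best <- list(rss = Inf)
  for (b in exp(seq(log(0.2), log(6), length.out = nb))) {
    for (e in exp(seq(log(0.3), log(80), length.out = ne))) {
      f <- 1 / (1 + exp(b * (log(dat$dose) - log(e))))
      X <- cbind(1 - f, f)
      cf <- tryCatch(qr.coef(qr(X), dat$response), error = function(x) NULL)
      if (is.null(cf) || anyNA(cf)) next
      rss <- sum((dat$response - X %*% cf)^2)
      if (rss < best$rss) best <- list(rss = rss, b = b, c = cf[1],
                                       d = cf[2], e = e)
    }
  }
  best
}

# Build a synthetic scene with hand-placed nuclei (bypasses dart throwing),
# for tests that need exact control over positions.
make_scene <- function(x, y, radius_px, dead = FALSE, field_size = c(120L, 160L),
                       well_center_xy = NULL, well_radius_px = NULL,
                       peak_intensity = 0.6, background_level = 0.05,
                       out_of_well_level = 0, noise_sd = 0, seed = 1L) {
  h <- field_size[1]; w <- field_size[2]
  if (is.null(well_center_xy)) well_center_xy <- c((w + 1) / 2, (h + 1) / 2)
  if (is.null(well_radius_px)) well_radius_px <- ceiling(sqrt(h^2 + w^2))
  n <- length(x)
  structure(
    list(field_width_px = w, field_height_px = h,
         well_center_xy = well_center_xy, well_radius_px = well_radius_px,
         nuclei = data.frame(x = x, y = y,
                             radius_px = rep_len(radius_px, n),
                             peak_intensity = rep_len(peak_intensity, n),
                             dead = rep_len(dead, n)),
         background_level = background_level,
         out_of_well_level = out_of_well_level, noise_sd = noise_sd,
         radius_range_px = range(radius_px), min_separation_px = 0,
         rim_margin_px = 0, edge_margin_px = 0, seed = as.integer(seed)),
    class = "synthetic_scene"
  )
}

# Render one Gaussian spot directly (independent of render_channels)
gaussian_spot_image <- function(h, w, x0, y0, sd, peak, background = 0) {
  gy <- exp(-((1:h) - y0)^2 / (2 * sd^2))
  gx <- exp(-((1:w) - x0)^2 / (2 * sd^2))
  background + peak * outer(gy, gx)
}
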