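#' Detection parameters for LoG nuclei counting
#'
#' Defaults are the screening settings used throughout the package:
#' a linear sigma grid of `num_sigma` scales on `[min_sigma, max_sigma]`,
#' a response threshold on unit-scaled intensities, an overlap-pruning
#' fraction, and a 4 x 4 median pre-smoothing neighbourhood.
#'
#' @param min_sigma,max_sigma LoG scale range in pixels.
#' @param num_sigma number of scales, evenly spaced inclusive of both ends.
#' @param threshold minimum scale-normalized response (on \[0, 1\]-scaled
#'   images) for a candidate blob.
#' @param overlap maximum allowed pairwise disk-overlap fraction; beyond it
#'   the lower-priority blob is pruned.
#' @param exclude_borders drop maxima on the image border (kept `FALSE`, the
#'   screening default).
#' @param median_neighborhood median pre-filter window `c(rows, cols)`.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(min_sigma = 1.5, max_sigma = 4, num_sigma = 10L,
                             threshold = 0.005, overlap = 0.35,
                             exclude_borders = FALSE,
                             median_neighborhood = c(4L, 4L)) {
  stopifnot(min_sigma > 0, min_sigma <= max_sigma, num_sigma >= 1,
            threshold >= 0, overlap >= 0, overlap <= 1,
            length(median_neighborhood) == 2L, all(median_neighborhood >= 1))
  structure(
    list(min_sigma = min_sigma, max_sigma = max_sigma,
         num_sigma = as.integer(num_sigma), threshold = threshold,
         overlap = overlap, exclude_borders = isTRUE(exclude_borders),
         median_neighborhood = as.integer(median_neighborhood)),
    class = "detection_params"
  )
}

#' Sigma grid of a detection-parameter set
#'
#' @param params a [detection_params()] object.
#' @return numeric vector of `num_sigma` scales, linear and inclusive.
#' @export
sigma_grid <- function(params) {
  if (params$num_sigma == 1L) return(params$min_sigma)
  seq(params$min_sigma, params$max_sigma, length.out = params$num_sigma)
}

#' Mask the image outside the well disk with the image average
#'
#' Pixels whose centres fall outside the well disk are replaced by the mean
#' intensity of the original, unmasked image, so that the dark plate area
#' around a round well does not interfere with blob detection.  Pixels inside
#' the disk are untouched.  One pass only: re-applying the mask changes the
#' result only through the updated image mean.
#'
#' @param image a [channel_image].
#' @param well_center_xy well centre `c(x, y)` in pixels.
#' @param well_radius_px well radius in pixels (> 0).
#' @return a [channel_image] with out-of-well pixels set to the original mean.
#' @export
mask_outside_well <- function(image, well_center_xy, well_radius_px) {
  stopifnot(inherits(image, "channel_image"))
  if (!is.numeric(well_radius_px) || well_radius_px <= 0) {
    stop("well radius must be positive", call. = FALSE)
  }
  px <- image$pixels
  out <- outside_well_mask(nrow(px), ncol(px), well_center_xy, well_radius_px)
  if (all(out)) {
    stop("well disk does not intersect the image", call. = FALSE)
  }
  px[out] <- mean(image$pixels)
  image$pixels <- px
  image
}

#' Median pre-smoothing
#'
#' Replaces each pixel by the median of its rectangular neighbourhood
#' (default 4 x 4).  Even-sized windows are anchored with the extra
#' row/column toward increasing index and use the sample median (mean of the
#' two middle order statistics); borders are handled by reflection.
#'
#' @param image a [channel_image].
#' @param neighborhood window size `c(rows, cols)`.
#' @return the smoothed [channel_image].
#' @export
median_smooth <- function(image, neighborhood = c(4L, 4L)) {
  stopifnot(inherits(image, "channel_image"),
            length(neighborhood) == 2L, all(neighborhood >= 1))
  image$pixels <- cpp_median_filter(image$pixels,
                                    as.integer(neighborhood[1]),
                                    as.integer(neighborhood[2]))
  image
}

# sampled, sum-normalized Gaussian kernel (support 4 sigma)
gauss_kernel <- function(sigma) {
  R <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-R):R
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# second-derivative-of-Gaussian kernel, zero-sum so flat images give zero
# response
gauss_d2_kernel <- function(sigma) {
  R <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-R):R
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- g * (x^2 - sigma^2) / sigma^4
  k - mean(k)
}

#' Scale-normalized negative LoG response volume
#'
#' For each scale sigma on the grid, computes `-sigma^2 * Laplacian(G_sigma *
#' I)` via two separable convolutions (second-derivative-of-Gaussian along
#' one axis, Gaussian along the other), with reflected borders.  Bright
#' spots on a dark background appear as positive maxima whose scale tracks
#' the spot's Gaussian sd.
#'
#' @param image a [channel_image] (already preprocessed by the caller).
#' @param params a [detection_params()] object.
#' @return a `height x width x num_sigma` array with attribute `"sigmas"`.
#' @export
log_scale_space <- function(image, params = detection_params()) {
  stopifnot(inherits(image, "channel_image"),
            inherits(params, "detection_params"))
  px <- image$pixels
  sigmas <- sigma_grid(params)
  support <- 2L * as.integer(ceiling(4 * max(sigmas))) + 1L
  if (nrow(px) < support || ncol(px) < support) {
    stop(sprintf("image (%d x %d) is smaller than the largest filter support (%d px)",
                 nrow(px), ncol(px), support), call. = FALSE)
  }
  vol <- array(0, dim = c(nrow(px), ncol(px), length(sigmas)))
  for (k in seq_along(sigmas)) {
    s <- sigmas[k]
    vol[, , k] <- cpp_log_response(px, gauss_kernel(s), gauss_d2_kernel(s), s)
  }
  attr(vol, "sigmas") <- sigmas
  vol
}

#' Detect blobs by scale-space LoG maxima with overlap pruning
#'
#' Candidates are the strict local maxima of the 3-D (y, x, scale) response
#' volume with response at or above `params$threshold` (plateau ties resolved
#' toward the lowest (y, x, scale) index; border maxima kept when
#' `exclude_borders` is `FALSE`).  Each blob is then modelled as a disk of
#' radius `sigma * sqrt(2)`; whenever two disks overlap by more than
#' `params$overlap` of the smaller disk's area, the lower-priority blob is
#' pruned (priority: larger sigma, then higher response, then lower (y, x)).
#'
#' @param image a preprocessed [channel_image]; use [count_image()] for the
#'   composed mask / smooth / detect pipeline.
#' @param params a [detection_params()] object.
#' @param prune apply overlap pruning (set `FALSE` to obtain the raw
#'   scale-space maxima).
#' @return a `blob_set`: data frame with columns `y`, `x`, `sigma`,
#'   `response`, sorted by (y, x), with the parameters and image identity
#'   attached as attributes.
#' @export
detect_blobs <- function(image, params = detection_params(), prune = TRUE) {
  vol <- log_scale_space(image, params)
  sigmas <- attr(vol, "sigmas")
  idx <- cpp_scale_space_maxima(as.vector(vol), dim(vol)[1], dim(vol)[2],
                                dim(vol)[3], params$threshold)
  blobs <- data.frame(
    y = as.numeric(idx[, 1]),
    x = as.numeric(idx[, 2]),
    sigma = sigmas[idx[, 3]],
    response = vol[idx]
  )
  if (params$exclude_borders && nrow(blobs) > 0) {
    h <- dim(vol)[1]; w <- dim(vol)[2]
    keep <- blobs$y > 1 & blobs$y < h & blobs$x > 1 & blobs$x < w
    blobs <- blobs[keep, , drop = FALSE]
  }
  if (prune) blobs <- prune_blobs(blobs, params$overlap)
  blobs <- blobs[order(blobs$y, blobs$x), , drop = FALSE]
  rownames(blobs) <- NULL
  attr(blobs, "params") <- params
  attr(blobs, "source") <- list(channel = image$channel,
                                well_id = image$well_id,
                                tile_index = image$tile_index)
  class(blobs) <- c("blob_set", "data.frame")
  blobs
}

#' Prune overlapping blobs
#'
#' Deterministic greedy pruning: blobs are visited in priority order (larger
#' sigma first, then higher response, then lower (y, x)) and kept only if
#' their model disk (radius `sigma * sqrt(2)`) overlaps every already-kept
#' disk by at most `overlap` of the smaller disk's area.  Pruning an
#' already-pruned set changes nothing.
#'
#' @param blobs data frame with columns `y`, `x`, `sigma`, `response`.
#' @param overlap maximum tolerated overlap fraction in \[0, 1\].
#' @return the surviving blobs, sorted by (y, x).
#' @export
prune_blobs <- function(blobs, overlap) {
  if (nrow(blobs) < 2L) return(blobs)
  ord <- order(-blobs$sigma, -blobs$response, blobs$y, blobs$x)
  b <- blobs[ord, , drop = FALSE]
  r <- b$sigma * sqrt(2)
  keep <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    ki <- which(keep)
    ok <- TRUE
    if (length(ki) > 0) {
      f <- disk_overlap_fraction(b$y[i], b$x[i], r[i],
                                 b$y[ki], b$x[ki], r[ki])
      if (any(f > overlap)) ok <- FALSE
    }
    keep[i] <- ok
  }
  res <- b[keep, , drop = FALSE]
  res <- res[order(res$y, res$x), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Overlap area of two disks divided by the smaller disk's area (vectorized
# over the second disk).
disk_overlap_fraction <- function(y1, x1, r1, y2, x2, r2) {
  d <- sqrt((y1 - y2)^2 + (x1 - x2)^2)
  rmin <- pmin(r1, r2)
  out <- numeric(length(d))
  contained <- d <= abs(r1 - r2)
  out[contained] <- 1
  lens <- !contained & d < (r1 + r2)
  if (any(lens)) {
    dl <- d[lens]; r2l <- r2[lens]
    a1 <- (dl^2 + r1^2 - r2l^2) / (2 * dl * r1)
    a2 <- (dl^2 + r2l^2 - r1^2) / (2 * dl * r2l)
    a1 <- pmin(pmax(a1, -1), 1); a2 <- pmin(pmax(a2, -1), 1)
    area <- r1^2 * acos(a1) + r2l^2 * acos(a2) -
      0.5 * sqrt(pmax(0, (-dl + r1 + r2l) * (dl + r1 - r2l) *
                         (dl - r1 + r2l) * (dl + r1 + r2l)))
    out[lens] <- area / (pi * rmin[lens]^2)
  }
  out
}

#' Count nuclei in one channel image
#'
#' Convenience composition of the full per-image chain: mask outside the well
#' (when well geometry is given), median smoothing, LoG blob detection with
#' overlap pruning.  When well geometry is given, only blobs whose centres lie
#' at least `rim_guard_px` inside the well rim are counted: the step between
#' the well interior and the mask fill produces edge responses in a thin band
#' at the rim, which is excluded from counting.
#'
#' @inheritParams mask_outside_well
#' @param params a [detection_params()] object.
#' @param well_center_xy,well_radius_px optional well geometry; `NULL` skips
#'   masking and rim guarding (e.g. for subarea images entirely inside a
#'   well).
#' @param rim_guard_px width of the rim exclusion band in pixels.
#' @return integer nucleus count.
#' @export
count_image <- function(image, params = detection_params(),
                        well_center_xy = NULL, well_radius_px = NULL,
                        rim_guard_px = 6) {
  stopifnot(inherits(image, "channel_image"))
  has_well <- !is.null(well_center_xy) && !is.null(well_radius_px)
  if (has_well) {
    image <- mask_outside_well(image, well_center_xy, well_radius_px)
  }
  image <- median_smooth(image, params$median_neighborhood)
  blobs <- detect_blobs(image, params)
  if (has_well && nrow(blobs) > 0) {
    d2 <- (blobs$x - well_center_xy[1])^2 + (blobs$y - well_center_xy[2])^2
    blobs <- blobs[d2 <= (well_radius_px - rim_guard_px)^2, , drop = FALSE]
  }
  nrow(blobs)
}

#' Match detected blobs to ground-truth nucleus positions
#'
#' Greedy nearest-pair matching: among all (truth, detection) pairs within
#' `max_dist` pixels, repeatedly commit the closest remaining pair.  Used to
#' score detection precision and recall on synthetic scenes.
#'
#' @param truth data frame with columns `x`, `y` (ground-truth centres).
#' @param detections data frame with columns `x`, `y` (blob centres).
#' @param max_dist maximum matching distance in pixels.
#' @return list with `n_matched`, `precision`, `recall`, and the matched
#'   index pairs.
#' @export
match_detections <- function(truth, detections, max_dist = 3) {
  nt <- nrow(truth); nd <- nrow(detections)
  if (nt == 0L || nd == 0L) {
    return(list(n_matched = 0L,
                precision = if (nd == 0L) NA_real_ else 0,
                recall = if (nt == 0L) NA_real_ else 0,
                pairs = data.frame(truth = integer(0), detection = integer(0))))
  }
  d <- outer(truth$x, detections$x, `-`)^2 + outer(truth$y, detections$y, `-`)^2
  cand <- which(d <= max_dist^2, arr.ind = TRUE)
  if (nrow(cand) > 0) cand <- cand[order(d[cand]), , drop = FALSE]
  used_t <- logical(nt); used_d <- logical(nd)
  pt <- integer(0); pd <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_t[i] && !used_d[j]) {
      used_t[i] <- TRUE; used_d[j] <- TRUE
      pt <- c(pt, i); pd <- c(pd, j)
    }
  }
  m <- length(pt)
  list(n_matched = m, precision = m / nd, recall = m / nt,
       pairs = data.frame(truth = pt, detection = pd))
}
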