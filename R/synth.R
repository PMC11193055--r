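#' Generate a synthetic well scene with known ground truth
#'
#' Places `n_cells` nucleus centres uniformly inside the well disk (dart
#' throwing with an optional minimum centre-to-centre separation) and assigns
#' each nucleus a radius, a peak intensity and a live/dead flag.  Exactly
#' `round(n_cells * dead_fraction)` nuclei are flagged dead.  The scene is the
#' ground truth against which rendered images and downstream counts can be
#' scored.
#'
#' Defaults emulate the screening setting the package targets: nuclei sized
#' so that their Gaussian spot scale (sd = radius / sqrt(2)) falls inside the
#' detector's default sigma grid \[1.5, 4\], a dark out-of-well area so the
#' masking stage is exercised, and mild additive Gaussian noise.  Nucleus
#' centres keep `rim_margin_px` away from the well rim (cells at the very rim
#' are not reliably imaged in round wells) and `edge_margin_px` away from the
#' field borders.
#'
#' @param n_cells number of nuclei (>= 0).
#' @param dead_fraction fraction of nuclei flagged dead, in \[0, 1\].
#' @param field_size image size as `c(height_px, width_px)`.
#' @param well_center_xy well centre as `c(x, y)` in pixels; default the
#'   field centre.
#' @param well_radius_px well disk radius in pixels; default inscribes the
#'   disk in the field with an 8 px border.  A radius larger than the field
#'   half-diagonal yields a "subarea" scene entirely inside the well, the
#'   geometry of an inner tile of a well mosaic.
#' @param radius_range_px nucleus radius range `c(r_min, r_max)` in pixels.
#' @param min_separation_px minimum pairwise centre distance (0 disables).
#' @param peak_range nucleus peak intensity range, unit-scaled.
#' @param background_level in-well background intensity, unit-scaled.
#' @param out_of_well_level intensity outside the well disk.
#' @param noise_sd sd of additive Gaussian pixel noise (unit-scaled).
#' @param rim_margin_px keep nucleus centres at least this far inside the
#'   well rim.
#' @param edge_margin_px keep nucleus centres at least this far from the
#'   field borders.
#' @param seed integer seed; the scene is fully reproducible from it.
#' @return an object of class `synthetic_scene` with a `nuclei` data frame
#'   (`x`, `y`, `radius_px`, `peak_intensity`, `dead`).
#' @export
generate_scene <- function(n_cells, dead_fraction = 0,
                           field_size = c(900L, 1200L),
                           well_center_xy = NULL, well_radius_px = NULL,
                           radius_range_px = c(2.1, 5.7),
                           min_separation_px = 8,
                           peak_range = c(0.3, 0.9),
                           background_level = 0.05,
                           out_of_well_level = 0,
                           noise_sd = 0.005,
                           rim_margin_px = 8,
                           edge_margin_px = 6,
                           seed = 1L) {
  assert_scalar_num(n_cells, "n_cells", lower = 0)
  assert_scalar_num(dead_fraction, "dead_fraction", lower = 0, upper = 1)
  stopifnot(length(field_size) == 2L, all(field_size >= 1))
  h <- as.integer(field_size[1]); w <- as.integer(field_size[2])
  if (is.null(well_center_xy)) well_center_xy <- c((w + 1) / 2, (h + 1) / 2)
  if (is.null(well_radius_px)) well_radius_px <- min(h, w) / 2 - 8
  assert_scalar_num(well_radius_px, "well_radius_px", lower = 1)
  stopifnot(length(radius_range_px) == 2L,
            radius_range_px[1] > 0,
            radius_range_px[1] <= radius_range_px[2])
  stopifnot(length(peak_range) == 2L, peak_range[1] <= peak_range[2],
            peak_range[2] <= 1)
  if (background_level < 0 || background_level >= peak_range[1]) {
    stop("background_level must satisfy 0 <= background < peak intensity",
         call. = FALSE)
  }

  n_cells <- as.integer(round(n_cells))
  n_dead <- as.integer(round(n_cells * dead_fraction))

  pts <- with_seed(seed, {
    xy <- place_points(n_cells, well_center_xy, well_radius_px - rim_margin_px,
                       h, w, min_separation_px, edge_margin_px)
    radius <- runif(n_cells, radius_range_px[1], radius_range_px[2])
    peak <- runif(n_cells, peak_range[1], peak_range[2])
    dead <- logical(n_cells)
    if (n_dead > 0) dead[sample.int(n_cells, n_dead)] <- TRUE
    data.frame(x = xy$x, y = xy$y, radius_px = radius,
               peak_intensity = peak, dead = dead)
  })

  structure(
    list(field_width_px = w, field_height_px = h,
         well_center_xy = well_center_xy, well_radius_px = well_radius_px,
         nuclei = pts, background_level = background_level,
         out_of_well_level = out_of_well_level, noise_sd = noise_sd,
         radius_range_px = radius_range_px, min_separation_px = min_separation_px,
         rim_margin_px = rim_margin_px, edge_margin_px = edge_margin_px,
         seed = as.integer(seed)),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_scene> %d x %d px, well r=%.0f px, ",
                     "%d nuclei (%d dead), noise sd %.3f, seed %d\n"),
              x$field_height_px, x$field_width_px, x$well_radius_px,
              nrow(x$nuclei), sum(x$nuclei$dead), x$noise_sd, x$seed))
  invisible(x)
}

# Dart-throwing placement with a cell-grid neighbour check.  Errors with the
# estimated placement capacity when the requested density is infeasible.
place_points <- function(n, center_xy, radius, h, w, min_sep, edge_margin) {
  if (n == 0L) return(list(x = numeric(0), y = numeric(0)))
  if (radius <= 0) stop("well too small for the requested rim margin",
                        call. = FALSE)
  xlim <- c(max(1 + edge_margin, center_xy[1] - radius),
            min(w - edge_margin, center_xy[1] + radius))
  ylim <- c(max(1 + edge_margin, center_xy[2] - radius),
            min(h - edge_margin, center_xy[2] + radius))
  if (xlim[1] >= xlim[2] || ylim[1] >= ylim[2]) {
    stop("placement region is empty (well disk outside the field?)",
         call. = FALSE)
  }
  # random sequential adsorption jams near 54.7% coverage of exclusion disks
  area <- (xlim[2] - xlim[1]) * (ylim[2] - ylim[1])
  if (min_sep > 0) {
    capacity <- floor(0.547 * area / (pi * (min_sep / 2)^2))
    if (n > capacity) {
      stop(sprintf(paste0("infeasible packing: %d nuclei requested but the ",
                          "placement capacity at min_separation %.1f px is ",
                          "about %d"), n, min_sep, capacity), call. = FALSE)
    }
  }

  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  use_grid <- min_sep > 0
  if (use_grid) {
    cell <- min_sep
    ncx <- max(1L, ceiling((xlim[2] - xlim[1]) / cell))
    ncy <- max(1L, ceiling((ylim[2] - ylim[1]) / cell))
    head_idx <- matrix(0L, ncy, ncx)   # index of last point in each cell
    nxt <- integer(n)                  # chained previous point indices
    min_sep2 <- min_sep^2
  }
  max_attempts <- max(2000L, 400L * n)
  attempts <- 0L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    x <- runif(1, xlim[1], xlim[2])
    y <- runif(1, ylim[1], ylim[2])
    if ((x - center_xy[1])^2 + (y - center_xy[2])^2 > radius^2) next
    if (use_grid) {
      cx <- min(ncx, max(1L, 1L + floor((x - xlim[1]) / cell)))
      cy <- min(ncy, max(1L, 1L + floor((y - ylim[1]) / cell)))
      ok <- TRUE
      for (gy in max(1L, cy - 1L):min(ncy, cy + 1L)) {
        for (gx in max(1L, cx - 1L):min(ncx, cx + 1L)) {
          k <- head_idx[gy, gx]
          while (k > 0L) {
            if ((xs[k] - x)^2 + (ys[k] - y)^2 < min_sep2) { ok <- FALSE; break }
            k <- nxt[k]
          }
          if (!ok) break
        }
        if (!ok) break
      }
      if (!ok) next
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
      nxt[placed] <- head_idx[cy, cx]
      head_idx[cy, cx] <- placed
    } else {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
  }
  if (placed < n) {
    stop(sprintf(paste0("infeasible packing: placed %d of %d nuclei after ",
                        "%d attempts (density too close to capacity)"),
                 placed, n, attempts), call. = FALSE)
  }
  list(x = xs, y = ys)
}

#' Render the two fluorescence channels of a synthetic scene
#'
#' Each nucleus is rendered as an isotropic 2-D Gaussian spot with
#' `sd = radius_px / sqrt(2)` added to the in-well background.  The Hoechst
#' channel contains all nuclei; the PI channel only the dead ones.  Additive
#' Gaussian noise (sd `scene$noise_sd`) is applied inside the well, the image
#' is clipped to \[0, 1\], and pixels outside the well disk are set to the
#' scene's out-of-well level.  Rendering is deterministic for a fixed scene
#' seed.
#'
#' @param scene a [generate_scene()] result.
#' @return a list with components `hoechst` and `pi`, both [channel_image]s.
#' @export
render_channels <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  hoechst <- render_one(scene, scene$nuclei, child_seed(scene$seed, 1L))
  pi_img <- render_one(scene, scene$nuclei[scene$nuclei$dead, , drop = FALSE],
                       child_seed(scene$seed, 2L))
  list(hoechst = channel_image(hoechst, "hoechst"),
       pi = channel_image(pi_img, "pi"))
}

render_one <- function(scene, nuclei, noise_seed) {
  h <- scene$field_height_px; w <- scene$field_width_px
  img <- matrix(scene$background_level, h, w)
  if (nrow(nuclei) > 0) {
    for (k in seq_len(nrow(nuclei))) {
      x0 <- nuclei$x[k]; y0 <- nuclei$y[k]
      s <- nuclei$radius_px[k] / sqrt(2)
      a <- nuclei$peak_intensity[k]
      R <- ceiling(4 * s)
      js <- max(1L, floor(x0 - R)):min(w, ceiling(x0 + R))
      is <- max(1L, floor(y0 - R)):min(h, ceiling(y0 + R))
      gy <- exp(-(is - y0)^2 / (2 * s^2))
      gx <- exp(-(js - x0)^2 / (2 * s^2))
      img[is, js] <- img[is, js] + a * outer(gy, gx)
    }
  }
  if (scene$noise_sd > 0) {
    img <- img + with_seed(noise_seed,
                           matrix(rnorm(h * w, 0, scene$noise_sd), h, w))
  }
  img <- pmin(pmax(img, 0), 1)
  out <- outside_well_mask(h, w, scene$well_center_xy, scene$well_radius_px)
  if (any(out)) img[out] <- scene$out_of_well_level
  img
}

# logical matrix: TRUE where the pixel centre lies outside the well disk
outside_well_mask <- function(h, w, center_xy, radius) {
  dx2 <- (seq_len(w) - center_xy[1])^2
  dy2 <- (seq_len(h) - center_xy[2])^2
  outer(dy2, dx2, `+`) > radius^2
}

#' Write a rendered scene to disk
#'
#' Writes one 16-bit grayscale TIFF per channel
#' (`<well>_hoechst.tif`, `<well>_pi.tif`, or 12 serpentine-ordered tiles
#' `<well>_<channel>_tile<k>.tif` when `tiles = TRUE`), a ground-truth CSV
#' (`x,y,radius_px,dead`), and a JSON manifest recording the seed, the well
#' geometry and all generator parameters.
#'
#' @param scene a [generate_scene()] result.
#' @param channels a [render_channels()] result for that scene.
#' @param out_dir output directory (created if missing).
#' @param well_id well label used in file names.
#' @param tiles write the 12-tile serpentine mosaic instead of one image
#'   per channel (field size must be divisible by the 3 x 4 grid).
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/<well>_manifest.json`).
#' @export
write_scene <- function(scene, channels, out_dir, well_id = "A1",
                        tiles = FALSE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir,
                                 call. = FALSE)
  files <- character(0)
  for (ch in c("hoechst", "pi")) {
    img <- channels[[ch]]
    if (tiles) {
      tls <- split_tiles(img, grid_shape = c(3L, 4L))
      for (k in seq_along(tls$tiles)) {
        f <- file.path(out_dir, sprintf("%s_%s_tile%d.tif", well_id, ch, k - 1L))
        write_channel_tiff(tls$tiles[[k]], f)
        files <- c(files, f)
      }
    } else {
      f <- file.path(out_dir, sprintf("%s_%s.tif", well_id, ch))
      write_channel_tiff(img, f)
      files <- c(files, f)
    }
  }
  truth_path <- file.path(out_dir, sprintf("%s_truth.csv", well_id))
  write.csv(scene$nuclei[, c("x", "y", "radius_px", "dead")], truth_path,
            row.names = FALSE)
  manifest <- list(
    tool = "wellcounter",
    version = as.character(utils::packageVersion("wellcounter")),
    well_id = well_id,
    seed = scene$seed,
    n_cells = nrow(scene$nuclei),
    n_dead = sum(scene$nuclei$dead),
    field_size = c(scene$field_height_px, scene$field_width_px),
    well_center_xy = scene$well_center_xy,
    well_radius_px = scene$well_radius_px,
    background_level = scene$background_level,
    out_of_well_level = scene$out_of_well_level,
    noise_sd = scene$noise_sd,
    radius_range_px = scene$radius_range_px,
    min_separation_px = scene$min_separation_px,
    tiles = tiles,
    files = basename(files),
    truth = basename(truth_path)
  )
  manifest_path <- file.path(out_dir, sprintf("%s_manifest.json", well_id))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
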