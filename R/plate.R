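#' Read a plate layout from CSV
#'
#' The layout maps wells of a 96-well (8 x 12) plate to experimental
#' conditions.  Required columns: `well`, `cell_line`, `treatment`,
#' `dose_uM`, `timepoint_h`, `replicate`, `role`, where `role` is one of
#' `sample`, `untreated_control`, `solvent_control`, `medium_control`.
#'
#' @param path CSV file path.
#' @return a data frame of class `plate_layout`.
#' @export
read_plate_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_plate_layout(df)
}

#' Validate (and class) a plate-layout data frame
#'
#' @param df data frame with the layout columns (see [read_plate_layout()]).
#' @return `df`, classed as `plate_layout`.
#' @export
validate_plate_layout <- function(df) {
  required <- c("well", "cell_line", "treatment", "dose_uM", "timepoint_h",
                "replicate", "role")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("layout is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  valid_wells <- as.vector(outer(LETTERS[1:8], 1:12, paste0))
  bad <- setdiff(df$well, valid_wells)
  if (length(bad) > 0) {
    stop("invalid well ids for an 8 x 12 plate: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$well)) {
    stop("duplicated well ids in layout", call. = FALSE)
  }
  roles <- c("sample", "untreated_control", "solvent_control", "medium_control")
  badrole <- setdiff(df$role, roles)
  if (length(badrole) > 0) {
    stop("invalid roles: ", paste(badrole, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("plate_layout", "data.frame")
  df
}

# serpentine acquisition order on a rows x cols grid: row 0 left-to-right,
# row 1 right-to-left, ...; returns the (row, col) of acquisition index k
serpentine_position <- function(k, grid_shape = c(3L, 4L)) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  r <- k %/% cols
  cwithin <- k %% cols
  c <- if (r %% 2L == 0L) cwithin else cols - 1L - cwithin
  c(row = r, col = c)
}

#' Bundle per-well tiles into a tile set
#'
#' @param tiles list of [channel_image]s in acquisition (meandering) order.
#' @param well_id well label.
#' @param grid_shape mosaic grid `c(rows, cols)`; the default 3 x 4 matches
#'   a well dissected into 12 subunits.
#' @return an object of class `tile_set`.
#' @export
tile_set <- function(tiles, well_id = NA_character_, grid_shape = c(3L, 4L)) {
  n <- prod(grid_shape)
  if (length(tiles) != n) {
    stop(sprintf("expected %d tiles for a %d x %d grid, got %d",
                 n, grid_shape[1], grid_shape[2], length(tiles)),
         call. = FALSE)
  }
  dims <- vapply(tiles, function(t) dim(t$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all tiles must have identical dimensions", call. = FALSE)
  }
  structure(list(well_id = well_id, tiles = tiles,
                 grid_shape = as.integer(grid_shape)),
            class = "tile_set")
}

#' Reassemble a tiled well image
#'
#' Tiles are laid out on a `grid_shape` grid with the acquisition order
#' interpreted as serpentine (first row left-to-right, second right-to-left,
#' and so on).  Tiles abut exactly; no blending.
#'
#' @param tiles a [tile_set()].
#' @return the mosaic as a [channel_image].
#' @export
reassemble <- function(tiles) {
  stopifnot(inherits(tiles, "tile_set"))
  th <- nrow(tiles$tiles[[1]]$pixels)
  tw <- ncol(tiles$tiles[[1]]$pixels)
  rows <- tiles$grid_shape[1]; cols <- tiles$grid_shape[2]
  mosaic <- matrix(0, rows * th, cols * tw)
  for (k in seq_along(tiles$tiles)) {
    pos <- serpentine_position(k - 1L, tiles$grid_shape)
    ri <- pos["row"] * th + seq_len(th)
    ci <- pos["col"] * tw + seq_len(tw)
    mosaic[ri, ci] <- tiles$tiles[[k]]$pixels
  }
  channel_image(mosaic, channel = tiles$tiles[[1]]$channel,
                well_id = tiles$well_id)
}

#' Split a well image into serpentine-ordered tiles
#'
#' Inverse of [reassemble()]: cuts the image into a `grid_shape` grid of
#' equal tiles and returns them in meandering acquisition order.
#'
#' @param image a [channel_image] whose dimensions are divisible by the grid.
#' @param grid_shape mosaic grid `c(rows, cols)`.
#' @return a [tile_set()].
#' @export
split_tiles <- function(image, grid_shape = c(3L, 4L)) {
  stopifnot(inherits(image, "channel_image"))
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  rows <- grid_shape[1]; cols <- grid_shape[2]
  if (h %% rows != 0L || w %% cols != 0L) {
    stop(sprintf("image %d x %d is not divisible into a %d x %d grid",
                 h, w, rows, cols), call. = FALSE)
  }
  th <- h %/% rows; tw <- w %/% cols
  tiles <- vector("list", rows * cols)
  for (k in seq_len(rows * cols)) {
    pos <- serpentine_position(k - 1L, grid_shape)
    ri <- pos["row"] * th + seq_len(th)
    ci <- pos["col"] * tw + seq_len(tw)
    tiles[[k]] <- channel_image(image$pixels[ri, ci, drop = FALSE],
                                channel = image$channel,
                                well_id = image$well_id,
                                tile_index = k - 1L)
  }
  tile_set(tiles, well_id = image$well_id, grid_shape = grid_shape)
}

#' Count live and dead nuclei in one well
#'
#' Runs [count_image()] with identical parameters on the Hoechst channel
#' (all nuclei) and the PI channel (dead nuclei).  The viable count is the
#' Hoechst count minus the PI count, clamped at zero (PI spillover artifacts
#' can push the difference negative; a warning is emitted).
#'
#' Detection runs on whole-well (reassembled) images: counting per tile with
#' borders included would double-count nuclei straddling tile seams.
#'
#' @param hoechst,pi [channel_image]s of the same well.
#' @param params a [detection_params()] object.
#' @inheritParams count_image
#' @return a one-row data frame of class `well_count` with columns
#'   `well`, `hoechst`, `pi`, `viable`.
#' @export
count_well <- function(hoechst, pi, params = detection_params(),
                       well_center_xy = NULL, well_radius_px = NULL,
                       rim_guard_px = 6) {
  stopifnot(inherits(hoechst, "channel_image"), inherits(pi, "channel_image"))
  if (hoechst$channel != "hoechst" || pi$channel != "pi") {
    stop("channel mismatch: expected one hoechst and one pi image",
         call. = FALSE)
  }
  if (!identical(dim(hoechst$pixels), dim(pi$pixels))) {
    stop("hoechst and pi images must cover the same well (equal dimensions)",
         call. = FALSE)
  }
  if (!is.na(hoechst$well_id) && !is.na(pi$well_id) &&
      hoechst$well_id != pi$well_id) {
    stop(sprintf("well mismatch: %s vs %s", hoechst$well_id, pi$well_id),
         call. = FALSE)
  }
  nh <- count_image(hoechst, params, well_center_xy, well_radius_px,
                    rim_guard_px)
  np <- count_image(pi, params, well_center_xy, well_radius_px, rim_guard_px)
  if (np > nh) {
    warning(sprintf("well %s: PI count (%d) exceeds Hoechst count (%d); viable clamped to 0",
                    hoechst$well_id, np, nh), call. = FALSE)
  }
  out <- data.frame(well = hoechst$well_id, hoechst = nh, pi = np,
                    viable = max(0L, nh - np))
  class(out) <- c("well_count", "data.frame")
  out
}

#' Proliferation series with fold changes relative to the seeding control
#'
#' Aggregates per-well viable counts by condition (cell line, treatment,
#' dose) and timepoint: mean, sd (`NA` for a single replicate) and n.  Fold
#' changes are relative to the reference timepoint (default 0 h, the plate
#' measured right after seeding): `fold_change(t) = mean viable(t) / mean
#' viable(reference)`.  The reference for a condition is its own 0 h wells
#' when present, otherwise the 0 h wells of the same cell line (the seeding
#' control plate is imaged before any treatment).
#'
#' @param counts data frame of per-well counts (`well`, `hoechst`, `pi`,
#'   `viable`), e.g. rows from [count_well()].
#' @param layout a [read_plate_layout()] data frame.
#' @param reference_timepoint reference time in hours (default 0).
#' @return a data frame of class `growth_series`: one row per condition and
#'   timepoint with `mean_viable`, `sd_viable`, `n`, `fold_change`.
#' @export
growth_series <- function(counts, layout, reference_timepoint = 0) {
  df <- merge(counts, as.data.frame(layout), by = "well")
  if (nrow(df) == 0L) stop("no wells shared between counts and layout",
                           call. = FALSE)
  agg <- stats::aggregate(
    df$viable,
    by = list(cell_line = df$cell_line, treatment = df$treatment,
              dose_uM = df$dose_uM, timepoint_h = df$timepoint_h),
    FUN = function(v) c(mean = mean(v),
                        sd = if (length(v) > 1) sd(v) else NA_real_,
                        n = length(v))
  )
  out <- data.frame(agg[, 1:4],
                    mean_viable = agg$x[, "mean"],
                    sd_viable = agg$x[, "sd"],
                    n = as.integer(agg$x[, "n"]))
  out$fold_change <- NA_real_
  for (i in seq_len(nrow(out))) {
    ref <- out[out$timepoint_h == reference_timepoint &
                 out$cell_line == out$cell_line[i] &
                 out$treatment == out$treatment[i] &
                 out$dose_uM == out$dose_uM[i], , drop = FALSE]
    if (nrow(ref) == 0L) {
      ref <- out[out$timepoint_h == reference_timepoint &
                   out$cell_line == out$cell_line[i], , drop = FALSE]
    }
    if (nrow(ref) == 0L) {
      stop(sprintf("no %g h reference wells for condition %s / %s / %g uM",
                   reference_timepoint, out$cell_line[i], out$treatment[i],
                   out$dose_uM[i]), call. = FALSE)
    }
    out$fold_change[i] <- out$mean_viable[i] / mean(ref$mean_viable)
  }
  out <- out[order(out$cell_line, out$treatment, out$dose_uM, out$timepoint_h), ]
  rownames(out) <- NULL
  class(out) <- c("growth_series", "data.frame")
  out
}

#' Survival and killing rate of a treated group versus untreated controls
#'
#' Survival is the ratio of group means: mean viable count of the treated
#' wells over mean viable count of the untreated control wells at the same
#' condition/timepoint; the killing rate is its complement.  Survival above 1
#' (treated growing faster than control) is reported as-is.  For
#' transparency, the alternative mean-of-per-well-ratios convention is also
#' reported (`survival_paired`, `NA` unless the groups pair 1:1).
#'
#' @param treated,untreated numeric vectors of viable counts (or `well_count`
#'   data frames, from which the `viable` column is taken).
#' @return list with `survival`, `killing`, `survival_paired`, `n_treated`,
#'   `n_untreated`.
#' @export
survival_rate <- function(treated, untreated) {
  tv <- if (is.data.frame(treated)) treated$viable else treated
  uv <- if (is.data.frame(untreated)) untreated$viable else untreated
  if (length(uv) == 0L || mean(uv) <= 0) {
    stop("untreated control group is empty or has zero mean viable count",
         call. = FALSE)
  }
  s <- mean(tv) / mean(uv)
  paired <- if (length(tv) == length(uv)) mean(tv / uv) else NA_real_
  list(survival = s, killing = 1 - s, survival_paired = paired,
       n_treated = length(tv), n_untreated = length(uv))
}
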