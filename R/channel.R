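#' Construct a channel image
#'
#' A `channel_image` is one grayscale fluorescence field: a matrix of
#' unit-scaled intensities in \[0, 1\] plus acquisition metadata (which dye
#' channel, which well, optionally which tile of the well mosaic).
#'
#' Pixel coordinates follow the matrix convention used throughout the
#' package: `y` is the row index, `x` the column index, both 1-based at
#' pixel centres.
#'
#' @param pixels numeric matrix of intensities in \[0, 1\].
#' @param channel `"hoechst"` (all nuclei) or `"pi"` (dead nuclei only).
#' @param well_id well label such as `"A1"`, or `NA`.
#' @param tile_index optional 0-based acquisition index (0-11) when the
#'   image is one tile of a well mosaic.
#' @param magnification_note free-text metadata (e.g. `"10x"`).
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel = c("hoechst", "pi"),
                          well_id = NA_character_, tile_index = NULL,
                          magnification_note = "") {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have positive height and width", call. = FALSE)
  }
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1 + 1e-12) {
    stop("channel_image intensities must be finite and unit-scaled in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(pixels = pixels, channel = channel, well_id = well_id,
         tile_index = tile_index, magnification_note = magnification_note),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, well %s%s, %d x %d px, range [%.4f, %.4f]\n",
              x$channel, x$well_id,
              if (!is.null(x$tile_index)) paste0(", tile ", x$tile_index) else "",
              nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Convert a raw image array to a unit-scaled grayscale channel image
#'
#' Colour images (height x width x 3) are collapsed with the Rec.709
#' luminance weights (0.2126, 0.7152, 0.0722).  Integer-scaled inputs are
#' divided by the maximum of their inferred bit depth (255 for 8-bit,
#' 65535 for 16-bit); inputs already in \[0, 1\] are passed through.
#'
#' @param x numeric matrix, or a height x width x 3 array.
#' @param max_value intensity value mapping to 1.0.  Default `"auto"`:
#'   1 if all values are within \[0, 1\], else 255 if within \[0, 255\],
#'   else 65535.
#' @inheritParams channel_image
#' @return a [channel_image].
#' @export
to_grayscale <- function(x, channel = "hoechst", well_id = NA_character_,
                         tile_index = NULL, max_value = "auto") {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) {
      x <- x[, , 1L]
    } else if (dim(x)[3] == 3L) {
      x <- 0.2126 * x[, , 1L] + 0.7152 * x[, , 2L] + 0.0722 * x[, , 3L]
    } else {
      stop("unsupported channel count: ", dim(x)[3], call. = FALSE)
    }
  }
  if (!is.matrix(x)) stop("input must be a matrix or 3-channel array",
                          call. = FALSE)
  x <- x * 1.0
  if (identical(max_value, "auto")) {
    mx <- max(x)
    max_value <- if (mx <= 1) 1 else if (mx <= 255) 255 else 65535
  }
  channel_image(pmin(pmax(x / max_value, 0), 1), channel = channel,
                well_id = well_id, tile_index = tile_index)
}

#' Read a grayscale TIFF as a channel image
#'
#' @param path TIFF file path (8/16-bit grayscale or RGB).
#' @inheritParams channel_image
#' @return a [channel_image].
#' @export
read_channel_tiff <- function(path, channel = "hoechst",
                              well_id = NA_character_, tile_index = NULL) {
  if (!file.exists(path)) stop("TIFF not found: ", path, call. = FALSE)
  px <- tiff::readTIFF(path)   # already scaled to [0, 1]
  if (length(dim(px)) == 3L) {
    return(to_grayscale(px, channel = channel, well_id = well_id,
                        tile_index = tile_index, max_value = 1))
  }
  channel_image(px, channel = channel, well_id = well_id,
                tile_index = tile_index)
}

#' Write a channel image as a 16-bit grayscale TIFF
#'
#' Intensities are quantized to 16 bits (`round(v * 65535) / 65535`) before
#' writing, so a read-back reproduces the stored array to within one
#' quantization step (1/65535).
#'
#' @param image a [channel_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(image, path) {
  stopifnot(inherits(image, "channel_image"))
  q <- round(image$pixels * 65535) / 65535
  ok <- tryCatch(
    tiff::writeTIFF(q, path, bits.per.sample = 16L, compression = "none"),
    error = function(e) {
      stop(sprintf("failed to write TIFF '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  invisible(path)
}
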