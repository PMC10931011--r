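# Per-pixel distortion fields, image resampling, checkerboard differencing
# and fluoroscopy video-volume operations.

#' Map a distortion model to a per-pixel field
#'
#' Evaluates the distortion shift of the interior model at every pixel
#' centre.
#'
#' @param iop A `fluoro_iop`.
#' @param raster_size Dimensions `c(rows, cols)`.
#' @return A `distortion_field`: list with `dx`, `dy` rasters (px shift per
#'   pixel), the generating `iop` and `raster_size`.
#' @export
distortion_field <- function(iop, raster_size = c(512, 512)) {
  stopifnot(inherits(iop, "fluoro_iop"))
  nr <- raster_size[1]; nc <- raster_size[2]
  g <- expand.grid(row0 = 0:(nr - 1), col0 = 0:(nc - 1))
  cc <- raster_to_centered(g$row0, g$col0, raster_size)
  d <- distortion_shift(cc$x - iop$xP, cc$y - iop$yP, iop)
  structure(list(dx = matrix(d$dx, nr, nc), dy = matrix(d$dy, nr, nc),
                 iop = iop, raster_size = raster_size),
            class = "distortion_field")
}

#' @export
print.distortion_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf("<distortion field %dx%d: max shift %.3f px, mean %.3f px>\n",
              x$raster_size[1], x$raster_size[2], max(mag), mean(mag)))
  invisible(x)
}

# vectorized bilinear/nearest sampling of a raster at 0-based (row, col)
sample_raster <- function(raster, row0, col0,
                          interpolation = c("bilinear", "nearest"),
                          fill = 0) {
  interpolation <- match.arg(interpolation)
  nr <- nrow(raster); nc <- ncol(raster)
  out <- rep(as.numeric(fill), length(row0))
  if (interpolation == "nearest") {
    r <- round(row0); c <- round(col0)
    ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
    out[ok] <- raster[cbind(r[ok] + 1, c[ok] + 1)]
  } else {
    ok <- row0 >= 0 & row0 <= nr - 1 & col0 >= 0 & col0 <= nc - 1
    r0 <- pmin(floor(row0), nr - 2)  # clamp so the exact last edge samples
    c0 <- pmin(floor(col0), nc - 2)
    fr <- row0 - r0; fc <- col0 - c0
    ri <- r0[ok] + 1
    ci <- c0[ok] + 1
    v00 <- raster[cbind(ri, ci)]
    v01 <- raster[cbind(ri, ci + 1)]
    v10 <- raster[cbind(ri + 1, ci)]
    v11 <- raster[cbind(ri + 1, ci + 1)]
    out[ok] <- v00 * (1 - fr[ok]) * (1 - fc[ok]) + v01 * (1 - fr[ok]) * fc[ok] +
      v10 * fr[ok] * (1 - fc[ok]) + v11 * fr[ok] * fc[ok]
  }
  attr(out, "valid") <- if (exists("ok")) ok else NULL
  out
}

#' Correct a raster for lens/intensifier distortion
#'
#' Inverse-mapping resampling: the output value at each ideal pixel is
#' sampled from the input raster at its distorted position (ideal position
#' plus the field shift), bilinearly by default. Pixels mapping outside the
#' source raster take `fill` and are masked.
#'
#' @param raster Numeric matrix (rows x cols).
#' @param field A [distortion_field()] of matching size.
#' @param interpolation `"bilinear"` or `"nearest"` (for label imagery).
#' @param fill Fill value for unmapped pixels.
#' @return Corrected raster, same size and 8-bit depth as the input, with a
#'   logical `mask` attribute marking valid pixels.
#' @export
correct_image <- function(raster, field,
                          interpolation = c("bilinear", "nearest"),
                          fill = 0) {
  interpolation <- match.arg(interpolation)
  if (!all(dim(raster) == field$raster_size))
    rlang::abort("field size does not match raster",
                 class = "fluorocal_invalid_argument")
  nr <- nrow(raster); nc <- ncol(raster)
  g <- expand.grid(row0 = 0:(nr - 1), col0 = 0:(nc - 1))
  cc <- raster_to_centered(g$row0, g$col0, dim(raster))
  src <- centered_to_raster(cc$x + as.vector(field$dx),
                            cc$y + as.vector(field$dy), dim(raster))
  v <- sample_raster(raster, src$row0, src$col0, interpolation, fill)
  out <- matrix(v, nr, nc)
  mask <- matrix(attr(v, "valid") %||% TRUE, nr, nc)
  if (is.integer(raster)) {
    out <- round(out)  # round-half-even
    storage.mode(out) <- "integer"
  }
  attr(out, "mask") <- mask
  out
}

#' Checkerboard difference visualization of a distortion field
#'
#' Absolute difference between a virtual checkerboard and the same
#' checkerboard warped through the distortion field; zero everywhere for a
#' null field, radially increasing for pure radial distortion.
#'
#' @param field A [distortion_field()].
#' @param square_px Checkerboard square edge (px).
#' @return Numeric matrix of absolute differences.
#' @export
checkerboard_difference <- function(field, square_px = 32) {
  cb <- make_checkerboard(field$raster_size, square_px)
  warped <- correct_image(cb + 0, field, fill = NA)
  d <- abs(cb - warped)
  d[is.na(d)] <- 0
  d
}

# ---------------------------------------------------------------------------
# Video volumes

#' Stack video frames into a volume
#'
#' @param frames List of equally sized rasters, in temporal order.
#' @return A `fluoro_volume`: 3D array (rows x cols x frames).
#' @export
stack_volume <- function(frames) {
  if (length(frames) < 2)
    rlang::abort("a volume needs at least 2 frames",
                 class = "fluorocal_invalid_argument")
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    rlang::abort("all frames must share dimensions",
                 class = "fluorocal_invalid_argument")
  vol <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  class(vol) <- c("fluoro_volume", class(vol))
  vol
}

#' Unstack a volume into its frames
#'
#' @param vol A `fluoro_volume`.
#' @return List of rasters (bit-exact round trip with [stack_volume()]).
#' @export
unstack_volume <- function(vol) {
  lapply(seq_len(dim(vol)[3]), function(t) vol[, , t])
}

#' Temporal slice of a video volume
#'
#' Extracts the motion profile at a fixed image column: the result at
#' (row, t) is frame t sampled at that column and row, visualizing e.g. the
#' periodic peaks and troughs of diaphragm motion.
#'
#' @param vol A `fluoro_volume`.
#' @param column 1-based column index.
#' @return Raster of size rows x n_frames.
#' @export
slice_volume <- function(vol, column) {
  d <- dim(vol)
  if (column < 1 || column > d[2])
    rlang::abort("column outside volume width",
                 class = "fluorocal_invalid_argument")
  vol[, column, ]
}

#' Difference of two frames
#'
#' @param a,b Equally sized rasters.
#' @param absolute Return |a - b| (default) or the signed difference.
#' @return Raster of differences.
#' @export
frame_difference <- function(a, b, absolute = TRUE) {
  if (!all(dim(a) == dim(b)))
    rlang::abort("frames must share dimensions",
                 class = "fluorocal_invalid_argument")
  d <- a - b
  if (absolute) abs(d) else d
}

#' Correct every frame of a volume
#'
#' @param vol A `fluoro_volume`.
#' @param field A [distortion_field()].
#' @param ... Passed to [correct_image()].
#' @return A corrected `fluoro_volume`.
#' @export
correct_volume <- function(vol, field, ...) {
  stack_volume(lapply(unstack_volume(vol), correct_image, field = field, ...))
}
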