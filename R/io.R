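# Readers and writers: observation/coordinate CSV tables, PNG/TIFF rasters,
# JSON reports, YAML run configuration.

#' Write an observation table
#'
#' CSV with header `image_id,point_id,x_px,y_px,sigma_px` (coordinates in
#' the centred frame) plus a JSON sidecar recording the raster size so the
#' centre convention is unambiguous.
#'
#' @param observations Tibble with `image_id`, `point_id`, `x`, `y`,
#'   `sigma`.
#' @param path Output CSV path.
#' @param raster_size Dimensions noted in the sidecar.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path, raster_size = c(512, 512)) {
  out <- tibble::tibble(image_id = observations$image_id,
                        point_id = observations$point_id,
                        x_px = observations$x, y_px = observations$y,
                        sigma_px = observations$sigma)
  readr::write_csv(out, path)
  jsonlite::write_json(list(raster_size = raster_size, frame = "centered"),
                       paste0(path, ".sidecar.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an observation table
#'
#' @param path CSV path written by [write_observations()] (or matching its
#'   schema).
#' @param sigma0 Precision assigned when the `sigma_px` column is absent.
#' @return Tibble with `image_id`, `point_id`, `x`, `y`, `sigma`.
#' @export
read_observations <- function(path, sigma0 = 0.2) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("image_id", "point_id", "x_px", "y_px")
  if (!all(need %in% names(df)))
    rlang::abort(paste0("observation table lacks column(s): ",
                        paste(setdiff(need, names(df)), collapse = ", ")),
                 class = "fluorocal_parse_error")
  bad <- which(!is.finite(df$x_px) | !is.finite(df$y_px))
  if (length(bad) > 0)
    rlang::abort(sprintf("malformed observation row(s): %s",
                         paste(utils::head(bad + 1L, 5), collapse = ", ")),
                 class = "fluorocal_parse_error")
  tibble::tibble(image_id = df$image_id, point_id = df$point_id,
                 x = df$x_px, y = df$y_px,
                 sigma = if ("sigma_px" %in% names(df)) df$sigma_px else sigma0)
}

#' Write / read object-point coordinate tables
#'
#' CSV with header `point_id,X_mm,Y_mm,Z_mm`.
#'
#' @param points Tibble with `point_id`, `X`, `Y`, `Z`.
#' @param path CSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_points <- function(points, path) {
  readr::write_csv(tibble::tibble(point_id = points$point_id,
                                  X_mm = points$X, Y_mm = points$Y,
                                  Z_mm = points$Z), path)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("point_id", "X_mm", "Y_mm", "Z_mm")
  if (!all(need %in% names(df)))
    rlang::abort(paste0("coordinate table lacks column(s): ",
                        paste(setdiff(need, names(df)), collapse = ", ")),
                 class = "fluorocal_parse_error")
  tibble::tibble(point_id = df$point_id, X = df$X_mm, Y = df$Y_mm,
                 Z = df$Z_mm)
}

#' Read and write 8-bit rasters (PNG/TIFF)
#'
#' Grayscale matrices with values 0..255; format chosen by file extension.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param raster Matrix with values in 0..255.
#' @return The raster matrix (read) or `path` invisibly (write).
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              rlang::abort(paste0("unsupported raster format: .", ext),
                           class = "fluorocal_invalid_argument"))
  if (length(dim(a)) == 3) a <- a[, , 1]
  m <- round(a * 255)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path) {
  a <- pmin(pmax(raster / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(a, path),
         tif = ,
         tiff = tiff::writeTIFF(a, path, bits.per.sample = 8),
         rlang::abort(paste0("unsupported raster format: .", ext),
                      class = "fluorocal_invalid_argument"))
  invisible(path)
}

#' Serialize an adjustment result to JSON
#'
#' Records interior estimates with standard deviations, selected terms,
#' interior-block correlations, fit summary and per-axis residual RMS.
#'
#' @param fit A `fluoro_calib`.
#' @param path Output JSON path.
#' @param terms Optionally the selected-term identifiers (defaults to the
#'   fit's active terms).
#' @return `path`, invisibly.
#' @export
write_calib_report <- function(fit, path, terms = fit$active_terms) {
  ti <- tidy(fit)
  g <- glance(fit)
  report <- list(
    selected_terms = as.list(terms),
    interior = lapply(seq_len(nrow(ti)), function(i)
      list(parameter = ti$parameter[i], estimate = ti$estimate[i],
           std_error = ti$std.error[i], significance = ti$statistic[i])),
    correlations = if (!is.null(fit$iop_correlations))
      as.data.frame(round(fit$iop_correlations, 4)) else NULL,
    summary = as.list(g))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Recognized keys: `preset`, `seed`, `paths` (free-form), and any
#' [adjust_config()] field under `adjustment:`.
#'
#' @param path YAML file.
#' @return List with `preset`, `seed`, `paths` and `adjustment` (an
#'   `adjust_config`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  adj <- do.call(adjust_config, y$adjustment %||% list())
  list(preset = y$preset %||% "F1", seed = y$seed %||% 1L,
       paths = y$paths %||% list(), adjustment = adj)
}
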