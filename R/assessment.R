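# Quality metrics: image-residual RMS, percent improvement, held-out 3D
# reconstruction and inter-bead distance residuals.

#' Per-axis RMS of image residuals
#'
#' @param residuals Data frame with columns `vx`, `vy` (px).
#' @return Named vector `c(rms_x, rms_y)`.
#' @export
image_rms <- function(residuals) {
  stopifnot(nrow(residuals) >= 1)
  c(rms_x = sqrt(mean(residuals$vx^2)), rms_y = sqrt(mean(residuals$vy^2)))
}

#' Percent improvement between a pre- and post-correction metric
#'
#' `round(100 * (1 - post / pre))`, as printed in calibration reports.
#'
#' @param pre,post Metric before and after correction; `pre` must be
#'   positive.
#' @return Integer percent.
#' @examples
#' percent_improvement(1.27, 0.22)  # 83
#' @export
percent_improvement <- function(pre, post) {
  stopifnot(pre > 0)
  round(100 * (1 - post / pre))
}

#' Reconstruct object points from held-out test images
#'
#' Free-network adjustment over a disjoint test image set with the interior
#' model held fixed (with or without its distortion terms): only exterior
#' orientations and object coordinates are estimated, giving an assessment
#' of 3D reconstruction accuracy detached from the calibration fit.
#'
#' @param test_network A `fluoro_network` whose images are disjoint from the
#'   calibration set and whose `iop` is the fixed interior model under test.
#' @param config An [adjust_config()].
#' @return Tibble of estimated object points (`point_id`, `X`, `Y`, `Z`),
#'   with the full `fluoro_calib` attached as attribute `fit`.
#' @export
reconstruct_heldout <- function(test_network, config = adjust_config()) {
  if (nrow(test_network$images) < 2)
    rlang::abort("held-out reconstruction needs at least 2 test images",
                 class = "fluorocal_under_determined")
  fit <- estimate(test_network, config = config, fix_iop = TRUE)
  out <- fit$network$points
  attr(out, "fit") <- fit
  out
}

#' Inter-bead distance residuals against surveyed truth
#'
#' Datum-free 3D accuracy: over all unique point pairs common to both sets,
#' the residual is the estimated inter-bead distance minus the surveyed one;
#' summarized by mean, sample standard deviation and RMSE.
#'
#' @param estimated,truth Data frames with `point_id`, `X`, `Y`, `Z` (mm).
#' @return Named vector `c(mean_mm, sd_mm, rmse_mm)`.
#' @export
distance_residuals <- function(estimated, truth) {
  common <- intersect(estimated$point_id, truth$point_id)
  if (length(common) < 2)
    rlang::abort("need at least 2 common point ids",
                 class = "fluorocal_invalid_argument")
  e <- estimated[match(common, estimated$point_id), c("X", "Y", "Z")]
  t <- truth[match(common, truth$point_id), c("X", "Y", "Z")]
  de <- as.vector(stats::dist(e))
  dt <- as.vector(stats::dist(t))
  r <- de - dt
  c(mean_mm = mean(r), sd_mm = stats::sd(r), rmse_mm = sqrt(mean(r^2)))
}

#' Pre/post comparison report
#'
#' Emits the standard calibration-report table: one row per metric with its
#' pre-correction value, post-correction value, and integer percent
#' improvement.
#'
#' @param pre,post Named numeric vectors (or one-row data frames) holding the
#'   same metric set, e.g. the output of [image_rms()] plus a variance
#'   factor, or of [distance_residuals()].
#' @return Tibble with columns `metric`, `pre`, `post`,
#'   `improvement_pct`.
#' @export
build_report <- function(pre, post) {
  pre <- unlist(pre)
  post <- unlist(post)
  if (is.null(names(pre)) || !setequal(names(pre), names(post)))
    rlang::abort("pre and post must carry the same named metric set",
                 class = "fluorocal_invalid_argument")
  post <- post[names(pre)]
  tibble::tibble(
    metric = names(pre),
    pre = unname(pre),
    post = unname(post),
    improvement_pct = ifelse(abs(pre) > 0,
                             round(100 * (1 - abs(post) / abs(pre))),
                             NA_integer_))
}

#' Split a network into calibration and test image sets
#'
#' Station split (default 75/25) used for held-out accuracy assessment.
#' The test stations are taken at a regular stride through the station
#' list, with the seed rotating the starting offset: station lists group
#' parallel, tilted and back-face poses, and a stratified draw keeps the
#' small test network geometrically strong enough to reconstruct a planar
#' target (a purely random draw can land on parallel poses only, which are
#' depth-degenerate for a plane).
#'
#' @param network A `fluoro_network`.
#' @param test_fraction Fraction of images assigned to the test set.
#' @param seed Integer seed (rotates the stratified offset).
#' @return List with `train` and `test` networks.
#' @export
split_network <- function(network, test_fraction = 0.25, seed = 1) {
  ids <- network$images$image_id
  n <- length(ids)
  n_test <- max(2L, round(n * test_fraction))
  stride <- max(1L, floor(n / n_test))
  offset <- as.integer(seed) %% stride
  pos <- pmin(n, round(seq(1, n - stride + 1, length.out = n_test)) + offset)
  test_ids <- unique(ids[pos])
  list(train = subset_network(network, setdiff(ids, test_ids)),
       test = subset_network(network, test_ids))
}
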