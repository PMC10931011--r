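# Observation network container.

#' Bundle-adjustment network
#'
#' Bundles the labeled image observations with initial values for the
#' exterior orientations, object points and interior model.
#'
#' @param observations Tibble with `image_id`, `point_id`, `x`, `y` (px,
#'   centred frame) and `sigma` (px, a priori precision).
#' @param images Tibble of initial exterior orientations (`image_id`, `Xc`,
#'   `Yc`, `Zc`, `omega`, `phi`, `kappa`).
#' @param points Tibble of initial object coordinates (`point_id`, `X`, `Y`,
#'   `Z`).
#' @param iop Initial `fluoro_iop`.
#' @return A `fluoro_network`.
#' @export
fluoro_network <- function(observations, images, points, iop) {
  observations <- tibble::as_tibble(observations)
  images <- tibble::as_tibble(images)
  points <- tibble::as_tibble(points)
  need <- c("image_id", "point_id", "x", "y", "sigma")
  missing_cols <- setdiff(need, names(observations))
  if (length(missing_cols) > 0)
    rlang::abort(paste0("observations lack column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "fluorocal_invalid_argument")
  structure(list(observations = observations, images = images,
                 points = points, iop = iop),
            class = "fluoro_network")
}

#' Validate network invariants
#'
#' Checks that every observation references an existing image and point,
#' every image has at least six observations, every point is observed in at
#' least two images, observations are unique per (image, point), and sigmas
#' are positive.
#'
#' @param network A `fluoro_network`.
#' @return The network, invisibly; aborts on violation.
#' @export
validate_network <- function(network) {
  obs <- network$observations
  if (any(!is.finite(obs$x)) || any(!is.finite(obs$y)) || any(obs$sigma <= 0))
    rlang::abort("observations must be finite with sigma > 0",
                 class = "fluorocal_invariant_violation")
  if (anyDuplicated(obs[, c("image_id", "point_id")]) > 0)
    rlang::abort("duplicate (image_id, point_id) observation",
                 class = "fluorocal_invariant_violation")
  if (!all(obs$image_id %in% network$images$image_id) ||
      !all(obs$point_id %in% network$points$point_id))
    rlang::abort("observation references unknown image or point",
                 class = "fluorocal_invariant_violation")
  n_img <- table(obs$image_id)
  if (any(n_img < 6))
    rlang::abort(sprintf("image(s) with fewer than 6 observations: %s",
                         paste(names(n_img)[n_img < 6], collapse = ", ")),
                 class = "fluorocal_invariant_violation")
  n_pt <- table(obs$point_id)
  if (any(n_pt < 2))
    rlang::abort(sprintf("point(s) observed in fewer than 2 images: %s",
                         paste(utils::head(names(n_pt)[n_pt < 2], 5),
                               collapse = ", ")),
                 class = "fluorocal_invariant_violation")
  invisible(network)
}

#' @export
print.fluoro_network <- function(x, ...) {
  cat(sprintf("<fluoro network: %d observations, %d images, %d points, %d distortion terms>\n",
              nrow(x$observations), nrow(x$images), nrow(x$points),
              length(x$iop$active_terms)))
  invisible(x)
}

#' Subset a network by image
#'
#' Keeps the given images and drops points left with fewer than two
#' observations (their remaining observations are dropped too).
#'
#' @param network A `fluoro_network`.
#' @param image_ids Images to keep.
#' @return A `fluoro_network`.
#' @export
subset_network <- function(network, image_ids) {
  obs <- network$observations[network$observations$image_id %in% image_ids, ]
  n_pt <- table(obs$point_id)
  keep_pts <- as.numeric(names(n_pt)[n_pt >= 2])
  obs <- obs[obs$point_id %in% keep_pts, ]
  net <- fluoro_network(observations = obs,
                        images = network$images[
                          network$images$image_id %in% image_ids, ],
                        points = network$points[
                          network$points$point_id %in% keep_pts, ],
                        iop = network$iop)
  attr(net, "truth") <- attr(network, "truth")
  attr(net, "design") <- attr(network, "design")
  net
}
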