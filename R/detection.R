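# Sub-pixel bead centroid detection and grid labeling: morphological
# enhancement, thresholding/segmentation, shoelace polygon centroids, and
# projective assignment of grid identifiers.

to_ebimage <- function(raster) EBImage::Image(t(raster) / 255)
from_ebimage <- function(img) t(as.matrix(EBImage::imageData(img))) * 255

#' Morphological enhancement of bead targets
#'
#' Morphological differencing with a disc structuring element larger than
#' the bead diameter: for dark (radiopaque) beads on a bright field the
#' grayscale closing minus the original; for bright blobs the original minus
#' its opening. Background maps to ~0, bead responses are positive, and the
#' output is invariant to adding a constant to the input.
#'
#' The collimation surround (the dark region touching the raster border,
#' outside the circular field of view) is flattened to the field's median
#' level first, so the mask boundary leaves no morphological response that
#' could bias beads imaged near the field edge.
#'
#' @param raster 8-bit raster (matrix, rows x cols).
#' @param radius Structuring-element radius (px).
#' @param polarity `"dark"` (default, radiopaque beads absorb) or
#'   `"bright"`.
#' @return Non-negative real raster of the same size.
#' @export
enhance <- function(raster, radius = 5, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (2 * radius + 1 > min(dim(raster)))
    rlang::abort("structuring element larger than the raster",
                 class = "fluorocal_invalid_argument")
  raster <- suppress_surround(raster, polarity)
  kern <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  img <- to_ebimage(raster)
  out <- if (polarity == "dark") {
    EBImage::closing(img, kern) - img
  } else {
    img - EBImage::opening(img, kern)
  }
  pmax(from_ebimage(out), 0)
}

# flatten the border-touching collimation mask to the field level
suppress_surround <- function(raster, polarity = "dark") {
  rng <- range(raster)
  if (diff(rng) < 8) return(raster)
  thr <- mean(rng)
  outside <- if (polarity == "dark") raster < thr else raster > thr
  if (!any(outside) || all(outside)) return(raster)
  lab <- t(as.matrix(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(t(outside))))))
  border_labels <- setdiff(unique(c(lab[1, ], lab[nrow(lab), ],
                                    lab[, 1], lab[, ncol(lab)])), 0)
  if (length(border_labels) == 0) return(raster)
  mask <- matrix(lab %in% border_labels, nrow(raster))
  # grow the mask a little so partially dark boundary pixels (interpolation
  # remnants of the mask edge) are flattened too
  mask <- t(as.matrix(EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(mask)), EBImage::makeBrush(7, "disc"))))) > 0
  if (all(mask)) return(raster)
  raster[mask] <- stats::median(raster[!mask])
  raster
}

#' Segment enhanced bead responses into blob regions
#'
#' Thresholds the enhanced raster (Otsu by default), labels connected
#' components, filters them by area bounds, and attaches a sub-pixel
#' boundary polygon per region traced at the threshold level.
#'
#' @param enhanced Output of [enhance()].
#' @param threshold Fixed threshold; `NULL` for Otsu's rule on the enhanced
#'   raster.
#' @param area_bounds Acceptable component pixel-count range.
#' @return Tibble of blob regions: `label`, `area` (px^2), `polygon`
#'   (list-column of vertex matrices in centred coordinates, columns `x`,
#'   `y`). Empty tibble (zero rows) when nothing exceeds the threshold.
#' @export
segment <- function(enhanced, threshold = NULL, area_bounds = c(4, 200)) {
  empty <- tibble::tibble(label = integer(0), area = integer(0),
                          polygon = list())
  rng <- max(enhanced)
  if (rng <= 0) return(empty)
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(t(enhanced) / rng)) * rng
  binary <- enhanced > threshold
  if (!any(binary)) return(empty)
  lab <- t(as.matrix(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(t(binary))))))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= area_bounds[1] & areas <= area_bounds[2])
  if (length(keep) == 0) return(empty)
  dims <- dim(enhanced)
  # sub-pixel boundary polygons at the threshold level
  cl <- grDevices::contourLines(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                                z = enhanced, levels = threshold)
  polys <- vector("list", length(keep))
  names(polys) <- as.character(keep)
  for (ct in cl) {
    r0 <- mean(ct$x); c0 <- mean(ct$y)
    ri <- min(dims[1], max(1, round(r0) + 1))
    ci <- min(dims[2], max(1, round(c0) + 1))
    lb <- lab[ri, ci]
    if (lb == 0 || !(lb %in% keep)) next
    k <- as.character(lb)
    if (is.null(polys[[k]]) || nrow(polys[[k]]) < length(ct$x)) {
      cc <- raster_to_centered(ct$x, ct$y, dims)
      polys[[k]] <- cbind(x = cc$x, y = cc$y)
    }
  }
  got <- !vapply(polys, is.null, TRUE)
  tibble::tibble(label = keep[got],
                 area = areas[keep[got]],
                 polygon = unname(polys[got]))
}

# signed shoelace area and centroid of a closed polygon (matrix x, y)
polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps)
    return(c(x = mean(x), y = mean(y), area = 0))
  c(x = sum((x + x2) * cr) / (6 * A), y = sum((y + y2) * cr) / (6 * A),
    area = abs(A))
}

#' Sub-pixel centroids of segmented blobs
#'
#' Shoelace (area) centroid of each region's boundary polygon, in the
#' centred image frame.
#'
#' @param blobs Output of [segment()].
#' @return Tibble with `label`, `x`, `y` (px) and `polygon_area` (px^2).
#' @export
blob_centroids <- function(blobs) {
  if (nrow(blobs) == 0)
    return(tibble::tibble(label = integer(0), x = numeric(0), y = numeric(0),
                          polygon_area = numeric(0)))
  cs <- t(vapply(blobs$polygon, polygon_centroid, c(x = 0, y = 0, area = 0)))
  tibble::tibble(label = blobs$label, x = cs[, "x"], y = cs[, "y"],
                 polygon_area = cs[, "area"])
}

# --- lattice recovery -------------------------------------------------------
# The detected centroids form a (projectively deformed, FOV-clipped) square
# lattice. Integer lattice indices are grown outward from a seed point with
# locally propagated lattice vectors, which tolerates the smooth scale drift
# of tilted views far better than a global 4-corner homography.

# estimate the two dominant lattice vectors from nearest-neighbour offsets
lattice_vectors <- function(xy) {
  n <- nrow(xy)
  d2 <- outer(rowSums(xy^2), rowSums(xy^2), "+") - 2 * tcrossprod(xy)
  diag(d2) <- Inf
  nn_d <- sqrt(apply(d2, 1, min))
  spacing <- stats::median(nn_d)
  offs <- list()
  for (i in seq_len(n)) {
    close <- which(d2[i, ] < (1.4 * spacing)^2)
    for (j in close) offs[[length(offs) + 1L]] <- xy[j, ] - xy[i, ]
  }
  V <- do.call(rbind, offs)
  ang <- atan2(V[, 2], V[, 1]) %% pi  # direction mod half-turn
  # dominant lattice direction: circular mode of the neighbour-offset angles
  dens <- stats::density(c(ang, ang + pi, ang - pi), bw = 0.08,
                         from = 0, to = pi)
  a1 <- dens$x[which.max(dens$y)]
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% pi
    pmin(d, pi - d)
  }
  # median of a vector group after sign-aligning along direction `a`
  aligned_median <- function(rows, a) {
    u <- c(cos(a), sin(a))
    W <- V[rows, , drop = FALSE]
    s <- sign(W %*% u)
    s[s == 0] <- 1
    apply(W * as.vector(s), 2, stats::median)
  }
  grp1 <- circ_dist(ang, a1) < pi / 6
  v1 <- aligned_median(grp1, a1)
  a2 <- (a1 + pi / 2) %% pi
  grp2 <- circ_dist(ang, a2) < pi / 6
  if (sum(grp2) < 2) {  # fall back: rotate v1 by 90 degrees
    v2 <- c(-v1[2], v1[1])
  } else {
    v2 <- aligned_median(grp2, a2)
  }
  list(v1 = v1, v2 = v2, spacing = spacing)
}

# integer lattice indices by wavefront growth with local vector propagation
index_lattice <- function(xy, gate_fraction = 0.35) {
  n <- nrow(xy)
  lv <- lattice_vectors(xy)
  idx <- matrix(NA_integer_, n, 2)
  loc_v1 <- matrix(rep(lv$v1, each = n), n, 2)
  loc_v2 <- matrix(rep(lv$v2, each = n), n, 2)
  centre <- colMeans(xy)
  seed <- which.min(rowSums(sweep(xy, 2, centre)^2))
  idx[seed, ] <- c(0L, 0L)
  queue <- seed
  while (length(queue) > 0) {
    i <- queue[1]
    queue <- queue[-1]
    steps <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
    for (s in steps) {
      pred <- xy[i, ] + s[1] * loc_v1[i, ] + s[2] * loc_v2[i, ]
      d <- sqrt(rowSums(sweep(xy, 2, pred)^2))
      j <- which.min(d)
      if (d[j] > gate_fraction * lv$spacing) next
      tgt <- idx[i, ] + s
      if (!is.na(idx[j, 1])) next
      idx[j, ] <- tgt
      step_vec <- xy[j, ] - xy[i, ]
      if (s[1] != 0) {
        loc_v1[j, ] <- s[1] * step_vec
        loc_v2[j, ] <- loc_v2[i, ]
      } else {
        loc_v2[j, ] <- s[2] * step_vec
        loc_v1[j, ] <- loc_v1[i, ]
      }
      queue <- c(queue, j)
    }
  }
  idx
}

# the 8 square-lattice symmetries as integer maps applied to (i, j)
lattice_symmetries <- list(
  function(ij) ij,
  function(ij) cbind(-ij[, 2], ij[, 1]),
  function(ij) cbind(-ij[, 1], -ij[, 2]),
  function(ij) cbind(ij[, 2], -ij[, 1]),
  function(ij) cbind(ij[, 2], ij[, 1]),
  function(ij) cbind(-ij[, 1], ij[, 2]),
  function(ij) cbind(-ij[, 2], -ij[, 1]),
  function(ij) cbind(ij[, 1], -ij[, 2])
)

#' Assign grid identifiers to detected centroids
#'
#' Recovers the integer lattice structure of the detected centroids
#' (neighbour-offset lattice vectors, wavefront index growth), registers it
#' to the nominal grid over the eight square-lattice symmetries and feasible
#' offsets (both chiralities, so mirror-ordered back-face imagery labels
#' correctly), fits and refines a projective mapping on the matched pairs,
#' and assigns each centroid the nearest nominal identifier inside a
#' residual gate. Accepted assignments are injective. A square grid carries
#' no orientation cue, so absolute identifiers need manual seed pairs; they
#' select the lattice symmetry, while automatic mode breaks the tie
#' deterministically.
#'
#' @param centroids Tibble with `x`, `y` (at least 4 rows).
#' @param field Nominal object points (`point_id`, `X`, `Y`).
#' @param seed_pairs Optional manual tibble with `x`, `y`, `point_id` (at
#'   least 4 rows) fixing the orientation.
#' @param gate_fraction Residual gate as a fraction of the projected
#'   nearest-neighbour grid spacing; the default tolerates distortion-level
#'   departures from the projective fit while staying below the
#'   half-spacing ambiguity limit.
#' @return Tibble with `x`, `y`, `point_id`, `residual` for accepted
#'   assignments.
#' @export
label_grid <- function(centroids, field, seed_pairs = NULL,
                       gate_fraction = 0.45) {
  if (nrow(centroids) < 4)
    rlang::abort("grid labeling needs at least 4 centroids",
                 class = "fluorocal_invalid_argument")
  det_xy <- cbind(centroids$x, centroids$y)
  nom <- cbind(field$X, field$Y)
  assign_with <- function(H) {
    pr <- t(H %*% t(cbind(nom, 1)))
    pr <- pr[, 1:2] / pr[, 3]
    if (!all(is.finite(pr)))
      return(list(nearest = integer(0), resid = numeric(0),
                  ok = logical(0), score = -Inf, mean_resid = Inf))
    spacing <- stats::median(apply(pr, 1, function(p) {
      d <- sqrt(rowSums(sweep(pr, 2, p)^2))
      min(d[d > 0])
    }))
    gate <- gate_fraction * spacing
    dmat <- outer(rowSums(det_xy^2), rowSums(pr^2), "+") -
      2 * det_xy %*% t(pr)
    nearest <- max.col(-dmat)
    resid <- sqrt(pmax(0, dmat[cbind(seq_len(nrow(det_xy)), nearest)]))
    ok <- resid <= gate
    list(nearest = nearest, resid = resid, ok = ok,
         score = sum(ok), mean_resid = mean(resid[ok]))
  }
  if (!is.null(seed_pairs) && nrow(seed_pairs) < 4)
    rlang::abort("at least 4 manual seed pairs required",
                 class = "fluorocal_invalid_argument")
  # recover integer lattice indices, then resolve the square-lattice
  # symmetry and offset against the nominal grid; manual seed pairs pick
  # the symmetry, otherwise the tie is broken deterministically
  ij <- index_lattice(det_xy, gate_fraction)
  have <- which(!is.na(ij[, 1]))
  if (length(have) < 4)
    rlang::abort("grid structure not recoverable from the centroids",
                 class = "fluorocal_invalid_argument")
  seed_det <- NULL
  if (!is.null(seed_pairs)) {
    # nearest detected centroid for each operator-seeded point
    seed_det <- vapply(seq_len(nrow(seed_pairs)), function(i)
      which.min((centroids$x - seed_pairs$x[i])^2 +
                  (centroids$y - seed_pairs$y[i])^2), 1L)
  }
  ux <- sort(unique(field$X)); uy <- sort(unique(field$Y))
  nom_rc <- cbind(match(field$X, ux), match(field$Y, uy))
  best <- NULL
  best_agree <- -1
  for (sym in lattice_symmetries) {
    tij <- sym(ij[have, , drop = FALSE])
    # candidate offsets keeping the transformed indices inside the grid
    r_off <- (1 - min(tij[, 1])):(length(ux) - max(tij[, 1]))
    c_off <- (1 - min(tij[, 2])):(length(uy) - max(tij[, 2]))
    if (length(r_off) < 1 || length(c_off) < 1) next
    for (ro in r_off) for (co in c_off) {
      rc <- cbind(tij[, 1] + ro, tij[, 2] + co)
      ids <- field$point_id[match(paste(rc[, 1], rc[, 2]),
                                  paste(nom_rc[, 1], nom_rc[, 2]))]
      if (any(is.na(ids))) next
      agree <- 0L
      if (!is.null(seed_det)) {
        lat_ids <- rep(NA_integer_, nrow(det_xy))
        lat_ids[have] <- ids
        agree <- sum(lat_ids[seed_det] == seed_pairs$point_id,
                     na.rm = TRUE)
      }
      H <- tryCatch(dlt_homography(nom[ids, , drop = FALSE],
                                   det_xy[have, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(H)) next
      cand <- assign_with(H)
      better <- is.null(best) || agree > best_agree ||
        (agree == best_agree &&
           (cand$score > best$score ||
              (cand$score == best$score &&
                 isTRUE(cand$mean_resid < best$mean_resid))))
      if (better) {
        best <- cand
        best_agree <- agree
      }
    }
  }
  if (is.null(best) || best$score < 4 ||
      (!is.null(seed_det) && best_agree < 1))
    rlang::abort("grid structure not recoverable from the centroids",
                 class = "fluorocal_invalid_argument")
  # refine on all matched pairs, then reassign
  for (it in 1:2) {
    H <- dlt_homography(nom[best$nearest[best$ok], , drop = FALSE],
                        det_xy[best$ok, , drop = FALSE])
    best <- assign_with(H)
  }
  ids <- field$point_id[best$nearest]
  ids[!best$ok] <- NA
  dup <- ids[!is.na(ids)][duplicated(ids[!is.na(ids)])]
  if (length(dup) > 0)
    rlang::abort(paste0("ambiguous assignment: multiple centroids claim id(s) ",
                        paste(unique(dup), collapse = ", ")),
                 class = "fluorocal_ambiguous_assignment")
  out <- tibble::tibble(x = centroids$x, y = centroids$y,
                        point_id = ids, residual = best$resid)
  out[!is.na(out$point_id), ]
}

#' Full detection pipeline for one raster
#'
#' [enhance()] then [segment()] then [blob_centroids()] then [label_grid()],
#' returning an observation table ready for adjustment.
#'
#' @param raster 8-bit raster.
#' @param field Nominal object points.
#' @param image_id Identifier recorded in the output.
#' @param sigma A priori precision assigned to the measurements (px).
#' @param ... Passed to [enhance()] / [segment()] / [label_grid()].
#' @inheritParams enhance
#' @inheritParams segment
#' @return Tibble with `image_id`, `point_id`, `x`, `y`, `sigma`.
#' @export
detect_beads <- function(raster, field, image_id = 1L, sigma = 0.2,
                         radius = 5, polarity = "dark", threshold = NULL,
                         area_bounds = c(4, 200), ...) {
  enh <- enhance(raster, radius = radius, polarity = polarity)
  blobs <- segment(enh, threshold = threshold, area_bounds = area_bounds)
  cents <- blob_centroids(blobs)
  lab <- label_grid(cents, field, ...)
  tibble::tibble(image_id = image_id, point_id = lab$point_id,
                 x = lab$x, y = lab$y, sigma = sigma)
}
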