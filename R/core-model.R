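# Collinearity model, rotation parameterization and the additive
# distortion-correction term pool.

#' Canonical pool of distortion term identifiers
#'
#' Term families, in tie-break order: radial (`k1`, `k2`, `k3`), decentering
#' (`p1`, `p2`), affinity (`a1`, `a2`), sigmoid/spiral (`s1`) and local
#' bivariate cubic monomials (`l1`..`l4`).
#'
#' @format Character vector of the twelve term identifiers.
#' @export
term_pool <- c("k1", "k2", "k3", "p1", "p2", "a1", "a2", "s1",
               "l1", "l2", "l3", "l4")

#' Interior orientation model
#'
#' Principal point, principal distance and the active distortion coefficients
#' of one imaging system. Inactive terms contribute exactly zero shift.
#'
#' @param xP,yP Principal point offset from the raster centre (px).
#' @param c Principal distance (px), must be positive.
#' @param coefficients Named numeric vector of distortion coefficients; names
#'   must be drawn from [term_pool].
#' @param active_terms Character vector of active term identifiers. Defaults to
#'   `names(coefficients)`. Supplying a coefficient for a term not listed here
#'   is an error.
#' @return An object of class `fluoro_iop`.
#' @examples
#' iop(c = 1100, coefficients = c(k1 = 5e-8, a1 = 2e-3))
#' @export
iop <- function(xP = 0, yP = 0, c = 1000,
                coefficients = numeric(0), active_terms = names(coefficients)) {
  coefficients <- unlist(coefficients)
  if (is.null(coefficients)) coefficients <- numeric(0)
  if (is.null(active_terms)) active_terms <- character(0)
  stopifnot(is.numeric(xP), is.numeric(yP), is.numeric(c),
            length(c) == 1L, is.finite(c))
  if (c <= 0) rlang::abort("principal distance `c` must be > 0",
                           class = "fluorocal_invalid_argument")
  bad <- setdiff(active_terms, term_pool)
  if (length(bad) > 0)
    rlang::abort(paste0("unknown distortion term(s): ",
                        paste(bad, collapse = ", ")),
                 class = "fluorocal_invalid_argument")
  inactive <- setdiff(names(coefficients), active_terms)
  if (length(inactive) > 0)
    rlang::abort(paste0("coefficient given for inactive term(s): ",
                        paste(inactive, collapse = ", ")),
                 class = "fluorocal_invariant_violation")
  co <- stats::setNames(numeric(length(active_terms)), active_terms)
  co[names(coefficients)] <- coefficients
  # keep canonical pool order
  co <- co[intersect(term_pool, active_terms)]
  structure(list(xP = xP, yP = yP, c = c, coefficients = co,
                 active_terms = names(co)),
            class = "fluoro_iop")
}

#' @export
print.fluoro_iop <- function(x, ...) {
  cat("<interior orientation>\n")
  cat(sprintf("  principal point (%.4f, %.4f) px, principal distance %.4f px\n",
              x$xP, x$yP, x$c))
  if (length(x$coefficients) == 0) {
    cat("  no active distortion terms\n")
  } else {
    cat("  distortion terms:\n")
    for (nm in names(x$coefficients))
      cat(sprintf("    %-3s %+.6e\n", nm, x$coefficients[[nm]]))
  }
  invisible(x)
}

#' Set or zero distortion coefficients of an interior model
#'
#' @param x A `fluoro_iop`.
#' @param coefficients Named numeric vector replacing the coefficient set (the
#'   active terms become the names given).
#' @return A new `fluoro_iop`.
#' @export
set_coefficients <- function(x, coefficients) {
  stopifnot(inherits(x, "fluoro_iop"))
  iop(xP = x$xP, yP = x$yP, c = x$c, coefficients = coefficients)
}

#' Zero all distortion terms of an interior model
#'
#' Used for pre-correction baselines: keeps the principal point and principal
#' distance but drops every distortion term.
#'
#' @param x A `fluoro_iop`.
#' @return A `fluoro_iop` with an empty active-term set.
#' @export
zero_distortion <- function(x) {
  stopifnot(inherits(x, "fluoro_iop"))
  iop(xP = x$xP, yP = x$yP, c = x$c)
}

# ---------------------------------------------------------------------------
# Rotations

#' Rotation matrix from omega-phi-kappa angles
#'
#' Builds the 3x3 rotation `M = R3(kappa) %*% R2(phi) %*% R1(omega)` with
#' omega the primary rotation about X, phi secondary about Y and kappa
#' tertiary about Z (right-handed axes, counter-clockwise positive).
#'
#' @param omega,phi,kappa Rotation angles in radians.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @examples
#' rotation_matrix(0, 0, 0)           # identity
#' rotation_matrix(0.1, -0.2, 0.3)
#' @export
rotation_matrix <- function(omega, phi, kappa) {
  if (!all(is.finite(c(omega, phi, kappa))))
    rlang::abort("rotation angles must be finite",
                 class = "fluorocal_invalid_argument")
  rot_z(kappa) %*% rot_y(phi) %*% rot_x(omega)
}

rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a),
                              0, 1, 0,
                              sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0,
                              -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

# derivatives of the elementary rotations
drot_x <- function(a) matrix(c(0, 0, 0,
                               0, -sin(a), cos(a),
                               0, -cos(a), -sin(a)), 3, 3, byrow = TRUE)
drot_y <- function(a) matrix(c(-sin(a), 0, -cos(a),
                               0, 0, 0,
                               cos(a), 0, -sin(a)), 3, 3, byrow = TRUE)
drot_z <- function(a) matrix(c(-sin(a), cos(a), 0,
                               -cos(a), -sin(a), 0,
                               0, 0, 0), 3, 3, byrow = TRUE)

# dM/domega, dM/dphi, dM/dkappa as a list of 3x3 matrices
rotation_derivs <- function(omega, phi, kappa) {
  list(omega = rot_z(kappa) %*% rot_y(phi) %*% drot_x(omega),
       phi   = rot_z(kappa) %*% drot_y(phi) %*% rot_x(omega),
       kappa = drot_z(kappa) %*% rot_y(phi) %*% rot_x(omega))
}

#' Recover omega-phi-kappa angles from a rotation matrix
#'
#' Inverse of [rotation_matrix()] (gimbal-lock-free for |phi| < pi/2).
#'
#' @param M 3x3 rotation matrix.
#' @return Named numeric vector `c(omega, phi, kappa)` in radians.
#' @export
rotation_angles <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(3, 3)))
  phi <- asin(max(-1, min(1, M[3, 1])))
  omega <- atan2(-M[3, 2], M[3, 3])
  kappa <- atan2(-M[2, 1], M[1, 1])
  c(omega = omega, phi = phi, kappa = kappa)
}

# ---------------------------------------------------------------------------
# Reduced coordinates and distortion terms

#' Reduce image coordinates about the principal point
#'
#' @param x,y Image coordinates (px, centred frame).
#' @param iop A `fluoro_iop`.
#' @return Tibble with columns `xbar`, `ybar`, `r2`.
#' @export
reduce_coords <- function(x, y, iop) {
  xbar <- x - iop$xP
  ybar <- y - iop$yP
  tibble::tibble(xbar = xbar, ybar = ybar, r2 = xbar^2 + ybar^2)
}

# Per-term basis functions (shift per unit coefficient), vectorized over
# xbar/ybar. Returns list(bx, by) each length(xbar) for one term id.
term_basis <- function(term, xbar, ybar) {
  r2 <- xbar^2 + ybar^2
  z <- rep(0, length(xbar))
  switch(term,
    k1 = list(bx = xbar * r2, by = ybar * r2),
    k2 = list(bx = xbar * r2^2, by = ybar * r2^2),
    k3 = list(bx = xbar * r2^3, by = ybar * r2^3),
    p1 = list(bx = r2 + 2 * xbar^2, by = 2 * xbar * ybar),
    p2 = list(bx = 2 * xbar * ybar, by = r2 + 2 * ybar^2),
    a1 = list(bx = xbar, by = z),
    a2 = list(bx = ybar, by = z),
    s1 = list(bx = -ybar * r2, by = xbar * r2),
    l1 = list(bx = xbar^2 * ybar, by = z),
    l2 = list(bx = xbar * ybar^2, by = z),
    l3 = list(bx = z, by = xbar^2 * ybar),
    l4 = list(bx = z, by = xbar * ybar^2),
    rlang::abort(paste0("unknown term: ", term),
                 class = "fluorocal_invalid_argument")
  )
}

#' Distortion shift at reduced image coordinates
#'
#' Sum of the active term contributions: Brown-style radial and decentering,
#' affinity (x-equation only), sigmoid spiral, and local cubic monomials.
#' With all coefficients zero the shift is exactly (0, 0).
#'
#' @param xbar,ybar Reduced coordinates (px), vectors of equal length.
#' @param iop A `fluoro_iop`.
#' @return Tibble with columns `dx`, `dy` (px).
#' @examples
#' m <- iop(c = 1100, coefficients = c(k1 = 1e-7))
#' distortion_shift(100, 0, m)   # dx = 1e-7 * 100 * 1e4 = 0.1 px
#' @export
distortion_shift <- function(xbar, ybar, iop) {
  stopifnot(inherits(iop, "fluoro_iop"), length(xbar) == length(ybar))
  dx <- rep(0, length(xbar))
  dy <- dx
  for (nm in names(iop$coefficients)) {
    b <- term_basis(nm, xbar, ybar)
    dx <- dx + iop$coefficients[[nm]] * b$bx
    dy <- dy + iop$coefficients[[nm]] * b$by
  }
  tibble::tibble(dx = dx, dy = dy)
}

# Analytic gradient of the distortion shift wrt (xbar, ybar).
# Returns list(gxx, gxy, gyx, gyy), each vectorized.
distortion_gradient <- function(xbar, ybar, iop) {
  co <- iop$coefficients
  g <- function(nm) if (nm %in% names(co)) co[[nm]] else 0
  k1 <- g("k1"); k2 <- g("k2"); k3 <- g("k3")
  p1 <- g("p1"); p2 <- g("p2"); a1 <- g("a1"); a2 <- g("a2")
  s1 <- g("s1"); l1 <- g("l1"); l2 <- g("l2"); l3 <- g("l3"); l4 <- g("l4")
  r2 <- xbar^2 + ybar^2
  S <- k1 * r2 + k2 * r2^2 + k3 * r2^3
  Tm <- k1 + 2 * k2 * r2 + 3 * k3 * r2^2
  list(
    gxx = S + 2 * xbar^2 * Tm + 6 * p1 * xbar + 2 * p2 * ybar + a1 -
      2 * s1 * xbar * ybar + 2 * l1 * xbar * ybar + l2 * ybar^2,
    gxy = 2 * xbar * ybar * Tm + 2 * p1 * ybar + 2 * p2 * xbar + a2 -
      s1 * (r2 + 2 * ybar^2) + l1 * xbar^2 + 2 * l2 * xbar * ybar,
    gyx = 2 * xbar * ybar * Tm + 2 * p1 * ybar + 2 * p2 * xbar +
      s1 * (r2 + 2 * xbar^2) + 2 * l3 * xbar * ybar + l4 * ybar^2,
    gyy = S + 2 * ybar^2 * Tm + 2 * p1 * xbar + 6 * p2 * ybar +
      2 * s1 * xbar * ybar + l3 * xbar^2 + 2 * l4 * xbar * ybar
  )
}

# ---------------------------------------------------------------------------
# Projection

#' Project object points into an image
#'
#' Collinearity projection: object points are rotated into the camera frame,
#' scaled by the principal distance, offset by the principal point and shifted
#' by the distortion model evaluated at the distortion-free projected
#' position.
#'
#' @param points Data frame with columns `point_id`, `X`, `Y`, `Z` (mm).
#' @param eop One-row data frame (or list) with `Xc`, `Yc`, `Zc` (mm) and
#'   `omega`, `phi`, `kappa` (radians); an `image_id` column is carried over
#'   when present.
#' @param iop A `fluoro_iop`.
#' @param w_epsilon Minimum |W| denominator (mm); points with |W| below it
#'   raise a point-at-infinity condition.
#' @return Tibble with `point_id`, `x`, `y` (px, centred frame).
#' @examples
#' pts <- tibble::tibble(point_id = 1, X = 0, Y = 0, Z = 0)
#' cam <- list(Xc = 0, Yc = 0, Zc = 500, omega = pi, phi = 0, kappa = 0)
#' project_points(pts, cam, iop(c = 1100))
#' @export
project_points <- function(points, eop, iop, w_epsilon = 1e-9) {
  pr <- project_core(points, eop, iop, w_epsilon)
  out <- tibble::tibble(point_id = points$point_id, x = pr$x, y = pr$y)
  if (!is.null(eop$image_id)) out <- tibble::add_column(
    out, image_id = rep(eop$image_id[[1]], nrow(out)), .before = 1)
  out
}

# Internal projection keeping intermediates needed for linearization.
project_core <- function(points, eop, iop, w_epsilon = 1e-9) {
  M <- rotation_matrix(eop$omega[[1]], eop$phi[[1]], eop$kappa[[1]])
  D <- cbind(points$X - eop$Xc[[1]],
             points$Y - eop$Yc[[1]],
             points$Z - eop$Zc[[1]])
  UVW <- D %*% t(M)
  W <- UVW[, 3]
  if (any(abs(W) <= w_epsilon))
    rlang::abort("point at infinity: |W| below epsilon (target in the principal plane)",
                 class = "fluorocal_point_at_infinity")
  xbar <- -iop$c * UVW[, 1] / W
  ybar <- iop$c * UVW[, 2] / W
  d <- distortion_shift(xbar, ybar, iop)
  list(x = iop$xP + xbar + d$dx, y = iop$yP + ybar + d$dy,
       xbar = xbar, ybar = ybar, UVW = UVW, D = D, M = M)
}

#' Remove distortion from observed image points
#'
#' Inverts the additive distortion model by fixed-point iteration: finds the
#' ideal point whose distorted position reproduces the observation.
#'
#' @param x,y Observed image coordinates (px, centred frame).
#' @param iop A `fluoro_iop`.
#' @param tol Convergence tolerance on the round-trip error (px).
#' @param max_iter Maximum fixed-point iterations.
#' @return Tibble with columns `x`, `y` of the undistorted points.
#' @export
undistort_points <- function(x, y, iop, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(iop, "fluoro_iop"), length(x) == length(y))
  ox <- x - iop$xP
  oy <- y - iop$yP
  ux <- ox
  uy <- oy
  for (i in seq_len(max_iter)) {
    d <- distortion_shift(ux, uy, iop)
    nx <- ox - d$dx
    ny <- oy - d$dy
    err <- max(abs(nx - ux), abs(ny - uy), 0)
    ux <- nx
    uy <- ny
    if (err < tol) {
      return(tibble::tibble(x = iop$xP + ux, y = iop$yP + uy))
    }
  }
  rlang::abort("distortion field not invertible at the requested tolerance",
               class = "fluorocal_non_invertible_field")
}

# ---------------------------------------------------------------------------
# Degrees of freedom

#' Free-network redundancy
#'
#' Standard bookkeeping: two equations per observed image point, minus six
#' exterior-orientation unknowns per image, three coordinates per object
#' point and the interior-orientation unknowns, plus the seven inner
#' constraints that restore the datum rank.
#'
#' @param n_obs_points Number of observed image points (one per bead per image).
#' @param n_images Number of images.
#' @param n_object_points Number of object points.
#' @param n_iop_params Number of interior-orientation unknowns (principal
#'   point + principal distance + active distortion terms).
#' @return Integer redundancy; raises an under-determined-network condition
#'   when it is not positive.
#' @examples
#' degrees_of_freedom(1998, 22, 121, 8)
#' @export
degrees_of_freedom <- function(n_obs_points, n_images, n_object_points,
                               n_iop_params) {
  stopifnot(n_obs_points > 0, n_images > 0, n_object_points > 0,
            n_iop_params >= 0)
  dof <- as.integer(2 * n_obs_points - (6 * n_images + 3 * n_object_points +
                                          n_iop_params) + 7)
  if (dof <= 0)
    rlang::abort(sprintf("network under-determined: redundancy %d <= 0", dof),
                 class = "fluorocal_under_determined")
  dof
}

# ---------------------------------------------------------------------------
# Raster frame conversion

#' Convert between centred image coordinates and raster indices
#'
#' The photogrammetric frame has its origin at the raster centre, x to the
#' right and y upward; raster indices are 0-based (row, col) with pixel
#' centres at integer indices.
#'
#' @param x,y Centred coordinates (px).
#' @param row0,col0 0-based raster indices.
#' @param dim Raster dimensions `c(n_rows, n_cols)`.
#' @return Tibble with the converted coordinates.
#' @export
centered_to_raster <- function(x, y, dim) {
  tibble::tibble(row0 = (dim[1] - 1) / 2 - y,
                 col0 = x + (dim[2] - 1) / 2)
}

#' @rdname centered_to_raster
#' @export
raster_to_centered <- function(row0, col0, dim) {
  tibble::tibble(x = col0 - (dim[2] - 1) / 2,
                 y = (dim[1] - 1) / 2 - row0)
}
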