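# Collinearity model, rotations, distortion terms.

test_that("rotation matrix matches the elementary-rotation product and is proper", {
  # independent brute-force oracle: explicit elementary matrices
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)),
                           3, 3, byrow = TRUE)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)),
                           3, 3, byrow = TRUE)
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  expect_equal(rotation_matrix(0, 0, 0), diag(3))
  M <- rotation_matrix(0, 0, pi / 2)
  expect_equal(crossprod(M), diag(3), tolerance = 1e-12)
  expect_equal(det(M), 1, tolerance = 1e-12)
  expect_equal(M[3, 3], 1)  # pure tertiary rotation leaves Z fixed
  set.seed(42)
  for (i in 1:50) {
    a <- stats::runif(3, -pi / 2 + 0.01, pi / 2 - 0.01)
    M <- rotation_matrix(a[1], a[2], a[3])
    expect_lt(max(abs(M - Rz(a[3]) %*% Ry(a[2]) %*% Rx(a[1]))), 1e-12)
    expect_equal(unname(rotation_angles(M)), a, tolerance = 1e-10)
  }
  expect_error(rotation_matrix(NaN, 0, 0), class = "fluorocal_invalid_argument")
})

test_that("rotation matrices are orthonormal with det +1 over random angles", {
  set.seed(7)
  worst_orth <- 0
  worst_det <- 0
  for (i in 1:1000) {
    a <- stats::runif(3, -pi, pi)
    M <- rotation_matrix(a[1], a[2], a[3])
    worst_orth <- max(worst_orth, max(abs(crossprod(M) - diag(3))))
    worst_det <- max(worst_det, abs(det(M) - 1))
  }
  expect_lt(worst_orth, 1e-10)
  expect_lt(worst_det, 1e-10)
})

test_that("reduced coordinates are offsets about the principal point", {
  m <- iop(xP = 2, yP = -1, c = 1000)
  expect_equal(as.numeric(reduce_coords(2, -1, m)), c(0, 0, 0))
  expect_equal(reduce_coords(3, 4, iop(c = 1000))$r2, 25)
  set.seed(1)
  x <- stats::runif(20, -200, 200); y <- stats::runif(20, -200, 200)
  rc <- reduce_coords(x, y, m)
  expect_equal(rc$r2, (x - 2)^2 + (y + 1)^2)
})

test_that("distortion shift evaluates the active term polynomial", {
  null_model <- iop(c = 1000)
  d <- distortion_shift(c(0, 50, -120), c(0, -30, 80), null_model)
  expect_equal(d$dx, c(0, 0, 0))
  expect_equal(d$dy, c(0, 0, 0))
  # r = 0: every family except affinity vanishes by construction; affinity
  # vanishes too since xbar = ybar = 0
  full <- iop(c = 1000, coefficients = c(k1 = 1e-7, k2 = 1e-12, k3 = 1e-18,
                                         p1 = 1e-6, p2 = -2e-6, a1 = 1e-3,
                                         a2 = -5e-4, s1 = 2e-8, l1 = 1e-9,
                                         l2 = 1e-9, l3 = -1e-9, l4 = 1e-9))
  d0 <- distortion_shift(0, 0, full)
  expect_equal(c(d0$dx, d0$dy), c(0, 0))
  # hand-evaluated radial example
  d1 <- distortion_shift(100, 0, iop(c = 1000, coefficients = c(k1 = 1e-7)))
  expect_equal(d1$dx, 0.1)
  expect_equal(d1$dy, 0)
  # hand-evaluated mixed example at (50, -40), r2 = 4100
  m <- iop(c = 1000, coefficients = c(p1 = 1e-6, a2 = 2e-3, s1 = 1e-8))
  d2 <- distortion_shift(50, -40, m)
  expect_equal(d2$dx, 1e-6 * (4100 + 2 * 2500) + 2e-3 * (-40) -
                 1e-8 * (-40) * 4100)
  expect_equal(d2$dy, 2 * 1e-6 * 50 * (-40) + 1e-8 * 50 * 4100)
})

test_that("distortion shift is linear in each coefficient", {
  set.seed(3)
  xb <- stats::runif(30, -240, 240); yb <- stats::runif(30, -240, 240)
  base <- c(k1 = 1e-7, k2 = 3e-13, k3 = 1e-18, p1 = 2e-6, p2 = -1e-6,
            a1 = 1e-3, a2 = 4e-4, s1 = 3e-8, l1 = 2e-9, l2 = -1e-9,
            l3 = 1e-9, l4 = 2e-9)
  for (nm in term_pool) {
    one <- distortion_shift(xb, yb, iop(c = 1000, coefficients = base[nm]))
    alpha <- 3.7
    scaled <- distortion_shift(xb, yb,
                               iop(c = 1000, coefficients = alpha * base[nm]))
    expect_lt(max(abs(scaled$dx - alpha * one$dx)), 1e-12)
    expect_lt(max(abs(scaled$dy - alpha * one$dy)), 1e-12)
  }
})

test_that("coefficients for inactive terms are rejected", {
  expect_error(iop(c = 1000, coefficients = c(k1 = 1e-7), active_terms = "k2"),
               class = "fluorocal_invariant_violation")
  expect_error(iop(c = 1000, coefficients = c(zz = 1)),
               class = "fluorocal_invalid_argument")
  expect_error(iop(c = -5), class = "fluorocal_invalid_argument")
})

test_that("projection reproduces the step-by-step collinearity evaluation", {
  m <- iop(xP = 3, yP = -2, c = 1150,
           coefficients = c(k1 = 2e-7, a1 = 1e-3, s1 = 1e-8))
  # axial ray with no distortion maps to the principal point
  ax <- project_points(tibble::tibble(point_id = 1, X = 0, Y = 0, Z = 0),
                       list(Xc = 0, Yc = 0, Zc = 600, omega = pi, phi = 0,
                            kappa = 0), iop(xP = 3, yP = -2, c = 1150))
  expect_equal(c(ax$x, ax$y), c(3, -2), tolerance = 1e-10)
  # ray-scaling invariance (zero distortion)
  cam <- list(Xc = 40, Yc = -30, Zc = 650, omega = pi + 0.2, phi = 0.1,
              kappa = 0.4)
  m0 <- iop(xP = 3, yP = -2, c = 1150)
  p1 <- tibble::tibble(point_id = 1, X = 10, Y = 25, Z = 0)
  lam <- 2.5
  p2 <- tibble::tibble(point_id = 1,
                       X = cam$Xc + lam * (p1$X - cam$Xc),
                       Y = cam$Yc + lam * (p1$Y - cam$Yc),
                       Z = cam$Zc + lam * (p1$Z - cam$Zc))
  expect_equal(project_points(p1, cam, m0)[, c("x", "y")],
               project_points(p2, cam, m0)[, c("x", "y")], tolerance = 1e-12)
  # independent sequential-formula oracle
  set.seed(9)
  for (i in 1:20) {
    pt <- tibble::tibble(point_id = 1, X = stats::runif(1, -120, 120),
                         Y = stats::runif(1, -120, 120),
                         Z = stats::runif(1, -10, 10))
    M <- rotation_matrix(cam$omega, cam$phi, cam$kappa)
    uvw <- M %*% c(pt$X - cam$Xc, pt$Y - cam$Yc, pt$Z - cam$Zc)
    xb <- -m$c * uvw[1] / uvw[3]
    yb <- m$c * uvw[2] / uvw[3]
    r2 <- xb^2 + yb^2
    dx <- 2e-7 * xb * r2 + 1e-3 * xb - 1e-8 * yb * r2
    dy <- 2e-7 * yb * r2 + 1e-8 * xb * r2
    pr <- project_points(pt, cam, m)
    expect_equal(pr$x, m$xP + xb + dx, tolerance = 1e-12)
    expect_equal(pr$y, m$yP + yb + dy, tolerance = 1e-12)
  }
})

test_that("projection flags points in the principal plane", {
  cam <- list(Xc = 0, Yc = 0, Zc = 500, omega = pi, phi = 0, kappa = 0)
  in_plane <- tibble::tibble(point_id = 1, X = 100, Y = 0, Z = 500)
  expect_error(project_points(in_plane, cam, iop(c = 1000)),
               class = "fluorocal_point_at_infinity")
})

test_that("undistortion inverts the distortion model", {
  m0 <- iop(c = 1000)
  u <- undistort_points(c(10, -50), c(20, 110), m0)
  expect_equal(u$x, c(10, -50))
  expect_equal(u$y, c(20, 110))
  m <- iop(xP = 1, yP = -1, c = 1000,
           coefficients = c(k1 = 8e-8, p1 = 1e-6, a1 = 2e-3, s1 = 2e-8))
  set.seed(5)
  xi <- stats::runif(50, -200, 200); yi <- stats::runif(50, -200, 200)
  d <- distortion_shift(xi - m$xP, yi - m$yP, m)
  back <- undistort_points(xi + d$dx, yi + d$dy, m)
  expect_lt(max(abs(back$x - xi)), 1e-6)
  expect_lt(max(abs(back$y - yi)), 1e-6)
  # k1-only: radial root-finder oracle r_obs = r (1 + k1 r^2)
  k1 <- 1e-7
  mk <- iop(c = 1000, coefficients = c(k1 = k1))
  for (r_true in c(30, 90, 150, 220)) {
    r_obs <- r_true * (1 + k1 * r_true^2)
    got <- undistort_points(r_obs, 0, mk)
    root <- stats::uniroot(function(r) r * (1 + k1 * r^2) - r_obs,
                           c(0, 400), tol = 1e-12)$root
    expect_equal(got$x, root, tolerance = 1e-6)
    expect_equal(got$x, r_true, tolerance = 1e-6)
  }
})

test_that("round-trip undistortion holds across edge-of-field magnitudes", {
  # ~5 px shift at the field edge
  m <- iop(c = 1000, coefficients = c(k1 = 5 / 240^3))
  th <- seq(0, 2 * pi, length.out = 40)
  for (r in c(60, 140, 239)) {
    xi <- r * cos(th); yi <- r * sin(th)
    d <- distortion_shift(xi, yi, m)
    back <- undistort_points(xi + d$dx, yi + d$dy, m)
    expect_lt(max(abs(back$x - xi), abs(back$y - yi)), 1e-6)
  }
})

test_that("free-network redundancy bookkeeping", {
  expect_identical(degrees_of_freedom(1998, 22, 121, 8), 3500L)
  expect_identical(degrees_of_freedom(1505, 18, 121, 11), 2535L)
  # boundary: counts tuned to zero redundancy are flagged under-determined
  expect_error(degrees_of_freedom(7, 1, 5, 0),
               class = "fluorocal_under_determined")
})

test_that("centred frame and raster indices convert consistently", {
  dims <- c(512, 512)
  ctr <- centered_to_raster(0, 0, dims)
  expect_equal(c(ctr$row0, ctr$col0), c(255.5, 255.5))
  set.seed(11)
  x <- stats::runif(20, -255, 255); y <- stats::runif(20, -255, 255)
  rc <- centered_to_raster(x, y, dims)
  back <- raster_to_centered(rc$row0, rc$col0, dims)
  expect_equal(back$x, x)
  expect_equal(back$y, y)
  # y axis points up: larger y means smaller row index
  expect_lt(centered_to_raster(0, 10, dims)$row0,
            centered_to_raster(0, -10, dims)$row0)
})
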