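# Synthetic bead-phantom generator: target field, image-capture network,
# observations, rendered rasters. Every downstream module is testable from
# these without external data.

#' Target field specification
#'
#' A planar acrylic plate with a regular grid of radiopaque beads. The
#' default is an 11 x 11 grid of 121 beads at 25.4 mm spacing (254 mm plate);
#' `preset = "printed"` gives the 25.4 mm plate variant.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param spacing Bead spacing (mm).
#' @param plate_size Plate edge length (mm); defaults to spacing * (n + 1).
#' @param bead_radius Bead radius (mm).
#' @param preset `"default"` (254 mm plate) or `"printed"` (25.4 mm plate).
#' @return A `target_field_spec` list.
#' @export
target_field_spec <- function(n_rows = 11, n_cols = 11, spacing = 25.4,
                              plate_size = NULL, bead_radius = NULL,
                              preset = c("default", "printed")) {
  preset <- match.arg(preset)
  if (preset == "printed") spacing <- 25.4 / 10
  if (is.null(plate_size)) plate_size <- spacing * (max(n_rows, n_cols) + 1)
  if (is.null(bead_radius)) bead_radius <- spacing / 20
  stopifnot(n_rows >= 2, n_cols >= 2, spacing > 2 * bead_radius)
  if (spacing * (n_rows - 1) > plate_size || spacing * (n_cols - 1) > plate_size)
    rlang::abort("bead grid does not fit on the plate",
                 class = "fluorocal_invalid_argument")
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 plate_size = plate_size, bead_radius = bead_radius),
            class = "target_field_spec")
}

#' Generate the planar bead target field
#'
#' Beads on a regular grid centred at the origin in the plate plane (Z = 0),
#' identifiers assigned row-major.
#'
#' @param spec A [target_field_spec()].
#' @return Tibble with `point_id`, `X`, `Y`, `Z` (mm).
#' @examples
#' field <- make_target_field(target_field_spec())
#' nrow(field)  # 121
#' @export
make_target_field <- function(spec = target_field_spec()) {
  g <- expand.grid(col = seq_len(spec$n_cols), row = seq_len(spec$n_rows))
  tibble::tibble(
    point_id = seq_len(nrow(g)),
    X = (g$col - (spec$n_cols + 1) / 2) * spec$spacing,
    Y = ((spec$n_rows + 1) / 2 - g$row) * spec$spacing,
    Z = 0
  )
}

#' Image-capture network design
#'
#' Station layout emulating the calibration protocol: a set of
#' parallel-translated stations over the intensifier field of view, one
#' 30-degree tilted station per quadrant (frame rotated 90 degrees in the
#' stand between quadrants), and optionally the same quadrant sweep with the
#' plate flipped 180 degrees to its back face.
#'
#' @param preset `"F1"` (22 stations), `"C1"`/`"C2"` (18), or `"mini"`
#'   (8 stations, front face only — intended for fast tests), or `"custom"`.
#' @param n_parallel_stations,n_tilt_quadrants,tilt_angle,include_back_face
#'   Station layout; `tilt_angle` in degrees.
#' @param fov_radius Circular field-of-view radius (px).
#' @param raster_size Raster dimensions `c(rows, cols)`.
#' @param principal_distance Nominal principal distance (px).
#' @param stand_rotation_step In-stand frame rotation between quadrants (deg).
#' @param fill_fraction Fraction of the FOV radius the flat plate spans; sets
#'   the plate-to-intensifier standoff.
#' @return A `network_design` list.
#' @export
network_design <- function(preset = c("F1", "C1", "C2", "mini", "custom"),
                           n_parallel_stations = NULL,
                           n_tilt_quadrants = 4,
                           tilt_angle = 30,
                           include_back_face = NULL,
                           fov_radius = 240,
                           raster_size = c(512, 512),
                           principal_distance = 1100,
                           stand_rotation_step = 90,
                           fill_fraction = 0.8) {
  preset <- match.arg(preset)
  if (is.null(n_parallel_stations))
    n_parallel_stations <- switch(preset, F1 = 14, C1 = 10, C2 = 10,
                                  mini = 4, custom = 10)
  if (is.null(include_back_face))
    include_back_face <- switch(preset, mini = FALSE, TRUE)
  stopifnot(tilt_angle > 0, tilt_angle < 90, fov_radius > 0,
            principal_distance > 0)
  structure(list(preset = preset,
                 n_parallel_stations = n_parallel_stations,
                 n_tilt_quadrants = n_tilt_quadrants,
                 tilt_angle = tilt_angle,
                 include_back_face = include_back_face,
                 fov_radius = fov_radius,
                 raster_size = raster_size,
                 principal_distance = principal_distance,
                 stand_rotation_step = stand_rotation_step,
                 fill_fraction = fill_fraction),
            class = "network_design")
}

#' @export
print.network_design <- function(x, ...) {
  n <- x$n_parallel_stations + x$n_tilt_quadrants * (1 + x$include_back_face)
  cat(sprintf("<network design '%s': %d stations (%d parallel, %d tilted%s)>\n",
              x$preset, n, x$n_parallel_stations,
              x$n_tilt_quadrants * (1 + x$include_back_face),
              if (x$include_back_face) ", both faces" else ""))
  invisible(x)
}

# camera rotation looking from C toward `target`, W > 0 along the boresight
look_at <- function(C, target = c(0, 0, 0), up = c(0, 1, 0)) {
  r3 <- target - C
  r3 <- r3 / sqrt(sum(r3^2))
  if (abs(sum(up * r3)) > 0.99) up <- c(1, 0, 0)
  r1 <- c(up[2] * r3[3] - up[3] * r3[2],
          up[3] * r3[1] - up[1] * r3[3],
          up[1] * r3[2] - up[2] * r3[1])
  r1 <- r1 / sqrt(sum(r1^2))
  r2 <- c(r3[2] * r1[3] - r3[3] * r1[2],
          r3[3] * r1[1] - r3[1] * r1[3],
          r3[1] * r1[2] - r3[2] * r1[1])
  rbind(r1, r2, r3, deparse.level = 0)
}

# plate-to-intensifier standoff implied by the design (mm, for a given field)
design_standoff <- function(design, field) {
  half_extent <- max(abs(c(field$X, field$Y)))
  half_extent * design$principal_distance /
    (design$fill_fraction * design$fov_radius)
}

#' Generate the exterior orientations of a capture network
#'
#' @param design A [network_design()].
#' @param field Object-point tibble from [make_target_field()].
#' @return Tibble of exterior orientations: `image_id`, `Xc`, `Yc`, `Zc`
#'   (mm), `omega`, `phi`, `kappa` (radians), and a `face` column
#'   (`"front"`/`"back"`).
#' @examples
#' eops <- make_network(network_design("F1"), make_target_field())
#' nrow(eops)  # 22
#' @export
make_network <- function(design, field) {
  D <- design_standoff(design, field)
  fov_at_plate <- design$fov_radius * D / design$principal_distance
  stations <- list()
  add <- function(C, M, face) {
    a <- rotation_angles(M)
    stations[[length(stations) + 1L]] <<- tibble::tibble(
      Xc = C[1], Yc = C[2], Zc = C[3],
      omega = a[["omega"]], phi = a[["phi"]], kappa = a[["kappa"]],
      face = face)
  }
  # parallel-translated stations, alternating landscape/portrait kappa
  npar <- design$n_parallel_stations
  for (i in seq_len(npar)) {
    if (i == 1L) {
      off <- c(0, 0)
    } else {
      ang <- 2 * pi * (i - 2) / max(1, npar - 1)
      rad <- fov_at_plate * ifelse(i %% 2 == 0, 0.38, 0.25)
      off <- rad * c(cos(ang), sin(ang))
    }
    M <- look_at(c(off[1], off[2], D), target = c(off[1], off[2], 0))
    M <- rot_z(pi / 2 * ((i - 1) %% 4)) %*% M
    add(c(off[1], off[2], D), M, "front")
  }
  # tilted stations per quadrant, front face
  tilt <- design$tilt_angle * pi / 180
  step <- design$stand_rotation_step * pi / 180
  for (q in seq_len(design$n_tilt_quadrants)) {
    az <- (q - 1) * step + pi / 4
    C <- D * c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt))
    M <- rot_z((q - 1) * step) %*% look_at(C)
    add(C, M, "front")
  }
  # back-face sweep: camera on the -Z side of the plate
  if (design$include_back_face) {
    for (q in seq_len(design$n_tilt_quadrants)) {
      az <- (q - 1) * step + 3 * pi / 4
      C <- D * c(sin(tilt) * cos(az), sin(tilt) * sin(az), -cos(tilt))
      M <- rot_z((q - 1) * step) %*% look_at(C)
      add(C, M, "back")
    }
  }
  out <- dplyr::bind_rows(stations)
  tibble::add_column(out, image_id = seq_len(nrow(out)), .before = 1)
}

#' Reference distortion coefficient shape
#'
#' Relative magnitudes of the five-term reference model (radial, decentering,
#' affinity-dominant, sigmoid) used by the synthetic presets; scaled by
#' [calibrate_distortion_magnitude()].
#'
#' @return Named numeric vector of coefficients.
#' @export
reference_coefficients <- function() {
  c(k1 = 7e-8, p1 = 1.5e-6, p2 = -1.0e-6, a1 = 4e-3, s1 = 3e-8)
}

#' Simulate image observations of the bead field
#'
#' Projects every bead into every station with the truth interior model,
#' keeps points inside the circular intensifier field of view, and adds
#' seeded white observation noise. Beads are visible from both faces (X-rays
#' penetrate the plate). The returned network carries perturbed nominal
#' coordinates and closed-form exterior-orientation estimates as initial
#' values; the generating truth rides along as an attribute.
#'
#' @param scenario List with `iop_truth` (a `fluoro_iop`), `eops_truth`,
#'   `points_truth`, `noise_sigma` (px) and `seed`.
#' @param design A [network_design()].
#' @param init_eops Estimate initial exterior orientations from the simulated
#'   observations (default). Disable to keep the truth values as initials.
#' @param point_jitter Half-width of the uniform perturbation applied to the
#'   nominal object coordinates (mm), emulating machine-drilling tolerance.
#' @param fov_margin Beads closer than this to the collimation mask edge
#'   (px) are treated as unmeasurable and dropped, matching the blob extent
#'   the centroiding needs.
#' @return A `fluoro_network`.
#' @export
simulate_observations <- function(scenario, design, init_eops = TRUE,
                                  point_jitter = 0.5, fov_margin = 6) {
  stopifnot(inherits(scenario$iop_truth, "fluoro_iop"))
  pts <- scenario$points_truth
  eops <- scenario$eops_truth
  sigma <- if (scenario$noise_sigma > 0) scenario$noise_sigma else 0.2
  half <- (min(design$raster_size) - 1) / 2
  obs <- withr::with_seed(scenario$seed, {
    per_image <- lapply(seq_len(nrow(eops)), function(j) {
      pr <- project_points(pts, eops[j, ], scenario$iop_truth)
      keep <- sqrt(pr$x^2 + pr$y^2) <= design$fov_radius - fov_margin &
        abs(pr$x) <= half & abs(pr$y) <= half
      pr <- pr[keep, ]
      if (scenario$noise_sigma > 0) {
        pr$x <- pr$x + stats::rnorm(nrow(pr), 0, scenario$noise_sigma)
        pr$y <- pr$y + stats::rnorm(nrow(pr), 0, scenario$noise_sigma)
      }
      pr
    })
    dplyr::bind_rows(per_image)
  })
  obs$sigma <- sigma
  nominal <- withr::with_seed(scenario$seed + 1L, {
    p <- pts
    p$X <- p$X + stats::runif(nrow(p), -point_jitter, point_jitter)
    p$Y <- p$Y + stats::runif(nrow(p), -point_jitter, point_jitter)
    p$Z <- p$Z + stats::runif(nrow(p), -point_jitter, point_jitter)
    p
  })
  iop0 <- iop(c = design$principal_distance)
  net <- fluoro_network(observations = obs,
                        images = eops[, c("image_id", "Xc", "Yc", "Zc",
                                          "omega", "phi", "kappa")],
                        points = nominal, iop = iop0)
  attr(net, "truth") <- scenario
  attr(net, "design") <- design
  if (init_eops) net <- initialize_eops(net)
  net
}

#' Scale the reference distortion to a target pre-correction RMS
#'
#' Finds the multiple of [reference_coefficients()] for which a
#' no-distortion-term adjustment of noiseless simulated observations leaves
#' an x-axis image-residual RMS at the requested level (within 2 percent),
#' enabling experiments pinned to a stated pre-correction fit.
#'
#' @param design A [network_design()].
#' @param target_pre_rms Target pre-correction RMS (px); 0 returns a
#'   distortion-free model.
#' @param field Object points (defaults to the standard 121-bead field).
#' @param reference Coefficient shape to scale.
#' @param iop_truth_core Optional list with `xP`, `yP`, `c` truth values of
#'   the core interior parameters.
#' @param max_iter Secant iterations.
#' @return A `fluoro_iop` carrying the scaled truth coefficients.
#' @export
calibrate_distortion_magnitude <- function(design, target_pre_rms,
                                           field = make_target_field(),
                                           reference = reference_coefficients(),
                                           iop_truth_core = NULL,
                                           max_iter = 4) {
  core <- iop_truth_core %||% list(xP = 1.2, yP = -0.8,
                                   c = design$principal_distance * 1.003)
  mk <- function(s) iop(xP = core$xP, yP = core$yP, c = core$c,
                        coefficients = reference * s)
  if (target_pre_rms <= 0) return(mk(0))
  eops <- make_network(design, field)
  pre_rms_x <- function(s) {
    scen <- list(iop_truth = mk(s), eops_truth = eops, points_truth = field,
                 noise_sigma = 0, seed = 760561)
    net <- simulate_observations(scen, design)
    # only the residual RMS is needed here: stop once it stabilizes
    fit <- estimate(net, active_terms = character(0),
                    config = adjust_config(stall_tol = 1e-5))
    glance(fit)$rms_x
  }
  s <- 1
  for (i in seq_len(max_iter)) {
    r <- pre_rms_x(s)
    if (abs(r - target_pre_rms) / target_pre_rms < 0.02) break
    s <- s * target_pre_rms / r
  }
  mk(s)
}

#' Simulate a complete calibration scenario
#'
#' Convenience wrapper reproducing a full study condition: bead field,
#' station network, truth distortion scaled to a stated pre-correction RMS,
#' and noisy observations.
#'
#' @param preset Network preset name (see [network_design()]).
#' @param target_pre_rms Pre-correction x-RMS the truth distortion is scaled
#'   to (px).
#' @param noise_sigma Observation noise (px, per axis).
#' @param seed Integer seed controlling all randomness.
#' @param field_spec A [target_field_spec()].
#' @return List with `network` (a `fluoro_network`), `design`, `field`, and
#'   `truth` (the generating scenario).
#' @export
simulate_scenario <- function(preset = "F1", target_pre_rms = 1.27,
                              noise_sigma = 0.2, seed = 1,
                              field_spec = target_field_spec()) {
  design <- network_design(preset)
  field <- make_target_field(field_spec)
  iop_truth <- calibrate_distortion_magnitude(design, target_pre_rms, field)
  scen <- list(iop_truth = iop_truth,
               eops_truth = make_network(design, field),
               points_truth = field,
               noise_sigma = noise_sigma, seed = seed)
  net <- simulate_observations(scen, design)
  list(network = net, design = design, field = field, truth = scen)
}

# ---------------------------------------------------------------------------
# Raster synthesis

#' Render a synthetic fluoroscopic raster for one image
#'
#' Bright circular intensifier field of view on a dark surround, with dark
#' Gaussian-profile bead blobs centred at each observation's sub-pixel
#' position.
#'
#' @param network A `fluoro_network`.
#' @param image_id Image to render.
#' @param blob_sigma Gaussian profile sd of a bead blob (px).
#' @param bg,surround,depth Background level inside the FOV, level outside
#'   it, and peak bead absorption (8-bit counts).
#' @param noise_sd Optional seeded Gaussian pixel noise (counts).
#' @param seed Seed for the pixel noise.
#' @return Integer matrix (rows x cols) with values in 0..255; the FOV
#'   radius is attached as attribute `fov_radius`.
#' @export
render_image <- function(network, image_id, blob_sigma = 1.6,
                         bg = 210, surround = 30, depth = 170,
                         noise_sd = 0, seed = 1) {
  design <- attr(network, "design")
  dims <- if (!is.null(design)) design$raster_size else c(512, 512)
  fov <- if (!is.null(design)) design$fov_radius else (min(dims) - 1) / 2
  obs <- network$observations[network$observations$image_id == image_id, ]
  if (nrow(obs) == 0)
    rlang::abort("image has no visible observations",
                 class = "fluorocal_invalid_argument")
  nr <- dims[1]; nc <- dims[2]
  cc <- raster_to_centered(rep(0, nc), 0:(nc - 1), dims)  # per-column x
  rr <- raster_to_centered(0:(nr - 1), rep(0, nr), dims)  # per-row y
  xs <- matrix(cc$x, nr, nc, byrow = TRUE)
  ys <- matrix(rr$y, nr, nc)
  img <- matrix(surround, nr, nc)
  inside <- xs^2 + ys^2 <= fov^2
  img[inside] <- bg
  rc <- centered_to_raster(obs$x, obs$y, dims)
  w <- ceiling(5 * blob_sigma)
  for (k in seq_len(nrow(obs))) {
    if (sqrt(obs$x[k]^2 + obs$y[k]^2) > fov) next
    r0 <- round(rc$row0[k]); c0 <- round(rc$col0[k])
    ri <- max(0, r0 - w):min(nr - 1, r0 + w)
    ci <- max(0, c0 - w):min(nc - 1, c0 + w)
    dr <- outer((ri - rc$row0[k])^2, (ci - rc$col0[k])^2, "+")
    img[ri + 1, ci + 1] <- img[ri + 1, ci + 1] -
      depth * exp(-dr / (2 * blob_sigma^2))
  }
  if (noise_sd > 0)
    img <- img + withr::with_seed(seed, matrix(stats::rnorm(nr * nc, 0, noise_sd),
                                               nr, nc))
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  attr(img, "fov_radius") <- fov
  img
}

#' Virtual checkerboard raster
#'
#' @param raster_size Dimensions `c(rows, cols)`.
#' @param square_px Square edge length (px), at least 2.
#' @return Integer matrix of 0/255 values.
#' @examples
#' cb <- make_checkerboard(c(512, 512), 32)
#' mean(cb)  # 127.5
#' @export
make_checkerboard <- function(raster_size = c(512, 512), square_px = 32) {
  if (square_px < 2)
    rlang::abort("square_px must be >= 2", class = "fluorocal_invalid_argument")
  r <- floor((0:(raster_size[1] - 1)) / square_px)
  cl <- floor((0:(raster_size[2] - 1)) / square_px)
  m <- 255L * ((outer(r, cl, "+")) %% 2L)
  storage.mode(m) <- "integer"
  m
}
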