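# Free-network self-calibrating bundle adjustment: initialization,
# linearization, inner-constraint datum, Gauss-Markov iteration and
# significance-driven distortion-term selection.

#' Adjustment configuration
#'
#' @param max_iterations Iteration cap for the Gauss-Markov loop.
#' @param tol_px Convergence tolerance on principal point/principal distance
#'   updates (px), also applied to distortion-term updates through their
#'   image-space effect.
#' @param tol_mm Tolerance on coordinate updates (mm, object points and
#'   camera positions).
#' @param tol_rad Tolerance on angle updates (radians).
#' @param sigma0 Default a priori observation precision (px) when a table
#'   carries none.
#' @param significance_ratio Retention gate: |estimate| / sigma must reach
#'   this ratio (10 encodes a standard deviation an order of magnitude
#'   smaller than the parameter).
#' @param correlation_cap Retention gate: maximum absolute correlation a new
#'   term may have with the retained interior parameters.
#' @param datum `"free_inner_constraints"` (default) or `"fixed_control"`
#'   (object points held fixed at their initial values).
#' @param stall_tol Optional early stop: when positive, iteration also ends
#'   once the residual quadratic form changes by less than this relative
#'   amount over two consecutive iterations. Used for candidate screening in
#'   [select_terms()]; 0 disables it.
#' @return An `adjust_config` list.
#' @export
adjust_config <- function(max_iterations = 50,
                          tol_px = 1e-4, tol_mm = 1e-6, tol_rad = 1e-8,
                          sigma0 = 0.2,
                          significance_ratio = 10,
                          correlation_cap = 0.95,
                          datum = c("free_inner_constraints", "fixed_control"),
                          stall_tol = 0) {
  datum <- match.arg(datum)
  stopifnot(tol_px > 0, tol_mm > 0, tol_rad > 0, sigma0 > 0,
            correlation_cap > 0, correlation_cap < 1, stall_tol >= 0)
  structure(list(max_iterations = max_iterations, tol_px = tol_px,
                 tol_mm = tol_mm, tol_rad = tol_rad, sigma0 = sigma0,
                 significance_ratio = significance_ratio,
                 correlation_cap = correlation_cap, datum = datum,
                 stall_tol = stall_tol),
            class = "adjust_config")
}

# ---------------------------------------------------------------------------
# Closed-form exterior orientation initialization (plane-based resection)

#' Initialize exterior orientations from the observations
#'
#' Closed-form pose per image: the (near-planar) nominal object points are
#' expressed in their best-fit plane, a projective mapping from plane to
#' image coordinates is estimated by the normalized direct linear transform,
#' and the mapping is decomposed into a rotation and camera position using
#' the nominal principal distance.
#'
#' @param network A `fluoro_network` (initial interior model supplies the
#'   nominal principal distance).
#' @return The network with its `images` replaced by the estimated exterior
#'   orientations.
#' @export
initialize_eops <- function(network) {
  pts <- network$points
  iop0 <- network$iop
  # best-fit plane of the nominal points
  P <- as.matrix(pts[, c("X", "Y", "Z")])
  P0 <- colMeans(P)
  sv <- svd(sweep(P, 2, P0))
  B3 <- sv$v
  if (det(B3) < 0) B3[, 3] <- -B3[, 3]
  en_all <- sweep(P, 2, P0) %*% B3[, 1:2]
  rows <- lapply(seq_len(nrow(network$images)), function(j) {
    img <- network$images$image_id[j]
    obs <- network$observations[network$observations$image_id == img, ]
    if (nrow(obs) < 6)
      rlang::abort(sprintf("image %s has %d correspondences; at least 6 required",
                           img, nrow(obs)),
                   class = "fluorocal_initialization_failure")
    m <- match(obs$point_id, pts$point_id)
    en <- en_all[m, , drop = FALSE]
    H <- dlt_homography(en, cbind(obs$x - iop0$xP, obs$y - iop0$yP))
    pose <- decompose_homography(H, iop0$c)
    M_obj <- pose$M %*% t(B3)
    C_obj <- P0 + as.vector(B3 %*% pose$C)
    a <- rotation_angles(M_obj)
    tibble::tibble(image_id = img, Xc = C_obj[1], Yc = C_obj[2], Zc = C_obj[3],
                   omega = a[["omega"]], phi = a[["phi"]], kappa = a[["kappa"]])
  })
  network$images <- dplyr::bind_rows(rows)
  network
}

# normalized DLT for a plane-to-image homography; en: n x 2, xy: n x 2
dlt_homography <- function(en, xy) {
  norm_T <- function(p) {
    mu <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    rbind(c(sc, 0, -sc * mu[1]), c(0, sc, -sc * mu[2]), c(0, 0, 1))
  }
  T1 <- norm_T(en); T2 <- norm_T(xy)
  a <- t(T1 %*% t(cbind(en, 1)))
  b <- t(T2 %*% t(cbind(xy, 1)))
  n <- nrow(a)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-a, matrix(0, n, 3), b[, 1] * a)
  A[seq(2, 2 * n, 2), ] <- cbind(matrix(0, n, 3), -a, b[, 2] * a)
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  solve(T2) %*% Hn %*% T1
}

# decompose H ~ diag(-c, c, 1) [m1 m2 t] into rotation + camera position
# (plane coordinates)
decompose_homography <- function(H, c) {
  A <- diag(c(-1 / c, 1 / c, 1)) %*% H
  lam <- 2 / (sqrt(sum(A[, 1]^2)) + sqrt(sum(A[, 2]^2)))
  if (lam * A[3, 3] < 0) lam <- -lam  # boresight W > 0 at the plane origin
  R0 <- cbind(lam * A[, 1], lam * A[, 2],
              pracma_cross(lam * A[, 1], lam * A[, 2]))
  sv <- svd(R0)
  M <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  tvec <- lam * A[, 3]
  list(M = M, C = as.vector(-t(M) %*% tvec))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---------------------------------------------------------------------------
# Linearization

# parameter bookkeeping for a network + active term set
param_index <- function(network, active_terms, fix_iop = FALSE,
                        fix_points = FALSE) {
  n_img <- nrow(network$images)
  n_pts <- nrow(network$points)
  eop_names <- as.vector(t(outer(network$images$image_id,
                                 c("Xc", "Yc", "Zc", "omega", "phi", "kappa"),
                                 function(i, f) paste0(f, "[", i, "]"))))
  pt_names <- if (fix_points) character(0) else
    as.vector(t(outer(network$points$point_id, c("X", "Y", "Z"),
                      function(i, f) paste0(f, "[", i, "]"))))
  iop_names <- if (fix_iop) character(0) else c("xP", "yP", "c", active_terms)
  classes <- c(rep(c("mm", "mm", "mm", "rad", "rad", "rad"), n_img),
               rep("mm", length(pt_names)),
               if (fix_iop) character(0) else
                 c("px", "px", "px", rep("coef", length(active_terms))))
  list(n_img = n_img, n_pts = n_pts,
       n_eop = 6L * n_img,
       n_pt_par = length(pt_names),
       pt_offset = 6L * n_img,
       iop_offset = 6L * n_img + length(pt_names),
       names = c(eop_names, pt_names, iop_names),
       classes = classes,
       iop_cols = if (fix_iop) integer(0) else
         6L * n_img + length(pt_names) + seq_len(3L + length(active_terms)),
       n_par = length(eop_names) + length(pt_names) + length(iop_names),
       fix_iop = fix_iop, fix_points = fix_points,
       active_terms = active_terms)
}

#' Build the linearized observation system
#'
#' Assembles the Jacobian of the projection model with respect to the
#' exterior orientations (per-image blocks), object coordinates (per-point
#' blocks) and the interior block (principal point, principal distance,
#' active distortion terms), together with the misclosure vector and
#' observation weights. Distortion is differentiated through the full chain
#' rule at the distortion-free projected position, so the rows agree with
#' numerical differentiation of [project_points()].
#'
#' @param network A `fluoro_network` holding the current values.
#' @param active_terms Distortion terms carried in the interior block.
#' @param fix_iop,fix_points Drop the corresponding parameter blocks.
#' @param w_epsilon Projection denominator guard (mm).
#' @return List with `J` (2m x p), `l` (misclosure, observed minus computed),
#'   `w` (weights 1/sigma^2), `index` (parameter bookkeeping) and `obs`.
#' @export
build_design <- function(network, active_terms = network$iop$active_terms,
                         fix_iop = FALSE, fix_points = FALSE,
                         w_epsilon = 1e-9) {
  idx <- param_index(network, active_terms, fix_iop, fix_points)
  obs <- network$observations
  pts <- network$points
  m <- nrow(obs)
  iop_cur <- network$iop
  J <- matrix(0, 2 * m, idx$n_par)
  l <- numeric(2 * m)
  img_ids <- network$images$image_id
  obs_rows <- match(obs$image_id, img_ids)
  pt_rows <- match(obs$point_id, pts$point_id)
  for (j in seq_along(img_ids)) {
    sel <- which(obs_rows == j)
    if (length(sel) == 0) next
    eop <- network$images[j, ]
    sub_pts <- pts[pt_rows[sel], ]
    pr <- project_core(sub_pts, eop, iop_cur, w_epsilon)
    U <- pr$UVW[, 1]; V <- pr$UVW[, 2]; W <- pr$UVW[, 3]
    cc <- iop_cur$c
    g <- distortion_gradient(pr$xbar, pr$ybar, iop_cur)
    rx <- 2 * sel - 1
    ry <- 2 * sel
    l[rx] <- obs$x[sel] - pr$x
    l[ry] <- obs$y[sel] - pr$y
    M <- pr$M
    dM <- rotation_derivs(eop$omega, eop$phi, eop$kappa)
    chain_x <- function(dxb, dyb) (1 + g$gxx) * dxb + g$gxy * dyb
    chain_y <- function(dxb, dyb) g$gyx * dxb + (1 + g$gyy) * dyb
    ecol <- (j - 1) * 6
    # camera position (negative of the object-point derivatives)
    for (mcoord in 1:3) {
      dxb <- (-cc / W) * (M[1, mcoord] - (U / W) * M[3, mcoord])
      dyb <- (cc / W) * (M[2, mcoord] - (V / W) * M[3, mcoord])
      J[cbind(rx, ecol + mcoord)] <- chain_x(-dxb, -dyb)
      J[cbind(ry, ecol + mcoord)] <- chain_y(-dxb, -dyb)
      if (!fix_points) {
        pc <- idx$pt_offset + (pt_rows[sel] - 1) * 3 + mcoord
        J[cbind(rx, pc)] <- chain_x(dxb, dyb)
        J[cbind(ry, pc)] <- chain_y(dxb, dyb)
      }
    }
    # angles
    for (ai in 1:3) {
      dUVW <- pr$D %*% t(dM[[ai]])
      dxb <- (-cc / W) * (dUVW[, 1] - (U / W) * dUVW[, 3])
      dyb <- (cc / W) * (dUVW[, 2] - (V / W) * dUVW[, 3])
      J[cbind(rx, ecol + 3 + ai)] <- chain_x(dxb, dyb)
      J[cbind(ry, ecol + 3 + ai)] <- chain_y(dxb, dyb)
    }
    if (!fix_iop) {
      io <- idx$iop_offset
      J[cbind(rx, io + 1)] <- 1          # xP
      J[cbind(ry, io + 2)] <- 1          # yP
      dxb <- pr$xbar / cc
      dyb <- pr$ybar / cc
      J[cbind(rx, io + 3)] <- chain_x(dxb, dyb)
      J[cbind(ry, io + 3)] <- chain_y(dxb, dyb)
      for (t in seq_along(active_terms)) {
        b <- term_basis(active_terms[t], pr$xbar, pr$ybar)
        J[cbind(rx, io + 3 + t)] <- b$bx
        J[cbind(ry, io + 3 + t)] <- b$by
      }
    }
  }
  w <- rep(1 / obs$sigma^2, each = 2)
  list(J = J, l = l, w = w, index = idx, obs = obs)
}

# ---------------------------------------------------------------------------
# Inner constraints

#' Inner-constraint matrix over the object points
#'
#' Seven rows spanning the free-network datum null space of the point cloud:
#' three translations, three differential rotations about the centroid, and
#' one scale.
#'
#' @param points Tibble with `X`, `Y`, `Z`.
#' @return 7 x 3n matrix of rank 7.
#' @export
inner_constraints <- function(points) {
  P <- as.matrix(points[, c("X", "Y", "Z")])
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  G <- matrix(0, 7, 3 * n)
  ix <- seq(1, 3 * n, 3); iy <- ix + 1; iz <- ix + 2
  G[1, ix] <- 1
  G[2, iy] <- 1
  G[3, iz] <- 1
  G[4, iy] <- -Pc[, 3]; G[4, iz] <- Pc[, 2]   # rotation about X
  G[5, ix] <- Pc[, 3];  G[5, iz] <- -Pc[, 1]  # rotation about Y
  G[6, ix] <- -Pc[, 2]; G[6, iy] <- Pc[, 1]   # rotation about Z
  G[7, ix] <- Pc[, 1];  G[7, iy] <- Pc[, 2]; G[7, iz] <- Pc[, 3]  # scale
  if (qr(G)$rank < 7)
    rlang::abort("degenerate point set: inner constraints rank-deficient",
                 class = "fluorocal_rank_deficiency")
  G
}

# ---------------------------------------------------------------------------
# Estimation

pack_params <- function(network, idx) {
  ev <- as.vector(t(as.matrix(
    network$images[, c("Xc", "Yc", "Zc", "omega", "phi", "kappa")])))
  pv <- if (idx$fix_points) numeric(0) else
    as.vector(t(as.matrix(network$points[, c("X", "Y", "Z")])))
  iv <- if (idx$fix_iop) numeric(0) else {
    co <- stats::setNames(numeric(length(idx$active_terms)), idx$active_terms)
    have <- intersect(names(network$iop$coefficients), idx$active_terms)
    co[have] <- network$iop$coefficients[have]
    c(network$iop$xP, network$iop$yP, network$iop$c, co)
  }
  c(ev, pv, iv)
}

unpack_params <- function(p, network, idx) {
  em <- matrix(p[seq_len(idx$n_eop)], ncol = 6, byrow = TRUE)
  network$images$Xc <- em[, 1]; network$images$Yc <- em[, 2]
  network$images$Zc <- em[, 3]; network$images$omega <- em[, 4]
  network$images$phi <- em[, 5]; network$images$kappa <- em[, 6]
  if (!idx$fix_points) {
    pm <- matrix(p[idx$pt_offset + seq_len(idx$n_pt_par)], ncol = 3,
                 byrow = TRUE)
    network$points$X <- pm[, 1]; network$points$Y <- pm[, 2]
    network$points$Z <- pm[, 3]
  }
  if (!idx$fix_iop) {
    iv <- p[idx$iop_offset + seq_len(3 + length(idx$active_terms))]
    network$iop <- iop(xP = iv[1], yP = iv[2], c = iv[3],
                       coefficients = stats::setNames(
                         iv[-(1:3)], idx$active_terms))
  }
  network
}

# residual vector (observed minus computed) at the network's current values
network_residuals <- function(network) {
  obs <- network$observations
  img_ids <- network$images$image_id
  obs_rows <- match(obs$image_id, img_ids)
  pt_rows <- match(obs$point_id, network$points$point_id)
  vx <- numeric(nrow(obs))
  vy <- vx
  for (j in seq_along(img_ids)) {
    sel <- which(obs_rows == j)
    if (length(sel) == 0) next
    pr <- project_core(network$points[pt_rows[sel], ], network$images[j, ],
                       network$iop)
    vx[sel] <- obs$x[sel] - pr$x
    vy[sel] <- obs$y[sel] - pr$y
  }
  list(vx = vx, vy = vy)
}

# weighted residual quadratic form at the network's current values
network_vpv <- function(network) {
  v <- network_residuals(network)
  sum((v$vx^2 + v$vy^2) / network$observations$sigma^2)
}

#' Free-network self-calibrating bundle adjustment
#'
#' Gauss-Markov iteration on the linearized collinearity model: all exterior
#' orientations, object coordinates and the interior block (principal point,
#' principal distance, the requested distortion terms) are estimated in one
#' weighted least-squares adjustment, with the seven inner constraints
#' appended to the normal equations to define the free-network datum at the
#' initial object coordinates.
#'
#' @param network A `fluoro_network` carrying initial values.
#' @param active_terms Distortion terms to estimate (default: the terms
#'   already active in the network's interior model).
#' @param config An [adjust_config()].
#' @param fix_iop Hold the interior model fixed (used for held-out
#'   reconstruction).
#' @return A `fluoro_calib` object; see [tidy.fluoro_calib()],
#'   [glance.fluoro_calib()], [augment.fluoro_calib()].
#' @export
estimate <- function(network, active_terms = network$iop$active_terms,
                     config = adjust_config(), fix_iop = FALSE) {
  validate_network(network)
  # canonical observation order: makes the assembly (and so the estimates)
  # independent of the order the observations arrived in
  ord <- order(match(network$observations$image_id, network$images$image_id),
               network$observations$point_id)
  inv_ord <- order(ord)
  network$observations <- network$observations[ord, ]
  fix_points <- config$datum == "fixed_control"
  idx <- param_index(network, active_terms, fix_iop, fix_points)
  m <- nrow(network$observations)
  n_iop <- if (fix_iop) 0L else 3L + length(active_terms)
  n_con <- if (fix_points) 0L else 7L
  dof <- 2L * m - (6L * idx$n_img + idx$n_pt_par + n_iop) + n_con
  if (dof <= 0)
    rlang::abort(sprintf("network under-determined: redundancy %d <= 0", dof),
                 class = "fluorocal_under_determined")
  cur <- network
  if (!fix_iop) {
    co <- stats::setNames(numeric(length(active_terms)), active_terms)
    have <- intersect(names(network$iop$coefficients), active_terms)
    co[have] <- network$iop$coefficients[have]
    cur$iop <- iop(xP = network$iop$xP, yP = network$iop$yP,
                   c = network$iop$c, coefficients = co)
  }
  G0 <- if (fix_points) NULL else inner_constraints(network$points)
  p <- pack_params(cur, idx)
  vpv_hist <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  K_last <- NULL
  s_last <- NULL
  for (it in seq_len(config$max_iterations)) {
    n_iter <- it
    d <- build_design(cur, active_terms, fix_iop, fix_points)
    sw <- sqrt(d$w)
    Jw <- d$J * sw
    s <- sqrt(colSums(Jw^2))
    s[s == 0 | !is.finite(s)] <- 1
    Jw <- sweep(Jw, 2, s, "/")
    N <- crossprod(Jw)
    u <- crossprod(Jw, d$l * sw)
    if (!fix_points) {
      Gf <- matrix(0, 7, idx$n_par)
      Gf[, idx$pt_offset + seq_len(idx$n_pt_par)] <- G0
      Gf <- sweep(Gf, 2, s, "/")
      Gf <- Gf / sqrt(rowSums(Gf^2))
      K <- rbind(cbind(N, t(Gf)), cbind(Gf, matrix(0, 7, 7)))
      rhs <- c(u, numeric(7))
    } else {
      K <- N
      rhs <- u
    }
    sol <- tryCatch(solve(K, rhs), error = function(e) {
      dg <- diag(N)
      worst <- idx$names[which.min(dg)]
      rlang::abort(sprintf(
        "normal matrix singular beyond the datum defect (weakest parameter: %s)",
        worst), class = "fluorocal_configuration_deficiency", parent = e)
    })
    delta <- sol[seq_len(idx$n_par)] / s
    # Gauss-Newton step with backtracking: halve the update while it
    # increases the residual quadratic form (keeps the iteration monotone
    # from rough closed-form initial values)
    vpv_prev <- if (length(vpv_hist)) vpv_hist[length(vpv_hist)] else
      network_vpv(cur)
    step <- 1
    for (bt in 0:8) {
      cand <- unpack_params(p + step * delta, cur, idx)
      vpv <- network_vpv(cand)
      if (vpv <= vpv_prev || bt == 8) break
      step <- step / 2
    }
    delta <- step * delta
    p <- p + delta
    cur <- unpack_params(p, cur, idx)
    vpv_hist <- c(vpv_hist, vpv)
    nh <- length(vpv_hist)
    if (nh >= 4 && all(diff(vpv_hist[(nh - 3):nh]) > 0))
      rlang::abort("adjustment diverging: residual quadratic form grew in 3 consecutive iterations",
                   class = "fluorocal_divergence")
    # per-class convergence; distortion-term updates measured by their
    # rms image-space effect recovered from the column-equilibrated system
    cls <- idx$classes
    eff <- abs(delta)
    coef_cols <- which(cls == "coef")
    if (length(coef_cols) > 0)
      eff[coef_cols] <- abs(sol[coef_cols]) / sqrt(2 * m * mean(d$w))
    ok <- all(c(eff[cls == "mm"] < config$tol_mm,
                eff[cls == "rad"] < config$tol_rad,
                eff[cls == "px"] < config$tol_px,
                eff[cls == "coef"] < config$tol_px))
    K_last <- K
    s_last <- s
    if (isTRUE(ok)) {
      converged <- TRUE
      break
    }
    stall <- config$stall_tol %||% 0
    if (stall > 0 && length(vpv_hist) >= 3) {
      rel <- abs(diff(utils::tail(vpv_hist, 3))) / utils::tail(vpv_hist, 1)
      if (all(rel < stall)) break
    }
  }
  # final residuals and covariance
  vres <- network_residuals(cur)
  vpv <- sum((vres$vx^2 + vres$vy^2) / network$observations$sigma^2)
  vf <- vpv / dof
  Q <- tryCatch({
    Ki <- solve(K_last)
    Qs <- Ki[seq_len(idx$n_par), seq_len(idx$n_par), drop = FALSE]
    Qs / tcrossprod(s_last)
  }, error = function(e) matrix(NA_real_, idx$n_par, idx$n_par))
  sigmas <- sqrt(pmax(0, vf * diag(Q)))
  corr_iop <- NULL
  if (length(idx$iop_cols) > 1) {
    Qi <- Q[idx$iop_cols, idx$iop_cols, drop = FALSE]
    dn <- sqrt(diag(Qi))
    corr_iop <- Qi / tcrossprod(dn)
    nm <- c("xP", "yP", "c", active_terms)
    dimnames(corr_iop) <- list(nm, nm)
  }
  res <- tibble::tibble(image_id = network$observations$image_id,
                        point_id = network$observations$point_id,
                        vx = vres$vx, vy = vres$vy)[inv_ord, ]
  cur$observations <- cur$observations[inv_ord, ]
  structure(list(
    network = cur,
    residuals = res,
    variance_factor = vf,
    vpv = vpv,
    dof = dof,
    n_iterations = n_iter,
    converged = converged,
    param_table = tibble::tibble(parameter = idx$names,
                                 class = idx$classes,
                                 estimate = p,
                                 sigma = sigmas),
    iop_correlations = corr_iop,
    active_terms = active_terms,
    fix_iop = fix_iop,
    config = config
  ), class = "fluoro_calib")
}

#' Greedy significance-driven distortion-term selection
#'
#' Forward selection from a candidate pool: at each step every remaining
#' candidate is fitted together with the retained set (warm-started from the
#' current estimates); candidates qualify when their estimate is at least
#' `significance_ratio` times its standard deviation and their absolute
#' correlation with the retained interior parameters stays at or below
#' `correlation_cap`. The qualifying candidate with the largest
#' variance-factor reduction is retained (ties broken by family order:
#' radial, decentering, affinity, sigmoid, local). Selection stops when no
#' candidate qualifies. Deterministic given the network.
#'
#' Candidate fits are scored with relaxed convergence tolerances (the
#' significance and correlation gates involve ratios far from their bounds,
#' so micro-converged scoring fits are unnecessary); the retained set is
#' refit at the full tolerances of `config` after every retention, so the
#' returned fit is fully converged.
#'
#' @param network A `fluoro_network`.
#' @param candidate_pool Candidate term identifiers.
#' @param config An [adjust_config()].
#' @param screen_factor Relaxation factor applied to the convergence
#'   tolerances during candidate screening.
#' @return List with `terms` (retained identifiers), `fit` (final
#'   `fluoro_calib`) and `trace` (per-evaluation diagnostics).
#' @export
select_terms <- function(network, candidate_pool = term_pool,
                         config = adjust_config(), screen_factor = 100) {
  candidate_pool <- intersect(term_pool, candidate_pool)  # canonical order
  screen_cfg <- config
  screen_cfg$tol_px <- config$tol_px * screen_factor
  screen_cfg$tol_mm <- config$tol_mm * screen_factor
  screen_cfg$tol_rad <- config$tol_rad * screen_factor
  screen_cfg$stall_tol <- max(config$stall_tol %||% 0, 2e-4)
  current <- estimate(network, character(0), config)
  retained <- character(0)
  trace <- list()
  repeat {
    cands <- setdiff(candidate_pool, retained)
    if (length(cands) == 0) break
    evals <- lapply(cands, function(cand) {
      terms <- c(retained, cand)
      fit <- tryCatch(
        estimate(warm_network(current), terms, screen_cfg),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      pt <- fit$param_table
      est <- pt$estimate[pt$parameter == cand]
      sg <- pt$sigma[pt$parameter == cand]
      ratio <- if (is.finite(sg) && sg > 0) abs(est) / sg else 0
      maxcorr <- 0
      if (!is.null(fit$iop_correlations)) {
        others <- setdiff(colnames(fit$iop_correlations), cand)
        maxcorr <- max(abs(fit$iop_correlations[cand, others]))
      }
      list(term = cand, fit = fit, vf = fit$variance_factor,
           ratio = ratio, maxcorr = maxcorr)
    })
    evals <- Filter(Negate(is.null), evals)
    if (length(evals) == 0) break
    tr <- tibble::tibble(
      step = length(retained) + 1L,
      term = vapply(evals, `[[`, "", "term"),
      variance_factor = vapply(evals, `[[`, 0, "vf"),
      significance_ratio = vapply(evals, `[[`, 0, "ratio"),
      max_correlation = vapply(evals, `[[`, 0, "maxcorr"))
    trace[[length(trace) + 1L]] <- tr
    qual <- tr$significance_ratio >= config$significance_ratio &
      tr$max_correlation <= config$correlation_cap &
      tr$variance_factor < current$variance_factor
    if (!any(qual)) break
    # largest variance-factor reduction among qualifiers; candidate_pool
    # order (family order) breaks ties
    qi <- which(qual)
    best <- qi[order(tr$variance_factor[qi],
                     match(tr$term[qi], term_pool))][1]
    retained <- c(retained, tr$term[best])
    current <- estimate(warm_network(evals[[best]]$fit), retained, config)
  }
  list(terms = retained, fit = current,
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble())
}

# network carrying a fit's estimates as initial values
warm_network <- function(fit) {
  net <- fit$network
  attr(net, "truth") <- attr(fit$network, "truth")
  net
}
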