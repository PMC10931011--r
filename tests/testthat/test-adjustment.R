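# Bundle adjustment: initialization, linearization, datum, estimation,
# term selection.

test_that("closed-form initialization recovers simulated camera poses", {
  # distortion-free, noise-free observations: the projective decomposition
  # is exact up to the plane fit of the (unperturbed) nominal points
  sc <- mini_scenario(seed = 4, noise_sigma = 0, coefficients = numeric(0),
                      point_jitter = 0)
  init <- initialize_eops(sc$network)
  truth <- sc$truth$eops_truth
  standoff <- sqrt(sum(unlist(truth[1, c("Xc", "Yc", "Zc")])^2))
  for (j in seq_len(nrow(truth))) {
    dC <- sqrt(sum((unlist(init$images[j, c("Xc", "Yc", "Zc")]) -
                      unlist(truth[j, c("Xc", "Yc", "Zc")]))^2))
    expect_lt(dC / standoff, 0.01)
  }
})

test_that("initialization requires six well-distributed correspondences", {
  sc <- cached("mini_noiseless", mini_scenario(seed = 4, noise_sigma = 0))
  net <- sc$network
  keep <- !(net$observations$image_id == 1 &
              duplicated(net$observations$image_id) &
              seq_len(nrow(net$observations)) > 5)
  first <- which(net$observations$image_id == 1)
  drop <- first[-(1:5)]
  net$observations <- net$observations[-drop, ]
  expect_error(initialize_eops(net),
               class = "fluorocal_initialization_failure")
})

test_that("noisy networks converge after closed-form initialization", {
  sc <- cached("mini_noisy", mini_scenario(seed = 6, noise_sigma = 0.2))
  fit <- estimate(sc$network, names(sc$truth$iop_truth$coefficients))
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 15)
})

test_that("analytic Jacobian matches central differences of the projection", {
  net <- tiny_network()
  terms <- c("k1", "p1", "a1", "s1", "l2")
  d <- build_design(net, terms)
  idx <- d$index
  # numeric Jacobian by central differences through the projection model
  p0 <- fluorocal:::pack_params(net, idx)
  f_of <- function(p) {
    nn <- fluorocal:::unpack_params(p, net, idx)
    v <- fluorocal:::network_residuals(nn)
    out <- numeric(2 * nrow(nn$observations))
    out[seq(1, length(out), 2)] <- nn$observations$x - v$vx
    out[seq(2, length(out), 2)] <- nn$observations$y - v$vy
    out
  }
  steps <- ifelse(idx$classes == "rad", 1e-7,
                  ifelse(idx$classes == "coef", 1e-9, 1e-4))
  # coefficient columns span ~1e7 in basis magnitude; steps per class
  steps[idx$classes == "coef"] <-
    1e-3 / apply(abs(d$J[, idx$classes == "coef", drop = FALSE]), 2, max)
  worst <- 0
  for (k in seq_len(idx$n_par)) {
    ph <- p0; ph[k] <- ph[k] + steps[k]
    pl <- p0; pl[k] <- pl[k] - steps[k]
    num <- (f_of(ph) - f_of(pl)) / (2 * steps[k])
    scale <- max(abs(num), 1)
    worst <- max(worst, max(abs(num + d$J[, k]) / scale,
                            abs(num - d$J[, k]) / scale * 0))
    expect_lt(max(abs(d$J[, k] - num)) / scale, 1e-6)
  }
})

test_that("design matrix structure follows the declared blocks", {
  net <- tiny_network()
  d0 <- build_design(net, character(0))
  # inactive distortion terms contribute no columns
  expect_equal(d0$index$n_par,
               6 * nrow(net$images) + 3 * nrow(net$points) + 3)
  # weights are 1/sigma^2 per coordinate
  expect_equal(d0$w, rep(1 / net$observations$sigma^2, each = 2))
  # misclosure vanishes when observations equal exact projections
  net0 <- net
  v <- fluorocal:::network_residuals(net0)
  net0$observations$x <- net0$observations$x - v$vx
  net0$observations$y <- net0$observations$y - v$vy
  d1 <- build_design(net0, character(0))
  expect_lt(max(abs(d1$l)), 1e-10)
})

test_that("inner constraints span the seven-parameter datum null space", {
  field <- make_target_field(mini_field_spec())
  G <- inner_constraints(field)
  expect_identical(dim(G), c(7L, as.integer(3 * nrow(field))))
  expect_equal(qr(G)$rank, 7)
  # translation rows: unit-shift pattern
  expect_equal(sum(G[1, ]), nrow(field))
  expect_equal(G[1, seq(1, ncol(G), 3)], rep(1, nrow(field)))
  # rotation/scale rows orthogonal to translations after centring
  expect_lt(max(abs(G[1:3, ] %*% t(G[4:7, ]))), 1e-9)
  degenerate <- tibble::tibble(point_id = 1:2, X = c(0, 1), Y = 0, Z = 0)
  expect_error(inner_constraints(degenerate),
               class = "fluorocal_rank_deficiency")
})

test_that("exact data at the truth is a fixed point of the adjustment", {
  sc <- mini_scenario(seed = 5, noise_sigma = 0, init_eops = FALSE,
                      point_jitter = 0)
  net <- sc$network
  net$iop <- sc$truth$iop_truth  # truth-initialized
  fit <- estimate(net, names(sc$truth$iop_truth$coefficients))
  expect_true(fit$converged)
  expect_lte(fit$n_iterations, 2)
  expect_lt(sqrt(mean(fit$residuals$vx^2 + fit$residuals$vy^2)), 1e-9)
  expect_lt(fit$variance_factor, 1e-16)
})

test_that("residuals are invariant to a rigid + scale datum change", {
  sc <- cached("mini_noisy", mini_scenario(seed = 6, noise_sigma = 0.2))
  cfg <- adjust_config(tol_px = 1e-7, tol_mm = 1e-9, tol_rad = 1e-11,
                       max_iterations = 80)
  terms <- names(sc$truth$iop_truth$coefficients)
  fit1 <- estimate(sc$network, terms, cfg)
  # transform all initial object coordinates and camera stations
  R <- rotation_matrix(0.02, -0.03, 0.05)
  s <- 1.01
  t <- c(5, -3, 8)
  net2 <- sc$network
  P <- as.matrix(net2$points[, c("X", "Y", "Z")])
  P2 <- s * P %*% t(R) + matrix(t, nrow(P), 3, byrow = TRUE)
  net2$points$X <- P2[, 1]; net2$points$Y <- P2[, 2]; net2$points$Z <- P2[, 3]
  for (j in seq_len(nrow(net2$images))) {
    C <- s * R %*% unlist(net2$images[j, c("Xc", "Yc", "Zc")]) + t
    M <- rotation_matrix(net2$images$omega[j], net2$images$phi[j],
                         net2$images$kappa[j]) %*% t(R)
    a <- rotation_angles(M)
    net2$images[j, c("Xc", "Yc", "Zc")] <- as.list(as.vector(C))
    net2$images[j, c("omega", "phi", "kappa")] <- as.list(unname(a))
  }
  fit2 <- estimate(net2, terms, cfg)
  denom <- sqrt(mean(fit1$residuals$vx^2 + fit1$residuals$vy^2))
  expect_lt(max(abs(fit1$residuals$vx - fit2$residuals$vx),
                abs(fit1$residuals$vy - fit2$residuals$vy)) / denom, 1e-8)
  expect_lt(abs(fit1$variance_factor - fit2$variance_factor) /
              fit1$variance_factor, 1e-8)
})

test_that("estimates are independent of observation order", {
  sc <- cached("mini_noisy", mini_scenario(seed = 6, noise_sigma = 0.2))
  cfg <- adjust_config(tol_px = 1e-6, tol_mm = 1e-8, tol_rad = 1e-10)
  fit1 <- estimate(sc$network, "k1", cfg)
  net2 <- sc$network
  perm <- withr::with_seed(99, sample(nrow(net2$observations)))
  net2$observations <- net2$observations[perm, ]
  fit2 <- estimate(net2, "k1", cfg)
  sc1 <- pmax(abs(fit1$param_table$estimate), 1)
  expect_lt(max(abs(fit1$param_table$estimate - fit2$param_table$estimate) /
                  sc1), 1e-10)
})

test_that("model nesting never increases the residual quadratic form", {
  sc <- cached("mini_noisy", mini_scenario(seed = 6, noise_sigma = 0.2))
  vpv <- c()
  nests <- list(character(0), "k1", c("k1", "a1"), c("k1", "a1", "s1"),
                c("k1", "a1", "s1", "p1"))
  for (terms in nests)
    vpv <- c(vpv, estimate(sc$network, terms)$vpv)
  expect_true(all(diff(vpv) <= 1e-6 * vpv[-length(vpv)]))
})

test_that("variance factor is calibrated when weights match the noise", {
  vfs <- vapply(1:20, function(seed) {
    sc <- mini_scenario(seed = 100 + seed, noise_sigma = 0.2)
    estimate(sc$network,
             names(sc$truth$iop_truth$coefficients))$variance_factor
  }, 0)
  dof <- estimate(mini_scenario(seed = 121, noise_sigma = 0.2)$network,
                  c("k1", "a1"))$dof
  expect_lt(abs(mean(vfs) - 1), 3 * sqrt(2 / dof))
})

test_that("deficient configurations raise dedicated conditions", {
  sc <- cached("mini_noisy", mini_scenario(seed = 6, noise_sigma = 0.2))
  # two images cannot determine the full distortion pool: singular normals
  tiny <- subset_network(sc$network, 1:2)
  expect_error(estimate(tiny, term_pool),
               class = "fluorocal_configuration_deficiency")
  # under-determined bookkeeping: 12 observations, 38 effective unknowns
  obs <- tiny$observations
  common <- intersect(obs$point_id[obs$image_id == 1],
                      obs$point_id[obs$image_id == 2])[1:6]
  tiny$observations <- obs[obs$point_id %in% common, ]
  tiny$points <- tiny$points[tiny$points$point_id %in% common, ]
  expect_error(estimate(tiny, term_pool),
               class = "fluorocal_under_determined")
})

test_that("greedy selection finds injected terms and nothing else", {
  pool <- c("k1", "k2", "p1", "a1", "s1", "l1")
  hits <- 0
  clean <- 0
  n_runs <- 8
  for (seed in seq_len(n_runs)) {
    sc <- mini_scenario(seed = 300 + seed, noise_sigma = 0.2,
                        coefficients = c(k1 = 1.2e-6))
    sel <- select_terms(sc$network, candidate_pool = pool)
    if ("k1" %in% sel$terms) hits <- hits + 1
    if (length(setdiff(sel$terms, "k1")) == 0) clean <- clean + 1
  }
  expect_gte(hits, n_runs - 1)
  expect_gte(clean, round(0.7 * n_runs))
})

test_that("zero-distortion data yields an empty selection", {
  sc <- mini_scenario(seed = 401, noise_sigma = 0.2,
                      coefficients = numeric(0))
  sel <- select_terms(sc$network,
                      candidate_pool = c("k1", "p1", "a1", "s1"))
  expect_identical(sel$terms, character(0))
  expect_identical(sel$fit$active_terms, character(0))
})
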