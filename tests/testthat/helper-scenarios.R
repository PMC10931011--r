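# Shared fixtures: small synthetic networks built in code. Expensive
# scenarios are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 7x7 grid, 8-station front-face network: fast enough for per-operation tests
mini_field_spec <- function() target_field_spec(n_rows = 7, n_cols = 7)

mini_scenario <- function(seed = 1, noise_sigma = 0.2,
                          coefficients = c(k1 = 5e-7, a1 = 2e-2),
                          init_eops = TRUE, point_jitter = 0.5) {
  design <- network_design("mini")
  field <- make_target_field(mini_field_spec())
  scen <- list(
    iop_truth = iop(xP = 1.0, yP = -0.5, c = design$principal_distance * 1.002,
                    coefficients = coefficients),
    eops_truth = make_network(design, field),
    points_truth = field,
    noise_sigma = noise_sigma, seed = seed)
  net <- simulate_observations(scen, design, init_eops = init_eops,
                               point_jitter = point_jitter)
  list(network = net, design = design, field = field, truth = scen)
}

# tiny 3-image network for Jacobian-level checks
tiny_network <- function(seed = 2, noise_sigma = 0.1) {
  design <- network_design("custom", n_parallel_stations = 1,
                           n_tilt_quadrants = 2, include_back_face = FALSE)
  field <- make_target_field(target_field_spec(n_rows = 4, n_cols = 4))
  scen <- list(
    iop_truth = iop(xP = 0.5, yP = 0.3, c = design$principal_distance,
                    coefficients = c(k1 = 3e-7)),
    eops_truth = make_network(design, field),
    points_truth = field,
    noise_sigma = noise_sigma, seed = seed)
  simulate_observations(scen, design)
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
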