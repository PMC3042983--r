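# quadrature oracle for log s differences: integrate the raw
# 2*drift/diffusion^2 integrand (no algebraic simplification)
log_s_diff_quadrature <- function(params, p1, p2) {
  integrand <- function(xi) {
    2 * (params$E * params$I * xi -
           params$E * xi * (xi - params$p_b) / params$R) /
      (params$sigma^2 * params$E^2 * xi^2)
  }
  -stats::integrate(integrand, p1, p2, rel.tol = 1e-12)$value
}

test_that("closed-form log scale density agrees with quadrature of the raw integrand", {
  params <- csf_params(sigma = 0.8)
  expect_equal(
    scale_log_density(params, 35) - scale_log_density(params, 30),
    log_s_diff_quadrature(params, 30, 35), tolerance = 1e-9)
  set.seed(31)
  for (i in 1:5) {
    pp <- random_valid_params(frac_of_bound = runif(1, 0.2, 0.9))
    p1 <- runif(1, 5, 20)
    p2 <- p1 + runif(1, 1, 20)
    expect_equal(scale_log_density(pp, p2) - scale_log_density(pp, p1),
                 log_s_diff_quadrature(pp, p1, p2), tolerance = 1e-9)
  }
})

test_that("scale density is minimized exactly at the deterministic equilibrium", {
  set.seed(32)
  for (i in 1:10) {
    pp <- random_valid_params(frac_of_bound = runif(1, 0.1, 0.9))
    eq <- equilibrium_icp(pp)
    h <- 1e-5
    d_at_eq <- (scale_log_density(pp, eq + h) -
                  scale_log_density(pp, eq - h)) / (2 * h)
    expect_lt(abs(d_at_eq), 1e-6)
    expect_gt(scale_log_density(pp, eq * 0.8), scale_log_density(pp, eq))
    expect_gt(scale_log_density(pp, eq * 1.2), scale_log_density(pp, eq))
  }
})

test_that("scale-function increments are additive and converge under node doubling", {
  params <- default_params()
  iac <- log_scale_increment(params, 20, 40)
  iab <- log_scale_increment(params, 20, 30)
  ibc <- log_scale_increment(params, 30, 40)
  # logaddexp additivity
  m <- max(iab, ibc)
  expect_equal(iac, m + log1p(exp(-abs(iab - ibc))), tolerance = 1e-8)
  expect_equal(log_scale_increment(params, 30, 40, n_nodes = 16),
               log_scale_increment(params, 30, 40, n_nodes = 32),
               tolerance = 1e-8)
  expect_error(log_scale_increment(params, -1, 10), "p_lo")
})

test_that("scale computations stay finite although the integrand spans hundreds of orders", {
  params <- default_params()  # sigma = 0.5: exponent range > 500
  rng <- scale_log_density(params, 0.1) - scale_log_density(params, 18.5)
  expect_gt(rng, 500)
  v <- log_scale_increment(params, 0.1, 40)
  expect_true(is.finite(v))
})

test_that("hitting probability honors boundary conditions and monotonicity in x", {
  params <- csf_params(sigma = 1.2)
  expect_identical(hitting_probability(params, x = 30, a = 30, b = 40), 0)
  expect_identical(hitting_probability(params, x = 40, a = 30, b = 40), 1)
  xs <- seq(30, 40, by = 0.5)
  us <- sapply(xs, function(x) hitting_probability(params, x))
  expect_true(all(diff(us) >= 0))
  expect_true(all(us >= 0 & us <= 1))
  expect_error(hitting_probability(params, x = 20, a = 30, b = 40), "a <= x")
  expect_error(hitting_probability(csf_params(sigma = 0), 35),
               "deterministic limit")
})

test_that("hitting probability is invariant to the arbitrary scale-density constant", {
  # shifting log s by a constant (equivalently multiplying s by a positive
  # constant, or moving the inner-integral anchor) must not change u;
  # reconstruct u from increments computed against two different anchors
  params <- csf_params(sigma = 1.1)
  u <- hitting_probability(params, 35, a = 30, b = 40)
  for (anchor in c(10, 25)) {
    shift <- scale_log_density(params, anchor)
    lo <- log_scale_increment(params, 30, 35) - shift
    hi <- log_scale_increment(params, 35, 40) - shift
    expect_equal(stats::plogis(lo - hi), u, tolerance = 1e-10)
  }
})

test_that("the boundary-value route matches the scale-function route", {
  params <- csf_params(sigma = 1.2)
  u_scale <- hitting_probability(params, 35, a = 30, b = 40)
  u_bvp <- bvp_hitting_probability(params, x = 35, b = 40, epsilon = 30,
                                   n_grid = 1e4)
  expect_equal(u_bvp, u_scale, tolerance = 1e-6)
  # second configuration: lower epsilon, moderate noise
  params2 <- csf_params(sigma = 1.0)
  u_scale2 <- hitting_probability(params2, 30, a = 15, b = 40)
  u_bvp2 <- bvp_hitting_probability(params2, x = 30, b = 40, epsilon = 15,
                                    n_grid = 2e4)
  expect_equal(u_bvp2, u_scale2, tolerance = 1e-6)
  # monotone along the solution grid
  xs <- seq(31, 39, by = 1)
  us <- sapply(xs, function(x) {
    bvp_hitting_probability(params, x = x, b = 40, epsilon = 30, n_grid = 5e3)
  })
  expect_true(all(diff(us) >= 0))
  expect_error(bvp_hitting_probability(params, x = 35, b = 40, epsilon = 0),
               "epsilon")
})

test_that("the scale integral diverges at the origin, making the a -> 0 probability degenerate", {
  # with a stationary distribution, 0 is an entrance boundary: S(eps) -> -inf
  # so u -> 1 at fixed x as eps -> 0
  params <- default_params()
  incs <- sapply(c(1, 0.1, 0.01), function(eps) {
    log_scale_increment(params, eps, 35)
  })
  expect_true(all(diff(incs) > 0))   # integral grows without bound
  # at these eps the probability has already saturated at 1 to double
  # precision, so require nondecreasing-within-roundoff plus the limit
  us <- sapply(c(1, 0.1, 0.01), function(eps) {
    bvp_hitting_probability(csf_params(sigma = 1.2), x = 35, b = 40,
                            epsilon = eps, n_grid = 2e4)
  })
  expect_true(all(diff(us) >= -1e-9))
  expect_gt(us[3], 0.999)
})

test_that("Monte-Carlo estimates are sane at the barriers and reproducible", {
  params <- csf_params(sigma = 0.8)
  # adjacent to the upper barrier the probability approaches 1 (the strongly
  # negative drift at 40 mmHg keeps it below 1 at finite distance)
  mc <- mc_hitting_probability(params, x = 39.99, a = 30, b = 40,
                               n_paths = 1000, dt = 1e-4, seed = 12)
  expect_gte(mc$estimate, 0.9)
  expect_gt(hitting_probability(params, 39.99),
            hitting_probability(params, 39.9))
  expect_equal(mc$censored_frac, 0)
  mc2 <- mc_hitting_probability(params, x = 39.99, a = 30, b = 40,
                                n_paths = 1000, dt = 1e-4, seed = 12)
  expect_identical(mc$estimate, mc2$estimate)
  # a censoring-dominated configuration is refused: starting at the
  # stationary mean between distant barriers, almost no path exits quickly
  expect_error(
    mc_hitting_probability(csf_params(sigma = 0.3), x = 18.5, a = 1, b = 60,
                           n_paths = 200, dt = 1e-3, t_max = 1, seed = 1),
    "censored")
})

test_that("analytic and Monte-Carlo hitting probabilities agree across random configurations", {
  set.seed(33)
  for (i in 1:5) {
    pp <- csf_params(E = runif(1, 0.1, 0.2), R = runif(1, 5, 10),
                     p_b = runif(1, 6, 10), I = runif(1, 1, 2),
                     sigma = runif(1, 0.9, 1.3))
    a <- runif(1, 26, 30)
    b <- runif(1, 38, 42)
    x <- runif(1, a + 2, b - 2)
    u <- hitting_probability(pp, x, a = a, b = b)
    mc <- mc_hitting_probability(pp, x, a = a, b = b, n_paths = 4000,
                                 dt = 5e-4, seed = 100 + i)
    expect_lt(abs(u - mc$estimate), 3 * mc$se + 0.005)
  }
})

test_that("risk curves have the plateau-then-steep-rise convex shape", {
  params <- default_params()
  rc <- risk_curve(params, axis = "sigma")
  expect_equal(nrow(rc), 19)
  expect_true(all(rc$probability >= 0 & rc$probability <= 1))
  expect_true(all(diff(rc$probability) >= 0))
  expect_true(all(diff(diff(rc$probability)) >= -1e-6))
  expect_lt(rc$probability[1], 1e-6)                       # plateau
  # steep threshold behavior: an order of magnitude over sigma 0.8 -> 1.2
  u12 <- hitting_probability(csf_params(sigma = 1.2), 35)
  u08 <- hitting_probability(csf_params(sigma = 0.8), 35)
  expect_gt(u12 / u08, 10)

  rcR <- risk_curve(csf_params(sigma = 0.8), axis = "R")
  expect_true(all(diff(rcR$probability) >= 0))
  expect_true(all(diff(diff(rcR$probability)) >= -1e-6))
  expect_lt(rcR$probability[1], 1e-6)
})

test_that("risk surface rows and columns are consistent with the curves", {
  params <- default_params()
  R_grid <- seq(6, 12, by = 2)
  s_grid <- seq(0.6, 1.2, by = 0.2)
  surf <- risk_surface(params, R_grid = R_grid, sigma_grid = s_grid)
  expect_true(all(surf$probability >= 0 & surf$probability <= 1))
  # slice at sigma = 0.8 equals the R-curve exactly
  slice <- surf$probability[surf$sigma == 0.8]
  rcR <- risk_curve(csf_params(sigma = 0.8), axis = "R", grid = R_grid)
  expect_identical(slice, rcR$probability)
  # monotone nondecreasing along sigma at each fixed R
  m <- as.matrix(surf)
  expect_true(all(apply(m, 1, function(row) all(diff(row) >= 0))))
})
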