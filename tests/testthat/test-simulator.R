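test_that("Brownian paths start at zero, are seed-reproducible, and have correct increment variance", {
  bp1 <- brownian_path(t_max = 10, dt = 0.01, seed = 42)
  bp2 <- brownian_path(t_max = 10, dt = 0.01, seed = 42)
  expect_identical(bp1$W, bp2$W)
  expect_identical(bp1$W[1], 0)
  big <- brownian_path(t_max = 1000, dt = 0.01, seed = 7)
  v <- stats::var(diff(big$W))
  expect_gt(v, 0.0095)
  expect_lt(v, 0.0105)
})

test_that("both stochastic schemes reduce to the deterministic solution when sigma = 0", {
  params <- csf_params(sigma = 0)
  for (scheme in c("log-euler", "euler-maruyama")) {
    traj <- simulate_icp(params, t_max = 30, dt = 1e-3, p_init = 8,
                         seed = 1, scheme = scheme)
    expect_lt(max(abs(traj$icp_mmHg -
                        deterministic_icp(params, traj$time_min, 8))), 0.01)
  }
})

test_that("trajectories are reproducible and both schemes share the driving noise", {
  params <- default_params()
  t1 <- simulate_icp(params, t_max = 2, dt = 1e-3, seed = 5)
  t2 <- simulate_icp(params, t_max = 2, dt = 1e-3, seed = 5)
  expect_identical(t1$icp_mmHg, t2$icp_mmHg)
  # driving the log-Euler scheme with the explicit Brownian path of the same
  # seed reproduces the seeded run exactly
  bp <- brownian_path(t_max = 2, dt = 1e-3, seed = 5)
  t3 <- simulate_icp(params, p_init = params$p_b, scheme = "log-euler",
                     brownian = bp)
  expect_equal(t3$icp_mmHg, t1$icp_mmHg, tolerance = 1e-12)
})

test_that("log-Euler paths stay strictly positive at high noise", {
  params <- csf_params(sigma = 1.3)
  traj <- simulate_icp(params, t_max = 60, dt = 1e-3, p_init = 1, seed = 3)
  expect_true(all(traj$icp_mmHg > 0))
})

test_that("Euler-Maruyama completes breach-free at default conditions", {
  # at dt = 1e-3 and standard parameters breaches are vanishingly rare;
  # a handful of 60-min paths must run clean
  params <- default_params()
  for (s in 1:3) {
    traj <- simulate_icp(params, t_max = 60, dt = 1e-3, seed = s,
                         scheme = "euler-maruyama")
    expect_true(all(traj$icp_mmHg > 0))
  }
})

test_that("Euler-Maruyama reports a positivity breach instead of continuing", {
  # extreme noise far above the stationary-existence bound forces a breach
  params <- csf_params(sigma = 60)
  expect_error(
    simulate_icp(params, t_max = 10, dt = 0.05, p_init = 0.5, seed = 2,
                 scheme = "euler-maruyama"),
    "positivity breach.*step", ignore.case = TRUE)
})

test_that("exact path solution starts at p_init and matches the logistic solution when noise-free", {
  params <- csf_params(sigma = 0)
  bp <- brownian_path(t_max = 30, dt = 1e-2, seed = 1)
  bp$W <- rep(0, nrow(bp))
  traj <- exact_icp(params, bp, p_init = 8)
  expect_identical(traj$icp_mmHg[1], 8)
  expect_lt(max(abs(traj$icp_mmHg -
                      deterministic_icp(params, traj$time_min, 8))), 1e-10)
})

test_that("long log-Euler runs recover the stationary mean", {
  params <- default_params()
  traj <- simulate_icp(params, t_max = 2000, dt = 1e-2, seed = 4,
                       scheme = "log-euler", thin = 100L)
  x <- traj$icp_mmHg[traj$time_min > 200]
  n_batches <- 12
  batches <- tapply(x, rep(seq_len(n_batches), each = length(x) / n_batches),
                    mean)
  se <- stats::sd(batches) / sqrt(n_batches)
  expect_lt(abs(mean(x) - stationary_mean(params)), 3 * se)
})

test_that("Euler-Maruyama converges strongly to the exact path solution", {
  params <- default_params()
  study <- strong_convergence_order(params, p_init = 8, t_max = 5,
                                    dts = c(1e-2, 5e-3, 2.5e-3),
                                    ref_dt = 1e-4, n_paths = 50, seed = 9)
  expect_true(all(diff(study$strong_error) < 0))
  expect_gt(attr(study, "order"), 0.4)
})

test_that("ensemble summaries behave in the degenerate and deterministic cases", {
  params <- default_params()
  single <- simulate_icp_ensemble(params, t_max = 1, dt = 1e-2, n_paths = 1,
                                  seed = 8)
  path <- simulate_icp(params, t_max = 1, dt = 1e-2,
                       seed = csfsde:::derive_seed(8, 1))
  expect_equal(single$mean, path$icp_mmHg)
  det <- simulate_icp_ensemble(csf_params(sigma = 0), t_max = 1, dt = 1e-2,
                               n_paths = 5, seed = 8, scheme = "deterministic")
  expect_true(all(det$sd == 0))
  expect_equal(det$mean,
               deterministic_icp(csf_params(sigma = 0), det$time_min, 8))
  # quantile curves are ordered
  stoch <- simulate_icp_ensemble(params, t_max = 2, dt = 1e-2, n_paths = 50,
                                 seed = 8)
  expect_true(all(stoch$q05 <= stoch$q50 & stoch$q50 <= stoch$q95))
})

test_that("ensemble cross-sectional mean at a late time matches the stationary mean", {
  params <- default_params()
  ens <- simulate_icp_ensemble(params, t_max = 400, dt = 1e-2, n_paths = 400,
                               seed = 10, thin = 4000L)
  final <- ens[nrow(ens), ]
  se <- final$sd / sqrt(attr(ens, "n_paths"))
  expect_lt(abs(final$mean - stationary_mean(params)), 3 * se)
})

test_that("long-run occupancy matches the stationary gamma distribution", {
  params <- default_params()
  traj <- simulate_icp(params, t_max = 5000, dt = 1e-2, seed = 6,
                       scheme = "log-euler", thin = 100L)
  x <- traj$icp_mmHg[traj$time_min > 500]
  g <- stationary_gamma(params)
  ks <- suppressWarnings(
    stats::ks.test(x, stats::pgamma, shape = g$shape, rate = g$rate)$statistic
  )
  expect_lt(unname(ks), 0.03)
})
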