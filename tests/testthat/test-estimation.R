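test_that("homodimer algebra gives the closed-form solutions per convention", {
  # doubled-monomer replication convention: O = I/2 - d/alpha
  hp <- solve_homodimer_K(1, 0.06, 2, "doubled_monomer")
  expect_equal(hp$O_free, 0.47, tolerance = 1e-12)
  expect_equal(hp$K, 0.06 / (2 * 0.47^2), tolerance = 1e-12)
  expect_equal(hp$K, 0.1358, tolerance = 1e-3)
  # mass-balance convention: O = I - 2 d/alpha
  hm <- solve_homodimer_K(1, 0.06, 2, "mass_balance")
  expect_equal(hm$O_free, 0.94, tolerance = 1e-12)
  expect_equal(hm$K, 0.06 / (2 * 0.94^2), tolerance = 1e-12)
  expect_equal(hm$K, 0.0340, tolerance = 2e-3)
  # the solution satisfies its own defining equations
  expect_equal(2 * hm$K * hm$O_free^2 + hm$O_free, 1)  # conservation, Ii = 1
  expect_equal(2 * hm$K * hm$O_free^2, 2 * 0.06 / 2)   # d = alpha K O^2, alpha = 2
})

test_that("homodimer targets outside the feasible region are rejected", {
  expect_error(solve_homodimer_K(0.05, 0.06, 2), "infeasible")
  expect_error(solve_homodimer_K(1, 1.01, 2), "infeasible")
  expect_silent(solve_homodimer_K(1, 0.99, 2))
})

test_that("cross-constant root scan inverts a forward-generated target", {
  K_known <- c(14, 1.5)
  I_pair <- c(1, 0.2)
  alpha <- c(2, 0.1, 1)
  d_fwd <- craclab:::cross_pair_influx(25, K_known, I_pair, alpha)
  root <- solve_cross_K(K_known, I_pair, alpha, d_fwd)
  expect_equal(root, 25, tolerance = 1e-6)
  # zero cross-binding limit
  d0 <- craclab:::cross_pair_influx(1e-6, K_known, I_pair, alpha)
  root0 <- solve_cross_K(K_known, I_pair, alpha, d0, scan_range = c(1e-8, 500))
  expect_lt(root0, 1e-4)
})

test_that("targets below the attainable influx produce a no-root error", {
  K_known <- c(14, 1.5)
  alpha <- c(2, 0.1, 1)
  floor_val <- craclab:::cross_pair_influx(500, K_known, c(1, 0.2), alpha)
  expect_error(
    solve_cross_K(K_known, c(1, 0.2), alpha, 0.9 * floor_val),
    "no root")
})

test_that("feasibility boundary exists and cross dimers must conduct weakly", {
  h11 <- solve_homodimer_K(1, 0.06, 2)
  h22 <- solve_homodimer_K(0.2, 0.002, 1)
  fb <- feasibility_boundary(c(h11$K, h22$K), c(1, 0.2), a_ii = 2, a_jj = 1,
                             d_pair = 0.05,
                             ratio_grid = exp(seq(log(1.5), log(200), length.out = 20)))
  expect_true(fb$boundary_found)
  # roots exist at large ratios (small cross conductance), not small ones
  g <- fb$scanned_grid
  expect_true(all(g$root_exists[g$ratio > fb$ratio_boundary * 1.2]))
  expect_false(any(g$root_exists[g$ratio < fb$ratio_boundary / 1.2]))
})

test_that("feasibility boundary is invariant to jointly rescaling d and alpha", {
  h11 <- solve_homodimer_K(1, 0.06, 2)
  h22 <- solve_homodimer_K(0.2, 0.002, 1)
  grid <- exp(seq(log(2), log(120), length.out = 15))
  fb1 <- feasibility_boundary(c(h11$K, h22$K), c(1, 0.2), 2, 1, 0.05,
                              ratio_grid = grid)
  s <- 3
  h11s <- solve_homodimer_K(1, s * 0.06, s * 2)
  h22s <- solve_homodimer_K(0.2, s * 0.002, s * 1)
  expect_equal(h11s$K, h11$K)
  fb2 <- feasibility_boundary(c(h11s$K, h22s$K), c(1, 0.2), s * 2, s * 1,
                              s * 0.05, ratio_grid = grid)
  expect_equal(fb2$ratio_boundary, fb1$ratio_boundary, tolerance = 1e-6)
})

test_that("a target above the zero-cross influx is infeasible when cross dimers are weak", {
  h11 <- solve_homodimer_K(1, 0.06, 2)
  h22 <- solve_homodimer_K(0.2, 0.002, 1)
  d_hi <- 1.2 * craclab:::cross_pair_influx(1e-9, c(h11$K, h22$K), c(1, 0.2),
                                            c(2, 0.1, 1))
  fb <- feasibility_boundary(c(h11$K, h22$K), c(1, 0.2), 2, 1, d_hi,
                             ratio_grid = exp(seq(log(20), log(2000), length.out = 12)))
  expect_false(fb$boundary_found)
  expect_false(any(fb$scanned_grid$root_exists))
})

test_that("least-squares fit recovers the generating constants without noise", {
  cal <- gen_calibration(ref$K, ref$I, ref$alpha, noise_frac = 0)
  init <- init_from_algebra(cal, ref$I, ref$alpha)
  fit <- fit_all_K(cal, ref$I, ref$alpha, init)
  expect_true(fit$converged)
  expect_lte(fit$rss, fit$init_rss)
  expect_lt(max(abs(unclass(fit$K_estimates) / unclass(ref$K) - 1)), 0.05)
})

test_that("an optimal starting point is a fixed point of the fit", {
  cal <- gen_calibration(ref$K, ref$I, ref$alpha, noise_frac = 0)
  fit <- fit_all_K(cal, ref$I, ref$alpha, ref$K)
  expect_lt(fit$rss, 1e-16)
  expect_lt(max(abs(unclass(fit$K_estimates) / unclass(ref$K) - 1)), 1e-4)
})

test_that("fit residuals never exceed the initialization residuals", {
  set.seed(7)
  for (i in 1:3) {
    cal <- gen_calibration(ref$K, ref$I, ref$alpha, noise_frac = 0.05, seed = i)
    init <- init_from_algebra(cal, ref$I, ref$alpha)
    fit <- fit_all_K(cal, ref$I, ref$alpha, init)
    expect_lte(fit$rss, fit$init_rss)
  }
})

test_that("fitting the printed targets separates ORAI1-containing influxes", {
  # the printed target set is not exactly representable by the dimer model
  # (the wild type cannot conduct less than the ORAI3 single knockout), so a
  # least-squares compromise cannot reproduce every strict inequality; what
  # must survive is the 25-fold split between genotypes with and without
  # ORAI1, and the dominance of the ORAI1 homodimer target
  cal <- influx_calibration()
  init <- init_from_algebra(cal, ref$I, ref$alpha)
  fit <- fit_all_K(cal, ref$I, ref$alpha, init, weighting = "relative")
  pred <- vapply(craclab:::calibration_genotypes(), function(g) {
    st <- solve_equilibrium(apply_genotype(ref$I, orai_genotype(g)), fit$K_estimates)
    total_influx(st, ref$alpha)
  }, numeric(1))
  hi <- pred[c("d11", "d12", "d13", "d123")]
  lo <- pred[c("d22", "d23", "d33")]
  expect_gt(min(hi), 10 * max(lo))
  expect_lte(fit$rss, fit$init_rss)
})
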