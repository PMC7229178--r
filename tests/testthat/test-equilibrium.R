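test_that("no binding means free monomers equal the totals", {
  st <- solve_equilibrium(isoform_totals(1, 0.2, 0.2),
                          binding_constants(0, 0, 0, 0, 0, 0))
  expect_equal(c(st$O1, st$O2, st$O3), c(1, 0.2, 0.2))
  expect_equal(c(st$O11, st$O12, st$O13, st$O22, st$O23, st$O33), rep(0, 6))
})

test_that("single-isoform equilibrium matches the closed-form quadratic root", {
  # 2 k O^2 + O = 1  =>  O = (-1 + sqrt(1 + 8 k)) / (4 k)
  for (k in c(0.1, 3.7, 14, 250)) {
    st <- solve_equilibrium(isoform_totals(1, 0, 0),
                            binding_constants(k, 0, 0, 0, 0, 0))
    expect_equal(st$O1, (-1 + sqrt(1 + 8 * k)) / (4 * k), tolerance = 1e-12)
    expect_equal(st$O2, 0)
    expect_equal(st$O11, k * st$O1^2)
  }
})

test_that("Newton solution agrees with the damped fixed-point oracle", {
  set.seed(42)
  for (i in 1:40) {
    I <- stats::runif(3, 0.05, 2)
    K <- random_K_draw()
    st <- solve_equilibrium(isoform_totals(I[1], I[2], I[3]), K)
    O_oracle <- oracle_fixed_point(I, unclass(K))
    expect_lt(max(abs(c(st$O1, st$O2, st$O3) - O_oracle)), 1e-8)
    expect_lt(st$conservation_residual, 1e-10)
  }
})

test_that("stored dimers satisfy the mass-action relations exactly", {
  st <- solve_equilibrium(ref$I, ref$K)
  K <- unclass(ref$K)
  expect_identical(st$O12, K[["K12"]] * st$O1 * st$O2)
  expect_identical(st$O33, K[["K33"]] * st$O3^2)
})

test_that("genotype masking zeroes absent isoforms only", {
  tot <- isoform_totals(1, 0.2, 0.2)
  expect_equal(unclass(apply_genotype(tot, orai_genotype(1:3))),
               unclass(tot))
  expect_equal(unname(unclass(apply_genotype(tot, orai_genotype(3)))),
               c(0, 0, 0.2))
  expect_equal(unname(unclass(apply_genotype(tot, orai_genotype(integer(0))))),
               c(0, 0, 0))
})

test_that("total influx is the conductance-weighted sum over dimers", {
  st <- solve_equilibrium(ref$I, ref$K)
  expect_equal(total_influx(st, dimer_conductances(0, 0, 0, 0, 0, 0)), 0)
  a11_only <- dimer_conductances(1.7, 0, 0, 0, 0, 0)
  expect_equal(total_influx(st, a11_only), 1.7 * st$O11)
  # term-by-term hand sum
  a <- unclass(ref$alpha)
  hand <- a[["a11"]] * st$O11 + a[["a12"]] * st$O12 + a[["a13"]] * st$O13 +
    a[["a22"]] * st$O22 + a[["a23"]] * st$O23 + a[["a33"]] * st$O33
  expect_identical(total_influx(st, ref$alpha), hand)
})

test_that("influx scales linearly with a common conductance factor", {
  st <- solve_equilibrium(ref$I, ref$K)
  a <- unclass(ref$alpha)
  scaled <- do.call(dimer_conductances, as.list(3.14 * a))
  expect_identical(total_influx(st, scaled), 3.14 * total_influx(st, ref$alpha))
})

test_that("genotype influx table reproduces the expected knockout ordering", {
  tab <- genotype_influx_table(ref$I, ref$K, ref$alpha)
  J <- setNames(tab$J_in, tab$genotype)
  # ORAI1 alone conducts most; ORAI2/3 presence suppresses; ORAI3 alone least
  expect_gt(J[["ORAI2_3_DKO"]], J[["ORAI3_SKO"]])
  expect_gte(J[["ORAI3_SKO"]], J[["WT"]])
  expect_gte(J[["ORAI2_SKO"]], J[["WT"]])
  expect_gt(J[["WT"]], J[["ORAI1_3_DKO"]])
  expect_gte(J[["ORAI1_3_DKO"]], J[["ORAI1_SKO"]])
  expect_gt(J[["ORAI1_SKO"]], J[["ORAI1_2_DKO"]])
  expect_identical(J[["ORAI_TKO"]], 0)
  expect_equal(tab$J_rel[tab$genotype == "WT"], 1)
})

test_that("raising a cross constant sequesters both partner monomers", {
  grid <- c(0, 5, 19, 80, 300)
  o1 <- o2 <- numeric(length(grid))
  for (i in seq_along(grid)) {
    K <- binding_constants(K11 = 14, K12 = grid[i], K13 = 17,
                           K22 = 1.5, K23 = 14, K33 = 0.93)
    st <- solve_equilibrium(ref$I, K)
    o1[i] <- st$O1; o2[i] <- st$O2
  }
  expect_true(all(diff(o1) < 0))
  expect_true(all(diff(o2) < 0))
})

test_that("calibrated influx puts genotypes on the wild-type target scale", {
  expect_equal(calibrated_influx(ref$I, ref$K, ref$alpha, orai_genotype(1:3)),
               0.045)
  expect_equal(calibrated_influx(ref$I, ref$K, ref$alpha,
                                 orai_genotype(integer(0))), 0)
})
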