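# construct traces on a 2 s grid mimicking the imaging cadence
make_trace <- function(f, duration = 960, dt = 2) {
  t <- seq(0, duration, by = dt)
  list(t = t, v = f(t))
}

triangle <- function(t, center, width = 30, height = 1) {
  pmax(0, height * (1 - abs(t - center) / (width / 2)))
}

test_that("a flat trace is a non-responder", {
  tr <- make_trace(function(t) rep(0.3, length(t)))
  cl <- classify_trace(tr$t, tr$v, stim_time = 60)
  expect_identical(cl$label, "non_responder")
  expect_true(is.na(cl$n_oscillations))
})

test_that("a sustained step above the 25% line for over 5 min is a plateau", {
  # rise to 1.0 at stimulation, held at 0.5 of peak for 6 min, then back down
  tr <- make_trace(function(t) {
    0.3 + ifelse(t >= 70 & t <= 80, 0.7,
          ifelse(t > 80 & t <= 80 + 360, 0.35, 0))
  })
  cl <- classify_trace(tr$t, tr$v, stim_time = 60)
  expect_identical(cl$label, "plateau")
})

test_that("the plateau duration rule is sharp at 5 minutes", {
  hold_trace <- function(D) {
    make_trace(function(t) 0.3 + ifelse(t >= 100 & t <= 100 + D, 0.5, 0))
  }
  rules <- classification_rules(smooth_window = 0)
  short <- hold_trace(298)
  long <- hold_trace(302)
  expect_identical(classify_trace(short$t, short$v, 60, rules)$label,
                   "non_responder")  # one broad spike, no repeats
  expect_identical(classify_trace(long$t, long$v, 60, rules)$label, "plateau")
})

test_that("a train of baseline-returning spikes is oscillating with exact count", {
  centers <- seq(150, 750, length.out = 6)
  tr <- make_trace(function(t) 0.3 + Reduce(`+`, lapply(centers, triangle, t = t)))
  cl <- classify_trace(tr$t, tr$v, stim_time = 60)
  expect_identical(cl$label, "oscillating")
  expect_identical(cl$n_oscillations, 6L)
  expect_identical(count_oscillations(tr$t, tr$v, 60), 6L)
})

test_that("only maxima separated by a return to baseline are counted", {
  rules <- classification_rules(smooth_window = 0)
  # five well-separated spike complexes; three carry a secondary maximum on
  # an elevated shoulder that never returns to baseline in between, so the
  # trace has 8 maxima but only 5 countable oscillations
  spike <- function(t, c0, bump) {
    knots_x <- if (bump) {
      c0 + c(-20, 0, 20, 44, 50, 56, 70, 90)
    } else {
      c0 + c(-20, 0, 20)
    }
    knots_y <- if (bump) c(0, 1, 0.5, 0.5, 0.8, 0.5, 0.5, 0) else c(0, 1, 0)
    stats::approx(knots_x, knots_y, xout = t, yleft = 0, yright = 0)$y
  }
  centers <- c(150, 290, 430, 570, 710)
  tr <- make_trace(function(t) {
    0.3 + Reduce(`+`, Map(function(c0, b) spike(t, c0, b),
                          centers, c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  })
  raw_maxima <- which(diff(sign(diff(tr$v))) < 0) + 1
  expect_gte(length(raw_maxima), 8)
  expect_identical(count_oscillations(tr$t, tr$v, 60, rules), 5L)
  expect_identical(classify_trace(tr$t, tr$v, 60, rules)$label, "oscillating")
})

test_that("classification requires a sufficiently long recording", {
  tr <- make_trace(function(t) rep(0.3, length(t)), duration = 300)
  expect_error(classify_trace(tr$t, tr$v, 60), "too short")
  expect_error(classify_trace(c(1, 2, 2, 3), c(0, 0, 0, 0), 1), "increasing")
})

test_that("SOCE magnitude measures the re-addition rise over a baseline window", {
  t <- seq(0, 600, by = 2)
  # flat baseline 0.4, re-add at 300 s, peak +0.8
  v <- 0.4 + triangle(t, 360, width = 120, height = 0.8)
  expect_equal(as.numeric(soce_magnitude(t, v, readd_time = 300)), 0.8,
               tolerance = 1e-12)
  # drifting baseline: the window mean, not a single point, sets the reference
  drift <- 0.4 + 0.001 * t
  v2 <- drift + triangle(t, 360, width = 120, height = 0.8)
  expected <- max(v2[t >= 300]) - mean(drift[t >= 240 & t < 300])
  expect_equal(as.numeric(soce_magnitude(t, v2, 300)), expected, tolerance = 1e-12)
  # no rise: clipped at zero and flagged
  flatv <- rep(0.4, length(t)) - 0.001 * t
  m <- soce_magnitude(t, flatv, 300)
  expect_identical(as.numeric(m), 0)
  expect_true(attr(m, "clipped"))
  expect_error(soce_magnitude(t, v, NA), "required")
})

test_that("CDI remaining fraction matches closed forms", {
  t <- seq(0, 150, by = 0.5)
  expect_equal(cdi_remaining_fraction(t, rep(-85, length(t))), 1.0)
  # exponential decay with tau = 100 ms evaluated at 146 ms
  expect_equal(cdi_remaining_fraction(t, -exp(-t / 100)), exp(-1.46),
               tolerance = 1e-9)
  # complete inactivation before 146 ms
  expect_equal(cdi_remaining_fraction(t, -pmax(1 - t / 100, 0)), 0)
  expect_error(cdi_remaining_fraction(t, rep(0, length(t))), "zero peak")
  expect_error(cdi_remaining_fraction(seq(0, 100, 0.5), rep(1, 201)), "cover")
})

test_that("three-cube FRET correction subtracts both crosstalk terms", {
  expect_equal(fret_fc(1000, 800, 700, 0, 0), 700)
  expect_equal(fret_fc(1000, 800, 0.5 * 1000 + 0.06 * 800, 0.5, 0.06), 0)
  set.seed(3)
  for (i in 1:10) {
    x <- stats::runif(5, 0, 2000)
    expect_identical(fret_fc(x[1], x[2], x[3], x[4] / 1000, x[5] / 1000),
                     x[3] - x[4] / 1000 * x[1] - x[5] / 1000 * x[2])
  }
})

test_that("apparent FRET efficiency behaves per formula variant", {
  expect_equal(efret(0, I_DD = 1000, G = 2.5), 0)
  expect_equal(efret(2.5 * 1000, I_DD = 1000, G = 2.5), 0.5)
  # the replication variant carries an extra Fc factor
  expect_equal(efret(2, I_DD = 1, G = 2, formula = "replication"), 1.0)
  expect_equal(efret(2, I_DD = 1, G = 2, formula = "standard"), 0.5)
  expect_error(efret(0, 0, G = 2.5), "undefined")
})

test_that("E-FRET is invariant under uniform intensity scaling", {
  for (s in c(0.1, 1, 7)) {
    fc <- fret_fc(s * 1000, s * 800, s * 1400, 0.5, 0.06)
    expect_equal(efret(fc, s * 1000, G = 2.5),
                 efret(fret_fc(1000, 800, 1400, 0.5, 0.06), 1000, G = 2.5),
                 tolerance = 1e-12)
  }
})

test_that("NFAT translocation ratio is nuclear over total", {
  expect_equal(nfat_ratio(500, 500), 1)
  expect_equal(nfat_ratio(0, 500), 0)
  expect_equal(nfat_ratio(250, 500), 0.5)
  expect_error(nfat_ratio(10, 0), "> 0")
  expect_error(nfat_ratio(600, 500), "nuclear")
})

test_that("coverslip summaries compute class percentages and mean counts", {
  s <- summarize_coverslip(rep(c("oscillating", "plateau", "non_responder"),
                               c(13, 5, 2)))
  expect_equal(s$pct_oscillating, 65)
  expect_equal(s$pct_plateau, 25)
  expect_equal(s$pct_nonresponding, 10)
  expect_equal(s$pct_oscillating + s$pct_plateau + s$pct_nonresponding, 100)

  s2 <- summarize_coverslip(rep("plateau", 7))
  expect_equal(c(s2$pct_oscillating, s2$pct_plateau, s2$pct_nonresponding),
               c(0, 100, 0))

  s3 <- summarize_coverslip(rep("oscillating", 3), n_oscillations = c(4, 6, 8))
  expect_equal(s3$mean_oscillations, 6)

  expect_error(summarize_coverslip(character(0)), "no cells")
  expect_error(summarize_coverslip(c("oscillating", "weird")), "unknown")
})

test_that("every classified trace receives exactly one of the three labels", {
  ts <- gen_population(population_spec(n_cells = 30, seed = 11))
  cl <- classify_cells(ts$traces, ts$meta)
  expect_identical(nrow(cl), 30L)
  expect_true(all(cl$label %in% c("oscillating", "plateau", "non_responder")))
  s <- summarize_coverslip(cl$label)
  expect_equal(s$pct_oscillating + s$pct_plateau + s$pct_nonresponding, 100)
})
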