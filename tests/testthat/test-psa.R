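test_that("quartile-doubling rule builds the stated triangulars", {
  tq <- triangular_from_quartiles(10, 8, 13)
  expect_equal(c(tq$min, tq$mode, tq$max), c(6, 10, 16))
  tq2 <- triangular_from_quartiles(0.36, 0.30, 0.40)
  expect_equal(c(tq2$min, tq2$mode, tq2$max), c(0.24, 0.36, 0.44))
  expect_error(triangular_from_quartiles(5, 5, 5), "zero-width")
  expect_error(triangular_from_quartiles(10, 12, 13), "q1 <= mean")
})

test_that("sd fallback builds a symmetric triangular with the right sd", {
  ts <- triangular_from_sd(100, 0.5)
  expect_equal(ts$mode, 100)
  expect_equal(ts$max - ts$mode, 50 * sqrt(6))
  expect_equal(sqrt(tri_var(ts)), 50)
  expect_equal(tri_mean(ts), 100)

  neg <- triangular_from_sd(-0.28, 0.5)
  expect_equal(neg$mode, -0.28)
  expect_lt(neg$min, neg$max)
  expect_equal(sqrt(tri_var(neg)), 0.14)

  expect_error(triangular_from_sd(0), "no scale")
})

test_that("triangular sampler moments match closed forms within 3 se", {
  set.seed(31)
  n <- 1e5
  for (spec in list(triangular(6, 10, 16), triangular_from_sd(100, 0.5),
                    triangular(-1, -0.28, 0.2))) {
    x <- rtriangular(n, spec)
    expect_true(all(x >= spec$min & x <= spec$max))
    se_mean <- sqrt(tri_var(spec) / n)
    expect_lt(abs(mean(x) - tri_mean(spec)), 3 * se_mean)
    # se of the sample variance ~ sqrt((m4 - v^2)/n); bound loosely by
    # 3 * sqrt(2/n) * v which covers the light-tailed triangular
    expect_lt(abs(var(x) - tri_var(spec)),
              3 * sqrt(2 / n) * tri_var(spec) + 3 * se_mean^2)
  }
})

test_that("PSA is bit-identical under a fixed seed", {
  p <- load_registry()
  a <- psa("base1", p, n_iter = 2000, seed = 5)
  b <- psa("base1", p, n_iter = 2000, seed = 5)
  expect_identical(a$samples, b$samples)
  expect_identical(a$quadrants, b$quadrants)
  expect_identical(a$ceac, b$ceac)
})

test_that("degenerate PSA collapses to the deterministic result", {
  p <- load_registry()
  for (id in names(p$scenarios)) {
    ps <- psa(id, p, n_iter = 3, sd_fraction = 0)
    det <- incremental(scenario_outcomes(p, id))
    expect_equal(unique(ps$samples$delta_cost), det[["delta_cost"]],
                 info = id)
    expect_equal(unique(ps$samples$delta_effect), det[["delta_effect"]],
                 info = id)
  }
})

test_that("single-draw PSA yields degenerate fractions", {
  ps <- psa("base1", load_registry(), n_iter = 1, seed = 9)
  expect_true(all(ps$quadrants %in% c(0, 1)))
  expect_equal(sum(ps$quadrants), 1)
})

test_that("quadrant fractions partition the sample cloud", {
  set.seed(17)
  for (i in 1:20) {
    cloud <- data.frame(delta_cost = rnorm(200, 0, 800),
                        delta_effect = rnorm(200, 0, 0.05))
    fr <- quadrant_fractions(cloud, wtp = 50000)
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    expect_true(all(fr >= 0))
  }
  # boundary conventions
  expect_equal(quadrant_fractions(
    data.frame(delta_cost = 1, delta_effect = -1), 50000)[["NW"]], 1)
  expect_equal(quadrant_fractions(
    data.frame(delta_cost = 100, delta_effect = 0.01),
    50000)[["NE_below_wtp"]], 1)  # ICER 10000 <= 50000
  expect_equal(quadrant_fractions(
    data.frame(delta_cost = 5, delta_effect = 0), 50000)[["NW"]], 1)
  expect_equal(quadrant_fractions(
    data.frame(delta_cost = 0, delta_effect = 0), 50000)[["NW"]], 1)
  expect_error(quadrant_fractions(
    data.frame(delta_cost = numeric(0), delta_effect = numeric(0)),
    50000), "empty")
})

test_that("acceptability curve is the NMB indicator and sums to one", {
  # all samples costlier & more effective: P monotone nondecreasing,
  # switching on at each sample's ICER
  set.seed(19)
  cloud <- data.frame(delta_cost = runif(300, 50, 2000),
                      delta_effect = runif(300, 0.001, 0.05))
  cv <- ceac(cloud, seq(0, 2e5, by = 5000))
  expect_true(all(diff(cv$p_evlt) >= 0))
  expect_equal(cv$p_evlt + cv$p_hls, rep(1, nrow(cv)))
  # wtp = 0: fraction with negative incremental cost
  mixed <- data.frame(delta_cost = c(-10, -5, 3, 8),
                      delta_effect = c(0.1, -0.2, 0.3, 0))
  expect_equal(ceac(mixed, 0)$p_evlt, 0.5)
  # a dominated point mass is never accepted
  pm <- data.frame(delta_cost = 466.66, delta_effect = -0.0075)
  expect_true(all(ceac(pm, seq(0, 1e5, 1e4))$p_evlt == 0))
})

test_that("certainty at threshold equals the CEAC at that threshold", {
  p <- load_registry()
  ps <- psa("alt10", p, n_iter = 4000, seed = 13,
            wtp_grid = c(0, 50000, 100000))
  expect_identical(ps$certainty_ce,
                   ps$ceac$p_evlt[ps$ceac$wtp == 50000])
  expect_true(ps$certainty_ce >= 0 && ps$certainty_ce <= 1)
})

test_that("two-level decomposition preserves the parameter means", {
  p <- load_registry()
  ps <- psa("base2", p, n_iter = 400, seed = 21, two_level = TRUE,
            n_inner = 20)
  det <- incremental(scenario_outcomes(p, "base2"))
  # averaging inner draws keeps the cloud centred on the point estimate
  expect_equal(mean(ps$samples$delta_cost), det[["delta_cost"]],
               tolerance = 0.25)
  expect_equal(nrow(ps$samples), 400)
})

test_that("explicit distribution overrides are honoured", {
  p <- load_registry()
  ps <- psa("base1", p, n_iter = 500, seed = 3, sd_fraction = 0,
            dists = list(cost_evlt = triangular(1390, 1391, 1392)))
  # only the overridden parameter varies: deltas stay in its band
  expect_true(all(ps$samples$delta_cost >= 1390 - 924.00 &
                    ps$samples$delta_cost <= 1392 - 924.00))
  expect_equal(unique(ps$samples$delta_effect),
               incremental(scenario_outcomes(p, "base1"))[["delta_effect"]])
})
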