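test_that("two-point-per-class MLE is analytically forced", {
  m <- fit_gda(c(0, 2, 10, 14), c(1, 1, 0, 0), "road")
  expect_equal(m$mu1, 1)
  expect_equal(m$var1, 1)
  expect_equal(m$mu0, 12)
  expect_equal(m$var0, 4)
  expect_equal(m$xi, 0.5)
  expect_equal(m$n1, 2L)
  expect_equal(m$n0, 2L)
})

test_that("degenerate fitting sets are rejected or floored", {
  expect_error(fit_gda(c(1, 2, 3, 4), c(1, 0, 0, 0), "road"), ">= 2")
  expect_error(fit_gda(c(1, 2, 3), c(0, 0, 0), "road"), "both classes")
  expect_error(fit_gda(c(1, 2), c(1, 0), "water"), ">= 2")
  # identical distances within a class hit the variance floor of (1 m)^2
  m <- fit_gda(c(5, 5, 100, 200), c(1, 1, 0, 0), "water")
  expect_equal(m$var1, 1)
})

test_that("MLE recovers known parameters within 3 standard errors", {
  n <- 10000; xi <- 0.1
  n1 <- round(n * xi); n0 <- n - n1
  mu1 <- 500; s1 <- 100; mu0 <- 2000; s0 <- 400
  d <- herdscan:::with_seed(2024, c(rnorm(n1, mu1, s1), rnorm(n0, mu0, s0)))
  y <- c(rep(1, n1), rep(0, n0))
  m <- fit_gda(d, y, "road")
  expect_lt(abs(m$mu1 - mu1), 3 * s1 / sqrt(n1))
  expect_lt(abs(m$mu0 - mu0), 3 * s0 / sqrt(n0))
  expect_lt(abs(m$var1 - s1^2), 3 * s1^2 * sqrt(2 / n1))
  expect_lt(abs(m$var0 - s0^2), 3 * s0^2 * sqrt(2 / n0))
  expect_lt(abs(m$xi - xi), 3 * sqrt(xi * (1 - xi) / n))
})

make_model <- function(xi, mu0, s0, mu1, s1, kind = "road") {
  structure(list(xi = xi, mu0 = mu0, var0 = s0^2, mu1 = mu1, var1 = s1^2,
                 infra_kind = kind, n0 = 100L, n1 = 100L,
                 d_min = 0, d_max = 4000),
            class = "gda_model")
}

test_that("Bayes posterior matches direct density evaluation", {
  m <- make_model(0.1, 1000, 500, 100, 50)
  d <- seq(0, 4000, by = 25)
  expect_equal(posterior_probability(m, d),
               posterior_oracle(0.1, 1000, 500, 100, 50, d),
               tolerance = 1e-12)
  expect_equal(posterior_probability(m, 100), 0.849, tolerance = 1e-3)
})

test_that("posterior degenerates to the prior when classes are identical", {
  m <- make_model(0.3, 700, 200, 700, 200)
  d <- seq(0, 3000, by = 10)
  expect_equal(posterior_probability(m, d), rep(0.3, length(d)),
               tolerance = 1e-12)
  # symmetric case: equal variances, midpoint, even prior
  ms <- make_model(0.5, 1000, 150, 200, 150)
  expect_equal(posterior_probability(ms, 600), 0.5, tolerance = 1e-12)
})

test_that("posterior normalizes and is monotone under equal variances", {
  m <- make_model(0.2, 1500, 300, 250, 300)
  d <- seq(0, 5000, by = 7)
  p1 <- posterior_probability(m, d)
  # swap the classes: P(y=0 | d) under the same generative model
  msw <- make_model(0.8, 250, 300, 1500, 300)
  p0 <- posterior_probability(msw, d)
  expect_lt(max(abs(p1 + p0 - 1)), 1e-12)
  # mu1 < mu0, sigma0 = sigma1: likelihood ratio strictly decreasing in d
  expect_true(all(diff(p1) < 0))
})

test_that("integrating the posterior against the marginal returns the prior", {
  xi <- 0.25
  m <- make_model(xi, 1800, 400, 300, 120)
  n <- 20000
  draws <- herdscan:::with_seed(77, {
    y <- rbinom(n, 1, xi)
    rnorm(n, ifelse(y == 1, m$mu1, m$mu0), ifelse(y == 1, sqrt(m$var1), sqrt(m$var0)))
  })
  p <- posterior_probability(m, draws)
  se <- sd(p) / sqrt(n)
  expect_lt(abs(mean(p) - xi), 3 * se)
})

test_that("GDA holdout split is stratified and disjoint from training", {
  y <- c(rep(1, 40), rep(0, 160))
  sp <- gda_holdout_split(y, 0.2, seed = 3)
  expect_length(intersect(sp$fit, sp$train), 0)
  expect_setequal(c(sp$fit, sp$train), seq_along(y))
  expect_equal(sum(y[sp$fit] == 1), 8)
  expect_equal(sum(y[sp$fit] == 0), 32)
  expect_error(gda_holdout_split(c(1, 1, 0, 0), 0.5), "too small")
})

test_that("aux feature vectors have the documented arity and ordering", {
  mw <- make_model(0.2, 2000, 500, 200, 100, "water")
  mr <- make_model(0.2, 2000, 500, 250, 120, "road")
  rec <- list(d_water_m = 300, d_road_m = 400)
  v1 <- build_aux_features(list(water = mw), rec)
  expect_length(v1, 3L)
  expect_named(v1, c("water_p0", "water_p1", "water_posterior"))
  v2 <- build_aux_features(list(water = mw, road = mr), rec)
  expect_length(v2, 6L)
  expect_named(v2, c("water_p0", "water_p1", "water_posterior",
                     "road_p0", "road_p1", "road_posterior"))
  expect_equal(unname(v2["water_posterior"]),
               posterior_probability(mw, 300), tolerance = 1e-12)
  expect_true(all(v2 >= 0 & v2 <= 1))
  expect_error(build_aux_features(list(water = mw), list(d_road_m = 1)),
               "d_water_m")
  expect_error(build_aux_features(list(road = "x"), rec), "invalid GDA model")
})

test_that("raw-distance mode min-max-normalizes onto [0, 1]", {
  mw <- make_model(0.2, 2000, 500, 200, 100, "water")  # d_min 0, d_max 4000
  lo <- build_aux_features(list(water = mw), list(d_water_m = 0), "raw_distance")
  hi <- build_aux_features(list(water = mw), list(d_water_m = 4000), "raw_distance")
  expect_equal(unname(lo), 0)
  expect_equal(unname(hi), 1)
  expect_length(lo, 1L)
})

test_that("fusion wiring dimensions follow the strategy", {
  f2 <- fusion_spec("aux2", embed_dim = 512, aux_dim = 4)
  expect_equal(f2$head_input_dim, 516L)
  expect_null(f2$combiner_input_dim)
  f1 <- fusion_spec("aux1", embed_dim = 512, aux_dim = 4)
  expect_equal(f1$head_input_dim, 512L)
  expect_equal(f1$combiner_input_dim, 5L)
  f12 <- fusion_spec("aux12", embed_dim = 32, aux_dim = 6)
  expect_equal(f12$head_input_dim, 38L)
  expect_equal(f12$combiner_input_dim, 7L)
  f0 <- fusion_spec("none", embed_dim = 32)
  expect_equal(f0$head_input_dim, 32L)
  expect_error(fusion_spec("none", 32, aux_dim = 3), "no auxiliary")
  expect_error(fusion_spec("aux1", 32, aux_dim = 0), "requires aux_dim")
})

test_that("GDA models serialize to JSON and back", {
  dir <- withr::local_tempdir()
  m <- fit_gda(c(10, 30, 800, 900, 1000), c(1, 1, 0, 0, 0), "water")
  p <- file.path(dir, "gda.json")
  write_gda_json(m, p)
  m2 <- read_gda_json(p)
  expect_equal(posterior_probability(m2, c(50, 500, 950)),
               posterior_probability(m, c(50, 500, 950)), tolerance = 1e-12)
})
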