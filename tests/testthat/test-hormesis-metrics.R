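test_that("dose transform maps control to the intercept and inverts", {
  expect_identical(transform_concentration(0), 0)
  expect_identical(transform_concentration(1), 1)
  expect_identical(transform_concentration(1023), 10)
  expect_error(transform_concentration(-1), "non-negative")
  x <- runif(50, 0, 12)
  expect_equal(transform_concentration(untransform_concentration(x)), x)
})

test_that("hdi finds the shortest window with leftmost tie-breaking", {
  expect_equal(hdi(1:100, 0.95), c(low = 1, high = 95))
  expect_equal(hdi(rep(3.5, 60)), c(low = 3.5, high = 3.5))
  expect_error(hdi(numeric(0)), "no finite draws")
  # symmetric unimodal: HDI close to the equal-tailed interval
  set.seed(1)
  z <- rnorm(1e5)
  h <- hdi(z)
  q <- quantile(z, c(0.025, 0.975))
  expect_lt(max(abs(h - q)), 0.05)
  # HDI is never wider than the equal-tailed interval
  expect_lte(h["high"] - h["low"], q[2] - q[1])
})

test_that("closed-form derived metrics match hand-worked single draws", {
  # no curvature: logit(0.25) = -1.0986 crossed at x = 1.0986
  post <- fake_posterior(matrix(c(0, -1, 0), 1))
  lc <- lethal_concentration(post, 0.5, week = 6)
  expect_equal(lc$median, 2^1.0986123 - 1, tolerance = 1e-6)
  expect_equal(lc$fraction_defined, 1)

  post <- fake_posterior(matrix(c(0, 2, -0.5), 1))
  expect_equal(stimulation_limit(post, 6)$median, 15)
  pk <- peak_concentration(post, 6)
  expect_equal(pk$median[pk$metric == "peak_conc"], 3)
  expect_equal(pk$median[pk$metric == "peak_survival"],
               plogis(0 + 2 * 2 - 0.5 * 4))

  # hormesis absent: peak sits at the control
  post <- fake_posterior(matrix(c(0.3, 0, -0.2), 1))
  pk <- peak_concentration(post, 6)
  expect_equal(pk$median[pk$metric == "peak_conc"], 0)

  # control survival: all draws at b0 = 0 give exactly one half
  post <- fake_posterior(matrix(c(0, 1, -0.3), 1))
  expect_equal(control_survival(post, 6)$median, 0.5)
})

test_that("derived metrics agree with a bisection oracle to 1e-8 in x", {
  set.seed(42)
  n <- 300
  b <- cbind(rnorm(n, 0.4, 0.3), abs(rnorm(n, 2.5, 0.6)),
             -abs(rnorm(n, 0.45, 0.1)))
  post <- fake_posterior(b)
  for (f in c(0.10, 0.25, 0.50)) {
    x_pkg <- mesotox:::descending_root(b[, 1], b[, 2], b[, 3],
                                       qlogis((1 - f) * plogis(b[, 1])))
    x_orc <- vapply(seq_len(n), function(i) {
      vtx <- -b[i, 2] / (2 * b[i, 3])
      bisect_dose(b[i, 1], b[i, 2], b[i, 3],
                  qlogis((1 - f) * plogis(b[i, 1])), vtx, 60)
    }, 0)
    expect_lt(max(abs(x_pkg - x_orc), na.rm = TRUE), 1e-8)
  }
  # stimulation limit against bisection of p(x) = p0 on x > x_peak
  x_lim <- -b[, 2] / b[, 3]
  x_orc <- vapply(seq_len(n), function(i)
    bisect_dose(b[i, 1], b[i, 2], b[i, 3], b[i, 1],
                -b[i, 2] / (2 * b[i, 3]) + 1e-9, 60), 0)
  expect_lt(max(abs(x_lim - x_orc)), 1e-8)
})

test_that("parabola identities hold on every draw", {
  set.seed(7)
  n <- 500
  b <- cbind(rnorm(n, 0.4, 0.5), abs(rnorm(n, 3, 1)),
             -abs(rnorm(n, 0.5, 0.15)))
  x_peak <- -b[, 2] / (2 * b[, 3])
  x_lim <- -b[, 2] / b[, 3]
  expect_equal(x_lim, 2 * x_peak)
  c_peak <- untransform_concentration(x_peak)
  c_lim <- untransform_concentration(x_lim)
  expect_equal(c_lim, (c_peak + 1)^2 - 1)
})

test_that("LCx nest monotonically on the descending limb", {
  set.seed(11)
  b <- cbind(rnorm(200, 0.4, 0.3), abs(rnorm(200, 2.5, 0.5)),
             -abs(rnorm(200, 0.45, 0.08)))
  post <- fake_posterior(b)
  lc10 <- lethal_concentration(post, 0.10, 6)$median
  lc25 <- lethal_concentration(post, 0.25, 6)$median
  lc50 <- lethal_concentration(post, 0.50, 6)$median
  expect_lt(lc10, lc25)
  expect_lt(lc25, lc50)
})

test_that("undefined draws are excluded and reported", {
  # one healthy draw, one with positive curvature (no descending crossing)
  b <- rbind(c(0.4, 2, -0.5), c(0.4, 0.1, 0.2))
  post <- fake_posterior(b)
  lc <- lethal_concentration(post, 0.5, 6)
  expect_equal(lc$fraction_defined, 0.5)
  sl <- stimulation_limit(post, 6)
  expect_equal(sl$fraction_defined, 0.5)
  # linear form refuses curvature-only metrics
  post_lin <- fake_posterior(matrix(c(0, -1), 1), form = "linear")
  expect_error(stimulation_limit(post_lin, 6), "quadratic")
  expect_error(peak_concentration(post_lin, 6), "quadratic")
  expect_error(lethal_concentration(post, 1.5, 6), "must be in")
})
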