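test_that("AICc comparison flags equivalent fits and refuses REML", {
  set.seed(1)
  d <- data.frame(y = rnorm(40), x = rnorm(40),
                  g = factor(rep(1:8, each = 5)))
  f <- fit_lmm(y ~ x, d, "g", REML = FALSE)
  cmp <- aicc_compare(list(a = f, b = f))
  expect_equal(cmp$daicc, c(0, 0))
  expect_true(all(cmp$equivalent))
  expect_error(aicc_compare(list(fit_lmm(y ~ x, d, "g", REML = TRUE), f)),
               "ML")
  # AICc approaches AIC as n grows relative to k
  expect_equal(aicc(-10, 3, 1e6), -2 * -10 + 6, tolerance = 1e-4)
  expect_true(is.na(aicc(-10, 5, 6)))
})

test_that("OLRE binomial GLMM matches a Gauss-Hermite quadrature oracle", {
  set.seed(14)
  n <- 60
  x <- runif(n, 0, 4)
  u <- rnorm(n, 0, 0.7)
  size <- rep(20, n)
  y <- rbinom(n, size, plogis(-0.5 + 0.4 * x + u))
  d <- data.frame(y = y, size = size, x = x)
  fit <- fit_binomial_glmm(cbind(y, size - y) ~ x, d, grouping = "olre")
  orc <- ghq_olre_binomial(y, size, cbind(1, x), n_nodes = 20)
  expect_lt(max(abs(fit$coefficients$estimate - orc$beta)), 1e-3)
  expect_lt(abs(sqrt(fit$re_variance[[1]]) - orc$sigma), 2e-2)
})

test_that("GLMM without overdispersion collapses to the plain GLM", {
  set.seed(2)
  n <- 200
  x <- runif(n, 0, 4)
  y <- rbinom(n, 20, plogis(0.3 - 0.4 * x))
  d <- data.frame(y = y, size = 20, x = x)
  mm <- fit_binomial_glmm(cbind(y, size - y) ~ x, d, grouping = "olre")
  gg <- glm(cbind(y, 20 - y) ~ x, binomial(), data = d)
  expect_lt(max(abs(mm$coefficients$estimate - coef(gg))), 1e-2)
  expect_lt(mm$re_variance[[1]], 5e-2)
})

test_that("balanced LMM reproduces closed-form one-way ANOVA estimators", {
  set.seed(4)
  g <- 12; m <- 6
  tank <- factor(rep(1:g, each = m))
  u <- rnorm(g, 0, 0.8)
  y <- 2 + u[as.integer(tank)] + rnorm(g * m, 0, 0.5)
  d <- data.frame(y = y, tank = tank)
  fit <- fit_lmm(y ~ 1, d, "tank", REML = TRUE)
  # closed forms for the balanced one-way random-effects model
  ms <- anova(aov(y ~ tank, data = d))
  msa <- ms$`Mean Sq`[1]; mse <- ms$`Mean Sq`[2]
  expect_equal(fit$coefficients$estimate[1], mean(y), tolerance = 1e-6)
  expect_equal(unname(fit$re_variance[[1]]), (msa - mse) / m,
               tolerance = 1e-5)
  s2 <- attr(lme4::VarCorr(fit$fit), "sc")^2
  expect_equal(unname(s2), mse, tolerance = 1e-5)
})

test_that("LMM recovers a known slope with near-nominal CI coverage", {
  set.seed(6)
  hits <- 0
  for (r in 1:40) {
    tank <- factor(rep(1:15, each = 8))
    x <- rep(runif(15, 0, 5), each = 8)
    y <- 1 + 0.2 * x + rnorm(15, 0, 0.5)[as.integer(tank)] +
      rnorm(120, 0, 0.4)
    fit <- fit_lmm(y ~ x, data.frame(y, x, tank), "tank")
    cf <- fit$coefficients
    b <- cf$estimate[cf$term == "x"]; se <- cf$se[cf$term == "x"]
    hits <- hits + (b - 1.96 * se <= 0.2 && 0.2 <= b + 1.96 * se)
  }
  expect_gte(hits / 40, 0.85)
})

test_that("one-way ANOVA with Tukey matches the two-group t-test", {
  set.seed(9)
  y <- c(rnorm(12, 0), rnorm(12, 0.8))
  g <- factor(rep(c("a", "b"), each = 12))
  out <- anova_tukey(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(out$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$p, tt$p.value, tolerance = 1e-10)
  expect_equal(out$df, c(1, 22))
  # degenerate identical data take the p = 1 path
  flat <- suppressWarnings(
    anova_tukey(rep(1, 10), factor(rep(c("a", "b"), each = 5))))
  expect_equal(flat$p, 1)
  expect_error(anova_tukey(1:3, factor(c("a", "a", "b"))), ">= 2 obs")
})

test_that("Kruskal-Wallis handles ties and degenerate input", {
  out <- kruskal_wallis(c(1, 2, 3, 4, 5, 6),
                        factor(rep(c("a", "b"), 3)))
  ref <- kruskal.test(c(1, 2, 3, 4, 5, 6), factor(rep(c("a", "b"), 3)))
  expect_equal(out$H, unname(ref$statistic))
  flat <- kruskal_wallis(rep(2, 10), factor(rep(c("a", "b"), each = 5)))
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)
})

test_that("Kruskal-Wallis type-I error is near nominal", {
  set.seed(10)
  rej <- mean(replicate(1500, {
    kruskal_wallis(rnorm(30), factor(rep(1:6, each = 5)))$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("BCa interval matches boot and degenerates sensibly", {
  skip_if_not_installed("boot")
  set.seed(12)
  v <- rlnorm(25, 0, 0.8)
  ours <- bca_bootstrap_ci(v, mean, B = 8000, seed = 3)
  bb <- boot::boot(v, function(d, i) mean(d[i]), R = 8000)
  ci <- boot::boot.ci(bb, type = "bca")$bca[4:5]
  expect_equal(ours$estimate, mean(v))
  expect_lt(abs(ours$low - ci[1]), 0.12 * sd(v))
  expect_lt(abs(ours$high - ci[2]), 0.12 * sd(v))

  const <- bca_bootstrap_ci(rep(2.5, 10), mean, B = 1000, seed = 1)
  expect_equal(c(const$low, const$high), c(2.5, 2.5))

  # symmetric data: BCa close to the raw percentile interval
  set.seed(13)
  z <- rnorm(1e4)
  b <- bca_bootstrap_ci(z, mean, B = 2000, seed = 2)
  expect_lt(abs(b$z0), 0.05)
  expect_lt(abs(b$a), 0.01)
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(0.3), 0.3)
  set.seed(15)
  for (r in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_bonferroni(p)
    # direct definition: sorted cumulative max of (m - j + 1) p_(j)
    m <- length(p)
    o <- order(p)
    direct <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))[order(o)]
    expect_equal(adj, direct)
    expect_true(all(adj >= p))
    sh <- sample(m)
    expect_equal(holm_bonferroni(p[sh]), adj[sh])
  }
})

test_that("sex-ratio model filters to sexable stages and finds no effect", {
  set.seed(16)
  n <- 400
  d <- data.frame(tank_id = factor(rep(1:20, each = 20)),
                  conc = rep(c(0, 74, 147, 291, 579), each = 80),
                  gosner = runif(n, 30, 46),
                  sex = sample(c("F", "M"), n, replace = TRUE))
  fit <- fit_sex_ratio_glmm(d)
  expect_equal(fit$n, sum(d$gosner >= 36))
  cf <- fit$coefficients
  b <- cf$estimate[cf$term == "x"]; se <- cf$se[cf$term == "x"]
  expect_lt(abs(b / se), 3) # no fabricated diquat effect under the null
  # boundary: stage 35 out, stage 36 in
  d2 <- data.frame(tank_id = factor(c(1, 1, 2, 2)),
                   conc = c(0, 0, 10, 10), gosner = c(35, 36, 35.9, 36.1),
                   sex = c("F", "M", "F", "M"))
  fit2 <- suppressWarnings(fit_sex_ratio_glmm(d2))
  expect_equal(fit2$n, 2)
})

test_that("conditional predictions invert the link at zero random effect", {
  set.seed(17)
  d <- data.frame(y = rbinom(80, 15, 0.7), size = 15,
                  x = runif(80, 0, 3))
  fit <- fit_binomial_glmm(cbind(y, size - y) ~ x, d, grouping = "olre")
  pr <- predict_conditional(fit, data.frame(x = c(0, 2)))
  cf <- fit$coefficients$estimate
  expect_equal(pr$fit, plogis(cf[1] + cf[2] * c(0, 2)), tolerance = 1e-8)
  expect_true(all(pr$lwr <= pr$fit & pr$fit <= pr$upr))
})
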