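test_that("Shannon index matches hand computation", {
  expect_equal(shannon_index(rep(25, 4)), log(4))
  expect_equal(shannon_index(c(0, 300, 0)), 0)
  expect_equal(shannon_index(c(300, 100)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_error(shannon_index(c(0, 0)), "all-zero")
  expect_error(shannon_index(c(-1, 5)), "negative")
  # the uniform profile maximizes H for a fixed number of taxa
  set.seed(1)
  for (r in 1:20) {
    k <- sample(3:10, 1)
    expect_lte(shannon_index(rgamma(k, 2)), log(k) + 1e-12)
  }
})

test_that("Bray-Curtis matches hand computation and is a proper index", {
  m <- rbind(a = c(2, 0), b = c(1, 1))
  expect_equal(as.vector(bray_curtis(m)), 0.5)
  m <- rbind(a = c(5, 3, 2), b = c(5, 3, 2))
  expect_equal(as.vector(bray_curtis(m)), 0)
  m <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(as.vector(bray_curtis(m)), 1)
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 2))), "zero total")
  set.seed(2)
  for (r in 1:10) {
    m <- matrix(rpois(60, 5) + 1, 6)
    d <- as.matrix(bray_curtis(m))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("NMDS recovers an exact planar configuration with ~zero stress", {
  set.seed(3)
  pts <- matrix(rnorm(24), ncol = 2)
  d <- dist(pts)
  ord <- suppressWarnings(nmds(d, k = 2, n_starts = 10, seed = 1))
  expect_lt(ord$stress, 1e-3)
  # stress is reproduced by an independent stress-1 computation
  expect_lt(stress1_recompute(ord$coordinates, d), 1e-3)
})

test_that("NMDS stress agrees with its definition on noisy data", {
  set.seed(4)
  m <- matrix(rpois(11 * 8, 8), 11)
  d <- bray_curtis(m + 1)
  ord <- suppressWarnings(nmds(d, k = 2, n_starts = 20, seed = 2))
  expect_equal(ord$stress, stress1_recompute(ord$coordinates, d),
               tolerance = 1e-3)
  expect_gte(ord$stress, 0)
})

test_that("PERMANOVA on Euclidean distances equals classical ANOVA F", {
  set.seed(5)
  y <- c(rnorm(8, 0), rnorm(8, 1.2))
  g <- factor(rep(c("a", "b"), each = 8))
  pv <- permanova(dist(y), g, n_perm = 199, seed = 1)
  an <- anova(aov(y ~ g))
  expect_equal(pv$F, an$`F value`[1], tolerance = 1e-10)
  expect_equal(pv$R2,
               an$`Sum Sq`[1] / sum(an$`Sum Sq`), tolerance = 1e-10)
})

test_that("PERMANOVA p-values respect permutation resolution and inputs", {
  set.seed(6)
  m <- matrix(rpois(14 * 6, 6) + 1, 14)
  g <- factor(rep(c("a", "b"), each = 7))
  pv <- permanova(bray_curtis(m), g, n_perm = 99, seed = 2)
  expect_gte(pv$p, 1 / 100)
  expect_true(pv$R2 >= 0 && pv$R2 <= 1)
  expect_error(permanova(bray_curtis(m), factor(c("a", rep("b", 13))),
                         n_perm = 99), "singleton")
})

test_that("dispersion test flags a constructed spread difference only", {
  set.seed(7)
  a <- matrix(rnorm(10 * 3), 10)
  b <- matrix(rnorm(10 * 3), 10) * 4
  g <- factor(rep(c("a", "b"), each = 10))
  out <- dispersion_homogeneity(dist(rbind(a, b)), g, n_perm = 199,
                                seed = 1)
  expect_lt(out$p, 0.05)
  expect_gt(out$dispersions[["b"]], out$dispersions[["a"]])
  same <- dispersion_homogeneity(
    dist(rbind(a, matrix(rnorm(10 * 3), 10))), g, n_perm = 199, seed = 2)
  expect_gt(same$p, 0.05)
})

test_that("dominance share aggregates exactly on constructed data", {
  m <- rbind(t1 = c(40, 40, 20), t2 = c(90, 0, 10))
  colnames(m) <- c("tol1", "tol2", "other")
  trt <- c("ctl", "high")
  sh <- dominance_share(m, c("tol1", "tol2"), trt)
  expect_equal(sh[["ctl"]], 0.8)
  expect_equal(sh[["high"]], 0.9)
  expect_equal(unname(dominance_share(m, character(0), trt)), c(0, 0))
  single <- matrix(c(10, 20), 2, dimnames = list(NULL, "only"))
  expect_equal(unname(dominance_share(single, "only", c("a", "b"))),
               c(1, 1))
  expect_error(dominance_share(m, "missing_taxon", trt), "missing_taxon")
})

test_that("diversity contrasts match the emmeans delta-method oracle", {
  skip_if_not_installed("emmeans")
  set.seed(8)
  trt <- factor(rep(c("0", "74", "147"), times = 10))
  day <- factor(rep(c("0", "7"), each = 15))
  H <- rnorm(30, 1.5, 0.2) - 0.5 * (trt != "0") * (day == "7")
  out <- diversity_lm_contrasts(H, trt, day)
  em <- emmeans::emmeans(out$model, ~ treatment | day)
  ec <- as.data.frame(emmeans::contrast(em, method = "trt.vs.ctrl",
                                        ref = 1))
  for (r in seq_len(nrow(out$contrasts))) {
    row <- out$contrasts[r, ]
    match_row <- ec[ec$day == row$day &
                      ec$contrast == paste0("treatment", row$treatment,
                                            " - treatment0"), ]
    expect_equal(row$estimate, match_row$estimate, tolerance = 1e-8)
    expect_equal(row$se, match_row$SE, tolerance = 1e-8)
  }
})

test_that("interaction-free data give identical contrasts across days", {
  trt <- factor(rep(c("0", "74", "147"), times = 8))
  day <- factor(rep(c("0", "7"), each = 12))
  # purely additive construction, no noise
  H <- 2 + 0.3 * (trt == "74") - 0.2 * (trt == "147") + 0.1 * (day == "7")
  out <- suppressWarnings(diversity_lm_contrasts(H, trt, day))$contrasts
  for (tr in c("74", "147")) {
    e <- out$estimate[out$treatment == tr]
    expect_equal(e[1], e[2], tolerance = 1e-10)
  }
})

test_that("chlorophyll-biomass fit reports the squared correlation", {
  set.seed(9)
  chl <- runif(40, 1, 50)
  bio <- 3 * chl + rnorm(40, 0, 20)
  out <- chlorophyll_biomass_lm(bio, chl)
  expect_equal(out$r_squared, cor(bio, chl)^2, tolerance = 1e-10)
  expect_lt(out$p, 0.01)
})
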