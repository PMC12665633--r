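test_that("beta solver inverts the closed-form toxicity metrics", {
  b <- solve_beta_from_metrics(0.5, 1, 8)
  expect_equal(unname(b["b0"]), 0)
  expect_lt(b["b2"], 0)
  # round trip through the derived-metric closed forms
  post <- fake_posterior(matrix(b, 1))
  pk <- peak_concentration(post, 6)
  expect_equal(pk$median[pk$metric == "peak_conc"], 1, tolerance = 1e-9)
  expect_equal(lethal_concentration(post, 0.5, 6)$median, 8,
               tolerance = 1e-9)
  # an LC50 at the implied stimulation limit is geometrically impossible
  expect_error(solve_beta_from_metrics(0.5, 1, 3), "stimulation limit")

  # defaults: implied stimulation limit is (10 + 1)^2 - 1 = 120 ug/L
  b6 <- solve_beta_from_metrics(0.60, 10, 155)
  expect_lt(b6["b2"], 0)
  post6 <- fake_posterior(matrix(b6, 1))
  expect_equal(stimulation_limit(post6, 6)$median, 120, tolerance = 1e-9)
  expect_equal(lethal_concentration(post6, 0.5, 6)$median, 155,
               tolerance = 1e-9)

  # no hormesis limit: c_peak = 0 collapses to a monotone logistic
  b0 <- solve_beta_from_metrics(0.5, 0, 100)
  expect_equal(unname(b0["b2"]), 0)
  expect_lt(b0["b1"], 0)

  # infeasible: LC50 below the implied stimulation limit
  expect_error(solve_beta_from_metrics(0.6, 10, 100), "stimulation limit")
})

test_that("the generator is deterministic under its seed", {
  a <- simulate_experiment(sim_config(seed = 11, replicates = 2,
                                      tadpoles_per_tank = 3))
  b <- simulate_experiment(sim_config(seed = 11, replicates = 2,
                                      tadpoles_per_tank = 3))
  expect_identical(a, b)
  c <- simulate_experiment(sim_config(seed = 12, replicates = 2,
                                      tadpoles_per_tank = 3))
  expect_false(identical(a$amphipods$n_alive, c$amphipods$n_alive))
})

test_that("generated datasets satisfy every data-model invariant", {
  for (s in 1:3) {
    ds <- simulate_experiment(sim_config(seed = 20 + s))
    expect_equal(nrow(validate_dataset(ds)$errors), 0)
  }
  ds0 <- simulate_null_experiment(sim_config(seed = 30))
  expect_equal(nrow(validate_dataset(ds0)$errors), 0)
})

test_that("generator moments match the configured study conditions", {
  # large control-only design: observed weekly survival near 82/67/60%
  cf <- sim_config(nominal = 0, replicates = 400, dt50 = numeric(0),
                   growth_log2_effect = 0, tadpoles_per_tank = 0,
                   seed = 41)
  ds <- simulate_experiment(cf)
  am <- ds$amphipods
  for (w in c(2, 4, 6)) {
    obs_mean <- mean(am$n_alive[am$week == w] / am$n_atrisk[am$week == w])
    # the logit-normal tank effect shrinks the mean slightly toward 1/2
    target <- mean(plogis(qlogis(cf$surv_p0[[as.character(w)]]) +
                            rnorm(1e5, 0, cf$sigma_tank)))
    expect_lt(abs(obs_mean - target), 0.015)
  }

  # percent-of-nominal moment at the default design
  ds <- simulate_experiment(sim_config(seed = 42))
  ch <- merge(ds$chemistry, ds$tanks[, c("tank_id", "nominal_conc")])
  at1 <- ch[ch$day == 0 & ch$nominal_conc > 0, ]
  pct <- 100 * at1$value / at1$nominal_conc
  expect_equal(length(pct), 25)
  expect_lt(abs(mean(pct) - 84), 3 * 100 * 0.10 / sqrt(25))

  # amphipod survival is cumulative across check weeks within a cage
  am <- ds$amphipods
  wide <- reshape(am[, c("cage_id", "week", "n_alive")],
                  idvar = "cage_id", timevar = "week", direction = "wide")
  expect_true(all(wide$n_alive.4 <= wide$n_alive.2))
  expect_true(all(wide$n_alive.6 <= wide$n_alive.4))
})

test_that("day-21 detection contract: low treatments censored, top two not", {
  ds <- simulate_experiment(sim_config(seed = 43))
  ch <- merge(ds$chemistry, ds$tanks[, c("tank_id", "nominal_conc")])
  d21 <- detection_status_table(ch, 21)
  low <- d21$nominal_conc %in% c(0, 74, 147, 291)
  expect_true(all(d21$n_detected[low] == 0))
  expect_true(all(d21$n_detected[!low] > 0))
})

test_that("the null generator removes every treatment effect", {
  cf <- sim_config(seed = 44)
  ds <- simulate_null_experiment(cf)
  am <- merge(ds$amphipods, ds$tanks[, c("tank_id", "nominal_conc")])
  # week-6 survival unrelated to treatment (compare extremes, generous MC margin)
  s_ctl <- mean(am$n_alive[am$week == 6 & am$nominal_conc == 0]) / 20
  s_top <- mean(am$n_alive[am$week == 6 & am$nominal_conc == 1153]) / 20
  expect_lt(abs(s_ctl - s_top), 0.25)
  # composition share of the tolerant taxa is flat across treatments
  m <- community_matrix(ds, 7)
  sh <- dominance_share(m, c("Chlorella_spp", "Scenedesmus_quadricauda"),
                        factor(attr(m, "treatment")))
  expect_lt(max(sh) - min(sh), 0.25)
})
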