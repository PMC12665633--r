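#' Run the full mesocosm analysis pipeline
#'
#' Executes the analysis stages in dependency order over a validated
#' dataset and returns a bundle of result tables: exposure fate
#' (percent-of-nominal, dissipation fits, detection status), the amphipod
#' hormetic survival model with derived toxicity metrics and optional
#' exact-LOO model comparison, amphipod growth/reproduction, tadpole
#' endpoint models, and phytoplankton community analytics. One global seed
#' deterministically spawns per-stage substreams so skipping a stage never
#' perturbs another stage's randomness.
#'
#' @param ds a `mesotox_dataset` that passes [validate_dataset()] with zero
#'   errors.
#' @param stages subset of `c("chemistry", "amphipods", "tadpoles",
#'   "algae")`.
#' @param seed global seed.
#' @param mcmc list overriding MCMC settings (`chains`, `warmup`, `iter`).
#' @param run_loo run the exact leave-one-out model comparison (the
#'   slowest stage component).
#' @param loo_mcmc list of reduced MCMC settings for the LOO refits
#'   (`chains`, `warmup`, `iter`).
#' @param n_perm permutations for PERMANOVA / dispersion tests.
#' @return named list of stage results (class `mesotox_results`); each
#'   element holds the fitted objects and flat summary tables ready for
#'   [write_results()].
#' @export
run_pipeline <- function(ds, stages = c("chemistry", "amphipods",
                                        "tadpoles", "algae"),
                         seed = 1, mcmc = list(), run_loo = FALSE,
                         loo_mcmc = list(chains = 2, warmup = 2000,
                                         iter = 3000),
                         n_perm = 999) {
  stages <- match.arg(stages, several.ok = TRUE)
  v <- validate_dataset(ds)
  if (nrow(v$errors) > 0)
    stop("dataset failed validation with ", nrow(v$errors),
         " error(s); see validate_dataset()")
  # independent substream per stage: stage results do not depend on which
  # other stages run
  stage_seed <- function(stage)
    seed * 131L + match(stage, c("chemistry", "amphipods", "tadpoles",
                                 "algae"))
  out <- list()

  if ("chemistry" %in% stages)
    out$chemistry <- .stage_chemistry(ds)
  if ("amphipods" %in% stages)
    out$amphipods <- .stage_amphipods(ds, stage_seed("amphipods"), mcmc,
                                      run_loo, loo_mcmc)
  if ("tadpoles" %in% stages)
    out$tadpoles <- .stage_tadpoles(ds, stage_seed("tadpoles"))
  if ("algae" %in% stages)
    out$algae <- .stage_algae(ds, stage_seed("algae"), n_perm)
  structure(out, class = "mesotox_results")
}

.stage_chemistry <- function(ds) {
  tk <- ds$tanks
  ch <- merge(ds$chemistry, tk[, c("tank_id", "nominal_conc")],
              by = "tank_id")
  at1h <- ch[ch$day == 0 & ch$nominal_conc > 0, ]
  pon <- suppressWarnings(
    percent_of_nominal(at1h$value, at1h$nominal_conc))
  fits <- list()
  for (trt in sort(unique(ch$nominal_conc[ch$nominal_conc > 0]))) {
    sub <- ch[ch$nominal_conc == trt, ]
    fit <- tryCatch(
      fit_dissipation(sub$day, sub$value, sub$below_detection),
      error = function(e) NULL)
    if (!is.null(fit))
      fits[[length(fits) + 1]] <- data.frame(
        nominal_conc = trt, k_per_day = fit$k, dt50_days = fit$DT50,
        n_used = fit$n_used, n_censored = fit$n_censored,
        r_squared = fit$r_squared)
  }
  detect21 <- tryCatch(detection_status_table(ch, 21),
                       error = function(e) NULL)
  list(percent_of_nominal = pon,
       summary = data.frame(mean_pct_nominal = pon$mean,
                            se_pct_nominal = pon$se, n = pon$n,
                            min_pct = pon$min, max_pct = pon$max),
       dissipation = do.call(rbind, fits),
       detection_day21 = detect21)
}

.stage_amphipods <- function(ds, seed, mcmc, run_loo, loo_mcmc) {
  set.seed(seed)
  obs <- survival_observations(ds)
  spec <- do.call(hormesis_model_spec, mcmc)
  fit <- NULL
  for (attempt in 1:3) { # escalate chain length if the Rhat gate trips
    spec_a <- spec
    spec_a$warmup <- spec$warmup * 2^(attempt - 1)
    spec_a$iter <- spec$iter * 2^(attempt - 1)
    fit <- tryCatch(fit_hormetic_model(obs, spec_a),
                    mesotox_convergence_error = function(e) e)
    if (!inherits(fit, "condition")) break
  }
  if (inherits(fit, "condition")) stop(fit)
  metrics <- do.call(rbind, lapply(fit$weeks, function(w)
    derived_metrics(fit, w)))
  ctrl_obs <- obs[obs$conc == 0, ]
  observed_control <- aggregate(
    cbind(surv = ctrl_obs$n_alive / ctrl_obs$n_atrisk) ~ week,
    data = ctrl_obs, FUN = mean)

  loo <- NULL
  if (run_loo) {
    specs <- list(quadratic = hormesis_model_spec("quadratic"),
                  linear = hormesis_model_spec("linear"),
                  null = hormesis_model_spec("null"))
    loo <- do.call(exact_loo_compare,
                   c(list(obs = obs, specs = specs), loo_mcmc))
  }

  am6 <- ds$amphipods[ds$amphipods$week == 6, ]
  am6 <- merge(am6, ds$tanks[, c("tank_id", "nominal_conc",
                                 "initial_measured_conc")], by = "tank_id")
  growth <- am6[!is.na(am6$growth_mg), ]
  growth_test <- if (nrow(growth) > 0 &&
                     length(unique(growth$nominal_conc)) >= 2)
    anova_tukey(log2(growth$growth_mg), factor(growth$nominal_conc))
  else NULL

  repro <- am6[am6$n_alive > 0 & !is.na(am6$n_juveniles), ]
  repro_cmp <- NULL
  if (nrow(repro) > 3) {
    repro$x <- transform_concentration(repro$initial_measured_conc)
    f1 <- fit_binomial_glmm(
      cbind(n_juveniles, n_alive) ~ x, repro, grouping = "olre")
    f0 <- fit_binomial_glmm(
      cbind(n_juveniles, n_alive) ~ 1, repro, grouping = "olre")
    repro_cmp <- aicc_compare(list(treatment = f1, null = f0))
  }
  list(fit = fit, derived_metrics = metrics,
       observed_control_survival = observed_control, loo = loo,
       growth_anova = growth_test, reproduction_aicc = repro_cmp)
}

.stage_tadpoles <- function(ds, seed) {
  set.seed(seed)
  td <- merge(ds$tadpoles,
              ds$tanks[, c("tank_id", "initial_measured_conc")],
              by = "tank_id")
  td$x <- transform_concentration(td$initial_measured_conc)
  td$surv <- as.integer(td$survived)

  ml_fit <- function(f) fit_binomial_glmm(f, td, grouping = "tank_id")
  surv_fits <- list(null = ml_fit(cbind(surv, 1 - surv) ~ 1),
                    linear = ml_fit(cbind(surv, 1 - surv) ~ x),
                    quadratic = ml_fit(cbind(surv, 1 - surv) ~ x + I(x^2)))
  surv_cmp <- aicc_compare(surv_fits)
  # conditional predictions come from the better dose-response shape; the
  # AICc table says whether the no-effect model is competitive
  dose_cmp <- surv_cmp[surv_cmp$model != "null", ]
  best <- surv_fits[[dose_cmp$model[1]]]
  nd <- data.frame(x = c(0, max(td$x)))
  surv_pred <- predict_conditional(best, nd)

  alive <- td[td$survived & !is.na(td$gosner), ]
  alive$dev_rate <- (alive$gosner - 25) / alive$days_elapsed
  alive$log2_dev <- log2(alive$dev_rate)
  alive$treated <- as.integer(alive$initial_measured_conc > 0)
  # the development response may follow the dose log-linearly or jump for
  # any exposure; compare both shapes (and a null) by ML AICc and report
  # conditional predictions from the best
  dev_ml <- list(
    null = fit_lmm(log2_dev ~ 1, alive, grouping = "tank_id", REML = FALSE),
    linear = fit_lmm(log2_dev ~ x, alive, grouping = "tank_id",
                     REML = FALSE),
    step = fit_lmm(log2_dev ~ treated, alive, grouping = "tank_id",
                   REML = FALSE))
  dev_cmp <- aicc_compare(dev_ml)
  dev_form <- switch(dev_cmp$model[1], null = log2_dev ~ 1,
                     linear = log2_dev ~ x, step = log2_dev ~ treated)
  dev_fit <- fit_lmm(dev_form, alive, grouping = "tank_id")
  dev_nd <- data.frame(x = c(0, max(td$x)), treated = c(0L, 1L))
  dev_pred <- predict_conditional(dev_fit, dev_nd)

  alive$log2_mass <- log2(alive$mass_g)
  alive$gs <- alive$gosner - 25
  mass_fit <- fit_lmm(log2_mass ~ x + gs + I(gs^2), alive,
                      grouping = "tank_id")
  bx <- mass_fit$coefficients
  b <- bx$estimate[bx$term == "x"]
  se <- bx$se[bx$term == "x"]
  mass_effect <- data.frame(
    log2_coef = b, pct_per_doubling = 100 * (2^b - 1),
    pct_low = 100 * (2^(b - 1.96 * se) - 1),
    pct_high = 100 * (2^(b + 1.96 * se) - 1))

  alive$hsi <- 100 * alive$liver_g / alive$mass_g
  alive$log2_hsi <- log2(alive$hsi)
  hsi_fit <- fit_lmm(log2_hsi ~ x + gs + I(gs^2), alive,
                     grouping = "tank_id")

  sex_fit <- tryCatch(fit_sex_ratio_glmm(
    data.frame(tank_id = alive$tank_id, conc = alive$initial_measured_conc,
               gosner = alive$gosner, sex = alive$sex)),
    error = function(e) NULL)

  stress <- merge(ds$stress, ds$tanks[, c("tank_id", "nominal_conc")],
                  by = "tank_id")
  stress_tests <- if (nrow(stress) > 0) list(
    hne = kruskal_wallis(stress$hne_ug_g, factor(stress$nominal_conc)),
    protein_carbonyl = kruskal_wallis(stress$protein_carbonyl_nmol_mg,
                                      factor(stress$nominal_conc)),
    hne_ci = bca_bootstrap_ci(stress$hne_ug_g, seed = seed),
    protein_carbonyl_ci = bca_bootstrap_ci(
      stress$protein_carbonyl_nmol_mg, seed = seed + 1)) else NULL

  list(survival_aicc = surv_cmp, survival_fits = surv_fits,
       survival_pred = surv_pred, overall_survival = mean(td$surv),
       dev_fit = dev_fit, dev_model_aicc = dev_cmp,
       dev_pred_log2 = dev_pred,
       dev_rates = data.frame(
         group = c("control", "top"),
         rate = 2^dev_pred$fit, low = 2^dev_pred$lwr, high = 2^dev_pred$upr),
       mass_fit = mass_fit, mass_effect = mass_effect, hsi_fit = hsi_fit,
       sex_fit = sex_fit, stress = stress_tests)
}

.stage_algae <- function(ds, seed, n_perm) {
  set.seed(seed)
  days <- sort(unique(ds$algae$day))
  per_day <- list()
  div_rows <- list()
  for (d in days) {
    m <- community_matrix(ds, d)
    trt <- factor(attr(m, "treatment"))
    dist <- bray_curtis(m)
    disp <- dispersion_homogeneity(dist, trt, n_perm = n_perm,
                                   seed = seed + d)
    pmv <- permanova(dist, trt, n_perm = n_perm, seed = seed + d)
    ord <- nmds(dist, k = 2, n_starts = 30, seed = seed + d)
    tx <- c("Chlorella_spp", "Scenedesmus_quadricauda")
    dom <- if (all(tx %in% colnames(m)))
      dominance_share(m, tx, trt) else NULL
    per_day[[as.character(d)]] <- list(
      permanova = pmv, dispersion = disp, nmds = ord, dominance = dom)
    H <- apply(m, 1, shannon_index)
    div_rows[[as.character(d)]] <- data.frame(
      tank_id = rownames(m), day = d, treatment = as.character(trt),
      shannon = H)
  }
  div <- do.call(rbind, div_rows)
  contrasts <- diversity_lm_contrasts(div$shannon, div$treatment,
                                      factor(div$day))
  chl <- merge(
    aggregate(biomass_mg_m3 ~ tank_id + day, data = ds$algae, FUN = sum),
    ds$chlorophyll, by = c("tank_id", "day"))
  chl_lm <- if (nrow(chl) > 3)
    chlorophyll_biomass_lm(chl$biomass_mg_m3, chl$chl_ug_l) else NULL

  perm_table <- do.call(rbind, lapply(names(per_day), function(d)
    data.frame(day = as.numeric(d), F = per_day[[d]]$permanova$F,
               R2 = per_day[[d]]$permanova$R2, p = per_day[[d]]$permanova$p,
               dispersion_p = per_day[[d]]$dispersion$p,
               nmds_stress = per_day[[d]]$nmds$stress)))
  list(per_day = per_day, permanova_table = perm_table,
       diversity = div, diversity_contrasts = contrasts,
       chlorophyll_biomass = chl_lm)
}

#' Flatten pipeline results into writeable tables
#'
#' @param res a `mesotox_results` object from [run_pipeline()].
#' @return named list of data frames for [write_results()].
#' @export
results_tables <- function(res) {
  out <- list()
  if (!is.null(res$chemistry)) {
    out$fate_summary <- res$chemistry$summary
    if (!is.null(res$chemistry$dissipation))
      out$dissipation_fits <- res$chemistry$dissipation
  }
  if (!is.null(res$amphipods)) {
    out$derived_metrics <- res$amphipods$derived_metrics
    out$lcx_estimates <- res$amphipods$derived_metrics[
      grepl("^LC", res$amphipods$derived_metrics$metric), ]
    if (!is.null(res$amphipods$loo)) out$loo_table <- res$amphipods$loo$table
    if (!is.null(res$amphipods$reproduction_aicc))
      out$reproduction_aicc <- res$amphipods$reproduction_aicc
  }
  if (!is.null(res$tadpoles)) {
    out$tadpole_survival_aicc <- res$tadpoles$survival_aicc
    out$tadpole_dev_rates <- res$tadpoles$dev_rates
    out$tadpole_mass_effect <- res$tadpoles$mass_effect
  }
  if (!is.null(res$algae)) {
    out$permanova_table <- res$algae$permanova_table
    out$diversity <- res$algae$diversity
    out$diversity_contrasts <- res$algae$diversity_contrasts$contrasts
  }
  out
}
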