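#' Solve quadratic-logit coefficients from toxicity metrics
#'
#' Inverts the hormetic survival curve: given control survival `p0`, the
#' peak (hormetic) concentration `c_peak` and the LC50 defined relative to
#' control, returns `(b0, b1, b2)` with `b0 = logit(p0)`,
#' `x_peak = -b1 / (2 b2)` and `b0 + b1 x50 + b2 x50^2 = logit(p0 / 2)`
#' where `x = log2(c + 1)`. The returned coefficients reproduce the inputs
#' through [peak_concentration()] and [lethal_concentration()].
#'
#' @param p0 control survival probability in (0, 1).
#' @param c_peak concentration of peak survival (ug/L); 0 collapses to a
#'   monotone logistic curve.
#' @param lc50 concentration halving survival relative to control (ug/L);
#'   must exceed the implied stimulation limit `(c_peak + 1)^2 - 1`.
#' @return named vector `c(b0, b1, b2)`.
#' @export
solve_beta_from_metrics <- function(p0, c_peak, lc50) {
  stopifnot(p0 > 0, p0 < 1, c_peak >= 0, lc50 > c_peak)
  p0 <- unname(p0); c_peak <- unname(c_peak); lc50 <- unname(lc50)
  b0 <- qlogis(p0)
  if (is.infinite(lc50)) return(c(b0 = b0, b1 = 0, b2 = 0))
  xp <- transform_concentration(c_peak)
  x50 <- transform_concentration(lc50)
  if (xp == 0) { # no hormesis: monotone logistic through the LC50
    return(c(b0 = b0, b1 = (qlogis(p0 / 2) - b0) / x50, b2 = 0))
  }
  den <- x50^2 - 2 * xp * x50
  if (den <= 0)
    stop("no hormetic solution: lc50 must exceed the implied ",
         "stimulation limit (c_peak + 1)^2 - 1 = ",
         round((c_peak + 1)^2 - 1, 2), " ug/L")
  b2 <- (qlogis(p0 / 2) - b0) / den
  c(b0 = b0, b1 = -2 * b2 * xp, b2 = b2)
}

#' Configuration of the synthetic mesocosm experiment
#'
#' Defaults encode the study conditions: a control plus five diquat
#' treatments in geometric progression, five replicate tanks each, two
#' amphipod cages of 20 per tank, 15 tadpoles per tank; measured 1-h
#' concentrations averaging 84% of nominal; amphipod survival following a
#' quadratic-logit hormetic curve peaking near 10 ug/L with control
#' survival 82/67/60% and LC50 170/162/155 ug/L at weeks 2/4/6 (the week-4
#' LC50 interpolates the stated 2- and 6-week values); tadpole survival
#' rising from 77.5% (control) to 90% (top treatment) on a logit-linear
#' path; development accelerating from 0.092 to 0.333 Gosner stages/day in
#' any diquat treatment; mass increasing 2.29% per concentration doubling;
#' phytoplankton composition shifting toward two tolerant green-algae taxa
#' with increasing diquat; oxidative-stress markers unaffected.
#'
#' @param nominal nominal treatment concentrations (ug/L), first is control.
#' @param replicates tanks per treatment.
#' @param cages_per_tank,amphipods_per_cage,tadpoles_per_tank design counts.
#' @param frac_nominal_mean,frac_nominal_sd per-tank measured/nominal
#'   fraction at 1 h.
#' @param dt50 first-order dissipation half-life (days) per treatment.
#' @param detection_limit reporting detection limit (ug/L).
#' @param surv_p0 control survival per exposure week.
#' @param surv_c_peak,surv_lc50 hormetic peak and LC50 (ug/L) per week.
#' @param sigma_tank SD of tank random effects on the logit scale.
#' @param growth_ctrl_mg control wet weight per amphipod (mg) at week 6.
#' @param growth_log2_effect additive log2 growth effect per treatment.
#' @param tad_surv_ctrl,tad_surv_top tadpole survival at control and top
#'   treatment.
#' @param dev_rate_ctrl,dev_rate_trt Gosner stages/day.
#' @param mass_pct_per_doubling percent mass increase per concentration
#'   doubling.
#' @param dev_log_slope residual log-linear concentration slope of the
#'   development rate within the treated groups.
#' @param repro_log_slope log-linear concentration slope of the juvenile
#'   production rate per surviving amphipod.
#' @param algae_shift_intercept,algae_shift_slope logistic coefficients of
#'   the tolerant-taxa share against transformed dose after day 0; a zero
#'   slope removes the composition shift entirely.
#' @param algae_day41_floor minimum tolerant share at day 41 (community
#'   drift affecting the controls late in the experiment); `NA` disables.
#' @param algae_day41_atten multiplier attenuating the treated-group shift
#'   by day 41 (diversity partially converges late in the experiment).
#' @param algae_dirichlet Dirichlet concentration parameter controlling
#'   tank-to-tank compositional variability (smaller = noisier).
#' @param chl_sdlog lognormal measurement noise of chlorophyll-a around
#'   its biomass-proportional expectation.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(nominal = c(0, 74, 147, 291, 579, 1153),
                       replicates = 5,
                       cages_per_tank = 2,
                       amphipods_per_cage = 20,
                       tadpoles_per_tank = 15,
                       frac_nominal_mean = 0.84,
                       frac_nominal_sd = 0.10,
                       dt50 = c(2, 2, 2, 3.5, 3.5),
                       detection_limit = 5,
                       surv_p0 = c(`2` = 0.82, `4` = 0.67, `6` = 0.60),
                       surv_c_peak = 10,
                       surv_lc50 = c(`2` = 170, `4` = 162, `6` = 155),
                       sigma_tank = 0.3,
                       growth_ctrl_mg = 0.35,
                       growth_log2_effect = c(0, 0.55, 0.75, 0.75, 0.65, 0.6),
                       tad_surv_ctrl = 0.775,
                       tad_surv_top = 0.90,
                       dev_rate_ctrl = 0.092,
                       dev_rate_trt = 0.333,
                       mass_pct_per_doubling = 2.29,
                       dev_log_slope = 0.01,
                       repro_log_slope = 0.10,
                       algae_shift_intercept = -4.9,
                       algae_shift_slope = 0.9,
                       algae_day41_floor = 0.55,
                       algae_day41_atten = 0.85,
                       algae_dirichlet = 9,
                       chl_sdlog = 0.25,
                       seed = 1L) {
  stopifnot(nominal[1] == 0, all(nominal >= 0), replicates > 0,
            length(dt50) == length(nominal) - 1,
            all(surv_p0 > 0 & surv_p0 < 1),
            tad_surv_ctrl > 0, tad_surv_ctrl < 1,
            tad_surv_top > 0, tad_surv_top < 1,
            length(growth_log2_effect) == length(nominal))
  structure(as.list(environment()), class = "sim_config")
}

# taxon pool: two diquat-tolerant green algae first, then other greens,
# cryptophytes, diatoms, cyanobacteria
.sim_taxa <- function() {
  list(names = c("Chlorella_spp", "Scenedesmus_quadricauda",
                 "Ankistrodesmus_falcatus", "Oocystis_sp", "Pediastrum_sp",
                 "Cryptomonas_sp", "Navicula_sp", "Nitzschia_sp",
                 "Cyclotella_sp", "Microcystis_sp", "Anabaena_sp",
                 "Euglena_sp"),
       baseline = c(4, 3, 4, 3, 3, 3, 4, 3, 3, 2, 2, 2),
       tolerant = c(1, 2),
       # rough per-cell biomass (pg) differences between taxa
       cell_mass = c(30, 60, 25, 40, 120, 90, 150, 110, 80, 15, 20, 200))
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a complete mesocosm experiment
#'
#' Generates every table of the data model with the statistical structure
#' the analyses assume: chemistry with lognormal measurement noise,
#' first-order decay and censoring at the detection limit; amphipod cage
#' counts drawn binomially on the quadratic-logit hormetic curve with
#' shared tank effects; tadpole fates on a logit-linear concentration path;
#' development, mass, liver and sex outcomes; per-day algal count matrices
#' whose composition diverges with treatment after day 0; and
#' treatment-independent stress markers. Fully reproducible under the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return a `mesotox_dataset`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  n_trt <- length(cf$nominal)
  n_tank <- n_trt * cf$replicates
  trt_idx <- rep(seq_len(n_trt), each = cf$replicates)
  tank_id <- sprintf("T%02d", seq_len(n_tank))
  nominal <- cf$nominal[trt_idx]

  ## chemistry: per-tank 1-h fraction of nominal, first-order decay
  frac <- pmax(rnorm(n_tank, cf$frac_nominal_mean, cf$frac_nominal_sd), 0.3)
  conc_1h <- nominal * frac
  group_mean_1h <- tapply(conc_1h, trt_idx, mean)[as.character(trt_idx)]
  tanks <- data.frame(tank_id = tank_id, block = NA_character_,
                      nominal_conc = nominal,
                      initial_measured_conc = unname(group_mean_1h))

  all_days <- c(0, 7)
  subset_days <- c(1, 2, 4, 21, 41)
  subset_tanks <- unlist(lapply(split(tank_id, trt_idx), head, 2))
  chem <- list()
  for (i in seq_len(n_tank)) {
    days <- sort(c(all_days, if (tank_id[i] %in% subset_tanks) subset_days))
    if (nominal[i] == 0) {
      v <- rep(cf$detection_limit, length(days))
      bd <- rep(TRUE, length(days))
    } else {
      dt50 <- cf$dt50[trt_idx[i] - 1]
      noise <- ifelse(days == 0, 1, rlnorm(length(days), 0, 0.12))
      v <- conc_1h[i] * 2^(-days / dt50) * noise
      bd <- v < cf$detection_limit
      v[bd] <- cf$detection_limit
    }
    chem[[i]] <- data.frame(tank_id = tank_id[i], day = days,
                            analyte = "diquat", value = v,
                            below_detection = bd,
                            detection_limit = cf$detection_limit)
  }
  chemistry <- do.call(rbind, chem)

  ## amphipods: cumulative survival on the per-week hormetic curves
  weeks <- as.numeric(names(cf$surv_p0))
  beta <- lapply(seq_along(weeks), function(w)
    solve_beta_from_metrics(cf$surv_p0[w], cf$surv_c_peak, cf$surv_lc50[w]))
  x <- transform_concentration(group_mean_1h)
  u <- rnorm(n_tank, 0, cf$sigma_tank)
  p_week <- sapply(beta, function(b)
    plogis(b["b0"] + b["b1"] * x + b["b2"] * x^2 + u))
  amph <- list()
  for (i in seq_len(n_tank)) {
    for (cg in seq_len(cf$cages_per_tank)) {
      alive <- cf$amphipods_per_cage
      prev_p <- 1
      for (w in seq_along(weeks)) {
        # conditional survival between check weeks keeps counts monotone
        p_cond <- min(p_week[i, w] / prev_p, 1)
        alive <- rbinom(1, alive, p_cond)
        prev_p <- max(p_week[i, w], 1e-12)
        juv <- if (alive > 0)
          rpois(1, alive * exp(log(0.8) + cf$repro_log_slope * x[i] +
                                 rnorm(1, 0, 0.4))) else 0
        growth <- if (weeks[w] == 6 && alive > 0)
          2^(log2(cf$growth_ctrl_mg) + cf$growth_log2_effect[trt_idx[i]] +
               0.3 * u[i] + rnorm(1, 0, 0.15)) else NA_real_
        amph[[length(amph) + 1]] <- data.frame(
          tank_id = tank_id[i], cage_id = paste0(tank_id[i], "C", cg),
          week = weeks[w], n_atrisk = cf$amphipods_per_cage,
          n_alive = alive, n_juveniles = juv, growth_mg = growth)
      }
    }
  }
  amphipods <- do.call(rbind, amph)

  ## tadpoles
  x_top <- max(x)
  t_b0 <- qlogis(cf$tad_surv_ctrl)
  t_b1 <- (qlogis(cf$tad_surv_top) - t_b0) / x_top
  u_t <- rnorm(n_tank, 0, 0.3)
  dev_step <- log(cf$dev_rate_trt / cf$dev_rate_ctrl)
  tad <- list()
  for (i in seq_len(n_tank)) {
    p_surv <- plogis(t_b0 + t_b1 * x[i] + u_t[i])
    tank_dev <- rnorm(1, 0, 0.10)
    for (j in seq_len(cf$tadpoles_per_tank)) {
      survived <- rbinom(1, 1, p_surv) == 1
      if (!survived) {
        tad[[length(tad) + 1]] <- data.frame(
          tank_id = tank_id[i], tadpole_id = paste0(tank_id[i], "D", j),
          survived = FALSE, gosner = NA_real_, days_elapsed = NA_real_,
          mass_g = NA_real_, liver_g = NA_real_, sex = "unknown")
        next
      }
      treated <- nominal[i] > 0
      lograte <- log(cf$dev_rate_ctrl) +
        (if (treated) dev_step +
           cf$dev_log_slope * (x[i] - min(x[nominal > 0])) else 0) +
        tank_dev + rnorm(1, 0, 0.25)
      rate <- exp(lograte)
      days <- min(53, (46 - 25) / rate)
      gosner <- min(46, 25 + rate * 53)
      b_mass <- log2(1 + cf$mass_pct_per_doubling / 100)
      mass <- 2^(log2(1.1) + 0.050 * (gosner - 25) -
                   0.0010 * (gosner - 25)^2 + b_mass * x[i] +
                   0.3 * u_t[i] + rnorm(1, 0, 0.22))
      hsi <- exp(log(3) + 0.02 * (gosner - 36) + rnorm(1, 0, 0.20))
      liver <- mass * hsi / 100
      true_sex <- sample(c("F", "M"), 1)
      sex <- if (gosner >= 36) {
        if (runif(1) < 0.05) "unknown" else true_sex
      } else if (runif(1) < 0.70) "unknown" else true_sex
      tad[[length(tad) + 1]] <- data.frame(
        tank_id = tank_id[i], tadpole_id = paste0(tank_id[i], "D", j),
        survived = TRUE, gosner = gosner, days_elapsed = days,
        mass_g = mass, liver_g = liver, sex = sex)
    }
  }
  tadpoles <- if (length(tad)) do.call(rbind, tad) else
    .empty_table("tadpoles")

  ## algae: multinomial counts whose composition diverges after day 0
  tx <- .sim_taxa()
  base_p <- tx$baseline / sum(tx$baseline)
  tol_split <- c(0.55, 0.45)
  algae <- list()
  chl <- list()
  base_share <- sum(base_p[tx$tolerant])
  share_fun <- function(xv, day) {
    if (day == 0 || cf$algae_shift_slope == 0)
      return(rep(base_share, length(xv)))
    s <- plogis(cf$algae_shift_intercept + cf$algae_shift_slope * xv)
    # by day 41 the control community has drifted toward dominance and
    # the treated groups have partially converged back
    if (day == 41 && is.finite(cf$algae_day41_floor))
      pmax(cf$algae_day41_atten * s, cf$algae_day41_floor)
    else pmax(s, base_share)
  }
  for (day in c(0, 7, 41)) {
    sh <- share_fun(x, day)
    for (i in seq_len(n_tank)) {
      p <- base_p
      p[tx$tolerant] <- 0
      p <- p / sum(p) * (1 - sh[i])
      p[tx$tolerant] <- sh[i] * tol_split
      p_tank <- .rdirichlet1(p * cf$algae_dirichlet)
      n_cells <- 300 + rpois(1, 150)
      counts <- as.vector(rmultinom(1, n_cells, p_tank))
      biomass <- counts * tx$cell_mass * rlnorm(length(counts), 0, 0.2) / 50
      algae[[length(algae) + 1]] <- data.frame(
        tank_id = tank_id[i], day = day, taxon = tx$names,
        count = counts, biomass_mg_m3 = biomass)
      chl[[length(chl) + 1]] <- data.frame(
        tank_id = tank_id[i], day = day,
        chl_ug_l = 0.08 * sum(biomass) * rlnorm(1, 0, cf$chl_sdlog))
    }
  }
  algae <- do.call(rbind, algae)
  chlorophyll <- do.call(rbind, chl)

  ## oxidative stress markers: null treatment effect, skewed distributions
  stress <- data.frame(
    tank_id = tank_id,
    hne_ug_g = rlnorm(n_tank, log(323.8) - 0.79^2 / 2, 0.79),
    protein_carbonyl_nmol_mg = rlnorm(n_tank, log(1.19) - 0.36^2 / 2, 0.36))

  structure(list(tanks = tanks, chemistry = chemistry,
                 amphipods = amphipods, tadpoles = tadpoles, algae = algae,
                 chlorophyll = chlorophyll, stress = stress),
            class = "mesotox_dataset")
}

#' Simulate a null experiment (all treatment effects removed)
#'
#' As [simulate_experiment()] but with every treatment effect zeroed:
#' amphipod survival flat at the control level per week, no tadpole
#' survival/development/mass effects, no community-composition shift, no
#' growth or reproduction effects. Used by type-I-error suites.
#'
#' @param config a [sim_config()].
#' @return a `mesotox_dataset`.
#' @export
simulate_null_experiment <- function(config = sim_config()) {
  cf <- config
  cf$surv_c_peak <- 0
  cf$surv_lc50 <- setNames(rep(Inf, length(cf$surv_p0)), names(cf$surv_p0))
  cf$growth_log2_effect <- rep(0, length(cf$nominal))
  cf$tad_surv_top <- cf$tad_surv_ctrl
  cf$dev_rate_trt <- cf$dev_rate_ctrl
  cf$mass_pct_per_doubling <- 0
  cf$dev_log_slope <- 0
  cf$repro_log_slope <- 0
  cf$algae_shift_slope <- 0
  simulate_experiment(cf)
}

#' Survival observations from a dataset's amphipod table
#'
#' @param ds a `mesotox_dataset`.
#' @param conc_scale concentration labelling passed to [conc_from()].
#' @return data frame ready for [fit_hormetic_model()].
#' @export
survival_observations <- function(ds, conc_scale = "measured_group_mean") {
  conc <- conc_from(ds, conc_scale)
  am <- ds$amphipods
  data.frame(tank_id = am$tank_id, conc = unname(conc[am$tank_id]),
             week = am$week, n_alive = am$n_alive, n_atrisk = am$n_atrisk)
}
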