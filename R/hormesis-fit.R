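#' Log2(c + 1) dose transform
#'
#' Diquat concentrations are increased by one before log2-transformation so
#' that the model intercept corresponds to the control (0 ug/L) treatment.
#'
#' @param conc concentration in ug/L, non-negative.
#' @return transformed dose `log2(conc + 1)`; 0 exactly when `conc` is 0.
#' @export
transform_concentration <- function(conc) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative")
  log2(conc + 1)
}

#' Inverse of [transform_concentration()]
#' @param x transformed dose
#' @return concentration in ug/L
#' @export
untransform_concentration <- function(x) 2^x - 1

#' Specify a hormetic survival model
#'
#' Binomial survival on the logit scale as a polynomial in the transformed
#' diquat dose `x = log2(conc + 1)`, with a Normal random intercept per tank
#' absorbing extra-binomial variation:
#' `logit(p) = b0[week] + b1 * x + b2 * x^2 + u_tank`.
#'
#' @param form `"null"` (intercept only), `"linear"`, or `"quadratic"`.
#' @param week_structure `"separate_fits"` fits each exposure week on its
#'   own; `"joint"` fits one model with a week-specific intercept and slopes
#'   shared across weeks.
#' @param priors list with elements `b0`, `b1`, `b2` (each `c(mean, sd)` of a
#'   Normal prior on the logit scale) and `sigma` (scale of the half-Normal
#'   prior on the tank standard deviation; 0 removes the random effect).
#' @param chains,warmup,iter MCMC settings per chain.
#' @param check_convergence error when any split-Rhat is at or above
#'   `rhat_tol`.
#' @param rhat_tol convergence gate on split-Rhat (default 1.01).
#' @return an object of class `hormesis_model_spec`.
#' @export
hormesis_model_spec <- function(form = c("quadratic", "linear", "null"),
                                week_structure = c("separate_fits", "joint"),
                                priors = list(b0 = c(0, 2.5), b1 = c(0, 2.5),
                                              b2 = c(0, 2.5), sigma = 1),
                                chains = 4, warmup = 3000, iter = 8000,
                                check_convergence = TRUE, rhat_tol = 1.01) {
  form <- match.arg(form)
  week_structure <- match.arg(week_structure)
  stopifnot(chains >= 2, warmup > 0, iter > 0)
  if (form == "quadratic" && is.null(priors$b2))
    stop("quadratic form requires a prior for b2")
  structure(list(form = form, week_structure = week_structure,
                 priors = priors, chains = chains, warmup = warmup,
                 iter = iter, check_convergence = check_convergence,
                 rhat_tol = rhat_tol),
            class = "hormesis_model_spec")
}

# split-Rhat of Gelman et al.: each chain split in half, classic
# between/within variance ratio over the 2*C half-chains
split_rhat <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    m <- length(ch) %/% 2
    halves <- c(halves, list(ch[seq_len(m)], ch[m + seq_len(m)]))
  }
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.fit_single <- function(y, n_trials, X, tank_idx, n_tank, prior_mean,
                        prior_sd, sigma_prior_sd, spec, par_names,
                        ridge_dirs, ridge_tankw) {
  include_ranef <- sigma_prior_sd > 0
  K <- ncol(X)
  # sample in the QR-orthogonalised basis: the raw x / x^2 columns induce
  # near-degenerate posterior correlation that random-walk proposals cannot
  # traverse; on gamma = R beta the posterior is far closer to isotropic
  qrX <- qr(X)
  Q <- qr.Q(qrX); R <- qr.R(qrX)
  sgn <- sign(diag(R)); sgn[sgn == 0] <- 1
  Q <- Q %*% diag(sgn, K); R <- diag(sgn, K) %*% R
  prior_mu_g <- drop(R %*% prior_mean)
  prior_prec_g <- solve(R %*% diag(prior_sd^2, K) %*% t(R))
  dirs_g <- R %*% ridge_dirs

  # initialise near the fixed-effect GLM fit, jittered per chain
  init <- tryCatch({
    g <- suppressWarnings(glm.fit(X, cbind(y, n_trials - y),
                                  family = binomial()))
    b <- coef(g); b[!is.finite(b)] <- 0; pmax(pmin(b, 5), -5)
  }, error = function(e) rep(0, K))
  init_g <- drop(R %*% init)

  chains <- vector("list", spec$chains)
  for (c in seq_len(spec$chains)) {
    g0 <- init_g + rnorm(K, 0, 0.3)
    chains[[c]] <- hormesis_chain_cpp(
      y, n_trials, Q, as.integer(tank_idx - 1L), n_tank,
      prior_mu_g, prior_prec_g, max(sigma_prior_sd, 1e-12),
      spec$warmup, spec$iter, g0, exp(rnorm(1, log(0.3), 0.3)),
      include_ranef, dirs_g, ridge_tankw)
    # back-transform the draws to the model scale
    chains[[c]]$beta <- t(backsolve(R, t(chains[[c]]$beta)))
  }

  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  colnames(beta) <- par_names
  sigma <- unlist(lapply(chains, `[[`, "sigma"))
  u <- do.call(rbind, lapply(chains, `[[`, "u"))
  loglik <- do.call(rbind, lapply(chains, `[[`, "loglik"))

  mon_pars <- par_names
  if (include_ranef) mon_pars <- c(mon_pars, "sigma_tank")
  rhat <- ess <- setNames(numeric(length(mon_pars)), mon_pars)
  for (j in seq_len(K)) {
    per_chain <- lapply(chains, function(ch) ch$beta[, j])
    rhat[j] <- split_rhat(per_chain)
    ess[j] <- sum(vapply(per_chain,
                         function(v) coda::effectiveSize(coda::mcmc(v)), 0))
  }
  if (include_ranef) {
    per_chain <- lapply(chains, function(ch) log(ch$sigma + 1e-300))
    rhat["sigma_tank"] <- split_rhat(per_chain)
    ess["sigma_tank"] <- sum(vapply(per_chain,
                                    function(v) coda::effectiveSize(coda::mcmc(v)), 0))
  }

  list(beta = beta, sigma = sigma, u = u, loglik = loglik,
       diagnostics = data.frame(parameter = mon_pars, rhat = rhat,
                                ess = ess, row.names = NULL))
}

#' Fit the Bayesian hormetic survival model
#'
#' Samples from `n_alive ~ Binomial(n_atrisk, p)` with
#' `logit(p) = b0[week] + b1 x + b2 x^2 + u_tank`, `u_tank ~ N(0, sigma^2)`,
#' using an adaptive Metropolis-within-Gibbs sampler (block random-walk on
#' the regression coefficients with covariance adapted during warmup,
#' per-tank random-effect updates, log-scale update for sigma).
#'
#' @param obs data frame with columns `tank_id`, `conc` (ug/L), `week`,
#'   `n_alive`, `n_atrisk`.
#' @param spec a [hormesis_model_spec()].
#' @return object of class `hormesis_posterior`: posterior draws, per-tank
#'   effects, split-Rhat / effective-sample-size diagnostics, and the
#'   pointwise log-likelihood matrix used for exact LOO.
#' @export
fit_hormetic_model <- function(obs, spec = hormesis_model_spec()) {
  stopifnot(is.data.frame(obs),
            all(c("tank_id", "conc", "week", "n_alive", "n_atrisk") %in%
                  names(obs)))
  if (any(obs$n_atrisk <= 0)) stop("n_atrisk must be positive")
  if (any(obs$n_alive < 0 | obs$n_alive > obs$n_atrisk))
    stop("n_alive must lie in [0, n_atrisk]")
  ndist <- length(unique(obs$conc))
  if (spec$form == "linear" && ndist < 2)
    stop("linear form needs >= 2 distinct concentrations")
  if (spec$form == "quadratic" && ndist < 3)
    stop("quadratic form needs >= 3 distinct concentrations")

  if (all(obs$n_alive == 0) || all(obs$n_alive == obs$n_atrisk))
    warning("degenerate all-dead or all-alive data: possible separation")

  obs$tank_id <- factor(obs$tank_id)
  x <- transform_concentration(obs$conc)
  weeks <- sort(unique(obs$week))
  pr <- spec$priors

  slope_names <- switch(spec$form, null = character(0), linear = "b1",
                        quadratic = c("b1", "b2"))
  slope_mean <- c(b1 = pr$b1[1], b2 = pr$b2[1])[slope_names]
  slope_sd <- c(b1 = pr$b1[2], b2 = pr$b2[2])[slope_names]
  slope_cols <- function(xv) switch(spec$form, null = NULL, linear = cbind(xv),
                                    quadratic = cbind(xv, xv^2))

  if (spec$week_structure == "separate_fits") {
    fits <- list()
    for (w in weeks) {
      sel <- obs$week == w
      X <- cbind(rep(1, sum(sel)), slope_cols(x[sel]))
      par_names <- c("b0", slope_names)
      tk <- droplevels(obs$tank_id[sel])
      Wt <- X[match(seq_len(nlevels(tk)), as.integer(tk)), , drop = FALSE]
      fits[[as.character(w)]] <- c(
        .fit_single(obs$n_alive[sel], obs$n_atrisk[sel], X,
                    as.integer(tk), nlevels(tk),
                    c(pr$b0[1], slope_mean), c(pr$b0[2], slope_sd),
                    pr$sigma, spec, par_names,
                    diag(ncol(X)), Wt),
        list(tank_levels = levels(tk), obs_index = which(sel)))
    }
    diag_all <- do.call(rbind, lapply(names(fits), function(w) {
      d <- fits[[w]]$diagnostics; d$week <- as.numeric(w); d
    }))
    post <- list(spec = spec, weeks = weeks, fits = fits,
                 diagnostics = diag_all, obs = obs, x = x)
  } else {
    Wd <- sapply(weeks, function(w) as.numeric(obs$week == w))
    X <- cbind(Wd, slope_cols(x))
    par_names <- c(paste0("b0_w", weeks), slope_names)
    tk <- obs$tank_id
    nw <- length(weeks); ns <- length(slope_names)
    # ridge directions: the all-weeks intercept shift plus each slope
    # column (dose is constant within tank across weeks)
    dirs <- cbind(c(rep(1, nw), rep(0, ns)))
    x_tank <- x[match(seq_len(nlevels(tk)), as.integer(tk))]
    tankw <- cbind(rep(1, nlevels(tk)))
    if (ns >= 1) { dirs <- cbind(dirs, c(rep(0, nw), 1, rep(0, ns - 1)))
                   tankw <- cbind(tankw, x_tank) }
    if (ns >= 2) { dirs <- cbind(dirs, c(rep(0, nw + 1), 1))
                   tankw <- cbind(tankw, x_tank^2) }
    fit <- .fit_single(obs$n_alive, obs$n_atrisk, X, as.integer(tk),
                       nlevels(tk),
                       c(rep(pr$b0[1], length(weeks)), slope_mean),
                       c(rep(pr$b0[2], length(weeks)), slope_sd),
                       pr$sigma, spec, par_names, dirs, tankw)
    fit$tank_levels <- levels(tk)
    fit$obs_index <- seq_len(nrow(obs))
    d <- fit$diagnostics; d$week <- NA_real_
    post <- list(spec = spec, weeks = weeks, fits = list(joint = fit),
                 diagnostics = d, obs = obs, x = x)
  }
  class(post) <- "hormesis_posterior"

  bad <- post$diagnostics$rhat >= spec$rhat_tol
  if (any(bad)) {
    msg <- paste0("MCMC convergence failure (split-Rhat >= ", spec$rhat_tol,
                  "): ",
                  paste(post$diagnostics$parameter[bad], collapse = ", "))
    if (spec$check_convergence)
      stop(structure(class = c("mesotox_convergence_error", "error",
                               "condition"),
                     list(message = msg, call = sys.call(),
                          diagnostics = post$diagnostics)))
    warning(msg)
  }
  post
}

# per-draw (b0, b1, b2, sigma) matrix for one exposure week
draws_for_week <- function(post, week) {
  stopifnot(inherits(post, "hormesis_posterior"))
  if (!week %in% post$weeks) stop("no fit for week ", week)
  if (post$spec$week_structure == "separate_fits") {
    f <- post$fits[[as.character(week)]]
    b <- f$beta
    b0 <- b[, "b0"]
  } else {
    f <- post$fits$joint
    b <- f$beta
    b0 <- b[, paste0("b0_w", week)]
  }
  b1 <- if ("b1" %in% colnames(b)) b[, "b1"] else rep(0, nrow(b))
  b2 <- if ("b2" %in% colnames(b)) b[, "b2"] else rep(0, nrow(b))
  cbind(b0 = b0, b1 = b1, b2 = b2, sigma = f$sigma)
}

#' @export
print.hormesis_posterior <- function(x, ...) {
  cat("Hormetic survival model (", x$spec$form, ", ",
      x$spec$week_structure, ")\n", sep = "")
  cat("Weeks:", paste(x$weeks, collapse = ", "), "\n")
  cat("Draws:", nrow(draws_for_week(x, x$weeks[1])),
      "(", x$spec$chains, "chains )\n")
  cat("Max split-Rhat:", round(max(x$diagnostics$rhat), 4),
      "; min ESS:", round(min(x$diagnostics$ess)), "\n")
  invisible(x)
}
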