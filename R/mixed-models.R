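#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`, defined for `n > k + 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.fit_result <- function(fit, data, estimation, note = NULL) {
  ll <- as.numeric(logLik(fit))
  k <- attr(logLik(fit), "df")
  n <- nobs(fit)
  cf <- if (inherits(fit, "merMod")) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               row.names = NULL)
  } else {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               p = s[, 4], row.names = NULL)
  }
  re_var <- if (inherits(fit, "merMod")) {
    vc <- lme4::VarCorr(fit)
    setNames(vapply(vc, function(v) v[1, 1], 0), names(vc))
  } else NULL
  structure(list(fit = fit, coefficients = cf, re_variance = re_var,
                 loglik = ll, k = k, n = n,
                 aicc = aicc(ll, k, n), estimation = estimation,
                 converged = !isTRUE(attr(fit, "mesotox_nonconv")),
                 note = note),
            class = "mesotox_fit")
}

#' @export
print.mesotox_fit <- function(x, ...) {
  cat("Model fit (", x$estimation, "), n =", x$n, ", AICc =",
      round(x$aicc, 2), "\n")
  print(x$coefficients, row.names = FALSE)
  if (!is.null(x$re_variance))
    cat("Random-effect variance:",
        paste(names(x$re_variance), round(x$re_variance, 4),
              collapse = "; "), "\n")
  if (!is.null(x$note)) cat("Note:", x$note, "\n")
  invisible(x)
}

#' Binomial GLMM with an observation-level random effect
#'
#' Laplace-approximated ML fit of a binomial mixed model with a single
#' random-intercept term. An observation-level random effect (one level per
#' row) absorbs extra-binomial (overdispersion) variation; alternatively any
#' grouping column can be used.
#'
#' @param formula model formula for the fixed effects with a
#'   `cbind(successes, failures)` response.
#' @param data data frame.
#' @param grouping name of the random-intercept column, or `"olre"` to add
#'   an observation-level random effect, or `NULL` for a plain GLM.
#' @return a `mesotox_fit` (coefficients on the logit scale, random-effect
#'   variance, log-likelihood, AICc).
#' @export
fit_binomial_glmm <- function(formula, data, grouping = "olre") {
  if (is.null(grouping)) {
    fit <- glm(formula, data = data, family = binomial())
    return(.fit_result(fit, data, "ML", note = "fixed-effects GLM"))
  }
  if (identical(grouping, "olre")) {
    data$.obs <- factor(seq_len(nrow(data)))
    grouping <- ".obs"
  }
  if (!grouping %in% names(data))
    stop("grouping column '", grouping, "' not found")
  f <- update(formula, paste(". ~ . + (1 | ", grouping, ")"))
  fit <- withCallingHandlers(
    lme4::glmer(f, data = data, family = binomial(),
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE)),
    warning = function(w) {
      if (grepl("failed to converge|unable to evaluate", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  .fit_result(fit, data, "Laplace")
}

#' Gaussian linear mixed model with one random intercept
#'
#' @param formula fixed-effects formula.
#' @param data data frame.
#' @param grouping random-intercept column.
#' @param REML use REML (reported coefficients) or ML (AICc comparisons).
#' @return a `mesotox_fit`; singular fits (group variance estimated at 0)
#'   are flagged in `$note`, not fatal.
#' @export
fit_lmm <- function(formula, data, grouping, REML = TRUE) {
  stopifnot(grouping %in% names(data))
  f <- update(formula, paste(". ~ . + (1 | ", grouping, ")"))
  fit <- suppressMessages(lme4::lmer(f, data = data, REML = REML))
  note <- if (lme4::isSingular(fit)) "singular fit: group variance at 0"
  .fit_result(fit, data, if (REML) "REML" else "ML", note = note)
}

#' Conditional (average-group) predictions on the response scale
#'
#' Predictions for an average group (random effects set to zero), the
#' "average mesocosm" interpretation. For binomial fits the result is a
#' probability. The confidence interval is a Wald interval on the link
#' scale from the fixed-effect covariance.
#'
#' @param fit a `mesotox_fit`.
#' @param newdata data frame of predictor values.
#' @param level confidence level.
#' @export
predict_conditional <- function(fit, newdata, level = 0.95) {
  mod <- fit$fit
  is_mer <- inherits(mod, "merMod")
  X <- model.matrix(if (is_mer) lme4::nobars(formula(mod, fixed.only = TRUE)[-2])
                    else formula(mod)[-2], newdata)
  b <- if (is_mer) lme4::fixef(mod) else coef(mod)
  V <- as.matrix(vcov(mod))
  eta <- drop(X %*% b)
  se <- sqrt(rowSums((X %*% V) * X))
  z <- qnorm(1 - (1 - level) / 2)
  link <- if (is_mer) {
    fam <- family(mod)
    if (fam$family == "binomial") plogis else identity
  } else if (inherits(mod, "glm") && family(mod)$family == "binomial")
    plogis else identity
  data.frame(newdata, fit = link(eta), lwr = link(eta - z * se),
             upr = link(eta + z * se))
}

#' AICc model comparison table
#'
#' Delta-AICc relative to the best model; fits with `dAICc < 2` are flagged
#' as providing essentially equivalent fits.
#'
#' @param fits named list of `mesotox_fit` objects on identical response
#'   rows, all fitted by ML (or Laplace ML); REML fits are refused.
#' @export
aicc_compare <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  est <- vapply(fits, function(f) f$estimation, "")
  if (any(est == "REML"))
    stop("AICc comparison across fixed-effect structures requires ML fits")
  ns <- vapply(fits, function(f) f$n, 0)
  if (length(unique(ns)) != 1)
    stop("models fitted to different numbers of observations")
  a <- vapply(fits, function(f) f$aicc, 0)
  out <- data.frame(model = names(fits), k = vapply(fits, function(f) f$k, 0),
                    loglik = vapply(fits, function(f) f$loglik, 0),
                    aicc = a, daicc = a - min(a), row.names = NULL)
  out$equivalent <- out$daicc < 2
  out[order(out$daicc), ]
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param values numeric response.
#' @param groups factor of group labels.
#' @return list: `F`, `df` (between, within), `p`, and the Tukey pairwise
#'   table (diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 observations")
  d <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = d)
  an <- anova(fit)
  Fv <- an[["F value"]][1]
  if (var(values) < 1e-24 || !is.finite(Fv)) { # all observations tied
    Fv <- 0
    p <- 1
  } else p <- an[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$g
  list(F = Fv, df = c(an$Df[1], an$Df[2]), p = p,
       pairwise = data.frame(comparison = rownames(tk), tk, row.names = NULL,
                             check.names = FALSE))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' g - 1 degrees of freedom. All-tied data give H = 0, p = 1.
#'
#' @param values numeric response.
#' @param groups factor of group labels.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1, p = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' Nonparametric bootstrap of a statistic with the BCa correction: the bias
#' term `z0` from the bootstrap distribution's position of the point
#' estimate and the acceleration `a` from jackknife skewness.
#'
#' @param values numeric sample (n >= 3).
#' @param statistic function of a numeric vector (default mean).
#' @param B number of bootstrap resamples (>= 1000).
#' @param level confidence level.
#' @param seed integer seed; the interval is deterministic given the seed.
#' @return list: `estimate`, `low`, `high`, `z0`, `a`.
#' @export
bca_bootstrap_ci <- function(values, statistic = mean, B = 2000,
                             level = 0.95, seed = 1) {
  n <- length(values)
  stopifnot(n >= 3, B >= 1000)
  est <- statistic(values)
  if (length(unique(values)) == 1)
    return(list(estimate = est, low = est, high = est, z0 = 0, a = 0))
  set.seed(seed)
  boots <- vapply(seq_len(B),
                  function(i) statistic(sample(values, n, replace = TRUE)), 0)
  z0 <- qnorm(mean(boots < est) + 0.5 * mean(boots == est))
  jack <- vapply(seq_len(n), function(i) statistic(values[-i]), 0)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den == 0) 0 else num / den
  alpha <- (1 - level) / 2
  adj <- function(q) pnorm(z0 + (z0 + qnorm(q)) / (1 - a * (z0 + qnorm(q))))
  lo <- quantile(boots, adj(alpha), names = FALSE, type = 6)
  hi <- quantile(boots, adj(1 - alpha), names = FALSE, type = 6)
  list(estimate = est, low = lo, high = hi, z0 = z0, a = a)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Adjusted p-values reported in the input order; dominates the raw values
#' and is invariant to input order.
#'
#' @param pvalues vector of raw p-values in `[0, 1]`.
#' @export
holm_bonferroni <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  p.adjust(pvalues, method = "holm")
}

#' Sex-ratio GLMM restricted to sexable stages
#'
#' Morphological sex is unreliable before Gosner stage 36, so the analysis
#' is restricted to individuals at stage >= 36. The response is female vs.
#' not (male or unknown). A tank random intercept is attempted first; when
#' that fit does not converge (or is singular with an unstable gradient)
#' the model falls back to a plain GLM without tank-level variation.
#'
#' @param tadpoles data frame with columns `tank_id`, `conc`, `gosner`,
#'   `sex` (levels F, M, unknown).
#' @param min_stage minimum Gosner stage retained (default 36).
#' @return a `mesotox_fit`; `$note` records any fallback.
#' @export
fit_sex_ratio_glmm <- function(tadpoles, min_stage = 36) {
  d <- tadpoles[!is.na(tadpoles$gosner) & tadpoles$gosner >= min_stage, ]
  if (nrow(d) == 0) stop("no tadpoles at or above the minimum Gosner stage")
  d$female <- as.integer(d$sex == "F")
  d$x <- transform_concentration(d$conc)
  if (length(unique(d$female)) == 1)
    warning("all retained tadpoles have the same sex classification")
  mixed <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(female ~ x + (1 | tank_id), data = d,
                  family = binomial(),
                  control = lme4::glmerControl(optimizer = "bobyqa"))))
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    if (!conv) NULL else fit
  }, error = function(e) NULL)
  if (!is.null(mixed)) return(.fit_result(mixed, d, "Laplace"))
  fit <- glm(female ~ x, data = d, family = binomial())
  .fit_result(fit, d, "ML",
              note = "tank random effect dropped (mixed fit did not converge)")
}

#' @importFrom stats nobs family formula update dbinom
NULL
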