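#' Highest density continuous interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws; when several windows tie on width the leftmost is taken.
#'
#' @param draws numeric vector of posterior draws (>= 50 unless the vector is
#'   degenerate).
#' @param mass probability mass to cover (default 0.95).
#' @return named numeric `c(low, high)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0) stop("hdi: no finite draws")
  stopifnot(mass > 0, mass <= 1)
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) return(c(low = s[1], high = s[n]))
  widths <- s[(m):n] - s[seq_len(n - m + 1)]
  i <- which.min(widths) # which.min takes the first (leftmost) minimum
  c(low = s[i], high = s[i + m - 1])
}

summarize_metric <- function(metric, week, values, n_total) {
  values <- values[is.finite(values)]
  fd <- length(values) / n_total
  if (length(values) == 0) {
    return(data.frame(metric = metric, week = week, median = NA_real_,
                      hdi_low = NA_real_, hdi_high = NA_real_,
                      fraction_defined = 0))
  }
  h <- hdi(values)
  out <- data.frame(metric = metric, week = week,
                    median = median(values), hdi_low = h[["low"]],
                    hdi_high = h[["high"]], fraction_defined = fd)
  if (fd < 0.9)
    attr(out, "flag") <- "metric undefined in more than 10% of draws"
  out
}

#' Posterior control survival
#'
#' Survival probability at zero diquat for an average tank (u = 0):
#' per draw `plogis(b0[week])`.
#'
#' @param post a fitted [fit_hormetic_model()] posterior.
#' @param week exposure week to summarize.
#' @return one-row data frame: metric, week, posterior median, 95% HDI,
#'   fraction of draws where the metric is defined.
#' @export
control_survival <- function(post, week) {
  d <- draws_for_week(post, week)
  summarize_metric("control_survival", week, plogis(d[, "b0"]), nrow(d))
}

# descending-limb root of b2 x^2 + b1 x + (b0 - target_logit) = 0, per draw
descending_root <- function(b0, b1, b2, target_logit) {
  cc <- b0 - target_logit
  x <- rep(NA_real_, length(b0))
  lin <- abs(b2) < 1e-12
  # linear: x = (target - b0)/b1, requires decreasing survival (b1 < 0)
  ok <- lin & b1 < 0
  x[ok] <- -cc[ok] / b1[ok]
  # quadratic with curvature: keep the largest real root beyond the vertex
  qu <- !lin
  disc <- b1^2 - 4 * b2 * cc
  ok <- qu & disc >= 0 & b2 < 0
  # for b2 < 0 the larger root is (-b1 + sqrt(disc)) / (2 b2) with the minus
  # branch; write both and take max
  r1 <- (-b1 + sqrt(pmax(disc, 0))) / (2 * b2)
  r2 <- (-b1 - sqrt(pmax(disc, 0))) / (2 * b2)
  x[ok] <- pmax(r1[ok], r2[ok])
  x[is.finite(x) & x < 0] <- NA_real_
  x
}

#' Lethal concentration LCx as a posterior quantity
#'
#' Per draw, the concentration causing a fractional reduction `f` in survival
#' relative to the control level `p0 = plogis(b0)`: the descending-limb
#' solution of `b2 x^2 + b1 x + (b0 - logit((1 - f) p0)) = 0`,
#' back-transformed `c = 2^x - 1`. Draws with no real non-negative solution
#' are excluded and reported through `fraction_defined`.
#'
#' @param post fitted posterior.
#' @param f fractional reduction in survival, in (0, 1); 0.5 gives the LC50.
#' @param week exposure week.
#' @param relative if `FALSE`, target an absolute survival probability
#'   `1 - f` instead of a reduction relative to control.
#' @return one-row summary data frame (metric, week, median, HDI,
#'   fraction_defined).
#' @export
lethal_concentration <- function(post, f = 0.5, week, relative = TRUE) {
  if (!is.numeric(f) || f <= 0 || f >= 1) stop("f must be in (0, 1)")
  d <- draws_for_week(post, week)
  p0 <- plogis(d[, "b0"])
  target <- if (relative) qlogis((1 - f) * p0) else qlogis(rep(1 - f, nrow(d)))
  x <- descending_root(d[, "b0"], d[, "b1"], d[, "b2"], target)
  summarize_metric(sprintf("LC%d", round(100 * f)), week,
                   untransform_concentration(x), nrow(d))
}

#' Limiting concentration of stimulation
#'
#' The concentration at which hormetic survival returns to the control
#' level: the nonzero root of `b1 x + b2 x^2 = 0`, i.e. `x = -b1/b2`,
#' defined for draws with `b1 > 0` and `b2 < 0`.
#'
#' @inheritParams control_survival
#' @export
stimulation_limit <- function(post, week) {
  if (post$spec$form != "quadratic")
    stop("stimulation limit requires the quadratic form")
  d <- draws_for_week(post, week)
  x <- ifelse(d[, "b1"] > 0 & d[, "b2"] < 0, -d[, "b1"] / d[, "b2"],
              NA_real_)
  summarize_metric("stimulation_limit", week, untransform_concentration(x),
                   nrow(d))
}

#' Concentration and survival at the hormetic peak
#'
#' Vertex of the quadratic on the transformed-dose scale,
#' `x* = -b1 / (2 b2)` for draws with negative curvature; returns both the
#' peak concentration `2^x* - 1` and the peak survival probability.
#'
#' @inheritParams control_survival
#' @return two-row data frame (`peak_conc`, `peak_survival`).
#' @export
peak_concentration <- function(post, week) {
  if (post$spec$form != "quadratic")
    stop("peak concentration requires the quadratic form")
  d <- draws_for_week(post, week)
  ok <- d[, "b2"] < 0
  xs <- ifelse(ok, -d[, "b1"] / (2 * d[, "b2"]), NA_real_)
  xs[is.finite(xs) & xs < 0] <- NA_real_
  ps <- plogis(d[, "b0"] + d[, "b1"] * xs + d[, "b2"] * xs^2)
  rbind(summarize_metric("peak_conc", week, untransform_concentration(xs),
                         nrow(d)),
        summarize_metric("peak_survival", week, ps, nrow(d)))
}

#' Table of all derived toxicity metrics for one week
#'
#' @inheritParams control_survival
#' @param fractions LCx reduction fractions to include.
#' @export
derived_metrics <- function(post, week, fractions = c(0.10, 0.25, 0.50)) {
  out <- control_survival(post, week)
  for (f in fractions)
    out <- rbind(out, lethal_concentration(post, f, week))
  if (post$spec$form == "quadratic") {
    out <- rbind(out, stimulation_limit(post, week),
                 peak_concentration(post, week))
  }
  out
}
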