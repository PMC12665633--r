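#' Measured concentration as percent of nominal
#'
#' Per-tank `100 * measured / nominal` for treated tanks, summarized with
#' mean, standard error, extremes. Controls (nominal 0) are excluded with a
#' warning.
#'
#' @param measured per-tank 1-h measured concentrations (ug/L).
#' @param nominal matching nominal concentrations (ug/L).
#' @return list: `mean`, `se`, `n`, `min`, `max`, `percent` (per tank).
#' @export
percent_of_nominal <- function(measured, nominal) {
  stopifnot(length(measured) == length(nominal))
  drop0 <- nominal == 0
  if (any(drop0)) {
    warning(sum(drop0), " control tank(s) with nominal 0 excluded")
    measured <- measured[!drop0]
    nominal <- nominal[!drop0]
  }
  pct <- 100 * measured / nominal
  n <- length(pct)
  list(mean = mean(pct), se = sd(pct) / sqrt(n), n = n,
       min = min(pct), max = max(pct), percent = pct)
}

#' First-order dissipation fit
#'
#' Least-squares fit of `log(concentration)` on day over uncensored
#' observations; `DT50 = log(2) / k`. Censored (below-detection) points are
#' excluded and their count reported.
#'
#' @param day days post-application.
#' @param value measured concentration (ug/L).
#' @param below_detection logical censoring flag.
#' @return list: `k` (per-day first-order rate, positive when declining),
#'   `DT50` (days; `Inf` flagged when k <= 0), `n_used`, `n_censored`,
#'   `r_squared`, `model`.
#' @export
fit_dissipation <- function(day, value, below_detection = rep(FALSE, length(day))) {
  keep <- !below_detection & is.finite(value) & value > 0
  n_cens <- sum(below_detection)
  if (sum(keep) < 3)
    stop("need >= 3 uncensored timepoints (have ", sum(keep), ")")
  fit <- lm(log(value[keep]) ~ day[keep])
  k <- -unname(coef(fit)[2])
  if (abs(k) < 1e-12) k <- 0
  dt50 <- if (k <= 0) Inf else log(2) / k
  list(k = k, DT50 = dt50, n_used = sum(keep), n_censored = n_cens,
       r_squared = summary(fit)$r.squared, model = fit)
}

#' Detected vs below-detection counts per treatment at one day
#'
#' @param chemistry chemistry table (columns `tank_id`, `day`, `value`,
#'   `below_detection`) already joined with a `nominal_conc` column.
#' @param at_day sampling day to tabulate.
#' @return data frame: nominal_conc, n_detected, n_censored.
#' @export
detection_status_table <- function(chemistry, at_day) {
  d <- chemistry[chemistry$day == at_day, ]
  if (nrow(d) == 0) stop("day ", at_day, " not present")
  agg <- aggregate(below_detection ~ nominal_conc, data = d,
                   FUN = function(v) c(det = sum(!v), cens = sum(v)))
  data.frame(nominal_conc = agg$nominal_conc,
             n_detected = agg$below_detection[, "det"],
             n_censored = agg$below_detection[, "cens"])
}
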