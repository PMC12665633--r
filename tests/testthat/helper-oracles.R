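# Independent oracles used across the suite. These never call the code
# paths they check.

# bisection root of p(x) = target on [lo, hi] for the logit-quadratic curve
bisect_dose <- function(b0, b1, b2, target_logit, lo, hi, tol = 1e-10) {
  g <- function(x) b0 + b1 * x + b2 * x^2 - target_logit
  if (g(lo) * g(hi) > 0) return(NA_real_)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# maximum likelihood for the observation-level random-effect binomial GLMM
# by direct Gauss-Hermite quadrature (one independent 1-D integral per
# observation), maximized with optim. Oracle for the Laplace route.
ghq_olre_binomial <- function(y, n, X, n_nodes = 20) {
  gh <- function(k) { # Golub-Welsch via eigen of the Jacobi matrix
    i <- seq_len(k - 1)
    a <- sqrt(i / 2)
    E <- eigen(diag(0, k) + rbind(cbind(0, diag(a, k - 1)), 0) +
                 t(rbind(cbind(0, diag(a, k - 1)), 0)), symmetric = TRUE)
    list(nodes = E$values, weights = E$vectors[1, ]^2 * sqrt(pi))
  }
  q <- gh(n_nodes)
  nodes <- q$nodes * sqrt(2)          # standard-normal scaling
  wts <- q$weights / sqrt(pi)
  nll <- function(par) {
    beta <- par[-length(par)]
    sigma <- exp(par[length(par)])
    eta0 <- drop(X %*% beta)
    ll <- 0
    for (i in seq_along(y)) {
      p <- plogis(eta0[i] + sigma * nodes)
      ll <- ll + log(sum(wts * dbinom(y[i], n[i], p)))
    }
    -ll
  }
  k <- ncol(X) + 1
  fit <- optim(c(rep(0, ncol(X)), log(0.5)), nll, method = "BFGS",
               control = list(maxit = 500))
  list(beta = fit$par[-k], sigma = exp(fit$par[k]), loglik = -fit$value)
}

# Kruskal stress-1 of a configuration against dissimilarities, recomputed
# from its definition (monotone regression of configuration distances on
# the dissimilarity order)
stress1_recompute <- function(coords, d) {
  dd <- as.vector(d)
  conf <- as.vector(dist(coords))
  o <- order(dd)
  iso <- isoreg(seq_along(o), conf[o])
  dhat <- iso$yf
  sqrt(sum((conf[o] - dhat)^2) / sum(conf[o]^2))
}

# small survival dataset on a known logit-quadratic curve
make_survival_obs <- function(beta, sigma = 0.3, week = 6,
                              conc = c(0, 74, 147, 291, 579, 1153),
                              reps = 5, cages = 2, n_per_cage = 20) {
  tank <- rep(seq_len(length(conc) * reps), each = cages)
  cvec <- rep(rep(conc, each = reps), each = cages)
  x <- log2(cvec + 1)
  u <- rnorm(length(conc) * reps, 0, sigma)
  p <- plogis(beta[1] + beta[2] * x + beta[3] * x^2 + u[tank])
  data.frame(tank_id = paste0("T", tank), conc = cvec, week = week,
             n_alive = rbinom(length(tank), n_per_cage, p),
             n_atrisk = n_per_cage)
}

# minimal posterior object around a fixed draw matrix, for closed-form
# metric checks without running MCMC
fake_posterior <- function(b, sigma = rep(0.3, nrow(b)), week = 6,
                           form = "quadratic") {
  colnames(b) <- c("b0", "b1", "b2")[seq_len(ncol(b))]
  fit <- list(beta = b, sigma = sigma, u = matrix(0, nrow(b), 1),
              tank_levels = "T1")
  post <- list(spec = list(form = form, week_structure = "separate_fits"),
               weeks = week, fits = setNames(list(fit), as.character(week)))
  class(post) <- "hormesis_posterior"
  post
}
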