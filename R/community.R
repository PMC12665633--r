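#' Shannon diversity index
#'
#' `H = -sum p_i log(p_i)` over taxa with positive counts, natural log.
#'
#' @param counts non-negative counts (or biomass) for one sample.
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  s <- sum(counts)
  if (s <= 0) stop("all-zero count vector")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)`; symmetric, zero diagonal,
#' bounded in `[0, 1]` for non-negative data.
#'
#' @param counts sample-by-taxon matrix with positive row sums.
#' @return a `dist` object.
#' @export
bray_curtis <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative entries")
  if (any(rowSums(counts) == 0))
    stop("rows with zero total are undefined under Bray-Curtis")
  vegan::vegdist(counts, method = "bray")
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 (monotone regression of configuration
#' distances on dissimilarity ranks) over random restarts; stress below 0.1
#' is read as a good (non-arbitrary) ordination.
#'
#' @param d `dist` object.
#' @param k number of ordination axes.
#' @param n_starts random starts.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return list of class `mesotox_nmds`: `coordinates`, `stress` (0-1
#'   scale), `converged`, `n_starts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_starts = 50, seed = 1) {
  n <- attr(d, "Size")
  if (n < k + 2) stop("need at least k + 2 points")
  set.seed(seed)
  m <- vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                      trace = 0, autotransform = FALSE, wascores = FALSE)
  structure(list(coordinates = m$points, stress = m$stress,
                 converged = m$converged > 0, n_starts = n_starts,
                 seed = seed, engine = m),
            class = "mesotox_nmds")
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Pseudo-F from the partitioned sums of squared dissimilarities, with the
#' p-value from free permutation of group labels:
#' `p = (number of permuted F >= observed + 1) / (n_perm + 1)`.
#'
#' @param d `dist` object.
#' @param groups factor of group labels (>= 2 groups, each with >= 2
#'   members).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list of class `mesotox_permanova`: `F`, `R2`, `p`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("singleton groups are refused")
  set.seed(seed)
  dd <- data.frame(g = groups)
  a <- vegan::adonis2(d ~ g, data = dd, permutations = n_perm)
  structure(list(F = a$F[1], R2 = a$R2[1], p = a$`Pr(>F)`[1],
                 n_perm = n_perm, table = a),
            class = "mesotox_permanova")
}

#' Homogeneity of multivariate group dispersions
#'
#' Principal-coordinates embedding of the dissimilarities (negative
#' eigenvalues handled by the imaginary-part correction of distances to
#' centroids), per-group mean distance to the group centroid, and a
#' permutation F-test. Non-significance supports reading a significant
#' PERMANOVA as a location (mean) effect.
#'
#' @inheritParams permanova
#' @return list: `p`, `F`, `dispersions` (per-group mean distance to
#'   centroid).
#' @export
dispersion_homogeneity <- function(d, groups, n_perm = 999, seed = 1) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("singleton groups are refused")
  set.seed(seed)
  bd <- vegan::betadisper(d, groups, type = "centroid")
  pt <- vegan::permutest(bd, permutations = n_perm)
  list(p = pt$tab$`Pr(>F)`[1], F = pt$tab$F[1],
       dispersions = tapply(bd$distances, bd$group, mean))
}

#' Linear-model contrasts of Shannon diversity
#'
#' Fits `H ~ treatment * day` by least squares and computes every
#' treatment-vs-control contrast within each day as a linear combination of
#' coefficients, with delta-method standard errors and Holm-adjusted
#' p-values.
#'
#' @param H per-tank diversity values.
#' @param treatment treatment factor; its first level is the control.
#' @param day day factor.
#' @return list: `model` (the lm), `contrasts` (day, treatment, estimate,
#'   se, t, p_raw, p_holm, or NA when inestimable).
#' @export
diversity_lm_contrasts <- function(H, treatment, day) {
  treatment <- factor(treatment)
  day <- factor(day)
  d <- data.frame(H = H, treatment = treatment, day = day)
  # a single sampling day degenerates to a one-way model
  fit <- if (nlevels(day) > 1) lm(H ~ treatment * day, data = d)
         else lm(H ~ treatment, data = d)
  b <- coef(fit)
  V <- vcov(fit)
  ctrl <- levels(treatment)[1]
  rows <- list()
  for (dy in levels(day)) {
    for (tr in levels(treatment)[-1]) {
      # contrast vector for mean(tr, dy) - mean(ctrl, dy)
      cv <- setNames(numeric(length(b)), names(b))
      main <- paste0("treatment", tr)
      intx <- paste0("treatment", tr, ":day", dy)
      if (!main %in% names(cv)) next
      cv[main] <- 1
      if (intx %in% names(cv)) cv[intx] <- 1
      est <- sum(cv * b)
      if (anyNA(b[cv != 0])) {
        rows[[length(rows) + 1]] <- data.frame(
          day = dy, treatment = tr, estimate = NA_real_, se = NA_real_,
          t = NA_real_, p_raw = NA_real_)
        next
      }
      se <- sqrt(drop(t(cv) %*% V %*% cv))
      tv <- est / se
      p <- 2 * pt(-abs(tv), df = fit$df.residual)
      rows[[length(rows) + 1]] <- data.frame(
        day = dy, treatment = tr, estimate = est, se = se, t = tv,
        p_raw = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_holm <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_holm[ok] <- holm_bonferroni(out$p_raw[ok])
  list(model = fit, contrasts = out)
}

#' Per-treatment share of listed taxa
#'
#' Fraction of total counts (or biomass) contributed by the listed taxa,
#' aggregated within each treatment group.
#'
#' @param counts sample-by-taxon matrix.
#' @param taxa character vector of column names.
#' @param treatment treatment label per row.
#' @export
dominance_share <- function(counts, taxa, treatment) {
  counts <- as.matrix(counts)
  missing <- setdiff(taxa, colnames(counts))
  if (length(missing) > 0)
    stop("unknown taxa: ", paste(missing, collapse = ", "))
  tot <- tapply(rowSums(counts), treatment, sum)
  if (length(taxa) == 0)
    return(setNames(rep(0, length(tot)), names(tot)))
  part <- tapply(rowSums(counts[, taxa, drop = FALSE]), treatment, sum)
  setNames(as.numeric(part / tot), names(tot))
}

#' Chlorophyll-biomass correspondence
#'
#' Least-squares fit of microscopy biomass on chlorophyll-a, reported as a
#' check that the two biomass proxies agree.
#'
#' @param biomass total phytoplankton biomass per sample.
#' @param chlorophyll chlorophyll-a per sample.
#' @return list: `r_squared`, `p`, `model`.
#' @export
chlorophyll_biomass_lm <- function(biomass, chlorophyll) {
  fit <- lm(biomass ~ chlorophyll)
  s <- summary(fit)
  list(r_squared = s$r.squared,
       p = unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                     lower.tail = FALSE)),
       model = fit)
}
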