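#' Expected beta-diversity under random sampling from a fixed species pool
#'
#' The null expectation of the gamma-beta relationship when communities are
#' assembled by pure random draws: for each pool size gamma, pool relative
#' abundances are drawn from `abundance_model`, `n_communities` communities
#' of `n_individuals` reads are sampled multinomially from the pool, and
#' the Bray-Curtis beta-dispersion (mean distance to centroid) is recorded;
#' replicates give the Monte-Carlo mean and standard error per gamma. If
#' local communities were mere samples of the pool, observed gamma-beta
#' relationships should track this curve.
#'
#' @param gammas integer vector of pool sizes (taxon counts), all >= 1.
#' @param n_individuals reads per simulated community.
#' @param n_communities communities per replicate.
#' @param replicates Monte-Carlo replicates per gamma.
#' @param abundance_model `"lognormal"` (sdlog 1) or `"uniform"` pool
#'   relative abundances.
#' @param seed integer seed; the curve is bit-reproducible given it.
#' @return object of class `gamma_beta_curve`: data frame `gamma`,
#'   `mean_dispersion`, `se`, plus the simulation parameters as attributes.
#' @export
expected_beta_vs_gamma <- function(gammas, n_individuals = 800,
                                   n_communities = 10, replicates = 200,
                                   abundance_model = c("lognormal", "uniform"),
                                   seed = 1) {
  abundance_model <- match.arg(abundance_model)
  if (any(gammas < 1)) stop_validation("gamma must be >= 1")
  if (n_individuals < 1 || replicates < 1)
    stop_validation("n_individuals and replicates must be >= 1")
  res <- with_seed(seed, {
    lapply(gammas, function(g) {
      disp <- vapply(seq_len(replicates), function(r) {
        p <- if (abundance_model == "uniform") rep(1 / g, g)
             else { w <- stats::rlnorm(g, 0, 1); w / sum(w) }
        comm <- t(stats::rmultinom(n_communities, n_individuals, p))
        if (g == 1) return(0)
        rownames(comm) <- paste0("c", seq_len(n_communities))
        colnames(comm) <- paste0("t", seq_len(g))
        bc <- bray_curtis(community_table(comm))
        mean(beta_dispersion(bc)$distance_to_centroid)
      }, numeric(1))
      c(mean = mean(disp), se = stats::sd(disp) / sqrt(replicates))
    })
  })
  curve <- data.frame(gamma = gammas,
                      mean_dispersion = vapply(res, `[[`, numeric(1), "mean"),
                      se = vapply(res, `[[`, numeric(1), "se"))
  structure(curve, class = c("gamma_beta_curve", "data.frame"),
            n_individuals = n_individuals, n_communities = n_communities,
            replicates = replicates, abundance_model = abundance_model,
            seed = seed)
}

#' Observed gamma-beta relationship across groups
#'
#' Per group, the species pool (Chao2 gamma from [estimate_gamma()]) is
#' regressed against the group's mean beta-dispersion (from
#' [beta_dispersion()]); the slope, R-squared, p-value and a direction call
#' summarize whether larger pools go with larger beta-diversity.
#'
#' @param table a [community_table()].
#' @param dm `dist_matrix` of community dissimilarities for the same
#'   samples.
#' @param groups group label per sample; at least 3 distinct groups.
#' @param alpha significance level for the direction call.
#' @return object of class `gamma_beta_regression`: slope, `r2`, `p_value`,
#'   `direction` in `{"positive", "negative", "none"}`, and the per-group
#'   table.
#' @export
observed_gamma_beta <- function(table, dm, groups, alpha = 0.05) {
  if (length(unique(groups)) < 3)
    stop_validation("need >= 3 groups as regression units")
  gam <- estimate_gamma(table, groups)
  disp <- beta_dispersion(dm, groups)
  mdisp <- tapply(disp$distance_to_centroid, disp$group, mean)
  dat <- data.frame(group = gam$group, gamma = gam$S_chao2,
                    mean_dispersion = as.numeric(mdisp[gam$group]))
  fit <- stats::lm(mean_dispersion ~ gamma, data = dat)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  p <- sm$coefficients[2, 4]
  direction <- if (is.na(p) || p >= alpha) "none"
               else if (slope > 0) "positive" else "negative"
  structure(list(slope = slope, slope_se = sm$coefficients[2, 2],
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared, p_value = p, direction = direction,
                 alpha = alpha, per_group = dat),
            class = "gamma_beta_regression")
}

#' @export
print.gamma_beta_regression <- function(x, ...) {
  cat(sprintf("Observed gamma-beta regression: slope %.4g, R2 %.3f, p %.3g -> %s\n",
              x$slope, x$r2, x$p_value, x$direction))
  invisible(x)
}

#' Species-pool decoupling verdict
#'
#' Compares the observed gamma-beta regression with the random-sampling
#' expectation. The verdict is `"pool-driven"` only when the observed
#' direction is positive and the observed slope lies within the expected
#' curve's 95 percent Monte-Carlo band around its fitted slope; any other
#' outcome (negative or absent observed relationship, or a slope outside
#' the band) is `"decoupled"`, meaning the species pool does not explain
#' local beta-diversity and assembly processes must.
#'
#' @param curve a `gamma_beta_curve` from [expected_beta_vs_gamma()].
#' @param observed a `gamma_beta_regression` from [observed_gamma_beta()].
#' @return object of class `decoupling_report` with the verdict and the
#'   compared slopes.
#' @export
decoupling_report <- function(curve, observed) {
  stopifnot(inherits(curve, "gamma_beta_curve"),
            inherits(observed, "gamma_beta_regression"))
  g <- curve$gamma
  w <- g - mean(g)
  cexp <- w / sum(w^2)                       # linear slope estimator weights
  slope_exp <- sum(cexp * curve$mean_dispersion)
  se_exp <- sqrt(sum(cexp^2 * curve$se^2))   # MC error propagated to the slope
  lo <- slope_exp - 1.96 * se_exp
  hi <- slope_exp + 1.96 * se_exp
  within <- observed$slope >= lo && observed$slope <= hi
  verdict <- if (observed$direction == "positive" && within)
    "pool-driven" else "decoupled"
  structure(list(verdict = verdict, observed_slope = observed$slope,
                 observed_direction = observed$direction,
                 expected_slope = slope_exp, expected_band = c(lo, hi)),
            class = "decoupling_report")
}

#' @export
print.decoupling_report <- function(x, ...) {
  cat("Species-pool test:", x$verdict, "\n")
  cat(sprintf("  observed slope %.4g (%s); expected slope %.4g, 95%% band [%.4g, %.4g]\n",
              x$observed_slope, x$observed_direction, x$expected_slope,
              x$expected_band[1], x$expected_band[2]))
  invisible(x)
}
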