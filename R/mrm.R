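#' Unfold a distance matrix into its lower triangle
#'
#' Pair ordering is fixed as (2,1), (3,1), ..., (n, n-1), so matrices
#' sharing labels unfold to aligned vectors.
#'
#' @param dm a `dist_matrix`.
#' @return data frame `i`, `j`, `value` with `n (n-1) / 2` rows.
#' @export
unfold <- function(dm) unfold_pairs(dm)

#' Refold an unfolded vector into a distance matrix
#'
#' Inverse of [unfold()] given the original label order.
#'
#' @param values numeric vector of lower-triangle values in [unfold()]
#'   order.
#' @param labels the matrix labels.
#' @param signed see [dist_matrix()].
#' @return a `dist_matrix`.
#' @export
refold <- function(values, labels, signed = FALSE) {
  n <- length(labels)
  if (length(values) != n * (n - 1) / 2)
    stop_validation("values length does not match labels")
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- values
  m <- m + t(m)
  dist_matrix(m, signed = signed)
}

#' Multiple regression on distance matrices (MRM)
#'
#' OLS of the unfolded response matrix on the unfolded predictor matrices,
#' with significance from a matrix permutation test: each permutation
#' relabels the response matrix's samples (permuting rows and columns
#' jointly, which preserves the distance-matrix dependence structure) and
#' recomputes R-squared and coefficients;
#' `p = (1 + #(perm >= obs)) / (1 + n_perm)`, one-tailed on R-squared and
#' two-tailed (on `|b|`) per coefficient.
#'
#' @param response a `dist_matrix`.
#' @param predictors a named list of `dist_matrix` objects sharing the
#'   response's labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return object of class `mrm_fit`: `coefficients`, `r2`, `p_r2`,
#'   `p_coef`, `n_perm`, `n_pairs`.
#' @export
mrm_fit <- function(response, predictors, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop_validation("n_perm must be >= 99")
  if (!is.list(predictors)) predictors <- list(predictor = predictors)
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    names(predictors) <- paste0("predictor", seq_along(predictors))
  labels <- rownames(response)
  X <- vapply(predictors, function(p) unfold_pairs(subset_dm(p, labels))$value,
              numeric(length(labels) * (length(labels) - 1) / 2))
  X <- cbind(`(Intercept)` = 1, X)
  # collinearity guard: name the offending predictor pair
  if (ncol(X) > 2) {
    cx <- abs(stats::cor(X[, -1, drop = FALSE]))
    diag(cx) <- 0
    if (any(cx > 1 - 1e-10)) {
      bad <- which(cx == max(cx), arr.ind = TRUE)[1, ]
      stop_validation("collinear predictors: ",
                      paste(colnames(cx)[bad], collapse = " and "))
    }
  }
  if (kappa(qr.R(qr(scale(X[, -1, drop = FALSE])))) > 1e10)
    stop_validation("predictor matrix is numerically singular")
  y <- unfold_pairs(response)$value
  fit_once <- function(yv) {
    f <- stats::lm.fit(X, yv)
    b <- f$coefficients
    r2 <- 1 - sum(f$residuals^2) / sum((yv - mean(yv))^2)
    list(b = b, r2 = r2)
  }
  obs <- fit_once(y)
  n <- length(labels)
  rm_ <- unclass(response)
  ge_r2 <- 0
  ge_b <- numeric(ncol(X))
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      p <- sample.int(n)
      yp <- rm_[p, p][lower.tri(rm_)]
      pf <- fit_once(yp)
      ge_r2 <- ge_r2 + (pf$r2 >= obs$r2)
      ge_b <- ge_b + (abs(pf$b) >= abs(obs$b))
    }
  })
  structure(list(coefficients = obs$b, r2 = obs$r2,
                 p_r2 = (1 + ge_r2) / (1 + n_perm),
                 p_coef = stats::setNames((1 + ge_b) / (1 + n_perm),
                                          colnames(X)),
                 n_perm = n_perm, n_pairs = length(y),
                 predictor_names = names(predictors)),
            class = "mrm_fit")
}

#' @export
print.mrm_fit <- function(x, ...) {
  cat(sprintf("MRM: R2 %.4f (permutation p %.4g, %d perms, %d pairs)\n",
              x$r2, x$p_r2, x$n_perm, x$n_pairs))
  print(data.frame(coefficient = x$coefficients, p = x$p_coef), digits = 4)
  invisible(x)
}

#' Euclidean distance matrix of one environmental variable
#'
#' Absolute difference of the z-scored variable between samples; samples
#' with missing values are dropped pairwise (the count is reported via a
#' message).
#'
#' @param metadata a `sample_metadata` frame.
#' @param var environmental variable name.
#' @param standardize z-score before differencing.
#' @return a `dist_matrix` over the samples with non-missing values.
#' @export
env_distance <- function(metadata, var, standardize = TRUE) {
  v <- metadata[[var]]
  if (is.null(v)) stop_validation("variable not in metadata: ", var)
  ok <- !is.na(v)
  if (any(!ok)) message(sum(!ok), " sample(s) with missing ", var, " dropped")
  v <- v[ok]
  if (standardize && stats::sd(v) > 0) v <- (v - mean(v)) / stats::sd(v)
  d <- abs(outer(v, v, "-"))
  dimnames(d) <- list(metadata$sample_id[ok], metadata$sample_id[ok])
  dist_matrix(d)
}

#' MRM attribution of beta-diversity
#'
#' Runs the three model families that partition explained beta-diversity,
#' per group: (a) assembly processes, `beta ~ betaNTI` (the signed betaNTI
#' matrix as-is by default, `|betaNTI|` optionally); (b) biotic
#' interactions, `beta ~ topology distance`; (c) environment, one
#' single-predictor model per environmental variable's z-scored Euclidean
#' distance, ranked by R-squared.
#'
#' @param beta_dm response `dist_matrix` (Bray-Curtis or betaMNTD).
#' @param bnti_dm signed betaNTI `dist_matrix` (or NULL to skip model a).
#' @param topo_dm topology `dist_matrix` (or NULL to skip model b).
#' @param metadata a `sample_metadata` frame supplying env variables.
#' @param env_vars environmental variable names (default the metadata's
#'   recorded env variables).
#' @param groups optional named vector sample id -> group; NULL = one
#'   pooled group `"all"`.
#' @param n_perm,seed passed to [mrm_fit()].
#' @param abs_bnti use `|betaNTI|` for model (a).
#' @return data frame of class `mrm_attribution`: `group`, `model`,
#'   `variable`, `coefficient`, `r2`, `p`, `n_pairs`.
#' @export
attribution_suite <- function(beta_dm, bnti_dm = NULL, topo_dm = NULL,
                              metadata, env_vars = NULL, groups = NULL,
                              n_perm = 999, seed = 1, abs_bnti = FALSE) {
  env_vars <- env_vars %||% attr(metadata, "env_vars")
  samples <- rownames(beta_dm)
  if (is.null(groups)) groups <- stats::setNames(rep("all", length(samples)), samples)
  rows <- list()
  for (g in unique(groups[samples])) {
    ids <- samples[groups[samples] == g]
    if (length(ids) < 4) next
    resp <- subset_dm(beta_dm, ids)
    run <- function(model, variable, pred) {
      fit <- mrm_fit(resp, stats::setNames(list(pred), variable),
                     n_perm = n_perm, seed = seed)
      data.frame(group = g, model = model, variable = variable,
                 coefficient = unname(fit$coefficients[2]),
                 r2 = fit$r2, p = fit$p_r2, n_pairs = fit$n_pairs,
                 stringsAsFactors = FALSE)
    }
    if (!is.null(bnti_dm)) {
      b <- subset_dm(bnti_dm, ids)
      if (abs_bnti) b <- dist_matrix(abs(unclass(b)))
      rows[[length(rows) + 1L]] <- run("assembly", "betaNTI", b)
    }
    if (!is.null(topo_dm))
      rows[[length(rows) + 1L]] <- run("biotic", "topology",
                                       subset_dm(topo_dm, ids))
    for (v in env_vars) {
      ed <- env_distance(metadata, v)
      use <- intersect(ids, rownames(ed))
      if (length(use) < 4) next
      fit <- mrm_fit(subset_dm(beta_dm, use),
                     stats::setNames(list(subset_dm(ed, use)), v),
                     n_perm = n_perm, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, model = "environment", variable = v,
        coefficient = unname(fit$coefficients[2]),
        r2 = fit$r2, p = fit$p_r2, n_pairs = fit$n_pairs,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # rank environment models by explained variance within group
  out <- out[order(out$group, out$model, -out$r2), ]
  rownames(out) <- NULL
  class(out) <- c("mrm_attribution", "data.frame")
  out
}
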