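#' Great-circle distance matrix between samples
#'
#' Haversine distance in kilometres (Earth radius 6371.0088 km) from the
#' metadata coordinates.
#'
#' @param metadata a `sample_metadata` frame.
#' @return a `dist_matrix` labeled by sample id, in km.
#' @export
geographic_distance <- function(metadata) {
  bad <- is.na(metadata$latitude) | is.na(metadata$longitude)
  if (any(bad))
    stop_validation("missing coordinates for: ",
                    paste(metadata$sample_id[bad], collapse = ", "))
  xy <- cbind(metadata$longitude, metadata$latitude)
  d <- geosphere::distm(xy, xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
  dimnames(d) <- list(metadata$sample_id, metadata$sample_id)
  diag(d) <- 0
  dist_matrix(d)
}

# Lower-triangle unfolding shared by DDR and MRM; fixed pair order
# (2,1), (3,1), ..., (n, n-1).
unfold_pairs <- function(dm) {
  m <- unclass(dm)
  n <- nrow(m)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  data.frame(i = rownames(m)[idx[, 1]], j = colnames(m)[idx[, 2]],
             value = m[idx], stringsAsFactors = FALSE)
}

#' Distance-decay regression
#'
#' Ordinary least squares of pairwise community dissimilarity on pairwise
#' geographic distance (raw km by default), over the lower triangle of the
#' two matrices. Because the `n (n-1) / 2` pairs are not independent
#' observations, the parametric p-value is nominal; an optional
#' Mantel-style permutation p (permuting sample labels of the community
#' matrix) is available via `n_perm`.
#'
#' @param community_dm `dist_matrix` of dissimilarities (Bray-Curtis or
#'   betaMNTD).
#' @param geo_dm `dist_matrix` of geographic distances (km).
#' @param group character vector of sample ids to restrict to, or `"all"`.
#' @param kind label recorded in the fit (`"bray"` or `"bmntd"`).
#' @param log_distance regress on `log10(km + 1)` instead of raw km.
#' @param n_perm number of label permutations for the optional permutation
#'   p-value (0 = skip).
#' @param seed seed for the permutations.
#' @return object of class `ddr_fit`: slope (dissimilarity per km),
#'   intercept, `r2`, `p_value`, `n_pairs`, and `p_perm` when requested.
#' @export
fit_ddr <- function(community_dm, geo_dm, group = "all", kind = "bray",
                    log_distance = FALSE, n_perm = 0, seed = 1) {
  labels <- if (identical(group, "all")) rownames(community_dm) else group
  if (length(labels) < 3) stop_validation("group needs >= 3 samples")
  cdm <- subset_dm(community_dm, labels)
  gdm <- subset_dm(geo_dm, labels)
  y <- unfold_pairs(cdm)$value
  x <- unfold_pairs(gdm)$value
  if (log_distance) x <- log10(x + 1)
  if (stats::sd(x) == 0) stop_validation("zero variance in distances: degenerate fit")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  out <- list(group = if (identical(group, "all")) "all" else "subset",
              labels = labels, kind = kind,
              slope = slope, intercept = unname(stats::coef(fit)[1]),
              r2 = sm$r.squared,
              p_value = sm$coefficients[2, 4],
              n_pairs = length(y), log_distance = log_distance,
              nonindependent_pairs = TRUE)
  if (n_perm > 0) {
    obs <- abs(slope)
    n <- length(labels)
    m <- unclass(cdm)
    perm_ge <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(k) {
        p <- sample.int(n)
        yp <- m[p, p][lower.tri(m)]
        abs(unname(stats::coef(stats::lm(yp ~ x))[2])) >= obs
      }, logical(1)))
    })
    out$p_perm <- (1 + perm_ge) / (1 + n_perm)
    out$n_perm <- n_perm
  }
  class(out) <- "ddr_fit"
  out
}

#' @export
print.ddr_fit <- function(x, ...) {
  cat(sprintf("Distance-decay (%s, %s): slope %.3e per km, R2 %.3f, p %.3g (n_pairs %d)\n",
              x$kind, x$group, x$slope, x$r2, x$p_value, x$n_pairs))
  if (!is.null(x$p_perm))
    cat(sprintf("  permutation p (%d perms): %.4f\n", x$n_perm, x$p_perm))
  cat("  note: pairwise observations are non-independent; parametric p is nominal\n")
  invisible(x)
}

#' Compare distance-decay slopes across groups
#'
#' Fits one pooled linear model `dissimilarity ~ distance * group` over all
#' retained within-group pairs (saturated per-group coding, so each group's
#' marginal slope equals its own separate regression), then reports all
#' pairwise slope differences with standard errors from the model
#' covariance and t-tests on the residual degrees of freedom. With
#' `include_all = TRUE` an `"All"` pseudo-group containing every pair
#' enters the same pooled model; its pairs then overlap the named groups
#' and the output flags the comparison as non-disjoint.
#'
#' @param community_dm,geo_dm `dist_matrix` objects sharing labels.
#' @param groups vector of group labels, one per sample of `community_dm`.
#' @param include_all add the `"All"` pseudo-group of every pair.
#' @return object of class `slope_contrasts`: `$fits` (per-group slope,
#'   intercept, SE, n_pairs) and `$contrasts` (pair of groups, slope
#'   difference, SE, df, p, disjoint flag).
#' @export
compare_slopes <- function(community_dm, geo_dm, groups, include_all = FALSE) {
  samples <- rownames(community_dm)
  if (length(groups) != length(samples))
    stop_validation("groups length must match samples")
  sizes <- table(groups)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("group(s) with < 3 samples excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  keep_groups <- setdiff(names(sizes), small)
  if (length(keep_groups) < 2 && !include_all)
    stop_validation("need >= 2 groups with >= 3 samples")
  cm <- unclass(subset_dm(community_dm, samples))
  gm <- unclass(subset_dm(geo_dm, samples))
  idx <- which(lower.tri(cm), arr.ind = TRUE)
  gi <- groups[idx[, 1]]; gj <- groups[idx[, 2]]
  rows <- list()
  for (g in keep_groups) {
    sel <- gi == g & gj == g
    rows[[g]] <- data.frame(y = cm[idx[sel, , drop = FALSE]],
                            x = gm[idx[sel, , drop = FALSE]], g = g)
  }
  if (include_all)
    rows[["All"]] <- data.frame(y = cm[idx], x = gm[idx], g = "All")
  dat <- do.call(rbind, rows)
  dat$g <- factor(dat$g, levels = c(keep_groups, if (include_all) "All"))
  fit <- stats::lm(y ~ 0 + g + x:g, data = dat)
  cf <- stats::coef(fit); V <- stats::vcov(fit)
  lv <- levels(dat$g)
  slope_name <- function(g) paste0("g", g, ":x")
  fits <- data.frame(group = lv,
                     intercept = unname(cf[paste0("g", lv)]),
                     slope = unname(cf[slope_name(lv)]),
                     slope_se = sqrt(diag(V)[slope_name(lv)]),
                     n_pairs = as.integer(table(dat$g)[lv]),
                     row.names = NULL, stringsAsFactors = FALSE)
  dfres <- fit$df.residual
  combs <- utils::combn(lv, 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    a <- combs[1, k]; b <- combs[2, k]
    dd <- cf[slope_name(a)] - cf[slope_name(b)]
    se <- sqrt(V[slope_name(a), slope_name(a)] + V[slope_name(b), slope_name(b)] -
               2 * V[slope_name(a), slope_name(b)])
    data.frame(group_a = a, group_b = b, slope_diff = unname(dd),
               se = se, df = dfres,
               p_value = 2 * stats::pt(-abs(dd / se), dfres),
               disjoint = !(a == "All" || b == "All"),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, contrasts = contrasts, df_residual = dfres),
            class = "slope_contrasts")
}

#' @export
print.slope_contrasts <- function(x, ...) {
  cat("Distance-decay slope contrasts (pooled model, residual df",
      x$df_residual, ")\n")
  print(x$fits, digits = 4)
  print(x$contrasts, digits = 4)
  invisible(x)
}
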