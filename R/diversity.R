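#' Rarefy a community table to even depth
#'
#' Global singletons (taxa whose total count across the whole table is 1)
#' are removed first; each remaining sample is then subsampled without
#' replacement to exactly `depth` reads. Samples with fewer than `depth`
#' reads are dropped with a warning, and taxa left with all-zero columns
#' are removed.
#'
#' @param table a [community_table()].
#' @param depth rarefaction depth (reads per sample), conventionally 800
#'   for low-yield functional-gene amplicons.
#' @param seed integer seed making the subsampling reproducible.
#' @param remove_singletons drop global singletons before rarefying.
#' @return a rarefied [community_table()]; every row sums to `depth`.
#' @export
rarefy <- function(table, depth = 800, seed = 1, remove_singletons = TRUE) {
  if (depth <= 0) stop_validation("depth must be >= 1")
  m <- unclass(table)
  if (remove_singletons) m <- m[, colSums(m) != 1L, drop = FALSE]
  keep <- rowSums(m) >= depth
  if (!any(keep)) stop_validation("all samples below rarefaction depth")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(m)[!keep], collapse = ", "), call. = FALSE)
  m <- m[keep, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(m, 1, function(x) {
      reads <- sample(rep.int(seq_along(x), x), depth)
      tabulate(reads, nbins = length(x))
    }))
  })
  dimnames(out) <- dimnames(m)
  out <- out[, colSums(out) > 0, drop = FALSE]
  community_table(out)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum_j |x_j - y_j| / sum_j (x_j + y_j)`, in `[0, 1]`.
#'
#' @param table a [community_table()] (or numeric matrix, samples x taxa).
#' @return a `dist_matrix` of pairwise dissimilarities.
#' @export
bray_curtis <- function(table) {
  m <- unclass(table)
  if (nrow(m) < 2) stop_validation("need at least 2 samples")
  rs <- rowSums(m)
  if (sum(rs == 0) >= 2)
    stop_validation("Bray-Curtis undefined for a pair of all-zero samples")
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  den <- outer(rs, rs, "+")
  bc <- num / den
  diag(bc) <- 0
  dist_matrix(bc)
}

# Minimum patristic distance from every taxon to each community:
# M[i, s] = min over taxa j present in sample s of D[i, j]. A taxon present
# in s has M = 0 (its own nearest relative is itself).
min_dist_to_community <- function(D, presence) {
  vapply(seq_len(ncol(presence)), function(s) {
    cols <- presence[, s]
    if (!any(cols)) return(rep(NA_real_, nrow(D)))
    do.call(pmin, lapply(which(cols), function(j) D[, j]))
  }, numeric(nrow(D)))
}

# Core betaMNTD kernel shared with the null model: F is taxa x samples
# weights (rows summing to 1 per sample over present taxa), D taxa x taxa
# patristic distances, presence taxa x samples logical.
bmntd_kernel <- function(D, presence, Fw) {
  M <- min_dist_to_community(D, presence)
  A <- crossprod(Fw, M)            # A[k, m] = sum_i F[i,k] * M[i,m]
  B <- (A + t(A)) / 2
  diag(B) <- 0
  B
}

#' Beta mean nearest taxon distance (betaMNTD)
#'
#' For communities k and m, the average patristic distance from each taxon
#' in one community to its closest relative in the other:
#' `0.5 * (sum_i f_ik min_j d_ij + sum_j f_jm min_i d_ji)`, abundance-
#' weighted by default (uniform weights over present taxa otherwise).
#' Shared taxa contribute zero (their nearest relative is themselves).
#'
#' @param table a [community_table()].
#' @param tree a `phylo` whose tips include every taxon with nonzero counts.
#' @param abundance_weighted weight taxa by within-sample relative
#'   abundance (TRUE) or uniformly (FALSE).
#' @return a `dist_matrix` of pairwise betaMNTD values.
#' @export
beta_mntd <- function(table, tree, abundance_weighted = TRUE) {
  m <- unclass(table)
  present_taxa <- colnames(m)[colSums(m) > 0]
  miss <- setdiff(present_taxa, tree$tip.label)
  if (length(miss))
    stop_validation("taxa missing from tree: ", paste(miss, collapse = ", "))
  m <- m[, present_taxa, drop = FALSE]
  D <- stats::cophenetic(tree)[present_taxa, present_taxa]
  presence <- t(m) > 0
  Fw <- community_weights(m, abundance_weighted)
  B <- bmntd_kernel(D, presence, Fw)
  dimnames(B) <- list(rownames(m), rownames(m))
  dist_matrix(B)
}

# taxa x samples weight matrix (columns sum to 1)
community_weights <- function(m, abundance_weighted) {
  if (abundance_weighted) {
    Fw <- t(m / rowSums(m))
  } else {
    pres <- t(m) > 0
    Fw <- pres / rep(colSums(pres), each = nrow(pres))
  }
  Fw
}

#' Per-sample beta-diversity as multivariate dispersion
#'
#' Embeds the dissimilarity matrix by principal coordinates (with the
#' standard imaginary-axis correction for negative eigenvalues) and returns
#' each sample's distance to its group centroid, giving a single
#' beta-diversity value per sample. Computed with [vegan::betadisper()].
#'
#' @param dm a `dist_matrix` of community dissimilarities.
#' @param groups vector of group labels, one per sample in `dm` (a single
#'   label recycles to one global group).
#' @param centroid_type `"centroid"` or `"spatial_median"`.
#' @return data frame: `sample_id`, `group`, `distance_to_centroid`.
#' @export
beta_dispersion <- function(dm, groups = "all",
                            centroid_type = c("centroid", "spatial_median")) {
  centroid_type <- match.arg(centroid_type)
  n <- nrow(dm)
  if (length(groups) == 1L) groups <- rep(groups, n)
  if (length(groups) != n) stop_validation("groups length must match samples")
  type <- if (centroid_type == "centroid") "centroid" else "median"
  if (max(abs(unclass(dm))) < 1e-14) {
    # fully degenerate input: all samples coincide
    dists <- rep(0, n)
  } else {
    # negative PCoA eigenvalues are handled by vegan's imaginary-axis
    # correction (squared distances floored at zero); silence its notice
    bd <- suppressWarnings(
      vegan::betadisper(stats::as.dist(unclass(dm)), group = factor(groups),
                        type = type))
    dists <- as.numeric(bd$distances)
  }
  data.frame(sample_id = rownames(dm), group = as.character(groups),
             distance_to_centroid = dists,
             stringsAsFactors = FALSE)
}

#' Incidence-based (Chao2) gamma-diversity per group
#'
#' Estimates the group species pool from incidence frequencies:
#' `S_chao2 = S_obs + ((N-1)/N) * Q1^2 / (2 Q2)` when `Q2 > 0`, and the
#' bias-corrected `S_obs + ((N-1)/N) * Q1 (Q1 - 1) / 2` when `Q2 = 0`,
#' where `Q1`/`Q2` count taxa occurring in exactly one / two samples of the
#' group. Groups of a single sample return `S_obs` with extrapolation
#' flagged unavailable.
#'
#' @param table a [community_table()].
#' @param groups group label per sample (single label = one pooled group).
#' @return data frame: `group`, `S_obs`, `Q1`, `Q2`, `N`, `S_chao2`,
#'   `extrapolated`.
#' @export
estimate_gamma <- function(table, groups = "all") {
  m <- unclass(table)
  if (length(groups) == 1L) groups <- rep(groups, nrow(m))
  if (length(groups) != nrow(m)) stop_validation("groups length must match samples")
  out <- lapply(split(seq_len(nrow(m)), groups), function(idx) {
    inc <- colSums(m[idx, , drop = FALSE] > 0)
    S <- sum(inc > 0); Q1 <- sum(inc == 1); Q2 <- sum(inc == 2)
    N <- length(idx)
    if (N < 2) {
      data.frame(S_obs = S, Q1 = Q1, Q2 = Q2, N = N, S_chao2 = S,
                 extrapolated = FALSE)
    } else {
      add <- if (Q2 > 0) ((N - 1) / N) * Q1^2 / (2 * Q2)
             else ((N - 1) / N) * Q1 * (Q1 - 1) / 2
      data.frame(S_obs = S, Q1 = Q1, Q2 = Q2, N = N, S_chao2 = S + add,
                 extrapolated = TRUE)
    }
  })
  res <- do.call(rbind, out)
  data.frame(group = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}
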