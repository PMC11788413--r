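#' Filter taxa by overall relative abundance
#'
#' Retains taxa whose total count divided by the grand total is at least
#' `min_rel_abund` (default 0.01 percent, the conventional prefilter
#' before co-occurrence network construction).
#'
#' @param table a [community_table()].
#' @param min_rel_abund minimum overall relative abundance in `[0, 1)`.
#' @return the filtered [community_table()].
#' @export
filter_taxa <- function(table, min_rel_abund = 1e-4) {
  if (min_rel_abund < 0 || min_rel_abund >= 1)
    stop_validation("min_rel_abund must be in [0, 1)")
  m <- unclass(table)
  rel <- colSums(m) / sum(m)
  keep <- rel >= min_rel_abund
  if (!any(keep)) stop_validation("no taxa pass the abundance filter")
  community_table(m[, keep, drop = FALSE])
}

#' Pairwise Spearman correlations between taxa
#'
#' Computes rho with mid-rank tie handling on per-sample relative
#' abundances, a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`, and Benjamini-Hochberg adjusted
#' p-values over all evaluated pairs. Pairs involving a constant taxon
#' vector are excluded (rho undefined) and counted in the
#' `"n_excluded"` attribute.
#'
#' @param table a [community_table()] with at least 4 samples.
#' @return data frame of class `correlation_set`: `taxon_i`, `taxon_j`,
#'   `rho`, `p`, `p_adj`; attributes `n_samples`, `taxa`, `n_excluded`.
#' @export
spearman_correlations <- function(table) {
  m <- unclass(table)
  n <- nrow(m)
  if (n < 4) stop_validation("need >= 4 samples for correlations")
  rel <- m / rowSums(m)
  constant <- apply(rel, 2, function(x) stats::sd(x) == 0)
  ranks <- apply(rel[, !constant, drop = FALSE], 2, rank)
  R <- stats::cor(ranks)
  taxa <- colnames(ranks)
  idx <- which(lower.tri(R), arr.ind = TRUE)
  rho <- R[idx]
  rho_c <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- rho_c * sqrt((n - 2) / (1 - rho_c^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  out <- data.frame(taxon_i = taxa[idx[, 1]], taxon_j = taxa[idx[, 2]],
                    rho = rho, p = p, p_adj = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  n_const <- sum(constant)
  structure(out, class = c("correlation_set", "data.frame"),
            n_samples = n, taxa = taxa,
            n_excluded = n_const * (ncol(m) - n_const) +
              choose(n_const, 2))
}

# rebuild the full rho matrix from a correlation_set
corr_matrix <- function(corr) {
  taxa <- attr(corr, "taxa")
  R <- diag(1, length(taxa))
  dimnames(R) <- list(taxa, taxa)
  i <- match(corr$taxon_i, taxa); j <- match(corr$taxon_j, taxa)
  R[cbind(i, j)] <- corr$rho
  R[cbind(j, i)] <- corr$rho
  R
}

#' Random-matrix-theory correlation threshold
#'
#' Scans candidate cut-offs: at each `s` the correlation matrix is
#' hard-thresholded (entries with `|rho| < s` zeroed, unit diagonal), its
#' eigenvalue spectrum is unfolded with a cubic smoothing spline on the
#' cumulative spectral density, and the nearest-neighbor spacing
#' distribution (NNSD) of the unfolded eigenvalues is tested against the
#' Poisson law `exp(-s)` by a Kolmogorov-Smirnov test. The returned
#' threshold is the smallest `s` whose NNSD is Poisson-consistent
#' (KS p > `ks_alpha`) - the Wigner-to-Poisson transition separating
#' correlated signal from random noise. If no candidate qualifies the
#' configured `fallback` (0.68 by default) is returned with a warning.
#'
#' @param corr a `correlation_set` from [spearman_correlations()].
#' @param scan candidate thresholds to test, in increasing order.
#' @param fallback value returned when the scan finds no transition.
#' @param ks_alpha KS significance level declaring Poisson consistency.
#' @param spline_df degrees of freedom of the unfolding spline.
#' @return the chosen threshold, with attributes `ks_p` (its KS p-value)
#'   and `scan` (per-candidate results).
#' @export
rmt_threshold <- function(corr, scan = seq(0.30, 0.90, by = 0.01),
                          fallback = 0.68, ks_alpha = 0.05, spline_df = 10) {
  R <- corr_matrix(corr)
  results <- data.frame(threshold = as.numeric(scan),
                        n_eigen = rep(NA_integer_, length(scan)),
                        ks_p = rep(NA_real_, length(scan)))
  if (length(scan)) {
    for (k in seq_along(scan)) {
      s <- scan[k]
      M <- R
      M[abs(M) < s] <- 0
      diag(M) <- 1
      # keep taxa with at least one surviving off-diagonal entry
      deg <- rowSums(M != 0) - 1
      M <- M[deg > 0, deg > 0, drop = FALSE]
      if (nrow(M) < 10) next
      ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
      # duplicate eigenvalues carry no spacing information; drop them
      ev <- ev[c(TRUE, diff(ev) > 1e-8)]
      if (length(ev) < 10) next
      results$n_eigen[k] <- length(ev)
      fit <- stats::smooth.spline(ev, seq_along(ev),
                                  df = min(spline_df, length(ev) - 1))
      unfolded <- stats::predict(fit, ev)$y
      sp <- diff(unfolded)
      sp <- sp[sp > 0]
      if (length(sp) < 5) next
      sp <- sp / mean(sp)
      results$ks_p[k] <- suppressWarnings(
        stats::ks.test(sp, stats::pexp, rate = 1)$p.value)
      if (!is.na(results$ks_p[k]) && results$ks_p[k] > ks_alpha) {
        return(structure(s, ks_p = results$ks_p[k],
                         scan = results[seq_len(k), ]))
      }
    }
  }
  warning("no Wigner-to-Poisson transition found in scan; using fallback ",
          fallback, call. = FALSE)
  structure(fallback, ks_p = NA_real_, scan = results, fallback_used = TRUE)
}

#' Build a co-occurrence network
#'
#' Edges connect taxon pairs with `|rho| >= threshold` and BH-adjusted
#' p below `fdr_alpha`; isolated taxa are dropped. An empty edge set gives
#' an empty network with a warning rather than an error.
#'
#' @param corr a `correlation_set`.
#' @param threshold correlation magnitude cut-off in `(0, 1]` (e.g. the
#'   value returned by [rmt_threshold()]).
#' @param fdr_alpha FDR ceiling for edges (default 0.001).
#' @return an [igraph::graph] with edge attributes `weight` (rho) and
#'   `sign`, and graph attributes `threshold` and `fdr_alpha`.
#' @export
build_network <- function(corr, threshold, fdr_alpha = 0.001) {
  if (threshold <= 0 || threshold > 1)
    stop_validation("threshold must be in (0, 1]")
  keep <- abs(corr$rho) >= threshold & corr$p_adj < fdr_alpha
  edges <- corr[keep, , drop = FALSE]
  if (!nrow(edges))
    warning("no edges survive the threshold/FDR filters; empty network",
            call. = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon_i", "taxon_j")], directed = FALSE,
    vertices = unique(c(edges$taxon_i, edges$taxon_j)))
  igraph::E(g)$weight <- edges$rho
  igraph::E(g)$sign <- sign(edges$rho)
  g <- igraph::set_graph_attr(g, "threshold", as.numeric(threshold))
  g <- igraph::set_graph_attr(g, "fdr_alpha", fdr_alpha)
  g
}

#' Topological properties of a co-occurrence network
#'
#' Summaries used as proxies for biotic interactions: node and edge
#' counts, average degree, average shortest-path length over connected
#' pairs, mean local clustering coefficient, connectivity (connectance:
#' realized fraction of possible edges), and modularity plus module count
#' from greedy modularity maximization (deterministic).
#'
#' @param net an [igraph::graph] from [build_network()].
#' @param modularity_seed seed kept for interface stability (the greedy
#'   algorithm is deterministic).
#' @return one-row data frame of class `network_topology`: `n_nodes`,
#'   `n_edges`, `n_modules`, `average_degree`, `average_path_length`,
#'   `clustering_coefficient`, `connectivity`, `modularity`, `empty`.
#' @export
topology <- function(net, modularity_seed = 1) {
  n <- igraph::vcount(net); m <- igraph::ecount(net)
  if (n == 0 || m == 0) {
    out <- data.frame(n_nodes = 0L, n_edges = 0L, n_modules = 0L,
                      average_degree = 0, average_path_length = 0,
                      clustering_coefficient = 0, connectivity = 0,
                      modularity = 0, empty = TRUE)
    class(out) <- c("network_topology", "data.frame")
    return(out)
  }
  # correlation weights (possibly negative) must not enter path lengths or
  # modularity: topology is computed on the unweighted graph
  apl <- igraph::mean_distance(net, directed = FALSE, unconnected = TRUE,
                               weights = NA)
  cc <- igraph::transitivity(net, type = "localaverage", isolates = "zero")
  comm <- with_seed(modularity_seed,
    igraph::cluster_fast_greedy(net, weights = NA))
  out <- data.frame(n_nodes = n, n_edges = m,
                    n_modules = length(comm),
                    average_degree = 2 * m / n,
                    average_path_length = apl,
                    clustering_coefficient = cc,
                    connectivity = m / (n * (n - 1) / 2),
                    modularity = igraph::modularity(comm),
                    empty = FALSE)
  class(out) <- c("network_topology", "data.frame")
  out
}

#' Per-sample network topology
#'
#' For each sample, the topology of the subgraph of `net` induced by the
#' taxa present in that sample - the construction that turns a group-level
#' network into per-sample topology vectors, so that a sample-by-sample
#' topology distance (conformable with the beta-diversity matrix) can be
#' built for MRM.
#'
#' @param net an [igraph::graph].
#' @param table the [community_table()] the network was built from.
#' @param modularity_seed passed to [topology()].
#' @return data frame: one `network_topology` row per sample, with a
#'   `unit` column of sample ids.
#' @export
sample_topologies <- function(net, table, modularity_seed = 1) {
  m <- unclass(table)
  rows <- lapply(rownames(m), function(s) {
    taxa <- colnames(m)[m[s, ] > 0]
    sub <- igraph::induced_subgraph(net,
      intersect(taxa, igraph::V(net)$name))
    cbind(unit = s, topology(sub, modularity_seed))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Euclidean distance between topology vectors
#'
#' Stacks the eight topological properties per unit (sample or group),
#' optionally z-standardizes each property across units (properties with
#' zero variance contribute nothing), and returns pairwise Euclidean
#' distances.
#'
#' @param per_unit data frame with a `unit` column and topology columns,
#'   e.g. from [sample_topologies()].
#' @param standardize z-score each property across units.
#' @return a `dist_matrix` labeled by unit.
#' @export
topology_distance <- function(per_unit, standardize = TRUE) {
  props <- c("n_nodes", "n_edges", "n_modules", "average_degree",
             "average_path_length", "clustering_coefficient",
             "connectivity", "modularity")
  miss <- setdiff(props, names(per_unit))
  if (length(miss))
    stop_validation("missing topology properties: ", paste(miss, collapse = ", "))
  if (nrow(per_unit) < 2) stop_validation("need >= 2 units")
  X <- as.matrix(per_unit[, props])
  if (anyNA(X)) stop_validation("missing property values")
  rownames(X) <- per_unit$unit
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
    X[, sds == 0] <- 0
  }
  d <- as.matrix(stats::dist(X))
  dist_matrix(d)
}
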