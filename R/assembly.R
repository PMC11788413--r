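#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of betaMNTD against a taxa-shuffle null:
#' `betaNTI = (betaMNTD_obs - mean(betaMNTD_null)) / sd(betaMNTD_null)`.
#' Each null replicate shuffles taxon identities across the tree tips once
#' and recomputes betaMNTD for the whole table, so all pairs share the
#' same null draws per replicate (statistically identical to per-pair
#' shuffles, about `n^2`-fold cheaper). Pairs whose null spread is zero
#' (e.g. a star phylogeny leaves betaMNTD invariant under relabeling) get
#' betaNTI 0 and the matrix carries a `"degenerate"` attribute marking
#' them. `|betaNTI| > 2` signals selection: variable if above +2,
#' homogeneous if below -2.
#'
#' @param table a [community_table()].
#' @param tree a `phylo` covering all taxa with nonzero counts.
#' @param n_null number of null randomizations (>= 99; 999 conventional).
#' @param abundance_weighted weight betaMNTD by relative abundance.
#' @param seed integer seed; the matrix is deterministic given it.
#' @return a signed `dist_matrix` of betaNTI values with attributes
#'   `"degenerate"` (logical matrix) and `"unevaluable"` for pairs with
#'   fewer than 2 taxa in their union.
#' @export
beta_nti <- function(table, tree, n_null = 999, abundance_weighted = TRUE,
                     seed = 1) {
  if (n_null < 99) stop_validation("n_null must be >= 99")
  m <- unclass(table)
  present_taxa <- colnames(m)[colSums(m) > 0]
  miss <- setdiff(present_taxa, tree$tip.label)
  if (length(miss))
    stop_validation("taxa missing from tree: ", paste(miss, collapse = ", "))
  m <- m[, present_taxa, drop = FALSE]
  n_taxa <- ncol(m); n_samp <- nrow(m)
  Dfull <- stats::cophenetic(tree)
  n_tips <- nrow(Dfull)
  D <- Dfull[present_taxa, present_taxa]
  presence <- t(m) > 0
  Fw <- community_weights(m, abundance_weighted)
  obs <- bmntd_kernel(D, presence, Fw)
  sum1 <- matrix(0, n_samp, n_samp)
  sum2 <- matrix(0, n_samp, n_samp)
  with_seed(seed, {
    for (k in seq_len(n_null)) {
      # assign the observed taxa to a uniformly random subset of ALL tree
      # tips: the regional pool, not just the taxa that happen to occur
      perm <- sample.int(n_tips, n_taxa)
      Bn <- bmntd_kernel(Dfull[perm, perm, drop = FALSE], presence, Fw)
      sum1 <- sum1 + Bn
      sum2 <- sum2 + Bn * Bn
    }
  })
  mu <- sum1 / n_null
  va <- (sum2 - n_null * mu * mu) / (n_null - 1)
  sd_null <- sqrt(pmax(va, 0))
  # relative floor: running-sum cancellation leaves O(1e-8) dust where the
  # null distribution is actually constant (e.g. star phylogenies)
  degenerate <- sd_null < 1e-6 * (1 + abs(mu))
  nti <- matrix(0, n_samp, n_samp)
  nti[!degenerate] <- (obs[!degenerate] - mu[!degenerate]) / sd_null[!degenerate]
  diag(nti) <- 0
  # pairs with < 2 taxa in the union are unevaluable
  richness <- colSums(presence)
  shared <- crossprod(presence * 1)
  union_size <- outer(richness, richness, "+") - shared
  dimnames(nti) <- list(rownames(m), rownames(m))
  out <- dist_matrix(nti, signed = TRUE)
  attr(out, "degenerate") <- degenerate & upper.tri(degenerate)
  attr(out, "unevaluable") <- union_size < 2
  out
}

#' Abundance-based Raup-Crick metric (RCbray)
#'
#' Standardizes observed Bray-Curtis dissimilarity against a null model
#' that preserves each sample's richness and read total: per replicate a
#' null community is built for every sample by drawing its observed number
#' of taxa without replacement with probability proportional to occupancy
#' (fraction of samples occupied across the table), then allocating its
#' reads to the drawn taxa with probability proportional to total relative
#' abundance (one read guaranteed per drawn taxon). For each pair,
#' `RC = 2 * (#(BC_null < BC_obs) + 0.5 #(BC_null = BC_obs)) / n_null - 1`,
#' in `[-1, 1]`. With `|betaNTI| <= 2`, RC above +0.95 signals dispersal
#' limitation, below -0.95 homogenizing dispersal, and `|RC| <= 0.95`
#' drift.
#'
#' @param table a [community_table()].
#' @param n_null number of null replicates (>= 99; 999 conventional).
#' @param seed integer seed.
#' @return a signed `dist_matrix` of RCbray values in `[-1, 1]`.
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = 1) {
  if (n_null < 99) stop_validation("n_null must be >= 99")
  m <- unclass(table)
  m <- m[, colSums(m) > 0, drop = FALSE]
  n_samp <- nrow(m); n_taxa <- ncol(m)
  richness <- rowSums(m > 0)
  reads <- rowSums(m)
  if (any(richness > n_taxa))
    stop_validation("sample richness exceeds pool richness")
  occ <- colSums(m > 0) / n_samp
  abund <- colSums(m) / sum(m)
  bc_obs <- unclass(bray_curtis(community_table(m)))
  lower <- lower.tri(bc_obs)
  obs_v <- bc_obs[lower]
  less <- numeric(length(obs_v)); ties <- numeric(length(obs_v))
  with_seed(seed, {
    null_m <- matrix(0L, n_samp, n_taxa)
    for (k in seq_len(n_null)) {
      for (s in seq_len(n_samp)) {
        drawn <- sample.int(n_taxa, richness[s], prob = occ)
        x <- integer(n_taxa)
        x[drawn] <- 1L
        extra <- reads[s] - richness[s]
        if (extra > 0)
          x[drawn] <- x[drawn] + stats::rmultinom(1, extra, abund[drawn])[, 1]
        null_m[s, ] <- x
      }
      num <- as.matrix(stats::dist(null_m, method = "manhattan"))
      den <- outer(rowSums(null_m), rowSums(null_m), "+")
      bc_null <- (num / den)[lower]
      d <- bc_null - obs_v
      less <- less + (d < -1e-12)
      ties <- ties + (abs(d) <= 1e-12)
    }
  })
  frac <- (less + 0.5 * ties) / n_null
  rc <- matrix(0, n_samp, n_samp, dimnames = list(rownames(m), rownames(m)))
  rc[lower] <- 2 * frac - 1
  rc <- rc + t(rc)
  dist_matrix(rc, signed = TRUE)
}

#' Classify assembly processes from betaNTI and RCbray
#'
#' The five-way decision rule: `betaNTI > +2` = variable selection,
#' `betaNTI < -2` = homogeneous selection; otherwise `RCbray > +0.95` =
#' dispersal limitation, `RCbray < -0.95` = homogenizing dispersal, and
#' `|RCbray| <= 0.95` = ecological drift.
#'
#' @param bnti signed `dist_matrix` of betaNTI values.
#' @param rc signed `dist_matrix` of RCbray values with the same labels.
#' @return data frame of class `pairwise_process_table`: `sample_i`,
#'   `sample_j`, `bnti`, `rc`, `process`.
#' @export
classify_processes <- function(bnti, rc) {
  if (!identical(rownames(bnti), rownames(rc)))
    stop_validation("betaNTI and RCbray matrices must share labels")
  b <- unfold_pairs(bnti); r <- unfold_pairs(rc)
  process <- ifelse(b$value > 2, "variable_selection",
             ifelse(b$value < -2, "homogeneous_selection",
             ifelse(r$value > 0.95, "dispersal_limitation",
             ifelse(r$value < -0.95, "homogenizing_dispersal", "drift"))))
  out <- data.frame(sample_i = b$i, sample_j = b$j,
                    bnti = b$value, rc = r$value, process = process,
                    stringsAsFactors = FALSE)
  class(out) <- c("pairwise_process_table", "data.frame")
  out
}

#' Fractions of sample pairs per assembly process
#'
#' @param ppt a `pairwise_process_table` from [classify_processes()].
#' @param groups optional named vector mapping sample id to group label;
#'   `NULL` pools everything into one group `"all"`.
#' @param scope `"within_group"` keeps only same-group pairs;
#'   `"all_pairs"` assigns every pair to one pooled group per label pair's
#'   shared group (cross-group pairs are kept in group `"all"`).
#' @return data frame of class `process_fractions`: group, one column per
#'   process, `stochastic` (drift + dispersal limitation + homogenizing
#'   dispersal), `n_pairs`.
#' @export
process_fractions <- function(ppt, groups = NULL,
                              scope = c("within_group", "all_pairs")) {
  scope <- match.arg(scope)
  procs <- c("variable_selection", "homogeneous_selection",
             "dispersal_limitation", "homogenizing_dispersal", "drift")
  if (is.null(groups)) {
    ppt$group <- "all"
  } else {
    gi <- groups[ppt$sample_i]; gj <- groups[ppt$sample_j]
    if (scope == "within_group") {
      ppt <- ppt[!is.na(gi) & !is.na(gj) & gi == gj, , drop = FALSE]
      ppt$group <- groups[ppt$sample_i]
    } else {
      ppt$group <- ifelse(gi == gj, gi, "all")
    }
  }
  if (!nrow(ppt)) stop_validation("no pairs in scope")
  out <- do.call(rbind, lapply(split(ppt, ppt$group), function(d) {
    f <- vapply(procs, function(p) mean(d$process == p), numeric(1))
    data.frame(group = d$group[1], as.list(f),
               stochastic = sum(f[c("drift", "dispersal_limitation",
                                    "homogenizing_dispersal")]),
               n_pairs = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("process_fractions", "data.frame")
  out
}
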