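# Small programmatic fixtures shared across test files.

# random count table with guaranteed positive row sums
random_table <- function(n_samples, n_taxa, reads = 200, seed = 1) {
  set.seed(seed)
  m <- t(stats::rmultinom(n_samples, reads, prob = stats::runif(n_taxa) + 0.05))
  dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                      paste0("ASV_", seq_len(n_taxa)))
  community_table(m)
}

# brute-force Bray-Curtis: literal double loop over the formula
brute_bray <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  out
}

# brute-force betaMNTD: literal double loop over communities and members
brute_bmntd <- function(m, D, weighted = TRUE) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (k in seq_len(n)) for (l in seq_len(n)) {
    tk <- colnames(m)[m[k, ] > 0]; tl <- colnames(m)[m[l, ] > 0]
    fk <- if (weighted) m[k, tk] / sum(m[k, ]) else rep(1 / length(tk), length(tk))
    fl <- if (weighted) m[l, tl] / sum(m[l, ]) else rep(1 / length(tl), length(tl))
    t1 <- sum(fk * vapply(tk, function(i) min(D[i, tl]), numeric(1)))
    t2 <- sum(fl * vapply(tl, function(j) min(D[j, tk]), numeric(1)))
    out[k, l] <- 0.5 * (t1 + t2)
  }
  out
}

# a tiny labeled distance matrix from a symmetric value generator
random_dm <- function(n, seed = 1, labels = paste0("s", seq_len(n))) {
  set.seed(seed)
  x <- matrix(stats::runif(n * n), n, n)
  d <- (x + t(x)) / 2
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  dist_matrix(d)
}

# quick small scenario used in several tests
small_scenario <- function(process = "neutral_drift", strength = 1, seed = 1, ...) {
  assembly_scenario(process, strength = strength, n_taxa = 40,
                    n_regions = 3, sites_per_region = 2, quadrats_per_site = 2,
                    reads_per_sample = 1200, seed = seed, ...)
}

# recovery-scale scenario: the study conditions for process recovery
recovery_scenario <- function(process, seed) {
  assembly_scenario(process, strength = 10, n_taxa = 60, tree_tips = 360,
                    n_regions = 3, sites_per_region = 2, quadrats_per_site = 4,
                    trait_conservatism = 1, seed = seed)
}
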