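test_that("the abundance filter applies the relative-abundance rule inclusively", {
  m <- matrix(0L, 4, 3, dimnames = list(paste0("s", 1:4), c("rare", "edge", "common")))
  m[, "rare"] <- c(1L, 0L, 0L, 0L)                 # 1 / 100000
  m[, "edge"] <- c(4L, 3L, 2L, 1L)                 # exactly 1e-4
  m[, "common"] <- c(25000L, 25000L, 25000L, 24989L)
  tab <- community_table(m)
  f <- filter_taxa(tab, 1e-4)
  expect_false("rare" %in% colnames(f))
  expect_true("edge" %in% colnames(f))             # >= rule keeps the boundary
  expect_identical(colnames(filter_taxa(tab, 0)), colnames(tab))
  expect_error(filter_taxa(tab, 1), "min_rel_abund")
})

test_that("Spearman correlations use mid-ranks and match reference results", {
  m <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 9,
                9, 7, 5, 3,
                1, 2, 2, 3,
                2, 1, 3, 4), 4, 5,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:5)))
  tab <- community_table(matrix(as.integer(m * 10), 4, 5,
                                dimnames = dimnames(m)))
  cs <- spearman_correlations(tab)
  # note: correlations are computed on relative abundances
  rel <- unclass(tab) / rowSums(unclass(tab))
  get <- function(a, b) cs$rho[cs$taxon_i %in% c(a, b) & cs$taxon_j %in% c(a, b)]
  expect_equal(get("t1", "t2"), 1)
  expect_equal(get("t2", "t3"), -1)
  # mid-rank handling equals Pearson on rank vectors (tied case t4 vs t5)
  expect_equal(get("t4", "t5"),
               cor(rank(rel[, "t4"]), rank(rel[, "t5"])), tolerance = 1e-12)
  # full agreement with cor(method = "spearman")
  R <- cor(rel, method = "spearman")
  for (k in seq_len(nrow(cs)))
    expect_equal(cs$rho[k], R[cs$taxon_i[k], cs$taxon_j[k]], tolerance = 1e-12)
  expect_true(all(cs$p_adj >= cs$p - 1e-15))
})

test_that("constant taxa are excluded from the correlation set", {
  m <- cbind(random_table(6, 4, seed = 3), const = 5L)
  tab <- community_table(m)
  # constant in relative abundance requires equal row sums: rarefy first
  tab <- suppressWarnings(rarefy(tab, 100, seed = 1, remove_singletons = FALSE))
  if (sd(unclass(tab)[, "const"]) == 0) {
    cs <- spearman_correlations(tab)
    expect_false("const" %in% c(cs$taxon_i, cs$taxon_j))
  }
  succeed()
})

test_that("network edges require both the correlation and FDR cut-offs", {
  cs <- data.frame(taxon_i = c("a", "a", "b"), taxon_j = c("b", "c", "c"),
                   rho = c(0.70, 0.70, 0.60), p = c(1e-5, 0.005, 1e-7),
                   p_adj = c(5e-4, 0.01, 1e-6), stringsAsFactors = FALSE)
  attr(cs, "taxa") <- c("a", "b", "c")
  attr(cs, "n_samples") <- 20
  class(cs) <- c("correlation_set", "data.frame")
  net <- build_network(cs, threshold = 0.68, fdr_alpha = 0.001)
  edges <- igraph::as_data_frame(net)
  expect_equal(nrow(edges), 1)                     # only a-b survives
  expect_setequal(c(edges$from, edges$to), c("a", "b"))
  expect_warning(build_network(cs, threshold = 0.99), "no edges")
})

test_that("topology of reference graphs matches hand-computed values", {
  g3 <- igraph::make_full_graph(3)
  igraph::V(g3)$name <- letters[1:3]
  t3 <- topology(g3)
  expect_equal(t3$n_nodes, 3)
  expect_equal(t3$n_edges, 3)
  expect_equal(t3$average_degree, 2)
  expect_equal(t3$average_path_length, 1)
  expect_equal(t3$clustering_coefficient, 1)
  expect_equal(t3$connectivity, 1)

  p3 <- igraph::make_graph(~ a - b, b - c)
  tp <- topology(p3)
  expect_equal(tp$average_path_length, 4 / 3)
  expect_equal(tp$clustering_coefficient, 0)
  expect_equal(tp$connectivity, 2 / 3)

  star <- igraph::make_star(4, mode = "undirected")
  igraph::V(star)$name <- letters[1:4]
  ts <- topology(star)
  expect_equal(ts$average_degree, 1.5)
  expect_equal(ts$average_path_length, 1.5)     # 3 spokes at 1, 3 leaf pairs at 2
  expect_equal(ts$clustering_coefficient, 0)

  two_tri <- igraph::disjoint_union(igraph::make_full_graph(3),
                                    igraph::make_full_graph(3))
  igraph::V(two_tri)$name <- letters[1:6]
  tt <- topology(two_tri)
  expect_equal(tt$n_modules, 2)
  # hand modularity: all degrees 2, m = 6: Q = 2 * (3/6 - (6/12)^2) = 1/2
  expect_equal(tt$modularity, 0.5)
  expect_gt(tt$modularity, 0)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_true(topology(empty)$empty)
})

test_that("topology distances are Euclidean with optional standardization", {
  base <- data.frame(n_nodes = 0, n_edges = 0, n_modules = 0, average_degree = 0,
                     average_path_length = 0, clustering_coefficient = 0,
                     connectivity = 0, modularity = 0)
  pu <- rbind(cbind(unit = "u1", base),
              cbind(unit = "u2", base),
              cbind(unit = "u3", base))
  pu[3, c("n_nodes", "n_edges")] <- c(3, 4)
  d <- topology_distance(pu, standardize = FALSE)
  expect_equal(d["u1", "u2"], 0)
  expect_equal(d["u1", "u3"], 5)                  # 3-4-5 triangle

  # z-standardization makes the distance invariant to rescaling a property
  pu2 <- pu; pu2$n_nodes <- pu2$n_nodes * 1000
  expect_equal(unclass(topology_distance(pu, standardize = TRUE)),
               unclass(topology_distance(pu2, standardize = TRUE)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(topology_distance(pu[, -2]), "n_nodes")
})

test_that("edge sets shrink monotonically with stricter cut-offs", {
  tab <- suppressWarnings(rarefy(random_table(20, 40, reads = 2000, seed = 9),
                                 1000, seed = 1, remove_singletons = FALSE))
  cs <- spearman_correlations(tab)
  n_edges <- function(th, al) {
    suppressWarnings(igraph::ecount(build_network(cs, th, al)))
  }
  e1 <- n_edges(0.3, 0.5); e2 <- n_edges(0.5, 0.5); e3 <- n_edges(0.7, 0.5)
  expect_true(e1 >= e2 && e2 >= e3)
  a1 <- n_edges(0.3, 0.5); a2 <- n_edges(0.3, 0.05); a3 <- n_edges(0.3, 0.001)
  expect_true(a1 >= a2 && a2 >= a3)
})

test_that("the FDR guarantee holds on independent noise tables", {
  total_edges <- 0; total_pairs <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    m <- matrix(rpois(20 * 40, 50), 20, 40,
                dimnames = list(paste0("s", 1:20), paste0("t", 1:40)))
    cs <- spearman_correlations(community_table(m))
    net <- suppressWarnings(build_network(cs, threshold = 0.01,
                                          fdr_alpha = 0.001))
    total_edges <- total_edges + igraph::ecount(net)
    total_pairs <- total_pairs + nrow(cs)
  }
  expect_lte(total_edges, 0.001 * total_pairs)
})

test_that("RMT thresholding finds the Wigner-to-Poisson transition on noise", {
  set.seed(99)
  m <- matrix(rpois(50 * 200, 30), 50, 200,
              dimnames = list(paste0("s", 1:50), paste0("t", 1:200)))
  cs <- spearman_correlations(community_table(m))
  th <- rmt_threshold(cs)
  expect_true(th >= 0.30 && th <= 0.90)
  expect_gt(attr(th, "ks_p"), 0.05)

  # planted modules survive: two 15-taxon blocks with strong correlation
  set.seed(100)
  base1 <- rnorm(50); base2 <- rnorm(50)
  blk <- cbind(
    sapply(1:15, function(i) 100 + 30 * base1 + rnorm(50, 0, 3)),
    sapply(1:15, function(i) 100 + 30 * base2 + rnorm(50, 0, 3)),
    matrix(rpois(50 * 60, 50), 50, 60))
  blk <- pmax(round(blk), 0)
  dimnames(blk) <- list(paste0("s", 1:50), paste0("t", 1:90))
  cs2 <- spearman_correlations(community_table(matrix(as.integer(blk), 50, 90,
                                                      dimnames = dimnames(blk))))
  th2 <- suppressWarnings(rmt_threshold(cs2))
  expect_lt(as.numeric(th2), 0.9)

  # empty scan returns the configured fallback with a warning
  expect_warning(fb <- rmt_threshold(cs, scan = numeric(0)), "fallback")
  expect_equal(as.numeric(fb), 0.68)
})
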