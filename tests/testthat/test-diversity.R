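test_that("rarefaction removes singletons, evens depth, and drops shallow samples", {
  m <- matrix(c(900, 0, 1100, 1,
                500, 150, 50, 0,
                2000, 10, 30, 0), 3, 4, byrow = TRUE,
              dimnames = list(c("deep1", "shallow", "deep2"),
                              paste0("t", 1:4)))
  tab <- community_table(m)
  expect_warning(r <- rarefy(tab, depth = 800, seed = 2), "shallow")
  expect_true(all(rowSums(r) == 800))
  expect_false("t4" %in% colnames(r))          # global singleton removed first
  expect_false("shallow" %in% rownames(r))
  expect_identical(
    unclass(suppressWarnings(rarefy(tab, 800, seed = 2, remove_singletons = TRUE))),
    unclass(suppressWarnings(rarefy(tab, 800, seed = 2))))
  expect_error(rarefy(tab, depth = 0), "depth")
  expect_error(suppressWarnings(rarefy(community_table(
    matrix(5L, 1, 2, dimnames = list("a", c("t1", "t2")))), 800)), "below")
})

test_that("Bray-Curtis matches hand values and the brute-force oracle", {
  m <- matrix(c(1, 0, 3, 0, 2, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("x", "y"), c("t1", "t2", "t3")))
  bc <- bray_curtis(community_table(m))
  expect_equal(bc["x", "y"], 5 / 7)
  m2 <- rbind(m, z = c(1, 0, 3))
  bc2 <- bray_curtis(community_table(m2))
  expect_equal(bc2["x", "z"], 0)
  m3 <- matrix(c(1, 1, 0, 0, 0, 2), 2, 3, byrow = TRUE,
               dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  expect_equal(bray_curtis(community_table(m3))["a", "b"], 1)

  for (s in 1:20) {
    tab <- random_table(10, 30, seed = 300 + s)
    expect_equal(unclass(bray_curtis(tab)), brute_bray(unclass(tab)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # vegan as an independent reference implementation
    expect_equal(as.matrix(vegan::vegdist(unclass(tab), "bray")),
                 unclass(bray_curtis(tab)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("betaMNTD matches hand values, the oracle, and its invariances", {
  nwk <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  m <- matrix(c(5, 0, 0, 0, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("k", "m"), c("t1", "t2", "t3")))
  b <- beta_mntd(community_table(m), nwk, abundance_weighted = FALSE)
  expect_equal(b["k", "m"], 0.5 * (2 + (2 + 4) / 2))   # = 2.5

  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1);")
  m2 <- matrix(c(3, 0, 0, 0, 2, 0), 2, 3, byrow = TRUE,
               dimnames = list(c("k", "m"), c("t1", "t2", "t3")))
  expect_equal(beta_mntd(community_table(m2), star)["k", "m"], 2)

  tree <- simulate_tree(30, seed = 5)
  for (s in 1:20) {
    tab <- random_table(10, 30, seed = 400 + s)
    D <- cophenetic(tree)[colnames(tab), colnames(tab)]
    expect_equal(unclass(beta_mntd(tab, tree)),
                 brute_bmntd(unclass(tab), D), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }

  tab <- random_table(6, 30, seed = 77)
  b1 <- beta_mntd(tab, tree)
  expect_equal(b1["s1", "s1"], 0)
  # scaling all counts leaves the abundance-weighted metric unchanged
  b2 <- beta_mntd(community_table(unclass(tab) * 7L), tree)
  expect_equal(unclass(b1), unclass(b2), tolerance = 1e-12, ignore_attr = TRUE)
  # a taxon absent from both communities changes nothing
  ext <- cbind(unclass(tab), ASV_99 = 0L)
  tree2 <- simulate_tree(31, seed = 5)
  tree2$tip.label <- c(colnames(tab), "ASV_99")
  D31 <- cophenetic(tree2)
  expect_equal(unclass(beta_mntd(community_table(ext), tree2)),
               brute_bmntd(unclass(tab), D31[colnames(tab), colnames(tab)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(beta_mntd(tab, ape::drop.tip(tree, "ASV_1")), "ASV_1")
})

test_that("betaMNTD agrees with picante on a small table", {
  skip_if_not_installed("picante")
  tree <- simulate_tree(20, seed = 8)
  tab <- random_table(6, 20, seed = 12)
  mine <- beta_mntd(tab, tree)
  ref <- as.matrix(picante::comdistnt(unclass(tab), cophenetic(tree),
                                      abundance.weighted = TRUE))
  expect_equal(unclass(mine), ref[rownames(mine), colnames(mine)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("beta-dispersion reduces to known geometry", {
  d <- matrix(c(0, 0.6, 0.6, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  disp <- beta_dispersion(dist_matrix(d), groups = "g")
  expect_equal(disp$distance_to_centroid, c(0.3, 0.3), tolerance = 1e-9)

  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(beta_dispersion(dist_matrix(z))$distance_to_centroid,
               rep(0, 3), tolerance = 1e-9)

  # Euclidean input: dispersions equal coordinate-space distances to centroid
  set.seed(31)
  X <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(paste0("s", 1:8), NULL))
  dm <- as.matrix(dist(X))
  disp2 <- beta_dispersion(dist_matrix(dm))
  centroid <- colMeans(X)
  direct <- sqrt(colSums((t(X) - centroid)^2))
  expect_equal(disp2$distance_to_centroid, unname(direct), tolerance = 1e-9)
})

test_that("Chao2 gamma estimates follow the incidence formulas", {
  # N = 10, S_obs = 20, Q1 = 4, Q2 = 2 -> 20 + (9/10) * 16 / 4 = 23.6
  m <- matrix(0L, 10, 20, dimnames = list(paste0("s", 1:10), paste0("t", 1:20)))
  for (j in 1:14) m[1:3, j] <- 1L          # 14 taxa in >= 3 samples
  for (j in 15:18) m[j - 14, j] <- 1L      # Q1 = 4
  for (j in 19:20) m[1:2, j] <- 1L         # Q2 = 2
  g <- estimate_gamma(community_table(m))
  expect_equal(g$S_obs, 20)
  expect_equal(g$Q1, 4)
  expect_equal(g$Q2, 2)
  expect_equal(g$S_chao2, 23.6)

  m2 <- matrix(1L, 5, 7, dimnames = list(paste0("s", 1:5), paste0("t", 1:7)))
  g2 <- estimate_gamma(community_table(m2))
  expect_equal(g2$S_chao2, g2$S_obs)        # Q1 = Q2 = 0

  g3 <- estimate_gamma(community_table(m2[1, , drop = FALSE]))
  expect_false(g3$extrapolated)
  expect_equal(g3$S_chao2, 7)
})
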