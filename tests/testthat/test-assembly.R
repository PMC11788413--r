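test_that("betaNTI matches a brute-force reimplementation under the same shuffles", {
  tree <- simulate_tree(25, seed = 3)
  tab <- random_table(6, 25, seed = 14)
  n_null <- 120
  res <- beta_nti(tab, tree, n_null = n_null, seed = 42)

  # independent reimplementation: literal double-loop betaMNTD and explicit
  # storage of every null replicate, replaying the identical RNG stream
  m <- unclass(tab)
  m <- m[, colSums(m) > 0, drop = FALSE]
  Dfull <- cophenetic(tree)
  obs <- brute_bmntd(m, Dfull[colnames(m), colnames(m)])
  set.seed(42)
  nulls <- array(0, c(nrow(m), nrow(m), n_null))
  for (k in seq_len(n_null)) {
    perm <- sample.int(nrow(Dfull), ncol(m))
    Dn <- Dfull[perm, perm]
    dimnames(Dn) <- list(colnames(m), colnames(m))
    nulls[, , k] <- brute_bmntd(m, Dn)
  }
  mu <- apply(nulls, c(1, 2), mean)
  sg <- apply(nulls, c(1, 2), sd)
  z <- (obs - mu) / sg
  z[!is.finite(z) | sg < 1e-6 * (1 + abs(mu))] <- 0
  diag(z) <- 0
  expect_equal(unclass(res), z, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a star phylogeny degenerates the betaNTI null", {
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1,t5:1);")
  m <- matrix(c(3, 1, 0, 0, 0,
                0, 0, 2, 2, 0,
                1, 0, 0, 0, 4), 3, 5, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("t", 1:5)))
  res <- beta_nti(community_table(m), star, n_null = 99, seed = 1)
  expect_true(all(unclass(res) == 0))
  expect_true(any(attr(res, "degenerate")))
})

test_that("RCbray stays in range, is deterministic, and flags identical pairs", {
  tab <- random_table(8, 30, seed = 31)
  rc1 <- raup_crick_bray(tab, n_null = 199, seed = 7)
  rc2 <- raup_crick_bray(tab, n_null = 199, seed = 7)
  expect_identical(unclass(rc1), unclass(rc2))
  v <- unfold(rc1)$value
  expect_true(all(v >= -1 & v <= 1))

  # a duplicated sample: observed BC = 0 is the attainable minimum
  m <- unclass(tab)
  m <- rbind(m, dup = m[1, ])
  rc3 <- raup_crick_bray(community_table(m), n_null = 999, seed = 8)
  expect_lte(rc3["s1", "dup"], -0.99)
})

test_that("RCbray matches a brute-force replay of the null draws", {
  tab <- random_table(5, 20, seed = 77)
  n_null <- 150
  res <- raup_crick_bray(tab, n_null = n_null, seed = 11)

  m <- unclass(tab); m <- m[, colSums(m) > 0, drop = FALSE]
  n <- nrow(m); S <- ncol(m)
  rich <- rowSums(m > 0); reads <- rowSums(m)
  occ <- colSums(m > 0) / n; ab <- colSums(m) / sum(m)
  obs <- brute_bray(m)
  less <- ties <- matrix(0, n, n)
  set.seed(11)
  for (k in seq_len(n_null)) {
    nm <- matrix(0, n, S)
    for (s in seq_len(n)) {
      drawn <- sample.int(S, rich[s], prob = occ)
      x <- numeric(S); x[drawn] <- 1
      if (reads[s] > rich[s])
        x[drawn] <- x[drawn] + rmultinom(1, reads[s] - rich[s], ab[drawn])[, 1]
      nm[s, ] <- x
    }
    bcn <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      bcn[i, j] <- sum(abs(nm[i, ] - nm[j, ])) / sum(nm[i, ] + nm[j, ])
    d <- bcn - obs
    less <- less + (d < -1e-12)
    ties <- ties + (abs(d) <= 1e-12)
  }
  expected <- 2 * (less + 0.5 * ties) / n_null - 1
  diag(expected) <- 0
  expect_equal(unclass(res), expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the five-way classification applies the published thresholds", {
  labels <- paste0("s", 1:2)
  mk <- function(x) {
    m <- matrix(c(0, x, x, 0), 2, 2, dimnames = list(labels, labels))
    dist_matrix(m, signed = TRUE)
  }
  cases <- list(
    list(b = 2.5, r = 0.1, want = "variable_selection"),
    list(b = -2.5, r = 0.1, want = "homogeneous_selection"),
    list(b = 0.5, r = 0.97, want = "dispersal_limitation"),
    list(b = 0.5, r = -0.97, want = "homogenizing_dispersal"),
    list(b = 0.5, r = 0.2, want = "drift"),
    list(b = 2, r = 0.96, want = "dispersal_limitation"),   # boundary: |b| <= 2
    list(b = -2, r = -0.2, want = "drift"))
  for (cs in cases) {
    ppt <- classify_processes(mk(cs$b), mk(cs$r))
    expect_identical(ppt$process, cs$want)
  }
})

test_that("process fractions count pairs and report the stochastic total", {
  ppt <- data.frame(
    sample_i = paste0("s", 1:10), sample_j = paste0("t", 1:10),
    bnti = 0, rc = 0,
    process = c(rep("drift", 6), rep("dispersal_limitation", 4)),
    stringsAsFactors = FALSE)
  class(ppt) <- c("pairwise_process_table", "data.frame")
  fr <- process_fractions(ppt)
  expect_equal(fr$drift, 0.6)
  expect_equal(fr$dispersal_limitation, 0.4)
  expect_equal(fr$stochastic, 1.0)
  expect_equal(fr$n_pairs, 10L)
  expect_equal(fr$variable_selection + fr$homogeneous_selection +
               fr$dispersal_limitation + fr$homogenizing_dispersal + fr$drift,
               1, tolerance = 1e-12)

  ppt$process <- "variable_selection"
  fr2 <- process_fractions(ppt)
  expect_equal(fr2$variable_selection, 1)
  expect_equal(fr2$stochastic, 0)

  groups <- setNames(rep(c("A", "B"), each = 10),
                     c(paste0("s", 1:10), paste0("t", 1:10)))
  expect_error(process_fractions(ppt, groups = groups, scope = "within_group"),
               "no pairs")
})

test_that("unevaluable pairs with under two taxa in the union are flagged", {
  tree <- simulate_tree(10, seed = 2)
  m <- matrix(0L, 3, 10, dimnames = list(c("a", "b", "c"), tree$tip.label))
  m["a", 1] <- 5L                                  # single-taxon community
  m["b", 1] <- 3L                                  # same single taxon
  m["c", 2:5] <- 2L
  res <- beta_nti(community_table(m), tree, n_null = 99, seed = 1)
  expect_true(attr(res, "unevaluable")["a", "b"])
  expect_false(attr(res, "unevaluable")["a", "c"])
})
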