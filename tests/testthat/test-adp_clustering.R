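# 12-D feature space, Euclidean distance, Ward linkage, tree queries.

test_that("feature vectors are the 12 raw tensor elements in fixed order", {
  u <- 0.05
  iso <- matrix(c(u, u, u, 0, 0, 0), 1)
  pool <- make_pool(iso, iso)
  fm <- feature_matrix(pool)
  expect_equal(ncol(fm), 12L)
  expect_equal(unname(fm[1, ]), c(u, u, u, 0, 0, 0, u, u, u, 0, 0, 0))
  expect_equal(colnames(fm),
               c("u11_odd", "u22_odd", "u33_odd", "u12_odd", "u13_odd",
                 "u23_odd", "u11_even", "u22_even", "u33_even", "u12_even",
                 "u13_even", "u23_even"))
  # distinct toy tensors read back element-wise, unscaled
  uo <- matrix(1:6 / 100, 1)
  ue <- matrix(7:12 / 100, 1)
  fm2 <- feature_matrix(make_pool(uo, ue))
  expect_equal(unname(fm2[1, ]), c(1:6, 7:12) / 100)
})

test_that("the pairwise distance is Euclidean and satisfies metric axioms", {
  set.seed(41)
  u <- runif(12)
  expect_identical(adp_distance(u, u), 0)
  v <- u; v[7] <- v[7] + 0.03
  expect_equal(adp_distance(u, v), 0.03, tolerance = 1e-14)
  expect_error(adp_distance(u[1:6], v), "12 components")
  for (i in 1:200) {
    a <- rnorm(12); b <- rnorm(12); c_ <- rnorm(12)
    dab <- adp_distance(a, b)
    # brute-force term-by-term expansion
    expect_equal(dab, sqrt(sum(vapply(1:12, function(k) (a[k] - b[k])^2,
                                      numeric(1)))), tolerance = 1e-12)
    expect_gte(dab, 0)
    expect_equal(dab, adp_distance(b, a))
    expect_lte(dab, adp_distance(a, c_) + adp_distance(c_, b) + 1e-12)
  }
})

test_that("ward linkage matches the exhaustive minimum-variance oracle", {
  set.seed(42)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    uo <- t(replicate(n, rand_spd_u6()))
    ue <- t(replicate(n, rand_spd_u6()))
    pool <- make_pool(uo, ue)
    tree <- adp_ward(pool)
    oracle <- ward_oracle(feature_matrix(pool))
    expect_equal(hclust_partitions(tree$hclust), oracle$partitions)
    expect_equal(tree$hclust$height, oracle$heights, tolerance = 1e-9)
  }
})

test_that("ward trees are monotone and degenerate cases behave", {
  # two identical observations -> single merge at height 0
  iso <- matrix(c(0.03, 0.03, 0.03, 0, 0, 0), 1)
  pool2 <- make_pool(rbind(iso, iso), rbind(iso, iso))
  t2 <- adp_ward(pool2)
  expect_equal(t2$hclust$height, 0)
  expect_error(adp_ward(pool2[1, , drop = FALSE]), "at least 2")

  # one far outlier merges last
  base <- matrix(c(0.03, 0.03, 0.03, 0, 0, 0), 3, 6, byrow = TRUE) +
    matrix(rnorm(18, sd = 1e-4), 3)
  outlier <- matrix(c(0.3, 0.3, 0.3, 0, 0, 0), 1)
  pool4 <- make_pool(rbind(base, outlier), rbind(base, outlier))
  t4 <- adp_ward(pool4)
  last <- t4$hclust$merge[3, ]
  expect_true(-4L %in% last)

  # monotone heights on a larger random pool
  set.seed(43)
  uo <- t(replicate(60, rand_spd_u6()))
  ue <- t(replicate(60, rand_spd_u6()))
  t60 <- adp_ward(make_pool(uo, ue))
  expect_true(all(diff(t60$hclust$height) >= -1e-12))
})

test_that("linkage is invariant under observation permutation", {
  set.seed(44)
  uo <- t(replicate(30, rand_spd_u6()))
  ue <- t(replicate(30, rand_spd_u6()))
  pool <- make_pool(uo, ue)
  perm <- sample(30)
  t1 <- adp_ward(pool)
  t2 <- adp_ward(pool[perm, ])
  expect_equal(sort(t1$hclust$height), sort(t2$hclust$height),
               tolerance = 1e-9)
})

test_that("adding a constant to every feature leaves the tree unchanged", {
  set.seed(45)
  uo <- t(replicate(15, rand_spd_u6()))
  ue <- t(replicate(15, rand_spd_u6()))
  t1 <- adp_ward(make_pool(uo, ue))
  t2 <- adp_ward(make_pool(uo + 0.5, ue + 0.5))
  expect_equal(t1$hclust$height, t2$hclust$height, tolerance = 1e-9)
  expect_equal(t1$hclust$merge, t2$hclust$merge)
})

test_that("tree cuts validate inputs and respect duplicates", {
  set.seed(46)
  uo <- t(replicate(8, rand_spd_u6()))
  pool <- make_pool(rbind(uo, uo[1:2, ]), rbind(uo, uo[1:2, ]))
  tree <- adp_ward(pool)
  expect_equal(length(unique(cut_adp_tree(tree, k = 1))), 1L)
  # cut at height 0: exact duplicates share a label, everything else is alone
  lab0 <- cut_adp_tree(tree, h = 0)
  expect_equal(length(unique(lab0)), 8L)
  expect_equal(lab0[1], lab0[9])
  expect_equal(lab0[2], lab0[10])
  expect_error(cut_adp_tree(tree, k = 99), "between 1 and")
  expect_error(cut_adp_tree(tree), "exactly one")
  expect_error(cut_adp_tree(tree, k = 2, h = 1), "exactly one")
})

test_that("NPD observations are excluded from clustering by default", {
  uo <- rbind(t(replicate(4, rand_spd_u6())),
              c(0.05, 0.02, -0.01, 0, 0, 0))
  pool <- make_pool(uo, uo)
  expect_equal(nrow(adp_ward(pool)$leaves), 4L)
  expect_equal(nrow(adp_ward(pool, include_npd = TRUE)$leaves), 5L)
})

test_that("branch reports find an atom's observations and their purity", {
  set.seed(47)
  # 9 crystals observe the same atom with nearly identical tensors;
  # 30 background atoms are scattered far away
  target <- rand_spd_u6()
  obs <- t(replicate(9, target + rnorm(6, sd = 1e-4)))
  bg <- t(replicate(30, rand_spd_u6() + 0.3))
  pool <- rbind(
    make_pool(obs, obs, crystal = "multi", resno = rep(135L, 9),
              resid = "GLN", elety = rep("NE2", 9)),
    make_pool(bg, bg, crystal = "multi", resno = 200L + seq_len(30)))
  tree <- adp_ward(pool)
  br <- branch_composition(tree, list(resno = 135L, elety = "NE2"))
  expect_equal(br$n_matched, 9L)
  full <- br$table[br$table$n_in_subtree == 9L, ]
  expect_equal(full$subtree_size, 9L)   # minimal subtree is exactly the 9
  expect_equal(full$purity, 1)
  expect_equal(nrow(br$members), 9L)
  expect_error(branch_composition(tree, list(resid = "TRP")), "no leaf")
})

test_that("condition queries recover a planted treated cluster", {
  # plant a coherent condition effect: every treated odd-state tensor is the
  # archetype contracted along one fixed direction (the archetype's smallest
  # eigenvector), so the treated observations form a single branch
  set.seed(48)
  arch <- rand_spd_u6(0.08, 0.2)
  es <- tensor_eigen(arch)
  v3 <- es$vectors[, 3]
  treat_m <- tensor_matrix(arch) - 0.6 * es$values[3] * (v3 %*% t(v3))
  treat6 <- c(treat_m[1, 1], treat_m[2, 2], treat_m[3, 3],
              treat_m[1, 2], treat_m[1, 3], treat_m[2, 3])
  noise6 <- function(n) matrix(rnorm(6 * n, sd = 0.003), n)
  n <- 100L
  pool <- rbind(
    make_pool(rep(1, n) %o% treat6 + noise6(n),
              rep(1, n) %o% unname(arch) + noise6(n),
              crystal = "T", condition = "treated"),
    make_pool(rep(1, n) %o% unname(arch) + noise6(n),
              rep(1, n) %o% unname(arch) + noise6(n),
              crystal = "R", condition = "reference",
              resno = n + seq_len(n)))
  tree <- adp_ward(pool)
  br <- branch_composition(tree, "treated")
  top <- br$table[br$table$purity >= 0.95, ][1, ]
  expect_gte(top$recall, 0.95)
})
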