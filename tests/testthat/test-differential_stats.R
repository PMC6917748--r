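# Paired odd/even differencing, group summaries with 95% CIs, correlation.

test_that("paired differences equal independently recomputed metric gaps", {
  set.seed(31)
  n <- 20L
  uo <- t(replicate(n, rand_spd_u6()))
  ue <- t(replicate(n, rand_spd_u6()))
  colnames(uo) <- colnames(ue) <- c("u11", "u22", "u33", "u12", "u13", "u23")
  pool <- make_pool(uo, ue)
  d <- paired_differences(pool)
  for (i in seq_len(n)) {
    expect_equal(d$d_beq[i], beq(uo[i, ]) - beq(ue[i, ]), tolerance = 1e-12)
    expect_equal(d$d_aniso[i], aniso(uo[i, ]) - aniso(ue[i, ]),
                 tolerance = 1e-12)
  }
  # identical tensors -> exactly zero for both metrics
  d0 <- paired_differences(make_pool(uo, uo))
  expect_equal(d0$d_beq, rep(0, n))
  expect_equal(d0$d_aniso, rep(0, n))
  # odd = 2 x even (isotropic scaling): d_beq = beq(even), d_aniso = 0
  d2 <- paired_differences(make_pool(2 * ue, ue))
  expect_equal(d2$d_beq, beq(ue), tolerance = 1e-10)
  expect_equal(d2$d_aniso, rep(0, n), tolerance = 1e-10)
})

test_that("NPD observations are excluded from differences, not errors", {
  uo <- rbind(c(0.05, 0.04, 0.03, 0, 0, 0),
              c(0.05, 0.02, -0.01, 0, 0, 0))   # second is NPD
  pool <- make_pool(uo, uo)
  d <- paired_differences(pool)
  expect_equal(nrow(d), 1L)
  expect_equal(nrow(attr(d, "exclusions")), 1L)
})

test_that("swapping odd and even negates every difference and group mean", {
  set.seed(32)
  n <- 30L
  uo <- t(replicate(n, rand_spd_u6()))
  ue <- t(replicate(n, rand_spd_u6()))
  pool <- make_pool(uo, ue, resid = rep(c("ALA", "GLY", "TRP"), 10))
  pool_sw <- make_pool(ue, uo, resid = rep(c("ALA", "GLY", "TRP"), 10))
  d <- paired_differences(pool)
  dsw <- paired_differences(pool_sw)
  expect_equal(dsw$d_beq, -d$d_beq)
  expect_equal(dsw$d_aniso, -d$d_aniso)
  g <- group_summary(d, "aniso", by = "type")
  gsw <- group_summary(dsw, "aniso", by = "type")
  expect_equal(gsw$mean, -g$mean)
  expect_equal(gsw$ci_half, g$ci_half)   # widths unchanged
})

test_that("group summaries: symmetric pairs, t-based CI, n = 1 rule", {
  pool_df <- data.frame(condition = "reference", chain = "A",
                        resno = c(1L, 1L, 2L), insert = "",
                        resid = c("GLY", "GLY", "TRP"),
                        d_beq = c(0.5, -0.5, 0.3),
                        d_aniso = c(0.1, -0.1, 0.2))
  g <- group_summary(pool_df, "beq", by = "type")
  gly <- g[g$group == "GLY", ]
  expect_equal(gly$mean, 0)
  expect_equal(gly$n, 2L)
  # independent t-interval oracle
  expect_equal(gly$ci_half, qt(0.975, df = 1) * sd(c(0.5, -0.5)) / sqrt(2))
  # single-atom group: mean reported, CI missing
  trp <- g[g$group == "TRP", ]
  expect_equal(trp$mean, 0.3)
  expect_true(is.na(trp$ci_half))
  # group means invariant to row order
  g2 <- group_summary(pool_df[c(3, 1, 2), ], "beq", by = "type")
  expect_equal(g2, g)
})

test_that("CI half-width shrinks like 1/sqrt(n) on homogeneous groups", {
  set.seed(33)
  mean_width <- function(n) {
    mean(replicate(40, {
      d <- data.frame(condition = "reference", chain = "A",
                      resno = seq_len(n), insert = "", resid = "ALA",
                      d_beq = rnorm(n, sd = 1), d_aniso = 0)
      group_summary(d, "beq", by = "type")$ci_half
    }))
  }
  widths <- vapply(c(25L, 100L, 400L), mean_width, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.15)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.15)
})

test_that("residue profiles average the stated atom set", {
  m <- data.frame(chain = "A", resno = c(1L, 1L, 1L, 2L), insert = "",
                  resid = c("GLY", "GLY", "GLY", "TRP"),
                  beq = c(10, 20, 30, 40), aniso = c(0.2, 0.4, 0.6, 0.8))
  p <- residue_profile(m, by = "residue")
  expect_equal(p$mean_beq[p$group == "A-GLY-1"], 20)
  expect_equal(p$n_atoms, c(3L, 1L))
  pt <- residue_profile(m, by = "type")
  expect_equal(pt$mean_aniso[pt$group == "GLY"], 0.4)
  expect_warning(residue_profile(m[0, , drop = FALSE]), "empty")
})

test_that("per-type means over planted data recover the archetype B_eq", {
  ens <- local_ensemble()
  pool <- assemble_pool(ens$res$manifest)
  prof <- residue_profile(pool, by = "type")
  arch <- ens$res$archetypes
  # residue names encode archetypes: ALA=1, SER=2, CYS=3
  for (i in seq_len(nrow(arch))) {
    expected <- beq(arch[i, , drop = FALSE])
    got <- prof$mean_beq[prof$group == c("ALA", "SER", "CYS")[i]]
    n <- prof$n_atoms[prof$group == c("ALA", "SER", "CYS")[i]]
    # noise sd per diagonal element 0.003 => beq sd ~ 8pi^2/3*sqrt(3)*0.003
    tol <- 4 * (8 * pi^2 / 3) * sqrt(3) * ens$spec$noise_sd / sqrt(n)
    expect_lt(abs(got - expected), tol)
  }
})

test_that("pearson_cc matches the textbook formula and its invariances", {
  set.seed(34)
  x <- rnorm(50)
  expect_equal(pearson_cc(x, 2 * x + 5), 1, tolerance = 1e-12)
  expect_equal(pearson_cc(x, -x), -1, tolerance = 1e-12)
  y <- rnorm(50)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cc(x, y), direct, tolerance = 1e-12)
  # sign(a) * cc under affine maps
  expect_equal(pearson_cc(x, -3 * y + 1), -pearson_cc(x, y),
               tolerance = 1e-12)
  expect_error(pearson_cc(x, rep(1, 50)), "zero variance")
  expect_error(pearson_cc(1:2, 2:3), "at least 3")
})

test_that("cc_matrix and prediction comparison work on aligned profiles", {
  set.seed(35)
  base <- rnorm(30, 20, 5)
  profs <- data.frame(x1 = base, x2 = base + rnorm(30, sd = 1),
                      x3 = -base)
  cc <- cc_matrix(profs)
  expect_equal(diag(cc), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc, t(cc))
  expect_lt(cc["x1", "x3"], -0.99)

  prof <- data.frame(group = paste0("R", 1:30), mean_beq = base,
                     mean_aniso = runif(30), source = "experiment")
  pred <- data.frame(id = paste0("R", 1:30), value = 0.01 * base + 2)
  out <- compare_prediction(prof, pred, metric = "beq")
  expect_equal(out$cc, 1, tolerance = 1e-12)
  expect_equal(out$n, 30L)
})
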