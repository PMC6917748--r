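# Independent oracles and fixture builders used across the suite.

# Random symmetric positive-definite tensor (6 unique elements) built from
# an explicit rotation and eigenvalues -- independent of the package's
# sampling code.
rand_spd_u6 <- function(eig_min = 0.01, eig_max = 0.2) {
  e <- sort(runif(3, eig_min, eig_max), decreasing = TRUE)
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  u <- q %*% diag(e) %*% t(q)
  c(u11 = u[1, 1], u22 = u[2, 2], u33 = u[3, 3],
    u12 = u[1, 2], u13 = u[1, 3], u23 = u[2, 3])
}

rand_rotation3 <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_u6 <- function(u6, r) {
  m <- r %*% matrix(c(u6[1], u6[4], u6[5],
                      u6[4], u6[2], u6[6],
                      u6[5], u6[6], u6[3]), 3, 3) %*% t(r)
  c(u11 = m[1, 1], u22 = m[2, 2], u33 = m[3, 3],
    u12 = m[1, 2], u13 = m[1, 3], u23 = m[2, 3])
}

# Minimal atoms data frame in the parser's layout.
make_atoms <- function(n, tensors = NULL, resid = "ALA", elety = NULL,
                       chain = "A", resno = NULL, alt = "") {
  if (is.null(elety))
    elety <- paste0("C", seq_len(n))
  if (is.null(resno)) resno <- rep(1L, n)
  atoms <- data.frame(
    type = "ATOM", eleno = seq_len(n), elety = elety, alt = alt,
    resid = resid, chain = chain, resno = resno, insert = "",
    x = seq_len(n) * 3.8, y = 0, z = 0, occ = 1, b = 10,
    elesy = "C", stringsAsFactors = FALSE)
  if (!is.null(tensors)) {
    tensors <- matrix(tensors, ncol = 6)
    atoms[, c("u11", "u22", "u33", "u12", "u13", "u23")] <- tensors
    atoms$has_tensor <- TRUE
    atoms$npd <- is_npd(tensors)
  } else {
    atoms$has_tensor <- FALSE
    atoms$npd <- FALSE
  }
  atoms
}

# Build an observation-pool data frame directly from odd/even feature halves.
make_pool <- function(u_odd, u_even, crystal = "X1", condition = "reference",
                      resid = "ALA", resno = NULL, elety = NULL) {
  n <- nrow(u_odd)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(elety)) elety <- rep("CA", n)
  ucols <- c("u11", "u22", "u33", "u12", "u13", "u23")
  df <- data.frame(crystal = crystal, condition = condition, type = "ATOM",
                   chain = "A", resno = resno, insert = "", resid = resid,
                   elety = elety, alt = "", elesy = "C", occ = 1,
                   stringsAsFactors = FALSE)
  df[, paste0(ucols, "_odd")] <- u_odd
  df[, paste0(ucols, "_even")] <- u_even
  df$npd_odd <- is_npd(unname(as.matrix(u_odd)))
  df$npd_even <- is_npd(unname(as.matrix(u_even)))
  df$npd <- df$npd_odd | df$npd_even
  df$res_has_alt <- FALSE
  df
}

# Exhaustive Ward agglomeration oracle: at every step merge the pair of
# clusters with the smallest increase in total within-cluster sum of squares,
# Delta = nA*nB/(nA+nB) * ||mean_A - mean_B||^2. Returns the partition after
# each merge and the merge heights on the sqrt(2*Delta) scale used by
# Euclidean Ward trees.
ward_oracle <- function(x) {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    best_cost <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ma <- colMeans(x[a, , drop = FALSE])
      mb <- colMeans(x[b, , drop = FALSE])
      cost <- length(a) * length(b) / (length(a) + length(b)) *
        sum((ma - mb)^2)
      if (cost < best_cost - 1e-12) {
        best_cost <- cost
        best <- c(i, j)
      }
    }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    clusters <- c(clusters[-best], list(merged))
    heights[step] <- sqrt(2 * best_cost)
    partitions[[step]] <- canonical_partition(clusters)
  }
  list(partitions = partitions, heights = heights)
}

# Canonical form of a partition: sorted list of sorted member vectors.
canonical_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, 1L, 1L))]
}

# Partition sequence of an hclust tree: after merge s, the n-s clusters.
hclust_partitions <- function(hc) {
  n <- length(hc$height) + 1L
  lapply(seq_len(n - 1L), function(s) {
    lab <- cutree(hc, k = n - s)
    canonical_partition(unname(split(seq_len(n), lab)))
  })
}

# Adjusted Rand index from the contingency-table formula (direct oracle).
ari_direct <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  tot <- ch2(sum(tab))
  exp_idx <- sum_a * sum_b / tot
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Small on-disk two-state ensemble for I/O-level tests (memoised per session).
local_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "adpcluster-test-ens")
      spec <- synthetic_spec(n_crystals = 2L, n_atoms = 50L,
                             n_archetypes = 3L, seed = 42L)
      cache <<- list(res = generate_ensemble(spec, d), dir = d, spec = spec)
    }
    cache
  }
})
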