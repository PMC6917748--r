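# Hierarchical clustering of paired ADP observations. Each atom observed in
# one crystal contributes a 12-dimensional feature vector: the six unique
# tensor elements of its odd-state tensor followed by the six of its
# even-state tensor, in raw Angstrom^2 with no scaling, centering or
# whitening. Distances are plain Euclidean in this space; the tree is built
# with Ward's minimum-variance method, for which the Euclidean embedding is
# the natural setting.

#' Feature matrix of paired observations
#'
#' One row per observation, 12 ordered columns: `u11_odd, u22_odd, u33_odd,
#' u12_odd, u13_odd, u23_odd` then the same six `_even` components. Raw
#' tensor elements in Angstrom^2 -- by design no standardisation is applied,
#' so atoms group by displacement magnitude, ellipsoid shape and orientation
#' simultaneously.
#'
#' @param pool an `adp_pool` or its `pool` data frame.
#' @return Numeric matrix, n x 12.
#' @export
feature_matrix <- function(pool) {
  p <- if (inherits(pool, "adp_pool")) pool$pool else pool
  m <- as.matrix(p[, FEATURE_COLS, drop = FALSE])
  stopifnot(ncol(m) == 12L)
  m
}

#' Euclidean distance between two 12-D ADP feature vectors
#'
#' @param u,v numeric vectors of length 12 (see [feature_matrix()]).
#' @return Non-negative distance, Angstrom^2.
#' @export
adp_distance <- function(u, v) {
  if (length(u) != 12L || length(v) != 12L)
    stop("feature vectors must have exactly 12 components")
  sqrt(sum((u - v)^2))
}

#' Ward clustering of an ADP observation pool
#'
#' Agglomerative clustering of all paired observations under the Euclidean
#' distance over their 12-D feature vectors, using Ward's minimum-variance
#' criterion (each merge is the pair of clusters whose fusion least increases
#' the total within-cluster variance). Merge heights equal
#' sqrt(2 * increase in within-cluster sum of squares) and are monotone
#' non-decreasing. Observations flagged non-positive-definite are excluded by
#' default.
#'
#' @param pool an `adp_pool` or its `pool` data frame.
#' @param include_npd keep observations with a non-positive-definite tensor.
#' @return An object of class `adp_tree`: list with `hclust` (the merge
#'   history), `leaves` (data frame of observation identities, row i is leaf
#'   i) and `features` (the clustered matrix).
#' @export
adp_ward <- function(pool, include_npd = FALSE) {
  p <- if (inherits(pool, "adp_pool")) pool$pool else pool
  if (!include_npd && "npd" %in% names(p))
    p <- p[!p$npd, , drop = FALSE]
  if (nrow(p) < 2L)
    stop("need at least 2 observations to cluster")
  fm <- feature_matrix(p)
  hc <- stats::hclust(stats::dist(fm), method = "ward.D2")
  leaves <- p[, intersect(c("crystal", "condition", KEY_COLS, "elesy"),
                          names(p)), drop = FALSE]
  rownames(leaves) <- NULL
  structure(list(hclust = hc, leaves = leaves, features = fm),
            class = "adp_tree")
}

#' @export
print.adp_tree <- function(x, ...) {
  cat(sprintf("ADP Ward tree: %d observations, %d merges, max height %.4g\n",
              nrow(x$leaves), length(x$hclust$height),
              max(x$hclust$height)))
  invisible(x)
}

#' Flat cluster labels from an ADP tree
#'
#' Cuts the dendrogram either into `k` clusters or at linkage height `h`
#' (observations merged at or below `h` share a label).
#'
#' @param tree an `adp_tree`.
#' @param k desired number of clusters (1..n), or
#' @param h height threshold (>= 0); give exactly one of `k`, `h`.
#' @return Integer vector of cluster labels, one per leaf.
#' @export
cut_adp_tree <- function(tree, k = NULL, h = NULL) {
  n <- nrow(tree$leaves)
  if (is.null(k) == is.null(h))
    stop("give exactly one of k or h")
  if (!is.null(k) && (k < 1L || k > n))
    stop("k must be between 1 and the number of observations (", n, ")")
  if (!is.null(h) && h < 0) stop("height threshold must be >= 0")
  unname(stats::cutree(tree$hclust, k = k, h = h))
}

#' Export the merge history as a four-column table
#'
#' @param tree an `adp_tree`.
#' @return Data frame with one row per merge: `node_a`, `node_b` (negative =
#'   leaf index, positive = earlier merge), `height`, `size` (members of the
#'   newly formed cluster).
#' @export
linkage_table <- function(tree) {
  hc <- tree$hclust
  n <- length(hc$height) + 1L
  size <- integer(length(hc$height))
  for (i in seq_along(hc$height)) {
    size[i] <- sum(vapply(hc$merge[i, ],
                          function(j) if (j < 0) 1L else size[j], 1L))
  }
  data.frame(node_a = hc$merge[, 1L], node_b = hc$merge[, 2L],
             height = hc$height, size = size)
}

# Leaf sets of every internal node (list of integer vectors, node i = merge i).
node_leafsets <- function(hc) {
  sets <- vector("list", length(hc$height))
  for (i in seq_along(sets)) {
    grab <- function(j) if (j < 0) -j else sets[[j]]
    sets[[i]] <- c(grab(hc$merge[i, 1L]), grab(hc$merge[i, 2L]))
  }
  sets
}

#' Branch composition report for an atom identity or a condition
#'
#' The paper-style branch query: where in the tree do the repeated
#' observations of one atom (across crystals) sit? For an atom/residue query,
#' the report gives, for each count j = 1..m of matching leaves, the smallest
#' subtree containing at least j of them, with its size and purity (fraction
#' of its leaves matching the query). A perfectly reproducible atom shows up
#' as a small subtree holding most of its observations at purity near 1. For
#' a condition query (`"treated"`/`"reference"`), every subtree is scored by
#' condition purity and recall instead. The notion of "branch" used here --
#' minimal covering subtree -- is this package's operationalisation; the
#' dendrogram itself has no canonical branch cut.
#'
#' @param tree an `adp_tree`.
#' @param query a named list of atom identity fields to match (any subset of
#'   `chain`, `resno`, `insert`, `resid`, `elety`, `alt`), or a condition
#'   string `"treated"`/`"reference"`.
#' @param min_size smallest subtree size reported for condition queries.
#' @return A list of class `branch_report` with `query`, `n_matched` (total
#'   matching leaves) and `table`; for atom queries `table` has one row per
#'   covered count (`n_in_subtree`, `subtree_size`, `purity`, `node`), for
#'   condition queries one row per subtree (`node`, `size`, `n_match`,
#'   `purity`, `recall`), sorted by purity then recall. Leaf members of the
#'   best atom subtree are in `$members`.
#' @export
branch_composition <- function(tree, query, min_size = 2L) {
  leaves <- tree$leaves
  hc <- tree$hclust
  if (is.character(query) && length(query) == 1L &&
      query %in% c("treated", "reference")) {
    match_leaf <- leaves$condition == query
    mode <- "condition"
  } else {
    if (!is.list(query) || is.null(names(query)))
      stop("query must be a condition string or a named list of key fields")
    bad <- setdiff(names(query), c(KEY_COLS, "elesy"))
    if (length(bad)) stop("unknown query field(s): ", paste(bad, collapse = ", "))
    match_leaf <- rep(TRUE, nrow(leaves))
    for (f in names(query))
      match_leaf <- match_leaf & (leaves[[f]] == query[[f]])
    mode <- "atom"
  }
  m <- sum(match_leaf)
  if (m == 0L)
    stop("query matches no leaf in the tree")

  sets <- node_leafsets(hc)
  sizes <- lengths(sets)
  nmatch <- vapply(sets, function(s) sum(match_leaf[s]), 1L)

  if (mode == "condition") {
    keep <- sizes >= min_size
    tab <- data.frame(node = which(keep), size = sizes[keep],
                      n_match = nmatch[keep],
                      purity = nmatch[keep] / sizes[keep],
                      recall = nmatch[keep] / m)
    tab <- tab[order(-tab$purity, -tab$recall), , drop = FALSE]
    rownames(tab) <- NULL
    return(structure(list(query = query, n_matched = m, table = tab),
                     class = "branch_report"))
  }

  # atom mode: for each j, the smallest node containing >= j matches
  rows <- lapply(seq_len(m), function(j) {
    if (j == 1L)
      return(data.frame(n_in_subtree = 1L, subtree_size = 1L, purity = 1,
                        node = NA_integer_))
    cand <- which(nmatch >= j)
    best <- cand[which.min(sizes[cand])]
    data.frame(n_in_subtree = nmatch[best], subtree_size = sizes[best],
               purity = nmatch[best] / sizes[best], node = best)
  })
  tab <- unique(do.call(rbind, rows))
  rownames(tab) <- NULL
  best_node <- tab$node[which.max(tab$n_in_subtree * (tab$purity == max(tab$purity)))]
  members <- if (is.na(best_node)) leaves[match_leaf, , drop = FALSE]
             else leaves[sets[[best_node]], , drop = FALSE]
  structure(list(query = query, n_matched = m, table = tab,
                 members = members),
            class = "branch_report")
}

#' @export
print.branch_report <- function(x, ...) {
  cat("Branch composition report (minimal covering subtrees)\n")
  cat("  matched leaves:", x$n_matched, "\n")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Dendrogram + tensor-element heatmap
#'
#' Best-effort rendering of the clustered pool: the Ward dendrogram on top
#' and, below it, a heatmap whose rows are the 12 feature components and
#' whose columns are the leaves in dendrogram order, so similar tensor
#' element patterns appear as vertical bands.
#'
#' @param x an `adp_tree`.
#' @param max_leaves subsample warning threshold for legibility only.
#' @param ... passed to [graphics::image()].
#' @export
plot.adp_tree <- function(x, max_leaves = 2000L, ...) {
  hc <- x$hclust
  ord <- hc$order
  op <- graphics::par(mfrow = c(2, 1), mar = c(0.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(stats::as.dendrogram(hc), leaflab = "none",
                 ylab = "Ward height")
  graphics::par(mar = c(2, 4, 0.5, 1))
  graphics::image(x = seq_along(ord), y = 1:12,
                  z = x$features[ord, , drop = FALSE],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "", ylab = "tensor element", axes = FALSE, ...)
  graphics::axis(2, at = 1:12, labels = FEATURE_COLS, las = 2, cex.axis = 0.6)
  invisible(x)
}
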