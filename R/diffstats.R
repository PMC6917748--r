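# Paired-state differencing of per-atom displacement metrics and group
# summaries with 95% confidence intervals, plus per-residue profiles and
# Pearson correlation against external predictions.

#' Per-atom paired metric differences (odd minus even)
#'
#' For every paired observation, computes metric(odd tensor) - metric(even
#' tensor) for B_eq and ANISO. Observations with a non-positive-definite
#' tensor in either state are excluded (ANISO is not meaningful there) and
#' recorded in the `exclusions` attribute.
#'
#' @param pool an `adp_pool` from [assemble_pool()] or its `pool` data frame.
#' @return Data frame with the observation identity columns plus `d_beq`
#'   (Angstrom^2) and `d_aniso` (dimensionless); excluded observations are in
#'   `attr(, "exclusions")`.
#' @export
paired_differences <- function(pool) {
  p <- if (inherits(pool, "adp_pool")) pool$pool else pool
  npd <- if ("npd" %in% names(p)) p$npd else rep(FALSE, nrow(p))
  excl <- p[npd, setdiff(names(p), grep("^u[0-9]", names(p), value = TRUE)),
            drop = FALSE]
  p <- p[!npd, , drop = FALSE]
  uo <- as.matrix(p[, paste0(U_COLS, "_odd"), drop = FALSE])
  ue <- as.matrix(p[, paste0(U_COLS, "_even"), drop = FALSE])
  colnames(uo) <- colnames(ue) <- U_COLS
  out <- p[, intersect(c("crystal", "condition", "type", KEY_COLS, "elesy",
                         "res_has_alt"), names(p)), drop = FALSE]
  out$d_beq <- beq(uo) - beq(ue)
  out$d_aniso <- aniso(uo) - aniso(ue)
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Group summaries of paired differences with 95% confidence intervals
#'
#' Pools the per-atom differences of each group (across all crystals of each
#' condition, atoms treated as independent observations) and reports the
#' arithmetic mean with a two-sided 95% confidence interval of the mean based
#' on the Student t distribution with n-1 degrees of freedom. Groups with a
#' single atom report the mean but no interval (`ci_half` is NA); empty
#' groups are omitted.
#'
#' @param diffs data frame from [paired_differences()].
#' @param metric which difference to summarise, `"beq"` or `"aniso"`.
#' @param by `"type"` groups by amino-acid (residue) type, `"residue"` by
#'   individual residue (chain + number + name).
#' @param condition optional filter, `"treated"` or `"reference"`; by default
#'   each condition is summarised separately.
#' @param conf confidence level (default 0.95).
#' @return Data frame with `group`, `condition`, `n`, `mean`, `sd`,
#'   `ci_half` (half-width of the confidence interval, same units as the
#'   metric).
#' @export
group_summary <- function(diffs, metric = c("beq", "aniso"),
                          by = c("type", "residue"), condition = NULL,
                          conf = 0.95) {
  metric <- match.arg(metric)
  by <- match.arg(by)
  if (!is.null(condition)) diffs <- diffs[diffs$condition %in% condition, ,
                                          drop = FALSE]
  if (nrow(diffs) == 0L) {
    warning("no differences to summarise")
    return(data.frame(group = character(), condition = character(),
                      n = integer(), mean = numeric(), sd = numeric(),
                      ci_half = numeric()))
  }
  val <- diffs[[paste0("d_", metric)]]
  grp <- if (by == "type") diffs$resid else
    paste0(diffs$chain, "-", diffs$resid, "-", diffs$resno, diffs$insert)
  f <- interaction(grp, diffs$condition, drop = TRUE, sep = "\r")
  idx <- split(seq_along(val), f)
  rows <- lapply(idx, function(ii) {
    n <- length(ii)
    m <- mean(val[ii])
    s <- if (n > 1L) stats::sd(val[ii]) else NA_real_
    ci <- if (n > 1L) stats::qt(1 - (1 - conf) / 2, df = n - 1L) * s / sqrt(n)
          else NA_real_
    data.frame(n = n, mean = m, sd = s, ci_half = ci)
  })
  keys <- do.call(rbind, strsplit(names(idx), "\r", fixed = TRUE))
  out <- cbind(data.frame(group = keys[, 1L], condition = keys[, 2L],
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out[order(out$condition, out$group), , drop = FALSE]
}

#' Mean displacement metrics per residue or per amino-acid type
#'
#' Averages B_eq and ANISO over all equivalent atoms of each residue (or of
#' each residue type), pooling the selected crystals and states -- the
#' profile used to compare experimental displacements with normal-mode or
#' molecular-dynamics predictions.
#'
#' @param metrics data frame from [adp_metrics()] (rows may span several
#'   crystals/states), or an `adp_pool`, in which case both states of every
#'   observation enter the average.
#' @param by `"residue"` or `"type"`.
#' @param source label recorded in the output (e.g. `"experiment"`,
#'   `"prediction"`).
#' @return Data frame with `group`, `mean_beq`, `mean_aniso`, `n_atoms`,
#'   `source`.
#' @export
residue_profile <- function(metrics, by = c("residue", "type"),
                            source = "experiment") {
  by <- match.arg(by)
  if (inherits(metrics, "adp_pool") || !is.null(metrics$u11_odd))
    metrics <- pool_metrics(metrics)
  if (nrow(metrics) == 0L) {
    warning("empty selection: no atoms to profile")
    return(data.frame(group = character(), mean_beq = numeric(),
                      mean_aniso = numeric(), n_atoms = integer(),
                      source = character()))
  }
  grp <- if (by == "type") metrics$resid else
    paste0(metrics$chain, "-", metrics$resid, "-", metrics$resno,
           metrics$insert)
  out <- do.call(rbind, lapply(split(seq_len(nrow(metrics)), grp),
    function(ii) data.frame(mean_beq = mean(metrics$beq[ii]),
                            mean_aniso = mean(metrics$aniso[ii]),
                            n_atoms = length(ii))))
  out <- cbind(data.frame(group = rownames(out), stringsAsFactors = FALSE),
               out, data.frame(source = source))
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

# Long per-(atom, state) metrics from an observation pool.
pool_metrics <- function(pool) {
  p <- if (inherits(pool, "adp_pool")) pool$pool else pool
  p <- p[!(p$npd %||% FALSE), , drop = FALSE]
  id <- p[, intersect(c("crystal", "condition", KEY_COLS), names(p)),
          drop = FALSE]
  one_state <- function(suffix, state) {
    u <- as.matrix(p[, paste0(U_COLS, suffix), drop = FALSE])
    colnames(u) <- U_COLS
    cbind(id, data.frame(state = state, beq = beq(u), aniso = aniso(u)))
  }
  out <- rbind(one_state("_odd", "odd"), one_state("_even", "even"))
  rownames(out) <- NULL
  out
}

#' Pearson correlation coefficient with validity checks
#'
#' Standard product-moment correlation, used to compare experimental and
#' predicted per-residue displacement profiles and crystal-vs-crystal
#' self-consistency. Being scale-free, it is unaffected by the absolute
#' magnitude mismatch between experimental and simulated displacements.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Pairwise Pearson correlation matrix of aligned profiles
#'
#' @param profiles data frame or matrix whose columns are aligned value
#'   vectors (e.g. per-residue mean B_eq of each crystal or prediction).
#' @return Square symmetric correlation matrix.
#' @export
cc_matrix <- function(profiles) {
  m <- as.matrix(profiles)
  if (ncol(m) < 2L) stop("need at least two profiles")
  k <- ncol(m)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    out[i, j] <- out[j, i] <- pearson_cc(m[, i], m[, j])
  out
}

#' Correlate an experimental profile with an external prediction
#'
#' Predictions (e.g. from normal-mode analysis or molecular dynamics) enter
#' as a plain two-column table: an identifier matching the profile's `group`
#' column, and a value. Only groups present in both tables are compared.
#'
#' @param profile data frame from [residue_profile()].
#' @param prediction data frame whose first column is the identifier and
#'   second the predicted value (or a path to such a CSV/TSV file).
#' @param metric which experimental column to use, `"beq"` or `"aniso"`.
#' @return List with `cc` (Pearson coefficient) and `n` (matched groups).
#' @export
compare_prediction <- function(profile, prediction,
                               metric = c("beq", "aniso")) {
  metric <- match.arg(metric)
  if (is.character(prediction)) {
    sep <- if (grepl("\\.tsv$", prediction)) "\t" else ","
    prediction <- utils::read.table(prediction, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE)
  }
  if (ncol(prediction) < 2L) stop("prediction table needs >= 2 columns")
  hit <- match(profile$group, as.character(prediction[[1L]]))
  ok <- !is.na(hit)
  list(cc = pearson_cc(profile[[paste0("mean_", metric)]][ok],
                       as.numeric(prediction[[2L]][hit[ok]])),
       n = sum(ok))
}
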