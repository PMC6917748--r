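# Matching equivalent atoms between the two refined states of one crystal,
# and concatenating the per-crystal pairs into the multi-crystal observation
# pool that feeds the differential statistics and the clustering.

atom_key <- function(df) {
  do.call(paste, c(df[KEY_COLS], sep = "|"))
}

#' Pair equivalent atoms between the odd and even states of one crystal
#'
#' Atoms are matched on exact identity (chain, residue number, insertion
#' code, residue name, atom name, altloc). Only atoms carrying a tensor in
#' both states become paired observations; everything else is listed in the
#' exclusion report with a reason. Residues modelled with any alternate
#' conformation are flagged (`res_has_alt`) so downstream analyses can filter
#' them.
#'
#' @param odd,even `adp_structure` objects (or their `$atoms` data frames)
#'   parsed from the two states of the same crystal.
#' @param crystal crystal identifier carried into every observation.
#' @param condition experimental condition, `"treated"` or `"reference"`.
#' @return A list of class `adp_pairs`: `pairs` (one row per paired atom with
#'   tensor columns `u11_odd..u23_odd`, `u11_even..u23_even`, per-state `beq`
#'   and NPD flags) and `exclusions` (identity columns, `state`, `reason`).
#' @export
pair_states <- function(odd, even, crystal, condition = c("reference", "treated")) {
  condition <- match.arg(condition)
  o <- if (inherits(odd, "adp_structure")) odd$atoms else odd
  e <- if (inherits(even, "adp_structure")) even$atoms else even
  ko <- atom_key(o)
  ke <- atom_key(e)
  for (nm in list(list(k = ko, s = "odd"), list(k = ke, s = "even"))) {
    dup <- nm$k[duplicated(nm$k)]
    if (length(dup))
      stop("duplicate atom key in ", nm$s, " state: ", dup[1L])
  }

  excl <- list()
  note <- function(df, state, reason) {
    if (nrow(df)) {
      x <- df[, KEY_COLS, drop = FALSE]
      x$state <- state
      x$reason <- reason
      excl[[length(excl) + 1L]] <<- x
    }
  }

  note(o[!(ko %in% ke), , drop = FALSE], "odd", "unmatched in even")
  note(e[!(ke %in% ko), , drop = FALSE], "even", "unmatched in odd")

  o2 <- o[ko %in% ke, , drop = FALSE]
  e2 <- e[match(atom_key(o2), ke), , drop = FALSE]
  miss_o <- !o2$has_tensor & e2$has_tensor
  miss_e <- o2$has_tensor & !e2$has_tensor
  miss_b <- !o2$has_tensor & !e2$has_tensor
  note(o2[miss_o, , drop = FALSE], "both", "tensor missing in odd")
  note(o2[miss_e, , drop = FALSE], "both", "tensor missing in even")
  note(o2[miss_b, , drop = FALSE], "both", "tensor missing in both")

  keep <- o2$has_tensor & e2$has_tensor
  o2 <- o2[keep, , drop = FALSE]
  e2 <- e2[keep, , drop = FALSE]

  pairs <- cbind(
    data.frame(crystal = crystal, condition = condition,
               stringsAsFactors = FALSE),
    o2[, c("type", KEY_COLS, "elesy", "occ")],
    stats::setNames(o2[, U_COLS], paste0(U_COLS, "_odd")),
    stats::setNames(e2[, U_COLS], paste0(U_COLS, "_even")),
    data.frame(npd_odd = o2$npd, npd_even = e2$npd)
  )
  pairs$npd <- pairs$npd_odd | pairs$npd_even
  res_key <- paste(pairs$chain, pairs$resno, pairs$insert)
  alt_res <- unique(res_key[pairs$alt != ""])
  pairs$res_has_alt <- res_key %in% alt_res
  rownames(pairs) <- NULL

  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(chain = character(), resno = integer(), insert = character(),
               resid = character(), elety = character(), alt = character(),
               state = character(), reason = character())
  rownames(exclusions) <- NULL
  structure(list(pairs = pairs, exclusions = exclusions,
                 crystal = crystal, condition = condition),
            class = "adp_pairs")
}

#' @export
print.adp_pairs <- function(x, ...) {
  cat(sprintf("Crystal %s (%s): %d paired atoms, %d exclusions\n",
              x$crystal, x$condition, nrow(x$pairs), nrow(x$exclusions)))
  invisible(x)
}

#' Read a crystal manifest
#'
#' A manifest is a CSV/TSV table with columns `crystal`, `condition`
#' (`treated`/`reference`), `odd` and `even` (paths to the two state files,
#' resolved relative to the manifest's directory when not absolute).
#'
#' @param path manifest file path.
#' @return Data frame with absolute `odd`/`even` paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("crystal", "condition", "odd", "even")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$odd <- fix(m$odd)
  m$even <- fix(m$even)
  m
}

#' Assemble the multi-crystal observation pool
#'
#' Parses every (odd, even) pair in the manifest, pairs equivalent atoms per
#' crystal, applies the requested atom filters, and concatenates the result
#' into one pool -- the unit on which paired differences and the hierarchical
#' clustering operate.
#'
#' @param manifest data frame (or path to one, see [read_manifest()]) with
#'   columns `crystal`, `condition`, `odd`, `even`.
#' @param polymer_only drop HETATM records (waters, ions, ligands).
#' @param exclude_altloc drop atoms of residues modelled with any alternate
#'   conformation.
#' @return A list of class `adp_pool`: `pool` (concatenated paired
#'   observations), `exclusions`, `reports` (per-file parse reports) and
#'   `filters`.
#' @export
assemble_pool <- function(manifest, polymer_only = FALSE,
                          exclude_altloc = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) < 1L) stop("manifest has no crystal pairs")
  missing <- c(manifest$odd, manifest$even)
  missing <- missing[!file.exists(missing)]
  if (length(missing))
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "))

  pools <- vector("list", nrow(manifest))
  excls <- vector("list", nrow(manifest))
  reports <- list()
  n_filtered <- 0L
  for (i in seq_len(nrow(manifest))) {
    so <- read_anisou_pdb(manifest$odd[i])
    se <- read_anisou_pdb(manifest$even[i])
    reports[[paste0(manifest$crystal[i], ":odd")]] <- so$report
    reports[[paste0(manifest$crystal[i], ":even")]] <- se$report
    pr <- pair_states(so, se, crystal = manifest$crystal[i],
                      condition = manifest$condition[i])
    p <- pr$pairs
    if (polymer_only) {
      n_filtered <- n_filtered + sum(p$type != "ATOM")
      p <- p[p$type == "ATOM", , drop = FALSE]
    }
    if (exclude_altloc) {
      n_filtered <- n_filtered + sum(p$res_has_alt)
      p <- p[!p$res_has_alt, , drop = FALSE]
    }
    pools[[i]] <- p
    ex <- pr$exclusions
    if (nrow(ex)) ex$crystal <- manifest$crystal[i]
    excls[[i]] <- ex
  }
  pool <- do.call(rbind, pools)
  rownames(pool) <- NULL
  if (nrow(pool) == 0L) stop("empty pool: no paired tensor-bearing atoms")
  exclusions <- do.call(rbind, excls[vapply(excls, nrow, 1L) > 0])
  structure(list(pool = pool,
                 exclusions = exclusions %||% data.frame(),
                 reports = reports,
                 filters = list(polymer_only = polymer_only,
                                exclude_altloc = exclude_altloc,
                                n_filtered = n_filtered)),
            class = "adp_pool")
}

#' @export
print.adp_pool <- function(x, ...) {
  cat(sprintf("ADP observation pool: %d paired atoms from %d crystals\n",
              nrow(x$pool), length(unique(x$pool$crystal))))
  nex <- if (is.null(x$exclusions)) 0L else nrow(x$exclusions)
  cat(sprintf("  exclusions: %d; filtered: %d\n", nex,
              x$filters$n_filtered))
  invisible(x)
}
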