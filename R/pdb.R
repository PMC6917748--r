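# Fixed-column PDB parsing of ATOM/HETATM/ANISOU records.
#
# ANISOU stores the six unique elements of the displacement tensor as
# integers, U x 10^4 in Angstrom^2 in the orthogonal-Angstrom basis, in the
# order U11 U22 U33 U12 U13 U23 (columns 29-35, 36-42, ..., 64-70). Each
# ANISOU line refers to the ATOM/HETATM line bearing the same serial number
# and identity fields. General-purpose structure readers commonly discard
# these records, so the parsing is done here at line level.

pdb_field <- function(lines, from, to) trimws(substring(lines, from, to))

pdb_num <- function(lines, from, to) {
  suppressWarnings(as.numeric(substring(lines, from, to)))
}

# Infer an element symbol from the atom-name field when columns 77-78 are
# blank (common in older files). Digits are stripped; a leading character in
# column 13 signals a two-letter element for HETATMs, but for standard
# protein atoms the first alphabetic character is the element.
infer_element <- function(elety) {
  s <- gsub("[0-9']", "", elety)
  toupper(substring(s, 1L, 1L))
}

#' Read a PDB file with anisotropic displacement parameters
#'
#' Parses ATOM/HETATM records and attaches each ANISOU record to its matching
#' atom (same serial number and identity fields). ANISOU integer fields are
#' divided by 10^4 to give tensor elements in Angstrom^2. Hydrogen (and
#' deuterium) atoms are dropped, since riding hydrogens carry no
#' independently refined displacement parameters; the parse report counts
#' them.
#'
#' @param path path to a PDB-format file.
#' @return An object of class `adp_structure`: a list with
#'   \describe{
#'     \item{atoms}{data frame, one row per retained atom: `type`
#'       (ATOM/HETATM), `eleno`, `elety`, `alt`, `resid`, `chain`, `resno`,
#'       `insert`, `x`, `y`, `z`, `occ`, `b`, `elesy`, the six tensor columns
#'       `u11..u23`, `has_tensor`, and `npd` (non-positive-definite flag).}
#'     \item{report}{counts of parsed, hydrogen-dropped, tensor-bearing,
#'       tensorless and NPD atoms.}
#'     \item{path}{the source path.}
#'   }
#' @export
read_anisou_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_aniso <- rec == "ANISOU"
  al <- lines[is_atom]

  atoms <- data.frame(
    type   = trimws(rec[is_atom]),
    eleno  = as.integer(pdb_field(al, 7L, 11L)),
    elety  = pdb_field(al, 13L, 16L),
    alt    = pdb_field(al, 17L, 17L),
    resid  = pdb_field(al, 18L, 20L),
    chain  = pdb_field(al, 22L, 22L),
    resno  = as.integer(pdb_field(al, 23L, 26L)),
    insert = pdb_field(al, 27L, 27L),
    x      = pdb_num(al, 31L, 38L),
    y      = pdb_num(al, 39L, 46L),
    z      = pdb_num(al, 47L, 54L),
    occ    = pdb_num(al, 55L, 60L),
    b      = pdb_num(al, 61L, 66L),
    elesy  = toupper(pdb_field(al, 77L, 78L)),
    stringsAsFactors = FALSE
  )
  blank <- atoms$elesy == ""
  atoms$elesy[blank] <- infer_element(atoms$elety[blank])

  # attach ANISOU records by serial + identity key
  for (col in U_COLS) atoms[[col]] <- NA_real_
  atoms$has_tensor <- FALSE
  if (any(is_aniso)) {
    nl <- lines[is_aniso]
    akey <- paste(atoms$eleno, atoms$elety, atoms$alt, atoms$resid,
                  atoms$chain, atoms$resno, atoms$insert)
    nkey <- paste(as.integer(pdb_field(nl, 7L, 11L)),
                  pdb_field(nl, 13L, 16L), pdb_field(nl, 17L, 17L),
                  pdb_field(nl, 18L, 20L), pdb_field(nl, 22L, 22L),
                  as.integer(pdb_field(nl, 23L, 26L)),
                  pdb_field(nl, 27L, 27L))
    hit <- match(nkey, akey)
    if (anyNA(hit)) {
      bad <- which(is_aniso)[which(is.na(hit))[1L]]
      stop("ANISOU record with no matching atom at line ", bad, " of ", path)
    }
    uu <- cbind(pdb_num(nl, 29L, 35L), pdb_num(nl, 36L, 42L),
                pdb_num(nl, 43L, 49L), pdb_num(nl, 50L, 56L),
                pdb_num(nl, 57L, 63L), pdb_num(nl, 64L, 70L)) / 1e4
    atoms[hit, U_COLS] <- uu
    atoms$has_tensor[hit] <- TRUE
  }

  is_h <- atoms$elesy %in% c("H", "D")
  n_h <- sum(is_h)
  atoms <- atoms[!is_h, , drop = FALSE]
  rownames(atoms) <- NULL

  atoms$npd <- FALSE
  if (any(atoms$has_tensor))
    atoms$npd[atoms$has_tensor] <-
      is_npd(atoms[atoms$has_tensor, , drop = FALSE])

  report <- list(
    n_atom_records  = length(al),
    n_hydrogen      = n_h,
    n_atoms         = nrow(atoms),
    n_with_tensor   = sum(atoms$has_tensor),
    n_without_tensor = sum(!atoms$has_tensor),
    n_npd           = sum(atoms$npd)
  )
  structure(list(atoms = atoms, report = report, path = path),
            class = "adp_structure")
}

#' @export
print.adp_structure <- function(x, ...) {
  r <- x$report
  cat("ADP structure:", x$path, "\n")
  cat(sprintf("  %d atoms (%d hydrogens dropped): %d with ANISOU, %d without, %d NPD\n",
              r$n_atoms, r$n_hydrogen, r$n_with_tensor, r$n_without_tensor,
              r$n_npd))
  invisible(x)
}

# PDB atom-name field (cols 13-16): names shorter than 4 characters of
# one-letter elements are indented one space so the element aligns in col 14.
format_elety <- function(elety, elesy) {
  ifelse(nchar(elety) >= 4L | nchar(elesy) >= 2L,
         formatC(elety, width = -4L),
         formatC(paste0(" ", elety), width = -4L))
}

#' Write atoms (with optional ANISOU tensors) to a PDB file
#'
#' Emits standard fixed-column ATOM/HETATM lines and, for every atom with a
#' tensor, an ANISOU line whose integer fields are `round(u * 10^4)`.
#'
#' @param atoms data frame in the layout produced by [read_anisou_pdb()]
#'   (`type` and `eleno` are optional and default to ATOM / row number;
#'   tensor columns may be absent or NA for tensorless atoms).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_anisou_pdb <- function(atoms, path) {
  n <- nrow(atoms)
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(n)
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$has_tensor))
    atoms$has_tensor <- if ("u11" %in% names(atoms)) !is.na(atoms$u11)
                        else rep(FALSE, n)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  ht <- atoms$has_tensor
  if (any(ht)) {
    um <- u_as_matrix(atoms[ht, , drop = FALSE])
    if (any(abs(um) >= 10))
      stop("tensor element |u| >= 10 Angstrom^2 overflows the ANISOU field")
  }

  name4 <- format_elety(atoms$elety, atoms$elesy)
  id <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s",
                atoms$type, atoms$eleno, name4, atoms$alt, atoms$resid,
                atoms$chain, atoms$resno, atoms$insert)
  atom_lines <- sprintf("%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                        id, atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b,
                        atoms$elesy)
  out <- character(n + sum(ht) + 1L)
  pos <- 1L
  for (i in seq_len(n)) {
    out[pos] <- atom_lines[i]; pos <- pos + 1L
    if (ht[i]) {
      u <- round(as.numeric(atoms[i, U_COLS]) * 1e4)
      out[pos] <- sprintf("%s %7d%7d%7d%7d%7d%7d      %2s",
                          sub("^ATOM  ", "ANISOU",
                              sub("^HETATM", "ANISOU", substr(id[i], 1L, 27L))),
                          u[1L], u[2L], u[3L], u[4L], u[5L], u[6L],
                          atoms$elesy[i])
      pos <- pos + 1L
    }
  }
  out[pos] <- "END"
  writeLines(out, path)
  invisible(path)
}
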