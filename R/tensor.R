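#' Construct an ADP tensor from its six unique elements
#'
#' An atomic displacement parameter (ADP) tensor is a symmetric 3x3 matrix of
#' mean-square displacements in Angstrom^2, stored here as its six unique
#' elements in the fixed order (u11, u22, u33, u12, u13, u23) -- the order of
#' a PDB ANISOU record (after division by 10^4).
#'
#' @param u11,u22,u33 diagonal elements, Angstrom^2.
#' @param u12,u13,u23 off-diagonal elements, Angstrom^2.
#' @return A named numeric vector of length 6 with class `adp_tensor`.
#' @examples
#' adp_tensor(0.04, 0.02, 0.01)
#' @export
adp_tensor <- function(u11, u22, u33, u12 = 0, u13 = 0, u23 = 0) {
  u <- c(u11 = u11, u22 = u22, u33 = u33, u12 = u12, u13 = u13, u23 = u23)
  if (!all(is.finite(u)))
    stop("all six tensor elements must be finite")
  class(u) <- "adp_tensor"
  u
}

# Coerce a length-6 vector / 1-row slice to a plain named numeric u-vector.
as_u6 <- function(u) {
  if (is.data.frame(u)) u <- unlist(u[1, U_COLS], use.names = FALSE)
  u <- as.numeric(u)
  if (length(u) != 6L || !all(is.finite(u)))
    stop("expected six finite tensor elements (u11, u22, u33, u12, u13, u23)")
  names(u) <- U_COLS
  u
}

#' Expand a six-element ADP tensor to its symmetric 3x3 matrix
#'
#' @param u tensor as six unique elements (see [adp_tensor()]).
#' @return A symmetric 3x3 numeric matrix.
#' @export
tensor_matrix <- function(u) {
  u <- as_u6(u)
  matrix(c(u["u11"], u["u12"], u["u13"],
           u["u12"], u["u22"], u["u23"],
           u["u13"], u["u23"], u["u33"]), 3, 3)
}

#' Eigendecomposition of an ADP tensor
#'
#' Diagonalises the symmetric displacement tensor, U = P diag(E1,E2,E3) P^-1.
#' Eigenvalues are returned in descending order; each eigenvector's sign is
#' fixed so that its first component of magnitude above 1e-12 is positive,
#' giving a deterministic decomposition across platforms.
#'
#' @param u tensor as six unique elements.
#' @return A list of class `adp_eigen` with elements `values` (length 3,
#'   descending, Angstrom^2) and `vectors` (3x3 matrix, columns are unit
#'   eigenvectors).
#' @examples
#' tensor_eigen(adp_tensor(0.04, 0.02, 0.01))$values
#' @export
tensor_eigen <- function(u) {
  m <- tensor_matrix(u)
  e <- eigen(m, symmetric = TRUE)   # values already in decreasing order
  v <- e$vectors
  for (j in 1:3) {
    lead <- which(abs(v[, j]) > 1e-12)[1]
    if (!is.na(lead) && v[lead, j] < 0) v[, j] <- -v[, j]
  }
  structure(list(values = e$values, vectors = v), class = "adp_eigen")
}

#' Equivalent isotropic B-factor of an ADP tensor
#'
#' B_eq = 8 pi^2 tr(U) / 3, the isotropic B-factor equivalent to the
#' anisotropic tensor. Vectorised: accepts a single six-element tensor, a
#' matrix with six columns, or a data frame carrying columns u11..u23.
#'
#' @param u tensor(s); six elements, an n x 6 matrix, or a data frame.
#' @return Numeric vector of B_eq values, Angstrom^2.
#' @examples
#' beq(adp_tensor(0.01, 0.01, 0.01))  # 8 * pi^2 * 0.01
#' @export
beq <- function(u) {
  tr <- tensor_traces(u)
  8 * pi^2 * tr / 3
}

tensor_traces <- function(u) {
  if (is.data.frame(u)) {
    u[["u11"]] + u[["u22"]] + u[["u33"]]
  } else if (is.matrix(u)) {
    if (ncol(u) != 6L) stop("tensor matrix must have 6 columns")
    u[, 1L] + u[, 2L] + u[, 3L]
  } else {
    u <- as_u6(u)
    unname(u["u11"] + u["u22"] + u["u33"])
  }
}

#' Anisotropy of an ADP tensor
#'
#' ANISO = min(E) / max(E), the ratio of the smallest to the largest
#' eigenvalue of the displacement tensor. For positive-definite tensors the
#' value lies in (0, 1], with 1 indicating perfect isotropy (a spherical
#' thermal ellipsoid) and values near 0 an extreme ellipsoid. For a
#' non-positive-definite tensor (a refinement artifact) the ratio is <= 0 and
#' is returned as-is; flag such atoms with [is_npd()]. A tensor whose largest
#' eigenvalue is <= 0 has no meaningful ellipsoid and raises an error.
#'
#' @param u tensor(s); six elements, an n x 6 matrix, or a data frame.
#' @return Numeric vector of anisotropy ratios (dimensionless).
#' @examples
#' aniso(adp_tensor(0.04, 0.02, 0.01))  # 0.25
#' @export
aniso <- function(u) {
  ev <- tensor_eigenvalues(u)
  if (any(ev[, 1L] <= 0))
    stop("degenerate tensor: largest eigenvalue <= 0")
  unname(ev[, 3L] / ev[, 1L])
}

# n x 3 matrix of eigenvalues (descending) for one or many tensors.
tensor_eigenvalues <- function(u) {
  um <- u_as_matrix(u)
  t(apply(um, 1L, function(r) {
    eigen(matrix(c(r[1L], r[4L], r[5L],
                   r[4L], r[2L], r[6L],
                   r[5L], r[6L], r[3L]), 3, 3),
          symmetric = TRUE, only.values = TRUE)$values
  }))
}

u_as_matrix <- function(u) {
  if (is.data.frame(u)) {
    as.matrix(u[, U_COLS, drop = FALSE])
  } else if (is.matrix(u)) {
    if (ncol(u) != 6L) stop("tensor matrix must have 6 columns")
    u
  } else {
    matrix(as_u6(u), nrow = 1L)
  }
}

#' Flag non-positive-definite tensors
#'
#' A deposited ADP tensor is non-positive definite (NPD) when its smallest
#' eigenvalue is <= 0; such tensors have no physical thermal ellipsoid and
#' arise as refinement artifacts.
#'
#' @param u tensor(s); six elements, an n x 6 matrix, or a data frame.
#' @return Logical vector, TRUE where the smallest eigenvalue is <= 0.
#' @export
is_npd <- function(u) {
  ev <- tensor_eigenvalues(u)
  unname(ev[, 3L] <= 0)
}

#' Per-atom displacement metrics table
#'
#' Computes the eigenvalues, equivalent B-factor and anisotropy for every
#' tensor-bearing atom of a parsed structure, one row per atom.
#'
#' @param x an `adp_structure` from [read_anisou_pdb()], or a data frame with
#'   atom identity columns and u11..u23.
#' @param crystal,state optional labels copied into the output.
#' @return A data frame with the atom identity columns, `e1 >= e2 >= e3`
#'   (Angstrom^2), `beq` (Angstrom^2), `aniso` (dimensionless) and `npd`.
#' @export
adp_metrics <- function(x, crystal = NA_character_, state = NA_character_) {
  atoms <- if (inherits(x, "adp_structure")) x$atoms else x
  atoms <- atoms[atoms$has_tensor %||% rep(TRUE, nrow(atoms)), , drop = FALSE]
  if (nrow(atoms) == 0L)
    return(data.frame())
  ev <- tensor_eigenvalues(atoms)
  id_cols <- intersect(c("chain", "resno", "insert", "resid", "elety", "alt",
                         "elesy"), names(atoms))
  out <- cbind(
    data.frame(crystal = crystal, state = state),
    atoms[, id_cols, drop = FALSE],
    data.frame(e1 = ev[, 1L], e2 = ev[, 2L], e3 = ev[, 3L],
               beq = beq(atoms), aniso = ev[, 3L] / ev[, 1L],
               npd = ev[, 3L] <= 0)
  )
  rownames(out) <- NULL
  out
}
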