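# Synthetic multi-crystal two-state ensembles with planted ADP structure.
#
# The generator emulates the statistical skeleton of a paired-state ADP
# study: several crystals, each refined in an "odd" and an "even" state;
# per-atom symmetric positive-definite tensors drawn from a small set of
# planted archetypes plus element-wise Gaussian noise; and, in crystals
# labelled "treated", a condition-dependent anisotropy increase in the odd
# state (contraction of the smallest tensor eigenvalue). Coordinates sit on
# a self-avoiding 3.8-Angstrom random walk so the files are geometrically
# plausible PDB, but positions play no role in any metric.

#' Uniformly random 3-D rotation matrix
#'
#' Drawn by QR decomposition of a Gaussian matrix with sign correction
#' (Haar-uniform over SO(3)).
#'
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Symmetric matrix -> six unique elements in canonical order.
mat_to_u6 <- function(m) {
  c(u11 = m[1, 1], u22 = m[2, 2], u33 = m[3, 3],
    u12 = m[1, 2], u13 = m[1, 3], u23 = m[2, 3])
}

#' Sample well-separated SPD tensor archetypes
#'
#' Each archetype is R diag(E) R^T with eigenvalues drawn uniformly from
#' `eig_range` and R a uniformly random rotation. The whole set is
#' rejection-resampled until every pair is at least `min_separation` apart in
#' the 12-D clustering feature space (odd = even = archetype).
#'
#' @param k number of archetypes.
#' @param eig_range length-2 eigenvalue range, Angstrom^2, both > 0.
#' @param min_separation minimum pairwise 12-D Euclidean distance, Angstrom^2.
#' @param max_tries resampling budget before declaring the spec infeasible.
#' @return k x 6 matrix, one archetype tensor per row.
#' @export
sample_archetypes <- function(k, eig_range = c(0.02, 0.2),
                              min_separation = 0.06, max_tries = 1e4) {
  if (k < 1L) stop("k must be >= 1")
  if (any(eig_range <= 0)) stop("eigenvalue range must be strictly positive")
  for (try in seq_len(max_tries)) {
    arch <- t(vapply(seq_len(k), function(i) {
      e <- sort(stats::runif(3, eig_range[1L], eig_range[2L]),
                decreasing = TRUE)
      r <- random_rotation()
      mat_to_u6(r %*% diag(e) %*% t(r))
    }, numeric(6)))
    colnames(arch) <- U_COLS
    if (k == 1L) return(arch)
    # 12-D distance with both states equal to the archetype = sqrt(2) * 6-D
    d <- sqrt(2) * stats::dist(arch)
    if (min(d) >= min_separation) return(arch)
  }
  stop("could not place ", k, " archetypes at separation >= ",
       min_separation, " in ", max_tries, " attempts")
}

#' Specification of a synthetic two-state ensemble
#'
#' Defaults describe the package's standard validation ensemble: 6 crystals
#' (half treated), 200 atoms each, 4 tensor archetypes with eigenvalues in
#' 0.02-0.20 Angstrom^2 (B_eq roughly 5-50 Angstrom^2, typical of a cryo
#' high-resolution structure), archetype separation 0.06 Angstrom^2 with
#' element noise sd of separation/20, and a treated-state effect that
#' contracts the smallest eigenvalue of odd-state tensors by 20%.
#'
#' @param n_crystals number of crystals (each yields an odd and an even file).
#' @param n_atoms atoms per crystal.
#' @param n_archetypes number of planted tensor archetypes.
#' @param eig_range archetype eigenvalue range, Angstrom^2.
#' @param min_separation minimum pairwise archetype distance (12-D),
#'   Angstrom^2.
#' @param noise_sd sd of the Gaussian perturbation added to each tensor
#'   element, Angstrom^2.
#' @param treated_fraction fraction of crystals labelled "treated".
#' @param effect_factor multiplier in (0, 1] applied to the smallest
#'   eigenvalue of treated-crystal odd-state tensors (1 = no effect).
#' @param seed integer seed; generation is reproducible for a fixed seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_crystals = 6L, n_atoms = 200L,
                           n_archetypes = 4L, eig_range = c(0.02, 0.2),
                           min_separation = 0.06,
                           noise_sd = min_separation / 20,
                           treated_fraction = 0.5, effect_factor = 0.8,
                           seed = 1L) {
  stopifnot(n_crystals >= 1L, n_atoms >= 1L, n_archetypes >= 1L,
            all(eig_range > 0), noise_sd >= 0,
            treated_fraction >= 0, treated_fraction <= 1,
            effect_factor > 0, effect_factor <= 1)
  structure(list(n_crystals = as.integer(n_crystals),
                 n_atoms = as.integer(n_atoms),
                 n_archetypes = as.integer(n_archetypes),
                 eig_range = eig_range, min_separation = min_separation,
                 noise_sd = noise_sd, treated_fraction = treated_fraction,
                 effect_factor = effect_factor, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Clip eigenvalues from below to keep the tensor positive definite.
clip_spd <- function(u6, floor = 1e-4) {
  m <- tensor_matrix(u6)
  e <- eigen(m, symmetric = TRUE)
  if (e$values[3L] >= floor) return(u6)
  v <- pmax(e$values, floor)
  mat_to_u6(e$vectors %*% diag(v) %*% t(e$vectors))
}

# Contract the smallest eigenvalue by `factor` (the planted condition effect:
# the ellipsoid becomes more anisotropic).
contract_min_eigenvalue <- function(u6, factor) {
  m <- tensor_matrix(u6)
  e <- eigen(m, symmetric = TRUE)
  v <- e$values
  v[3L] <- v[3L] * factor
  mat_to_u6(e$vectors %*% diag(v) %*% t(e$vectors))
}

# Self-avoiding random walk with fixed step length (pseudo-backbone).
random_walk <- function(n, step = 3.8, min_dist = 3.0) {
  xyz <- matrix(0, n, 3)
  i <- 2L
  guard <- 0L
  while (i <= n) {
    d <- stats::rnorm(3)
    cand <- xyz[i - 1L, ] + step * d / sqrt(sum(d^2))
    if (i <= 2L ||
        min(sqrt(rowSums(sweep(xyz[1:(i - 2L), , drop = FALSE], 2, cand)^2))) >=
        min_dist) {
      xyz[i, ] <- cand
      i <- i + 1L
      guard <- 0L
    } else {
      guard <- guard + 1L
      if (guard > 500L) { # back off one step and retry
        i <- max(2L, i - 1L)
        guard <- 0L
      }
    }
  }
  xyz
}

# Residue-name palette used to label archetypes (atoms of one residue share
# an archetype, so per-type averages have a planted truth).
ARCH_RESNAMES <- c("ALA", "SER", "CYS", "THR", "VAL", "LEU", "ASP", "ASN",
                   "GLN", "LYS", "MET", "PHE", "TRP", "TYR", "HIS", "ARG")
RES_ATOMS <- c("N", "CA", "C", "O", "CB")

#' Generate a synthetic multi-crystal two-state PDB ensemble
#'
#' Writes, for every crystal, an odd-state and an even-state PDB file with
#' ANISOU records, plus a crystal manifest and a planted-truth table. Atoms
#' are organised as a single chain of five-atom (N, CA, C, O, CB) residues;
#' all atoms of a residue share a tensor archetype and the residue name
#' encodes the archetype, so both atom-key matching and per-type statistics
#' are exercised realistically.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return List with `manifest` (data frame, also written to
#'   `manifest.csv`), `truth` (per-atom archetype/condition labels and exact
#'   pre-quantisation tensors, also `truth.csv`), `archetypes` and `dir`.
#' @export
generate_ensemble <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  arch <- sample_archetypes(spec$n_archetypes, spec$eig_range,
                            spec$min_separation)

  n_res <- ceiling(spec$n_atoms / length(RES_ATOMS))
  res_arch <- rep_len(seq_len(spec$n_archetypes), n_res)
  atom_res <- rep(seq_len(n_res), each = length(RES_ATOMS))[seq_len(spec$n_atoms)]
  atom_arch <- res_arch[atom_res]
  elety <- rep_len(RES_ATOMS, spec$n_atoms)
  resid <- ARCH_RESNAMES[(res_arch - 1L) %% length(ARCH_RESNAMES) + 1L][atom_res]
  elesy <- substring(elety, 1L, 1L)

  n_treated <- round(spec$treated_fraction * spec$n_crystals)
  conditions <- rep(c("treated", "reference"),
                    c(n_treated, spec$n_crystals - n_treated))

  manifest <- data.frame(crystal = sprintf("XTAL%02d", seq_len(spec$n_crystals)),
                         condition = conditions,
                         odd = NA_character_, even = NA_character_,
                         stringsAsFactors = FALSE)
  truth <- vector("list", spec$n_crystals)

  for (ci in seq_len(spec$n_crystals)) {
    xyz <- random_walk(spec$n_atoms)
    treated <- conditions[ci] == "treated"
    base <- data.frame(
      type = "ATOM", eleno = seq_len(spec$n_atoms), elety = elety,
      alt = "", resid = resid, chain = "A", resno = atom_res, insert = "",
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], occ = 1,
      elesy = elesy, stringsAsFactors = FALSE)
    u_true <- list()
    for (state in c("odd", "even")) {
      u <- arch[atom_arch, , drop = FALSE] +
        matrix(stats::rnorm(6L * spec$n_atoms, sd = spec$noise_sd),
               ncol = 6L)
      u <- t(apply(u, 1L, clip_spd))
      if (treated && state == "odd" && spec$effect_factor < 1)
        u <- t(apply(u, 1L, contract_min_eigenvalue,
                     factor = spec$effect_factor))
      colnames(u) <- U_COLS
      u_true[[state]] <- u
      atoms <- base
      atoms[, U_COLS] <- u
      atoms$has_tensor <- TRUE
      atoms$b <- round(beq(u), 2)
      path <- file.path(dir, sprintf("%s_%s.pdb", manifest$crystal[ci], state))
      write_anisou_pdb(atoms, path)
      manifest[[state]][ci] <- path
    }
    truth[[ci]] <- cbind(
      data.frame(crystal = manifest$crystal[ci], condition = conditions[ci],
                 chain = "A", resno = atom_res, insert = "", resid = resid,
                 elety = elety, alt = "", archetype = atom_arch,
                 stringsAsFactors = FALSE),
      stats::setNames(as.data.frame(u_true$odd), paste0(U_COLS, "_odd")),
      stats::setNames(as.data.frame(u_true$even), paste0(U_COLS, "_even")))
  }
  truth <- do.call(rbind, truth)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  list(manifest = manifest, truth = truth, archetypes = arch, dir = dir)
}

#' Adjusted Rand index between a clustering and the planted truth
#'
#' Chance-corrected agreement between two partitions: 1 for identical
#' partitions, approximately 0 for independent ones.
#'
#' @param labels flat cluster labels (e.g. from [cut_adp_tree()]).
#' @param truth reference labels of the same length (e.g. the `archetype`
#'   column of the generator's truth table).
#' @return Adjusted Rand index in \[-1, 1\].
#' @export
recovery_score <- function(labels, truth) {
  if (length(labels) != length(truth))
    stop("labels and truth must have equal length")
  mclust::adjustedRandIndex(labels, truth)
}
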