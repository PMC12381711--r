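# Atom-local density-matrix eigen-descriptors.
#
# The occupied baseline orbitals are projected onto an identical set of
# atom-centred auxiliary Gaussian shells placed on every atom.  For each atom
# I and shell (n,l) the (2l+1)x(2l+1) local density matrix
#   (D_nl^I)_mm' = sum_i f_i <a_nlm^I|phi_i><phi_i|a_nlm'^I>
# is assembled; its eigenvalues are invariant under molecular rotation
# (rotations only mix the magnetic components unitarily) and form the
# fixed-length per-atom descriptor vector fed to the network.

#' Build an atom-centred auxiliary projection basis
#'
#' Shells carry even-tempered exponents `base * ratio^(k-1)` (bohr^-2),
#' k = 1..n_radial, for each angular momentum l = 0..l_max.  The identical
#' shell set is placed on every atom, so per-atom descriptors have fixed
#' length `sum(n_radial * (2l+1))` regardless of element or molecule.
#'
#' @param n_radial number of radial shells per l; scalar or vector of length
#'   `l_max + 1`
#' @param l_max maximum angular momentum of the auxiliary shells
#' @param base,ratio even-tempered exponent parameters; `base > 0`,
#'   `ratio > 1`
#' @return a `projection_basis`: shell table (n, l, exponent) in deterministic
#'   order (ascending l, ascending n within l) plus descriptor-length metadata
#' @export
build_projection_basis <- function(n_radial = c(4, 3, 2), l_max = 2,
                                   base = 0.25, ratio = 2.5) {
  if (base <= 0 || ratio <= 1) stop("need base > 0 and ratio > 1")
  if (l_max < 0) stop("l_max must be >= 0")
  if (length(n_radial) == 1) n_radial <- rep(n_radial, l_max + 1)
  if (length(n_radial) != l_max + 1)
    stop("n_radial must have one count per l = 0..l_max")
  if (any(n_radial < 1)) stop("need at least one radial shell per l")
  shells <- do.call(rbind, lapply(0:l_max, function(l) {
    k <- seq_len(n_radial[l + 1])
    data.frame(n = k, l = l, exponent = base * ratio^(k - 1))
  }))
  structure(list(shells = shells,
                 descriptor_length = sum((2 * shells$l + 1)),
                 spec = list(n_radial = as.integer(n_radial),
                             l_max = as.integer(l_max),
                             base = base, ratio = ratio)),
            class = "projection_basis")
}

#' @export
print.projection_basis <- function(x, ...) {
  cat(sprintf("<projection_basis> %d shells (l_max %d), %d descriptors/atom\n",
              nrow(x$shells), max(x$shells$l), x$descriptor_length))
  invisible(x)
}

# real solid harmonic monomial combinations (unnormalized; functions are
# L2-normalized numerically after assembly)
.solid_harmonics <- list(
  # l = 0
  list(list(mono = rbind(c(0, 0, 0)), coef = 1)),
  # l = 1: m = -1, 0, +1  ->  y, z, x
  list(list(mono = rbind(c(0, 1, 0)), coef = 1),
       list(mono = rbind(c(0, 0, 1)), coef = 1),
       list(mono = rbind(c(1, 0, 0)), coef = 1)),
  # l = 2: m = -2..2 -> xy, yz, 2z^2-x^2-y^2, xz, x^2-y^2
  list(list(mono = rbind(c(1, 1, 0)), coef = 1),
       list(mono = rbind(c(0, 1, 1)), coef = 1),
       list(mono = rbind(c(0, 0, 2), c(2, 0, 0), c(0, 2, 0)),
            coef = c(2, -1, -1)),
       list(mono = rbind(c(1, 0, 1)), coef = 1),
       list(mono = rbind(c(2, 0, 0), c(0, 2, 0)), coef = c(1, -1)))
)

# materialize the projection functions of `pbasis` on every atom of `mol`;
# returns a basis-function list with atom/shell/m bookkeeping attributes
build_projection_functions <- function(mol, pbasis) {
  if (max(pbasis$shells$l) > 2)
    stop("projection shells implemented for l <= 2")
  coords_bohr <- mol$coords * BOHR_PER_ANGSTROM
  bfs <- list()
  meta <- list()
  for (at in seq_len(nrow(coords_bohr))) {
    for (sh in seq_len(nrow(pbasis$shells))) {
      l <- pbasis$shells$l[sh]
      zeta <- pbasis$shells$exponent[sh]
      harmonics <- .solid_harmonics[[l + 1]]
      for (m in seq_along(harmonics)) {
        hm <- harmonics[[m]]
        nterm <- nrow(hm$mono)
        bfs[[length(bfs) + 1]] <- list(
          center = coords_bohr[at, ], alpha = rep(zeta, nterm),
          coef = hm$coef, mono = hm$mono, atom = at, l = l)
        meta[[length(meta) + 1]] <- c(atom = at, shell = sh,
                                      m = m - l - 1L)
      }
    }
  }
  bfs <- normalize_basis(bfs)
  attr(bfs, "meta") <- do.call(rbind, meta)
  bfs
}

#' Project occupied baseline orbitals onto the auxiliary shells
#'
#' Computes the inner products `<a_nlm^I | phi_i>` between every (normalized)
#' atom-centred auxiliary function and every occupied molecular orbital.
#'
#' @param scf an `scf_result` from [run_baseline()]
#' @param pbasis a [build_projection_basis()] object
#' @param occ_threshold orbitals with occupation above this enter the density
#'   matrix
#' @return `projection_coefficients`: for each atom and shell a
#'   `(2l+1) x n_occ` coefficient matrix, plus the occupations used
#' @export
compute_orbital_projections <- function(scf, pbasis, occ_threshold = 1e-6) {
  mol <- scf$molecule
  pfun <- build_projection_functions(mol, pbasis)
  meta <- attr(pfun, "meta")
  s_cross <- .ints_overlap(pack_basis(pfun), pack_basis(scf$basis))
  occ_sel <- which(scf$occupations > occ_threshold)
  if (ncol(s_cross) != nrow(scf$mo_coefficients))
    stop("AO/MO dimension mismatch")
  P <- s_cross %*% scf$mo_coefficients[, occ_sel, drop = FALSE]
  blocks <- list()
  for (at in seq_len(nrow(mol$coords))) {
    ab <- list()
    for (sh in seq_len(nrow(pbasis$shells))) {
      rows <- which(meta[, "atom"] == at & meta[, "shell"] == sh)
      ab[[sh]] <- P[rows, , drop = FALSE]
    }
    blocks[[at]] <- ab
  }
  structure(list(blocks = blocks, occupations = scf$occupations[occ_sel],
                 pbasis = pbasis, elements = mol$elements),
            class = "projection_coefficients")
}

#' Assemble local density matrices from orbital projections
#'
#' For each atom and shell, forms the occupation-weighted outer product
#' `D = P diag(f) P^T` over the occupied orbitals (f = 2 for a closed shell;
#' set `weighted = FALSE` for the plain orbital sum).
#'
#' @param proj a `projection_coefficients` object
#' @param occupations per-orbital occupation numbers aligned with the
#'   projection columns (defaults to those recorded in `proj`)
#' @param weighted apply occupation weights (default TRUE)
#' @return `local_density_matrices`: per atom, per shell, a symmetric
#'   positive-semidefinite `(2l+1) x (2l+1)` matrix
#' @export
assemble_local_density_matrices <- function(proj, occupations = NULL,
                                            weighted = TRUE) {
  f <- if (is.null(occupations)) proj$occupations else occupations
  if (any(f < 0)) stop("negative occupations")
  ncolP <- ncol(proj$blocks[[1]][[1]])
  if (length(f) != ncolP)
    stop("occupation vector length (", length(f),
         ") does not match projection columns (", ncolP, ")")
  w <- if (weighted) f else rep(1, length(f))
  blocks <- lapply(proj$blocks, function(ab) {
    lapply(ab, function(P) {
      D <- P %*% (w * t(P))
      (D + t(D)) / 2
    })
  })
  structure(list(blocks = blocks, pbasis = proj$pbasis,
                 elements = proj$elements),
            class = "local_density_matrices")
}

#' Eigenvalue descriptors of the local density matrices
#'
#' Extracts, per atom and shell, the eigenvalues of the local density-matrix
#' block, sorted descending within the shell, and concatenates them in the
#' deterministic shell order of the projection basis.  Eigenvalues are
#' invariant under rotations of the molecule, which act as orthogonal mixings
#' of the magnetic components.
#'
#' @param ldm a `local_density_matrices` object
#' @param sym_tol maximum allowed asymmetry of a block
#' @return `descriptor_set`: matrix `n_atoms x descriptor_length` plus element
#'   labels
#' @export
eigen_descriptors <- function(ldm, sym_tol = 1e-8) {
  desc <- t(vapply(ldm$blocks, function(ab) {
    unlist(lapply(ab, function(D) {
      if (max(abs(D - t(D))) > sym_tol)
        stop("local density-matrix block is not symmetric")
      sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
           decreasing = TRUE)
    }))
  }, numeric(ldm$pbasis$descriptor_length)))
  desc <- matrix(desc, nrow = length(ldm$blocks))
  structure(list(descriptors = desc, elements = ldm$elements,
                 pbasis_spec = ldm$pbasis$spec),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %d atoms x %d descriptors\n",
              nrow(x$descriptors), ncol(x$descriptors)))
  invisible(x)
}

#' Featurize a molecule
#'
#' The full feature pipeline: baseline SCF, orbital projections, local density
#' matrices, eigenvalue descriptors.  Returns the per-atom descriptors
#' together with the baseline total energy `E_L`.
#'
#' @inheritParams run_baseline
#' @param pbasis a [build_projection_basis()] object
#' @param weighted occupation-weight the density matrices (default TRUE)
#' @return list with `descriptors` (a `descriptor_set`) and `energy_baseline`
#'   (Hartree)
#' @export
featurize <- function(mol, method = "hf", ao_basis = "sto-3g",
                      pbasis = build_projection_basis(), weighted = TRUE) {
  scf <- run_baseline(mol, method, ao_basis)
  proj <- compute_orbital_projections(scf, pbasis)
  ldm <- assemble_local_density_matrices(proj, weighted = weighted)
  list(descriptors = eigen_descriptors(ldm),
       energy_baseline = scf$energy_baseline)
}
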