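# Restricted Hartree-Fock with DIIS convergence acceleration.

.supported_baselines <- c("hf")

#' Run the baseline electronic-structure calculation
#'
#' Solves the restricted closed-shell SCF problem for a molecule and returns
#' the converged orbitals, occupations and total energy that the descriptor
#' pipeline consumes.  The baseline supplies the low-level energy `E_L` of the
#' delta-learning decomposition `E_H = E_L + E_delta`.
#'
#' @param mol a [molecule()]; must be neutral closed-shell
#' @param method baseline method identifier; currently `"hf"`
#' @param ao_basis AO basis-set name, see [available_bases()]
#' @param conv convergence threshold on energy change and DIIS error (Hartree)
#' @param max_iter maximum SCF iterations
#' @return an `scf_result` with fields `mo_coefficients` (AO x MO),
#'   `mo_energies`, `occupations`, `ao_basis`, `method`, `energy_baseline`
#'   (Hartree), `converged`, and the integral set used
#' @export
run_baseline <- function(mol, method = "hf", ao_basis = "sto-3g",
                         conv = 1e-10, max_iter = 200) {
  method <- tolower(method)
  if (!method %in% .supported_baselines)
    stop("unknown baseline method '", method, "'; supported: ",
         paste(.supported_baselines, collapse = ", "))
  nel <- n_electrons(mol)
  if (mol$multiplicity != 1L || nel %% 2 != 0)
    stop("unsupported input: only neutral closed-shell (singlet, even ",
         "electron count) systems are handled")
  bfs <- build_ao_basis(mol, ao_basis)
  packed <- pack_basis(bfs)
  S <- .ints_overlap(packed, packed)
  Tk <- .ints_kinetic(packed)
  V <- .ints_nuclear(packed, as.numeric(atomic_numbers(mol)),
                     mol$coords * BOHR_PER_ANGSTROM)
  eri <- .ints_eri(packed)
  h <- Tk + V
  enuc <- nuclear_repulsion(mol)
  n <- nrow(S)
  nocc <- nel / 2L
  if (nocc > n) stop("AO basis too small for the electron count")

  # symmetric orthogonalization
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-8) stop("AO overlap matrix near-singular")
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)

  eri_mat <- matrix(eri, n * n, n * n)            # (munu | lambdasigma)
  eriK <- aperm(array(eri, c(n, n, n, n)), c(1, 3, 2, 4))
  eriK_mat <- matrix(eriK, n * n, n * n)          # (mulambda | nusigma)

  fock_build <- function(D) {
    J <- matrix(eri_mat %*% as.vector(D), n, n)
    K <- matrix(eriK_mat %*% as.vector(D), n, n)
    h + J - 0.5 * K
  }

  # diagonalize in the orthonormal basis, ascending orbital energies
  solve_fock <- function(F) {
    Fp <- t(X) %*% F %*% X
    ef <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ef$values)
    list(C = X %*% ef$vectors[, ord, drop = FALSE], eps = ef$values[ord])
  }

  sol <- solve_fock(h)
  C <- sol$C
  D <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  e_old <- Inf
  converged <- FALSE
  err_list <- list(); fock_list <- list()
  iter <- 0
  for (iter in seq_len(max_iter)) {
    F <- fock_build(D)
    e_elec <- 0.5 * sum(D * (h + F))
    # DIIS on the orbital-gradient residual FDS - SDF
    err <- F %*% D %*% S - S %*% D %*% F
    err_list[[length(err_list) + 1]] <- as.vector(err)
    fock_list[[length(fock_list) + 1]] <- F
    if (length(err_list) > 8) { err_list <- err_list[-1]; fock_list <- fock_list[-1] }
    m <- length(err_list)
    if (m >= 2) {
      B <- matrix(-1, m + 1, m + 1); B[m + 1, m + 1] <- 0
      for (a in seq_len(m)) for (b in seq_len(m))
        B[a, b] <- sum(err_list[[a]] * err_list[[b]])
      rhs <- c(rep(0, m), -1)
      cw <- tryCatch(solve(B, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(cw)) {
        F <- Reduce(`+`, Map(`*`, fock_list, cw))
      }
    }
    sol <- solve_fock(F)
    C <- sol$C
    D_new <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    de <- abs(e_elec - e_old)
    derr <- max(abs(err))
    e_old <- e_elec
    D <- D_new
    # tight orbital-gradient criterion: descriptors inherit MO accuracy
    if (de < conv && derr < 1e-8) { converged <- TRUE; break }
  }
  if (!converged)
    stop("SCF failed to converge in ", max_iter, " iterations (dE=",
         format(de, digits = 3), ", |FDS-SDF|=", format(derr, digits = 3), ")")

  F <- fock_build(D)
  sol <- solve_fock(F)
  e_elec <- 0.5 * sum(D * (h + F))
  occ <- c(rep(2, nocc), rep(0, n - nocc))
  structure(list(
    mo_coefficients = sol$C, mo_energies = sol$eps, occupations = occ,
    ao_basis = tolower(ao_basis), method = method,
    energy_baseline = e_elec + enuc, converged = TRUE, n_iter = iter,
    e_nuclear = enuc,
    ints = list(S = S, h = h, eri = array(eri, c(n, n, n, n))),
    basis = bfs, molecule = mol), class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("<scf_result> %s/%s  E = %.10f Ha  (%d AOs, %d iterations)\n",
              toupper(x$method), x$ao_basis, x$energy_baseline,
              length(x$mo_energies), x$n_iter))
  invisible(x)
}
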