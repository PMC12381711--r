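# Independent oracles used to validate the engine and descriptor pipeline.
# These deliberately use different algorithms from the package code paths:
# - Obara-Saika recursion for Gaussian overlaps (package uses McMurchie-Davidson)
# - determinant-enumeration FCI with Slater-Condon rules (package uses CCSD(T))
# - naive loop-based tensor contractions (package uses reshaped matrix products)

# ---------------------------------------------------------------------------
# Obara-Saika 1D overlap recursion
os_overlap_1d <- function(i, j, a, b, Ax, Bx) {
  p <- a + b
  mu <- a * b / p
  Px <- (a * Ax + b * Bx) / p
  S <- matrix(0, i + 2, j + 2)  # 1-based with padding
  S[1, 1] <- sqrt(pi / p) * exp(-mu * (Ax - Bx)^2)
  for (ii in 0:i) for (jj in 0:j) {
    if (ii == 0 && jj == 0) next
    if (ii > 0) {
      val <- (Px - Ax) * S[ii, jj + 1]
      if (ii > 1) val <- val + (ii - 1) / (2 * p) * S[ii - 1, jj + 1]
      if (jj > 0) val <- val + jj / (2 * p) * S[ii, jj]
      S[ii + 1, jj + 1] <- val
    } else {
      val <- (Px - Bx) * S[1, jj]
      if (jj > 1) val <- val + (jj - 1) / (2 * p) * S[1, jj - 1]
      S[1, jj + 1] <- val
    }
  }
  S[i + 1, j + 1]
}

# overlap of two generalized contracted Cartesian Gaussians given in the
# package's internal basis-function representation (centres already in bohr)
os_overlap_bf <- function(bf1, bf2) {
  s <- 0
  for (t1 in seq_along(bf1$alpha)) for (t2 in seq_along(bf2$alpha)) {
    a <- bf1$alpha[t1]; b <- bf2$alpha[t2]
    m1 <- bf1$mono[t1, ]; m2 <- bf2$mono[t2, ]
    s <- s + bf1$coef[t1] * bf2$coef[t2] *
      os_overlap_1d(m1[1], m2[1], a, b, bf1$center[1], bf2$center[1]) *
      os_overlap_1d(m1[2], m2[2], a, b, bf1$center[2], bf2$center[2]) *
      os_overlap_1d(m1[3], m2[3], a, b, bf1$center[3], bf2$center[3])
  }
  s
}

os_overlap_matrix <- function(bfsA, bfsB) {
  out <- matrix(0, length(bfsA), length(bfsB))
  for (i in seq_along(bfsA)) for (j in seq_along(bfsB))
    out[i, j] <- os_overlap_bf(bfsA[[i]], bfsB[[j]])
  out
}

# ---------------------------------------------------------------------------
# naive loop-based MO transformation (independent of the package's reshaping)
mo_eri_loops <- function(scf) {
  C <- scf$mo_coefficients
  n <- nrow(C)
  e <- scf$ints$eri
  # one index at a time, plain loops over target index
  for (pass in 1:4) {
    enew <- array(0, c(n, n, n, n))
    for (p in seq_len(n)) {
      acc <- array(0, c(n, n, n))
      for (mu in seq_len(n)) acc <- acc + C[mu, p] * e[mu, , , ]
      enew[p, , , ] <- acc
    }
    e <- aperm(enew, c(2, 3, 4, 1))
  }
  e
}

# ---------------------------------------------------------------------------
# determinant-enumeration FCI (exact diagonalization in the full CI space)
#
# Spin orbitals are indexed 2p-1 (alpha on spatial p) and 2p (beta).  The
# Hamiltonian is assembled with Slater-Condon rules and dense-diagonalized.

fci_energy <- function(scf) {
  C <- scf$mo_coefficients
  n <- nrow(C)
  h_mo <- t(C) %*% scf$ints$h %*% C
  eri_mo <- mo_eri_loops(scf)        # chemists' (pq|rs), spatial
  nel <- sum(scf$occupations)
  na <- nel / 2; nb <- nel / 2
  nso <- 2 * n
  sp_spat <- ceiling(seq_len(nso) / 2)
  sp_spin <- seq_len(nso) %% 2

  h_so <- function(p, q) {
    if (sp_spin[p] != sp_spin[q]) return(0)
    h_mo[sp_spat[p], sp_spat[q]]
  }
  # antisymmetrized <pq||rs> from spatial chemists' integrals
  w_so <- function(p, q, r, s) {
    coul <- 0; exch <- 0
    if (sp_spin[p] == sp_spin[r] && sp_spin[q] == sp_spin[s])
      coul <- eri_mo[sp_spat[p], sp_spat[r], sp_spat[q], sp_spat[s]]
    if (sp_spin[p] == sp_spin[s] && sp_spin[q] == sp_spin[r])
      exch <- eri_mo[sp_spat[p], sp_spat[s], sp_spat[q], sp_spat[r]]
    coul - exch
  }

  astr <- utils::combn(n, na, simplify = FALSE)
  bstr <- utils::combn(n, nb, simplify = FALSE)
  dets <- list()
  for (A in astr) for (B in bstr)
    dets[[length(dets) + 1]] <- sort(c(2 * A - 1, 2 * B))
  nd <- length(dets)

  inversions <- function(x) {
    inv <- 0
    for (i in seq_along(x)) inv <- inv + sum(x[seq_len(i - 1)] > x[i])
    inv
  }
  # phase of aligning det A (with holes replaced by particles in place) to
  # canonical sorted order
  sc_phase <- function(A, holes, parts) {
    A2 <- A
    for (k in seq_along(holes)) A2[A2 == holes[k]] <- parts[k]
    if (inversions(A2) %% 2 == 0) 1 else -1
  }

  H <- matrix(0, nd, nd)
  for (I in seq_len(nd)) {
    DI <- dets[[I]]
    for (J in I:nd) {
      DJ <- dets[[J]]
      holes <- setdiff(DI, DJ)
      parts <- setdiff(DJ, DI)
      nex <- length(holes)
      val <- 0
      if (nex == 0) {
        for (p in DI) val <- val + h_so(p, p)
        for (p in DI) for (q in DI) val <- val + 0.5 * w_so(p, q, p, q)
      } else if (nex == 1) {
        common <- intersect(DI, DJ)
        val <- h_so(holes, parts)
        for (q in common) val <- val + w_so(holes, q, parts, q)
        val <- val * sc_phase(DI, holes, parts)
      } else if (nex == 2) {
        val <- w_so(holes[1], holes[2], parts[1], parts[2]) *
          sc_phase(DI, holes, parts)
      }
      H[I, J] <- val
      H[J, I] <- val
    }
  }
  e0 <- min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  e0 + deltaqc:::nuclear_repulsion(scf$molecule)
}
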