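# Spin-orbital closed-shell CCSD with perturbative triples, used as the
# desk-scale high-level reference that supplies E_H labels.  Amplitude
# equations follow the standard spin-orbital intermediate formulation
# (one-/two-particle intermediates F and W, antisymmetrized integrals in
# physicists' notation).

# MO transformation of the two-electron integrals, chemists' (pq|rs)
mo_integrals <- function(scf) {
  C <- scf$mo_coefficients
  n <- nrow(C)
  e <- scf$ints$eri
  for (k in 1:4) {
    # transform leading index, then rotate axes so each index is hit once
    m <- matrix(e, n, n^3)
    e <- aperm(array(crossprod(C, m), c(n, n, n, n)), c(2, 3, 4, 1))
  }
  h_mo <- crossprod(C, scf$ints$h %*% C)
  list(eri = e, h = h_mo, eps = scf$mo_energies,
       nocc = sum(scf$occupations > 1e-6))
}

# antisymmetrized spin-orbital integrals <pq||rs> (physicists' notation);
# spin orbitals ordered (1a, 1b, 2a, 2b, ...) so the first n_electron
# spin orbitals are the occupied ones under aufbau filling
spin_orbital_ints <- function(mo) {
  n <- dim(mo$eri)[1]
  nso <- 2L * n
  spat <- ceiling(seq_len(nso) / 2)
  spin <- seq_len(nso) %% 2
  same <- outer(spin, spin, "==") * 1.0
  G <- mo$eri[spat, spat, spat, spat]        # [p,r,q,s] = (pr|qs)
  M <- array(same %o% same, c(nso, nso, nso, nso))
  coul <- aperm(G * M, c(1, 3, 2, 4))        # <pq|rs> delta terms
  exch <- aperm(G * M, c(1, 3, 4, 2))        # <pq|sr>
  list(ints = coul - exch, eps = mo$eps[spat], nso = nso)
}

#' Run the high-level reference calculation
#'
#' Computes a coupled-cluster singles-and-doubles energy with a perturbative
#' triples correction, CCSD(T), on top of restricted Hartree-Fock in the given
#' AO basis.  This supplies the high-level total energy `E_H` whose difference
#' from the baseline defines the training label.  Intended for small systems
#' only; a heavy-atom guard refuses inputs that are not desk-scale.
#'
#' @param mol a [molecule()]
#' @param ao_basis AO basis name
#' @param triples include the perturbative (T) correction (default TRUE)
#' @param max_heavy_atoms guard on the number of non-hydrogen atoms
#' @param conv amplitude-equation convergence threshold (Hartree)
#' @param max_iter maximum CC iterations
#' @return a `reference_energy` with `energy_high` (Hartree), `method_label`,
#'   plus the HF, CCSD-correlation and (T) components
#' @export
run_reference <- function(mol, ao_basis = "sto-3g", triples = TRUE,
                          max_heavy_atoms = 6, conv = 1e-9, max_iter = 150) {
  n_heavy <- sum(mol$elements != "H")
  if (n_heavy > max_heavy_atoms)
    stop("system too large for the desk-scale reference (", n_heavy,
         " heavy atoms > guard ", max_heavy_atoms, ")")
  scf <- run_baseline(mol, "hf", ao_basis)
  cc <- ccsd_from_scf(scf, triples = triples, conv = conv,
                      max_iter = max_iter)
  structure(list(
    energy_high = scf$energy_baseline + cc$e_corr + cc$e_t,
    method_label = paste0(if (triples) "ccsd(t)" else "ccsd", "/",
                          scf$ao_basis),
    energy_hf = scf$energy_baseline,
    e_corr_ccsd = cc$e_corr, e_triples = cc$e_t,
    converged = cc$converged, n_iter = cc$n_iter), class = "reference_energy")
}

#' @export
print.reference_energy <- function(x, ...) {
  cat(sprintf("<reference_energy> %s  E = %.10f Ha (corr %.6f, (T) %.6f)\n",
              x$method_label, x$energy_high, x$e_corr_ccsd, x$e_triples))
  invisible(x)
}

ccsd_from_scf <- function(scf, triples = TRUE, conv = 1e-9, max_iter = 150) {
  mo <- mo_integrals(scf)
  so <- spin_orbital_ints(mo)
  W <- so$ints
  eps <- so$eps
  nso <- so$nso
  no <- 2L * mo$nocc
  nv <- nso - no
  if (nv == 0)
    return(list(e_corr = 0, e_t = 0, converged = TRUE, n_iter = 0))
  o <- seq_len(no)
  v <- no + seq_len(nv)
  eo <- eps[o]; ev <- eps[v]

  Dia <- outer(eo, ev, "-")                                  # no x nv
  Dijab <- array(0, c(no, no, nv, nv))
  for (i in seq_len(no)) for (j in seq_len(no))
    Dijab[i, j, , ] <- eo[i] + eo[j] - outer(ev, ev, "+")

  Woovv <- W[o, o, v, v, drop = FALSE]
  t1 <- matrix(0, no, nv)
  t2 <- Woovv / Dijab
  e_mp2 <- 0.25 * sum(Woovv * t2)

  corr_energy <- function(t1, t2) {
    0.25 * sum(Woovv * t2) +
      0.5 * sum(einsum("ijab,ia->jb", Woovv, t1) * t1)
  }

  # DIIS storage
  t_hist <- list(); r_hist <- list()
  e_old <- e_mp2
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    tau_t <- t2 + 0.5 * (einsum("ia,jb->ijab", t1, t1) -
                         einsum("ib,ja->ijab", t1, t1))
    tau <- t2 + einsum("ia,jb->ijab", t1, t1) -
                einsum("ib,ja->ijab", t1, t1)

    Fae <- -0.5 * einsum("mnaf,mnef->ae", tau_t, Woovv) +
      einsum("mf,mafe->ae", t1, W[o, v, v, v, drop = FALSE])
    Fmi <- 0.5 * einsum("inef,mnef->mi", tau_t, Woovv) +
      einsum("ne,mnie->mi", t1, W[o, o, o, v, drop = FALSE])
    Fme <- einsum("nf,mnef->me", t1, Woovv)

    Wmnij <- W[o, o, o, o, drop = FALSE] +
      0.25 * einsum("ijef,mnef->mnij", tau, Woovv)
    Pje <- einsum("je,mnie->mnij", t1, W[o, o, o, v, drop = FALSE])
    Wmnij <- Wmnij + Pje - aperm(Pje, c(1, 2, 4, 3))

    Wabef <- W[v, v, v, v, drop = FALSE] +
      0.25 * einsum("mnab,mnef->abef", tau, Woovv)
    Pmb <- einsum("mb,amef->abef", t1, W[v, o, v, v, drop = FALSE])
    Wabef <- Wabef - Pmb + aperm(Pmb, c(2, 1, 3, 4))

    Wmbej <- W[o, v, v, o, drop = FALSE] +
      einsum("jf,mbef->mbej", t1, W[o, v, v, v, drop = FALSE]) -
      einsum("nb,mnej->mbej", t1, W[o, o, v, o, drop = FALSE]) -
      einsum("jnfb,mnef->mbej", 0.5 * t2 + einsum("jf,nb->jnfb", t1, t1),
             Woovv)

    # T1 residual
    rhs1 <- einsum("ie,ae->ia", t1, Fae) -
      einsum("ma,mi->ia", t1, Fmi) +
      einsum("imae,me->ia", t2, Fme) -
      einsum("nf,naif->ia", t1, W[o, v, o, v, drop = FALSE]) -
      0.5 * einsum("imef,maef->ia", t2, W[o, v, v, v, drop = FALSE]) -
      0.5 * einsum("mnae,nmei->ia", t2, W[o, o, v, o, drop = FALSE])
    t1_new <- rhs1 / Dia

    # T2 residual
    FbeX <- Fae - 0.5 * einsum("mb,me->be", t1, Fme)
    P1 <- einsum("ijae,be->ijab", t2, FbeX)
    FmjX <- Fmi + 0.5 * einsum("je,me->mj", t1, Fme)
    P2 <- einsum("imab,mj->ijab", t2, FmjX)
    rhs2 <- Woovv
    rhs2 <- rhs2 + P1 - aperm(P1, c(1, 2, 4, 3))
    rhs2 <- rhs2 - P2 + aperm(P2, c(2, 1, 3, 4))
    rhs2 <- rhs2 + 0.5 * einsum("mnab,mnij->ijab", tau, Wmnij)
    rhs2 <- rhs2 + 0.5 * einsum("ijef,abef->ijab", tau, Wabef)
    P3 <- einsum("imae,mbej->ijab", t2, Wmbej) -
      einsum("iema,mbej->ijab",
             array(einsum("ie,ma->iema", t1, t1), c(no, nv, no, nv)),
             W[o, v, v, o, drop = FALSE])
    P3 <- P3 - aperm(P3, c(2, 1, 3, 4)) - aperm(P3, c(1, 2, 4, 3)) +
      aperm(P3, c(2, 1, 4, 3))
    rhs2 <- rhs2 + P3
    P5 <- einsum("ie,abej->ijab", t1, W[v, v, v, o, drop = FALSE])
    rhs2 <- rhs2 + P5 - aperm(P5, c(2, 1, 3, 4))
    P6 <- einsum("ma,mbij->ijab", t1, W[o, v, o, o, drop = FALSE])
    rhs2 <- rhs2 - P6 + aperm(P6, c(1, 2, 4, 3))
    t2_new <- rhs2 / Dijab

    # DIIS over stacked amplitudes
    tvec <- c(t1_new, t2_new)
    rvec <- c(t1_new - t1, t2_new - t2)
    t_hist[[length(t_hist) + 1]] <- tvec
    r_hist[[length(r_hist) + 1]] <- rvec
    if (length(t_hist) > 6) { t_hist <- t_hist[-1]; r_hist <- r_hist[-1] }
    m <- length(t_hist)
    if (m >= 2) {
      B <- matrix(-1, m + 1, m + 1); B[m + 1, m + 1] <- 0
      for (a in seq_len(m)) for (b in seq_len(m))
        B[a, b] <- sum(r_hist[[a]] * r_hist[[b]])
      cw <- tryCatch(solve(B, c(rep(0, m), -1))[seq_len(m)],
                     error = function(e) NULL)
      if (!is.null(cw)) {
        tvec <- Reduce(`+`, Map(`*`, t_hist, cw))
      }
    }
    t1 <- matrix(tvec[seq_len(no * nv)], no, nv)
    t2 <- array(tvec[-seq_len(no * nv)], c(no, no, nv, nv))

    e_new <- corr_energy(t1, t2)
    rms <- sqrt(mean(rvec^2))
    if (abs(e_new - e_old) < conv && rms < sqrt(conv) * 10) {
      e_old <- e_new; converged <- TRUE; break
    }
    e_old <- e_new
  }
  if (!converged)
    stop("CCSD amplitude equations failed to converge in ", max_iter,
         " iterations")
  e_t <- 0
  if (triples && no >= 3 && nv >= 3) {
    e_t <- triples_correction(W, t1, t2, eo, ev, o, v)
  }
  list(e_corr = e_old, e_t = e_t, converged = converged, n_iter = iter,
       e_mp2 = e_mp2)
}

# perturbative (T) energy via full o^3 v^3 arrays (desk-scale systems only)
triples_correction <- function(W, t1, t2, eo, ev, o, v) {
  no <- length(eo); nv <- length(ev)
  # denominator D_ijkabc
  Dijk <- array(outer(outer(eo, eo, "+"), eo, "+"), c(no, no, no))
  Dabc <- array(outer(outer(ev, ev, "+"), ev, "+"), c(nv, nv, nv))
  D <- outer(Dijk, -Dabc, "+")

  P_ijk_abc <- function(X) {
    # P(i/jk) P(a/bc) applied to X_ijkabc:
    # (1 - P_ij - P_ik)(1 - P_ab - P_ac) X
    Y <- X - aperm(X, c(2, 1, 3, 4, 5, 6)) - aperm(X, c(3, 2, 1, 4, 5, 6))
    Y - aperm(Y, c(1, 2, 3, 5, 4, 6)) - aperm(Y, c(1, 2, 3, 6, 5, 4))
  }

  # disconnected: t1_ia <jk||bc>
  Xd <- einsum("ia,jkbc->ijkabc", t1, W[o, o, v, v, drop = FALSE])
  t3d_num <- P_ijk_abc(Xd)
  # connected: sum_e t2_jkae <ei||bc> - sum_m t2_imbc <ma||jk>
  Xc <- einsum("jkae,eibc->jkaibc", t2, W[v, o, v, v, drop = FALSE])
  Xc <- aperm(Xc, c(4, 1, 2, 3, 5, 6))          # -> ijkabc
  Xm <- einsum("imbc,majk->ibcajk", t2, W[o, v, o, o, drop = FALSE])
  Xm <- aperm(Xm, c(1, 5, 6, 4, 2, 3))          # -> ijkabc
  t3c_num <- P_ijk_abc(Xc - Xm)

  sum(t3c_num * (t3c_num + t3d_num) / D) / 36
}
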