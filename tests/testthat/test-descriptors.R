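# Local density-matrix eigen-descriptors.

test_that("projection basis enumerates shells and descriptor lengths", {
  pb <- build_projection_basis(n_radial = c(2, 1), l_max = 1, base = 0.5,
                               ratio = 2)
  expect_equal(pb$descriptor_length, 2 * 1 + 1 * 3)
  pb2 <- build_projection_basis(n_radial = 3, l_max = 0, base = 0.5,
                                ratio = 2)
  expect_equal(pb2$shells$exponent, c(0.5, 1.0, 2.0))
  pb3 <- build_projection_basis(n_radial = 2, l_max = 2, base = 0.3,
                                ratio = 3)
  expect_equal(pb3$descriptor_length, 2 * 1 + 2 * 3 + 2 * 5)
  # deterministic ordering: ascending n within ascending l
  expect_true(!is.unsorted(pb3$shells$l))
  expect_error(build_projection_basis(base = -1), "base")
  expect_error(build_projection_basis(ratio = 1), "ratio")
})

test_that("a projection shell matching a lone AO gives projection 1", {
  # He 6-31G outer s function is a single normalized s primitive; an s
  # projection shell with the same exponent is the identical function
  he <- molecule("He", matrix(0, 1, 3))
  zeta <- 0.2979640
  pb <- build_projection_basis(n_radial = 1, l_max = 0, base = zeta,
                               ratio = 2)
  pfun <- deltaqc:::build_projection_functions(he, pb)
  bfs <- deltaqc:::build_ao_basis(he, "6-31g")
  Sx <- deltaqc:::.ints_overlap(deltaqc:::pack_basis(pfun),
                                deltaqc:::pack_basis(bfs))
  expect_equal(Sx[1, 2], 1, tolerance = 1e-9)  # AO 2 is that primitive
})

test_that("orbital projections are translationally covariant", {
  h2o <- water()
  pb <- build_projection_basis()
  p1 <- compute_orbital_projections(run_baseline(h2o), pb)
  p2 <- compute_orbital_projections(
    run_baseline(translate_molecule(h2o, c(3.3, -1.2, 0.7))), pb)
  for (at in seq_along(p1$blocks)) for (sh in seq_along(p1$blocks[[at]])) {
    expect_lt(max(abs(abs(p1$blocks[[at]][[sh]]) -
                        abs(p2$blocks[[at]][[sh]]))), 1e-8)
  }
})

test_that("local density matrices equal the brute-force weighted outer product", {
  scf <- cached_h2o_scf()
  proj <- compute_orbital_projections(scf, build_projection_basis())
  ldm <- assemble_local_density_matrices(proj)
  f <- proj$occupations
  for (at in seq_along(proj$blocks)) for (sh in seq_along(proj$blocks[[at]])) {
    P <- proj$blocks[[at]][[sh]]
    D_ref <- matrix(0, nrow(P), nrow(P))
    for (i in seq_along(f))
      D_ref <- D_ref + f[i] * P[, i] %o% P[, i]
    D <- ldm$blocks[[at]][[sh]]
    expect_lt(max(abs(D - D_ref)), 1e-10)
    expect_lt(max(abs(D - t(D))), 1e-10)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("single-orbital single-shell density matrix reduces to 2c^2", {
  # one occupied orbital with occupation 2 and coefficient c on one s shell
  proj <- structure(list(
    blocks = list(list(matrix(0.37, 1, 1))), occupations = 2,
    pbasis = build_projection_basis(n_radial = 1, l_max = 0),
    elements = "H"), class = "projection_coefficients")
  ldm <- assemble_local_density_matrices(proj)
  expect_equal(ldm$blocks[[1]][[1]][1, 1], 2 * 0.37^2)
  # an orbital orthogonal to every shell on the atom gives zero blocks
  proj$blocks <- list(list(matrix(0, 1, 1)))
  expect_equal(assemble_local_density_matrices(proj)$blocks[[1]][[1]][1, 1],
               0)
  expect_error(assemble_local_density_matrices(proj, occupations = -1),
               "negative")
})

test_that("eigen descriptors are sorted, PSD, and match a char-poly oracle", {
  set.seed(21)
  # random symmetric PSD 5x5 block through a fake local-density container
  A <- matrix(rnorm(25), 5)
  D <- crossprod(A) / 5
  pb <- build_projection_basis(n_radial = c(1, 1, 1), l_max = 2)
  ldm <- structure(list(
    blocks = list(list(matrix(2, 1, 1), diag(0, 3), D)),
    pbasis = pb, elements = "O"), class = "local_density_matrices")
  ds <- eigen_descriptors(ldm)
  expect_equal(ncol(ds$descriptors), 9)
  expect_equal(ds$descriptors[1, 2:4], c(0, 0, 0))   # zero block slice
  lam <- ds$descriptors[1, 5:9]
  expect_true(all(diff(lam) <= 1e-12))               # descending in block
  # characteristic-polynomial oracle: fit the quintic det(D - x I) exactly
  # through 6 points, take its roots
  xs <- seq(-1, 3, length.out = 6)
  dets <- vapply(xs, function(x) det(D - x * diag(5)), 0)
  cf <- solve(outer(xs, 0:5, "^"), dets)
  roots <- sort(Re(polyroot(cf)), decreasing = TRUE)
  expect_equal(lam, roots, tolerance = 1e-9)
  # non-symmetric block rejected
  bad <- ldm; bad$blocks[[1]][[3]][1, 2] <- bad$blocks[[1]][[3]][1, 2] + 1e-4
  expect_error(eigen_descriptors(bad), "not symmetric")
})

test_that("descriptors are rotation and translation invariant", {
  pb <- build_projection_basis()
  set.seed(33)
  for (nm in c("H2O", "NH3")) {
    mol <- fixture_templates()[[nm]]
    d0 <- featurize(mol, "hf", "sto-3g", pb)$descriptors$descriptors
    for (k in 1:4) {
      m <- translate_molecule(rotate_molecule(mol, random_rotation()),
                              runif(3, -4, 4))
      d1 <- featurize(m, "hf", "sto-3g", pb)$descriptors$descriptors
      expect_lt(max(abs(d1 - d0)), 1e-7)
    }
  }
})

test_that("atom permutation permutes descriptor rows identically", {
  pb <- build_projection_basis()
  mol <- fixture_templates()$NH3
  d0 <- featurize(mol, "hf", "sto-3g", pb)$descriptors$descriptors
  perm <- c(3, 1, 4, 2)
  molp <- molecule(mol$elements[perm], mol$coords[perm, ],
                   mol$charge, mol$multiplicity)
  dp <- featurize(molp, "hf", "sto-3g", pb)$descriptors$descriptors
  expect_lt(max(abs(dp - d0[perm, ])), 1e-8)
})

test_that("featurization is deterministic and carries the baseline energy", {
  f1 <- cached_h2o_featurization()
  f2 <- featurize(water(), "hf", "sto-3g", build_projection_basis())
  expect_identical(f1$descriptors$descriptors, f2$descriptors$descriptors)
  expect_identical(f1$energy_baseline, f2$energy_baseline)
  expect_equal(f1$energy_baseline, run_baseline(water())$energy_baseline)
})

test_that("full pipeline agrees with a monolithic dense-algebra oracle", {
  # independent route: Obara-Saika overlaps -> P = S C_occ -> loops for
  # f-weighted P P^T -> base eigensolver, assembled in one block of code
  pb <- build_projection_basis()
  for (nm in c("H2", "H2O")) {
    mol <- fixture_templates()[[nm]]
    scf <- run_baseline(mol)
    d_pkg <- featurize(mol, "hf", "sto-3g", pb)$descriptors$descriptors
    pfun <- deltaqc:::build_projection_functions(mol, pb)
    meta <- attr(pfun, "meta")
    S_os <- os_overlap_matrix(pfun, scf$basis)
    occ <- which(scf$occupations > 1e-6)
    P <- S_os %*% scf$mo_coefficients[, occ, drop = FALSE]
    d_ora <- matrix(0, nrow(mol$coords), pb$descriptor_length)
    for (at in seq_len(nrow(mol$coords))) {
      vals <- c()
      for (sh in seq_len(nrow(pb$shells))) {
        rows <- which(meta[, "atom"] == at & meta[, "shell"] == sh)
        Pb <- P[rows, , drop = FALSE]
        D <- matrix(0, length(rows), length(rows))
        for (i in seq_along(occ))
          D <- D + scf$occupations[occ[i]] * Pb[, i] %o% Pb[, i]
        vals <- c(vals, sort(eigen(D, symmetric = TRUE)$values,
                             decreasing = TRUE))
      }
      d_ora[at, ] <- vals
    }
    expect_lt(max(abs(d_pkg - d_ora)), 1e-9)
  }
})
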