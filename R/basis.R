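# AO basis-set library and the flat Gaussian representation handed to the
# compiled integral engine.
#
# Exponents/contraction coefficients are the standard published Pople sets
# (STO-3G and 6-31G) for H, He, C, N, O.  Contraction coefficients refer to
# normalized primitives; each contracted function is renormalized numerically
# after assembly.

.sto3g_coef_1s <- c(0.15432897, 0.53532814, 0.44463454)
.sto3g_coef_2s <- c(-0.09996723, 0.39951283, 0.70115470)
.sto3g_coef_2p <- c(0.15591627, 0.60768372, 0.39195739)

.basis_library <- list(
  "sto-3g" = list(
    H = list(list(l = 0, exps = c(3.42525091, 0.62391373, 0.16885540),
                  coefs = .sto3g_coef_1s)),
    He = list(list(l = 0, exps = c(6.36242139, 1.15892300, 0.31364979),
                   coefs = .sto3g_coef_1s)),
    C = list(
      list(l = 0, exps = c(71.6168370, 13.0450960, 3.5305122),
           coefs = .sto3g_coef_1s),
      list(l = 0, exps = c(2.9412494, 0.6834831, 0.2222899),
           coefs = .sto3g_coef_2s),
      list(l = 1, exps = c(2.9412494, 0.6834831, 0.2222899),
           coefs = .sto3g_coef_2p)),
    N = list(
      list(l = 0, exps = c(99.1061690, 18.0523120, 4.8856602),
           coefs = .sto3g_coef_1s),
      list(l = 0, exps = c(3.7804559, 0.8784966, 0.2857144),
           coefs = .sto3g_coef_2s),
      list(l = 1, exps = c(3.7804559, 0.8784966, 0.2857144),
           coefs = .sto3g_coef_2p)),
    O = list(
      list(l = 0, exps = c(130.7093200, 23.8088610, 6.4436083),
           coefs = .sto3g_coef_1s),
      list(l = 0, exps = c(5.0331513, 1.1695961, 0.3803890),
           coefs = .sto3g_coef_2s),
      list(l = 1, exps = c(5.0331513, 1.1695961, 0.3803890),
           coefs = .sto3g_coef_2p))
  ),
  "6-31g" = list(
    H = list(
      list(l = 0, exps = c(18.73113696, 2.825394365, 0.6401216923),
           coefs = c(0.03349460434, 0.2347269535, 0.8137573261)),
      list(l = 0, exps = 0.1612777588, coefs = 1.0)),
    He = list(
      list(l = 0, exps = c(38.42163400, 5.778030000, 1.241774000),
           coefs = c(0.04013973935, 0.2612460970, 0.7931846246)),
      list(l = 0, exps = 0.2979640000, coefs = 1.0)),
    C = list(
      list(l = 0,
           exps = c(3047.524880, 457.3695180, 103.9486850, 29.21015530,
                    9.286662960, 3.163926960),
           coefs = c(0.001834737132, 0.01403732281, 0.06884262226,
                     0.2321844432, 0.4679413484, 0.3623119853)),
      list(l = 0, exps = c(7.868272350, 1.881288540, 0.5442492580),
           coefs = c(-0.1193324198, -0.1608541517, 1.143456438)),
      list(l = 1, exps = c(7.868272350, 1.881288540, 0.5442492580),
           coefs = c(0.06899906659, 0.3164239610, 0.7443082909)),
      list(l = 0, exps = 0.1687144782, coefs = 1.0),
      list(l = 1, exps = 0.1687144782, coefs = 1.0)),
    N = list(
      list(l = 0,
           exps = c(4173.511460, 627.4579110, 142.9020930, 40.23432930,
                    12.82021290, 4.390437010),
           coefs = c(0.001834772160, 0.01399462700, 0.06858655181,
                     0.2322408730, 0.4690699481, 0.3604551991)),
      list(l = 0, exps = c(11.62636186, 2.716279807, 0.7722183966),
           coefs = c(-0.1149611817, -0.1691174786, 1.145851947)),
      list(l = 1, exps = c(11.62636186, 2.716279807, 0.7722183966),
           coefs = c(0.06757974388, 0.3239072959, 0.7408951398)),
      list(l = 0, exps = 0.2120314975, coefs = 1.0),
      list(l = 1, exps = 0.2120314975, coefs = 1.0)),
    O = list(
      list(l = 0,
           exps = c(5484.671660, 825.2349460, 188.0469580, 52.96450000,
                    16.89757040, 5.799635340),
           coefs = c(0.001831074430, 0.01395017220, 0.06844507810,
                     0.2327143360, 0.4701928980, 0.3585208530)),
      list(l = 0, exps = c(15.53961625, 3.599933586, 1.013761750),
           coefs = c(-0.1107775495, -0.1480262627, 1.130767015)),
      list(l = 1, exps = c(15.53961625, 3.599933586, 1.013761750),
           coefs = c(0.07087426823, 0.3397528391, 0.7271585773)),
      list(l = 0, exps = 0.2700058226, coefs = 1.0),
      list(l = 1, exps = 0.2700058226, coefs = 1.0))
  )
)

#' Names of the AO basis sets shipped with the package
#' @return character vector
#' @export
available_bases <- function() names(.basis_library)

# Cartesian monomials spanning angular momentum l, fixed ordering
cart_monomials <- function(l) {
  out <- list()
  for (i in seq(l, 0)) for (j in seq(l - i, 0)) {
    out[[length(out) + 1]] <- c(i, j, l - i - j)
  }
  do.call(rbind, out)
}

# normalization constant of a primitive Cartesian Gaussian x^i y^j z^k e^(-a r^2)
prim_norm <- function(a, mono) {
  ijk <- as.numeric(mono)
  dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))
  (2 * a / pi)^0.75 * sqrt((4 * a)^sum(ijk) /
    (dfact(2 * ijk[1] - 1) * dfact(2 * ijk[2] - 1) * dfact(2 * ijk[3] - 1)))
}

# Build the contracted Cartesian AO basis for a molecule.  Each function is a
# list(center [bohr], alpha, coef, mono [nterm x 3], atom, l).
build_ao_basis <- function(mol, basis_name) {
  basis_name <- tolower(basis_name)
  lib <- .basis_library[[basis_name]]
  if (is.null(lib))
    stop("unknown AO basis '", basis_name, "'; available: ",
         paste(available_bases(), collapse = ", "))
  missing_el <- setdiff(unique(mol$elements), names(lib))
  if (length(missing_el))
    stop("basis '", basis_name, "' lacks element(s): ",
         paste(missing_el, collapse = ", "))
  coords_bohr <- mol$coords * BOHR_PER_ANGSTROM
  bfs <- list()
  for (at in seq_along(mol$elements)) {
    for (shell in lib[[mol$elements[at]]]) {
      monos <- cart_monomials(shell$l)
      for (m in seq_len(nrow(monos))) {
        mono <- monos[m, , drop = FALSE]
        nterm <- length(shell$exps)
        coef <- shell$coefs * vapply(shell$exps, prim_norm, 0, mono = mono)
        bfs[[length(bfs) + 1]] <- list(
          center = coords_bohr[at, ], alpha = shell$exps, coef = coef,
          mono = mono[rep(1, nterm), , drop = FALSE], atom = at, l = shell$l)
      }
    }
  }
  bfs <- normalize_basis(bfs)
  attr(bfs, "basis_name") <- basis_name
  bfs
}

# flatten a list of basis functions for the C++ engine
pack_basis <- function(bfs) {
  nterm <- vapply(bfs, function(b) length(b$alpha), 0L)
  centers <- do.call(rbind, lapply(bfs, function(b) {
    matrix(rep(b$center, length(b$alpha)), ncol = 3, byrow = TRUE)
  }))
  monos <- do.call(rbind, lapply(bfs, `[[`, "mono"))
  list(nterm = as.integer(nterm),
       cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
       alpha = unlist(lapply(bfs, `[[`, "alpha")),
       coef = unlist(lapply(bfs, `[[`, "coef")),
       li = as.integer(monos[, 1]), lj = as.integer(monos[, 2]),
       lk = as.integer(monos[, 3]))
}

# L2-normalize every function in place (exact, via the analytic self-overlap)
normalize_basis <- function(bfs) {
  s <- diag(.ints_overlap(pack_basis(bfs), pack_basis(bfs)))
  for (k in seq_along(bfs)) bfs[[k]]$coef <- bfs[[k]]$coef / sqrt(s[k])
  bfs
}

nuclear_repulsion <- function(mol) {
  z <- atomic_numbers(mol)
  xyz <- mol$coords * BOHR_PER_ANGSTROM
  e <- 0
  n <- length(z)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    e <- e + z[i] * z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  e
}
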