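#' @useDynLib deltaqc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames sd
NULL

# unit conversions used throughout: coordinates are Angstrom in files and in
# Molecule objects, bohr inside the integral engine; energies are Hartree
# internally, kcal/mol in reports.
BOHR_PER_ANGSTROM <- 1 / 0.52917721092
KCAL_PER_HARTREE <- 627.509474

.element_z <- c(H = 1, He = 2, C = 6, N = 7, O = 8)

#' Construct a molecule
#'
#' A molecule is the geometric input to every calculation: element symbols,
#' Cartesian coordinates in Angstrom, total charge and spin multiplicity.
#' Only neutral closed-shell (singlet) species are supported by the engine.
#'
#' @param elements character vector of element symbols (H, He, C, N, O)
#' @param coords numeric matrix, one row per atom, columns x, y, z in Angstrom
#' @param charge integer total charge
#' @param multiplicity spin multiplicity 2S+1; must be 1
#' @return an object of class `molecule`
#' @export
molecule <- function(elements, coords, charge = 0L, multiplicity = 1L) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) != nrow(coords))
    stop("elements and coordinate rows disagree (", length(elements),
         " vs ", nrow(coords), ")")
  unknown <- setdiff(elements, names(.element_z))
  if (length(unknown))
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (multiplicity < 1) stop("multiplicity must be a positive integer")
  structure(list(elements = as.character(elements), coords = coords,
                 charge = as.integer(charge),
                 multiplicity = as.integer(multiplicity)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms (%s), charge %d, multiplicity %d\n",
              nrow(x$coords), paste(x$elements, collapse = ""),
              x$charge, x$multiplicity))
  invisible(x)
}

n_electrons <- function(mol) {
  sum(.element_z[mol$elements]) - mol$charge
}

atomic_numbers <- function(mol) unname(.element_z[mol$elements])

#' Rigid-body transforms
#'
#' Utilities used to probe the rotational/translational invariance of
#' descriptors and energies.
#'
#' @param mol a `molecule`
#' @param rot 3x3 proper rotation matrix
#' @param shift length-3 translation in Angstrom
#' @return transformed `molecule`
#' @export
rotate_molecule <- function(mol, rot) {
  stopifnot(all(dim(rot) == c(3, 3)))
  mol$coords <- mol$coords %*% t(rot)
  mol
}

#' @rdname rotate_molecule
#' @export
translate_molecule <- function(mol, shift) {
  mol$coords <- sweep(mol$coords, 2, shift, "+")
  mol
}

#' Random proper rotation matrix
#'
#' Uniform over SO(3) via QR decomposition of a Gaussian matrix with the
#' determinant sign fixed.
#' @return 3x3 rotation matrix with determinant +1
#' @export
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  q <- q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Read / write XYZ geometry files
#'
#' Standard XYZ dialect: atom count, comment line, then one
#' `element x y z` line per atom (Angstrom). `read_xyz` returns a single
#' molecule (the first frame).
#'
#' @param path file path
#' @param charge,multiplicity metadata attached to the molecule
#' @return `read_xyz`: a `molecule`; `write_xyz`: the path, invisibly
#' @export
read_xyz <- function(path, charge = 0L, multiplicity = 1L) {
  lines <- readLines(path)
  mol <- parse_xyz_block(lines)
  mol$charge <- as.integer(charge)
  mol$multiplicity <- as.integer(multiplicity)
  mol
}

parse_xyz_block <- function(lines) {
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2)
    stop("malformed XYZ block: bad atom count")
  rows <- lines[3:(n + 2)]
  toks <- strsplit(trimws(rows), "\\s+")
  elements <- vapply(toks, `[[`, "", 1)
  coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  molecule(elements, coords)
}

format_xyz_block <- function(mol, comment = "") {
  c(as.character(nrow(mol$coords)), comment,
    sprintf("%-2s %18.10f %18.10f %18.10f", mol$elements,
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]))
}

#' @rdname read_xyz
#' @param mol a `molecule`
#' @param comment second header line
#' @export
write_xyz <- function(mol, path, comment = "") {
  writeLines(format_xyz_block(mol, comment), path)
  invisible(path)
}

min_interatomic_distance <- function(mol) {
  if (nrow(mol$coords) < 2) return(Inf)
  min(dist(mol$coords))
}
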