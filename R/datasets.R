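# Reaction-record management, grouped dataset splits, the feature store and
# the synthetic fixture generator.
#
# Records are JSON-lines with embedded XYZ blocks: one reaction per line with
# reactant / transition-state / product roles, an optional ordered path, and
# optional per-structure energies (E_H high-level, E_L baseline) in Hartree.

#' Construct a reaction record
#'
#' @param id reaction identifier
#' @param structures named list of structures; each entry is a list with
#'   `molecule` (a [molecule()]) and optional `energy_high`, `energy_low`
#' @param roles named list mapping `reactant`, `transition_state` (optional),
#'   `product` to structure IDs
#' @param path optional ordered character vector of structure IDs along the
#'   minimum-energy path; must start at the reactant and end at the product
#' @return a `reaction_record`
#' @export
reaction_record <- function(id, structures, roles, path = NULL) {
  for (need in c("reactant", "product")) {
    if (is.null(roles[[need]]))
      stop("reaction '", id, "': missing required role '", need, "'")
  }
  refd <- unlist(c(roles, path), use.names = FALSE)
  missing_s <- setdiff(refd, names(structures))
  if (length(missing_s))
    stop("reaction '", id, "': role/path references unknown structure(s): ",
         paste(missing_s, collapse = ", "))
  if (!is.null(path)) {
    if (path[1] != roles$reactant || path[length(path)] != roles$product)
      stop("reaction '", id,
           "': path must start at the reactant and end at the product")
  }
  structure(list(id = id, structures = structures, roles = roles,
                 path = path), class = "reaction_record")
}

#' @export
print.reaction_record <- function(x, ...) {
  cat(sprintf("<reaction_record> %s: %d structures, roles [%s]%s\n",
              x$id, length(x$structures),
              paste(names(x$roles), collapse = ", "),
              if (is.null(x$path)) "" else
                sprintf(", path of %d", length(x$path))))
  invisible(x)
}

structure_ids <- function(rec) names(rec$structures)

# ---------------------------------------------------------------------------
# JSON-lines serialization

record_to_json <- function(rec) {
  st <- lapply(rec$structures, function(s) {
    out <- list(xyz = format_xyz_block(s$molecule),
                charge = s$molecule$charge,
                multiplicity = s$molecule$multiplicity)
    if (!is.null(s$energy_high)) out$energy_high <- s$energy_high
    if (!is.null(s$energy_low)) out$energy_low <- s$energy_low
    out
  })
  jsonlite::toJSON(list(id = rec$id, roles = rec$roles, path = rec$path,
                        structures = st),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

record_from_json <- function(line, lineno = NA) {
  raw <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                  error = function(e)
                    stop("records line ", lineno, ": invalid JSON (",
                         conditionMessage(e), ")"))
  structures <- lapply(raw$structures, function(s) {
    mol <- parse_xyz_block(unlist(s$xyz))
    mol$charge <- as.integer(s$charge %||% 0L)
    mol$multiplicity <- as.integer(s$multiplicity %||% 1L)
    out <- list(molecule = mol)
    if (!is.null(s$energy_high)) out$energy_high <- s$energy_high
    if (!is.null(s$energy_low)) out$energy_low <- s$energy_low
    out
  })
  path <- if (is.null(raw$path)) NULL else unlist(raw$path)
  tryCatch(
    reaction_record(raw$id, structures, raw$roles, path),
    error = function(e)
      stop("records line ", lineno, ": ", conditionMessage(e)))
}

#' Read / write reaction records (JSON-lines)
#'
#' One reaction per line, geometries embedded as XYZ blocks, energies as
#' optional fields; the round trip is lossless.
#'
#' @param records list of [reaction_record()]s
#' @param path file path
#' @return `read_records`: list of `reaction_record`s
#' @export
write_records <- function(records, path) {
  writeLines(vapply(records, function(r) as.character(record_to_json(r)),
                    ""), path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(k) record_from_json(lines[k], k))
}

# ---------------------------------------------------------------------------
# splits

#' Split reactions into train / validation / test sets
#'
#' Splitting is at reaction level: all structures of a reaction stay in the
#' same split, preventing leakage between a reaction's conformers.  Split
#' sizes are the ratios rounded to integers preserving the total (largest
#' remainders get the spare units), so 100 reactions at 8:1:1 give exactly
#' 80/10/10.
#'
#' @param records list of [reaction_record()]s
#' @param ratios length-3 positive vector summing to 1 (train, valid, test)
#' @param seed RNG seed for the shuffle
#' @return list with `train`, `valid`, `test` lists of records
#' @export
split_dataset <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three positive numbers summing to 1")
  n <- length(records)
  raw <- n * ratios
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    give <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[give] <- sizes[give] + 1
  }
  set.seed(seed)
  ord <- sample.int(n)
  idx <- split(ord, rep(c("train", "valid", "test"), times = sizes))
  list(train = records[sort(idx$train)],
       valid = records[sort(idx$valid)],
       test = records[sort(idx$test)])
}

# ---------------------------------------------------------------------------
# fixture generator

#' Equilibrium template molecules for the fixture generator
#'
#' Small closed-shell molecules (H, C, N, O) at standard experimental
#' equilibrium geometries, in Angstrom.
#' @return named list of [molecule()]s
#' @export
fixture_templates <- function() {
  list(
    H2 = molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.741))),
    H2O = {
      a <- 104.52 / 2 * pi / 180; r <- 0.9572
      molecule(c("O", "H", "H"),
               rbind(c(0, 0, 0), c(0, r * sin(a), r * cos(a)),
                     c(0, -r * sin(a), r * cos(a))))
    },
    NH3 = {
      # C3v, r(NH) 1.012 A, HNH 106.7 deg
      r <- 1.012; theta <- 106.7 * pi / 180
      # place H on a cone around z
      cosb <- cos(theta); q <- (1 - cosb) * 3 / 2   # 1 - cos(alpha_cone)
      zc <- sqrt(max(0, 1 - q)); rc <- sqrt(q)
      ang <- 2 * pi * (0:2) / 3
      molecule(c("N", "H", "H", "H"),
               rbind(c(0, 0, 0),
                     t(vapply(ang, function(p)
                       r * c(rc * cos(p), rc * sin(p), zc), numeric(3)))))
    },
    CH4 = {
      r <- 1.087 / sqrt(3)
      molecule(c("C", "H", "H", "H", "H"),
               rbind(c(0, 0, 0), c(r, r, r), c(r, -r, -r), c(-r, r, -r),
                     c(-r, -r, r)))
    },
    CO = molecule(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.128))),
    N2 = molecule(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, 1.098))),
    HCN = molecule(c("H", "C", "N"),
                   rbind(c(0, 0, -1.064), c(0, 0, 0), c(0, 0, 1.156))),
    H2CO = molecule(c("C", "O", "H", "H"),
                    rbind(c(0, 0, 0), c(0, 0, 1.205),
                          c(0, 0.943, -0.587), c(0, -0.943, -0.587)))
  )
}

perturb_molecule <- function(mol, sigma, min_dist = 0.6, max_tries = 100) {
  for (k in seq_len(max_tries)) {
    m <- mol
    m$coords <- m$coords + matrix(rnorm(length(m$coords), sd = sigma),
                                  nrow(m$coords), 3)
    if (min_interatomic_distance(m) >= min_dist) return(m)
  }
  stop("could not generate a non-overlapping perturbed geometry ",
       "(sigma too large?)")
}

#' Generate a synthetic reaction fixture set
#'
#' Emits reaction records built from equilibrium templates of small
#' closed-shell organic molecules (H, C, N, O): Gaussian coordinate
#' perturbations stand in for reactant/product geometries, and a pseudo-path
#' of `path_length` structures linearly interpolates the two endpoints with a
#' sinusoidal midpoint bulge standing in for a minimum-energy path; the
#' mid-path structure is labelled as the transition state.  These are
#' geometric stand-ins, not true MEPs.  Optionally labels every structure
#' with baseline (`E_L`) and reference (`E_H`) energies through the engine.
#'
#' @param n_reactions number of reactions to generate
#' @param templates template names, a subset of
#'   `names(fixture_templates())`; cycled over reactions
#' @param sigma Gaussian coordinate perturbation (Angstrom)
#' @param path_length structures per pseudo-path (>= 3, default 8)
#' @param with_path attach the pseudo-path to the record (TS is kept either
#'   way)
#' @param labeled compute `E_L` (baseline) and `E_H` (reference) per structure
#' @param method,ao_basis engine settings used when `labeled = TRUE`
#' @param min_dist interatomic distance guard (Angstrom); offending
#'   perturbations are resampled
#' @param seed RNG seed; output is fully reproducible
#' @return list of [reaction_record()]s
#' @export
generate_fixture_set <- function(n_reactions = 20,
                                 templates = c("H2O", "NH3", "CH4", "H2CO"),
                                 sigma = 0.05, path_length = 8,
                                 with_path = FALSE, labeled = FALSE,
                                 method = "hf", ao_basis = "sto-3g",
                                 min_dist = 0.6, seed = 1L) {
  if (path_length < 3) stop("path_length must be >= 3")
  tpl <- fixture_templates()
  unknown <- setdiff(templates, names(tpl))
  if (length(unknown))
    stop("unknown template(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  records <- vector("list", n_reactions)
  for (k in seq_len(n_reactions)) {
    base <- tpl[[templates[(k - 1) %% length(templates) + 1]]]
    reac <- perturb_molecule(base, sigma, min_dist)
    prod <- perturb_molecule(base, sigma, min_dist)
    bulge <- matrix(rnorm(length(base$coords), sd = sigma),
                    nrow(base$coords), 3)
    tvals <- seq(0, 1, length.out = path_length)
    path_mols <- lapply(tvals, function(t) {
      m <- base
      m$coords <- (1 - t) * reac$coords + t * prod$coords +
        sin(pi * t) * bulge
      m
    })
    ok <- all(vapply(path_mols, function(m)
      min_interatomic_distance(m) >= min_dist, TRUE))
    if (!ok) {
      # damp the bulge until the guard passes
      for (damp in c(0.5, 0.25, 0.1, 0)) {
        path_mols <- lapply(tvals, function(t) {
          m <- base
          m$coords <- (1 - t) * reac$coords + t * prod$coords +
            damp * sin(pi * t) * bulge
          m
        })
        if (all(vapply(path_mols, function(m)
          min_interatomic_distance(m) >= min_dist, TRUE))) break
      }
    }
    rid <- sprintf("rxn%03d", k)
    ts_idx <- ceiling(path_length / 2)
    sids <- c(paste0(rid, "_reac"),
              paste0(rid, "_p", seq(2, path_length - 1)),
              paste0(rid, "_prod"))
    structures <- setNames(lapply(path_mols, function(m) list(molecule = m)),
                           sids)
    roles <- list(reactant = sids[1], transition_state = sids[ts_idx],
                  product = sids[path_length])
    if (!with_path) {
      keep <- unlist(roles)
      structures <- structures[keep]
      records[[k]] <- reaction_record(rid, structures, roles)
    } else {
      records[[k]] <- reaction_record(rid, structures, roles, path = sids)
    }
  }
  if (labeled) records <- label_records(records, method, ao_basis)
  records
}

#' Label reaction records through the engine
#'
#' Fills `energy_low` with the baseline energy and `energy_high` with the
#' desk-scale reference energy for every structure of every record.
#'
#' @param records list of [reaction_record()]s
#' @param method,ao_basis engine settings
#' @param triples include the perturbative triples correction
#' @return the records with energies filled
#' @export
label_records <- function(records, method = "hf", ao_basis = "sto-3g",
                          triples = TRUE) {
  lapply(records, function(rec) {
    rec$structures <- lapply(rec$structures, function(s) {
      scf <- run_baseline(s$molecule, method, ao_basis)
      ref <- run_reference(s$molecule, ao_basis, triples = triples)
      s$energy_low <- scf$energy_baseline
      s$energy_high <- ref$energy_high
      s
    })
    rec
  })
}

# ---------------------------------------------------------------------------
# feature store (JSON, keyed by structure ID, provenance in the header)

# hash over the canonical JSON text so the value survives serialization
# round trips (integer/double distinctions do not matter)
provenance_hash <- function(provenance) {
  p <- provenance[c("method", "ao_basis", "pbasis_spec")]
  rlang::hash(as.character(jsonlite::toJSON(p, auto_unbox = TRUE,
                                            digits = NA)))
}

#' Write / read the descriptor feature store
#'
#' One entry per structure ID: per-atom descriptor matrix, element labels and
#' the baseline energy.  The header records the featurization provenance
#' (baseline method, AO basis, projection-basis spec) and its hash; consumers
#' refuse stores whose provenance does not match the model checkpoint.
#'
#' @param entries named list (by structure ID); each entry has `descriptors`
#'   (matrix), `elements`, `energy_baseline`
#' @param path file path
#' @param provenance list with `method`, `ao_basis`, `pbasis_spec`
#' @return `read_feature_store`: list with `provenance`, `hash`, `entries`
#' @export
write_feature_store <- function(entries, path, provenance) {
  payload <- list(
    provenance = provenance,
    hash = provenance_hash(provenance),
    entries = lapply(entries, function(e) list(
      dim = dim(e$descriptors), data = as.vector(e$descriptors),
      elements = e$elements, energy_baseline = e$energy_baseline)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$provenance) || is.null(raw$hash))
    stop("corrupt feature store: missing provenance header")
  if (!identical(provenance_hash(raw$provenance), raw$hash))
    stop("corrupt feature store: provenance hash mismatch")
  entries <- lapply(raw$entries, function(e) {
    desc <- matrix(as.numeric(e$data), e$dim[1], e$dim[2])
    structure(list(descriptors = desc, elements = e$elements,
                   energy_baseline = e$energy_baseline),
              class = "store_entry")
  })
  list(provenance = raw$provenance, hash = raw$hash, entries = entries)
}

# store entry -> descriptor_set
entry_descriptors <- function(entry, pbasis_spec) {
  structure(list(descriptors = entry$descriptors,
                 elements = entry$elements, pbasis_spec = pbasis_spec),
            class = "descriptor_set")
}
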