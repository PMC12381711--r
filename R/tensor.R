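# Minimal named-index contraction over dense arrays (einsum-style, two
# operands, every shared index summed).  All coupled-cluster working equations
# are expressed through this single primitive, which keeps them close to their
# textbook form and testable against naive loop evaluation.

einsum <- function(spec, A, B = NULL) {
  spec <- gsub(" ", "", spec)
  parts <- strsplit(spec, "->")[[1]]
  ins <- strsplit(parts[1], ",")[[1]]
  out_idx <- if (length(parts) > 1) strsplit(parts[2], "")[[1]] else character()
  ia <- strsplit(ins[1], "")[[1]]
  if (is.null(dim(A))) dim(A) <- length(A)
  da <- dim(A)
  if (length(da) != length(ia)) stop("einsum: rank mismatch for operand A")
  if (is.null(B)) {
    # pure transpose / full trace not needed beyond permutation here
    perm <- match(out_idx, ia)
    if (anyNA(perm)) stop("einsum: unknown output index")
    return(aperm(A, perm))
  }
  ib <- strsplit(ins[2], "")[[1]]
  if (is.null(dim(B))) dim(B) <- length(B)
  db <- dim(B)
  if (length(db) != length(ib)) stop("einsum: rank mismatch for operand B")
  con <- intersect(ia, ib)
  if (any(out_idx %in% con)) stop("einsum: batched indices unsupported")
  freeA <- setdiff(ia, con)
  freeB <- setdiff(ib, con)
  if (!setequal(out_idx, c(freeA, freeB)))
    stop("einsum: output indices must be the free indices")
  pa <- c(match(freeA, ia), match(con, ia))
  pb <- c(match(con, ib), match(freeB, ib))
  dfa <- da[match(freeA, ia)]; dca <- da[match(con, ia)]
  dcb <- db[match(con, ib)]; dfb <- db[match(freeB, ib)]
  if (!identical(as.integer(dca), as.integer(dcb)))
    stop("einsum: contracted dimensions disagree")
  Am <- matrix(aperm(A, pa), max(prod(dfa), 1), max(prod(dca), 1))
  Bm <- matrix(aperm(B, pb), max(prod(dcb), 1), max(prod(dfb), 1))
  Cm <- Am %*% Bm
  dims_out <- c(dfa, dfb)
  if (length(dims_out) == 0) return(as.numeric(Cm))
  Carr <- array(Cm, dims_out)
  perm <- match(out_idx, c(freeA, freeB))
  aperm(Carr, perm)
}
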