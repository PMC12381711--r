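# Shared fixtures, built once per test run and cached (labelling with the
# coupled-cluster reference is the expensive step, so several test files
# share one labelled reaction set and one trained model).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

water <- function() fixture_templates()$H2O

# a converged H2O SCF shared by engine/descriptor tests
cached_h2o_scf <- function() cached("h2o_scf", run_baseline(water()))

cached_h2o_featurization <- function() {
  cached("h2o_feat", featurize(water(), "hf", "sto-3g",
                               build_projection_basis()))
}

# the default labelled fixture set: 28 reactions cycled over the four
# polyatomic templates, HF baseline + CCSD(T) reference labels
cached_labeled_records <- function() {
  cached("labeled_records",
         generate_fixture_set(n_reactions = 28, labeled = TRUE, seed = 2024))
}

# reaction-level 8:1:1 split of the labelled set, featurized + trained model
cached_trained <- function() {
  cached("trained", {
    records <- cached_labeled_records()
    pbasis <- build_projection_basis()
    prov <- list(method = "hf", ao_basis = "sto-3g",
                 pbasis_spec = pbasis$spec)
    feats <- list()
    for (rec in records) {
      for (sid in names(rec$structures)) {
        ft <- featurize(rec$structures[[sid]]$molecule, "hf", "sto-3g",
                        pbasis)
        feats[[sid]] <- list(descriptors = ft$descriptors,
                             energy_baseline = ft$energy_baseline)
      }
    }
    to_samples <- function(recs) {
      out <- list()
      for (rec in recs) for (sid in names(rec$structures)) {
        s <- rec$structures[[sid]]
        out[[length(out) + 1]] <- labeled_sample(
          feats[[sid]]$descriptors,
          make_label(s$energy_high, feats[[sid]]$energy_baseline), id = sid)
      }
      out
    }
    sp <- split_dataset(records, c(0.8, 0.1, 0.1), seed = 5)
    fit <- train_model(to_samples(sp$train), to_samples(sp$valid),
                       train_config(epochs = 1500, seed = 5),
                       provenance = prov)
    list(fit = fit, split = sp, feats = feats, records = records,
         pbasis = pbasis, prov = prov)
  })
}

# naive loop-based reference for einsum
einsum_loops <- function(spec, A, B) {
  spec <- gsub(" ", "", spec)
  parts <- strsplit(spec, "->")[[1]]
  ins <- strsplit(strsplit(parts[1], ",")[[1]], "")
  out_idx <- strsplit(parts[2], "")[[1]]
  ia <- ins[[1]]; ib <- ins[[2]]
  if (is.null(dim(A))) dim(A) <- length(A)
  if (is.null(dim(B))) dim(B) <- length(B)
  all_idx <- unique(c(ia, ib))
  sizes <- integer(length(all_idx)); names(sizes) <- all_idx
  sizes[ia] <- dim(A); sizes[ib] <- dim(B)
  grid <- do.call(expand.grid, lapply(sizes, seq_len))
  out <- array(0, unname(sizes[out_idx]))
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    names(g) <- all_idx
    val <- A[matrix(g[ia], 1)] * B[matrix(g[ib], 1)]
    pos <- matrix(g[out_idx], 1)
    out[pos] <- out[pos] + val
  }
  out
}
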