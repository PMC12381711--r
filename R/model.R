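# Atom-wise neural-network correction model.
#
# The correction energy is strictly additive over atoms,
#   E_delta = linear_head(sum_I d^I) + sum_I F_NN(d^I | w_elem(I)),
# which makes it size-consistent and invariant under atom reordering by
# construction.  A ridge linear head is fitted first on standardized summed
# descriptors; the network (3 x 108 GELU layers per element, zero-initialized
# output layer) learns the residual with Adam, batch 16, initial learning
# rate 3e-4 decayed stepwise by 0.96 every 500 epochs over 15,000 epochs.

#' Training hyperparameters
#'
#' Defaults follow the reference training protocol: Adam, batch size 16,
#' initial learning rate 3e-4 with a stepwise exponential decay factor 0.96
#' every 500 epochs, 15,000 epochs total, and a ridge pre-fit on the summed
#' descriptors.
#'
#' @param batch_size minibatch size (molecules per gradient step)
#' @param lr0 initial learning rate
#' @param decay_factor learning-rate decay factor, in (0, 1]
#' @param decay_interval epochs between decay steps
#' @param epochs total training epochs
#' @param ridge_strength ridge penalty of the linear pre-fit
#' @param hidden hidden-layer widths
#' @param seed RNG seed for init and batching
#' @param shared_network single network for all elements instead of
#'   per-element parameter sets
#' @return a `train_config` list
#' @export
train_config <- function(batch_size = 16, lr0 = 3e-4, decay_factor = 0.96,
                         decay_interval = 500, epochs = 15000,
                         ridge_strength = 1e-5, hidden = c(108, 108, 108),
                         seed = 1L, shared_network = FALSE) {
  stopifnot(batch_size >= 1, lr0 > 0, decay_factor > 0, decay_factor <= 1,
            decay_interval >= 1, epochs >= 1, ridge_strength > 0,
            all(hidden >= 1))
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0,
                 decay_factor = decay_factor,
                 decay_interval = as.integer(decay_interval),
                 epochs = as.integer(epochs),
                 ridge_strength = ridge_strength, hidden = as.integer(hidden),
                 seed = as.integer(seed),
                 shared_network = isTRUE(shared_network)),
            class = "train_config")
}

# learning rate at a given 1-based epoch
lr_schedule <- function(epoch, cfg) {
  cfg$lr0 * cfg$decay_factor^((epoch - 1) %/% cfg$decay_interval)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# ---------------------------------------------------------------------------
# labeled samples

#' Assemble a labeled training sample
#'
#' @param desc a `descriptor_set` (from [featurize()])
#' @param label energy label `E_H - E_L` in Hartree
#' @param id structure identifier
#' @return a `labeled_sample`
#' @export
labeled_sample <- function(desc, label, id = NA_character_) {
  stopifnot(inherits(desc, "descriptor_set"), is.finite(label))
  structure(list(desc = desc, label = label, id = id),
            class = "labeled_sample")
}

#' Label from a pair of total energies
#'
#' The delta-learning target: `E_delta = E_H - E_L` (Hartree).  When the
#' baseline is Hartree-Fock and the high level a correlated method, this is
#' the correlation energy.
#'
#' @param energy_high high-level total energy (Hartree)
#' @param energy_low baseline total energy (Hartree)
#' @return `E_H - E_L`
#' @export
make_label <- function(energy_high, energy_low) {
  stopifnot(is.finite(energy_high), is.finite(energy_low))
  energy_high - energy_low
}

# ---------------------------------------------------------------------------
# parameter container

new_model_params <- function(weights, ridge, scaler, meta) {
  structure(list(weights = weights, ridge = ridge, scaler = scaler,
                 meta = meta), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> elements %s, %d descriptors, hidden %s\n",
    paste(names(x$weights), collapse = "/"), x$meta$descriptor_length,
    paste(x$meta$hidden, collapse = "x")))
  invisible(x)
}

# Kaiming-style init; output layer zero-initialized so that an untrained
# network reduces exactly to the ridge head
init_network <- function(d_in, hidden) {
  dims <- c(d_in, hidden, 1L)
  net <- list()
  for (k in seq_len(length(dims) - 1)) {
    fan_in <- dims[k]
    W <- matrix(rnorm(dims[k] * dims[k + 1], sd = sqrt(2 / fan_in)),
                dims[k], dims[k + 1])
    b <- rep(0, dims[k + 1])
    if (k == length(dims) - 1) W[] <- 0
    net[[paste0("W", k)]] <- W
    net[[paste0("b", k)]] <- b
  }
  net
}

#' Initialize model parameters
#'
#' @param descriptor_length per-atom descriptor length
#' @param elements element symbols the model must support
#' @param cfg a [train_config()]
#' @param provenance list recording how features were produced (projection
#'   basis spec, baseline method, AO basis); stored so a model cannot be
#'   evaluated against features from a different pipeline
#' @return `model_params` with zero ridge head and zero-output networks
#' @export
init_model <- function(descriptor_length, elements, cfg = train_config(),
                       provenance = NULL) {
  set.seed(cfg$seed)
  keys <- if (cfg$shared_network) "all" else sort(unique(elements))
  weights <- setNames(lapply(keys, function(e)
    init_network(descriptor_length, cfg$hidden)), keys)
  new_model_params(
    weights = weights,
    ridge = list(w = rep(0, descriptor_length), b = 0),
    scaler = list(mean = rep(0, descriptor_length),
                  sd = rep(1, descriptor_length)),
    meta = list(descriptor_length = as.integer(descriptor_length),
                hidden = cfg$hidden, shared_network = cfg$shared_network,
                elements = keys, provenance = provenance))
}

element_key <- function(params, elements) {
  if (isTRUE(params$meta$shared_network)) return(rep("all", length(elements)))
  missing_el <- setdiff(unique(elements), names(params$weights))
  if (length(missing_el))
    stop("unsupported element(s) for this model: ",
         paste(missing_el, collapse = ", "))
  elements
}

standardize <- function(params, desc) {
  sweep(sweep(desc, 2, params$scaler$mean, "-"), 2, params$scaler$sd, "/")
}

# forward pass of one element-network over a matrix of atom rows; optionally
# keeps intermediates for backprop
net_forward <- function(net, X, keep = FALSE) {
  nlayer <- length(net) / 2
  H <- X; cache <- list(A0 = X)
  for (k in seq_len(nlayer)) {
    Z <- sweep(H %*% net[[paste0("W", k)]], 2, net[[paste0("b", k)]], "+")
    if (k < nlayer) {
      if (keep) cache[[paste0("Z", k)]] <- Z
      H <- gelu(Z)
      if (keep) cache[[paste0("A", k)]] <- H
    } else H <- Z
  }
  if (keep) list(out = as.numeric(H), cache = cache) else as.numeric(H)
}

#' Predict the correction energy for one structure
#'
#' `E_delta` is the ridge head on the summed standardized descriptors plus the
#' sum over atoms of the element network outputs.
#'
#' @param params a `model_params`
#' @param desc a `descriptor_set`
#' @return correction energy in Hartree
#' @export
predict_correction <- function(params, desc) {
  X <- desc$descriptors
  if (ncol(X) != params$meta$descriptor_length)
    stop("descriptor length ", ncol(X), " does not match model (",
         params$meta$descriptor_length, ")")
  keys <- element_key(params, desc$elements)
  Xs <- standardize(params, X)
  e <- sum(colSums(Xs) * params$ridge$w) + params$ridge$b * nrow(X)
  for (el in unique(keys)) {
    rows <- which(keys == el)
    e <- e + sum(net_forward(params$weights[[el]],
                             Xs[rows, , drop = FALSE]))
  }
  e
}

#' Predict a corrected total energy
#'
#' Featurizes the molecule with the model's own provenance (baseline method,
#' AO basis, projection basis) and returns `E_L + E_delta`.
#'
#' @param params a `model_params` carrying featurization provenance
#' @param mol a [molecule()]
#' @param method,ao_basis,pbasis override the stored provenance (rarely
#'   needed; defaults come from the checkpoint)
#' @return corrected total energy in Hartree
#' @export
predict_total <- function(params, mol, method = NULL, ao_basis = NULL,
                          pbasis = NULL) {
  prov <- params$meta$provenance
  method <- method %||% prov$method %||% "hf"
  ao_basis <- ao_basis %||% prov$ao_basis %||% "sto-3g"
  if (is.null(pbasis)) {
    pbasis <- if (!is.null(prov$pbasis_spec))
      do.call(build_projection_basis, prov$pbasis_spec)
    else build_projection_basis()
  }
  ft <- featurize(mol, method, ao_basis, pbasis)
  ft$energy_baseline + predict_correction(params, ft$descriptors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean-squared-error loss over a batch
#'
#' The training objective: the mean over the batch of squared deviations
#' between the label `E_H - E_L` and the predicted correction, in Hartree^2.
#'
#' @param params a `model_params`
#' @param batch list of [labeled_sample()]s
#' @return scalar loss (Ha^2)
#' @export
delta_loss <- function(params, batch) {
  if (!length(batch)) stop("empty batch")
  res <- vapply(batch, function(s)
    s$label - predict_correction(params, s$desc), 0)
  mean(res^2)
}

# ---------------------------------------------------------------------------
# ridge pre-fit

#' Ridge linear pre-fit on summed descriptors
#'
#' Minimizes `sum_i (E_label_i - w . sum_I d^I_i - b n_i)^2 +
#' strength ||w||^2` in closed form, where `n_i` is the atom count of sample
#' i: the intercept is per atom (and unpenalized), so the linear head is
#' strictly additive over atoms and the model stays size-consistent.  The
#' network subsequently fits the residual.
#'
#' @param samples list of [labeled_sample()]s with standardized descriptors
#' @param strength ridge penalty, must be > 0
#' @return list `w` (per-feature weights), `b` (per-atom intercept)
#' @export
ridge_prefit <- function(samples, strength) {
  if (length(samples) < 2) stop("need at least 2 samples")
  if (strength <= 0) stop("ridge strength must be > 0")
  X <- t(vapply(samples, function(s) colSums(s$desc$descriptors),
                numeric(ncol(samples[[1]]$desc$descriptors))))
  n_at <- vapply(samples, function(s) nrow(s$desc$descriptors), 0)
  y <- vapply(samples, `[[`, 0, "label")
  Xa <- cbind(X, n_at)
  A <- crossprod(Xa) + strength * diag(c(rep(1, ncol(X)), 0))
  wb <- solve(A, crossprod(Xa, y))
  list(w = as.numeric(wb[seq_len(ncol(X))]), b = as.numeric(wb[ncol(X) + 1]))
}

# ---------------------------------------------------------------------------
# training

# flatten/unflatten parameter lists for Adam state
flatten_nets <- function(weights) unlist(weights, use.names = FALSE)

#' Train the correction model
#'
#' Runs the ridge pre-fit, then minibatch Adam on the residuals for
#' `cfg$epochs` epochs with the stepwise learning-rate decay.  The checkpoint
#' with the best validation MAE is returned, along with the full history
#' (epoch, lr, train loss, validation MAE).
#'
#' @param train_set,valid_set lists of [labeled_sample()]s; IDs must be
#'   disjoint
#' @param cfg a [train_config()]
#' @param provenance featurization provenance stored in the checkpoint
#' @param verbose print progress every 500 epochs
#' @return list with `params` (best checkpoint), `history` (data.frame), and
#'   `final_params`
#' @export
train_model <- function(train_set, valid_set, cfg = train_config(),
                        provenance = NULL, verbose = FALSE) {
  if (!length(train_set) || !length(valid_set)) stop("empty split")
  ids_t <- vapply(train_set, `[[`, "", "id")
  ids_v <- vapply(valid_set, `[[`, "", "id")
  common <- intersect(ids_t[!is.na(ids_t)], ids_v[!is.na(ids_v)])
  if (length(common))
    stop("split leakage: structure IDs in both train and valid: ",
         paste(utils::head(common, 3), collapse = ", "))

  d_len <- ncol(train_set[[1]]$desc$descriptors)
  all_rows <- do.call(rbind, lapply(train_set,
                                    function(s) s$desc$descriptors))
  mu <- colMeans(all_rows)
  sdv <- apply(all_rows, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1

  elements <- unique(unlist(lapply(train_set, function(s) s$desc$elements)))
  params <- init_model(d_len, elements, cfg, provenance)
  params$scaler <- list(mean = mu, sd = sdv)

  # ridge pre-fit on standardized descriptors
  std_set <- lapply(train_set, function(s) {
    s$desc$descriptors <- standardize(params, s$desc$descriptors)
    s
  })
  params$ridge <- ridge_prefit(std_set, cfg$ridge_strength)

  # precompute standardized descriptor stacks per sample
  prep <- function(set) lapply(set, function(s) {
    list(X = standardize(params, s$desc$descriptors),
         keys = element_key(params, s$desc$elements),
         label = s$label,
         ridge_part = sum(colSums(standardize(params, s$desc$descriptors)) *
                          params$ridge$w) +
           params$ridge$b * nrow(s$desc$descriptors))
  })
  tr <- prep(train_set)
  va <- prep(valid_set)

  keys <- params$meta$elements
  nets <- params$weights
  adam_m <- lapply(nets, function(net) lapply(net, function(x) x * 0))
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  tstep <- 0

  va_stacks <- lapply(keys, function(el) {
    rows <- list(); samp <- integer()
    for (si in seq_along(va)) {
      sel <- which(va[[si]]$keys == el)
      if (length(sel)) {
        rows[[length(rows) + 1]] <- va[[si]]$X[sel, , drop = FALSE]
        samp <- c(samp, rep(si, length(sel)))
      }
    }
    list(X = do.call(rbind, rows), samp = samp)
  })
  names(va_stacks) <- keys
  va_resid0 <- vapply(va, function(s) s$label - s$ridge_part, 0)
  valid_mae <- function(nets) {
    pred <- numeric(length(va))
    for (el in keys) {
      st <- va_stacks[[el]]
      if (!length(st$samp)) next
      sums <- rowsum(net_forward(nets[[el]], st$X), group = st$samp)
      pred[as.integer(rownames(sums))] <- pred[as.integer(rownames(sums))] +
        sums[, 1]
    }
    mean(abs(va_resid0 - pred))
  }

  n_tr <- length(tr)
  history <- data.frame(epoch = integer(cfg$epochs), lr = numeric(cfg$epochs),
                        train_loss = numeric(cfg$epochs),
                        valid_mae = numeric(cfg$epochs))
  best <- list(mae = Inf, nets = nets, epoch = 0L)
  set.seed(cfg$seed + 1L)

  # stack all training atoms once: per element a row-block with the sample
  # index of every atom row, so a whole minibatch is one forward/backward
  # pass per element
  stacks <- lapply(keys, function(el) {
    rows <- list(); samp <- integer()
    for (si in seq_len(n_tr)) {
      sel <- which(tr[[si]]$keys == el)
      if (length(sel)) {
        rows[[length(rows) + 1]] <- tr[[si]]$X[sel, , drop = FALSE]
        samp <- c(samp, rep(si, length(sel)))
      }
    }
    list(X = do.call(rbind, rows), samp = samp)
  })
  names(stacks) <- keys
  ridge_parts <- vapply(tr, `[[`, 0, "ridge_part")
  labels <- vapply(tr, `[[`, 0, "label")

  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(epoch, cfg)
    ord <- sample.int(n_tr)
    nb <- ceiling(n_tr / cfg$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, n_tr)]
      in_batch <- logical(n_tr); in_batch[idx] <- TRUE
      # forward all atoms of the batch, grouped by element
      pred <- ridge_parts[idx]
      names(pred) <- as.character(idx)
      fw_cache <- list(); row_sel <- list()
      for (el in keys) {
        st <- stacks[[el]]
        rsel <- which(in_batch[st$samp])
        row_sel[[el]] <- rsel
        if (!length(rsel)) next
        fw <- net_forward(nets[[el]], st$X[rsel, , drop = FALSE],
                          keep = TRUE)
        fw_cache[[el]] <- fw
        sums <- rowsum(fw$out, group = st$samp[rsel])
        pred[rownames(sums)] <- pred[rownames(sums)] + sums[, 1]
      }
      resid <- labels[idx] - pred[as.character(idx)]
      ep_loss <- ep_loss + sum(resid^2)
      gout_by_sample <- numeric(n_tr)
      gout_by_sample[idx] <- -2 * resid / length(idx)
      # backward per element
      grads <- lapply(nets, function(net) lapply(net, function(x) x * 0))
      for (el in keys) {
        rsel <- row_sel[[el]]
        if (!length(rsel)) next
        st <- stacks[[el]]
        cache <- fw_cache[[el]]$cache
        net <- nets[[el]]
        nlayer <- length(net) / 2
        delta <- matrix(gout_by_sample[st$samp[rsel]], ncol = 1)
        for (k in seq(nlayer, 1)) {
          A_prev <- cache[[paste0("A", k - 1)]]
          grads[[el]][[paste0("W", k)]] <- crossprod(A_prev, delta)
          grads[[el]][[paste0("b", k)]] <- colSums(delta)
          if (k > 1) {
            delta <- delta %*% t(net[[paste0("W", k)]])
            delta <- delta * gelu_grad(cache[[paste0("Z", k - 1)]])
          }
        }
      }
      # Adam update
      tstep <- tstep + 1
      bc1 <- 1 - beta1^tstep; bc2 <- 1 - beta2^tstep
      for (el in keys) for (nm in names(nets[[el]])) {
        g <- grads[[el]][[nm]]
        adam_m[[el]][[nm]] <- beta1 * adam_m[[el]][[nm]] + (1 - beta1) * g
        adam_v[[el]][[nm]] <- beta2 * adam_v[[el]][[nm]] + (1 - beta2) * g^2
        nets[[el]][[nm]] <- nets[[el]][[nm]] -
          lr * (adam_m[[el]][[nm]] / bc1) /
          (sqrt(adam_v[[el]][[nm]] / bc2) + eps_adam)
      }
    }
    vm <- valid_mae(nets)
    history$epoch[epoch] <- epoch
    history$lr[epoch] <- lr
    history$train_loss[epoch] <- ep_loss / n_tr
    history$valid_mae[epoch] <- vm
    if (vm < best$mae) best <- list(mae = vm, nets = nets, epoch = epoch)
    if (!is.finite(ep_loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    if (verbose && epoch %% 500 == 0)
      message(sprintf("epoch %6d  lr %.2e  loss %.3e  valid MAE %.3e",
                      epoch, lr, ep_loss / n_tr, vm))
  }
  final_params <- params; final_params$weights <- nets
  params$weights <- best$nets
  params$meta$best_epoch <- best$epoch
  list(params = params, history = history, final_params = final_params)
}

# ---------------------------------------------------------------------------
# checkpoint I/O (JSON text; a model is unusable without its featurization
# provenance, so the provenance travels inside the file)

#' Save / load model checkpoints
#'
#' Checkpoints are JSON and carry the network weights, ridge head, feature
#' scaler, architecture metadata and featurization provenance.
#'
#' @param params a `model_params`
#' @param path file path
#' @return `load_checkpoint`: a `model_params`
#' @export
save_checkpoint <- function(params, path) {
  weights <- lapply(params$weights, function(net)
    lapply(net, function(x) {
      if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
      else list(dim = length(x), data = as.vector(x))
    }))
  jsonlite::write_json(
    list(weights = weights, ridge = params$ridge,
         scaler = params$scaler, meta = params$meta),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(raw$weights, function(net) {
    out <- list()
    for (nm in names(net)) {
      x <- net[[nm]]
      out[[nm]] <- if (length(x$dim) == 2)
        matrix(as.numeric(x$data), x$dim[1], x$dim[2])
      else as.numeric(x$data)
    }
    out
  })
  meta <- raw$meta
  meta$hidden <- as.integer(meta$hidden)
  new_model_params(weights = weights,
                   ridge = list(w = as.numeric(raw$ridge$w),
                                b = as.numeric(raw$ridge$b)),
                   scaler = list(mean = as.numeric(raw$scaler$mean),
                                 sd = as.numeric(raw$scaler$sd)),
                   meta = meta)
}
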