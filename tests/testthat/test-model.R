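# Atom-wise correction model: ridge pre-fit, prediction contracts, loss,
# training schedule and checkpointing.

fake_desc <- function(X, elements) {
  structure(list(descriptors = X, elements = elements,
                 pbasis_spec = list()), class = "descriptor_set")
}

random_samples <- function(n, d = 6, atoms = 3, seed = 1,
                           label_fn = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    X <- matrix(rnorm(atoms * d), atoms, d)
    lab <- if (is.null(label_fn)) rnorm(1) else label_fn(X)
    labeled_sample(fake_desc(X, rep(c("H", "O"), length.out = atoms)),
                   lab, id = paste0("s", k))
  })
}

test_that("ridge pre-fit satisfies its optimality conditions", {
  samples <- random_samples(20, seed = 4)
  head <- ridge_prefit(samples, strength = 1e-3)
  X <- t(sapply(samples, function(s) colSums(s$desc$descriptors)))
  y <- sapply(samples, `[[`, "label")
  # zero gradient of the penalized objective at the solution; every sample
  # here has 3 atoms, so the per-atom intercept contributes 3b
  resid <- y - X %*% head$w - head$b * 3
  grad_w <- -2 * drop(crossprod(X, resid)) + 2 * 1e-3 * head$w
  expect_lt(max(abs(grad_w)), 1e-8)
  expect_lt(abs(sum(resid)), 1e-8)               # intercept condition
  # exactly linear labels are recovered as strength -> 0+
  wtrue <- rnorm(6)
  lin <- random_samples(20, seed = 5, label_fn = function(X)
    sum(colSums(X) * wtrue) + 0.3)
  head2 <- ridge_prefit(lin, strength = 1e-10)
  expect_equal(head2$w, wtrue, tolerance = 1e-5)
  # infinite strength shrinks w to zero; the unpenalized per-atom intercept
  # tends to the least-squares constant (mean label / atom count here)
  head3 <- ridge_prefit(samples, strength = 1e10)
  expect_lt(max(abs(head3$w)), 1e-6)
  expect_equal(head3$b, mean(y) / 3, tolerance = 1e-8)
  expect_error(ridge_prefit(samples[1], 1e-3), "at least 2")
  expect_error(ridge_prefit(samples, 0), "strength")
})

test_that("zero model predicts zero correction and baseline totals", {
  params <- init_model(23, c("H", "O"))
  ft <- cached_h2o_featurization()
  expect_identical(predict_correction(params, ft$descriptors), 0)
  params$meta$provenance <- list(method = "hf", ao_basis = "sto-3g",
                                 pbasis_spec = build_projection_basis()$spec)
  expect_equal(predict_total(params, water()), ft$energy_baseline)
})

test_that("correction is additive over atoms and permutation invariant", {
  set.seed(8)
  params <- init_model(6, c("H", "O"))
  # give the networks nonzero output layers
  for (el in names(params$weights)) {
    params$weights[[el]]$W4 <- matrix(rnorm(108), 108, 1)
    params$weights[[el]]$b4 <- rnorm(1)
  }
  params$ridge <- list(w = rnorm(6), b = 0.17)
  X <- matrix(rnorm(18), 3, 6)
  d1 <- fake_desc(X, c("O", "H", "H"))
  e1 <- predict_correction(params, d1)
  # permutation invariance (exact)
  perm <- c(2, 3, 1)
  e_perm <- predict_correction(params, fake_desc(X[perm, ],
                                                 c("O", "H", "H")[perm]))
  expect_identical(e1, e_perm)
  # strict additivity: a non-interacting union predicts the sum
  d2 <- fake_desc(rbind(X, X), rep(c("O", "H", "H"), 2))
  e2 <- predict_correction(params, d2)
  expect_equal(e2, 2 * e1, tolerance = 1e-13)
  # unseen element refused
  expect_error(predict_correction(params, fake_desc(X, c("N", "H", "H"))),
               "unsupported element")
  expect_error(predict_correction(params, fake_desc(X[, 1:5], c("O", "H", "H"))),
               "descriptor length")
})

test_that("loss is the batch mean of squared label residuals", {
  params <- init_model(6, c("H", "O"))
  s0 <- random_samples(4, seed = 11)
  zero_lab <- lapply(s0, function(s) { s$label <- 0; s })
  expect_equal(delta_loss(params, zero_lab), 0)
  one <- s0[[1]]; one$label <- 1e-3
  expect_equal(delta_loss(params, list(one)), 1e-6)
  labs <- sapply(s0, `[[`, "label")
  expect_equal(delta_loss(params, s0), mean(labs^2))  # zero model predicts 0
  expect_error(delta_loss(params, list()), "empty")
})

test_that("learning-rate schedule is stepwise exponential", {
  cfg <- train_config(epochs = 2000)
  lr <- sapply(1:2000, deltaqc:::lr_schedule, cfg = cfg)
  expect_identical(lr, 3e-4 * 0.96^((0:1999) %/% 500))
  expect_identical(lr[500], 3e-4)        # decay strikes after epoch 500
  expect_identical(lr[501], 3e-4 * 0.96)
})

test_that("training overfits a small set and records a faithful history", {
  samples <- random_samples(12, d = 5, atoms = 2, seed = 13,
                            label_fn = function(X) 0.02 * tanh(sum(X)))
  cfg <- train_config(epochs = 600, seed = 3, hidden = c(32, 32, 32))
  fit <- train_model(samples[1:10], samples[11:12], cfg)
  h <- fit$history
  expect_equal(nrow(h), 600)
  expect_identical(h$lr, sapply(h$epoch, deltaqc:::lr_schedule, cfg = cfg))
  expect_lt(sqrt(min(h$train_loss)), 1e-3)
  # the returned checkpoint is the best-validation one
  expect_equal(min(h$valid_mae), h$valid_mae[fit$params$meta$best_epoch])
  best_mae <- mean(sapply(samples[11:12], function(s)
    abs(s$label - predict_correction(fit$params, s$desc))))
  final_mae <- mean(sapply(samples[11:12], function(s)
    abs(s$label - predict_correction(fit$final_params, s$desc))))
  expect_equal(best_mae, min(h$valid_mae), tolerance = 1e-10)
  expect_lte(best_mae, final_mae + 1e-12)
})

test_that("training is deterministic under a fixed seed", {
  samples <- random_samples(8, d = 4, atoms = 2, seed = 17)
  cfg <- train_config(epochs = 40, seed = 23, hidden = c(16, 16, 16))
  f1 <- train_model(samples[1:6], samples[7:8], cfg)
  f2 <- train_model(samples[1:6], samples[7:8], cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params$weights, f2$params$weights)
})

test_that("train/valid ID leakage is refused", {
  samples <- random_samples(6, seed = 19)
  expect_error(train_model(samples[1:4], samples[3:5], train_config()),
               "leakage")
})

test_that("checkpoints round-trip through JSON losslessly", {
  samples <- random_samples(8, d = 4, atoms = 2, seed = 29)
  fit <- train_model(samples[1:6], samples[7:8],
                     train_config(epochs = 30, seed = 1,
                                  hidden = c(12, 12, 12)),
                     provenance = list(method = "hf", ao_basis = "sto-3g",
                                       pbasis_spec = list(l_max = 2)))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit$params, path)
  p2 <- load_checkpoint(path)
  d <- samples[[1]]$desc
  expect_equal(predict_correction(p2, d),
               predict_correction(fit$params, d), tolerance = 1e-14)
  expect_identical(p2$meta$provenance$ao_basis, "sto-3g")
})
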