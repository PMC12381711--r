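# Reaction energetics, MEP utilities and error reporting.

KCAL <- deltaqc:::KCAL_PER_HARTREE

toy_record <- function(id = "rx1") {
  m <- water()
  reaction_record(id,
                  list(r = list(molecule = m), t = list(molecule = m),
                       p = list(molecule = m)),
                  roles = list(reactant = "r", transition_state = "t",
                               product = "p"))
}

test_that("reaction energetics follow their definitions and identity", {
  rec <- toy_record()
  e <- c(r = 0, t = 10, p = -5) / KCAL      # kcal/mol expressed in Hartree
  en <- reaction_energetics(rec, e)
  expect_equal(en$bhf, 10)
  expect_equal(en$bhr, 15)
  expect_equal(en$re, -5)
  # symmetric reaction: equal barriers
  en2 <- reaction_energetics(rec, c(r = -75.1, t = -75.05, p = -75.1))
  expect_equal(en2$bhf, en2$bhr)
  # algebraic identity on random triples
  set.seed(55)
  for (k in 1:20) {
    e3 <- setNames(rnorm(3, -75, 0.1), c("r", "t", "p"))
    en3 <- reaction_energetics(rec, e3)
    expect_lt(abs(en3$bhf - en3$bhr - en3$re), 1e-9)
  }
  # missing TS energies refused when barriers requested
  expect_error(reaction_energetics(rec, e[c("r", "p")]), "missing energies")
  norole <- reaction_record("rx2",
                            list(r = list(molecule = water()),
                                 p = list(molecule = water())),
                            roles = list(reactant = "r", product = "p"))
  expect_error(reaction_energetics(norole, e, barriers = TRUE),
               "no transition state")
})

test_that("MEP relative energies subtract the reactant and shift-invariance holds", {
  e <- c(-75.10, -75.08, -75.05, -75.02, -75.00, -75.03, -75.06, -75.09)
  rel <- mep_relative_energies(e)
  expect_identical(rel[1], 0)
  expect_equal(rel, (e - e[1]) * KCAL)
  expect_equal(mep_relative_energies(e + 0.37), rel)
  expect_error(mep_relative_energies(numeric(1)), "at least 2")
})

test_that("TS-adjacent relative energies are non-positive at a path maximum", {
  e <- c(-75.10, -75.08, -75.05, -75.02, -75.00, -75.03, -75.06, -75.09)
  ts <- which.max(e)
  r <- ts_adjacent_relatives(e, ts)
  expect_lte(r[["E1"]], 0)
  expect_lte(r[["E2"]], 0)
  expect_equal(r[["E1"]], (e[ts - 1] - e[ts]) * KCAL)
  expect_equal(r[["E2"]], (e[ts + 1] - e[ts]) * KCAL)
  # symmetric path about the TS
  es <- c(1, 3, 7, 3, 1) / KCAL
  rs <- ts_adjacent_relatives(es, 3)
  expect_equal(rs[["E1"]], rs[["E2"]])
  expect_error(ts_adjacent_relatives(e, 1), "neighbours")
  expect_error(ts_adjacent_relatives(e, length(e)), "neighbours")
})

test_that("error metrics match hand arithmetic and satisfy RMSE >= MAE", {
  expect_equal(error_metrics(c(1, 2, 3), c(1, 2, 3)),
               c(mae = 0, rmse = 0))
  expect_equal(error_metrics(c(1, -1, 1, -1), c(0, 0, 0, 0)),
               c(mae = 1, rmse = 1))
  expect_equal(error_metrics(c(0, 2), c(0, 0)),
               c(mae = 1, rmse = sqrt(2)))
  set.seed(61)
  for (k in 1:20) {
    m <- error_metrics(rnorm(17), rnorm(17))
    expect_gte(m[["rmse"]], m[["mae"]])
  }
  expect_error(error_metrics(1:3, 1:4), "equal")
})

test_that("benchmark report: oracle predictions give zero error, zero model gives baseline error", {
  records <- generate_fixture_set(n_reactions = 4, templates = "H2O",
                                  seed = 67)
  # synthetic labels: arbitrary but fixed energies
  set.seed(68)
  for (k in seq_along(records)) {
    for (sid in names(records[[k]]$structures)) {
      records[[k]]$structures[[sid]]$energy_high <- -75 + rnorm(1, 0, 0.01)
      records[[k]]$structures[[sid]]$energy_low <- -74.9 + rnorm(1, 0, 0.01)
    }
  }
  params <- init_model(23, c("H", "O"))
  lookup <- function(field) {
    function(mol, sid) {
      for (rec in records)
        if (sid %in% names(rec$structures))
          return(rec$structures[[sid]][[field]])
      stop("unknown sid")
    }
  }
  oracle <- benchmark_report(params, records, predict_fn = lookup("energy_high"))
  expect_equal(oracle$summary$mae, rep(0, 4))
  expect_equal(oracle$summary$rmse, rep(0, 4))
  raw <- benchmark_report(params, records, predict_fn = lookup("energy_low"))
  # the raw report equals independently recomputed baseline errors
  resid <- unlist(lapply(records, function(rec)
    sapply(rec$structures, function(s) s$energy_low - s$energy_high)))
  expect_equal(raw$summary$mae[1], mean(abs(resid)) * KCAL, tolerance = 1e-12)
  expect_equal(raw$summary$rmse[1], sqrt(mean(resid^2)) * KCAL,
               tolerance = 1e-12)
  expect_true(all(raw$summary$rmse >= raw$summary$mae))
  # report invariant under reaction reordering
  raw2 <- benchmark_report(params, rev(records),
                           predict_fn = lookup("energy_low"))
  expect_equal(raw2$summary, raw$summary)
  # unlabelled reactions are skipped with a warning and counted
  records[[2]]$structures[[1]]$energy_high <- NULL
  expect_warning(rep3 <- benchmark_report(params, records,
                                          predict_fn = lookup("energy_low")),
                 "skipping unlabelled")
  expect_equal(rep3$skipped, 1L)
})

test_that("per-reaction residuals match spreadsheet-style recomputation", {
  trained <- cached_trained()
  sp <- trained$split
  store_fn <- function(mol, sid) {
    trained$feats[[sid]]$energy_baseline +
      predict_correction(trained$fit$params,
                         trained$feats[[sid]]$descriptors)
  }
  report <- benchmark_report(trained$fit$params, sp$test,
                             predict_fn = store_fn)
  for (rec in sp$test) {
    e_pred <- sapply(names(rec$structures), function(sid) store_fn(NULL, sid))
    e_ref <- sapply(rec$structures, `[[`, "energy_high")
    row <- report$reactions[report$reactions$reaction == rec$id, ]
    expect_equal(row$re_pred,
                 unname(e_pred[rec$roles$product] -
                          e_pred[rec$roles$reactant]) * KCAL,
                 tolerance = 1e-12)
    expect_equal(row$re_ref,
                 (e_ref[[rec$roles$product]] - e_ref[[rec$roles$reactant]]) *
                   KCAL, tolerance = 1e-12)
    expect_equal(row$bhf_pred - row$bhr_pred, row$re_pred,
                 tolerance = 1e-9)
  }
})
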