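# Reaction-level energetics and error reporting: reaction energies,
# forward/reverse barrier heights, MEP relative energies, MAE/RMSE tables.
# Energies are compared per structure in Hartree and converted to kcal/mol
# once, at reporting.

#' Reaction energetics from per-structure energies
#'
#' Computes the reaction energy `RE = E_prod - E_react` and, when a
#' transition state is present, the forward and reverse barrier heights
#' `BHf = E_ts - E_react` and `BHr = E_ts - E_prod`.  The identity
#' `BHf - BHr = RE` holds to machine precision by construction.
#'
#' @param rec a [reaction_record()]
#' @param energies named numeric vector of total energies (Hartree), keyed by
#'   structure ID; must cover the reactant and product (and the transition
#'   state if barriers are requested)
#' @param barriers require and compute barrier heights (default: TRUE when
#'   the record has a transition state)
#' @return a `reaction_energetics` with Hartree inputs and kcal/mol derived
#'   quantities `re`, `bhf`, `bhr`
#' @export
reaction_energetics <- function(rec, energies,
                                barriers = !is.null(rec$roles$transition_state)) {
  need <- c(rec$roles$reactant, rec$roles$product)
  if (barriers) {
    if (is.null(rec$roles$transition_state))
      stop("reaction '", rec$id,
           "': barriers requested but no transition state")
    need <- c(need, rec$roles$transition_state)
  }
  miss <- setdiff(need, names(energies))
  if (length(miss))
    stop("reaction '", rec$id, "': missing energies for ",
         paste(miss, collapse = ", "))
  e_react <- unname(energies[rec$roles$reactant])
  e_prod <- unname(energies[rec$roles$product])
  e_ts <- if (barriers) unname(energies[rec$roles$transition_state]) else NA
  re <- (e_prod - e_react) * KCAL_PER_HARTREE
  bhf <- if (barriers) (e_ts - e_react) * KCAL_PER_HARTREE else NA
  bhr <- if (barriers) (e_ts - e_prod) * KCAL_PER_HARTREE else NA
  structure(list(id = rec$id, e_react = e_react, e_ts = e_ts,
                 e_prod = e_prod, re = re, bhf = bhf, bhr = bhr),
            class = "reaction_energetics")
}

#' Relative energies along a minimum-energy path
#'
#' Subtracts the first (reactant) energy from every point and converts to
#' kcal/mol; the first element is always 0 and the result is invariant under
#' a constant shift of the inputs.
#'
#' @param energies ordered numeric vector of path energies (Hartree),
#'   reactant first
#' @return relative energies in kcal/mol
#' @export
mep_relative_energies <- function(energies) {
  if (length(energies) < 2) stop("a path needs at least 2 points")
  (energies - energies[1]) * KCAL_PER_HARTREE
}

#' Relative energies of the structures adjacent to the transition state
#'
#' `E1 = E(ts-1) - E(ts)` and `E2 = E(ts+1) - E(ts)` in kcal/mol; both are
#' non-positive when the TS is the path maximum.
#'
#' @param energies ordered path energies (Hartree)
#' @param ts_index 1-based index of the transition state within the path
#' @return named numeric vector `c(E1, E2)` in kcal/mol
#' @export
ts_adjacent_relatives <- function(energies, ts_index) {
  if (ts_index <= 1 || ts_index >= length(energies))
    stop("transition state must have neighbours on both sides")
  c(E1 = (energies[ts_index - 1] - energies[ts_index]) * KCAL_PER_HARTREE,
    E2 = (energies[ts_index + 1] - energies[ts_index]) * KCAL_PER_HARTREE)
}

#' Mean absolute and root-mean-square error
#'
#' @param predicted,reference equal-length numeric vectors
#' @return named vector `c(mae, rmse)`
#' @export
error_metrics <- function(predicted, reference) {
  if (length(predicted) != length(reference) || !length(predicted))
    stop("predicted and reference must have equal, nonzero length")
  d <- predicted - reference
  c(mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Benchmark a model over labelled reaction records
#'
#' Predicts a corrected total energy for every labelled structure, assembles
#' per-reaction energetics, and reports MAE/RMSE (kcal/mol) for structure
#' energies, reaction energies and forward/reverse barrier heights, for both
#' the model and the raw baseline.  Records without complete reference labels
#' are skipped with a warning and counted.
#'
#' @param params a `model_params` (use a zero-initialized model to benchmark
#'   the raw baseline)
#' @param records list of [reaction_record()]s with `energy_high` labels
#' @param predict_fn optional function(molecule, structure_id) -> total
#'   energy (Hartree); defaults to [predict_total()] with `params`.  The
#'   structure ID lets callers serve predictions from a feature store
#' @return an `error_report`: summary data.frame (quantity, mae, rmse, n),
#'   per-reaction residual table, per-structure table, skipped-record count
#' @export
benchmark_report <- function(params, records, predict_fn = NULL) {
  if (is.null(predict_fn))
    predict_fn <- function(mol, sid) predict_total(params, mol)
  skipped <- 0L
  st_rows <- list(); rx_rows <- list()
  for (rec in records) {
    labs <- vapply(rec$structures, function(s)
      !is.null(s$energy_high), TRUE)
    if (!all(labs)) {
      warning("skipping unlabelled reaction '", rec$id, "'")
      skipped <- skipped + 1L
      next
    }
    e_pred <- vapply(names(rec$structures), function(sid)
      predict_fn(rec$structures[[sid]]$molecule, sid), 0)
    e_ref <- vapply(rec$structures, `[[`, 0, "energy_high")
    for (sid in names(rec$structures)) {
      st_rows[[length(st_rows) + 1]] <- data.frame(
        reaction = rec$id, structure = sid,
        e_pred = e_pred[[sid]], e_ref = e_ref[[sid]],
        abs_err_kcal = abs(e_pred[[sid]] - e_ref[[sid]]) * KCAL_PER_HARTREE)
    }
    has_ts <- !is.null(rec$roles$transition_state)
    en_pred <- reaction_energetics(rec, e_pred, barriers = has_ts)
    en_ref <- reaction_energetics(rec, e_ref, barriers = has_ts)
    rx_rows[[length(rx_rows) + 1]] <- data.frame(
      reaction = rec$id,
      re_pred = en_pred$re, re_ref = en_ref$re,
      bhf_pred = en_pred$bhf, bhf_ref = en_ref$bhf,
      bhr_pred = en_pred$bhr, bhr_ref = en_ref$bhr)
  }
  if (!length(st_rows)) stop("no labelled reactions to benchmark")
  st <- do.call(rbind, st_rows)
  rx <- do.call(rbind, rx_rows)
  summary_row <- function(quantity, pred, ref) {
    ok <- is.finite(pred) & is.finite(ref)
    m <- error_metrics(pred[ok], ref[ok])
    data.frame(quantity = quantity, mae = m[["mae"]], rmse = m[["rmse"]],
               n = sum(ok))
  }
  summ <- rbind(
    summary_row("structure_energy",
                st$e_pred * KCAL_PER_HARTREE, st$e_ref * KCAL_PER_HARTREE),
    summary_row("reaction_energy", rx$re_pred, rx$re_ref),
    summary_row("barrier_forward", rx$bhf_pred, rx$bhf_ref),
    summary_row("barrier_reverse", rx$bhr_pred, rx$bhr_ref))
  structure(list(summary = summ, reactions = rx, structures = st,
                 skipped = skipped), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report> (kcal/mol)\n")
  print(x$summary, row.names = FALSE)
  if (x$skipped) cat("skipped unlabelled reactions:", x$skipped, "\n")
  invisible(x)
}
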