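# Ensemble evaluation: Calpha / backbone / heavy-atom RMSD against a
# reference structure, the size-dependent success criterion, and per-length
# aggregate reporting.

selection_atoms <- function(selection) {
  switch(selection,
         ca = "CA",
         backbone = BACKBONE_ATOMS,
         heavy = NULL,
         stop("selection must be one of 'ca', 'backbone', 'heavy'"))
}

structure_atoms_df <- function(x) {
  if (inherits(x, "pep_model")) x <- model_as_structure(x)
  stopifnot(inherits(x, "pep_structure"))
  x$atoms
}

#' RMSD between a model and a reference structure
#'
#' Optimal-superposition RMSD over a named atom selection: `"ca"` (Calpha
#' only, cRMSD), `"backbone"` (N, CA, C, O; bRMSD) or `"heavy"` (all heavy
#' atoms present in both structures, intersected per residue; aRMSD).  Model
#' and reference must have the same residue count; residues are matched in
#' order.
#'
#' @param model a `pep_model` or `pep_structure`.
#' @param reference a `pep_structure` (or `pep_model`).
#' @param selection `"ca"`, `"backbone"` or `"heavy"`.
#' @return RMSD in Angstrom, with attribute `"n_atoms"` (atoms compared) and,
#'   for `"heavy"`, `"n_dropped"` (atoms absent from one side).
#' @export
rmsd_metric <- function(model, reference, selection = c("ca", "backbone", "heavy")) {
  selection <- match.arg(selection)
  am <- structure_atoms_df(model)
  ar <- structure_atoms_df(reference)
  rm_ <- sort(unique(am$res_index))
  rr <- sort(unique(ar$res_index))
  if (length(rm_) != length(rr))
    cyc_error("cycpep_domain_error",
              sprintf("residue counts differ: %d vs %d", length(rm_), length(rr)))
  want <- selection_atoms(selection)
  xa <- list(); xb <- list()
  dropped <- 0
  for (k in seq_along(rm_)) {
    sa <- am[am$res_index == rm_[k] & am$element != "H", , drop = FALSE]
    sb <- ar[ar$res_index == rr[k] & ar$element != "H", , drop = FALSE]
    nms <- if (is.null(want)) intersect(sa$atom, sb$atom) else
      intersect(want, intersect(sa$atom, sb$atom))
    if (is.null(want))
      dropped <- dropped + length(union(sa$atom, sb$atom)) - length(nms)
    else if (length(nms) < length(want))
      cyc_error("cycpep_domain_error",
                sprintf("residue %d misses %s atoms", rm_[k],
                        paste(setdiff(want, nms), collapse = ",")))
    if (length(nms) == 0) next
    xa[[k]] <- as.matrix(sa[match(nms, sa$atom), c("x", "y", "z")])
    xb[[k]] <- as.matrix(sb[match(nms, sb$atom), c("x", "y", "z")])
  }
  A <- do.call(rbind, xa)
  B <- do.call(rbind, xb)
  if (is.null(A) || nrow(A) < 3)
    cyc_error("cycpep_domain_error", "empty (or too small) atom intersection")
  out <- superposed_rmsd(B, A)
  attr(out, "n_atoms") <- nrow(A)
  if (selection == "heavy") attr(out, "n_dropped") <- dropped
  out
}

#' Size-dependent success criterion
#'
#' @param n0 reference length (default 3).
#' @param coefficient Angstrom scale (default 1.0).
#' @return A `success_criterion` list.
#' @export
success_criterion <- function(n0 = 3, coefficient = 1.0) {
  stopifnot(n0 >= 1, coefficient > 0)
  structure(list(n0 = as.integer(n0), coefficient = coefficient),
            class = "success_criterion")
}

#' RMSD cutoff for a successful prediction
#'
#' `coefficient * (1 + ln(n / n0))` Angstrom for a peptide of `n` residues:
#' 1.0 A at the reference length (3 by default), growing logarithmically so
#' that longer peptides get a proportionally looser cutoff.
#'
#' @param n peptide length (must be `>= n0`).
#' @param criterion a [success_criterion()].
#' @return Cutoff in Angstrom.
#' @export
success_cutoff <- function(n, criterion = success_criterion()) {
  if (any(n < criterion$n0))
    cyc_error("cycpep_domain_error", "n must be at least the reference length n0")
  criterion$coefficient * (1 + log(n / criterion$n0))
}

#' Best-of-ensemble accuracy
#'
#' The minimum RMSD to the reference over the first `top_k` models of the
#' ensemble (in generation order); this is the ensemble accuracy measure:
#' the RMSD of the best conformation.
#'
#' @param ensemble a `pep_ensemble` (or plain list of models).
#' @param reference a `pep_structure`.
#' @param selection `"ca"`, `"backbone"` or `"heavy"`.
#' @param top_k number of leading models considered (defaults to all).
#' @return Minimum RMSD in Angstrom.
#' @export
ensemble_accuracy <- function(ensemble, reference,
                              selection = c("ca", "backbone", "heavy"),
                              top_k = NULL) {
  selection <- match.arg(selection)
  models <- if (inherits(ensemble, "pep_ensemble")) ensemble$models else ensemble
  if (length(models) == 0)
    cyc_error("cycpep_domain_error", "ensemble is empty")
  if (is.null(top_k)) top_k <- length(models)
  if (top_k < 1 || top_k > length(models))
    cyc_error("cycpep_domain_error", "top_k must be in [1, ensemble size]")
  min(vapply(models[seq_len(top_k)], function(m)
    as.numeric(rmsd_metric(m, reference, selection)), numeric(1)))
}

#' Evaluate a benchmark of ensembles against references
#'
#' Computes per-peptide best cRMSD/bRMSD/aRMSD over the first `top_k` models,
#' the success flag (best RMSD of the primary metric within
#' [success_cutoff()] of the full peptide length), and per-length-bin
#' aggregates.  Bins are half-open on the left: a peptide of length n falls
#' in bin (a, b] iff a < n <= b.  Cases whose ensemble or reference violate
#' the RMSD preconditions are marked failed and excluded from aggregates.
#'
#' @param cases list of cases, each a list with `id`, `ensemble`,
#'   `reference`.
#' @param bins numeric vector of bin edges, e.g. `c(0, 10, 15, 20, 25, 30)`.
#' @param top_k leading models considered per ensemble.
#' @param criterion a [success_criterion()].
#' @param primary metric driving the success flag (default `"ca"`).
#' @return An `evaluation_report`: list with `rows` (per-peptide
#'   data.frame), `aggregates` (per-bin data.frame incl. an ALL row),
#'   `n_failed`.
#' @export
evaluate_benchmark <- function(cases, bins = c(0, 10, 15, 20, 25, 30),
                               top_k = 100, criterion = success_criterion(),
                               primary = "ca") {
  stopifnot(length(bins) >= 2, !is.unsorted(bins))
  rows <- list()
  n_failed <- 0
  for (cs in cases) {
    models <- if (inherits(cs$ensemble, "pep_ensemble")) cs$ensemble$models else cs$ensemble
    k <- min(top_k, length(models))
    n <- nrow(cs$reference$residues)
    row <- tryCatch({
      best <- vapply(c("ca", "backbone", "heavy"), function(sel)
        ensemble_accuracy(models, cs$reference, sel, top_k = k), numeric(1))
      cutoff <- success_cutoff(n, criterion)
      data.frame(id = cs$id, length = n,
                 best_crmsd = best[["ca"]], best_brmsd = best[["backbone"]],
                 best_armsd = best[["heavy"]], cutoff = cutoff,
                 success = unname(best[[primary_key(primary)]]) <= cutoff,
                 ensemble_size = k, failed = FALSE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = cs$id, length = n, best_crmsd = NA, best_brmsd = NA,
                 best_armsd = NA, cutoff = NA, success = NA,
                 ensemble_size = k, failed = TRUE, stringsAsFactors = FALSE)
    })
    n_failed <- n_failed + row$failed
    rows[[length(rows) + 1]] <- row
  }
  rows <- do.call(rbind, rows)
  ok <- rows[!rows$failed, , drop = FALSE]
  agg <- list()
  bin_of <- cut(ok$length, bins, right = TRUE)
  for (b in levels(bin_of)) {
    sub <- ok[!is.na(bin_of) & bin_of == b, , drop = FALSE]
    if (nrow(sub) == 0) next
    agg[[length(agg) + 1]] <- aggregate_rows(b, sub)
  }
  agg[[length(agg) + 1]] <- aggregate_rows("ALL", ok)
  structure(list(rows = rows, aggregates = do.call(rbind, agg),
                 n_failed = n_failed),
            class = "evaluation_report")
}

primary_key <- function(primary) {
  switch(primary, ca = "ca", backbone = "backbone", heavy = "heavy",
         stop("primary must be 'ca', 'backbone' or 'heavy'"))
}

aggregate_rows <- function(label, sub) {
  data.frame(bin = label, n = nrow(sub),
             mean_crmsd = mean(sub$best_crmsd),
             mean_brmsd = mean(sub$best_brmsd),
             mean_armsd = mean(sub$best_armsd),
             success_rate = 100 * mean(sub$success),
             stringsAsFactors = FALSE)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d peptides (%d failed)\n",
              nrow(x$rows), x$n_failed))
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as tab-separated text
#'
#' Two TSV files: `path` gets the per-peptide rows, and
#' `<path>.aggregates.tsv` the per-bin summary.
#'
#' @param report an `evaluation_report`.
#' @param path output file for the per-peptide table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report$rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(report$aggregates, paste0(path, ".aggregates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
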