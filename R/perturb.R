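#' Perturbation scenario
#'
#' Absolute replacement values (or ranges) for the rates most likely
#' affected by an experimental perturbation.  Range-valued replacements are
#' sub-gridded within each ensemble member and the envelope of predictions
#' reported.
#'
#' @param label scenario name.
#' @param replacements named list; each element a scalar rate (/s; bp/min
#'   for `k6_bp_min`) or a `c(lower, upper)` range.
#' @return An object of class `perturbation_scenario`.
#' @export
perturbation_scenario <- function(label, replacements = list()) {
  nm <- c("k1", "k_rev1", "k2", "k_rev2", "k3", "k_rev3", "k4", "k5",
          "k6_bp_min", "k7")
  bad <- setdiff(names(replacements), nm)
  if (length(bad)) stop("scenario touches unknown rate(s): ",
                        paste(bad, collapse = ", "))
  for (v in replacements)
    if (!all(is.finite(v)) || any(v < 0) || !length(v) %in% 1:2)
      stop("replacements must be non-negative scalars or c(lower, upper)")
  structure(list(label = label, replacements = replacements),
            class = "perturbation_scenario")
}

.scenarios <- list(
  `tfiib-20min` = list(
    STM = list(list(k2 = c(0.004, 0.04)),
               list(k_rev1 = 0.04, k2 = c(0.004, 0.04)),
               list(k1 = 0.0006, k2 = c(0.004, 0.04))),
    TFO = list(list(k3 = 0.0008),
               list(k3 = 0.0008, k_rev3 = c(0, 0.12)))),
  `tfiib-60min` = list(
    STM = list(list(k2 = c(0.002, 0.02)),
               list(k_rev1 = 0.06, k2 = c(0.002, 0.02)),
               list(k1 = 0.0005, k2 = c(0.002, 0.02))),
    TFO = list(list(k3 = 0.0004),
               list(k3 = 0.0004, k_rev3 = c(0, 0.24)))),
  `kin28-cmk` = list(
    STM = list(list(k5 = 0.02),
               list(k5 = 0.02, k_rev3 = c(0, 0.24)),
               list(k5 = 0.02, k_rev1 = 0.06),
               list(k5 = 0.02, k1 = 0.0005)),
    TFO = list(list(k5 = 0.02),
               list(k5 = 0.02, k_rev3 = c(0, 0.24)),
               list(k5 = 0.02, k3 = 0.0005))),
  `gcn4-pd` = list(
    STM = list(list(k_rev3 = c(0, 0.048)),
               list(k2 = c(0.009, 0.09), k_rev3 = c(0, 0.039)))),
  `gcn4-null` = list(
    STM = list(list(k1 = 0.0006))))

#' Packaged perturbation presets
#'
#' Named scenarios for the chemical-genetic perturbations modeled in the
#' study: TFIIB depletion (20 and 60 min), TFIIH kinase inhibition
#' (`kin28-cmk`), and the Gcn4 positioning-domain and null mutants.
#' Several alternative models exist per experiment and gene class
#' (combinations of rate changes that fit the data); select one with
#' `model`.
#'
#' @param name scenario name; see `names(preset_scenarios())`.
#' @param gene_class `"STM"` or `"TFO"`.
#' @param model model number within the experiment/class (1-based).
#' @return A [perturbation_scenario()].
#' @examples
#' preset_scenario("kin28-cmk", "TFO", 1)  # initiation slowed to 0.02 /s
#' @export
preset_scenario <- function(name, gene_class = c("TFO", "STM"), model = 1) {
  gene_class <- match.arg(gene_class)
  if (!name %in% names(.scenarios))
    stop("unknown scenario; available: ",
         paste(names(.scenarios), collapse = ", "))
  cls <- .scenarios[[name]][[gene_class]]
  if (is.null(cls))
    stop("scenario ", name, " has no ", gene_class, " models")
  if (model < 1 || model > length(cls))
    stop("scenario ", name, " ", gene_class, " has models 1..", length(cls))
  perturbation_scenario(paste0(name, "/", gene_class, "/", model),
                        cls[[model]])
}

#' @rdname preset_scenario
#' @export
preset_scenarios <- function() .scenarios

#' Re-simulate an ensemble under a perturbation
#'
#' Each ensemble member is re-simulated with the scenario's replacement
#' rates (range-valued replacements are sub-gridded within the member) and
#' the region-wise change in prediction (perturbed minus baseline) is
#' recorded in empirical units: the member's occupancy-to-CPMn conversion
#' factor is fixed by L2-scaling its baseline prediction to the fitted
#' empirical vector and held for the perturbed prediction, so absolute
#' decreases or increases are preserved.  The ensemble mean, spread, and
#' envelope of the changes are returned.
#'
#' @param ensemble a `model_ensemble` from [grid_search()].
#' @param scenario a [perturbation_scenario()].
#' @param sim optional [sim_config()] override (defaults to the ensemble's).
#' @param subgrid sub-grid points per range-valued replacement.
#' @param max_members re-simulate at most this many top-scoring members.
#' @return A data.frame of class `perturbation_result` with columns
#'   `region`, `delta_mean`, `delta_sd`, `delta_lo`, `delta_hi` (envelope
#'   over members and sub-grids); per-member deltas in attribute
#'   `member_deltas`.
#' @export
apply_perturbation <- function(ensemble, scenario, sim = NULL, subgrid = 3,
                               max_members = 50) {
  stopifnot(inherits(ensemble, "model_ensemble"),
            inherits(scenario, "perturbation_scenario"))
  if (!nrow(ensemble$entries)) stop("empty ensemble")
  if (is.null(sim)) sim <- ensemble$cfg$sim
  gene_class <- ensemble$cfg$gene_class
  arch <- default_architecture(gene_class)
  regions <- region_order(gene_class)
  emp <- ensemble$empirical$values
  members <- ensemble_rates(ensemble)
  n_use <- min(length(members), max_members)

  repl_axes <- lapply(scenario$replacements, function(v)
    if (length(v) == 2) seq(v[1], v[2], length.out = subgrid) else v)
  repl_grid <- if (length(repl_axes))
    expand.grid(repl_axes, KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1)  # identity scenario: one empty replacement

  deltas <- NULL
  for (i in seq_len(n_use)) {
    base_pred <- as.numeric(ensemble$entries[i, regions])
    # occupancy -> empirical-unit conversion fixed by the baseline fit and
    # held for the perturbed prediction, so absolute changes are preserved
    s <- sqrt(sum(emp^2)) / sqrt(sum(base_pred^2))
    for (j in seq_len(nrow(repl_grid))) {
      pr <- update_rates(members[[i]], as.list(repl_grid[j, , drop = FALSE]))
      prof <- simulate_population(pr, arch, sim)
      pv <- as.numeric(aggregate_regions(prof, gene_class)$values)
      deltas <- rbind(deltas, (pv - base_pred) * s)
    }
  }
  colnames(deltas) <- regions
  out <- data.frame(region = regions,
                    delta_mean = colMeans(deltas),
                    delta_sd = apply(deltas, 2, sd),
                    delta_lo = apply(deltas, 2, min),
                    delta_hi = apply(deltas, 2, max),
                    row.names = NULL)
  attr(out, "member_deltas") <- deltas
  attr(out, "scenario") <- scenario$label
  class(out) <- c("perturbation_result", "data.frame")
  out
}

#' Score a modeled perturbation against observed changes
#'
#' Cosine similarity between the model's region-wise change vector and the
#' empirical change vector; unlike occupancy vectors these may be negative,
#' and sign disagreement is penalized (a score of -1 means perfectly
#' opposite changes).
#'
#' @param delta_model,delta_empirical numeric change-per-region vectors
#'   (matching order) or `perturbation_result` objects (the `delta_mean`
#'   column is used).
#' @return A similarity score in `[-1, 1]`.
#' @export
score_perturbation_fit <- function(delta_model, delta_empirical) {
  dm <- if (inherits(delta_model, "perturbation_result"))
    delta_model$delta_mean else as.numeric(delta_model)
  de <- if (inherits(delta_empirical, "perturbation_result"))
    delta_empirical$delta_mean else as.numeric(delta_empirical)
  if (length(dm) != length(de)) stop("change vectors differ in length")
  nm <- sqrt(sum(dm^2)); ne <- sqrt(sum(de^2))
  if (nm == 0 || ne == 0) stop("similarity undefined for a zero vector")
  sum(dm * de) / (nm * ne)
}
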