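#' Transcription-cycle rate set
#'
#' Bundles the ten first-order rates of the transcription-cycle model with a
#' gene-class tag.  Two recruitment routes are modeled: STM genes recruit
#' polymerase to the UAS (`k1`/`k_rev1`) and transfer it to the promoter
#' (`k2`/`k_rev2`); TFO genes recruit polymerase directly to the promoter
#' (`k3`).  In both classes promoter-bound polymerase can dissociate at
#' `k_rev3` until TFIIH arrives (`k4`), after which initiation (`k5`),
#' elongation (`k6`) and terminator release (`k7`) are irreversible.
#'
#' Class-irrelevant rates are forced to zero: for TFO genes the UAS rates
#' (`k1`, `k_rev1`, `k2`, `k_rev2`), and for STM genes the direct promoter
#' recruitment rate `k3`.
#'
#' @param k1 UAS association rate (/s).
#' @param k_rev1 UAS dissociation rate (/s).
#' @param k2 UAS-to-promoter transfer rate (/s); aggregates the requirement
#'   for early general transcription factors.
#' @param k_rev2 promoter-to-UAS reversal rate (/s); only possible before
#'   TFIIH arrival and only when the UAS is empty.
#' @param k3 direct promoter recruitment rate (/s; TFO genes).
#' @param k_rev3 promoter dissociation rate (/s; pre-TFIIH only).
#' @param k4 TFIIH recruitment rate (/s); the committed step.
#' @param k5 initiation / promoter escape rate (/s).
#' @param k6_bp_min elongation rate in bp per minute (stored internally in
#'   bp/s).
#' @param k7 terminator release rate (/s).
#' @param gene_class `"TFO"` or `"STM"` (the internal class `"minimal"` is
#'   used by [minimal_occupancy()]).
#' @return An object of class `rate_set`.
#' @examples
#' rate_set(gene_class = "TFO", k3 = 0.002, k_rev3 = 0.015, k4 = 0.0175)
#' @seealso [default_rates()] for the published standard-growth rates.
#' @export
rate_set <- function(k1 = 0, k_rev1 = 0, k2 = 0, k_rev2 = 0,
                     k3 = 0, k_rev3 = 0, k4 = 0, k5 = 0,
                     k6_bp_min = 1000, k7 = 0,
                     gene_class = c("TFO", "STM", "minimal")) {
  gene_class <- match.arg(gene_class)
  k <- c(k1 = k1, k_rev1 = k_rev1, k2 = k2, k_rev2 = k_rev2, k3 = k3,
         k_rev3 = k_rev3, k4 = k4, k5 = k5, k6_bp_min = k6_bp_min, k7 = k7)
  if (!all(is.finite(k)) || any(k < 0))
    stop("all rates must be finite and non-negative")
  if (gene_class == "TFO") k[c("k1", "k_rev1", "k2", "k_rev2")] <- 0
  if (gene_class == "STM") k["k3"] <- 0
  if (gene_class == "minimal")
    k[c("k1", "k_rev1", "k2", "k_rev2", "k3", "k_rev3", "k4")] <- 0
  out <- as.list(k)
  out$k6 <- k[["k6_bp_min"]] / 60  # bp/s, internal unit
  out$gene_class <- gene_class
  structure(out, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set> gene_class =", x$gene_class, "\n")
  k <- unlist(x[c("k1", "k_rev1", "k2", "k_rev2", "k3", "k_rev3",
                  "k4", "k5", "k7")])
  print(k)
  cat("k6 =", x$k6_bp_min, "bp/min (", format(x$k6, digits = 4), "bp/s )\n")
  invisible(x)
}

#' Update rates in a rate set
#'
#' @param rates a [rate_set()].
#' @param ... named replacement values among `k1`, `k_rev1`, `k2`, `k_rev2`,
#'   `k3`, `k_rev3`, `k4`, `k5`, `k6_bp_min`, `k7`.
#' @return A new `rate_set` with the replacements applied.
#' @export
update_rates <- function(rates, ...) {
  repl <- list(...)
  if (length(repl) && is.list(repl[[1]]) && is.null(names(repl)))
    repl <- repl[[1]]
  nm <- c("k1", "k_rev1", "k2", "k_rev2", "k3", "k_rev3", "k4", "k5",
          "k6_bp_min", "k7")
  bad <- setdiff(names(repl), nm)
  if (length(bad)) stop("unknown rate(s): ", paste(bad, collapse = ", "))
  args <- modifyList(rates[nm], repl)
  args$gene_class <- rates$gene_class
  do.call(rate_set, args)
}

#' Gene compartment architecture
#'
#' The transcribed region is modeled as `n_transcript_bins` identical
#' compartments of `compartment_length` bp (1200 bp at the defaults);
#' the UAS (STM genes only), promoter, and terminator are each a single
#' compartment of the same length.
#'
#' @param compartment_length compartment size in bp (default 120).
#' @param n_transcript_bins number of transcript compartments (default 10).
#' @param has_uas does the gene have a UAS compartment? (`TRUE` for STM).
#' @param has_terminator include a terminator compartment (default `TRUE`).
#' @return An object of class `gene_architecture`.
#' @export
gene_architecture <- function(compartment_length = 120,
                              n_transcript_bins = 10,
                              has_uas = FALSE, has_terminator = TRUE) {
  stopifnot(compartment_length > 0, n_transcript_bins >= 1,
            is.logical(has_uas), is.logical(has_terminator))
  if (!has_terminator)
    stop("architectures without a terminator compartment are not supported")
  structure(list(compartment_length = compartment_length,
                 n_transcript_bins = as.integer(n_transcript_bins),
                 has_uas = has_uas, has_terminator = TRUE),
            class = "gene_architecture")
}

#' @export
print.gene_architecture <- function(x, ...) {
  cat("<gene_architecture>", if (x$has_uas) "UAS +" else "",
      "promoter +", x$n_transcript_bins, "x", x$compartment_length,
      "bp transcript bins + terminator\n")
  invisible(x)
}

#' Default architecture for a gene class
#' @param gene_class `"TFO"`, `"STM"` or `"minimal"`.
#' @param ... passed to [gene_architecture()].
#' @return A `gene_architecture` with the UAS flag set for STM genes.
#' @export
default_architecture <- function(gene_class = c("TFO", "STM", "minimal"), ...) {
  gene_class <- match.arg(gene_class)
  gene_architecture(has_uas = gene_class == "STM", ...)
}

#' Compartment labels for an architecture
#' @param arch a [gene_architecture()].
#' @return Character vector of compartment names in gene order.
#' @export
compartment_labels <- function(arch) {
  c(if (arch$has_uas) "UAS", "promoter",
    paste0("bin_", seq_len(arch$n_transcript_bins)), "terminator")
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: 1000 s runs, occupancy averaged
#' over the final 60 s, 100,000 gene replicates.
#'
#' @param t_total simulated time in seconds.
#' @param measure_window two-element interval (seconds) over which
#'   time-averaged occupancy is recorded; must lie within `[0, t_total]`.
#' @param n_genes number of independent gene replicates.
#' @param seed master seed; per-gene streams are derived from
#'   (seed, gene index).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(t_total = 1000, measure_window = c(940, 1000),
                       n_genes = 100000, seed = 1) {
  stopifnot(length(measure_window) == 2, t_total > 0,
            measure_window[1] >= 0, measure_window[2] <= t_total,
            measure_window[1] < measure_window[2], n_genes >= 1)
  structure(list(t_total = t_total,
                 measure_window = as.numeric(measure_window),
                 n_genes = as.integer(n_genes), seed = as.numeric(seed)),
            class = "sim_config")
}

#' Elongation hop rate between compartments
#'
#' Converts an elongation rate in bp/min into the per-second rate at which a
#' polymerase advances one compartment.
#'
#' @param k6_bp_per_min elongation rate, bp per minute.
#' @param compartment_length compartment size in bp.
#' @return Hop rate in /s: `(k6_bp_per_min / 60) / compartment_length`.
#' @examples
#' hop_rate(1000, 120)  # 0.1389 /s
#' @export
hop_rate <- function(k6_bp_per_min, compartment_length) {
  if (!is.finite(k6_bp_per_min) || k6_bp_per_min <= 0)
    stop("elongation rate must be positive")
  if (!is.finite(compartment_length) || compartment_length <= 0)
    stop("compartment length must be positive")
  (k6_bp_per_min / 60) / compartment_length
}

# ---- published rate presets -------------------------------------------------

.fixed_rates <- list(k1 = 0.002, k_rev1 = 0.003, k3 = 0.002, k5 = 0.1,
                     k6_bp_min = 1000, k7 = 0.0325)

.free_ranges <- list(
  chec = list(k2 = c(0.03, 0.1), k_rev2 = c(0, 0.07),
              k_rev3 = c(0, 0.03), k4 = c(0.0075, 0.0275)),
  chip = list(k2 = c(0.03, 0.1), k_rev2 = c(0, 0.1),
              k_rev3 = c(0, 0.03), k4 = c(0.025, 0.1)),
  gcn4 = list(k2 = c(0.03, 0.1), k_rev2 = c(0, 0.04),
              k_rev3 = c(0, 0.03), k4 = c(0.01, 0.03)))

#' Functional ranges of the free rates
#'
#' The free (fitted) rates and their search ranges for each empirical
#' dataset.  STM fits free `k2`, `k_rev2`, `k_rev3` and `k4`; TFO fits,
#' which have no UAS, free only `k_rev3` and `k4`.
#'
#' @param gene_class `"STM"` or `"TFO"`.
#' @param dataset `"chec"` (standard growth ChEC), `"chip"` (standard growth
#'   ChIP) or `"gcn4"`.
#' @return Named list of `c(lower, upper)` ranges (/s).
#' @export
functional_ranges <- function(gene_class = c("STM", "TFO"),
                              dataset = c("chec", "chip", "gcn4")) {
  gene_class <- match.arg(gene_class)
  dataset <- match.arg(dataset)
  r <- .free_ranges[[dataset]]
  if (gene_class == "TFO") r <- r[c("k_rev3", "k4")]
  r
}

#' Published standard-growth rate set
#'
#' Fixed rates from the literature (UAS association/dissociation, direct
#' promoter recruitment, initiation via TFIIH residency, 1 kb/min
#' elongation, 30 s terminator pause) with free rates set to the midpoints
#' of their functional ranges unless overridden.
#'
#' @inheritParams functional_ranges
#' @param ... overrides for any rate (see [rate_set()]).
#' @return A [rate_set()].
#' @examples
#' default_rates("TFO")
#' default_rates("STM", k_rev3 = 0.01)
#' @export
default_rates <- function(gene_class = c("TFO", "STM"),
                          dataset = c("chec", "chip", "gcn4"), ...) {
  gene_class <- match.arg(gene_class)
  dataset <- match.arg(dataset)
  free <- lapply(functional_ranges(gene_class, dataset), mean)
  args <- modifyList(c(.fixed_rates, free), list(...))
  args$gene_class <- gene_class
  do.call(rate_set, args)
}

#' Rate set forced to reproduce ChIP-like occupancy
#'
#' The published rates cannot reproduce the transcript-dominated occupancy
#' seen by ChIP.  This preset applies the modifications that can: no
#' promoter dissociation (`k_rev3 = 0`), effectively instantaneous TFIIH
#' recruitment (`k4` set to a large finite cap), doubled initiation
#' (`k5 = 0.2`/s) and a termination rate of 0.14/s.
#'
#' @param gene_class `"TFO"` or `"STM"`.
#' @param k4_cap finite stand-in for instantaneous TFIIH recruitment (/s).
#' @return A [rate_set()].
#' @export
chip_forced_rates <- function(gene_class = c("TFO", "STM"), k4_cap = 10) {
  gene_class <- match.arg(gene_class)
  default_rates(gene_class, dataset = "chip",
                k_rev3 = 0, k4 = k4_cap, k5 = 0.2, k7 = 0.14)
}
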