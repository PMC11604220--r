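#' Parameters of the minimal promoter/elongation/terminator model
#'
#' A reduced model used to ask whether published dwell times alone predict
#' promoter and terminator enrichment relative to the transcribed region:
#' a polymerase is assumed to be immediately present at the promoter
#' (instantaneous refill after escape), escapes into the transcript at a
#' rate inverse to the promoter dwell time (gated on bin 1 being empty),
#' elongates across the bins, and pauses at the terminator with release
#' rate inverse to the termination dwell.
#'
#' @param promoter_dwell promoter dwell time, seconds.
#' @param elongation_rate elongation rate, bp per minute.
#' @param termination_dwell terminator dwell time, seconds.
#' @param gene_length transcribed length, bp (default 1200; must be a
#'   multiple of `compartment_length`).
#' @param compartment_length compartment size in bp (default 120).
#' @return An object of class `minimal_params`.
#' @export
minimal_params <- function(promoter_dwell, elongation_rate, termination_dwell,
                           gene_length = 1200, compartment_length = 120) {
  stopifnot(promoter_dwell > 0, elongation_rate > 0, termination_dwell > 0,
            gene_length > 0, compartment_length > 0)
  if (gene_length %% compartment_length != 0)
    stop("gene_length must be divisible by compartment_length")
  structure(list(promoter_dwell = promoter_dwell,
                 elongation_rate = elongation_rate,
                 termination_dwell = termination_dwell,
                 gene_length = gene_length,
                 compartment_length = compartment_length),
            class = "minimal_params")
}

minimal_rates_arch <- function(params) {
  list(rates = rate_set(k5 = 1 / params$promoter_dwell,
                        k6_bp_min = params$elongation_rate,
                        k7 = 1 / params$termination_dwell,
                        gene_class = "minimal"),
       arch = gene_architecture(
         compartment_length = params$compartment_length,
         n_transcript_bins = params$gene_length %/% params$compartment_length))
}

#' Simulate the minimal model
#'
#' @param params a [minimal_params()].
#' @param cfg a [sim_config()].
#' @param engine `"compiled"` Gillespie simulation or `"exact"` stationary
#'   occupancy from the Markov-chain oracle (standard errors zero).
#' @return An `occupancy_profile` over promoter, transcript bins, and
#'   terminator.
#'
#' @details Because the promoter refills instantaneously, its compartment
#' flag is trivially always set; the reported promoter occupancy is
#' instead the occupancy attributable to productively cycling polymerase,
#' escape flux times dwell time (Little's law).  Since the escape rate is
#' `1/promoter_dwell` gated on bin 1, this equals the probability that
#' bin 1 is empty, `1 - occ(bin_1)`: near 1 in the free-flowing regime and
#' small when the gene is congested.  Transcript-bin and terminator
#' occupancies are plain time averages (for which the two accountings
#' coincide).
#' @export
minimal_occupancy <- function(params, cfg, engine = c("compiled", "exact")) {
  engine <- match.arg(engine)
  ra <- minimal_rates_arch(params)
  prof <- if (engine == "exact") {
    occ <- ctmc_stationary_occupancy(ra$rates, ra$arch)
    new_occupancy_profile(names(occ), as.numeric(occ),
                          rep(0, length(occ)), Inf,
                          c(0, Inf), list(exact = TRUE))
  } else {
    simulate_population(ra$rates, ra$arch, cfg)
  }
  # flux x dwell accounting for the promoter (see Details)
  prof$mean[["promoter"]] <- 1 - prof$mean[["bin_1"]]
  prof$se[["promoter"]] <- prof$se[["bin_1"]]
  prof
}

#' Sweep the minimal model over a parameter grid
#'
#' For each combination the per-region occupancies are computed and two
#' flags recorded: promoter occupancy above the mean transcript-bin
#' occupancy, and terminator occupancy above the mean transcript-bin
#' occupancy.  With the stochastic engine a flag is set only when the
#' difference exceeds twice its Monte-Carlo standard error; with the exact
#' engine the comparison is direct.
#'
#' @param grid a list of [minimal_params()] or a data.frame with columns
#'   `promoter_dwell`, `elongation_rate`, `termination_dwell`.
#' @param cfg a [sim_config()].
#' @param engine see [minimal_occupancy()].
#' @return A data.frame, one row per combination: the parameters, promoter
#'   / mean transcript / terminator occupancy, and the two flags.
#' @export
sweep_minimal <- function(grid, cfg, engine = c("compiled", "exact")) {
  engine <- match.arg(engine)
  if (is.data.frame(grid))
    grid <- lapply(seq_len(nrow(grid)), function(i)
      minimal_params(grid$promoter_dwell[i], grid$elongation_rate[i],
                     grid$termination_dwell[i]))
  if (!length(grid)) stop("empty parameter grid")
  rows <- lapply(grid, function(p) {
    prof <- minimal_occupancy(p, cfg, engine)
    bins <- grep("^bin_", prof$compartments)
    m_tx <- mean(prof$mean[bins])
    se_tx <- if (engine == "exact") 0 else
      sqrt(sum(prof$se[bins]^2)) / length(bins)
    d_prom <- prof$mean[["promoter"]] - m_tx
    d_term <- prof$mean[["terminator"]] - m_tx
    se_prom <- sqrt(prof$se[["promoter"]]^2 + se_tx^2)
    se_term <- sqrt(prof$se[["terminator"]]^2 + se_tx^2)
    data.frame(promoter_dwell = p$promoter_dwell,
               elongation_rate = p$elongation_rate,
               termination_dwell = p$termination_dwell,
               promoter_occ = prof$mean[["promoter"]],
               transcript_occ = m_tx,
               terminator_occ = prof$mean[["terminator"]],
               promoter_above_transcript = d_prom > 2 * se_prom,
               terminator_above_transcript = d_term > 2 * se_term)
  })
  do.call(rbind, rows)
}

#' Default minimal-model sweep grid
#'
#' Crosses the literature ranges for promoter dwell (5-20 s), elongation
#' (1000-3000 bp/min), and termination pause (5-70 s).
#'
#' @param promoter_dwell,elongation_rate,termination_dwell vectors of values
#'   to cross.
#' @return A data.frame grid suitable for [sweep_minimal()].
#' @export
minimal_grid <- function(promoter_dwell = c(5, 10, 20),
                         elongation_rate = c(1000, 2000, 3000),
                         termination_dwell = c(5, 30, 70)) {
  expand.grid(promoter_dwell = promoter_dwell,
              elongation_rate = elongation_rate,
              termination_dwell = termination_dwell)
}
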