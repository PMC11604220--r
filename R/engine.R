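rates_vector <- function(rates, arch) {
  cls_code <- match(rates$gene_class, c("TFO", "STM", "minimal")) - 1L
  c(rates$k1, rates$k_rev1, rates$k2, rates$k_rev2, rates$k3, rates$k_rev3,
    rates$k4, rates$k5, rates$k6 / arch$compartment_length, rates$k7,
    cls_code)
}

new_occupancy_profile <- function(labels, mean, se, n_genes, window, events) {
  structure(list(compartments = labels,
                 mean = setNames(mean, labels),
                 se = setNames(se, labels),
                 n_genes = n_genes, window = window, events = events),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("<occupancy_profile>", x$n_genes, "genes, window [",
      x$window[1], ",", x$window[2], "] s\n")
  print(data.frame(compartment = x$compartments,
                   occupancy = unname(x$mean), se = unname(x$se)))
  cat("events:", paste(names(x$events), unlist(x$events), sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}

#' Simulate one gene with the Gillespie algorithm
#'
#' Exact stochastic simulation of a single model gene.  Occupancy is the
#' time-weighted fraction of the measurement window each compartment is
#' occupied (promoter occupancy counts both pre- and post-TFIIH
#' sub-states); event counts cover the full run.  The trajectory is
#' reproducible: the random stream is derived from
#' `(cfg$seed, gene_index)`, so gene `i` here is identical to gene `i` of
#' [simulate_population()] under the same configuration.
#'
#' @param rates a [rate_set()].
#' @param arch a [gene_architecture()] consistent with the gene class.
#' @param cfg a [sim_config()].
#' @param gene_index stream index (1-based).
#' @return A list with `occupancy` (named vector), `events`
#'   (recruitments, initiations, terminations) and `n_events`.
#' @export
simulate_gene <- function(rates, arch, cfg, gene_index = 1) {
  check_consistent(rates$gene_class, arch, rates)
  stopifnot(inherits(cfg, "sim_config"), gene_index >= 1)
  res <- .cpp_simulate(rates_vector(rates, arch), arch$n_transcript_bins,
                       arch$has_uas, cfg$t_total, cfg$measure_window[1],
                       cfg$measure_window[2], 1L, cfg$seed,
                       as.integer(gene_index) - 1L, FALSE)
  if (res$exclusion_violations > 0) stop("exclusion invariant violated")
  list(occupancy = setNames(res$mean, compartment_labels(arch)),
       events = list(recruitments = res$recruitments,
                     initiations = res$initiations,
                     terminations = res$terminations,
                     window_initiations = res$window_initiations,
                     window_terminations = res$window_terminations),
       n_events = res$n_events)
}

#' Simulate a gene population
#'
#' Runs [simulate_gene()] across `cfg$n_genes` independent replicates
#' (genes) and reports per-compartment mean time-averaged occupancy with
#' Monte-Carlo standard errors, plus summed event tallies.  Per-gene random
#' streams are derived deterministically from the master seed, so results
#' do not depend on execution order.
#'
#' @inheritParams simulate_gene
#' @param engine `"compiled"` (default) or `"reference"`, the pure-R
#'   implementation built directly on [list_transitions()].  The reference
#'   engine is orders of magnitude slower and intended for validation.
#' @return An `occupancy_profile`: compartment labels, mean occupancy in
#'   `[0, 1]`, standard errors, `n_genes`, measurement window, and event
#'   totals (`recruitments`, `initiations`, `terminations`; terminations
#'   equal the number of mRNAs produced).
#' @examples
#' p <- simulate_population(default_rates("TFO"), default_architecture("TFO"),
#'                          sim_config(n_genes = 200, seed = 1))
#' p$mean
#' @export
simulate_population <- function(rates, arch, cfg,
                                engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  check_consistent(rates$gene_class, arch, rates)
  stopifnot(inherits(cfg, "sim_config"))
  labels <- compartment_labels(arch)
  if (engine == "reference") {
    occ <- matrix(0, cfg$n_genes, length(labels))
    ev <- c(recruitments = 0, initiations = 0, terminations = 0)
    nev <- 0
    for (g in seq_len(cfg$n_genes)) {
      r <- simulate_gene_ref(rates, arch, cfg, g)
      occ[g, ] <- r$occupancy
      ev <- ev + unlist(r$events)
      nev <- nev + r$n_events
    }
    m <- colMeans(occ)
    se <- if (cfg$n_genes > 1) apply(occ, 2, sd) / sqrt(cfg$n_genes)
          else rep(NA_real_, length(labels))
    return(new_occupancy_profile(labels, m, se, cfg$n_genes,
                                 cfg$measure_window,
                                 c(as.list(ev), n_events = nev)))
  }
  res <- .cpp_simulate(rates_vector(rates, arch), arch$n_transcript_bins,
                       arch$has_uas, cfg$t_total, cfg$measure_window[1],
                       cfg$measure_window[2], cfg$n_genes, cfg$seed, 0L,
                       FALSE)
  if (res$exclusion_violations > 0) stop("exclusion invariant violated")
  new_occupancy_profile(labels, res$mean, res$se, cfg$n_genes,
                        cfg$measure_window,
                        list(recruitments = res$recruitments,
                             initiations = res$initiations,
                             terminations = res$terminations,
                             window_initiations = res$window_initiations,
                             window_terminations = res$window_terminations,
                             n_events = res$n_events))
}

# Pure-R single-gene Gillespie built directly on list_transitions();
# the validation counterpart of the compiled engine.  Uses R's RNG
# (seeded from cfg$seed and the gene index), restoring the caller's seed.
simulate_gene_ref <- function(rates, arch, cfg, gene_index = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((cfg$seed * 1000003 + gene_index) %% .Machine$integer.max)
  state <- transcription_state(arch, rates$gene_class)
  labels <- compartment_labels(arch)
  occ <- setNames(numeric(length(labels)), labels)
  w <- cfg$measure_window
  ev <- c(recruitments = 0, initiations = 0, terminations = 0)
  n_events <- 0
  t <- 0
  repeat {
    tr <- list_transitions(state, rates, arch)
    A <- sum(tr$propensity)
    t2 <- if (A <= 0) cfg$t_total else t + stats::rexp(1, A)
    lo <- max(t, w[1]); hi <- min(t2, w[2])
    if (hi > lo) {
      occup <- c(if (arch$has_uas) isTRUE(state$uas_occupied),
                 state$promoter_state != "EMPTY",
                 state$transcript_occupancy, state$terminator_occupied)
      occ <- occ + occup * (hi - lo)
    }
    if (A <= 0 || t2 >= cfg$t_total) break
    t <- t2
    i <- sample.int(nrow(tr), 1, prob = tr$propensity)
    e <- tr$event[i]
    n_events <- n_events + 1
    if (e %in% c("uas_recruit", "promoter_recruit"))
      ev["recruitments"] <- ev["recruitments"] + 1
    if (e == "initiation") ev["initiations"] <- ev["initiations"] + 1
    if (e == "terminator_release") ev["terminations"] <- ev["terminations"] + 1
    state <- apply_event(state, e, rates$gene_class)
  }
  list(occupancy = occ / diff(w), events = as.list(ev), n_events = n_events)
}

#' Write an occupancy profile as TSV
#' @param profile an `occupancy_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(profile, path) {
  df <- data.frame(compartment = profile$compartments,
                   occupancy = unname(profile$mean),
                   se = unname(profile$se))
  write.table(format(df, digits = 12), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
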