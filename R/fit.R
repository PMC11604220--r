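#' Grid-search fitting configuration
#'
#' @param gene_class `"STM"` (free rates `k2`, `k_rev2`, `k_rev3`, `k4`) or
#'   `"TFO"` (free rates `k_rev3`, `k4`).
#' @param ranges named list of `c(lower, upper)` search ranges for the free
#'   rates; defaults to the functional ranges of [functional_ranges()].
#' @param resolution grid points per free rate (scalar or named vector,
#'   minimum 2).
#' @param threshold ensemble inclusion threshold on cosine similarity
#'   (default 0.995); must lie in `(-1, 1]`.
#' @param fallback_top_n when no grid point reaches the threshold, report
#'   the best `fallback_top_n` models with the fallback flag set (the
#'   situation met when fitting ChIP-like shapes).
#' @param sim a [sim_config()] used for every grid point (common random
#'   numbers across points).
#' @param fixed a [rate_set()] supplying the fixed rates.
#' @param dataset preset tag used when `ranges`/`fixed` are defaulted.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(gene_class = c("TFO", "STM"), ranges = NULL,
                       resolution = 10, threshold = 0.995,
                       fallback_top_n = 20, sim = sim_config(),
                       fixed = NULL, dataset = c("chec", "chip", "gcn4")) {
  gene_class <- match.arg(gene_class)
  dataset <- match.arg(dataset)
  if (is.null(ranges)) ranges <- functional_ranges(gene_class, dataset)
  free <- if (gene_class == "STM") c("k2", "k_rev2", "k_rev3", "k4")
          else c("k_rev3", "k4")
  if (!setequal(names(ranges), free))
    stop("ranges must name exactly the free rates: ",
         paste(free, collapse = ", "))
  for (r in ranges)
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0)
      stop("each range must be c(lower, upper) with 0 <= lower <= upper")
  if (length(resolution) == 1) resolution <- setNames(rep(resolution,
                                                          length(free)), free)
  if (any(resolution < 2)) stop("resolution must be at least 2 per rate")
  if (threshold <= -1 || threshold > 1)
    stop("threshold must lie in (-1, 1]")
  if (is.null(fixed)) fixed <- default_rates(gene_class, dataset)
  stopifnot(inherits(sim, "sim_config"))
  structure(list(gene_class = gene_class, ranges = ranges[free],
                 resolution = resolution[free], threshold = threshold,
                 fallback_top_n = fallback_top_n, sim = sim, fixed = fixed),
            class = "fit_config")
}

#' Ensemble grid search against an empirical region vector
#'
#' Simulates every point of the Cartesian grid over the free-rate ranges,
#' aggregates each prediction into gene regions, and scores it against the
#' empirical vector with [cosine_similarity()].  All models whose score
#' reaches the threshold form the ensemble; if none do, the top
#' `fallback_top_n` models are returned with the fallback flag set.  The
#' ensemble-average prediction is the mean of the members' L2-scaled
#' region vectors.  Results are deterministic given the simulation seed.
#'
#' @param empirical a [region_vector()] (e.g. CPMn region means).
#' @param cfg a [fit_config()] with matching gene class.
#' @return An object of class `model_ensemble`: `entries` (data.frame of
#'   free rates, score, and per-region predictions, sorted by descending
#'   score), `threshold`, `fallback`, `average` (ensemble-average
#'   [region_vector()] in empirical units), `empirical`, and `cfg`.
#' @export
grid_search <- function(empirical, cfg) {
  stopifnot(inherits(empirical, "region_vector"), inherits(cfg, "fit_config"))
  if (empirical$gene_class != cfg$gene_class)
    stop("empirical gene_class does not match the fit configuration")
  axes <- lapply(names(cfg$ranges), function(p)
    seq(cfg$ranges[[p]][1], cfg$ranges[[p]][2],
        length.out = cfg$resolution[[p]]))
  names(axes) <- names(cfg$ranges)
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("empty grid")
  arch <- default_architecture(cfg$gene_class)
  regions <- region_order(cfg$gene_class)
  pred <- matrix(NA_real_, nrow(grid), length(regions),
                 dimnames = list(NULL, regions))
  score <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rates <- update_rates(cfg$fixed, as.list(grid[i, , drop = FALSE]))
    prof <- simulate_population(rates, arch, cfg$sim)
    rv <- aggregate_regions(prof, cfg$gene_class)
    pred[i, ] <- rv$values
    score[i] <- cosine_similarity(rv, empirical)
  }
  pass <- which(score >= cfg$threshold)
  fallback <- length(pass) == 0
  sel <- if (fallback) order(score, decreasing = TRUE)[
    seq_len(min(cfg$fallback_top_n, length(score)))]
  else pass[order(score[pass], decreasing = TRUE)]
  entries <- cbind(grid[sel, , drop = FALSE], score = score[sel],
                   as.data.frame(pred[sel, , drop = FALSE]))
  rownames(entries) <- NULL
  scaled <- t(apply(pred[sel, , drop = FALSE], 1, l2_scale,
                    empirical = empirical$values))
  avg <- region_vector(colMeans(scaled), cfg$gene_class,
                       units = empirical$units)
  structure(list(entries = entries, threshold = cfg$threshold,
                 fallback = fallback, average = avg,
                 empirical = empirical, cfg = cfg),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("<model_ensemble>", nrow(x$entries), "models",
      if (x$fallback) "(fallback: threshold not reached)"
      else paste0("(score >= ", x$threshold, ")"), "\n")
  cat("best score:", format(max(x$entries$score), digits = 6), "\n")
  print(utils::head(x$entries, 5))
  invisible(x)
}

#' Member rate sets of an ensemble
#' @param ensemble a `model_ensemble`.
#' @return List of [rate_set()]s, one per entry, fixed rates filled in.
#' @export
ensemble_rates <- function(ensemble) {
  free <- names(ensemble$cfg$ranges)
  lapply(seq_len(nrow(ensemble$entries)), function(i)
    update_rates(ensemble$cfg$fixed,
                 as.list(ensemble$entries[i, free, drop = FALSE])))
}

#' Write / read ensembles and region vectors as TSV
#'
#' Region-vector files have columns `gene_class`, `region`, `value`
#' (and optionally `se`); ensemble files carry one row per member.
#'
#' @param x object to write.
#' @param path file path.
#' @return `path` (writers) or the reconstructed object (readers).
#' @export
write_ensemble_tsv <- function(x, path) {
  stopifnot(inherits(x, "model_ensemble"))
  write.table(format(x$entries, digits = 10), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_tsv
#' @param units unit tag for the values read.
#' @export
read_region_tsv <- function(path, units = "CPMn") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_class", "region", "value") %in% names(df)))
    stop("region TSV must have columns gene_class, region, value")
  cls <- unique(df$gene_class)
  if (length(cls) != 1) stop("region TSV must contain a single gene class")
  region_vector(setNames(df$value, df$region), cls, units = units)
}

#' @rdname write_ensemble_tsv
#' @export
write_region_tsv <- function(x, path) {
  stopifnot(inherits(x, "region_vector"))
  df <- data.frame(gene_class = x$gene_class, region = x$regions,
                   value = unname(x$values))
  write.table(format(df, digits = 12), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
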