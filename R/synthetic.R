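with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

#' Replicate-noise specification
#'
#' Emulates between-replicate variability of region-level signal.  The
#' default, multiplicative gaussian noise on region values, matches the
#' form in which the empirical data enter the fit (region-level replicate
#' means); `poisson-counts-then-cpm` draws counts at a given depth for
#' end-to-end tests of count-derived signal.
#'
#' @param model `"none"`, `"gaussian-on-regions"` or
#'   `"poisson-counts-then-cpm"`.
#' @param amplitude relative SD (gaussian) or total count depth (poisson).
#' @param n_replicates number of replicates (default 3, as in a typical
#'   ChEC experiment).
#' @param seed RNG seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("gaussian-on-regions", "none",
                                 "poisson-counts-then-cpm"),
                       amplitude = 0.05, n_replicates = 3, seed = 1) {
  model <- match.arg(model)
  stopifnot(amplitude >= 0, n_replicates >= 1)
  structure(list(model = model, amplitude = amplitude,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "noise_spec")
}

#' Synthetic empirical region vectors with known ground truth
#'
#' Simulates the true occupancy under `true_rates`, aggregates it into
#' regions, applies replicate noise, and converts to a pseudo-CPMn
#' magnitude with a single L2-based scale factor (the one that gives the
#' noise-free vector the norm `target_norm`), so the relative replicate
#' noise survives the unit change.  The ground truth (rates and noise-free
#' vector) is returned alongside, enabling parameter-recovery tests.
#'
#' @param true_rates a [rate_set()].
#' @param arch a [gene_architecture()]; defaults to the class default.
#' @param cfg a [sim_config()].
#' @param noise a [noise_spec()].
#' @param target_norm L2 norm given to each replicate (pseudo-CPMn units).
#' @return A list: `replicates` (list of [region_vector()]s), `mean`
#'   (replicate-average region vector), `truth` (list with `rates`,
#'   `occupancy` region vector, and `scaled` noise-free pseudo-CPMn
#'   vector).
#' @export
synth_region_vectors <- function(true_rates, arch = NULL, cfg = sim_config(),
                                 noise = noise_spec(), target_norm = 100) {
  if (is.null(arch)) arch <- default_architecture(true_rates$gene_class)
  prof <- simulate_population(true_rates, arch, cfg)
  truth <- aggregate_regions(prof, true_rates$gene_class)
  v <- truth$values
  if (all(v == 0)) stop("true rates produce zero occupancy everywhere")
  # one common occupancy -> pseudo-CPMn conversion factor (from the truth),
  # so replicate noise structure is preserved by the unit change
  scale_to <- function(x) x * target_norm / sqrt(sum(v^2))
  reps <- with_local_seed(noise$seed, {
    lapply(seq_len(noise$n_replicates), function(r) {
      w <- switch(noise$model,
        none = v,
        `gaussian-on-regions` =
          pmax(v * (1 + rnorm(length(v), 0, noise$amplitude)), 0),
        `poisson-counts-then-cpm` =
          rpois(length(v), v / sum(v) * noise$amplitude))
      if (all(w == 0)) w <- v  # degenerate draw: fall back to truth shape
      region_vector(scale_to(setNames(w, names(v))), true_rates$gene_class,
                    units = "pseudo-CPMn")
    })
  })
  mean_v <- Reduce(`+`, lapply(reps, function(r) r$values)) / length(reps)
  list(replicates = reps,
       mean = region_vector(mean_v, true_rates$gene_class,
                            units = "pseudo-CPMn"),
       truth = list(rates = true_rates, occupancy = truth,
                    scaled = region_vector(scale_to(v),
                                           true_rates$gene_class,
                                           units = "pseudo-CPMn")))
}

#' Synthetic genome fixture specification
#'
#' Describes a small single-contig genome whose coverage is constructed so
#' that every gene's four regions have exactly specified per-base means
#' and every site carries a specified oriented profile, giving exact
#' ground truth for [region_signal()], [metagene()] and [metasite()].
#'
#' @param n_genes number of genes (strands alternate).
#' @param gene_span TSS-to-TES distance in bp (default 1200).
#' @param region_means length-4 vector (UAS, promoter, transcript,
#'   terminator per-bp means) or an `n_genes` x 4 matrix.
#' @param baseline coverage value outside regions and site windows.
#' @param n_sites number of oriented point sites.
#' @param site_profile signal over `[-site_flank, +site_flank]` around each
#'   site (default: a triangular peak).
#' @param site_flank half-window of the site profile.
#' @param nascent per-gene replicate-mean nascent counts (recycled).
#' @param contig_length optional; computed from the layout when `NULL` and
#'   validated for feasibility otherwise.
#' @param seed recorded in the manifest.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 6, gene_span = 1200,
                         region_means = c(2, 4, 6, 8), baseline = 0,
                         n_sites = 4, site_profile = NULL, site_flank = 250,
                         nascent = 100, contig_length = NULL, seed = 1) {
  stopifnot(n_genes >= 1, gene_span >= 102)
  if (is.null(site_profile)) {
    off <- -site_flank:site_flank
    site_profile <- pmax(0, 1 - abs(off) / 50) * 10
  }
  if (length(site_profile) != 2 * site_flank + 1)
    stop("site_profile must have length 2 * site_flank + 1")
  if (is.matrix(region_means)) {
    if (!all(dim(region_means) == c(n_genes, 4)))
      stop("region_means matrix must be n_genes x 4")
  } else if (length(region_means) == 4) {
    region_means <- matrix(region_means, n_genes, 4, byrow = TRUE)
  } else stop("region_means must have 4 values (UAS, promoter, transcript, terminator)")
  colnames(region_means) <- c("UAS", "promoter", "transcript", "terminator")
  margin <- 1600  # > metagene flank (1000) and UAS extent (500)
  pitch <- gene_span + 2 * margin
  site_pitch <- 2 * site_flank + 600
  needed <- n_genes * pitch + n_sites * site_pitch + margin
  if (is.null(contig_length)) contig_length <- needed
  if (contig_length < needed)
    stop("contig_length ", contig_length, " cannot fit the layout (needs ",
         needed, ")")
  structure(list(n_genes = n_genes, gene_span = gene_span,
                 region_means = region_means, baseline = baseline,
                 n_sites = n_sites, site_profile = site_profile,
                 site_flank = site_flank,
                 nascent = rep_len(nascent, n_genes),
                 contig_length = contig_length, margin = margin,
                 pitch = pitch, site_pitch = site_pitch, seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic genome fixture
#'
#' Builds the annotation, coverage and site tables described by a
#' [fixture_spec()], optionally writing them to disk as plain-text files
#' (bedGraph coverage, BED6 genes and sites, TSV nascent counts and
#' ground-truth region means, YAML manifest).
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (`NULL` to skip writing).
#' @return A list: `track` ([coverage_track()]), `genes`
#'   ([gene_annotation()]), `regions` (`region_set`), `sites` (data.frame),
#'   `truth` (per-gene region means), and `paths` when written.
#' @export
synth_genome_fixture <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  ctg <- "chrS"
  cov <- rep(spec$baseline, spec$contig_length)

  strands <- rep(c("+", "-"), length.out = spec$n_genes)
  tss <- tes <- integer(spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    slot0 <- (i - 1) * spec$pitch
    if (strands[i] == "+") {
      tss[i] <- slot0 + spec$margin + 1
      tes[i] <- tss[i] + spec$gene_span
    } else {
      tss[i] <- slot0 + spec$margin + 1 + spec$gene_span
      tes[i] <- tss[i] - spec$gene_span
    }
  }
  genes <- gene_annotation(data.frame(
    gene = sprintf("g%02d", seq_len(spec$n_genes)), contig = ctg,
    strand = strands, tss = tss, tes = tes,
    class = rep(c("STM", "TFO"), length.out = spec$n_genes),
    nascent = spec$nascent))
  regions <- define_regions(genes)
  rmap <- c(UAS = "UAS", promoter = "promoter", transcript = "transcript",
            terminator = "terminator")
  for (i in seq_len(nrow(regions))) {
    g <- match(regions$gene[i], genes$gene)
    cov[regions$start[i]:regions$end[i]] <-
      spec$region_means[g, rmap[[regions$region[i]]]]
  }

  site0 <- spec$n_genes * spec$pitch
  sites <- data.frame(
    contig = rep(ctg, spec$n_sites),
    pos = site0 + (seq_len(spec$n_sites) - 1) * spec$site_pitch +
      spec$site_flank + 300,
    strand = rep(c("+", "-"), length.out = spec$n_sites))
  if (spec$n_sites > 0) {
    for (i in seq_len(spec$n_sites)) {
      idx <- (sites$pos[i] - spec$site_flank):(sites$pos[i] + spec$site_flank)
      prof <- spec$site_profile
      if (sites$strand[i] == "-") prof <- rev(prof)
      cov[idx] <- cov[idx] + prof
    }
  }

  track <- coverage_track(setNames(list(cov), ctg), units = "CPMn")
  truth <- data.frame(gene = genes$gene,
                      spec$region_means, check.names = FALSE)

  out <- list(track = track, genes = genes, regions = regions,
              sites = sites, truth = truth, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_bedgraph(track, p("coverage.bedGraph"))
    gr <- GenomicRanges::GRanges(
      ctg, IRanges::IRanges(pmin(tss, tes), pmax(tss, tes)),
      strand = strands, name = genes$gene, score = 0)
    rtracklayer::export(gr, p("genes.bed"), format = "BED")
    sgr <- GenomicRanges::GRanges(
      ctg, IRanges::IRanges(sites$pos, sites$pos),
      strand = sites$strand, name = sprintf("s%02d", seq_len(spec$n_sites)),
      score = 0)
    rtracklayer::export(sgr, p("sites.bed"), format = "BED")
    write.table(genes[, c("gene", "class", "nascent")], p("nascent.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth, p("truth_regions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    yaml::write_yaml(list(
      generator = "synth_genome_fixture",
      package_version = as.character(packageVersion("txkinetics")),
      seed = spec$seed, contig = ctg, contig_length = spec$contig_length,
      n_genes = spec$n_genes, gene_span = spec$gene_span,
      baseline = spec$baseline, n_sites = spec$n_sites,
      site_flank = spec$site_flank), p("manifest.yaml"))
    out$paths <- vapply(c("coverage.bedGraph", "genes.bed", "sites.bed",
                          "nascent.tsv", "truth_regions.tsv",
                          "manifest.yaml"), p, character(1))
  }
  out
}
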