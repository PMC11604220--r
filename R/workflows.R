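.wf_keys <- list(
  simulate = c("gene_class", "dataset", "rates", "n_transcript_bins",
               "compartment_length", "t_total", "window", "n_genes", "seed"),
  `minimal-sweep` = c("promoter_dwell", "elongation_rate",
                      "termination_dwell", "n_genes", "seed", "engine"),
  fit = c("region_tsv", "gene_class", "dataset", "resolution", "threshold",
          "fallback_top_n", "n_genes", "seed"),
  perturb = c("region_tsv", "gene_class", "dataset", "scenario", "model",
              "resolution", "threshold", "n_genes", "seed", "subgrid",
              "max_members"),
  `synth-regions` = c("gene_class", "dataset", "rates", "noise_model",
                      "amplitude", "n_replicates", "n_genes", "seed",
                      "target_norm"),
  `synth-fixture` = c("n_genes", "gene_span", "region_means", "baseline",
                      "n_sites", "seed"),
  `region-signal` = c("coverage", "genes_bed", "mode"),
  metagene = c("coverage", "genes_bed", "flank", "bins_per_segment"),
  metasite = c("coverage", "sites_bed", "flank", "window", "step"))

wf_get <- function(config, key, default) {
  if (!is.null(config[[key]]) && !identical(config[[key]], "NULL"))
    config[[key]] else default
}

wf_write <- function(df, path) {
  write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  path
}

#' Run a named analysis workflow
#'
#' Thin, reproducible entry points tying the package's stages together.
#' Every run writes its outputs as TSV plus a `manifest.yaml` recording the
#' subcommand, the fully resolved configuration, the seed, and the package
#' version; [rerun_manifest()] reproduces the run byte-for-byte from the
#' manifest alone.  Unknown configuration keys are rejected (no silent
#' defaults for misspelled parameters).
#'
#' Subcommands: `simulate` (population occupancy for a rate set),
#' `minimal-sweep` (dwell-time/elongation sweep table), `fit` (grid-search
#' ensemble from a region-vector TSV), `perturb` (perturbation preset
#' applied to a freshly fitted ensemble), `synth-regions` /
#' `synth-fixture` (synthetic-data generation), `region-signal`,
#' `metagene`, `metasite` (coverage analyses).
#'
#' @param subcommand one of the names above.
#' @param config named list of parameters, or path to a YAML file holding
#'   one.
#' @param out_dir output directory (created if needed).
#' @param overwrite allow writing into a directory that already contains a
#'   manifest.
#' @return Named character vector of output paths (including the
#'   manifest), invisibly.
#' @export
run_workflow <- function(subcommand, config = list(), out_dir,
                         overwrite = FALSE) {
  if (!subcommand %in% names(.wf_keys))
    stop("unknown subcommand '", subcommand, "'; available: ",
         paste(names(.wf_keys), collapse = ", "))
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  bad <- setdiff(names(config), .wf_keys[[subcommand]])
  if (length(bad))
    stop("unknown configuration key(s) for ", subcommand, ": ",
         paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  if (file.exists(manifest_path) && !overwrite)
    stop("output directory already holds a manifest; use overwrite = TRUE")

  paths <- switch(subcommand,
    simulate = wf_simulate(config, out_dir),
    `minimal-sweep` = wf_minimal_sweep(config, out_dir),
    fit = wf_fit(config, out_dir),
    perturb = wf_perturb(config, out_dir),
    `synth-regions` = wf_synth_regions(config, out_dir),
    `synth-fixture` = wf_synth_fixture(config, out_dir),
    `region-signal` = wf_region_signal(config, out_dir),
    metagene = wf_metagene(config, out_dir),
    metasite = wf_metasite(config, out_dir))

  yaml::write_yaml(list(subcommand = subcommand, config = config,
                        package_version =
                          as.character(packageVersion("txkinetics"))),
                   manifest_path)
  invisible(c(paths, manifest = manifest_path))
}

#' Reproduce a workflow run from its manifest
#' @param manifest_path path to a `manifest.yaml` written by
#'   [run_workflow()].
#' @param out_dir output directory for the reproduced run.
#' @return As [run_workflow()].
#' @export
rerun_manifest <- function(manifest_path, out_dir) {
  m <- yaml::read_yaml(manifest_path)
  run_workflow(m$subcommand, m$config, out_dir, overwrite = TRUE)
}

wf_sim_cfg <- function(config, default_n = 10000) {
  sim_config(t_total = wf_get(config, "t_total", 1000),
             measure_window = wf_get(config, "window", c(940, 1000)),
             n_genes = wf_get(config, "n_genes", default_n),
             seed = wf_get(config, "seed", 1))
}

wf_rates <- function(config) {
  gene_class <- wf_get(config, "gene_class", "TFO")
  r <- default_rates(gene_class, wf_get(config, "dataset", "chec"))
  overrides <- wf_get(config, "rates", NULL)
  if (!is.null(overrides)) r <- update_rates(r, overrides)
  r
}

wf_simulate <- function(config, out_dir) {
  rates <- wf_rates(config)
  arch <- default_architecture(
    rates$gene_class,
    compartment_length = wf_get(config, "compartment_length", 120),
    n_transcript_bins = wf_get(config, "n_transcript_bins", 10))
  prof <- simulate_population(rates, arch, wf_sim_cfg(config))
  c(occupancy = write_occupancy_tsv(prof, file.path(out_dir,
                                                    "occupancy.tsv")))
}

wf_minimal_sweep <- function(config, out_dir) {
  grid <- minimal_grid(
    wf_get(config, "promoter_dwell", c(5, 10, 20)),
    wf_get(config, "elongation_rate", c(1000, 2000, 3000)),
    wf_get(config, "termination_dwell", c(5, 30, 70)))
  tab <- sweep_minimal(grid, wf_sim_cfg(config, 2000),
                       engine = wf_get(config, "engine", "compiled"))
  c(sweep = wf_write(tab, file.path(out_dir, "sweep.tsv")))
}

wf_fit_ensemble <- function(config) {
  path <- config$region_tsv
  if (is.null(path)) stop("fit requires a region_tsv input")
  if (!file.exists(path)) stop("region_tsv not found: ", path)
  emp <- read_region_tsv(path)
  cfg <- fit_config(emp$gene_class,
                    resolution = wf_get(config, "resolution", 5),
                    threshold = wf_get(config, "threshold", 0.995),
                    fallback_top_n = wf_get(config, "fallback_top_n", 20),
                    sim = wf_sim_cfg(config, 5000),
                    dataset = wf_get(config, "dataset", "chec"))
  grid_search(emp, cfg)
}

wf_fit <- function(config, out_dir) {
  ens <- wf_fit_ensemble(config)
  c(ensemble = write_ensemble_tsv(ens, file.path(out_dir, "ensemble.tsv")),
    average = write_region_tsv(ens$average, file.path(out_dir,
                                                      "average.tsv")))
}

wf_perturb <- function(config, out_dir) {
  ens <- wf_fit_ensemble(config)
  sc <- preset_scenario(wf_get(config, "scenario", "kin28-cmk"),
                        ens$cfg$gene_class, wf_get(config, "model", 1))
  d <- apply_perturbation(ens, sc,
                          subgrid = wf_get(config, "subgrid", 3),
                          max_members = wf_get(config, "max_members", 10))
  c(deltas = wf_write(as.data.frame(d), file.path(out_dir, "deltas.tsv")))
}

wf_synth_regions <- function(config, out_dir) {
  rates <- wf_rates(config)
  sv <- synth_region_vectors(
    rates, cfg = wf_sim_cfg(config),
    noise = noise_spec(wf_get(config, "noise_model", "gaussian-on-regions"),
                       amplitude = wf_get(config, "amplitude", 0.05),
                       n_replicates = wf_get(config, "n_replicates", 3),
                       seed = wf_get(config, "seed", 1)),
    target_norm = wf_get(config, "target_norm", 100))
  reps <- do.call(rbind, lapply(seq_along(sv$replicates), function(i)
    data.frame(replicate = i, gene_class = sv$replicates[[i]]$gene_class,
               region = sv$replicates[[i]]$regions,
               value = unname(sv$replicates[[i]]$values))))
  c(replicates = wf_write(reps, file.path(out_dir, "replicates.tsv")),
    mean = write_region_tsv(sv$mean, file.path(out_dir, "mean.tsv")),
    truth = write_region_tsv(sv$truth$scaled,
                             file.path(out_dir, "truth.tsv")))
}

wf_synth_fixture <- function(config, out_dir) {
  spec <- fixture_spec(
    n_genes = wf_get(config, "n_genes", 6),
    gene_span = wf_get(config, "gene_span", 1200),
    region_means = unlist(wf_get(config, "region_means", c(2, 4, 6, 8))),
    baseline = wf_get(config, "baseline", 0),
    n_sites = wf_get(config, "n_sites", 4),
    seed = wf_get(config, "seed", 1))
  fx <- synth_genome_fixture(spec, out_dir)
  fx$paths
}

wf_load_track <- function(config) {
  path <- config$coverage
  if (is.null(path)) stop("a 'coverage' bedGraph path is required")
  if (!file.exists(path)) stop("coverage not found: ", path)
  read_bedgraph(path, units = "CPMn")
}

wf_load_genes <- function(config) {
  path <- config$genes_bed
  if (is.null(path)) stop("a 'genes_bed' path is required")
  if (!file.exists(path)) stop("genes_bed not found: ", path)
  read_genes_bed(path)
}

wf_region_signal <- function(config, out_dir) {
  tab <- region_signal(wf_load_track(config),
                       define_regions(wf_load_genes(config)),
                       mode = wf_get(config, "mode", "per-bp-mean"))
  c(region_signal = wf_write(tab, file.path(out_dir, "region_signal.tsv")))
}

wf_metagene <- function(config, out_dir) {
  prof <- metagene(wf_load_track(config), wf_load_genes(config),
                   flank = wf_get(config, "flank", 1000),
                   bins_per_segment = wf_get(config, "bins_per_segment", 100))
  c(metagene = wf_write(as.data.frame(prof),
                        file.path(out_dir, "metagene.tsv")))
}

wf_metasite <- function(config, out_dir) {
  path <- config$sites_bed
  if (is.null(path) || !file.exists(path))
    stop("a 'sites_bed' path is required")
  gr <- rtracklayer::import(path, format = "BED")
  sites <- data.frame(contig = as.character(GenomeInfoDb::seqnames(gr)),
                      pos = BiocGenerics::start(gr),
                      strand = as.character(BiocGenerics::strand(gr)))
  prof <- metasite(wf_load_track(config), sites,
                   flank = wf_get(config, "flank", 250),
                   window = wf_get(config, "window", 10),
                   step = wf_get(config, "step", 5))
  c(metasite = wf_write(as.data.frame(prof),
                        file.path(out_dir, "metasite.tsv")))
}
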