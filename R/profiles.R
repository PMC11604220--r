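get_segment <- function(track, contig, start, end, gene = "?") {
  v <- track$values[[contig]]
  if (is.null(v)) stop("contig ", contig, " absent from track (gene ", gene, ")")
  if (start < 1 || end > length(v))
    stop("region [", start, ", ", end, "] outside contig ", contig,
         " for gene ", gene)
  v[start:end]
}

#' Per-gene, per-region signal
#'
#' Bins a coverage track into the fixed gene regions.  `per-bp-mean` is
#' the region sum divided by region length; `fraction-of-total` divides
#' each gene's length-normalized region value by the sum of its four
#' length-normalized values, so fractions sum to 1 per gene.
#'
#' @param track a [coverage_track()].
#' @param regions a `region_set` from [define_regions()].
#' @param mode `"per-bp-mean"` or `"fraction-of-total"`.
#' @return A data.frame with columns `gene`, `region`, `value`.
#' @export
region_signal <- function(track, regions,
                          mode = c("per-bp-mean", "fraction-of-total")) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "coverage_track"), inherits(regions, "region_set"))
  val <- vapply(seq_len(nrow(regions)), function(i)
    mean(get_segment(track, regions$contig[i], regions$start[i],
                     regions$end[i], regions$gene[i])), numeric(1))
  out <- data.frame(gene = regions$gene, region = regions$region, value = val)
  if (mode == "fraction-of-total") {
    tot <- tapply(out$value, out$gene, sum)
    out$value <- out$value / as.numeric(tot[out$gene])
  }
  out
}

bin_means <- function(v, n_bins) {
  idx <- floor((seq_along(v) - 1) * n_bins / length(v))
  as.numeric(tapply(v, factor(idx, levels = 0:(n_bins - 1)), mean))
}

average_tracks <- function(track) {
  if (inherits(track, "coverage_track")) return(track)
  stopifnot(is.list(track), length(track) >= 1)
  base <- track[[1]]
  for (t in track[-1]) {
    if (!identical(names(t$values), names(base$values)) ||
        !identical(lengths(t$values), lengths(base$values)))
      stop("replicate tracks differ in shape")
  }
  vals <- lapply(names(base$values), function(ctg)
    Reduce(`+`, lapply(track, function(t) t$values[[ctg]])) / length(track))
  names(vals) <- names(base$values)
  structure(list(values = vals, units = base$units), class = "coverage_track")
}

#' Metagene profile
#'
#' Length-normalized average signal over many genes, in three segments:
#' `flank` bp upstream of the TSS, the transcript (TSS to TES), and
#' `flank` bp downstream of the TES, each divided into `bins_per_segment`
#' equal bins (bin mean of the per-base signal).  Replicate tracks are
#' averaged per base first, then per gene, then across genes.  Minus-strand
#' genes are orientation-flipped before averaging.  Genes whose flanks
#' extend past the contig are clipped with a warning.
#'
#' @param track a [coverage_track()] or list of replicate tracks.
#' @param genes a [gene_annotation()].
#' @param flank upstream/downstream extent in bp (default 1000).
#' @param bins_per_segment bins per segment (default 100; 300 bins total).
#' @return A data.frame of class `meta_profile` with columns `segment`
#'   (`upstream`, `transcript`, `downstream`), `bin` (1-based within
#'   segment), `mean`; attribute `n_genes`.
#' @export
metagene <- function(track, genes, flank = 1000, bins_per_segment = 100) {
  track <- average_tracks(track)
  stopifnot(inherits(genes, "gene_annotation"))
  if (!nrow(genes)) stop("no genes supplied")
  nb <- bins_per_segment
  clipped <- FALSE
  per_gene <- lapply(seq_len(nrow(genes)), function(i) {
    ctg <- genes$contig[i]; tss <- genes$tss[i]; tes <- genes$tes[i]
    len <- length(track$values[[ctg]])
    if (is.null(track$values[[ctg]]))
      stop("contig ", ctg, " absent from track")
    if (genes$strand[i] == "+") {
      up <- c(max(1, tss - flank), tss - 1)
      tx <- c(tss, tes)
      dn <- c(tes + 1, min(len, tes + flank))
      segs <- list(up, tx, dn)
      vecs <- lapply(segs, function(s)
        get_segment(track, ctg, s[1], s[2], genes$gene[i]))
    } else {
      up <- c(tss + 1, min(len, tss + flank))
      tx <- c(tes, tss)
      dn <- c(max(1, tes - flank), tes - 1)
      segs <- list(up, tx, dn)
      vecs <- lapply(segs, function(s)
        rev(get_segment(track, ctg, s[1], s[2], genes$gene[i])))
    }
    if (diff(segs[[1]]) + 1 < flank || diff(segs[[3]]) + 1 < flank)
      clipped <<- TRUE
    unlist(lapply(vecs, bin_means, n_bins = nb))
  })
  if (clipped) warning("some gene flanks were clipped at contig boundaries")
  mat <- do.call(rbind, per_gene)
  out <- data.frame(
    segment = rep(c("upstream", "transcript", "downstream"), each = nb),
    bin = rep(seq_len(nb), 3),
    mean = colMeans(mat))
  attr(out, "n_genes") <- nrow(genes)
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' Metasite profile around oriented point features
#'
#' Base-resolution average of the track over `[-flank, +flank]` around each
#' site (e.g. TATA boxes or TF binding sites), orientation-flipped for
#' minus-strand sites, optionally smoothed with the standard sliding
#' window.  Sites whose window would extend past the contig are excluded.
#'
#' @param track a [coverage_track()] or list of replicate tracks.
#' @param sites data.frame with columns `contig`, `pos` (1-based) and
#'   `strand`.
#' @param flank half-window in bp (default 250).
#' @param smooth apply [smooth_signal()]? (default `TRUE`).
#' @param window,step smoothing parameters.
#' @return A data.frame of class `meta_profile` with columns `offset`
#'   (relative to the site, 0 at the site) and `mean`; attribute `n_sites`
#'   counts contributing sites.
#' @export
metasite <- function(track, sites, flank = 250, smooth = TRUE,
                     window = 10, step = 5) {
  track <- average_tracks(track)
  stopifnot(all(c("contig", "pos", "strand") %in% names(sites)))
  if (!nrow(sites)) stop("no sites supplied")
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    v <- track$values[[sites$contig[i]]]
    if (is.null(v)) next
    lo <- sites$pos[i] - flank; hi <- sites$pos[i] + flank
    if (lo < 1 || hi > length(v)) next  # clipped site: excluded
    w <- v[lo:hi]
    if (sites$strand[i] == "-") w <- rev(w)
    rows[[length(rows) + 1]] <- w
  }
  if (!length(rows)) stop("no usable sites (all clipped or off-track)")
  prof <- colMeans(do.call(rbind, rows))
  offsets <- -flank:flank
  if (smooth) {
    sm <- smooth_signal(prof, window = window, step = step,
                        positions = offsets)
    out <- data.frame(offset = sm$position, mean = sm$value)
  } else {
    out <- data.frame(offset = offsets, mean = prof)
  }
  attr(out, "n_sites") <- length(rows)
  class(out) <- c("meta_profile", "data.frame")
  out
}

#' Region enrichment of a factor relative to a reference
#'
#' For each gene and region, the ratio of the factor's length-normalized
#' signal to the reference's (e.g. a kinase relative to total polymerase)
#' is computed per replicate; replicate-level means over genes give a
#' per-region ratio with a between-replicate standard error.  Genes with a
#' zero reference value in any region are skipped and recorded in the
#' `skipped` attribute.
#'
#' @param factor_signal,reference_signal lists of replicate matrices
#'   (genes x regions, identical dimnames; e.g. built from
#'   [region_signal()] output with `xtabs` or `reshape`).
#' @return A data.frame with `region`, `ratio`, `se`, `n_replicates`;
#'   per-replicate ratios in attribute `replicates`.
#' @export
relative_region_enrichment <- function(factor_signal, reference_signal) {
  if (inherits(factor_signal, "matrix")) factor_signal <- list(factor_signal)
  if (inherits(reference_signal, "matrix"))
    reference_signal <- list(reference_signal)
  if (length(factor_signal) != length(reference_signal))
    stop("replicate counts differ")
  skipped <- character(0)
  reps <- mapply(function(f, r) {
    if (!identical(dimnames(f), dimnames(r)))
      stop("factor and reference matrices must share genes and regions")
    ok <- apply(r, 1, function(x) all(x > 0))
    skipped <<- union(skipped, rownames(r)[!ok])
    colMeans(f[ok, , drop = FALSE] / r[ok, , drop = FALSE])
  }, factor_signal, reference_signal)
  reps <- matrix(reps, ncol = length(factor_signal),
                 dimnames = list(colnames(factor_signal[[1]]), NULL))
  n <- ncol(reps)
  out <- data.frame(region = rownames(reps),
                    ratio = rowMeans(reps),
                    se = if (n > 1) apply(reps, 1, sd) / sqrt(n)
                         else rep(NA_real_, nrow(reps)),
                    n_replicates = n, row.names = NULL)
  attr(out, "replicates") <- reps
  attr(out, "skipped") <- skipped
  out
}

#' z-score for a difference of enrichment ratios
#'
#' Normal-approximation z for the difference between two per-region ratios,
#' using the root of the summed squared replicate standard errors, with a
#' two-sided p-value.
#'
#' @param a,b outputs of [relative_region_enrichment()] with matching
#'   regions.
#' @return A data.frame with `region`, `difference`, `z`, `p`.
#' @export
enrichment_z <- function(a, b) {
  stopifnot(identical(a$region, b$region))
  d <- a$ratio - b$ratio
  se <- sqrt(a$se^2 + b$se^2)
  z <- d / se
  data.frame(region = a$region, difference = d, z = z,
             p = 2 * pnorm(-abs(z)))
}
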