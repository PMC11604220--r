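#' Gene annotation table
#'
#' Validates and tags a data.frame of gene annotations.  Coordinates are
#' 1-based genomic positions; `tss < tes` on the plus strand and
#' `tss > tes` on the minus strand.  `nascent` holds the replicate-mean
#' nascent RNA count used for expression filtering.
#'
#' @param df data.frame with columns `gene`, `contig`, `strand` (`"+"` or
#'   `"-"`), `tss`, `tes`, and optionally `class` (e.g. `"STM"`, `"TFO"`,
#'   `"repressed"`) and `nascent`.
#' @return The validated data.frame with class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene", "contig", "strand", "tss", "tes")
  if (!all(need %in% names(df)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(df$tss == df$tes)) stop("TSS must differ from TES")
  plus <- df$strand == "+"
  if (any(df$tss[plus] > df$tes[plus]) || any(df$tss[!plus] < df$tes[!plus]))
    stop("TSS/TES order inconsistent with strand")
  if (anyDuplicated(df$gene)) stop("duplicate gene ids")
  if (!"class" %in% names(df)) df$class <- "other"
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Filter genes by nascent expression
#'
#' Keeps genes whose replicate-mean nascent RNA count reaches the
#' threshold (default 50, the cutoff used to define the expressed STM and
#' TFO gene sets).  Genes with missing counts are excluded; their ids are
#' recorded in the `excluded` attribute with a reason.
#'
#' @param genes a [gene_annotation()] with a `nascent` column.
#' @param min_mean_count inclusive threshold.
#' @return The filtered [gene_annotation()].
#' @export
filter_expressed <- function(genes, min_mean_count = 50) {
  if (!"nascent" %in% names(genes))
    stop("annotation has no 'nascent' column")
  missing_ct <- is.na(genes$nascent)
  keep <- !missing_ct & genes$nascent >= min_mean_count
  excluded <- data.frame(
    gene = genes$gene[!keep],
    reason = ifelse(missing_ct[!keep], "missing nascent count",
                    "below threshold"))
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

# Offsets of the fixed gene regions, inclusive and relative to the anchor
# (TSS or TES at offset 0).
.region_offsets <- list(
  UAS = c(anchor = "tss", lo = -500, hi = -151),
  promoter = c(anchor = "tss", lo = -150, hi = 25),
  transcript = c(anchor = NA, lo = 26, hi = -76),  # +26 from TSS to -76 from TES
  terminator = c(anchor = "tes", lo = -75, hi = 150))

#' Define fixed gene regions around TSS and TES
#'
#' Computes, per gene, the four analysis regions from inclusive offsets
#' anchored at the TSS/TES (anchor = offset 0): UAS -500..-151 from the
#' TSS; promoter -150..+25 from the TSS (176 bases); transcript +26 from
#' the TSS to -76 from the TES; terminator -75..+150 around the TES.
#' Minus-strand genes are exact mirror images.  Genes whose transcript
#' would be empty after the promoter/terminator encroachment (TES - TSS
#' closer than 102 bp) are excluded with a reason, recorded in the
#' `excluded` attribute.
#'
#' @param genes a [gene_annotation()].
#' @return A data.frame of class `region_set` with columns `gene`,
#'   `contig`, `strand`, `region`, `start`, `end` (1-based inclusive
#'   genomic coordinates, `start <= end`).
#' @examples
#' g <- gene_annotation(data.frame(gene = "g1", contig = "chr1",
#'                                 strand = "+", tss = 10000, tes = 12000))
#' define_regions(g)
#' @export
define_regions <- function(genes) {
  stopifnot(inherits(genes, "gene_annotation"))
  span <- abs(genes$tes - genes$tss)
  ok <- span >= 102  # transcript must hold at least one base
  excluded <- data.frame(
    gene = genes$gene[!ok],
    reason = rep("transcript shorter than region offsets", sum(!ok)))
  rows <- lapply(which(ok), function(i) {
    tss <- genes$tss[i]; tes <- genes$tes[i]
    s <- genes$strand[i]
    if (s == "+") {
      reg <- rbind(UAS = c(tss - 500, tss - 151),
                   promoter = c(tss - 150, tss + 25),
                   transcript = c(tss + 26, tes - 76),
                   terminator = c(tes - 75, tes + 150))
    } else {
      reg <- rbind(UAS = c(tss + 151, tss + 500),
                   promoter = c(tss - 25, tss + 150),
                   transcript = c(tes + 76, tss - 26),
                   terminator = c(tes - 150, tes + 75))
    }
    data.frame(gene = genes$gene[i], contig = genes$contig[i], strand = s,
               region = rownames(reg), start = reg[, 1], end = reg[, 2],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), contig = character(),
                      strand = character(), region = character(),
                      start = integer(), end = integer())
  attr(out, "excluded") <- excluded
  class(out) <- c("region_set", "data.frame")
  out
}

#' Read genes from BED6
#'
#' BED intervals (0-based half-open) become 1-based annotations; the TSS
#' is the 5' end of the interval on the annotated strand.
#'
#' @param path BED6 file (name column = gene id).
#' @param classes optional named vector mapping gene id to class.
#' @param nascent optional named vector of replicate-mean nascent counts.
#' @return A [gene_annotation()].
#' @export
read_genes_bed <- function(path, classes = NULL, nascent = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st == "*")) stop("gene BED must be stranded")
  df <- data.frame(
    gene = S4Vectors::mcols(gr)$name,
    contig = as.character(GenomeInfoDb::seqnames(gr)),
    strand = st,
    tss = ifelse(st == "+", BiocGenerics::start(gr), BiocGenerics::end(gr)),
    tes = ifelse(st == "+", BiocGenerics::end(gr), BiocGenerics::start(gr)))
  if (!is.null(classes)) df$class <- unname(classes[df$gene])
  if (!is.null(nascent)) df$nascent <- unname(nascent[df$gene])
  gene_annotation(df)
}
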