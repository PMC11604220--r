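#' Per-base coverage track
#'
#' A per-contig container of per-base signal, with a units tag
#' (`"counts"` for raw cleavage/read counts, `"CPM"`/`"CPMn"` after
#' normalization, `"delta"` for differences).
#'
#' @param values named list of numeric vectors, one per contig.
#' @param units unit tag.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, units = "counts") {
  if (!is.list(values) || is.null(names(values)) || !length(values))
    stop("values must be a non-empty named list of per-contig vectors")
  for (v in values) {
    if (!is.numeric(v) || !length(v)) stop("empty contig vector")
    if (!all(is.finite(v))) stop("coverage values must be finite")
    if (units == "counts" && any(v < 0))
      stop("raw counts must be non-negative")
  }
  structure(list(values = values, units = units), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track>", x$units, "|",
      paste(names(x$values), lengths(x$values), sep = ":", collapse = ", "),
      "\n")
  invisible(x)
}

track_total <- function(track) sum(vapply(track$values, sum, numeric(1)))

#' Read / write coverage as bedGraph
#'
#' Four-column bedGraph (0-based half-open intervals) read through
#' rtracklayer; positions are expanded to a per-base vector per contig.
#' Bases not covered by any interval are zero.
#'
#' @param path bedGraph file.
#' @param seqlengths optional named contig lengths; defaults to the largest
#'   end coordinate seen per contig.
#' @param units unit tag to attach.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, seqlengths = NULL, units = "counts") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  contigs <- as.character(unique(GenomeInfoDb::seqnames(gr)))
  vals <- lapply(contigs, function(ctg) {
    g <- gr[GenomeInfoDb::seqnames(gr) == ctg]
    len <- if (!is.null(seqlengths)) seqlengths[[ctg]]
           else max(BiocGenerics::end(g))
    v <- numeric(len)
    st <- BiocGenerics::start(g); en <- BiocGenerics::end(g)
    sc <- S4Vectors::mcols(g)$score
    for (i in seq_along(g)) v[st[i]:en[i]] <- sc[i]
    v
  })
  names(vals) <- contigs
  coverage_track(vals, units = units)
}

#' @rdname read_bedgraph
#' @param track a [coverage_track()] to write.
#' @export
write_bedgraph <- function(track, path) {
  grl <- lapply(names(track$values), function(ctg) {
    r <- rle(track$values[[ctg]])
    en <- cumsum(r$lengths)
    st <- en - r$lengths + 1
    keep <- r$values != 0
    GenomicRanges::GRanges(ctg, IRanges::IRanges(st[keep], en[keep]),
                           score = r$values[keep])
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Counts-per-million normalization
#'
#' Scales every base by `1e6 / total`, where `total` is the genome-wide sum
#' of the track, so the normalized track sums to one million.  Applying it
#' twice equals applying it once.
#'
#' @param track a [coverage_track()] with positive total signal.
#' @param units unit tag of the result (default `"CPM"`).
#' @return The normalized [coverage_track()].
#' @export
cpm_normalize <- function(track, units = "CPM") {
  stopifnot(inherits(track, "coverage_track"))
  tot <- track_total(track)
  if (tot <= 0) stop("cannot CPM-normalize a track with no signal")
  coverage_track(lapply(track$values, function(v) v * 1e6 / tot),
                 units = units)
}

#' Subtract a control track or profile
#'
#' Element-wise difference between a specific signal and its background
#' control (e.g. soluble MNase), requiring identical shapes and units.
#' Negative values are retained (depletion relative to background is
#' meaningful and displayed in the underlying assays).
#'
#' @param specific,control two [coverage_track()]s with identical contigs,
#'   lengths and units, or two meta-profile data.frames with identical
#'   positions.
#' @return The difference, same shape as `specific`.
#' @export
subtract_background <- function(specific, control) {
  if (inherits(specific, "coverage_track") &&
      inherits(control, "coverage_track")) {
    if (!identical(specific$units, control$units))
      stop("unit mismatch: ", specific$units, " vs ", control$units)
    if (!identical(names(specific$values), names(control$values)) ||
        !identical(lengths(specific$values), lengths(control$values)))
      stop("track shapes differ")
    vals <- Map(`-`, specific$values, control$values)
    out <- structure(list(values = vals,
                          units = paste0(specific$units, " (bg-subtracted)")),
                     class = "coverage_track")
    return(out)
  }
  if (is.data.frame(specific) && is.data.frame(control)) {
    pcol <- intersect(c("offset", "position", "bin"), names(specific))[1]
    if (is.na(pcol) || !identical(specific[[pcol]], control[[pcol]]))
      stop("profile shapes differ")
    out <- specific
    out$mean <- specific$mean - control$mean
    return(out)
  }
  stop("specific and control must both be tracks or both be profiles")
}

#' Sliding-window smoothing
#'
#' Means over consecutive windows of width `window` advanced by `step`
#' positions; windows are truncated at the right boundary and reported at
#' their (truncated) center position.
#'
#' @param x numeric signal.
#' @param window window width in positions (>= 1).
#' @param step advance between window starts (>= 1).
#' @param positions coordinates of `x` (default `1:length(x)`).
#' @return A data.frame with columns `position` (window center) and `value`.
#' @examples
#' smooth_signal(c(rep(0, 5), rep(10, 5)), window = 10, step = 5)
#' @export
smooth_signal <- function(x, window = 10, step = 5,
                          positions = seq_along(x)) {
  stopifnot(window >= 1, step >= 1, length(positions) == length(x))
  n <- length(x)
  starts <- seq(1, n, by = step)
  ends <- pmin(starts + window - 1, n)
  data.frame(
    position = (positions[starts] + positions[ends]) / 2,
    value = vapply(seq_along(starts), function(i)
      mean(x[starts[i]:ends[i]]), numeric(1)))
}
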