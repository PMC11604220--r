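region_order <- function(gene_class) {
  if (gene_class == "STM") c("UAS", "promoter", "transcript", "utr3")
  else c("promoter", "transcript", "utr3")
}

#' Per-region signal vector
#'
#' The object compared between model and data: one scalar per gene region,
#' in model occupancy units or empirical CPM-normalized cleavage (CPMn).
#' STM vectors carry (UAS, promoter, transcript, 3'UTR); TFO vectors, whose
#' model has no UAS compartment, carry (promoter, transcript, 3'UTR).
#'
#' @param values numeric values, one per region, in region order (a named
#'   vector is reordered by name).
#' @param gene_class `"STM"` or `"TFO"`.
#' @param units unit tag, e.g. `"occupancy"` or `"CPMn"`.
#' @return An object of class `region_vector`.
#' @export
region_vector <- function(values, gene_class = c("TFO", "STM"),
                          units = "occupancy") {
  gene_class <- match.arg(gene_class)
  regions <- region_order(gene_class)
  if (!is.null(names(values))) {
    if (!setequal(names(values), regions))
      stop("region names must be exactly: ", paste(regions, collapse = ", "))
    values <- values[regions]
  } else if (length(values) != length(regions)) {
    stop("expected ", length(regions), " values for a ", gene_class, " vector")
  }
  if (!all(is.finite(values)) || any(values < 0))
    stop("region values must be finite and non-negative")
  structure(list(values = setNames(as.numeric(values), regions),
                 regions = regions, gene_class = gene_class, units = units),
            class = "region_vector")
}

#' @export
print.region_vector <- function(x, ...) {
  cat("<region_vector>", x$gene_class, "(", x$units, ")\n")
  print(x$values)
  invisible(x)
}

#' Collapse an occupancy profile into gene regions
#'
#' UAS, promoter and 3'UTR values are copied from their single compartments
#' (the terminator compartment maps to the 3'UTR region); the transcript
#' value is the arithmetic mean of the transcript bins.
#'
#' @param profile an `occupancy_profile` from [simulate_population()].
#' @param gene_class `"STM"` or `"TFO"`; must match the profile's
#'   compartments.
#' @return A [region_vector()] in occupancy units.
#' @export
aggregate_regions <- function(profile, gene_class = c("TFO", "STM")) {
  gene_class <- match.arg(gene_class)
  m <- profile$mean
  need_uas <- gene_class == "STM"
  if (need_uas && !"UAS" %in% names(m))
    stop("STM aggregation requires a UAS compartment in the profile")
  if (!need_uas && "UAS" %in% names(m))
    stop("TFO aggregation on a profile with a UAS compartment")
  bins <- grep("^bin_", names(m))
  if (!length(bins) || !all(c("promoter", "terminator") %in% names(m)))
    stop("profile compartments do not match the expected architecture")
  vals <- c(if (need_uas) c(UAS = unname(m["UAS"])),
            promoter = unname(m["promoter"]),
            transcript = mean(m[bins]),
            utr3 = unname(m["terminator"]))
  region_vector(vals, gene_class, units = "occupancy")
}

region_values <- function(x) {
  if (inherits(x, "region_vector")) x$values else as.numeric(x)
}

check_matching_regions <- function(model, empirical) {
  if (inherits(model, "region_vector") && inherits(empirical, "region_vector")) {
    if (!identical(model$regions, empirical$regions))
      stop("region labels differ between the two vectors")
  } else if (length(region_values(model)) != length(region_values(empirical))) {
    stop("vectors differ in length")
  }
}

#' Cosine similarity between model and empirical region vectors
#'
#' `sum(M * E) / (||M|| * ||E||)`, ranging from -1 (perfect inverse
#' alignment) through 0 (orthogonal) to 1 (perfect alignment).  Scale
#' invariant, so model occupancies can be compared directly with CPMn.
#'
#' @param model,empirical [region_vector()]s with matching regions, or bare
#'   numeric vectors of equal length.
#' @return A score in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 2, 2), c(2, 4, 4))  # 1
#' @export
cosine_similarity <- function(model, empirical) {
  check_matching_regions(model, empirical)
  m <- region_values(model); e <- region_values(empirical)
  nm <- sqrt(sum(m^2)); ne <- sqrt(sum(e^2))
  if (nm == 0 || ne == 0)
    stop("cosine similarity undefined for a zero vector")
  sum(m * e) / (nm * ne)
}

#' Scale a model vector to the empirical magnitude
#'
#' L2-normalizes the model prediction and rescales it to the L2 norm of the
#' empirical data, approximating the unit conversion from occupancy to
#' CPM/CPMn.  Cosine similarity is unchanged by this scaling.
#'
#' @inheritParams cosine_similarity
#' @return The scaled vector, same class as `model`, in empirical units.
#' @export
l2_scale <- function(model, empirical) {
  check_matching_regions(model, empirical)
  m <- region_values(model); e <- region_values(empirical)
  nm <- sqrt(sum(m^2))
  if (nm == 0) stop("cannot scale a zero model vector")
  scaled <- m * sqrt(sum(e^2)) / nm
  if (inherits(model, "region_vector")) {
    out <- model
    out$values <- setNames(scaled, model$regions)
    out$units <- if (inherits(empirical, "region_vector")) empirical$units
                 else "scaled"
    out
  } else scaled
}
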