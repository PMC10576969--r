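#' Filter images by minimum imaged area
#'
#' Density estimated from a very small imaged area extrapolates poorly, so
#' images below a minimum area (default 1 m^2) are removed before analysis.
#' The boundary is strictly-less-than: an image of exactly the minimum area
#' is kept. The filter provenance (records in, records removed, threshold)
#' is recorded in \code{metadata()} of the result.
#'
#' @param x a \linkS4class{VmeImageSet}.
#' @param min_area_m2 minimum imaged area in m^2 (default 1).
#' @return the filtered \linkS4class{VmeImageSet}; inspect
#'   \code{metadata(x)$area_filter} for counts.
#' @export
filterByArea <- function(x, min_area_m2 = 1) {
  stopifnot(is(x, "VmeImageSet"))
  if (min_area_m2 < 0) stop("min_area_m2 must be non-negative")
  keep <- colData(x)$area_m2 >= min_area_m2
  out <- x[, keep]
  metadata(out)$area_filter <- list(
    records_in = ncol(x),
    records_removed = sum(!keep),
    records_kept = sum(keep),
    min_area_m2 = min_area_m2)
  out
}

#' Convert counts to per-area densities and richness
#'
#' Resolves every annotation taxon to a canonical registry name, keeps the
#' taxa counted as VME indicators under the chosen body or consensus rule
#' (columns resolving to the same canonical taxon are pooled), and divides
#' counts by the imaged area. Per-image summaries are attached to
#' \code{colData}: overall indicator density (individuals/m^2), indicator
#' richness (taxa), and richness density (taxa/m^2). Annotation columns that
#' cannot be resolved, or that are not indicators under the chosen rule, are
#' excluded from the sums and listed in \code{metadata()$excluded_taxa}.
#'
#' @param x a \linkS4class{VmeImageSet}.
#' @param registry a \linkS4class{VmeRegistry}.
#' @param body a management-body id, \code{"union"} (default: an indicator
#'   for any body) or \code{"intersection"}.
#' @param policy \code{"qualified_counts"} or \code{"strict"}.
#' @return a \linkS4class{VmeDensitySet}.
#' @examples
#' x <- makeFixture("tiny")
#' d <- computeDensities(x)
#' head(overallDensity(d))
#' @export
computeDensities <- function(x, registry = defaultRegistry(),
                             body = "union",
                             policy = c("qualified_counts", "strict")) {
  stopifnot(is(x, "VmeImageSet"))
  policy <- match.arg(policy)
  want <- indicatorTaxa(registry, body = body, policy = policy,
                        includeFeatures = FALSE)
  canon <- resolveTaxon(registry, rownames(x))
  keep <- !is.na(canon) & canon %in% want
  excluded <- rownames(x)[!keep]
  cts <- assay(x, "counts")[keep, , drop = FALSE]
  groups <- canon[keep]
  # pool annotation rows resolving to the same canonical taxon
  pooled <- rowsum(cts, group = groups)
  taxa <- sort(rownames(pooled))
  pooled <- pooled[taxa, , drop = FALSE]
  area <- colData(x)$area_m2
  dens <- sweep(pooled, 2, area, "/")
  cd <- colData(x)
  cd$overall_density <- as.numeric(colSums(dens))
  cd$richness <- as.integer(colSums(pooled > 0))
  cd$richness_density <- cd$richness / area
  out <- new("VmeDensitySet", SummarizedExperiment::SummarizedExperiment(
    assays = list(density = dens), colData = cd))
  metadata(out) <- c(metadata(x),
                     list(excluded_taxa = excluded, body = body,
                          policy = policy))
  out
}

#' @describeIn VmeDensitySet overall indicator density per image
#'   (individuals/m^2)
#' @param x a \code{VmeDensitySet}
#' @export
overallDensity <- function(x) setNames(colData(x)$overall_density, colnames(x))

#' @describeIn VmeDensitySet indicator taxon richness per image (taxa)
#' @export
richness <- function(x) setNames(colData(x)$richness, colnames(x))

#' @describeIn VmeDensitySet richness density per image (taxa/m^2)
#' @export
richnessDensity <- function(x)
  setNames(colData(x)$richness_density, colnames(x))

#' @describeIn VmeDensitySet expert Yes/Maybe/No labels per image
#' @export
imageLabels <- function(x) setNames(colData(x)$label, colnames(x))

#' Per-image density of a taxon group
#'
#' Sums per-image densities over the member taxa of a registry group
#' (\code{Cnidaria}, \code{Echinodermata}, \code{OtherTaxa}), of a single
#' canonical taxon, or of \code{"all"} (equal to the overall density).
#'
#' @param x a \linkS4class{VmeDensitySet}.
#' @param group registry group name, canonical taxon name, or \code{"all"}.
#' @param registry registry used to resolve group membership.
#' @return data.frame with \code{image_id}, \code{density}, \code{label}.
#' @export
groupDensity <- function(x, group, registry = defaultRegistry()) {
  stopifnot(is(x, "VmeDensitySet"))
  dens <- assay(x, "density")
  if (identical(group, "all")) {
    val <- colData(x)$overall_density
  } else if (group %in% .GROUPS) {
    members <- registry@entries$taxon[registry@entries$group == group]
    val <- colSums(dens[rownames(dens) %in% members, , drop = FALSE])
  } else {
    can <- resolveTaxon(registry, group)
    if (is.na(can)) stop("unknown taxon group: ", group)
    val <- if (can %in% rownames(dens)) dens[can, ] else rep(0, ncol(x))
  }
  data.frame(image_id = colnames(x), density = as.numeric(val),
             label = colData(x)$label, stringsAsFactors = FALSE)
}

#' Export a density table to CSV
#'
#' One row per image: image metadata summaries, one column per indicator
#' taxon density, then overall density, richness and richness density.
#'
#' @param x a \linkS4class{VmeDensitySet}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
exportDensities <- function(x, path) {
  df <- data.frame(image_id = colnames(x),
                   site = colData(x)$site,
                   label = colData(x)$label,
                   area_m2 = colData(x)$area_m2,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(t(assay(x, "density"))))
  df$overall_density <- colData(x)$overall_density
  df$richness <- colData(x)$richness
  df$richness_density <- colData(x)$richness_density
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
setMethod("show", "VmeDensitySet", function(object) {
  cat("VmeDensitySet:", nrow(object), "indicator taxa x", ncol(object),
      "images\n")
  af <- metadata(object)$area_filter
  if (!is.null(af))
    cat(sprintf("  area filter: %d in, %d removed (< %g m2)\n",
                af$records_in, af$records_removed, af$min_area_m2))
  if (ncol(object))
    cat(sprintf("  overall density: mean %.3g, max %.3g individuals/m2\n",
                mean(colData(object)$overall_density),
                max(colData(object)$overall_density)))
})
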