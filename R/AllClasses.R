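#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

# Canonical per-image metadata columns, in on-disk order. Everything not in
# this set (and not remapped by a schema) is treated as a taxon count column.
.META_COLS <- c("image_id", "laboratory", "site", "region", "depth_m",
                "area_m2", "pct_hard_substrate", "camera", "label",
                "reef_present", "chemo_present", "large_old_present",
                "functional_role_visible", "threatened_present")

.FLAG_COLS <- c("reef_present", "chemo_present", "large_old_present",
                "functional_role_visible", "threatened_present")

.LABELS <- c("Yes", "Maybe", "No")

.RANKS <- c("phylum", "class", "subclass", "order", "suborder", "family",
            "genus", "species", "feature")

.GROUPS <- c("Cnidaria", "Echinodermata", "OtherTaxa", "Feature")

.STATUSES <- c("indicator", "not_indicator", "qualified")

.FAO_CRITERIA <- c("uniqueness_rarity", "functional_significance",
                   "fragility", "life_history", "structural_complexity")

#' Registry of VME indicator taxa by management body
#'
#' Machine-readable encoding of the per-RFMO/A lists of Vulnerable Marine
#' Ecosystem (VME) indicator taxa. Each (taxon, body) cell holds one of three
#' statuses: \code{indicator} (a plain "yes" listing), \code{not_indicator},
#' or \code{qualified} (listed with a restriction or renaming note, e.g.
#' "only Cerianthidae" or "stalked only"). A synonym table maps common
#' alternate annotation labels (e.g. \code{Gorgonacea}) onto registry rows.
#'
#' @slot entries data.frame with one row per registry taxon/feature:
#'   \code{taxon}, \code{rank}, \code{group}, \code{parent}.
#' @slot status long-format data.frame with columns \code{taxon},
#'   \code{body}, \code{status}, \code{qualifier}, \code{flagged}; exactly
#'   one row per (taxon, body) pair. \code{flagged} marks cells whose source
#'   wording is ambiguous between restriction and synonymy and is stored
#'   verbatim rather than interpreted.
#' @slot bodies character vector of management-body identifiers.
#' @slot synonyms named character vector; names are lower-case aliases,
#'   values canonical registry taxon names.
#'
#' @seealso [loadRegistry()], [defaultRegistry()], [isIndicator()],
#'   [consensusList()], [resolveTaxon()]
#' @export
setClass("VmeRegistry",
  slots = c(entries = "data.frame", status = "data.frame",
            bodies = "character", synonyms = "character"))

setValidity("VmeRegistry", function(object) {
  e <- object@entries; s <- object@status
  msgs <- character()
  if (!all(c("taxon", "rank", "group", "parent") %in% names(e)))
    msgs <- c(msgs, "entries must have columns taxon, rank, group, parent")
  if (anyDuplicated(e$taxon))
    msgs <- c(msgs, paste("duplicate taxon row:",
                          e$taxon[duplicated(e$taxon)][1]))
  if (!all(e$rank %in% .RANKS))
    msgs <- c(msgs, "unrecognized taxonomic rank")
  if (!all(e$group %in% .GROUPS))
    msgs <- c(msgs, "unrecognized taxon group")
  ok_parent <- is.na(e$parent) | e$parent %in% e$taxon
  if (!all(ok_parent))
    msgs <- c(msgs, "parent must refer to another registry entry")
  if (!all(s$status %in% .STATUSES))
    msgs <- c(msgs, "status must be indicator/not_indicator/qualified")
  # qualifier present iff qualified
  has_q <- !is.na(s$qualifier) & nzchar(s$qualifier)
  if (!all(has_q == (s$status == "qualified")))
    msgs <- c(msgs, "qualifier must be present iff status is 'qualified'")
  # complete grid: one status per (taxon, body)
  key <- paste(s$taxon, s$body, sep = "\r")
  if (anyDuplicated(key))
    msgs <- c(msgs, "more than one status for a (taxon, body) pair")
  want <- length(e$taxon) * length(object@bodies)
  if (nrow(s) != want)
    msgs <- c(msgs, sprintf("status table has %d cells, expected %d",
                            nrow(s), want))
  # synonym resolution idempotent: canonical targets are registry taxa
  if (length(object@synonyms) &&
      !all(object@synonyms %in% e$taxon))
    msgs <- c(msgs, "synonym canonical names must be registry taxa")
  if (length(msgs)) msgs else TRUE
})

#' Per-image VME annotation dataset
#'
#' A \linkS4class{SummarizedExperiment} holding one benthic survey image per
#' column and one annotated taxon per row. The single assay, \code{counts},
#' stores non-negative integer individual counts. Per-image metadata lives in
#' \code{colData}: laboratory, site, optional management-body region, depth
#' (m), imaged seafloor area (m^2), percent hard substrate, camera, the
#' optional expert Yes/Maybe/No label, and five boolean evidence flags used
#' by the decision flow chart (reef present, chemosynthetic taxa present,
#' large/old individual present, visible functional role, threatened taxon
#' present).
#'
#' @seealso [readAnnotations()], [writeAnnotations()],
#'   [validateAnnotations()], [computeDensities()]
#' @export
setClass("VmeImageSet", contains = "SummarizedExperiment")

setValidity("VmeImageSet", function(object) {
  msgs <- character()
  if (!"counts" %in% assayNames(object))
    return("assay 'counts' is required")
  cts <- assay(object, "counts")
  if (ncol(object)) {
    if (anyNA(cts) || any(cts < 0) || any(cts != floor(cts)))
      msgs <- c(msgs, "counts must be non-negative integers")
  }
  cd <- colData(object)
  need <- setdiff(.META_COLS, "image_id")
  miss <- setdiff(need, names(cd))
  if (length(miss))
    msgs <- c(msgs, paste("missing metadata columns:",
                          paste(miss, collapse = ", ")))
  if (is.null(colnames(object)) && ncol(object) > 0)
    msgs <- c(msgs, "image_id (column names) required")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "duplicate image_id")
  if (length(msgs)) return(msgs)
  if (ncol(object)) {
    a <- cd$area_m2
    if (anyNA(a) || any(a <= 0))
      msgs <- c(msgs, "area_m2 must be present and > 0 for every image")
    p <- cd$pct_hard_substrate
    if (any(!is.na(p) & (p < 0 | p > 100)))
      msgs <- c(msgs, "pct_hard_substrate must lie in [0, 100]")
    d <- cd$depth_m
    if (any(!is.na(d) & d < 0))
      msgs <- c(msgs, "depth_m must be non-negative")
    lab <- cd$label
    if (any(!is.na(lab) & !lab %in% .LABELS))
      msgs <- c(msgs, "label must be Yes, Maybe or No")
    for (f in .FLAG_COLS)
      if (!is.logical(cd[[f]]) || anyNA(cd[[f]]))
        msgs <- c(msgs, paste(f, "must be TRUE/FALSE"))
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-image density table
#'
#' A \linkS4class{SummarizedExperiment} produced by [computeDensities()]:
#' rows are canonical VME indicator taxa, columns are images, and the
#' \code{density} assay holds individuals per square metre (count / imaged
#' area). \code{colData} carries the image metadata plus three derived
#' per-image summaries: \code{overall_density} (summed indicator density,
#' individuals/m^2), \code{richness} (number of indicator taxa present), and
#' \code{richness_density} (taxa/m^2). \code{metadata()} records the area
#' filter provenance and any annotation columns excluded because they could
#' not be resolved to an indicator taxon.
#'
#' @seealso [computeDensities()], [groupDensity()], [filterByArea()]
#' @export
setClass("VmeDensitySet", contains = "SummarizedExperiment")

setValidity("VmeDensitySet", function(object) {
  if (!"density" %in% assayNames(object))
    return("assay 'density' is required")
  d <- assay(object, "density")
  if (length(d) && (anyNA(d) || any(d < 0)))
    return("densities must be non-negative")
  cd <- colData(object)
  need <- c("overall_density", "richness", "richness_density")
  if (!all(need %in% names(cd)))
    return("colData must carry overall_density, richness, richness_density")
  if (ncol(object)) {
    if (max(abs(colSums(d) - cd$overall_density)) > 1e-9)
      return("overall_density must equal the per-image density sum")
  }
  TRUE
})

#' Flow-chart density and richness thresholds
#'
#' Configuration for the last three steps of the single-image VME decision
#' flow chart: \code{tau_S}, the number of distinct indicator taxa that
#' qualifies an image on richness alone; \code{tau_d}, per-taxon density
#' thresholds (individuals/m^2) for monotypic stands; and \code{tau_D}, the
#' combined indicator density threshold (individuals/m^2). The packaged
#' defaults ([defaultThresholds()]) are midpoints of the calibration Yes/No
#' group means and are placeholders intended to be replaced by regional
#' calibration, not fixed standards.
#'
#' @slot tau_S positive integer, richness threshold (taxa).
#' @slot tau_d named positive numeric, per-taxon density thresholds; names
#'   must resolve in the registry used for classification.
#' @slot tau_D positive number, combined density threshold.
#' @slot richness_metric \code{"count"} (raw taxon count, the default) or
#'   \code{"per_area"} (taxa per m^2) for the richness step.
#'
#' @seealso [thresholdConfig()], [readThresholds()], [classifyImages()]
#' @export
setClass("ThresholdConfig",
  slots = c(tau_S = "numeric", tau_d = "numeric", tau_D = "numeric",
            richness_metric = "character"))

setValidity("ThresholdConfig", function(object) {
  msgs <- character()
  if (length(object@tau_S) != 1 || is.na(object@tau_S) ||
      object@tau_S <= 0 || object@tau_S != floor(object@tau_S))
    msgs <- c(msgs, "tau_S must be a positive integer")
  if (length(object@tau_D) != 1 || is.na(object@tau_D) || object@tau_D <= 0)
    msgs <- c(msgs, "tau_D must be a positive number")
  if (length(object@tau_d)) {
    if (is.null(names(object@tau_d)) || any(!nzchar(names(object@tau_d))))
      msgs <- c(msgs, "tau_d must be a named numeric vector")
    if (anyNA(object@tau_d) || any(object@tau_d <= 0))
      msgs <- c(msgs, "tau_d thresholds must be positive")
  }
  if (length(object@richness_metric) != 1 ||
      !object@richness_metric %in% c("count", "per_area"))
    msgs <- c(msgs, "richness_metric must be 'count' or 'per_area'")
  if (length(msgs)) msgs else TRUE
})
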